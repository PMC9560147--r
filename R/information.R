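#' Planning hypotheses
#'
#' Two accounts of information processing during the delay phase:
#' \describe{
#'   \item{H0_delayed}{delayed planning: the delay is used only for
#'     uncertainty reduction, from the memory prior p(m) to p(m|s1) and in
#'     action space from p(a) to the memory-conditioned marginal p(a|m);
#'     concrete planning waits for the go-signal.}
#'   \item{H1_prospective}{concurrent prospective planning: all go-signals
#'     compatible with the cue are anticipated during the delay and an
#'     action plan p(a|m,s2) is formed for each; the per-condition cost
#'     carries a multiplier N that grows with the number of anticipated
#'     plans (1, 4, 4, 16 for target conditions '1', '11', '2', '4').}
#' }
#' @export
hypotheses <- c("H0_delayed", "H1_prospective")

#' H1 plan-multiplicity factors per target condition (1^2, 2^2, 2^2, 4^2).
#' @param cT character vector of target conditions.
#' @return integer vector of multipliers.
#' @export
nts_multiplier <- function(cT) {
  m <- c(`1` = 1L, `11` = 4L, `2` = 4L, `4` = 16L)[as.character(cT)]
  if (anyNA(m)) stop("unknown target condition")
  unname(m)
}

## memory-conditioned action marginal p(a|m) and go-signal posterior p(s2|m)
action_given_memory <- function(policy, task) {
  W2 <- policy$p_m_given_s1 %*% task$joint_s1s2      # p(m, s2)
  ps2m <- sweep(W2, 1, pmax(policy$p_m, LOG_FLOOR), "/")
  pam <- matrix(0, task$n_a, task$n_m)
  for (k in seq_len(task$n_s2))
    pam <- pam + sweep(policy$p_a_given_ms2[, , k], 2, ps2m[, k], "*")
  list(p_a_given_m = pam, p_s2_given_m = ps2m, p_ms2 = W2)
}

## per-(m,s2) divergence KL(p(a|m,s2) || p(a)), nats
action_kl_ms2 <- function(policy, task) {
  lpa <- log(pmax(policy$p_a, LOG_FLOOR))
  KL2 <- matrix(0, task$n_m, task$n_s2)
  for (k in seq_len(task$n_s2)) {
    Pk <- policy$p_a_given_ms2[, , k]
    KL2[, k] <- colSums(Pk * (log(pmax(Pk, LOG_FLOOR)) - lpa))
  }
  KL2
}

#' Condition-wise information costs of a solved policy
#'
#' For each of the task's conditions computes, in bits:
#' \itemize{
#' \item I1(cT,cS): the expected memory-formation cost
#'   E_{s1|c} KL(p(m|s1) || p(m)) — identical under both hypotheses;
#' \item I2(cT,cS) under \code{H0_delayed}: the expected action uncertainty
#'   reduction E_{s1|c} E_{m|s1} KL(p(a|m) || p(a)), with p(a|m) the
#'   policy-consistent memory-conditioned action marginal;
#' \item I2(cT,cS) under \code{H1_prospective}: the N-multiplied expected
#'   planning cost N_c E_{s1|c} E_{m|s1} E_{s2|s1} KL(p(a|m,s2) || p(a)).
#' }
#' The expected values EI1, EI2 average the per-condition costs with the
#' uniform condition prior; EU is the expected utility. Averaging
#' identities tie the profiles to global mutual informations:
#' mean(I1) = I(M;S1), mean(I2_H0) = I(A;M), and
#' mean(I2_H1 / N) = I(A;M) + I(A;S2|M).
#'
#' @param policy an \code{agent_policy} solved on \code{task}.
#' @param task the \code{drt_task}.
#' @param hypothesis \code{"H0_delayed"} or \code{"H1_prospective"}.
#' @return an object of class \code{information_profile}: a data.frame with
#'   one row per condition (columns \code{cT}, \code{cS}, \code{I1_bits},
#'   \code{I2_bits}, \code{NTS}) and attributes \code{hypothesis},
#'   \code{beta1}, \code{beta2}, \code{EI1}, \code{EI2}, \code{EU}.
#' @examples
#' task <- build_task(mini_geometry())
#' pol <- solve_policy(task, 100, 100)
#' condition_information(pol, task, "H1_prospective")
#' @export
condition_information <- function(policy, task,
                                  hypothesis = c("H0_delayed",
                                                 "H1_prospective")) {
  stopifnot(inherits(policy, "agent_policy"), inherits(task, "drt_task"))
  check_policy_task(policy, task)
  hypothesis <- match.arg(hypothesis)
  ln2 <- log(2)
  cond <- factor(task$s1_condition, levels = seq_len(task$n_conditions))

  P1 <- policy$p_m_given_s1
  lP1 <- log(pmax(P1, LOG_FLOOR))
  lpm <- log(pmax(policy$p_m, LOG_FLOOR))
  I1_s1 <- colSums(P1 * (lP1 - lpm))                  # KL(p(m|s1)||p(m))
  I1_c <- as.vector(tapply(I1_s1, cond, mean)) / ln2

  if (hypothesis == "H0_delayed") {
    am <- action_given_memory(policy, task)
    pam <- am$p_a_given_m
    KLm <- colSums(pam * (log(pmax(pam, LOG_FLOOR)) -
                          log(pmax(policy$p_a, LOG_FLOOR))))
    KLm[policy$p_m <= 0] <- 0
    I2_s1 <- as.vector(crossprod(P1, KLm))
    I2_c <- as.vector(tapply(I2_s1, cond, mean)) / ln2
    nts <- rep(1L, task$n_conditions)
  } else {
    KL2 <- action_kl_ms2(policy, task)
    I2_s1 <- colSums(P1 * tcrossprod(KL2, task$p_s2_given_s1))
    base_c <- as.vector(tapply(I2_s1, cond, mean)) / ln2
    nts <- nts_multiplier(task$conditions$cT)
    I2_c <- nts * base_c
  }

  prof <- data.frame(task$conditions,
                     I1_bits = pmax(I1_c, 0),
                     I2_bits = pmax(I2_c, 0),
                     NTS = nts)
  structure(prof,
            hypothesis = hypothesis,
            beta1 = policy$beta1, beta2 = policy$beta2,
            EI1 = mean(prof$I1_bits), EI2 = mean(prof$I2_bits),
            EU = expected_utility(policy, task),
            converged = policy$converged,
            class = c("information_profile", "data.frame"))
}

#' @export
print.information_profile <- function(x, ...) {
  cat(sprintf("Information profile under %s (beta1 = %g, beta2 = %g)\n",
              attr(x, "hypothesis"), attr(x, "beta1"), attr(x, "beta2")))
  print.data.frame(x, row.names = FALSE, digits = 4)
  cat(sprintf("E[I1] = %.4f bits, E[I2] = %.4f bits, E[U] = %.4f\n",
              attr(x, "EI1"), attr(x, "EI2"), attr(x, "EU")))
  invisible(x)
}

#' Expected utility of a policy
#'
#' E[U] = sum over the policy-induced joint of U(w,a); with the 0/1 utility
#' this is the expected hit rate, so E[U] = 1 - expected error rate.
#'
#' @param policy an \code{agent_policy}.
#' @param task the task it was solved on.
#' @return scalar in [0, 1].
#' @export
expected_utility <- function(policy, task) {
  stopifnot(inherits(policy, "agent_policy"), inherits(task, "drt_task"))
  check_policy_task(policy, task)
  expected_utility_tables(task, policy$p_m_given_s1, policy$p_a_given_ms2)
}

#' Global mutual informations of a policy (bits)
#'
#' Computed directly from the policy-induced joint, independently of the
#' per-condition accounting: I(M;S1), I(A;M) and I(A;M) + I(A;S2|M).
#'
#' @inheritParams expected_utility
#' @return named numeric vector \code{c(I_M_S1, I_A_M, I_A_MS2)} in bits.
#' @export
mutual_informations <- function(policy, task) {
  stopifnot(inherits(policy, "agent_policy"), inherits(task, "drt_task"))
  check_policy_task(policy, task)
  ln2 <- log(2)
  P1 <- policy$p_m_given_s1
  I_ms1 <- sum(task$p_s1 * colSums(P1 * (log(pmax(P1, LOG_FLOOR)) -
                                         log(pmax(policy$p_m, LOG_FLOOR)))))
  am <- action_given_memory(policy, task)
  pam <- am$p_a_given_m
  KLm <- colSums(pam * (log(pmax(pam, LOG_FLOOR)) -
                        log(pmax(policy$p_a, LOG_FLOOR))))
  KLm[policy$p_m <= 0] <- 0
  I_am <- sum(policy$p_m * KLm)
  KL2 <- action_kl_ms2(policy, task)
  I_ams2 <- sum(am$p_ms2 * KL2)
  c(I_M_S1 = I_ms1, I_A_M = I_am, I_A_MS2 = I_ams2) / ln2
}

#' Solve a grid of capacities and collect information profiles
#'
#' Runs the fixed-point solver once per (beta1, beta2) grid point and derives
#' both hypotheses' information profiles from the same solved policy.
#' Profiles of non-converged solves are flagged (attribute
#' \code{converged}) and excluded from fitting by default downstream.
#'
#' @param task a \code{drt_task}.
#' @param beta1_values,beta2_values capacity grids (crossed).
#' @param opts \code{\link{solver_options}} used for every solve.
#' @param cache_dir optional directory; solved profiles are cached there
#'   keyed by a content hash of (task geometry, capacities, options) and
#'   reused on identical reruns.
#' @param verbose print progress.
#' @return an object of class \code{capacity_grid}: list with
#'   \code{profiles} (named list, keys \code{"<hyp>|<beta1>|<beta2>"}),
#'   \code{beta1_values}, \code{beta2_values}, and a tidy data.frame
#'   \code{summary} (one row per hypothesis x grid point x condition).
#' @export
capacity_grid <- function(task, beta1_values, beta2_values,
                          opts = solver_options(), cache_dir = NULL,
                          verbose = FALSE) {
  stopifnot(inherits(task, "drt_task"),
            length(beta1_values) > 0, length(beta2_values) > 0)
  profiles <- list()
  for (b1 in beta1_values) for (b2 in beta2_values) {
    key_base <- grid_cache_key(task, b1, b2, opts)
    pol <- NULL
    cache_file <- if (!is.null(cache_dir))
      file.path(cache_dir, paste0(key_base, ".rds"))
    if (!is.null(cache_file) && file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      for (h in hypotheses)
        profiles[[grid_key(h, b1, b2)]] <- cached[[h]]
      next
    }
    if (verbose) message(sprintf("solving beta1 = %g, beta2 = %g", b1, b2))
    pol <- suppressWarnings(solve_policy(task, b1, b2, opts))
    pair <- list()
    for (h in hypotheses) {
      prof <- condition_information(pol, task, h)
      profiles[[grid_key(h, b1, b2)]] <- prof
      pair[[h]] <- prof
    }
    if (!is.null(cache_file)) {
      dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
      saveRDS(pair, cache_file)
    }
  }
  summary <- do.call(rbind, lapply(names(profiles), function(k) {
    p <- profiles[[k]]
    data.frame(hypothesis = attr(p, "hypothesis"),
               beta1 = attr(p, "beta1"), beta2 = attr(p, "beta2"),
               cT = p$cT, cS = p$cS,
               I1_bits = p$I1_bits, I2_bits = p$I2_bits, NTS = p$NTS,
               EU = attr(p, "EU"), converged = attr(p, "converged"))
  }))
  structure(list(profiles = profiles,
                 beta1_values = beta1_values, beta2_values = beta2_values,
                 summary = summary),
            class = "capacity_grid")
}

grid_key <- function(hypothesis, beta1, beta2)
  sprintf("%s|%.10g|%.10g", hypothesis, beta1, beta2)

grid_cache_key <- function(task, b1, b2, opts) {
  payload <- list(geometry = task$geometry, beta1 = b1, beta2 = b2,
                  opts = unclass(opts))
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(payload, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Look up one profile on a capacity grid
#'
#' @param grid a \code{capacity_grid}.
#' @param hypothesis hypothesis name.
#' @param beta1,beta2 capacities; must be on the grid.
#' @return an \code{information_profile}.
#' @export
grid_profile <- function(grid, hypothesis, beta1, beta2) {
  stopifnot(inherits(grid, "capacity_grid"))
  p <- grid$profiles[[grid_key(hypothesis, beta1, beta2)]]
  if (is.null(p)) {
    pts <- unique(grid$summary[, c("beta1", "beta2")])
    d <- sqrt((log(pts$beta1 + 1e-12) - log(beta1 + 1e-12))^2 +
              (log(pts$beta2 + 1e-12) - log(beta2 + 1e-12))^2)
    near <- pts[order(d)[seq_len(min(3, nrow(pts)))], ]
    stop(sprintf(
      "no profile at (%g, %g); nearest grid points: %s",
      beta1, beta2,
      paste(sprintf("(%g, %g)", near$beta1, near$beta2), collapse = ", ")))
  }
  p
}

#' @export
print.capacity_grid <- function(x, ...) {
  cat(sprintf("Capacity grid: %d x %d points, %d profiles\n",
              length(x$beta1_values), length(x$beta2_values),
              length(x$profiles)))
  eu <- unique(x$summary[, c("beta1", "beta2", "EU")])
  print(utils::head(eu, 10), row.names = FALSE, digits = 4)
  invisible(x)
}
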