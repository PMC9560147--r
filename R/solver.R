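#' Solver options for the bounded-rational fixed point
#'
#' @param max_iter maximum number of sweeps (default 10000).
#' @param tol convergence threshold on the maximum absolute change of any
#'   distribution entry per sweep (default 1e-10).
#' @param init initialization of the memory channel: \code{"identity"}
#'   (default; p(m|s1) concentrated on m = s1, the canonical
#'   symmetry-breaking choice since the memory alphabet is identified
#'   index-for-index with S1), \code{"uniform"}, or \code{"random"}.
#'   The uniform point is itself a fixed point of the update equations (the
#'   free-energy gain is then constant in m), so \code{"uniform"} is only
#'   useful to demonstrate that degeneracy.
#' @param eps mass spread off the diagonal for \code{"identity"} init
#'   (default 0.01; the information summaries of the converged point vary
#'   only weakly with it).
#' @param seed integer seed, used only for \code{"random"} init.
#' @param damping in [0,1): fraction of the previous memory channel retained
#'   per sweep (default 0, no damping).
#' @param trace if TRUE, record the variational objective after every sweep.
#' @return a list of class \code{solver_options}.
#' @export
solver_options <- function(max_iter = 10000L, tol = 1e-10,
                           init = c("identity", "uniform", "random"),
                           eps = 0.01, seed = 1L, damping = 0,
                           trace = FALSE) {
  init <- match.arg(init)
  stopifnot(tol > 0, max_iter >= 1, damping >= 0, damping < 1)
  structure(list(max_iter = as.integer(max_iter), tol = tol, init = init,
                 eps = eps, seed = as.integer(seed), damping = damping,
                 trace = isTRUE(trace)),
            class = "solver_options")
}

## column-wise softmax in log space with max subtraction
softmax_cols <- function(L) {
  mx <- L[cbind(max.col(t(L), ties.method = "first"), seq_len(ncol(L)))]
  E <- exp(sweep(L, 2, mx))
  sweep(E, 2, colSums(E), "/")
}

LOG_FLOOR <- 1e-300

#' Solve the two-channel utility-information trade-off
#'
#' Iterates the self-consistent fixed-point equations of the constrained
#' optimization
#' \deqn{\max E[U] - \beta_1^{-1} I(M;S_1) - \beta_2^{-1}(I(A;M) + I(A;S_2|M))}
#' over the memory channel p(m|s1) and the action channel p(a|m,s2):
#' p(m|s1) is proportional to p(m) exp(beta1 * dF(m,s1)) with dF the expected
#' free-energy gain of memory state m for cue s1; p(a|m,s2) is proportional
#' to p(a) exp(beta2 * sum_w p(w|m,s2) U(w,a)); the priors p(m), p(a) are the
#' policy-induced marginals, and p(w|m,s2) is obtained from the joint by
#' marginalizing over s1. One sweep updates, in order: p(w|m,s2) from the
#' current memory channel, then p(a|m,s2), p(a), dF, p(m|s1), p(m). All
#' exponentials use natural logarithms; information is converted to bits only
#' at reporting boundaries.
#'
#' Zero capacities are prior-forcing: at beta1 = 0 the memory channel is
#' pinned to the uniform prior (no optimization over that channel, zero
#' information), likewise the action channel at beta2 = 0.
#'
#' @param task a \code{\link{build_task}} result.
#' @param beta1 memory inverse temperature (capacity), >= 0.
#' @param beta2 action inverse temperature (capacity), >= 0.
#' @param opts a \code{\link{solver_options}} list.
#' @param warm optional \code{agent_policy} to warm-start from (used by
#'   \code{\link{solve_policy_annealed}}).
#' @return an object of class \code{agent_policy} with the solved channel
#'   tables (\code{p_m_given_s1}, \code{p_m}, \code{p_a_given_ms2},
#'   \code{p_a}, \code{p_w_given_ms2}), convergence record and the
#'   variational objective value at the solution.
#' @examples
#' task <- build_task(mini_geometry())
#' pol <- solve_policy(task, 50, 50)
#' pol$converged
#' @export
solve_policy <- function(task, beta1, beta2, opts = solver_options(),
                         warm = NULL) {
  stopifnot(inherits(task, "drt_task"))
  if (!is.numeric(beta1) || !is.numeric(beta2) || beta1 < 0 || beta2 < 0)
    stop("beta1 and beta2 must be nonnegative")
  M <- task$n_m; nA <- task$n_a; nS2 <- task$n_s2
  ps1 <- task$p_s1
  joint <- task$joint_s1s2               # p(s1, s2)
  ps2g <- task$p_s2_given_s1
  frames <- task$frame_targets           # targets inside each half-frame
  s1k <- task$s1_of_frame                # stimuli compatible with each frame
  agg <- task$agg_w

  ## -- init -------------------------------------------------------------
  if (!is.null(warm)) {
    P1 <- warm$p_m_given_s1; pm <- warm$p_m
    PA <- warm$p_a_given_ms2; pa <- warm$p_a
  } else {
    P1 <- switch(opts$init,
      identity = {
        X <- matrix(opts$eps / (M - 1), M, M); diag(X) <- 1 - opts$eps; X
      },
      uniform = matrix(1 / M, M, M),
      random = {
        old <- if (exists(".Random.seed", globalenv()))
          get(".Random.seed", globalenv())
        on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
                add = TRUE)
        set.seed(opts$seed)
        X <- matrix(stats::rexp(M * M), M, M)
        sweep(X, 2, colSums(X), "/")
      })
    pm <- as.vector(P1 %*% ps1)
    PA <- array(1 / nA, c(nA, M, nS2))
    pa <- rep(1 / nA, nA)
  }
  if (beta1 == 0) { P1 <- matrix(1 / M, M, M); pm <- rep(1 / M, M) }
  if (beta2 == 0) { PA <- array(1 / nA, c(nA, M, nS2)); pa <- rep(1 / nA, nA) }

  lPA <- log(pmax(PA, LOG_FLOOR))
  KL2 <- matrix(0, M, nS2)
  trace <- if (opts$trace) numeric(0) else NULL
  delta <- Inf; it <- 0L

  for (it in seq_len(opts$max_iter)) {
    delta <- 0

    ## p(w|m,s2) from the joint; frame-wise normalization. Zero-mass (m,s2)
    ## pairs fall back to the task prior p(w|s2).
    J <- P1 %*% agg                      # [m, w] joint p(m, s2=frame(w), w)
    Qk <- vector("list", nS2)
    for (k in seq_len(nS2)) {
      ws <- frames[[k]]
      sub <- t(J[, ws, drop = FALSE])    # |ws| x M
      z <- colSums(sub)
      pri <- colSums(agg[, ws, drop = FALSE]); pri <- pri / sum(pri)
      bad <- z <= 0
      sub <- sweep(sub, 2, ifelse(bad, 1, z), "/")
      if (any(bad)) sub[, bad] <- pri
      Qk[[k]] <- sub
    }

    ## action channel
    lpa <- log(pmax(pa, LOG_FLOOR))
    if (beta2 > 0) {
      for (k in seq_len(nS2)) {
        ws <- frames[[k]]
        L <- matrix(lpa, nA, M)
        arows <- c(rbind(2L * ws - 1L, 2L * ws))
        L[arows, ] <- L[arows, ] +
          beta2 * Qk[[k]][rep(seq_along(ws), each = 2L), , drop = FALSE]
        newPA <- softmax_cols(L)
        delta <- max(delta, max(abs(newPA - PA[, , k])))
        PA[, , k] <- newPA
        lPA[, , k] <- log(pmax(newPA, LOG_FLOOR))
      }
      W2 <- P1 %*% joint                 # p(m, s2)
      pa_new <- rep(0, nA)
      for (k in seq_len(nS2)) pa_new <- pa_new + as.vector(PA[, , k] %*% W2[, k])
      pa_new <- pa_new / sum(pa_new)
      delta <- max(delta, max(abs(pa_new - pa)))
      pa <- pa_new
      lpa <- log(pmax(pa, LOG_FLOOR))
    }

    ## free-energy gain dF(m, s1) and memory channel
    for (k in seq_len(nS2))
      KL2[, k] <- colSums(PA[, , k] * (lPA[, , k] - lpa))
    if (beta1 > 0) {
      DF <- matrix(0, M, M)              # [m, s1]
      inv_b2 <- if (beta2 > 0) 1 / beta2 else 0
      for (k in seq_len(nS2)) {
        ii <- s1k[[k]]
        pv <- ps2g[ii, k]
        ws <- frames[[k]]
        hit <- matrix(PA[2L * ws - 1L, , k], length(ws)) +
               matrix(PA[2L * ws, , k], length(ws))    # |ws| x M hit mass
        wpos <- match(task$w_of[ii, k], ws)
        DF[, ii] <- DF[, ii] +
          sweep(t(hit[wpos, , drop = FALSE]), 2, pv, "*") -
          inv_b2 * outer(KL2[, k], pv)
      }
      P1new <- softmax_cols(log(pmax(pm, LOG_FLOOR)) + beta1 * DF)
      if (opts$damping > 0)
        P1new <- opts$damping * P1 + (1 - opts$damping) * P1new
      delta <- max(delta, max(abs(P1new - P1)))
      P1 <- P1new
      pm_new <- as.vector(P1 %*% ps1)
      delta <- max(delta, max(abs(pm_new - pm)))
      pm <- pm_new
    }

    if (opts$trace)
      trace <- c(trace, policy_objective_internal(task, beta1, beta2,
                                                  P1, pm, PA, pa, KL2))
    if (delta < opts$tol) break
  }

  converged <- delta < opts$tol
  if (!converged)
    warning(sprintf(
      "fixed-point iteration did not converge in %d sweeps (residual %.3g)",
      opts$max_iter, delta))

  ## final p(w|m,s2) consistent with the returned memory channel
  J <- P1 %*% agg
  PW <- matrix(0, task$n_w, M)
  for (k in seq_len(nS2)) {
    ws <- frames[[k]]
    sub <- t(J[, ws, drop = FALSE])
    z <- colSums(sub)
    pri <- colSums(agg[, ws, drop = FALSE]); pri <- pri / sum(pri)
    bad <- z <= 0
    sub <- sweep(sub, 2, ifelse(bad, 1, z), "/")
    if (any(bad)) sub[, bad] <- pri
    PW[ws, ] <- sub
  }

  pol <- structure(list(
    beta1 = beta1, beta2 = beta2,
    p_m_given_s1 = P1, p_m = pm,
    p_a_given_ms2 = PA, p_a = pa,
    p_w_given_ms2 = PW,
    converged = converged, n_iter = it, residual = delta,
    opts = opts, trace = trace,
    task_dims = c(n_s1 = task$n_s1, n_a = task$n_a, n_s2 = task$n_s2)),
    class = "agent_policy")
  pol$objective_value <- variational_objective(pol, task)
  pol
}

#' Warm-started deterministic annealing of the memory capacity
#'
#' Solves a chain of problems with increasing beta1 (at the target beta2),
#' warm-starting each from the previous solution, then polishes at the target
#' capacities. At large capacities this reliably reaches fixed points with a
#' lower (more compressed) memory rate and a higher variational objective
#' than direct iteration.
#'
#' @inheritParams solve_policy
#' @param schedule increasing beta1 values visited before the target
#'   (values above \code{beta1} are dropped).
#' @export
solve_policy_annealed <- function(task, beta1, beta2,
                                  schedule = c(5, 10, 20, 50, 100, 200),
                                  opts = solver_options()) {
  sched <- schedule[schedule < beta1]
  pol <- NULL
  stage_opts <- opts
  stage_opts$max_iter <- min(opts$max_iter, 300L)
  stage_opts$tol <- max(opts$tol, 1e-8)
  for (b1 in sched)
    pol <- suppressWarnings(solve_policy(task, b1, beta2, stage_opts,
                                         warm = pol))
  solve_policy(task, beta1, beta2, opts, warm = pol)
}

## objective from raw tables (nats); KL2 is the per-(m,s2) action KL
policy_objective_internal <- function(task, beta1, beta2, P1, pm, PA, pa, KL2) {
  W2 <- P1 %*% task$joint_s1s2
  eu <- expected_utility_tables(task, P1, PA)
  lP1 <- log(pmax(P1, LOG_FLOOR)); lpm <- log(pmax(pm, LOG_FLOOR))
  I1 <- sum(task$p_s1 * colSums(P1 * (lP1 - lpm)))
  IA <- sum(W2 * KL2)
  pen1 <- if (beta1 > 0) I1 / beta1 else 0
  pen2 <- if (beta2 > 0) IA / beta2 else 0
  eu - pen1 - pen2
}

expected_utility_tables <- function(task, P1, PA) {
  eu <- 0
  for (k in seq_len(task$n_s2)) {
    ii <- task$s1_of_frame[[k]]
    ws <- task$frame_targets[[k]]
    hit <- matrix(PA[2L * ws - 1L, , k], length(ws)) +
           matrix(PA[2L * ws, , k], length(ws))
    wpos <- match(task$w_of[ii, k], ws)
    contrib <- rowSums(hit[wpos, , drop = FALSE] *
                       t(P1[, ii, drop = FALSE]))
    eu <- eu + sum(task$joint_s1s2[ii, k] * contrib)
  }
  eu
}

#' Variational objective of a policy
#'
#' Evaluates the constrained-optimization objective
#' E[U] - (1/beta1) I(M;S1) - (1/beta2) (I(A;M) + I(A;S2|M)) at the policy's
#' capacities, with the mutual informations computed from the policy-induced
#' joint in natural logarithms (the solver's internal log base). A zero
#' capacity contributes no penalty: that channel is prior-forced and carries
#' zero information.
#'
#' @param policy an \code{agent_policy}.
#' @param task the task it was solved on.
#' @return the objective value (scalar).
#' @export
variational_objective <- function(policy, task) {
  stopifnot(inherits(policy, "agent_policy"), inherits(task, "drt_task"))
  check_policy_task(policy, task)
  lpa <- log(pmax(policy$p_a, LOG_FLOOR))
  KL2 <- matrix(0, task$n_m, task$n_s2)
  for (k in seq_len(task$n_s2)) {
    Pk <- policy$p_a_given_ms2[, , k]
    KL2[, k] <- colSums(Pk * (log(pmax(Pk, LOG_FLOOR)) - lpa))
  }
  policy_objective_internal(task, policy$beta1, policy$beta2,
                            policy$p_m_given_s1, policy$p_m,
                            policy$p_a_given_ms2, policy$p_a, KL2)
}

#' Free-energy gain of a memory state for a cue stimulus
#'
#' The quantity entering the memory-channel update: the expected utility of
#' acting from memory state m when the cue was s1, minus (1/beta2) times the
#' expected action-channel divergence,
#' \deqn{\Delta F(m,s_1)=\sum_{a,s_2,w} p(a|m,s_2)p(s_2|s_1)p(w|s_1,s_2)U(w,a)
#'  - \beta_2^{-1}\sum_{a,s_2} p(a|m,s_2)p(s_2|s_1)\log\frac{p(a|m,s_2)}{p(a)}.}
#'
#' @param policy an \code{agent_policy}.
#' @param task the task it was solved on.
#' @param m memory state index.
#' @param s1 cue stimulus index.
#' @return scalar free-energy gain (natural-log units).
#' @export
delta_free_energy <- function(policy, task, m, s1) {
  stopifnot(inherits(policy, "agent_policy"), inherits(task, "drt_task"))
  check_policy_task(policy, task)
  if (!(m >= 1 && m <= task$n_m)) stop("invalid m index")
  if (!(s1 >= 1 && s1 <= task$n_s1)) stop("invalid s1 index")
  lpa <- log(pmax(policy$p_a, LOG_FLOOR))
  supp <- which(task$p_s2_given_s1[s1, ] > 0)
  val <- 0
  for (k in supp) {
    pk <- task$p_s2_given_s1[s1, k]
    w <- task$w_of[s1, k]
    pa_ms2 <- policy$p_a_given_ms2[, m, k]
    hit <- sum(pa_ms2[task$actions$w == w])
    kl <- sum(pa_ms2 * (log(pmax(pa_ms2, LOG_FLOOR)) - lpa))
    pen <- if (policy$beta2 > 0) kl / policy$beta2 else 0
    val <- val + pk * (hit - pen)
  }
  val
}

check_policy_task <- function(policy, task) {
  d <- policy$task_dims
  if (d["n_s1"] != task$n_s1 || d["n_a"] != task$n_a || d["n_s2"] != task$n_s2)
    stop("policy dimensions do not match task (policy solved on a different task?)")
  invisible(TRUE)
}

#' @export
print.agent_policy <- function(x, ...) {
  cat(sprintf("Bounded-rational policy (beta1 = %g, beta2 = %g)\n",
              x$beta1, x$beta2))
  cat(sprintf("  %s after %d sweeps (residual %.2e)\n",
              if (x$converged) "converged" else "NOT converged",
              x$n_iter, x$residual))
  cat(sprintf("  variational objective: %.6f\n", x$objective_value))
  invisible(x)
}
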