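#' Panel geometry for the delayed-response task
#'
#' The task screen is divided into `n_panels` response panels, each split into
#' two halves (\code{"A"} and \code{"B"}). A half-frame (panel x half) is the
#' go-signal unit. Each half holds a fixed multiset of reachable target
#' offsets; a target's distance is the L1 norm of its offset, equal to the
#' number of button presses of the movement sequence that reaches it.
#'
#' Only the set relations implied by this geometry (how many targets per half
#' per distance, which targets share a half or a panel) enter the model's
#' probabilities; the literal on-screen pixel layout does not.
#'
#' @param n_panels number of response panels (default 4).
#' @param offsets data.frame with columns \code{dist}, \code{ox}, \code{oy}
#'   giving the target offsets of one half; the same template is used for
#'   every half of every panel. Both coordinates must be nonzero so the two
#'   extremal monotone button-press paths to each target are distinct.
#' @return an object of class \code{panel_geometry}.
#' @examples
#' g <- default_geometry()
#' g$n_panels
#' @export
panel_geometry <- function(n_panels = 4,
                           offsets = data.frame(
                             dist = c(2, 3, 3, 4, 4),
                             ox   = c(1, 1, 2, 1, 3),
                             oy   = c(1, 2, 1, 3, 1))) {
  stopifnot(is.numeric(n_panels), n_panels >= 1)
  offsets <- as.data.frame(offsets)
  if (!all(c("dist", "ox", "oy") %in% names(offsets)))
    stop("`offsets` needs columns dist, ox, oy")
  if (any(abs(offsets$ox) + abs(offsets$oy) != offsets$dist))
    stop("offset distance must equal |ox| + |oy|")
  if (any(offsets$ox == 0 | offsets$oy == 0))
    stop("off-axis offsets required: both coordinates must be nonzero, ",
         "otherwise the two extremal monotone paths coincide")
  structure(list(n_panels = as.integer(n_panels),
                 offsets = offsets[order(offsets$dist, offsets$ox), ]),
            class = "panel_geometry")
}

#' @rdname panel_geometry
#' @details `default_geometry()` reproduces the study's printed cardinalities:
#'   per panel one distance-2 target, two distance-3 and two distance-4
#'   targets per half, four panels, giving 40 targets, 80 movement sequences,
#'   8 half-frames and 820 cue stimuli.
#' @export
default_geometry <- function() panel_geometry()

#' @rdname panel_geometry
#' @details `mini_geometry()` is a 2-panel task with only the distance-2
#'   targets (4 targets, 8 actions, 4 half-frames, 10 cue stimuli across the
#'   three constructible target conditions). Small enough for exhaustive
#'   brute-force checks.
#' @export
mini_geometry <- function()
  panel_geometry(n_panels = 2,
                 offsets = data.frame(dist = 2, ox = 1, oy = 1))

#' @rdname panel_geometry
#' @details `reduced_geometry()` keeps the full per-half target multiset
#'   (one distance-2, two distance-3, two distance-4 targets) but only two
#'   panels, so target conditions '1', '11' and '2' exist at all three
#'   sequence lengths (20 targets, 40 actions, 4 half-frames, 74 cue
#'   stimuli, 9 conditions). Unlike the mini task it has several targets
#'   per half, so memory formation is genuinely required. Used for fast
#'   capacity-grid sweeps and simulation studies.
#' @export
reduced_geometry <- function() panel_geometry(n_panels = 2)

#' @export
print.panel_geometry <- function(x, ...) {
  cat("Panel geometry:", x$n_panels, "panels x 2 halves,",
      nrow(x$offsets), "targets per half\n")
  cat("  distances per half:",
      paste(sprintf("%d:%d", as.integer(names(table(x$offsets$dist))),
                    as.integer(table(x$offsets$dist))), collapse = ", "), "\n")
  invisible(x)
}

target_conditions <- c("1", "11", "2", "4")

## Expected cue-set size from the combinatorics of the geometry:
## '1'  - any single cued target of distance cS;
## '11' - two targets in the two halves of one panel, same distance;
## '2'  - one target in each of two distinct panels, same distance;
## '4'  - one target in each of the four panels, same distance.
expected_cue_count <- function(cT, k_s, n_panels) {
  switch(cT,
         "1"  = 2L * n_panels * k_s,
         "11" = n_panels * k_s^2,
         "2"  = choose(n_panels, 2) * (2L * k_s)^2,
         "4"  = (2L * k_s)^n_panels,
         stop("unknown target condition: ", cT))
}

#' Build the delayed-response-task generative structure
#'
#' Enumerates the hidden world states W (target identities), movement
#' sequences A (two extremal monotone button-press paths per target),
#' go-signals S2 (half-frames), cue stimuli S1 (all condition-consistent
#' combinations of potential targets), and all task-defined probability
#' tables: the uniform within-condition cue distribution p(s1|cT,cS), its
#' marginal p(s1) under the uniform condition prior, the uniform go-signal
#' distribution p(s2|s1) over the cued targets' half-frames, the
#' deterministic target resolution w(s1,s2), and the 0/1 utility matrix
#' U(w,a) with exactly the two sequences reaching each target scoring 1.
#'
#' Enumeration order is deterministic (condition, then panel, then half,
#' then offset), so indices are stable across rebuilds.
#'
#' @param geometry a \code{\link{panel_geometry}}.
#' @return an object of class \code{drt_task}.
#' @examples
#' task <- build_task(mini_geometry())
#' task$n_s1          # 10 cue stimuli
#' cue_set(task, "2", 2)
#' @export
build_task <- function(geometry = default_geometry()) {
  stopifnot(inherits(geometry, "panel_geometry"))
  P <- geometry$n_panels
  off <- geometry$offsets
  dists <- sort(unique(off$dist))

  ## -- targets (world states W), ordered panel > half > offset --------------
  targets <- do.call(rbind, lapply(seq_len(P), function(p) {
    do.call(rbind, lapply(c("A", "B"), function(h) {
      data.frame(panel = p, half = h, dist = off$dist,
                 ox = off$ox, oy = off$oy)
    }))
  }))
  targets$w <- seq_len(nrow(targets))
  targets$frame <- (targets$panel - 1L) * 2L + (targets$half == "B") + 1L
  n_w <- nrow(targets)
  n_s2 <- 2L * P

  ## -- actions: two extremal monotone paths per target ----------------------
  actions <- data.frame(a = seq_len(2L * n_w),
                        w = rep(targets$w, each = 2L),
                        path = rep(c("hv", "vh"), n_w))
  n_a <- nrow(actions)

  ## -- conditions ------------------------------------------------------------
  cTs <- target_conditions
  if (P < 4) cTs <- setdiff(cTs, "4")
  if (P < 2) cTs <- setdiff(cTs, "2")
  conds <- expand.grid(cS = dists, cT = cTs, stringsAsFactors = FALSE)
  conds <- conds[order(match(conds$cT, target_conditions), conds$cS),
                 c("cT", "cS")]
  rownames(conds) <- NULL
  n_c <- nrow(conds)

  ## -- cue stimuli S1: condition-wise exhaustive enumeration -----------------
  s1_targets <- vector("list", 0L)
  s1_cond <- integer(0)
  for (ci in seq_len(n_c)) {
    cT <- conds$cT[ci]; cS <- conds$cS[ci]
    at_d <- function(p, h = NULL) {
      sel <- targets$dist == cS & targets$panel == p
      if (!is.null(h)) sel <- sel & targets$half == h
      targets$w[sel]
    }
    sets <- switch(cT,
      "1" = as.list(targets$w[targets$dist == cS]),
      "11" = {
        out <- list()
        for (p in seq_len(P))
          for (wa in at_d(p, "A")) for (wb in at_d(p, "B"))
            out[[length(out) + 1L]] <- c(wa, wb)
        out
      },
      "2" = {
        out <- list()
        for (p in seq_len(P - 1L)) for (q in seq(p + 1L, P))
          for (wp in at_d(p)) for (wq in at_d(q))
            out[[length(out) + 1L]] <- c(wp, wq)
        out
      },
      "4" = {
        per <- lapply(seq_len(P), at_d)
        grid <- do.call(expand.grid, rev(per))
        lapply(seq_len(nrow(grid)), function(r) rev(unlist(grid[r, ])))
      })
    n_expected <- expected_cue_count(cT, sum(off$dist == cS), P)
    if (length(sets) != n_expected)
      stop(sprintf(
        "cue-set enumeration for condition ('%s', %d) produced %d stimuli, expected %d",
        cT, cS, length(sets), n_expected))
    s1_targets <- c(s1_targets, sets)
    s1_cond <- c(s1_cond, rep(ci, length(sets)))
  }
  n_s1 <- length(s1_targets)
  N_c <- tabulate(s1_cond, n_c)

  ## default-geometry contract with the printed cue-set table
  if (P == 4 && identical(dists, c(2, 3, 4)) &&
      identical(as.integer(table(off$dist)), c(1L, 2L, 2L))) {
    printed <- c(8L, 16L, 16L, 4L, 16L, 16L, 24L, 96L, 96L, 16L, 256L, 256L)
    bad <- which(N_c != printed)
    if (length(bad))
      stop(sprintf(
        "cardinality violation: condition ('%s', %d) has %d stimuli, printed table says %d",
        conds$cT[bad[1]], conds$cS[bad[1]], N_c[bad[1]], printed[bad[1]]))
  }

  ## -- probability tables ----------------------------------------------------
  p_s1 <- 1 / (n_c * N_c[s1_cond])          # p(c)=1/n_c, uniform within cue set
  supp <- lapply(s1_targets, function(ws) sort(targets$frame[ws]))
  ## '11' sanity: the two cued targets must sit in different halves of one
  ## panel, otherwise the go-signal could not disambiguate them
  for (i in seq_len(n_s1))
    if (anyDuplicated(supp[[i]]))
      stop("ambiguous cue stimulus: two cued targets share a half-frame")

  w_of <- matrix(0L, n_s1, n_s2)            # w(s1,s2); 0 where p(s2|s1)=0
  p_s2_given_s1 <- matrix(0, n_s1, n_s2)
  for (i in seq_len(n_s1)) {
    ws <- s1_targets[[i]]
    fr <- targets$frame[ws]
    w_of[i, fr] <- ws
    p_s2_given_s1[i, fr] <- 1 / length(fr)
  }

  task <- structure(list(
    geometry = geometry,
    targets = targets, actions = actions, conditions = conds,
    s1_targets = s1_targets, s1_condition = s1_cond,
    cue_counts = N_c,
    p_s1 = p_s1, p_s2_given_s1 = p_s2_given_s1, w_of = w_of,
    n_w = n_w, n_a = n_a, n_s2 = n_s2, n_s1 = n_s1, n_m = n_s1,
    n_conditions = n_c), class = "drt_task")

  ## -- solver-side precomputations ------------------------------------------
  task$joint_s1s2 <- p_s2_given_s1 * p_s1   # p(s1, s2)
  task$frame_targets <- lapply(seq_len(n_s2),
                               function(k) targets$w[targets$frame == k])
  task$s1_of_frame <- lapply(seq_len(n_s2), function(k) which(w_of[, k] > 0L))
  ## agg_w[s1, w] = p(s1) p(s2=frame(w)|s1) for cued w; aggregates the joint
  ## p(m, s2, w) from p(m|s1) in one matrix product
  agg <- matrix(0, n_s1, n_w)
  for (i in seq_len(n_s1))
    agg[i, s1_targets[[i]]] <- task$joint_s1s2[i, targets$frame[s1_targets[[i]]]]
  task$agg_w <- agg
  task
}

#' @export
print.drt_task <- function(x, ...) {
  cat("Delayed-response task structure\n")
  cat(sprintf("  |W| = %d targets, |A| = %d movement sequences\n", x$n_w, x$n_a))
  cat(sprintf("  |S2| = %d half-frames, |S1| = |M| = %d cue stimuli\n",
              x$n_s2, x$n_s1))
  tab <- cbind(x$conditions, N = x$cue_counts)
  cat("  cue-set sizes:\n")
  print(tab, row.names = FALSE)
  invisible(x)
}

match_condition <- function(task, cT, cS) {
  ci <- which(task$conditions$cT == as.character(cT) &
              task$conditions$cS == as.numeric(cS))
  if (length(ci) != 1L)
    stop(sprintf("unknown condition ('%s', %s)", cT, cS))
  ci
}

#' Cue stimuli belonging to one task condition
#'
#' @param task a \code{drt_task}.
#' @param cT target condition, one of \code{"1"}, \code{"11"}, \code{"2"},
#'   \code{"4"}.
#' @param cS sequence length (2, 3 or 4).
#' @return integer vector of S1 indices; its length is the condition's
#'   cue-set size N.
#' @export
cue_set <- function(task, cT, cS) {
  stopifnot(inherits(task, "drt_task"))
  which(task$s1_condition == match_condition(task, cT, cS))
}

#' Go-signals compatible with a cue stimulus
#'
#' Returns the support of p(s2|s1): the half-frames of the cued targets.
#' Support size is 1, 2, 2 or 4 for target conditions '1', '11', '2', '4';
#' p(s2|s1) is uniform on it.
#'
#' @param task a \code{drt_task}.
#' @param s1 cue stimulus index.
#' @return integer vector of S2 indices.
#' @export
go_signal_support <- function(task, s1) {
  stopifnot(inherits(task, "drt_task"))
  if (!(is.numeric(s1) && length(s1) == 1L && s1 >= 1 && s1 <= task$n_s1))
    stop("invalid s1 index")
  which(task$p_s2_given_s1[s1, ] > 0)
}

#' Resolve the hidden target from cue and go-signal
#'
#' For every (s1, s2) with p(s2|s1) > 0 exactly one cued target of s1 lies
#' inside half-frame s2; this returns it.
#'
#' @inheritParams go_signal_support
#' @param s2 go-signal index.
#' @return the target index w, or an error if s2 is incompatible with s1.
#' @export
resolve_target <- function(task, s1, s2) {
  stopifnot(inherits(task, "drt_task"))
  w <- task$w_of[s1, s2]
  if (w == 0L) stop("go-signal ", s2, " has zero probability under cue ", s1)
  w
}

#' Task utility matrix
#'
#' U(w, a) = 1 if movement sequence a reaches target w, else 0. Each target
#' is reached by exactly its two extremal monotone paths.
#'
#' @param task a \code{drt_task}.
#' @return an \code{n_w} x \code{n_a} 0/1 matrix.
#' @export
utility_matrix <- function(task) {
  U <- matrix(0, task$n_w, task$n_a)
  U[cbind(task$actions$w, task$actions$a)] <- 1
  U
}

#' Cardinality summary of a task
#'
#' @param task a \code{drt_task}.
#' @return a data.frame with one row per condition (cue-set size N, number of
#'   compatible go-signals) plus attributes for the global set sizes.
#' @export
describe_task <- function(task) {
  stopifnot(inherits(task, "drt_task"))
  supp_size <- tapply(rowSums(task$p_s2_given_s1 > 0),
                      factor(task$s1_condition,
                             levels = seq_len(task$n_conditions)), unique)
  out <- cbind(task$conditions,
               N = task$cue_counts,
               n_go_signals = as.integer(supp_size))
  attr(out, "n_w") <- task$n_w
  attr(out, "n_a") <- task$n_a
  attr(out, "n_s2") <- task$n_s2
  attr(out, "n_s1") <- task$n_s1
  out
}
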