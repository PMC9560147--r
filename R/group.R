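#' Paired group comparison of per-subject fit statistics
#'
#' Compares a statistic (by default R2) between two paired sets of fits,
#' subject by subject, with one of: the two-level repeated-measures
#' comparison (algebraically a paired t-test), the Wilcoxon signed-rank
#' test, or a one-sided sign-flip permutation test on the mean paired
#' difference.
#'
#' @param fits_A,fits_B lists of \code{regression_fit}s (or numeric
#'   vectors), paired by \code{subject_id} when fits are given.
#' @param method \code{"paired_rmANOVA"} (paired t),
#'   \code{"wilcoxon_signrank"} or \code{"permutation_one_sided"}.
#' @param value name of the fit element compared (default \code{"R2"}).
#' @param alternative for the t and permutation tests: is A expected
#'   greater, less, or two.sided (Wilcoxon is two-sided as in the study).
#' @param bonferroni_divisor optional integer; when given, the corrected
#'   significance threshold 0.05 / divisor is recorded.
#' @param n_resamples sign-flip resamples for the permutation test.
#' @param seed permutation seed.
#' @return a list of class \code{group_comparison}: statistic name and
#'   value, p-value, n, effect direction, and correction record.
#' @export
compare_group <- function(fits_A, fits_B,
                          method = c("paired_rmANOVA", "wilcoxon_signrank",
                                     "permutation_one_sided"),
                          value = "R2",
                          alternative = c("greater", "two.sided", "less"),
                          bonferroni_divisor = NULL,
                          n_resamples = 10000L, seed = 1L) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  extract <- function(fits) {
    if (is.numeric(fits)) return(list(x = fits, id = seq_along(fits)))
    list(x = vapply(fits, function(f) as.numeric(f[[value]]), numeric(1)),
         id = vapply(fits, function(f) as.character(f$subject_id),
                     character(1)))
  }
  A <- extract(fits_A); B <- extract(fits_B)
  if (length(A$x) != length(B$x) || !setequal(A$id, B$id))
    stop("unpaired subjects: ",
         paste(union(setdiff(A$id, B$id), setdiff(B$id, A$id)),
               collapse = ", "))
  B$x <- B$x[match(A$id, B$id)]
  n <- length(A$x)
  if (n < 2) stop("need at least 2 paired subjects")
  d <- A$x - B$x

  if (method == "paired_rmANOVA") {
    if (stats::sd(d) == 0) {
      # constant paired difference: the t statistic is degenerate
      stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else
        switch(alternative,
               greater = if (mean(d) > 0) 0 else 1,
               less = if (mean(d) < 0) 0 else 1,
               two.sided = 0)
    } else {
      tt <- stats::t.test(A$x, B$x, paired = TRUE, alternative = alternative)
      stat <- unname(tt$statistic); p <- tt$p.value
    }
  } else if (method == "wilcoxon_signrank") {
    if (all(d == 0)) {
      stat <- 0; p <- 1
    } else {
      wt <- suppressWarnings(stats::wilcox.test(A$x, B$x, paired = TRUE))
      stat <- unname(wt$statistic); p <- wt$p.value
    }
  } else {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
            add = TRUE)
    set.seed(seed)
    obs <- mean(d)
    if (all(d == 0)) {
      stat <- 0; p <- 1
    } else {
      flips <- matrix(sample(c(-1, 1), n_resamples * n, replace = TRUE),
                      n_resamples, n)
      null_means <- as.vector(flips %*% d) / n
      stat <- obs
      p <- switch(alternative,
        greater   = (sum(null_means >= obs) + 1) / (n_resamples + 1),
        less      = (sum(null_means <= obs) + 1) / (n_resamples + 1),
        two.sided = (sum(abs(null_means) >= abs(obs)) + 1) / (n_resamples + 1))
    }
  }
  structure(list(
    statistic_name = method, statistic_value = stat, p_value = p,
    n_subjects = n,
    effect_direction = if (mean(d) > 0) "A_greater" else
                       if (mean(d) < 0) "B_greater" else "none",
    mean_difference = mean(d),
    correction = if (is.null(bonferroni_divisor)) "none" else "bonferroni",
    bonferroni_divisor = bonferroni_divisor,
    corrected_alpha = if (is.null(bonferroni_divisor)) NA_real_
                      else 0.05 / bonferroni_divisor),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, %s)\n",
              x$statistic_name, x$statistic_value, x$p_value,
              x$n_subjects, x$effect_direction))
  if (!is.null(x$bonferroni_divisor))
    cat(sprintf("  Bonferroni-corrected alpha: 0.05/%d = %.5f\n",
                x$bonferroni_divisor, x$corrected_alpha))
  invisible(x)
}

#' Correlation between model-predicted and behavioural performance
#'
#' Regresses observed performance (1 - error rate) on the model-predicted
#' expected utility across subjects, and validates the association with a
#' shuffle control: the regression is re-run on permuted subject pairings
#' and the fraction of significant (alpha = 0.05) shuffled slopes is
#' reported.
#'
#' @param predicted_EU per-subject model-predicted expected utilities.
#' @param error_rates per-subject observed error rates.
#' @param n_shuffles number of shuffled pairings (default 1000).
#' @param seed shuffle seed.
#' @return list of class \code{behavior_correlation}: \code{slope},
#'   \code{correlation}, \code{p_value} (slope t-test),
#'   \code{shuffle_significant_fraction}, \code{n_subjects}.
#' @export
behavior_correlation <- function(predicted_EU, error_rates,
                                 n_shuffles = 1000L, seed = 1L) {
  stopifnot(length(predicted_EU) == length(error_rates))
  n <- length(predicted_EU)
  if (n < 3) stop("need at least 3 subjects")
  perf <- 1 - error_rates
  if (stats::sd(predicted_EU) == 0 || stats::sd(perf) == 0)
    stop("zero variance in predicted or observed performance")
  fit <- stats::lm(perf ~ predicted_EU)
  sm <- suppressWarnings(summary(fit))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(seed)
  sig <- logical(n_shuffles)
  for (b in seq_len(n_shuffles)) {
    ps <- sample(perf)
    if (stats::sd(ps) == 0) { sig[b] <- FALSE; next }
    sb <- suppressWarnings(summary(stats::lm(ps ~ predicted_EU)))
    sig[b] <- sb$coefficients[2, 4] < 0.05
  }
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    correlation = stats::cor(predicted_EU, perf),
    p_value = sm$coefficients[2, 4],
    shuffle_significant_fraction = mean(sig),
    n_subjects = n),
    class = "behavior_correlation")
}

#' @export
print.behavior_correlation <- function(x, ...) {
  cat(sprintf(
    "Performance ~ predicted E[U]: slope %.3f, rho = %.3f, p = %.4g (n = %d)\n",
    x$slope, x$correlation, x$p_value, x$n_subjects))
  cat(sprintf("  shuffled pairings significant at 5%%: %.1f%%\n",
              100 * x$shuffle_significant_fraction))
  invisible(x)
}
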