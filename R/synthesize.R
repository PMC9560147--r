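#' Link functions relating information cost to signal amplitude
#'
#' The regression model relates condition-level activity to the two
#' information costs through a link f applied element-wise to I values in
#' bits: identity, square, log(1 + x), or the logistic sigmoid
#' 1 / (1 + exp(-x)). All four are monotone on the nonnegative I range.
#'
#' @param link one of \code{"linear"}, \code{"quadratic"},
#'   \code{"logarithmic"}, \code{"sigmoidal"}.
#' @return the link function.
#' @export
link_function <- function(link = c("linear", "quadratic", "logarithmic",
                                   "sigmoidal")) {
  link <- match.arg(link)
  switch(link,
         linear      = identity,
         quadratic   = function(x) x^2,
         logarithmic = function(x) log1p(x),
         sigmoidal   = function(x) 1 / (1 + exp(-x)))
}

#' Specification of one synthetic subject
#'
#' Ground truth for the generative model of condition-level activity:
#' betas(c) = alpha0 + alpha1 f(I1(c)) + alpha2 f(I2(c)) + N(0, noise_sd^2),
#' with the information profile taken from the subject's hypothesis and
#' capacities, and a behavioural error rate drawn as
#' Binomial(n_trials, 1 - E[U]) / n_trials.
#'
#' @param subject_id unique identifier.
#' @param hypothesis ground-truth planning hypothesis.
#' @param beta1,beta2 ground-truth capacities (must lie on the grid used for
#'   generation).
#' @param alpha0 intercept (baseline signal, unconstrained).
#' @param alpha1,alpha2 nonnegative information-cost coefficients.
#' @param link link function name, see \code{\link{link_function}}.
#' @param noise_sd residual standard deviation (activity units).
#' @param n_trials behavioural trial count (default 120, the study's
#'   typical session total).
#' @param seed integer seed making the subject reproducible.
#' @return a list of class \code{subject_spec}.
#' @export
subject_spec <- function(subject_id, hypothesis = "H1_prospective",
                         beta1 = 500, beta2 = 500,
                         alpha0 = 0, alpha1 = 1, alpha2 = 1,
                         link = "linear", noise_sd = 0,
                         n_trials = 120L, seed = 1L) {
  if (!hypothesis %in% hypotheses) stop("unknown hypothesis: ", hypothesis)
  if (alpha1 < 0 || alpha2 < 0)
    stop("alpha1 and alpha2 must be nonnegative (generative model respects ",
         "the non-negative regression assumption)")
  stopifnot(noise_sd >= 0, n_trials >= 1)
  link <- match.arg(link, c("linear", "quadratic", "logarithmic", "sigmoidal"))
  structure(list(subject_id = as.character(subject_id),
                 hypothesis = hypothesis,
                 beta1 = beta1, beta2 = beta2,
                 alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2,
                 link = link, noise_sd = noise_sd,
                 n_trials = as.integer(n_trials), seed = as.integer(seed)),
            class = "subject_spec")
}

#' Generate one subject's condition-level activity and behaviour
#'
#' @param spec a \code{\link{subject_spec}}.
#' @param grid a \code{\link{capacity_grid}} containing the spec's
#'   (hypothesis, beta1, beta2) profile.
#' @param roi_label free-form region label attached to the record.
#' @return a list of class \code{subject_betas}: \code{subject_id},
#'   \code{roi_label}, \code{betas} (one per condition, canonical condition
#'   order), \code{error_rate}, and the generating condition table.
#' @export
generate_subject <- function(spec, grid, roi_label = "synthetic") {
  stopifnot(inherits(spec, "subject_spec"), inherits(grid, "capacity_grid"))
  prof <- grid_profile(grid, spec$hypothesis, spec$beta1, spec$beta2)
  f <- link_function(spec$link)
  mu <- spec$alpha0 + spec$alpha1 * f(prof$I1_bits) +
        spec$alpha2 * f(prof$I2_bits)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()),
          add = TRUE)
  set.seed(spec$seed)
  betas <- mu + stats::rnorm(length(mu), 0, spec$noise_sd)
  eu <- attr(prof, "EU")
  err <- stats::rbinom(1L, spec$n_trials, max(0, min(1, 1 - eu))) /
         spec$n_trials
  structure(list(subject_id = spec$subject_id, roi_label = roi_label,
                 betas = as.numeric(betas), error_rate = err,
                 conditions = prof[, c("cT", "cS")],
                 spec = spec),
            class = "subject_betas")
}

#' @export
print.subject_betas <- function(x, ...) {
  cat(sprintf("Subject %s (%s): %d condition betas, error rate %.3f\n",
              x$subject_id, x$roi_label, length(x$betas), x$error_rate))
  invisible(x)
}

#' Generate a cohort of synthetic subjects
#'
#' @param specs list of \code{\link{subject_spec}}s with unique ids.
#' @param grid a solved \code{\link{capacity_grid}}.
#' @param roi_label region label shared by the cohort.
#' @return a list of class \code{cohort}: \code{subjects} (list of
#'   \code{subject_betas}) and \code{manifest} (data.frame of all
#'   ground-truth parameters, for recovery scoring).
#' @export
generate_cohort <- function(specs, grid, roi_label = "synthetic") {
  stopifnot(length(specs) > 0)
  ids <- vapply(specs, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  subjects <- lapply(specs, generate_subject, grid = grid,
                     roi_label = roi_label)
  manifest <- do.call(rbind, lapply(specs, function(s)
    data.frame(subject_id = s$subject_id, hypothesis = s$hypothesis,
               beta1 = s$beta1, beta2 = s$beta2,
               alpha0 = s$alpha0, alpha1 = s$alpha1, alpha2 = s$alpha2,
               link = s$link, noise_sd = s$noise_sd,
               n_trials = s$n_trials, seed = s$seed)))
  structure(list(subjects = subjects, manifest = manifest),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%s)\n",
              length(x$subjects),
              paste(sprintf("%s: %d", names(table(x$manifest$hypothesis)),
                            as.integer(table(x$manifest$hypothesis))),
                    collapse = ", ")))
  invisible(x)
}

#' Tidy data.frame of a cohort's condition-level betas
#'
#' @param x a \code{cohort}.
#' @param row.names,optional,... standard \code{as.data.frame} arguments
#'   (unused).
#' @return one row per subject x condition with columns \code{subject_id},
#'   \code{roi_label}, \code{cT}, \code{cS}, \code{beta},
#'   \code{error_rate}.
#' @export
as.data.frame.cohort <- function(x, row.names = NULL, optional = FALSE, ...) {
  do.call(rbind, lapply(x$subjects, function(s)
    data.frame(subject_id = s$subject_id, roi_label = s$roi_label,
               cT = s$conditions$cT, cS = s$conditions$cS,
               beta = s$betas, error_rate = s$error_rate)))
}

#' Across-condition spread of a subject's noiseless betas
#'
#' The reference scale for calibrating noise levels: the standard deviation
#' across conditions of the noise-free generative means.
#'
#' @param spec a \code{subject_spec}.
#' @param grid a solved \code{capacity_grid}.
#' @return scalar standard deviation.
#' @export
noiseless_spread <- function(spec, grid) {
  prof <- grid_profile(grid, spec$hypothesis, spec$beta1, spec$beta2)
  f <- link_function(spec$link)
  stats::sd(spec$alpha0 + spec$alpha1 * f(prof$I1_bits) +
            spec$alpha2 * f(prof$I2_bits))
}
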