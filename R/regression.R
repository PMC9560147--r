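## Least squares with a free intercept and sign-constrained slopes,
## solved exactly by enumerating the active sets of the two constraints
## (alpha1 >= 0, alpha2 >= 0). With only two inequality constraints the
## global constrained optimum is among the four candidate fits.
nnls2_fit <- function(y, x1, x2) {
  n <- length(y)
  fit_ls <- function(X) {
    qrX <- qr(X)
    cf <- qr.coef(qrX, y)
    cf[is.na(cf)] <- 0
    res <- y - X %*% cf
    list(coef = cf, rss = sum(res^2))
  }
  candidates <- list(
    both  = cbind(1, x1, x2),
    no_a2 = cbind(1, x1),
    no_a1 = cbind(1, x2),
    none  = cbind(rep(1, n)))
  best <- NULL
  for (nm in names(candidates)) {
    f <- fit_ls(candidates[[nm]])
    a1 <- switch(nm, both = f$coef[2], no_a2 = f$coef[2], 0)
    a2 <- switch(nm, both = f$coef[3], no_a1 = f$coef[2], 0)
    if (a1 < -1e-12 || a2 < -1e-12) next
    if (is.null(best) || f$rss < best$rss - 1e-12)
      best <- list(alpha0 = unname(f$coef[1]), alpha1 = max(a1, 0),
                   alpha2 = max(a2, 0), rss = f$rss)
  }
  best
}

#' Non-negative multilinear regression of activity on information costs
#'
#' Fits betas(c) = alpha0 + alpha1 f(I1(c)) + alpha2 f(I2(c)) by least
#' squares with alpha1, alpha2 constrained nonnegative (alpha0 free), for
#' the chosen link f. A constant design column leaves its coefficient
#' pinned at 0 with a warning.
#'
#' @param betas a \code{subject_betas} record (or a plain numeric vector of
#'   one value per condition in the profile's order).
#' @param profile an \code{\link{information_profile}}.
#' @param link link function name.
#' @return a list of class \code{regression_fit}: coefficients, \code{R2}
#'   (about-the-mean), \code{RSS}, fitted values, and metadata.
#' @export
fit_information_regression <- function(betas, profile, link = "linear") {
  y <- if (inherits(betas, "subject_betas")) betas$betas else as.numeric(betas)
  stopifnot(inherits(profile, "information_profile"))
  if (length(y) != nrow(profile))
    stop("need one observation per condition (", nrow(profile), ")")
  f <- link_function(link)
  x1 <- f(profile$I1_bits); x2 <- f(profile$I2_bits)
  for (nm in c("x1", "x2"))
    if (stats::sd(get(nm)) < 1e-12)
      warning("constant design column ", nm,
              "; its coefficient is pinned at 0")
  fit <- nnls2_fit(y, x1, x2)
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - fit$rss / tss else 0
  structure(list(
    subject_id = if (inherits(betas, "subject_betas")) betas$subject_id else NA,
    hypothesis = attr(profile, "hypothesis"),
    beta1 = attr(profile, "beta1"), beta2 = attr(profile, "beta2"),
    link = link,
    alpha0 = fit$alpha0, alpha1 = fit$alpha1, alpha2 = fit$alpha2,
    R2 = max(0, min(1, r2)), RSS = fit$rss,
    fitted = fit$alpha0 + fit$alpha1 * x1 + fit$alpha2 * x2,
    n = length(y)),
    class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "Fit %s under %s at (%g, %g), %s link: R2 = %.4f, alpha = (%.3g, %.3g, %.3g)\n",
    x$subject_id, x$hypothesis, x$beta1, x$beta2, x$link,
    x$R2, x$alpha0, x$alpha1, x$alpha2))
  invisible(x)
}

#' Nested F-test for the contribution of planning information I2
#'
#' Compares the full regression (I1, I2, intercept) with the reduced one
#' (I1, intercept) on the same conditions:
#' F = ((RSS_red - RSS_full) / 1) / (RSS_full / (n - 3)), with the p-value
#' from the F(1, n - 3) distribution (df (1, 9) for the 12-condition task).
#' Both residual sums come from ordinary (unconstrained) least squares —
#' the classical nested test, whose null distribution is exact, so
#' p-values are uniform when I2 truly contributes nothing. The sign
#' constraints apply to the reported coefficients of
#' \code{\link{fit_information_regression}}, not to this test statistic.
#'
#' @inheritParams fit_information_regression
#' @return list with \code{F}, \code{p}, the two residual sums, and
#'   \code{exact_fit} (TRUE when the full model has zero residual, in
#'   which case p = 0).
#' @export
nested_f_test <- function(betas, profile, link = "linear") {
  y <- if (inherits(betas, "subject_betas")) betas$betas else as.numeric(betas)
  f <- link_function(link)
  x1 <- f(profile$I1_bits); x2 <- f(profile$I2_bits)
  full_ls <- stats::lm.fit(cbind(1, x1, x2), y)
  full <- list(rss = sum(full_ls$residuals^2))
  red_ls <- stats::lm.fit(cbind(1, x1), y)
  red <- list(rss = sum(red_ls$residuals^2))
  n <- length(y); df2 <- n - 3
  if (full$rss <= 1e-14 * max(1, sum(y^2))) {
    if (red$rss <= 1e-14 * max(1, sum(y^2)))
      return(list(F = 0, p = 1, exact_fit = TRUE,
                  rss_full = full$rss, rss_reduced = red$rss))
    return(list(F = Inf, p = 0, exact_fit = TRUE,
                rss_full = full$rss, rss_reduced = red$rss))
  }
  Fstat <- max(0, (red$rss - full$rss)) / (full$rss / df2)
  p <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  list(F = Fstat, p = p, exact_fit = FALSE,
       rss_full = full$rss, rss_reduced = red$rss)
}

#' Best-fitting capacities for one subject on a capacity grid
#'
#' Fits the subject's condition betas against the information profile at
#' every converged grid point of one hypothesis and returns the fit with
#' the highest R2 (ties broken toward larger beta1 + beta2, then larger
#' beta2). The fit at the maximal-capacity point is returned alongside as
#' the "not-bounded" reference.
#'
#' @param betas a \code{subject_betas}.
#' @param grid a solved \code{\link{capacity_grid}}.
#' @param hypothesis hypothesis whose profiles to fit.
#' @param link link function name.
#' @return list of class \code{grid_fit} with elements \code{best}
#'   (a \code{regression_fit}), \code{not_bounded} (fit at the grid's
#'   maximal capacities), and \code{all} (data.frame of R2 over the grid).
#' @export
grid_search_fit <- function(betas, grid, hypothesis = "H1_prospective",
                            link = "linear") {
  stopifnot(inherits(grid, "capacity_grid"))
  keys <- names(grid$profiles)
  keep <- startsWith(keys, paste0(hypothesis, "|"))
  if (!any(keep)) stop("empty grid for hypothesis ", hypothesis)
  rows <- list(); fits <- list()
  for (k in keys[keep]) {
    prof <- grid$profiles[[k]]
    if (!isTRUE(attr(prof, "converged"))) next
    fit <- suppressWarnings(fit_information_regression(betas, prof, link))
    fits[[k]] <- fit
    rows[[k]] <- data.frame(beta1 = fit$beta1, beta2 = fit$beta2, R2 = fit$R2)
  }
  if (!length(fits)) stop("no converged grid points for ", hypothesis)
  tab <- do.call(rbind, rows)
  ord <- order(-tab$R2, -(tab$beta1 + tab$beta2), -tab$beta2)
  best <- fits[[rownames(tab)[ord[1]]]]
  bmax1 <- max(tab$beta1); bmax2 <- max(tab$beta2)
  nb_key <- rownames(tab)[tab$beta1 == bmax1 & tab$beta2 == bmax2]
  not_bounded <- if (length(nb_key)) fits[[nb_key[1]]]
  structure(list(best = best, not_bounded = not_bounded, all = tab),
            class = "grid_fit")
}

#' Leave-one-condition-out cross-validation error
#'
#' For each condition, refits the sign-constrained regression on the
#' remaining conditions and predicts the held-out beta; returns the mean
#' squared prediction error.
#'
#' @inheritParams fit_information_regression
#' @return scalar LOOCV mean squared error.
#' @export
loocv_information_fit <- function(betas, profile, link = "linear") {
  y <- if (inherits(betas, "subject_betas")) betas$betas else as.numeric(betas)
  f <- link_function(link)
  x1 <- f(profile$I1_bits); x2 <- f(profile$I2_bits)
  n <- length(y)
  err <- numeric(n)
  for (i in seq_len(n)) {
    fit <- nnls2_fit(y[-i], x1[-i], x2[-i])
    pred <- fit$alpha0 + fit$alpha1 * x1[i] + fit$alpha2 * x2[i]
    err[i] <- (y[i] - pred)^2
  }
  mean(err)
}
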