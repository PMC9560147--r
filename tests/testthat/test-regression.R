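test_that("noiseless data is interpolated exactly with recovered coefficients", {
  grid <- get_reduced_grid()
  prof <- grid_profile(grid, "H1_prospective", 500, 500)
  truth <- c(0.5, 1.0, 2.0)
  for (link in c("linear", "quadratic", "logarithmic", "sigmoidal")) {
    f <- link_function(link)
    y <- truth[1] + truth[2] * f(prof$I1_bits) + truth[3] * f(prof$I2_bits)
    fit <- fit_information_regression(y, prof, link)
    expect_equal(c(fit$alpha0, fit$alpha1, fit$alpha2), truth,
                 tolerance = 1e-8)
    expect_equal(fit$R2, 1, tolerance = 1e-10)
    expect_lt(loocv_information_fit(y, prof, link), 1e-12)
  }
})

test_that("the non-negativity constraint pins decreasing trends at zero", {
  prof <- synthetic_profile_12(I1 = rep(1, 12), I2 = seq(1, 12))
  y <- 10 - 0.5 * prof$I2_bits
  expect_warning(fit <- fit_information_regression(y, prof, "linear"),
                 "constant design")
  expect_identical(fit$alpha2, 0)
  expect_identical(fit$alpha1, 0)
  # the intercept absorbs the mean once both slopes are pinned
  expect_equal(fit$alpha0, mean(y), tolerance = 1e-10)
})

test_that("constrained and unconstrained solutions agree at interior optima", {
  set.seed(4)
  prof <- synthetic_profile_12(I1 = runif(12, 0, 5), I2 = runif(12, 0, 20))
  y <- 1 + 2 * prof$I1_bits + 0.5 * prof$I2_bits + rnorm(12, 0, 0.05)
  fit <- fit_information_regression(y, prof, "linear")
  ols <- coef(lm(y ~ prof$I1_bits + prof$I2_bits))
  expect_true(all(ols[-1] > 0))          # interior case
  expect_equal(unname(c(fit$alpha0, fit$alpha1, fit$alpha2)), unname(ols),
               tolerance = 1e-10)
})

test_that("coefficient recovery is unbiased across noisy subjects", {
  set.seed(9)
  prof <- synthetic_profile_12(I1 = runif(12, 0, 5), I2 = runif(12, 0, 20))
  a1 <- replicate(200, {
    y <- 0.2 + 0.5 * prof$I1_bits + 0.1 * prof$I2_bits + rnorm(12, 0, 0.2)
    fit_information_regression(y, prof, "linear")$alpha1
  })
  se <- sd(a1) / sqrt(length(a1))
  expect_lt(abs(mean(a1) - 0.5), 3 * se + 1e-3)
})

test_that("nested F-test has exact degrees of freedom and edge cases", {
  prof <- synthetic_profile_12(I1 = runif(12, 0, 5), I2 = runif(12, 0, 20))
  # y depending only on I1: F small; identical RSS gives F = 0, p = 1
  y <- 1 + prof$I1_bits
  nt <- nested_f_test(y, prof, "linear")
  expect_true(nt$exact_fit)              # exact interpolation by I1 alone
  y2 <- 1 + prof$I1_bits + 2 * prof$I2_bits
  nt2 <- nested_f_test(y2, prof, "linear")
  expect_true(nt2$exact_fit)
  expect_identical(nt2$p, 0)
  set.seed(2)
  y3 <- 1 + prof$I1_bits + rnorm(12, 0, 0.5)
  nt3 <- nested_f_test(y3, prof, "linear")
  manual_full <- lm(y3 ~ prof$I1_bits + prof$I2_bits)
  manual_red <- lm(y3 ~ prof$I1_bits)
  Fm <- (sum(resid(manual_red)^2) - sum(resid(manual_full)^2)) /
        (sum(resid(manual_full)^2) / 9)
  expect_equal(nt3$F, Fm, tolerance = 1e-10)
  expect_equal(nt3$p, pf(Fm, 1, 9, lower.tail = FALSE), tolerance = 1e-12)
})

test_that("nested F p-values are uniform when planning information is absent", {
  set.seed(101)
  prof <- synthetic_profile_12(I1 = runif(12, 0, 5), I2 = runif(12, 0, 20))
  pvals <- replicate(1000, {
    y <- 0.2 + 0.5 * prof$I1_bits + rnorm(12, 0, 0.3)
    nested_f_test(y, prof, "linear")$p
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("nested F-test detects a strong planning contribution", {
  set.seed(102)
  prof <- synthetic_profile_12(I1 = runif(12, 0, 5), I2 = runif(12, 0, 20))
  rejections <- replicate(1000, {
    y <- 0.2 + 0.5 * prof$I1_bits + 0.5 * prof$I2_bits + rnorm(12, 0, 0.3)
    nested_f_test(y, prof, "linear")$p < 0.05
  })
  expect_gte(mean(rejections), 0.95)
})

test_that("grid search returns the generating point and dominates the unbounded fit", {
  grid <- get_reduced_grid()
  # (5, 5) is the only non-saturated grid point, so its profile is unique;
  # at higher capacities profiles can coincide and ties go to larger beta
  sp <- subject_spec("s", "H1_prospective", 5, 5, alpha0 = 0.1,
                     alpha1 = 0.4, alpha2 = 0.2, noise_sd = 0, seed = 5)
  sb <- generate_subject(sp, grid)
  gf <- grid_search_fit(sb, grid, "H1_prospective")
  expect_identical(c(gf$best$beta1, gf$best$beta2), c(5, 5))
  expect_gte(gf$best$R2, gf$not_bounded$R2)
  expect_identical(c(gf$not_bounded$beta1, gf$not_bounded$beta2),
                   c(500, 500))
  # with noise, the bounded best still dominates by search-set inclusion
  sp$noise_sd <- 0.3
  sb2 <- generate_subject(sp, grid)
  gf2 <- grid_search_fit(sb2, grid, "H1_prospective")
  expect_gte(gf2$best$R2, gf2$not_bounded$R2)
  expect_error(grid_search_fit(sb2, grid, "H2"), "empty grid")
})

test_that("LOOCV error grows with the noise level", {
  grid <- get_reduced_grid()
  prof <- grid_profile(grid, "H1_prospective", 500, 500)
  mu <- 0.2 + 0.5 * prof$I1_bits + 0.1 * prof$I2_bits
  sds <- seq(0.05, 1, length.out = 20)
  set.seed(6)
  mses <- vapply(sds, function(s)
    mean(replicate(30, loocv_information_fit(mu + rnorm(length(mu), 0, s),
                                             prof, "linear"))),
    numeric(1))
  expect_gt(cor(sds, mses, method = "spearman"), 0)
})

test_that("LOOCV prefers the generating hypothesis at recovery noise", {
  grid <- get_reduced_grid()
  p1 <- grid_profile(grid, "H1_prospective", 500, 500)
  p0 <- grid_profile(grid, "H0_delayed", 500, 500)
  wins <- 0L; n <- 40L
  for (i in seq_len(n)) {
    sp <- subject_spec(paste0("s", i), "H1_prospective", 500, 500,
                       alpha0 = 0.2, alpha1 = 0.5, alpha2 = 0.1,
                       noise_sd = 0, seed = 300L + i)
    sp$noise_sd <- 0.25 * noiseless_spread(sp, grid)
    sb <- generate_subject(sp, grid)
    wins <- wins + (loocv_information_fit(sb, p1, "linear") <
                    loocv_information_fit(sb, p0, "linear"))
  }
  expect_gte(wins / n, 0.9)
})

test_that("observation count must match the condition count", {
  grid <- get_reduced_grid()
  prof <- grid_profile(grid, "H1_prospective", 500, 500)
  expect_error(fit_information_regression(1:5, prof), "observation")
})
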