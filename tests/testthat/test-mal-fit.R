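test_that("the curve reduces to its closed-form special cases", {
  expect_equal(mal_curve(1:10, alpha = 2, beta = 0, gamma = 0), rep(2, 10))
  expect_equal(mal_curve(1:10, alpha = 1, beta = -1, gamma = 0), 1 / (1:10))
  expect_error(mal_curve(2, alpha = -1, beta = 0, gamma = 0), "positive")
})

test_that("negative beta and gamma give an interior minimum at beta/gamma", {
  # parameters of a large-corpus English fit
  alpha <- 3.19
  beta <- -0.35
  gamma <- -0.054
  m_grid <- seq(2, 15, by = 0.01)
  y <- mal_curve(m_grid, alpha, beta, gamma)
  i_min <- which.min(y)
  expect_gt(i_min, 1)
  expect_lt(i_min, length(y))
  expect_equal(m_grid[i_min], beta / gamma, tolerance = 0.01)
  # the analytic extremum is a stationary point of the curve
  m_star <- mal_extremum(beta, gamma)
  h <- 1e-4
  deriv <- (mal_curve(m_star + h, alpha, beta, gamma) -
              mal_curve(m_star - h, alpha, beta, gamma)) / (2 * h)
  expect_lt(abs(deriv), 1e-8)
})

test_that("the extremum exists iff beta and gamma share a sign", {
  expect_equal(round(mal_extremum(-0.35, -0.054), 1), 6.5)
  expect_equal(round(mal_extremum(-0.056, -0.0088), 1), 6.4)
  expect_true(is.na(mal_extremum(-0.024, 0.026)))
  expect_true(is.na(mal_extremum(-0.1, 0)))
  expect_true(is.na(mal_extremum(0.058, -0.019)))
})

test_that("noiseless profiles are recovered exactly across realistic ranges", {
  for (alpha in c(2.5, 3.5)) {
    for (beta in c(-0.35, 0.06)) {
      for (gamma in c(-0.06, 0.06)) {
        prof <- generate_mal_profile(alpha, beta, gamma, m_range = 2:12,
                                     noise_sd = 0)
        fit <- fit_mal(prof)
        expect_true(fit$converged)
        expect_equal(fit$alpha, alpha, tolerance = 1e-6)
        expect_equal(fit$beta, beta, tolerance = 1e-6)
        expect_equal(fit$gamma, gamma, tolerance = 1e-6)
        expect_equal(fit$r_squared, 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("beta stays identifiable under mild multiplicative noise", {
  errs <- vapply(1:40, function(seed) {
    prof <- generate_mal_profile(2.8, -0.15, -0.02, m_range = 2:12,
                                 noise_sd = 0.01, seed = seed)
    abs(fit_mal(prof)$beta - (-0.15))
  }, numeric(1))
  expect_lt(median(errs), 0.05)
})

test_that("rescaling the response rescales alpha only", {
  prof <- generate_mal_profile(2.8, -0.15, -0.02, m_range = 2:12,
                               noise_sd = 0.02, seed = 4)
  fit1 <- fit_mal(prof)
  prof2 <- dplyr::mutate(prof, mean_y = mean_y * 3.7)
  fit2 <- fit_mal(prof2)
  expect_equal(fit2$alpha / fit1$alpha, 3.7, tolerance = 1e-5)
  expect_equal(fit2$beta, fit1$beta, tolerance = 1e-5)
  expect_equal(fit2$gamma, fit1$gamma, tolerance = 1e-5)
})

test_that("the hyperbolic null curve fits well but without inverted regime", {
  cv <- null_curve(0.48)
  prof <- tibble::tibble(m = 2:12, mean_y = null_mean_length(cv, 2:12),
                         count = 1000)
  fit <- fit_mal(prof)
  expect_true(fit$converged)
  expect_gte(fit$r_squared, 0.99)
  # the hyperbola cannot induce a material rising branch: any fitted
  # extremum sits at the upper edge of the range and the rise beyond it is
  # negligible compared to the curve scale
  if (is.finite(fit$extremum_m) && fit$extremum_m < 12) {
    expect_gt(fit$extremum_m, 10)
    rise <- predict(fit, 12) / predict(fit, fit$extremum_m) - 1
    expect_lt(rise, 1e-3)
  }
})

test_that("fit accessors expose parameters tidily", {
  prof <- generate_mal_profile(2.8, -0.15, -0.02, m_range = 2:12,
                               noise_sd = 0)
  fit <- fit_mal(prof)
  td <- tidy(fit)
  expect_equal(td$term, c("alpha", "beta", "gamma"))
  gl <- glance(fit)
  expect_equal(gl$n_bins, 11L)
  expect_true(gl$converged)
  expect_equal(predict(fit, 2), mal_curve(2, fit$alpha, fit$beta, fit$gamma))
  expect_error(fit_mal(prof[1:3, ]), "at least 4")
  # count weighting is accepted and reproduces the noiseless fit
  fitw <- fit_mal(prof, weights = "counts")
  expect_equal(fitw$beta, -0.15, tolerance = 1e-6)
})
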