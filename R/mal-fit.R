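# Menzerath-Altmann law: y = alpha * m^beta * exp(-gamma * m), fitted to a
# length profile by Levenberg-Marquardt nonlinear least squares. When
# beta * gamma > 0 the curve has an interior extremum at m* = beta/gamma,
# beyond which constituent size GROWS with construct size (the inverted
# regime) — the signature the memoryless null model cannot produce.

#' Evaluate the Menzerath-Altmann curve
#'
#' `y = alpha * m^beta * exp(-gamma * m)` — mean constituent (syllable)
#' length as a function of construct (word) length `m`. `alpha > 0` sets the
#' scale; `beta` is the power-law exponent and `gamma` the exponential rate,
#' both typically negative for natural language.
#'
#' @param m Construct length, >= 1 (real values allowed for plotting).
#' @param alpha,beta,gamma Curve parameters; `alpha` must be positive.
#' @return Predicted mean syllable length; vectorized over `m`.
#' @examples
#' mal_curve(2:10, alpha = 3.19, beta = -0.35, gamma = -0.054)
#' @export
mal_curve <- function(m, alpha, beta, gamma) {
  if (alpha <= 0) {
    abort("alpha must be positive")
  }
  alpha * m^beta * exp(-gamma * m)
}

#' Extremum of the Menzerath-Altmann curve
#'
#' The derivative of the curve vanishes at `m* = beta/gamma`, which is a
#' genuine interior extremum exactly when `beta * gamma > 0` (both
#' parameters of the same sign). Otherwise — including `gamma = 0` — the
#' curve is monotonic and `NA` is returned.
#'
#' @param beta,gamma Curve parameters.
#' @return `beta/gamma`, or `NA_real_` when no extremum exists.
#' @examples
#' mal_extremum(-0.35, -0.054)  # ~6.48: inverted regime beyond ~6.5 syllables
#' mal_extremum(-0.024, 0.026)  # NA: monotonic
#' @export
mal_extremum <- function(beta, gamma) {
  if (!is.finite(beta) || !is.finite(gamma) || beta * gamma <= 0) {
    return(NA_real_)
  }
  beta / gamma
}

#' Fit the Menzerath-Altmann law to a length profile
#'
#' Least-squares fit of `y = alpha * m^beta * exp(-gamma * m)` to the
#' `(m, mean_y)` bins of a length profile using the Levenberg-Marquardt
#' algorithm. The default start is `alpha0 = mean_y` at the smallest `m`,
#' `beta0 = gamma0 = -0.05`; on non-convergence a multi-start grid over
#' `beta0, gamma0 in {-0.2, -0.05, 0.05}` is tried and the converged fit
#' with the smallest residual sum of squares is kept. The fit is unweighted
#' by default; `weights = "counts"` weights bins by their token support.
#'
#' @param profile Length profile tibble with columns `m`, `mean_y` and
#'   (for count weighting) `count`; at least 4 bins.
#' @param init Optional named list `list(alpha =, beta =, gamma =)`
#'   overriding the default start.
#' @param weights `"none"` (default) or `"counts"`.
#' @return An object of class `"mal_fit"`: parameters, `r_squared` computed
#'   on the fitted bins, `extremum_m` (`NA` unless `beta * gamma > 0`),
#'   `converged`, residuals and fitted values. Non-convergence is reported
#'   through the flag, not an error.
#' @examples
#' prof <- generate_mal_profile(
#'   alpha = 2.8, beta = -0.15, gamma = -0.02,
#'   m_range = 2:12, count = 100, noise_sd = 0, seed = 1
#' )
#' fit <- fit_mal(prof)
#' glance(fit)
#' @export
fit_mal <- function(profile, init = NULL, weights = c("none", "counts")) {
  weights <- match.arg(weights)
  stopifnot(all(c("m", "mean_y") %in% names(profile)))
  if (nrow(profile) < 4) {
    abort("fitting three parameters requires at least 4 profile bins")
  }
  dat <- data.frame(m = profile$m, y = profile$mean_y)
  w <- if (weights == "counts") profile$count else rep(1, nrow(dat))

  starts <- list(default_mal_start(dat, init))
  if (is.null(init)) {
    grid <- expand.grid(beta = c(-0.2, -0.05, 0.05),
                        gamma = c(-0.2, -0.05, 0.05))
    starts <- c(starts, pmap(grid, function(beta, gamma) {
      list(alpha = starts[[1]]$alpha, beta = beta, gamma = gamma)
    }))
  }

  # prefer converged fits; among equals keep the smallest residual sum
  best <- NULL
  better <- function(cand, best) {
    is.null(best) ||
      (cand$converged && !best$converged) ||
      (cand$converged == best$converged && cand$ssr < best$ssr)
  }
  for (st in starts) {
    cand <- try_lm_fit(dat, w, st)
    if (!is.null(cand) && better(cand, best)) {
      best <- cand
    }
    if (!is.null(best) && best$converged && best$ssr < 1e-20) {
      break
    }
  }

  if (is.null(best)) {
    return(structure(
      list(
        alpha = NA_real_, beta = NA_real_, gamma = NA_real_,
        r_squared = NA_real_, extremum_m = NA_real_, converged = FALSE,
        fitted = rep(NA_real_, nrow(dat)),
        residuals = rep(NA_real_, nrow(dat)),
        data = as_tibble(profile), weights = weights
      ),
      class = "mal_fit"
    ))
  }

  ss_tot <- sum((dat$y - mean(dat$y))^2)
  r2 <- if (ss_tot > 0) 1 - best$ssr / ss_tot else NA_real_
  structure(
    list(
      alpha = best$par[["alpha"]],
      beta = best$par[["beta"]],
      gamma = best$par[["gamma"]],
      r_squared = r2,
      extremum_m = mal_extremum(best$par[["beta"]], best$par[["gamma"]]),
      converged = best$converged,
      fitted = best$fitted,
      residuals = dat$y - best$fitted,
      data = as_tibble(profile),
      weights = weights
    ),
    class = "mal_fit"
  )
}

default_mal_start <- function(dat, init) {
  if (!is.null(init)) {
    stopifnot(all(c("alpha", "beta", "gamma") %in% names(init)))
    return(init[c("alpha", "beta", "gamma")])
  }
  list(alpha = dat$y[which.min(dat$m)], beta = -0.05, gamma = -0.05)
}

try_lm_fit <- function(dat, w, start) {
  fit <- tryCatch(
    suppressWarnings(minpack.lm::nlsLM(
      y ~ alpha * m^beta * exp(-gamma * m),
      data = dat, start = start, weights = w,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, ftol = .Machine$double.eps,
        ptol = .Machine$double.eps
      )
    )),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(NULL)
  }
  par <- stats::coef(fit)
  if (par[["alpha"]] <= 0) {
    return(NULL)
  }
  fitted_y <- mal_curve(dat$m, par[["alpha"]], par[["beta"]], par[["gamma"]])
  list(
    par = par,
    fitted = fitted_y,
    ssr = sum((dat$y - fitted_y)^2),
    converged = isTRUE(fit$convInfo$isConv) ||
      # zero-residual fits can stop on ftol without raising the flag
      sum((dat$y - fitted_y)^2) < 1e-20
  )
}

#' @export
print.mal_fit <- function(x, ...) {
  cat("Menzerath-Altmann fit: y = alpha * m^beta * exp(-gamma m)\n")
  cat(sprintf("  alpha = %.4g, beta = %.4g, gamma = %.4g\n",
              x$alpha, x$beta, x$gamma))
  cat(sprintf("  R^2 = %.4f on %d bins; converged: %s\n",
              x$r_squared, nrow(x$data), x$converged))
  if (is.finite(x$extremum_m)) {
    cat(sprintf("  extremum (inverted regime onset) at m* = beta/gamma = %.1f\n",
                x$extremum_m))
  } else {
    cat("  no interior extremum (beta * gamma <= 0)\n")
  }
  invisible(x)
}

#' Tidy a Menzerath-Altmann fit
#'
#' @param x A `"mal_fit"` object.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @method tidy mal_fit
#' @export
tidy.mal_fit <- function(x, ...) {
  tibble(
    term = c("alpha", "beta", "gamma"),
    estimate = c(x$alpha, x$beta, x$gamma)
  )
}

#' One-row summary of a Menzerath-Altmann fit
#'
#' @param x A `"mal_fit"` object.
#' @param ... Unused.
#' @return A one-row tibble: `alpha`, `beta`, `gamma`, `r_squared`,
#'   `extremum_m`, `converged`, `n_bins`.
#' @method glance mal_fit
#' @export
glance.mal_fit <- function(x, ...) {
  tibble(
    alpha = x$alpha, beta = x$beta, gamma = x$gamma,
    r_squared = x$r_squared, extremum_m = x$extremum_m,
    converged = x$converged, n_bins = nrow(x$data)
  )
}

#' @export
predict.mal_fit <- function(object, m = object$data$m, ...) {
  mal_curve(m, object$alpha, object$beta, object$gamma)
}
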