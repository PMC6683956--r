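#' @export
print.curox_fit <- function(x, ...) {
  cat("Oxidative consumption kinetics fit\n")
  cat("  free parameters (1/(uM min)):\n")
  for (nm in names(x$coefficients))
    cat(sprintf("    %-5s = %.6g\n", nm, x$coefficients[[nm]]))
  cat(sprintf("  SSE = %.6g  (R^2: %s)\n", x$sse,
              paste(sprintf("%s %.4f", names(x$r_squared), x$r_squared),
                    collapse = ", ")))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.curox_fit <- function(object, ...) object$coefficients

#' Summary of a consumption kinetics fit
#'
#' @param object A `curox_fit` from [fit_rate_constants()].
#' @param ... Unused.
#' @return An object of class `summary.curox_fit` with the fitted
#'   constants, per-series R-squared, SSE at the initial guess and at the
#'   optimum, the full-stiff cross-check SSE and its relative deviation
#'   from the fitting-mode SSE, and convergence information.
#' @export
summary.curox_fit <- function(object, ...) {
  structure(list(coefficients = object$coefficients,
                 rate_constants = object$rate_constants,
                 r_squared = object$r_squared,
                 sse = object$sse,
                 sse_initial = object$sse_initial,
                 sse_full_stiff = object$sse_full_stiff,
                 # Relative mode disagreement; the 1e-12 floor keeps the
                 # ratio meaningful for noiseless fits with SSE ~ 0.
                 mode_agreement = abs(object$sse_full_stiff - object$sse) /
                   max(object$sse, 1e-12),
                 iterations = object$iterations,
                 converged = object$converged,
                 init = object$init,
                 n_series = length(object$observed),
                 n_obs = sum(vapply(object$observed, nrow, integer(1)))),
            class = "summary.curox_fit")
}

#' @export
print.summary.curox_fit <- function(x, ...) {
  cat("Oxidative consumption kinetics fit\n")
  cat(sprintf("  %d series, %d observations\n", x$n_series, x$n_obs))
  cat("  fitted constants (1/(uM min)):\n")
  for (nm in names(x$coefficients))
    cat(sprintf("    %-5s = %.6g   (initial guess %g)\n",
                nm, x$coefficients[[nm]], x$init[[nm]]))
  cat("  per-series R^2:\n")
  for (nm in names(x$r_squared))
    cat(sprintf("    %-24s %.4f\n", nm, x$r_squared[[nm]]))
  cat(sprintf("  SSE: initial %.6g -> optimum %.6g\n", x$sse_initial, x$sse))
  cat(sprintf("  full-stiff cross-check SSE %.6g (relative deviation %.2g)\n",
              x$sse_full_stiff, x$mode_agreement))
  cat(sprintf("  converged: %s", x$converged))
  if (!is.na(x$iterations)) cat(sprintf(" (%d objective evaluations)", x$iterations))
  cat("\n")
  invisible(x)
}

#' Predict from a consumption kinetics fit
#'
#' @param object A `curox_fit`.
#' @param times Prediction times, min; defaults to each fitted series' own
#'   sampling times.
#' @param species Species to predict; defaults to the fitted series'
#'   species labels.
#' @param scale `"normalized"` or `"uM"`.
#' @param ... Unused.
#' @return A named list of numeric prediction vectors, one per species.
#' @export
predict.curox_fit <- function(object, times = NULL, species = NULL,
                              scale = "normalized", ...) {
  if (is.null(species))
    species <- vapply(object$observed, attr, character(1), "species")
  species <- unique(species)
  out <- lapply(species, function(sp) {
    tt <- times
    if (is.null(tt)) {
      i <- which(vapply(object$observed, attr, character(1), "species") == sp)[1]
      tt <- object$observed[[i]]$time
    }
    predict_observable(object$config, sp, tt, scale)
  })
  names(out) <- species
  if (length(out) == 1L) out[[1]] else out
}

#' @export
fitted.curox_fit <- function(object, ...) {
  out <- object$predicted
  names(out) <- vapply(object$observed, attr, character(1), "species")
  if (length(out) == 1L) out[[1]] else out
}

#' @export
residuals.curox_fit <- function(object, ...) {
  out <- lapply(seq_along(object$observed), function(i)
    object$observed[[i]]$value - object$predicted[[i]])
  names(out) <- vapply(object$observed, attr, character(1), "species")
  if (length(out) == 1L) out[[1]] else out
}

#' Plot observed data against the fitted consumption curves
#'
#' @param x A `curox_fit`.
#' @param n_grid Number of points for the smooth model curve.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.curox_fit <- function(x, n_grid = 200, ...) {
  n <- length(x$observed)
  op <- graphics::par(mfrow = c(n, 1), mar = c(4, 4.5, 2, 1))
  on.exit(graphics::par(op))
  for (i in seq_len(n)) {
    s <- x$observed[[i]]
    sp <- attr(s, "species")
    grid <- seq(min(s$time), max(s$time), length.out = n_grid)
    curve_vals <- predict_observable(x$config, sp, grid, attr(s, "scale"))
    graphics::plot(s$time, s$value, xlab = "time (min)",
                   ylab = paste0(sp, " (", attr(s, "scale"), ")"),
                   main = sp, ...)
    graphics::lines(grid, curve_vals)
  }
  invisible(x)
}

#' Simulate replicate noisy observation sets from a fitted model
#'
#' Draws `nsim` new observation sets at the fitted series' sampling times,
#' using the fitted constants and additive Gaussian noise. The noise level
#' is taken from each series' declared `sigma` attribute, or `sigma`.
#'
#' @param object A `curox_fit`.
#' @param nsim Number of replicate sets.
#' @param seed Optional RNG seed.
#' @param sigma Fallback noise standard deviation when a series declares
#'   none.
#' @param ... Unused.
#' @return A list of length `nsim`; each element is a list of
#'   `observed_series` mirroring the fitted data.
#' @export
simulate.curox_fit <- function(object, nsim = 1, seed = NULL,
                               sigma = 0.02, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(r) {
    lapply(object$observed, function(s) {
      sd_r <- attr(s, "sigma")
      if (is.null(sd_r)) sd_r <- sigma
      generate_observed_series(object$config, s$time,
                               noise_model(sigma = sd_r, seed = NULL),
                               attr(s, "species"), scale = attr(s, "scale"))
    })
  })
}
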