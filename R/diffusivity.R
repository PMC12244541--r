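# Long-time diffusivity estimation from ensemble MSD.

#' Estimate the long-time diffusion coefficient from an MSD series
#'
#' In two dimensions `MSD(t) = 4 D t` at long times, so `D` is read off the
#' slope of MSD versus time. Samples before `t_min_s` are discarded: the
#' short-time MSD contains contributions from free diffusion by particles
#' that have not yet explored the hindered pore space, which biases `D`
#' upward. The default fit is ordinary least squares with a free intercept
#' (the intercept absorbs the short-time offset); `method = "endpoint"`
#' gives the pointwise alternative `MSD(t_end) / (4 t_end)` for comparison.
#'
#' @param series An [msd_series].
#' @param t_min_s Burn-in: only samples at `t >= t_min_s` enter the fit
#'   (default 0.001 s).
#' @param dp Free diffusivity used for normalization (cm^2/s); defaults to
#'   the value recorded in the series' simulation config.
#' @param method `"slope"` (default) or `"endpoint"`.
#' @return An object of class `diffusivity_estimate` with fields `d_cm2_s`,
#'   `d_normalized` (= d / dp), `fit_window_s`, `slope_stderr`,
#'   `n_particles`, `method`.
#' @export
estimate_diffusivity <- function(series, t_min_s = 0.001, dp = NULL,
                                 method = c("slope", "endpoint")) {
  stopifnot(inherits(series, "msd_series"))
  method <- match.arg(method)
  dp <- dp %||% series$config$diffusivity_dp %||% 1e-6
  keep <- series$times_s >= t_min_s
  t <- series$times_s[keep]
  m <- series$msd_cm2[keep]
  if (method == "slope") {
    if (length(t) < 3) {
      stop("need at least 3 MSD samples at t >= t_min_s, got ", length(t))
    }
    fit <- lm(m ~ t)
    slope <- coef(fit)[["t"]]
    # suppress summary.lm's perfect-fit warning: exact synthetic MSD input
    # is legitimate here
    se <- suppressWarnings(summary(fit)$coefficients["t", "Std. Error"])
    if (slope < 0) {
      warning("fitted MSD slope is negative; clamping D to 0")
      slope <- 0
    }
    d <- slope / 4
  } else {
    if (length(t) < 1) stop("no MSD samples at t >= t_min_s")
    t_last <- t[length(t)]
    d <- m[length(m)] / (4 * t_last)
    se <- NA_real_
  }
  structure(list(d_cm2_s = d,
                 d_normalized = d / dp,
                 fit_window_s = c(t_min_s, max(series$times_s)),
                 slope_stderr = se,
                 n_particles = series$n_particles,
                 method = method),
            class = "diffusivity_estimate")
}

#' @export
print.diffusivity_estimate <- function(x, ...) {
  cat(sprintf("<diffusivity_estimate> D = %.4g cm^2/s (D/Dp = %.3f), %s fit on [%.4g, %.4g] s\n",
              x$d_cm2_s, x$d_normalized, x$method,
              x$fit_window_s[1], x$fit_window_s[2]))
  invisible(x)
}

#' Write a diffusivity estimate to JSON
#'
#' @param estimate A [estimate_diffusivity()] result.
#' @param path Output JSON path.
#' @export
write_diffusivity_json <- function(estimate, path) {
  stopifnot(inherits(estimate, "diffusivity_estimate"))
  jsonlite::write_json(unclass(estimate), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
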