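# Segmented (two-step) IVIM fitting: log-linear D fit at high b, perfusion
# fraction from the back-extrapolated intercept, bounded nonlinear D* fit at
# low b.

#' Configuration of the segmented fit
#'
#' @param threshold b-value splitting the low (perfusion-sensitive) and high
#'   (diffusion-dominated) segments, s/mm^2.
#' @param dstar_bounds Box constraint for D*, mm^2/s. The default `[0, 0.1]`
#'   is the physiological range for white/gray matter; use `c(0, 0.2)` for
#'   tumor (GTV) tissue.
#' @param dstar_start Starting value for the D* optimization, mm^2/s.
#' @param high_inclusive,low_inclusive Whether the threshold b-value itself
#'   belongs to the high / low segment. Both default to `TRUE`: the threshold
#'   is a mandatory anchor of every optimized scheme and discarding it would
#'   waste an acquired point; set both to `FALSE` for the strict
#'   "greater/below the threshold" reading.
#' @param include_b0 Include b = 0 in the D* residuals (its residual vanishes
#'   at truth).
#' @param atbound_tol Tolerance (mm^2/s) within which a D* estimate counts as
#'   sitting on a constraint bound.
#' @param max_iter Iteration cap for the D* optimizer; exceeding it marks the
#'   fit non-converged.
#' @return An object of class `ivim_fit_config`.
#' @export
fit_config <- function(threshold = 200, dstar_bounds = c(0, 0.1),
                       dstar_start = 0, high_inclusive = TRUE,
                       low_inclusive = TRUE, include_b0 = TRUE,
                       atbound_tol = 1e-6, max_iter = 200L) {
  stopifnot(threshold > 0, length(dstar_bounds) == 2L,
            dstar_bounds[1] < dstar_bounds[2],
            dstar_start >= dstar_bounds[1], dstar_start <= dstar_bounds[2],
            atbound_tol > 0, max_iter >= 1)
  structure(list(threshold = threshold, dstar_bounds = dstar_bounds,
                 dstar_start = dstar_start,
                 high_inclusive = isTRUE(high_inclusive),
                 low_inclusive = isTRUE(low_inclusive),
                 include_b0 = isTRUE(include_b0),
                 atbound_tol = atbound_tol, max_iter = as.integer(max_iter)),
            class = "ivim_fit_config")
}

high_segment <- function(b, config) {
  b > config$threshold | (config$high_inclusive & b == config$threshold)
}

low_segment <- function(b, config) {
  (b < config$threshold & (config$include_b0 | b > 0)) |
    (config$low_inclusive & b == config$threshold)
}

normalize_curve <- function(curve) {
  i0 <- which(curve$bvalues == 0)
  if (length(i0) != 1L) stop("curve must contain exactly one b = 0 sample")
  if (curve$intensities[i0] <= 0) stop("b = 0 intensity must be positive")
  curve$intensities <- curve$intensities / curve$intensities[i0]
  curve
}

#' Log-linear fit of the diffusion coefficient at high b
#'
#' Fits an unweighted ordinary least-squares line to `(b, ln S(b)/S(0))` over
#' the high-b segment, where the IVIM decay is mono-exponential up to the
#' perfusion contamination. `D` is minus the slope; the log-space intercept is
#' returned for the perfusion-fraction step.
#'
#' @param curve A [signal_curve()] containing b = 0.
#' @param config An [fit_config()].
#' @return List with `D` (mm^2/s), `intercept` (log space) and `n_points`.
#'   Non-positive intensities in the segment are dropped; fewer than two
#'   usable points is an error.
#' @export
fit_high_b <- function(curve, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"))
  curve <- normalize_curve(curve)
  sel <- high_segment(curve$bvalues, config)
  b <- curve$bvalues[sel]
  y <- curve$intensities[sel]
  ok <- y > 0
  b <- b[ok]; y <- y[ok]
  if (length(b) < 2L)
    stop("need at least 2 positive intensities in the high-b segment")
  beta <- ols_line(b, log(y))
  list(D = -beta[2L], intercept = beta[1L], n_points = length(b))
}

# OLS line y ~ 1 + x, returning c(intercept, slope).
ols_line <- function(x, y) {
  xb <- mean(x)
  slope <- sum((x - xb) * (y - mean(y))) / sum((x - xb)^2)
  c(mean(y) - slope * xb, slope)
}

#' Perfusion fraction from the back-extrapolated intercept
#'
#' `f = (S(0) - S(int)) / S(0) = 1 - exp(intercept)` for a normalized curve.
#' Negative estimates are unphysical (noise or non-Gaussian diffusion) and
#' are flagged for discarding rather than clipped.
#'
#' @param intercept Log-space intercept from [fit_high_b()].
#' @return List with `f` and logical `discarded`.
#' @export
estimate_f <- function(intercept) {
  stopifnot(is.finite(intercept))
  f <- 1 - exp(intercept)
  list(f = f, discarded = f < 0)
}

#' Bounded nonlinear fit of the pseudo-diffusion coefficient
#'
#' With `D` and `f` fixed, estimates D* by bound-constrained nonlinear least
#' squares (Levenberg-Marquardt, [minpack.lm::nls.lm()]) on the low-b segment
#' residuals `S(b) - [f exp(-b D*) + (1 - f) exp(-b D)]`, started at
#' `config$dstar_start`.
#'
#' @param curve A [signal_curve()].
#' @param D,f Fixed estimates from the first two steps; a discarded
#'   (negative) `f` is an error.
#' @param config An [fit_config()].
#' @return List with `Dstar`, logical `at_bound` (estimate within
#'   `atbound_tol` of either constraint) and `converged`.
#' @export
fit_dstar <- function(curve, D, f, config = fit_config()) {
  stopifnot(inherits(curve, "signal_curve"), is.finite(D), is.finite(f))
  if (f < 0) stop("'f' is negative (discarded fit); D* cannot be estimated")
  curve <- normalize_curve(curve)
  sel <- low_segment(curve$bvalues, config)
  b <- curve$bvalues[sel]
  if (sum(b > 0) < 1L) stop("need at least one b > 0 sample in the low segment")
  y <- curve$intensities[sel]
  cst <- (1 - f) * exp(-b * D)
  dstar_solve(y, b, f, cst, config)
}

# Shared 1-parameter bounded least-squares solve for D*.
dstar_solve <- function(y, b, f, cst, config) {
  lo <- config$dstar_bounds[1L]
  hi <- config$dstar_bounds[2L]
  fit <- minpack.lm::nls.lm(
    par = config$dstar_start, lower = lo, upper = hi,
    fn = function(p) y - (f * exp(-b * p) + cst),
    control = minpack.lm::nls.lm.control(maxiter = config$max_iter))
  dstar <- as.numeric(fit$par)
  list(Dstar = dstar,
       at_bound = dstar <= lo + config$atbound_tol ||
                  dstar >= hi - config$atbound_tol,
       converged = fit$info %in% c(1L, 2L, 3L, 4L, 6L, 7L, 8L))
}

#' Segmented IVIM fit of a single curve
#'
#' Runs the three steps of the segmented procedure — [fit_high_b()],
#' [estimate_f()], [fit_dstar()] — on one signal curve. When the perfusion
#' fraction is negative the fit is recorded as discarded and no D* estimate
#' is attempted.
#'
#' @param curve A [signal_curve()].
#' @param config An [fit_config()].
#' @return An object of class `ivim_fit`: a list with `D`, `f`, `Dstar`,
#'   and flags `f_discarded`, `dstar_at_bound`, `converged`.
#' @export
#' @examples
#' sch <- acquisition_scheme(c(0, 30, 60, 90, 120, 150, 200, 400, 600, 800,
#'                             1000, 1200, 1500), "b-lin(13b)")
#' cur <- generate_noisy_curve(ivim_regimes()$Medium, sch, snr = 50, seed = 1)
#' fit_segmented(cur)
fit_segmented <- function(curve, config = fit_config()) {
  hb <- fit_high_b(curve, config)
  fe <- estimate_f(hb$intercept)
  if (fe$discarded) {
    fit <- list(D = hb$D, f = fe$f, Dstar = NA_real_, f_discarded = TRUE,
                dstar_at_bound = NA, converged = NA)
  } else {
    ds <- fit_dstar(curve, hb$D, fe$f, config)
    fit <- list(D = hb$D, f = fe$f, Dstar = ds$Dstar, f_discarded = FALSE,
                dstar_at_bound = ds$at_bound, converged = ds$converged)
  }
  structure(fit, class = "ivim_fit")
}

#' @export
print.ivim_fit <- function(x, ...) {
  cat(sprintf("<ivim_fit> D = %.4g mm^2/s, f = %.4g, D* = %.4g mm^2/s%s%s\n",
              x$D, x$f, x$Dstar,
              if (isTRUE(x$f_discarded)) " [f discarded]" else "",
              if (isTRUE(x$dstar_at_bound)) " [D* at bound]" else ""))
  invisible(x)
}

#' Segmented fit of a batch of curves
#'
#' Vectorized equivalent of [fit_segmented()] for many curves sharing one
#' b-value scheme (e.g. a Monte-Carlo batch or the voxels of a volume). The
#' log-linear D step is a single matrix least-squares solve; the D* step
#' loops the bounded optimizer over retained curves.
#'
#' @param intensities Matrix of intensities, one column per curve, rows
#'   ordered as `bvalues` (e.g. from [simulate_curves()]).
#' @param bvalues b-values for the rows; taken from
#'   `attr(intensities, "bvalues")` when omitted. An [acquisition_scheme()]
#'   is also accepted.
#' @param config An [fit_config()].
#' @return A data.frame with one row per curve and columns `D`, `f`,
#'   `Dstar`, `f_discarded`, `dstar_at_bound`, `converged`.
#' @export
fit_ivim_batch <- function(intensities, bvalues = NULL, config = fit_config()) {
  if (inherits(bvalues, "acquisition_scheme")) bvalues <- bvalues$bvalues
  bvalues <- bvalues %||% attr(intensities, "bvalues")
  if (is.null(bvalues)) stop("b-values not supplied and not attached to matrix")
  intensities <- as.matrix(intensities)
  stopifnot(length(bvalues) == nrow(intensities))
  i0 <- which(bvalues == 0)
  if (length(i0) != 1L) stop("curves must contain exactly one b = 0 sample")
  n <- ncol(intensities)
  y <- sweep(intensities, 2L, intensities[i0, ], "/")

  hi <- which(high_segment(bvalues, config))
  lo <- which(low_segment(bvalues, config))
  if (length(hi) < 2L) stop("need at least 2 b-values in the high segment")
  if (sum(bvalues[lo] > 0) < 1L) stop("need at least one b > 0 in the low segment")

  out <- data.frame(D = rep(NA_real_, n), f = NA_real_, Dstar = NA_real_,
                    f_discarded = NA, dstar_at_bound = NA, converged = NA)

  clean <- colSums(y[hi, , drop = FALSE] <= 0) == 0L
  if (any(clean)) {
    bh <- bvalues[hi]
    x <- cbind(1, bh)
    beta <- solve(crossprod(x), crossprod(x, log(y[hi, clean, drop = FALSE])))
    out$D[clean] <- -beta[2L, ]
    fhat <- 1 - exp(beta[1L, ])
    out$f[clean] <- fhat
    out$f_discarded[clean] <- fhat < 0
  }
  # rare non-positive intensities (possible only for user-supplied data):
  # fall back to the per-curve path with its point-exclusion rule
  for (j in which(!clean)) {
    fit <- fit_segmented(signal_curve(bvalues, intensities[, j]), config)
    out[j, ] <- fit[c("D", "f", "Dstar", "f_discarded", "dstar_at_bound",
                      "converged")]
  }

  bl <- bvalues[lo]
  ylo <- y[lo, , drop = FALSE]
  for (j in which(clean & !out$f_discarded)) {
    ds <- dstar_solve(ylo[, j], bl, out$f[j],
                      (1 - out$f[j]) * exp(-bl * out$D[j]), config)
    out$Dstar[j] <- ds$Dstar
    out$dstar_at_bound[j] <- ds$at_bound
    out$converged[j] <- ds$converged
  }
  out
}
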