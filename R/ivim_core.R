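# Domain types and the IVIM signal / noise model.

#' Define a perfusion regime
#'
#' A perfusion regime is a ground-truth triplet (D, D*, f) characterizing a
#' tissue condition in simulations: the tissue water diffusion coefficient D,
#' the pseudo-diffusion coefficient D* (capillary blood flow), and the
#' perfusion (flowing-blood) fraction f.
#'
#' @param D Diffusion coefficient, mm^2/s. Must be positive.
#' @param Dstar Pseudo-diffusion coefficient, mm^2/s. Must be positive.
#' @param f Perfusion fraction, dimensionless, in `[0, 1)`.
#' @param name Label for the regime.
#' @return An object of class `perfusion_regime`.
#' @seealso [ivim_regimes()] for the three literature-based presets.
#' @export
#' @examples
#' perfusion_regime(D = 1e-3, Dstar = 10e-3, f = 0.05, name = "Low")
perfusion_regime <- function(D, Dstar, f, name = "custom") {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D),
            is.numeric(Dstar), length(Dstar) == 1L, is.finite(Dstar),
            is.numeric(f), length(f) == 1L, is.finite(f))
  if (D <= 0) stop("'D' must be positive (mm^2/s)")
  if (Dstar <= 0) stop("'Dstar' must be positive (mm^2/s)")
  if (f < 0 || f >= 1) stop("'f' must lie in [0, 1)")
  structure(list(name = as.character(name), D = D, Dstar = Dstar, f = f),
            class = "perfusion_regime")
}

#' Literature-based perfusion regime presets
#'
#' The three simulation conditions used throughout the optimization:
#' Low (D = 1e-3, D* = 10e-3, f = 0.05), Medium (D = 1.5e-3, D* = 15e-3,
#' f = 0.30) and High (D = 1e-3, D* = 60e-3, f = 0.30), all in mm^2/s.
#'
#' @return A named list of three [perfusion_regime()] objects.
#' @export
ivim_regimes <- function() {
  list(
    Low    = perfusion_regime(1e-3,  10e-3, 0.05, "Low"),
    Medium = perfusion_regime(1.5e-3, 15e-3, 0.30, "Medium"),
    High   = perfusion_regime(1e-3,  60e-3, 0.30, "High")
  )
}

#' @export
print.perfusion_regime <- function(x, ...) {
  cat(sprintf("<perfusion_regime> %s: D = %g mm^2/s, D* = %g mm^2/s, f = %g\n",
              x$name, x$D, x$Dstar, x$f))
  invisible(x)
}

#' Define a b-value acquisition scheme
#'
#' An ordered set of unique b-values (s/mm^2) describing one diffusion
#' acquisition. Schemes always contain b = 0 (needed for normalization) and
#' are restricted to `[0, 1500]` s/mm^2, the range over which mono-exponential
#' behaviour of the diffusion compartment is a safe assumption.
#'
#' @param bvalues Numeric vector of unique non-negative b-values, s/mm^2.
#' @param name Optional scheme label.
#' @return An object of class `acquisition_scheme`.
#' @export
#' @examples
#' acquisition_scheme(c(0, 50, 100, 150, 200, 400, 1000), "b-CNAO(7b)")
acquisition_scheme <- function(bvalues, name = NULL) {
  stopifnot(is.numeric(bvalues), length(bvalues) >= 2L, all(is.finite(bvalues)))
  if (anyDuplicated(bvalues)) stop("b-values must be unique")
  if (any(bvalues < 0) || any(bvalues > 1500))
    stop("b-values must lie in [0, 1500] s/mm^2")
  if (!0 %in% bvalues) stop("scheme must contain b = 0")
  b <- sort(bvalues)
  structure(list(name = name %||% sprintf("scheme-%db", length(b)), bvalues = b),
            class = "acquisition_scheme")
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("<acquisition_scheme> %s: [%s] s/mm^2\n", x$name,
              paste(x$bvalues, collapse = " ")))
  invisible(x)
}

#' @export
length.acquisition_scheme <- function(x) length(x$bvalues)

#' Fixed anchor b-values of the optimization
#'
#' Every optimized scheme contains b = 0 (no diffusion weighting), b = 200
#' (the segmented-fitting threshold) and b = 1500 s/mm^2 (the upper limit).
#'
#' @return Numeric vector `c(0, 200, 1500)`.
#' @export
scheme_anchors <- function() c(0, 200, 1500)

has_anchors <- function(scheme) all(scheme_anchors() %in% scheme$bvalues)

#' Convert a decibel SNR figure to the linear noise divisor
#'
#' Noise is added with per-channel standard deviation `S0 / SNR`, where
#' `SNR` is the linear amplitude signal-to-noise ratio. Acquisition SNR is
#' conventionally quoted in decibels; this converts the quoted figure via
#' `10^(dB/20)`. The four simulation noise levels of the optimization study
#' are 15, 30, 50 and 80 dB (linear 5.6, 31.6, 316.2, 10000), with 50 dB
#' matching a typical in-vivo acquisition.
#'
#' @param db SNR in decibels (amplitude convention, 20 log10).
#' @return Linear SNR value(s) usable as the `snr` argument throughout the
#'   package.
#' @export
#' @examples
#' snr_from_db(50) # 316.2278
#' noise_levels()
snr_from_db <- function(db) {
  stopifnot(is.numeric(db), all(db > 0))
  10^(db / 20)
}

#' @rdname snr_from_db
#' @export
noise_levels <- function(db = c(15, 30, 50, 80)) {
  stats::setNames(snr_from_db(db), paste0(db, "dB"))
}

#' Noiseless IVIM signal
#'
#' Evaluates the normalized biexponential IVIM decay
#' `S(b)/S(0) = f exp(-b D*) + (1 - f) exp(-b D)`.
#'
#' @param b b-value(s), s/mm^2. Must be non-negative.
#' @param regime A [perfusion_regime()].
#' @return Normalized signal intensity in `(0, 1]`, one value per `b`.
#' @export
#' @examples
#' ivim_signal(200, ivim_regimes()$Low)
ivim_signal <- function(b, regime) {
  stopifnot(inherits(regime, "perfusion_regime"), is.numeric(b))
  if (any(b < 0)) stop("b-values must be non-negative")
  regime$f * exp(-b * regime$Dstar) + (1 - regime$f) * exp(-b * regime$D)
}

# Magnitude (Rician) corruption of a noiseless signal vector: each column is
# one realization of |S + sigma*(n_R + i n_I)| with n_R, n_I ~ N(0, 1).
magnitude_noise <- function(signal, sigma, n) {
  nb <- length(signal)
  if (sigma <= 0) return(matrix(signal, nb, n))
  zr <- matrix(rnorm(nb * n), nb, n)
  zi <- matrix(rnorm(nb * n), nb, n)
  sqrt((signal + sigma * zr)^2 + (sigma * zi)^2)
}

#' Simulate noisy IVIM signal curves
#'
#' Generates `n_curves` magnitude-noise realizations of the IVIM decay for a
#' regime on a scheme. Complex Gaussian noise with per-channel standard
#' deviation `S0 / snr` is added to the noiseless signal and the magnitude is
#' taken (Rician noise); every curve is then normalized by its own noisy
#' value at b = 0.
#'
#' @param regime A [perfusion_regime()].
#' @param scheme An [acquisition_scheme()]; must contain b = 0.
#' @param snr Signal-to-noise ratio, the plain divisor setting the noise
#'   scale; `Inf` gives noiseless curves.
#' @param n_curves Number of independent realizations.
#' @param seed Optional integer seed (the caller's RNG state is untouched).
#' @param S0 Unscaled baseline intensity (results are normalization-invariant).
#' @return A `length(scheme) x n_curves` matrix of normalized intensities
#'   with attribute `bvalues`.
#' @export
simulate_curves <- function(regime, scheme, snr, n_curves = 1L, seed = NULL,
                            S0 = 1) {
  stopifnot(inherits(scheme, "acquisition_scheme"), snr > 0, n_curves >= 1,
            S0 > 0)
  b <- scheme$bvalues
  if (!0 %in% b) stop("scheme must contain b = 0 for normalization")
  s <- S0 * ivim_signal(b, regime)
  m <- with_seed(seed,
                 magnitude_noise(s, if (is.finite(snr)) S0 / snr else 0,
                                 n_curves))
  m <- sweep(m, 2L, m[which(b == 0), ], "/")
  attr(m, "bvalues") <- b
  attr(m, "scheme_name") <- scheme$name
  m
}

#' Generate a single noisy signal curve
#'
#' Convenience wrapper around [simulate_curves()] returning one
#' `signal_curve` object.
#'
#' @inheritParams simulate_curves
#' @return A [signal_curve()].
#' @export
generate_noisy_curve <- function(regime, scheme, snr, seed = NULL, S0 = 1) {
  m <- simulate_curves(regime, scheme, snr, n_curves = 1L, seed = seed, S0 = S0)
  signal_curve(scheme$bvalues, as.numeric(m))
}

#' Construct a signal curve
#'
#' @param bvalues b-values, s/mm^2 (or an [acquisition_scheme()]).
#' @param intensities Non-negative signal intensities, one per b-value.
#' @return An object of class `signal_curve`.
#' @export
signal_curve <- function(bvalues, intensities) {
  if (inherits(bvalues, "acquisition_scheme")) bvalues <- bvalues$bvalues
  stopifnot(is.numeric(bvalues), is.numeric(intensities),
            length(bvalues) == length(intensities))
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(list(bvalues = bvalues, intensities = intensities),
            class = "signal_curve")
}

#' Read / write FSL-style b-value files
#'
#' A `.bval` file holds the b-values of an acquisition on a single
#' whitespace-separated line.
#'
#' @param path File path.
#' @param name Scheme label for the object read back.
#' @return `read_bval()` returns an [acquisition_scheme()];
#'   `write_bval()` returns `path` invisibly.
#' @export
read_bval <- function(path, name = NULL) {
  b <- scan(path, what = numeric(), quiet = TRUE)
  acquisition_scheme(b, name %||% sub("\\.bval$", "", basename(path)))
}

#' @param scheme An [acquisition_scheme()].
#' @rdname read_bval
#' @export
write_bval <- function(scheme, path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  writeLines(paste(format(scheme$bvalues, trim = TRUE, scientific = FALSE),
                   collapse = " "), path)
  invisible(path)
}
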