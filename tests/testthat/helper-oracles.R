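# Shared fixtures and independent oracles used across test files.

regimes <- ivim_regimes()
lib <- scheme_library()

# Noiseless curve for a regime on a scheme.
noiseless_curve <- function(regime, scheme) {
  signal_curve(scheme$bvalues, ivim_signal(scheme$bvalues, regime))
}

# Independent dense grid-search oracle for the D* step: minimizes the same
# low-segment sum of squared residuals by brute force.
grid_search_dstar <- function(curve, D, f, config = fit_config(),
                              resolution = 1e-5) {
  b <- curve$bvalues
  sel <- (b < config$threshold & (config$include_b0 | b > 0)) |
    (config$low_inclusive & b == config$threshold)
  bl <- b[sel]
  y <- curve$intensities[sel] / curve$intensities[b == 0]
  cand <- seq(config$dstar_bounds[1], config$dstar_bounds[2], by = resolution)
  ssr <- vapply(cand, function(d) {
    sum((y - (f * exp(-bl * d) + (1 - f) * exp(-bl * D)))^2)
  }, numeric(1))
  cand[which.min(ssr)]
}

# Textbook OLS slope/intercept on the log signal, the closed-form oracle for
# the high-b linear fit.
ols_oracle <- function(b, logy) {
  n <- length(b)
  slope <- (n * sum(b * logy) - sum(b) * sum(logy)) /
    (n * sum(b^2) - sum(b)^2)
  intercept <- mean(logy) - slope * mean(b)
  c(intercept = intercept, slope = slope)
}
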