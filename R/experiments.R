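# Predefined-scheme comparisons, cross-regime analysis and statistical tests.

#' Library of predefined b-value schemes
#'
#' The comparison schemes used throughout the simulation experiments: the
#' linearly spaced 13- and 7-value schemes, the clinical non-optimized
#' 7-value protocol (b-CNAO(7b)), and the optimized 13- and 7-value schemes
#' per perfusion regime. Extra user-supplied schemes (e.g. a 14-value
#' literature scheme) can be appended.
#'
#' @param extra Optional named list of [acquisition_scheme()] objects to
#'   append.
#' @return A named list of [acquisition_scheme()] objects.
#' @export
scheme_library <- function(extra = NULL) {
  lib <- list(
    "b-lin(13b)" = acquisition_scheme(
      c(0, 30, 60, 90, 120, 150, 200, 400, 600, 800, 1000, 1200, 1500),
      "b-lin(13b)"),
    "b-lin(7b)" = acquisition_scheme(
      c(0, 60, 120, 200, 600, 1000, 1500), "b-lin(7b)"),
    "b-CNAO(7b)" = acquisition_scheme(
      c(0, 50, 100, 150, 200, 400, 1000), "b-CNAO(7b)"),
    "b-opt(13b)-Low" = acquisition_scheme(
      c(0, 10, 30, 50, 60, 150, 200, 300, 400, 1200, 1300, 1400, 1500),
      "b-opt(13b)-Low"),
    "b-opt(13b)-Medium" = acquisition_scheme(
      c(0, 10, 20, 40, 50, 60, 200, 300, 400, 1200, 1300, 1400, 1500),
      "b-opt(13b)-Medium"),
    "b-opt(13b)-High" = acquisition_scheme(
      c(0, 10, 20, 30, 40, 50, 200, 300, 400, 500, 1300, 1400, 1500),
      "b-opt(13b)-High"),
    "b-opt(7b)-Low" = acquisition_scheme(
      c(0, 10, 30, 60, 200, 300, 1500), "b-opt(7b)-Low"),
    "b-opt(7b)-Medium" = acquisition_scheme(
      c(0, 20, 60, 200, 300, 1400, 1500), "b-opt(7b)-Medium"),
    "b-opt(7b)-High" = acquisition_scheme(
      c(0, 20, 200, 300, 1300, 1400, 1500), "b-opt(7b)-High"))
  if (!is.null(extra)) {
    stopifnot(is.list(extra),
              all(vapply(extra, inherits, logical(1), "acquisition_scheme")))
    lib <- c(lib, extra)
  }
  lib
}

#' Compare schemes under identical simulation conditions
#'
#' Runs one Monte-Carlo error batch per scheme (same regime, SNR and seed for
#' all schemes) and summarizes the retained parameter estimates with medians
#' and interquartile ranges.
#'
#' @param schemes List of [acquisition_scheme()] objects (length >= 2).
#' @param regime,snr,n_simulations,config,seed As in [monte_carlo_error()].
#' @return List with `errors` (one row per scheme), `params` (per-scheme,
#'   per-parameter median and IQR) and `reports` (the full
#'   [monte_carlo_error()] objects, with fits attached).
#' @export
compare_schemes <- function(schemes, regime, snr, n_simulations = 2000L,
                            config = fit_config(), seed = NULL) {
  stopifnot(is.list(schemes), length(schemes) >= 2L)
  reports <- lapply(schemes, function(sch) {
    monte_carlo_error(regime, sch, snr, n_simulations, config, seed = seed,
                      return_fits = TRUE)
  })
  errors <- do.call(rbind, lapply(reports, as.data.frame))
  params <- do.call(rbind, lapply(reports, function(r) {
    fits <- r$fits
    keep <- !fits$f_discarded & !is.na(fits$Dstar) & fits$converged
    keep[is.na(keep)] <- FALSE
    ret <- fits[keep, ]
    do.call(rbind, lapply(c("D", "f", "Dstar"), function(p) {
      data.frame(scheme = r$scheme, parameter = p,
                 median = median(ret[[p]]), iqr = unname(diff(
                   quantile(ret[[p]], c(0.25, 0.75)))),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(errors) <- rownames(params) <- NULL
  list(errors = errors, params = params, reports = reports)
}

#' Percent reduction of the total relative error
#'
#' @param sigma_opt `sigma_tot` of the optimized scheme.
#' @param sigma_ref `sigma_tot` of the reference scheme.
#' @return `100 * (sigma_ref - sigma_opt) / sigma_ref`.
#' @export
percent_reduction <- function(sigma_opt, sigma_ref) {
  100 * (sigma_ref - sigma_opt) / sigma_ref
}

#' Cross-regime evaluation of optimized schemes
#'
#' Evaluates every regime with every regime-optimized scheme (3 x 3 when the
#' three presets are used), reporting `sigma_tot` per cell and the absolute
#' difference, in percentage points, from the matched (diagonal) cell of the
#' same evaluation regime.
#'
#' @param schemes Named list of optimized schemes, one per regime; names
#'   must match `names(regimes)`.
#' @param regimes Named list of [perfusion_regime()] objects.
#' @param snr,n_simulations,config,seed As in [monte_carlo_error()].
#' @return A data.frame with one row per (evaluation regime, scheme regime)
#'   pair: the four errors plus `delta_pp`, the absolute `sigma_tot`
#'   difference from the diagonal in percentage points.
#' @export
cross_regime <- function(schemes, regimes = ivim_regimes(),
                         snr = snr_from_db(50),
                         n_simulations = 2000L, config = fit_config(),
                         seed = NULL) {
  stopifnot(is.list(schemes), !is.null(names(schemes)),
            all(names(schemes) %in% names(regimes)))
  cells <- expand.grid(eval_regime = names(regimes),
                       scheme_regime = names(schemes),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    er <- cells$eval_regime[i]; sr <- cells$scheme_regime[i]
    rep <- monte_carlo_error(regimes[[er]], schemes[[sr]], snr, n_simulations,
                             config, seed = seed)
    cbind(cells[i, ], as.data.frame(rep)[c("sigma_D", "sigma_f",
                                           "sigma_Dstar", "sigma_tot",
                                           "sigma_tot_se")])
  }))
  diag <- out[out$eval_regime == out$scheme_regime, ]
  out$delta_pp <- 100 * abs(out$sigma_tot -
                            diag$sigma_tot[match(out$eval_regime,
                                                 diag$eval_regime)])
  rownames(out) <- NULL
  out
}

#' Friedman test across b-value schemes with post-hoc comparisons
#'
#' Tests whether paired parameter estimates (or errors) differ across
#' schemes, using the Friedman rank test followed by pairwise Wilcoxon
#' signed-rank tests at a Bonferroni-adjusted threshold.
#'
#' @param x Numeric matrix: rows are paired observations (simulations),
#'   columns are conditions (schemes). At least two columns.
#' @param alpha Family-wise significance level.
#' @return List with the Friedman `statistic`, `p_value` and `significant`
#'   flag, the Bonferroni-adjusted pairwise threshold `alpha_pairwise`, and a
#'   `pairwise` data.frame of post-hoc signed-rank comparisons.
#' @export
test_scheme_differences <- function(x, alpha = 0.01) {
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("need at least two conditions")
  if (any(is.na(x))) stop("conditions must be equal-length, without NAs")
  ft <- friedman.test(x)
  k <- ncol(x)
  pairs <- utils::combn(k, 2)
  alpha_pw <- alpha / ncol(pairs)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    p <- wilcox.test(x[, a], x[, b], paired = TRUE, exact = FALSE)$p.value
    data.frame(cond_a = colnames(x)[a] %||% a, cond_b = colnames(x)[b] %||% b,
               p_value = p, significant = p < alpha_pw,
               stringsAsFactors = FALSE)
  }))
  list(statistic = unname(ft$statistic), p_value = ft$p.value,
       significant = ft$p.value < alpha, alpha = alpha,
       alpha_pairwise = alpha_pw, pairwise = pw)
}

#' Compare parameter distributions between two tissues
#'
#' Wilcoxon test between two samples of voxelwise parameter estimates
#' (paired by default, as when the same voxels are estimated under two
#' conditions, or matched white/gray-matter summaries per subject).
#'
#' @param a,b Non-empty numeric samples; equal length when `paired`.
#' @param alpha Significance level.
#' @param paired Use the signed-rank (paired) form.
#' @return List with `statistic`, `p_value`, `significant`, `alpha`.
#' @export
compare_tissues <- function(a, b, alpha = 0.05, paired = TRUE) {
  stopifnot(length(a) >= 1L, length(b) >= 1L)
  if (paired && length(a) != length(b))
    stop("paired comparison requires equal-length samples")
  if (paired && all(a == b))  # all-tied pairs: no evidence of a difference
    return(list(statistic = 0, p_value = 1, significant = FALSE,
                alpha = alpha))
  wt <- wilcox.test(a, b, paired = paired, exact = FALSE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha, alpha = alpha)
}

#' Coefficient of variation per group
#'
#' Sample standard deviation divided by the mean, per group — used to
#' summarize signal variability across b-values and tissue regions.
#'
#' @param x Numeric vector of intensities.
#' @param group Optional grouping factor/vector (e.g. interaction of b-value
#'   and region); when omitted, `x` is one group.
#' @return A named numeric vector of per-group CoV values. Groups need at
#'   least two values; a zero mean is an error.
#' @export
#' @examples
#' coefficient_of_variation(c(1, 3)) # sqrt(2)/2
coefficient_of_variation <- function(x, group = NULL) {
  stopifnot(is.numeric(x))
  if (is.null(group)) group <- rep_len("all", length(x))
  stopifnot(length(group) == length(x))
  vapply(split(x, group), function(v) {
    if (length(v) < 2L) stop("each group needs at least 2 values")
    m <- mean(v)
    if (m == 0) stop("group mean is zero; CoV undefined")
    sd(v) / m
  }, numeric(1))
}
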