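# Greedy forward selection of b-values, frequency aggregation over
# repetitions and SNR levels, optimal-scheme extraction, backward elimination.

#' Candidate b-value grids
#'
#' The search space of the scheme optimization: 19 low-range candidates
#' (10..190 s/mm^2, step 10), 12 high-range candidates (300..1400, step 100),
#' split at the segmented-fitting threshold, plus the three fixed anchors
#' {0, 200, 1500} present in every scheme.
#'
#' @return An object of class `candidate_grid` with elements `low`, `high`,
#'   `anchors`.
#' @export
candidate_grid <- function() {
  structure(list(low = seq(10, 190, by = 10),
                 high = seq(300, 1400, by = 100),
                 anchors = scheme_anchors()),
            class = "candidate_grid")
}

add_bvalue <- function(scheme, b, name = NULL) {
  acquisition_scheme(c(scheme$bvalues, b), name %||% scheme$name)
}

drop_bvalue <- function(scheme, b, name = NULL) {
  acquisition_scheme(setdiff(scheme$bvalues, b), name %||% scheme$name)
}

#' One greedy forward-selection step
#'
#' Evaluates `sigma_tot` of `current` extended by each candidate in `pool`
#' (a fresh Monte-Carlo batch per candidate) and returns the candidate
#' minimizing it. Ties are broken toward the lower b-value.
#'
#' @param current An [acquisition_scheme()].
#' @param pool Numeric vector of remaining candidate b-values.
#' @param regime,snr,n_simulations,config As in [monte_carlo_error()].
#' @param seed Integer seed; candidate batches use seeds derived from it
#'   (`derive_seed(seed, i)` for the i-th candidate in ascending order).
#' @param common_rng Use the same derived seed for every candidate (common
#'   random numbers; variance reduction for scaled-down runs).
#' @return List with `chosen` (the selected b-value) and `reports`, a
#'   data.frame of per-candidate errors.
#' @export
greedy_step <- function(current, pool, regime, snr, n_simulations = 2000L,
                        config = fit_config(), seed = NULL,
                        common_rng = FALSE) {
  stopifnot(length(pool) >= 1L)
  pool <- sort(pool)
  reports <- lapply(seq_along(pool), function(i) {
    s <- if (is.null(seed)) NULL
         else derive_seed(seed, if (common_rng) 0L else i)
    as.data.frame(monte_carlo_error(regime, add_bvalue(current, pool[i]),
                                    snr, n_simulations, config, seed = s))
  })
  reports <- do.call(rbind, reports)
  reports$candidate <- pool
  list(chosen = pool[which.min(reports$sigma_tot)], reports = reports)
}

#' One full greedy scheme optimization
#'
#' Starting from the anchor scheme {0, 200, 1500}, repeatedly adds the
#' candidate b-value minimizing `sigma_tot` until `target_size` b-values are
#' selected; each chosen value is removed from the candidate pool so the
#' scheme stays duplicate-free.
#'
#' @param regime A [perfusion_regime()].
#' @param snr Signal-to-noise ratio.
#' @param grid A [candidate_grid()].
#' @param n_simulations Simulations per candidate evaluation.
#' @param target_size Final number of b-values (anchors included).
#' @param config An [fit_config()].
#' @param seed Integer seed; step `s` uses stream `derive_seed(seed, s)`.
#' @param common_rng Passed to [greedy_step()].
#' @return An [acquisition_scheme()] of `target_size` b-values.
#' @export
optimize_scheme <- function(regime, snr, grid = candidate_grid(),
                            n_simulations = 2000L, target_size = 13L,
                            config = fit_config(), seed = NULL,
                            common_rng = FALSE) {
  stopifnot(inherits(grid, "candidate_grid"),
            target_size >= length(grid$anchors))
  current <- acquisition_scheme(grid$anchors,
                                sprintf("b-opt(%db)-%s", target_size,
                                        regime$name))
  pool <- sort(c(grid$low, grid$high))
  step <- 0L
  while (length(current) < target_size) {
    step <- step + 1L
    gs <- greedy_step(current, pool, regime, snr, n_simulations, config,
                      seed = if (is.null(seed)) NULL else derive_seed(seed, step),
                      common_rng = common_rng)
    current <- add_bvalue(current, gs$chosen)
    pool <- setdiff(pool, gs$chosen)
  }
  current
}

#' Selection-frequency table over repeated optimizations
#'
#' Repeats [optimize_scheme()] `repetitions` times per SNR level and tallies
#' how often each candidate b-value is selected. The aggregate frequency of a
#' candidate is the sum over SNR levels of its per-SNR relative frequency
#' (count / repetitions); the most frequent candidates define the final
#' optimal scheme.
#'
#' @param regime A [perfusion_regime()].
#' @param grid A [candidate_grid()].
#' @param snr_levels Numeric vector of SNR levels.
#' @param repetitions Optimization repetitions per SNR level.
#' @param n_simulations Simulations per candidate evaluation.
#' @param target_size Scheme size per optimization.
#' @param config An [fit_config()].
#' @param seed Integer seed; repetition `r` at SNR index `s` uses stream
#'   `derive_seed(seed, s * 100000 + r)`.
#' @param common_rng Passed down to [greedy_step()].
#' @return An object of class `frequency_table`: a data.frame with columns
#'   `snr`, `bvalue`, `range`, `count`, `rel_freq`, with attributes
#'   `repetitions`, `snr_levels` and `grid`. See [aggregate_frequencies()].
#' @export
build_frequency_table <- function(regime, grid = candidate_grid(),
                                  snr_levels = noise_levels(),
                                  repetitions = 100L, n_simulations = 2000L,
                                  target_size = 13L, config = fit_config(),
                                  seed = NULL, common_rng = FALSE) {
  stopifnot(repetitions >= 1)
  cand <- sort(c(grid$low, grid$high))
  tab <- expand.grid(bvalue = cand, snr = snr_levels,
                     KEEP.OUT.ATTRS = FALSE)[, c("snr", "bvalue")]
  tab$range <- ifelse(tab$bvalue %in% grid$low, "low", "high")
  tab$count <- 0L
  for (s in seq_along(snr_levels)) {
    for (r in seq_len(repetitions)) {
      sch <- optimize_scheme(
        regime, snr_levels[s], grid, n_simulations, target_size, config,
        seed = if (is.null(seed)) NULL else derive_seed(seed, s * 100000 + r),
        common_rng = common_rng)
      sel <- setdiff(sch$bvalues, grid$anchors)
      hit <- tab$snr == snr_levels[s] & tab$bvalue %in% sel
      tab$count[hit] <- tab$count[hit] + 1L
    }
  }
  tab$rel_freq <- tab$count / repetitions
  structure(tab, class = c("frequency_table", "data.frame"),
            repetitions = as.integer(repetitions), snr_levels = snr_levels,
            grid = grid)
}

#' Aggregate selection frequencies across SNR levels
#'
#' @param table A `frequency_table` from [build_frequency_table()].
#' @return A data.frame with columns `bvalue`, `range`, `freq` (sum of the
#'   per-SNR relative frequencies).
#' @export
aggregate_frequencies <- function(table) {
  stopifnot(inherits(table, "frequency_table"))
  agg <- aggregate(rel_freq ~ bvalue + range, data = as.data.frame(table), sum)
  names(agg)[names(agg) == "rel_freq"] <- "freq"
  agg[order(agg$bvalue), c("bvalue", "range", "freq")]
}

#' Extract the optimal scheme from a frequency table
#'
#' Takes the `n_low` most frequent low-range candidates and the `n_high`
#' most frequent high-range candidates (by SNR-summed relative frequency,
#' ties toward the lower b-value) and unions them with the anchors.
#'
#' @param table A `frequency_table`.
#' @param grid The [candidate_grid()] the table was built over.
#' @param n_low,n_high Candidates retained per range.
#' @param name Scheme label.
#' @return An [acquisition_scheme()] of `n_low + n_high + 3` b-values.
#' @export
select_optimal_scheme <- function(table, grid = attr(table, "grid"),
                                  n_low = 5L, n_high = 5L, name = NULL) {
  agg <- aggregate_frequencies(table)
  pick <- function(range, k) {
    a <- agg[agg$range == range & agg$freq > 0, ]
    if (nrow(a) < k)
      stop(sprintf("fewer than %d nonzero-frequency candidates in the %s range",
                   k, range))
    a <- a[order(-a$freq, a$bvalue), ]
    a$bvalue[seq_len(k)]
  }
  b <- c(grid$anchors, pick("low", n_low), pick("high", n_high))
  acquisition_scheme(b, name %||% sprintf("b-opt(%db)", length(b)))
}

#' Backward elimination of b-values
#'
#' Iteratively removes b-values from `start` until `min_size` remain,
#' monitoring `sigma_tot`. At each step the least-frequent remaining
#' non-anchor b-value of the low range and of the high range (frequencies
#' from `table`, ties toward the lower b-value) are the two removal
#' candidates; the one whose removal yields the smaller `sigma_tot` over a
#' fresh Monte-Carlo batch is eliminated. Anchors {0, 200, 1500} are never
#' removed. `rule = "global"` instead removes the single least-frequent
#' non-anchor value outright, using the batch only to record the error.
#'
#' @param start An [acquisition_scheme()] containing the anchors.
#' @param table A `frequency_table` covering the non-anchor values of
#'   `start` (values absent from the table count as frequency zero).
#' @param regime,snr,n_simulations,config As in [monte_carlo_error()].
#' @param min_size Stop when this many b-values remain.
#' @param seed Integer seed; step `s`, candidate `j` uses
#'   `derive_seed(seed, s * 100 + j)`; the starting-scheme report uses
#'   `derive_seed(seed, 0)`.
#' @param rule `"per_range"` (default, two-candidate rule) or `"global"`.
#' @return An object of class `elimination_trace`: a data.frame with one row
#'   per scheme from `start` down to `min_size` (columns `size`, `removed`,
#'   the four errors and `sigma_tot_se`), with the schemes themselves in
#'   `attr(, "schemes")`.
#' @export
backward_eliminate <- function(start, table, regime, snr,
                               n_simulations = 2000L, config = fit_config(),
                               min_size = 4L, seed = NULL,
                               rule = c("per_range", "global")) {
  rule <- match.arg(rule)
  stopifnot(inherits(start, "acquisition_scheme"), has_anchors(start),
            min_size >= length(scheme_anchors()))
  if (length(start) < min_size) stop("'start' is smaller than 'min_size'")
  freq <- aggregate_frequencies(table)
  freq_of <- function(b) {
    i <- match(b, freq$bvalue)
    ifelse(is.na(i), 0, freq$freq[i])
  }
  least_frequent <- function(b) b[order(freq_of(b), b)][1L]

  base <- monte_carlo_error(regime, start, snr, n_simulations, config,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 0L))
  rows <- list(cbind(size = length(start), removed = NA_real_,
                     as.data.frame(base)))
  schemes <- list(start)
  current <- start
  step <- 0L
  while (length(current) > min_size) {
    step <- step + 1L
    nonanchor <- setdiff(current$bvalues, scheme_anchors())
    lo <- nonanchor[nonanchor < 200]
    hi <- nonanchor[nonanchor > 200]
    cands <- if (rule == "global") least_frequent(nonanchor)
             else c(if (length(lo)) least_frequent(lo),
                    if (length(hi)) least_frequent(hi))
    reps <- lapply(seq_along(cands), function(j) {
      monte_carlo_error(regime, drop_bvalue(current, cands[j]), snr,
                        n_simulations, config,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, step * 100L + j))
    })
    tot <- vapply(reps, function(r) r$sigma_tot, numeric(1))
    k <- order(tot, cands)[1L]
    current <- drop_bvalue(current, cands[k])
    rows[[length(rows) + 1L]] <- cbind(size = length(current),
                                       removed = cands[k],
                                       as.data.frame(reps[[k]]))
    schemes[[length(schemes) + 1L]] <- current
  }
  trace <- do.call(rbind, rows)
  structure(trace, class = c("elimination_trace", "data.frame"),
            schemes = schemes)
}

#' Smallest scheme size reachable without a clear error increment
#'
#' Walks an elimination trace from the starting scheme downward and returns
#' the smallest size whose `sigma_tot` — and that of every larger scheme on
#' the path — stays within Monte-Carlo error of the starting scheme's value.
#' "Within Monte-Carlo error" means not exceeding the baseline by more than
#' `n_se` combined split-batch standard errors.
#'
#' @param trace An `elimination_trace` from [backward_eliminate()].
#' @param n_se Width of the tolerance band in combined standard errors.
#' @return Integer scheme size.
#' @export
reducible_size <- function(trace, n_se = 3) {
  stopifnot(inherits(trace, "elimination_trace"), nrow(trace) >= 1L)
  base <- trace[1L, ]
  ok <- trace$sigma_tot <= base$sigma_tot +
    n_se * sqrt(base$sigma_tot_se^2 + trace$sigma_tot_se^2)
  bad <- which(!ok)
  if (length(bad) == 0L) trace$size[nrow(trace)] else trace$size[min(bad) - 1L]
}
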