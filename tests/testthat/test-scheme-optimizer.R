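test_that("candidate grid holds the 19 + 12 candidates and the anchors", {
  grid <- candidate_grid()
  expect_identical(grid$low, seq(10, 190, by = 10))
  expect_identical(grid$high, seq(300, 1400, by = 100))
  expect_length(grid$low, 19L)
  expect_length(grid$high, 12L)
  expect_identical(grid$anchors, c(0, 200, 1500))
  expect_length(intersect(grid$low, grid$high), 0L)
})

test_that("greedy step equals brute-force enumeration under shared seeds", {
  anchors <- acquisition_scheme(scheme_anchors(), "anchors")
  pool <- c(20, 60, 150, 400, 1300)
  gs <- greedy_step(anchors, pool, regimes$Medium, snr = 50,
                    n_simulations = 150, seed = 31)
  # independent brute force: same derived seed stream, explicit argmin
  brute <- vapply(seq_along(pool), function(i) {
    monte_carlo_error(regimes$Medium,
                      acquisition_scheme(c(anchors$bvalues, pool[i])),
                      50, 150, seed = derive_seed(31, i))$sigma_tot
  }, numeric(1))
  expect_identical(gs$chosen, pool[which.min(brute)])
  expect_equal(gs$reports$sigma_tot, brute)
})

test_that("a pool of one is chosen regardless of error; ties go to lower b", {
  anchors <- acquisition_scheme(scheme_anchors())
  gs <- greedy_step(anchors, 700, regimes$Low, 50, n_simulations = 20,
                    seed = 1)
  expect_identical(gs$chosen, 700)
  # common random numbers make equal-error candidates possible; the
  # tie-break picks the first (lowest) candidate among minima
  ranked <- gs$reports$sigma_tot
  expect_identical(gs$chosen, gs$reports$candidate[which.min(ranked)])
})

test_that("optimize_scheme grows from the anchors to the target size", {
  grid <- candidate_grid()
  expect_identical(
    optimize_scheme(regimes$Medium, 50, grid, n_simulations = 10,
                    target_size = 3, seed = 2)$bvalues,
    c(0, 200, 1500))
  s4 <- optimize_scheme(regimes$Medium, 50, grid, n_simulations = 60,
                        target_size = 4, seed = 2)
  expect_length(s4, 4L)
  # equals the brute-force argmin over all 31 candidates, same seed stream
  pool <- sort(c(grid$low, grid$high))
  step_seed <- derive_seed(2, 1)
  brute <- vapply(seq_along(pool), function(i) {
    monte_carlo_error(regimes$Medium,
                      acquisition_scheme(c(0, 200, 1500, pool[i])),
                      50, 60, seed = derive_seed(step_seed, i))$sigma_tot
  }, numeric(1))
  expect_identical(setdiff(s4$bvalues, c(0, 200, 1500)),
                   pool[which.min(brute)])

  s13 <- optimize_scheme(regimes$Medium, 50, grid, n_simulations = 25,
                         target_size = 13, seed = 3)
  expect_length(s13, 13L)
  expect_true(all(c(0, 200, 1500) %in% s13$bvalues))
  expect_true(all(setdiff(s13$bvalues, c(0, 200, 1500)) %in%
                    c(grid$low, grid$high)))
  expect_false(anyDuplicated(s13$bvalues) > 0)
})

test_that("frequency tables conserve counts and frequencies", {
  grid <- candidate_grid()
  tab <- build_frequency_table(regimes$Medium, grid, snr_levels = c(30, 50),
                               repetitions = 3, n_simulations = 25,
                               target_size = 13, seed = 4)
  # per-SNR total selections = repetitions x 10 added b-values
  per_snr <- tapply(tab$count, tab$snr, sum)
  expect_true(all(per_snr == 3 * 10))
  expect_true(all(tab$count <= 3))
  expect_equal(tab$rel_freq, tab$count / 3)
  agg <- aggregate_frequencies(tab)
  expect_equal(sum(agg$freq), 2 * 10) # summed rel freqs over 2 SNR levels

  one <- build_frequency_table(regimes$Medium, grid, snr_levels = 50,
                               repetitions = 1, n_simulations = 25,
                               seed = 5)
  expect_true(all(one$rel_freq %in% c(0, 1)))
  expect_identical(sum(one$rel_freq == 1), 10L)
})

test_that("optimal-scheme extraction takes the top 5 per range with ties low", {
  grid <- candidate_grid()
  tab <- expand.grid(bvalue = sort(c(grid$low, grid$high)), snr = 50,
                     KEEP.OUT.ATTRS = FALSE)[, c("snr", "bvalue")]
  tab$range <- ifelse(tab$bvalue %in% grid$low, "low", "high")
  # low counts strictly decrease with b; high counts strictly increase
  tab$count <- ifelse(tab$range == "low", 200 - tab$bvalue, tab$bvalue)
  tab$rel_freq <- tab$count / 100
  tab <- structure(tab, class = c("frequency_table", "data.frame"),
                   repetitions = 100L, snr_levels = 50, grid = grid)
  sch <- select_optimal_scheme(tab, grid)
  expect_identical(sch$bvalues,
                   sort(c(0, 200, 1500, c(10, 20, 30, 40, 50),
                          c(1000, 1100, 1200, 1300, 1400))))
  # frequency ties prefer the lower b-value
  tab$count <- ifelse(tab$bvalue %in% c(30, 70, 110), 50L, tab$count)
  sch2 <- select_optimal_scheme(tab, grid)
  expect_true(all(c(10, 20, 40, 50, 30) %in% sch2$bvalues) ||
                all(c(10, 20, 40, 50, 60) %in% sch2$bvalues))
  expect_error(select_optimal_scheme(
    structure(transform(as.data.frame(tab), count = 0, rel_freq = 0),
              class = c("frequency_table", "data.frame"),
              repetitions = 100L, snr_levels = 50, grid = grid), grid),
    "nonzero-frequency")
})

test_that("backward elimination shrinks one value at a time, keeping anchors", {
  grid <- candidate_grid()
  tab <- build_frequency_table(regimes$Medium, grid, snr_levels = 50,
                               repetitions = 2, n_simulations = 25, seed = 6)
  start <- lib[["b-opt(13b)-Medium"]]
  tr <- backward_eliminate(start, tab, regimes$Medium, 50,
                           n_simulations = 100, min_size = 4, seed = 7)
  expect_identical(tr$size, seq(13L, 4L))
  expect_identical(diff(tr$size), rep(-1L, 9))
  schemes <- attr(tr, "schemes")
  for (s in schemes) expect_true(all(c(0, 200, 1500) %in% s$bvalues))
  expect_true(all(!tr$removed[-1] %in% c(0, 200, 1500)))
  # removed values leave the scheme for good
  for (k in 2:length(schemes))
    expect_identical(schemes[[k]]$bvalues,
                     setdiff(schemes[[k - 1]]$bvalues, tr$removed[k]))

  start4 <- acquisition_scheme(c(0, 60, 200, 1500))
  tr4 <- backward_eliminate(start4, tab, regimes$Medium, 50,
                            n_simulations = 50, seed = 8)
  expect_identical(nrow(tr4), 1L)
})

test_that("reducible_size finds the last size within the baseline error band", {
  fake <- data.frame(size = 13:4, removed = NA,
                     sigma_tot = c(rep(0.50, 5), 0.505, 0.52, 0.9, 1.2, 1.5),
                     sigma_tot_se = 0.01)
  fake <- structure(fake, class = c("elimination_trace", "data.frame"))
  expect_identical(reducible_size(fake), 7L)
  flat <- transform(fake, sigma_tot = 0.5)
  flat <- structure(flat, class = c("elimination_trace", "data.frame"))
  expect_identical(reducible_size(flat), 4L)
})

test_that("the optimization pipeline is deterministic under a master seed", {
  grid <- candidate_grid()
  a <- optimize_scheme(regimes$High, 50, grid, n_simulations = 25,
                       target_size = 6, seed = 99)
  b <- optimize_scheme(regimes$High, 50, grid, n_simulations = 25,
                       target_size = 6, seed = 99)
  expect_identical(a$bvalues, b$bvalues)
})
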