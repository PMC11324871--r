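test_that("spike detection finds strict local maxima with refractoriness", {
  times <- seq(0, 5000, by = 10)
  flat <- numeric(length(times))
  expect_equal(nrow(detect_spikes(flat, times)), 0)

  # single triangular pulse peaking at 3 mA -> one spike at the apex
  tri <- pmax(0, 3 - abs(times - 2000) / 100)
  got <- detect_spikes(tri, times, threshold = 1)
  expect_equal(nrow(got), 1)
  expect_equal(got$t_ns, 2000)
  expect_equal(got$peak_mA, 3)

  # sub-threshold peaks are ignored
  expect_equal(nrow(detect_spikes(0.2 * tri, times, threshold = 1)), 0)

  # two pulses 100 ns apart with min_separation 200 -> second suppressed;
  # brute-force scan is the oracle
  two <- pmax(0, 3 - abs(times - 2000) / 30) + pmax(0, 3 - abs(times - 2100) / 30)
  got2 <- detect_spikes(two, times, threshold = 1, min_separation = 200)
  oracle <- brute_force_spikes(two, times, threshold = 1, min_sep = 200)
  expect_equal(got2$t_ns, oracle)
  expect_equal(length(oracle), 1)

  # random traces agree with the oracle (property)
  set.seed(31)
  for (i in 1:20) {
    x <- abs(stats::rnorm(200, sd = 2))
    got3 <- detect_spikes(x, times[1:200], threshold = 1, min_separation = 50)
    expect_equal(got3$t_ns, brute_force_spikes(x, times[1:200], 1, 50))
  }
})

test_that("the streaming detector of the integrator matches detect_spikes", {
  cfg <- lattice_config(2, 2, v_in = 11.5, t_total = 40, t_transient = 0,
                        params = quiet_params(), record = "currents")
  sim <- simulate_lattice(cfg)
  ref <- detect_spikes(sim$traces, sim$trace_t_ns,
                       threshold = cfg$spike_threshold,
                       min_separation = cfg$min_separation,
                       n_rows = 2, n_cols = 2)
  expect_gt(nrow(sim$spikes), 0)
  expect_equal(sim$spikes$t_ns, ref$t_ns)
  expect_equal(sim$spikes$row, ref$row)
  expect_equal(sim$spikes$peak_mA, ref$peak_mA, tolerance = 1e-12)
})

test_that("coarse graining uses half-open bins and conserves spike counts", {
  sp <- data.frame(row = c(0, 1, 1), col = c(0, 0, 0),
                   t_ns = c(0, 399, 400), peak_mA = 2)
  occ <- coarse_grain(sp, 2, 1, window_ns = 400)
  expect_equal(dim(occ), c(2, 1, 2))
  expect_equal(occ[1, 1, 1], 1)   # t = 0 lands in the first bin
  expect_equal(occ[2, 1, 1], 1)   # t = 399 in the first bin
  expect_equal(occ[2, 1, 2], 1)   # t = 400 in the next (half-open)
  expect_equal(sum(occ), nrow(sp))

  set.seed(8)
  spr <- data.frame(row = sample(0:3, 200, TRUE), col = sample(0:4, 200, TRUE),
                    t_ns = runif(200, 0, 8000), peak_mA = 1)
  expect_equal(sum(coarse_grain(spr, 4, 5, 400)), 200)
})

test_that("Hoshen-Kopelman labelling handles the canonical small cases", {
  occ <- array(0L, c(3, 3, 2)); attr(occ, "window_ns") <- 400
  occ[2, 2, 1] <- 1L
  av <- label_avalanches(occ)
  expect_equal(av$sizes, 1L)

  # spatially adjacent sites in one bin form a single avalanche
  occ[2, 3, 1] <- 1L
  expect_equal(label_avalanches(occ)$sizes, 2L)

  # diagonal neighbours do not merge
  occ2 <- array(0L, c(3, 3, 1)); occ2[1, 1, 1] <- 1L; occ2[2, 2, 1] <- 1L
  expect_equal(sort(label_avalanches(occ2)$sizes), c(1L, 1L))

  # the same site in adjacent bins merges through time
  occ3 <- array(0L, c(2, 2, 3)); occ3[1, 1, 1] <- 2L; occ3[1, 1, 2] <- 1L
  expect_equal(label_avalanches(occ3)$sizes, 3L)            # spike count
  expect_equal(label_avalanches(occ3, size_measure = "cells")$sizes, 2L)
})

test_that("cluster sizes equal the BFS oracle on random lattices", {
  set.seed(99)
  for (i in 1:100) {
    dims <- c(sample(3:7, 1), sample(3:7, 1), sample(3:8, 1))
    occ <- random_occupancy(dims, density = runif(1, 0.1, 0.5))
    av <- label_avalanches(occ)
    expect_equal(sort(av$sizes), sort(bfs_avalanche_sizes(occ)))
    expect_equal(sum(av$sizes), sum(occ))  # spike-count conservation
    av2 <- label_avalanches(occ, size_measure = "cells")
    expect_equal(sort(av2$sizes),
                 sort(bfs_avalanche_sizes(occ, size_measure = "cells")))
  }
  # larger spatial reach merges over Manhattan distance 2
  occ <- array(0L, c(5, 5, 1)); occ[1, 1, 1] <- 1L; occ[1, 3, 1] <- 1L
  attr(occ, "window_ns") <- 400
  expect_equal(label_avalanches(occ, spatial_reach = 2)$sizes, 2L)
  expect_equal(sort(label_avalanches(occ, spatial_reach = 2)$sizes),
               sort(bfs_avalanche_sizes(occ, spatial_reach = 2)))
})

test_that("labelling is invariant under spike-event order", {
  set.seed(17)
  sp <- data.frame(row = sample(0:5, 300, TRUE), col = sample(0:5, 300, TRUE),
                   t_ns = runif(300, 0, 4000), peak_mA = 1)
  occ1 <- coarse_grain(sp, 6, 6, 400, 10)
  occ2 <- coarse_grain(sp[sample(nrow(sp)), ], 6, 6, 400, 10)
  expect_identical(occ1, occ2)
  expect_equal(sort(label_avalanches(occ1)$sizes),
               sort(label_avalanches(occ2)$sizes))
})

test_that("log-binned histograms are normalised and Scott-sized", {
  h <- size_histogram(c(1, 10, 100), bin_width_log10 = 1)
  expect_equal(nrow(h$table), 3)
  expect_equal(h$table$count, c(1, 1, 1))
  # densities integrate to one against linear bin width
  lin_w <- 10^h$table$hi10 - 10^h$table$lo10
  expect_equal(sum(h$table$density * lin_w), 1)

  s <- synth_powerlaw_sizes(2, 1, 1000, n = 5000, seed = 3)
  hs <- size_histogram(s)
  expect_false(hs$degenerate)
  expect_equal(hs$bin_width_log10,
               3.49 * stats::sd(log10(s)) * length(s)^(-1 / 3))
  lw <- 10^hs$table$hi10 - 10^hs$table$lo10
  expect_equal(sum(hs$table$density * lw), 1)

  hd <- size_histogram(rep(7, 50))
  expect_true(hd$degenerate)
  expect_error(size_histogram(numeric(0)), "non-empty")
})

test_that("power-law fits recover exact and sampled exponents", {
  # noiseless line in log-log space: exact recovery with r^2 = 1
  s <- 10^seq(0, 3, by = 0.25)
  fit <- fit_power_law(s, densities = s^(-1.5))
  expect_true(fit$success)
  expect_equal(fit$exponent, 1.5, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # sampling oracle: truncated s^-2, 1e4 draws
  sizes <- synth_powerlaw_sizes(2, 1, 1000, n = 1e4, seed = 11)
  fit2 <- fit_power_law(size_histogram(sizes))
  expect_true(fit2$success)
  expect_lt(abs(fit2$exponent - 2), 0.15)

  # guards: too few usable bins, degenerate histogram
  expect_false(fit_power_law(c(1, 10), densities = c(1, 0.1))$success)
  expect_false(fit_power_law(size_histogram(rep(3, 20)))$success)
})
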