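test_that("zero-flux Laplacian matches the stencil on interior, edge, corner", {
  T <- matrix(300, 5, 4)
  expect_true(all(lattice_laplacian(T) == 0))

  T2 <- T; T2[3, 2] <- 310
  L <- lattice_laplacian(T2)
  expect_equal(L[3, 2], -40)
  expect_equal(L[2, 2], 10)
  expect_equal(L[4, 2], 10)
  expect_equal(L[3, 1], 10)
  expect_equal(L[3, 3], 10)
  expect_equal(sum(L), 0)  # conservation under zero flux

  T3 <- T; T3[1, 1] <- 305  # corner has two neighbours
  expect_equal(lattice_laplacian(T3)[1, 1], -10)
  T4 <- T; T4[1, 2] <- 305  # edge has three
  expect_equal(lattice_laplacian(T4)[1, 2], -15)
})

test_that("configuration validation catches inconsistent inputs", {
  expect_error(lattice_config(2, 2, v_in = matrix(1, 3, 3)), "must be 2 x 2")
  expect_error(lattice_config(2, 2, v_in = 10, dt = 0), "dt")
  expect_error(lattice_config(2, 2, v_in = 10, t_total = 1, t_transient = 2),
               "t_total")
  expect_error(lattice_config(0, 2, v_in = 10), "positive")
  expect_error(lattice_config(2, 2, v_in = -1), "v_in")
})

test_that("the unbiased rest state is a fixed point of the drift", {
  cfg <- lattice_config(2, 2, v_in = 0, params = quiet_params())
  st <- new_lattice_state(cfg)
  st2 <- lattice_step(st, cfg)
  expect_equal(st2$V, st$V)
  expect_equal(st2$T, st$T)
})

test_that("below threshold the site settles at the insulating fixed point", {
  cfg <- lattice_config(1, 1, v_in = 5, t_total = 120, t_transient = 2,
                        params = quiet_params())
  sim <- simulate_lattice(cfg)
  expect_equal(nrow(sim$spikes), 0)
  V <- sim$final_state$V[1, 1]
  T <- sim$final_state$T[1, 1]
  hs <- hysteresis_state()  # branch never reverses below threshold
  R <- vo2_resistance(T, hs, cfg$params)
  RL <- cfg$params$R_load * 1e3
  # algebraic fixed point of the voltage equation at the settled R
  expect_equal(V, 5 * R / (R + RL), tolerance = 1e-5)
  # and of the heat balance
  expect_equal(V^2 / R, cfg$params$S_e * 1e-3 * (T - cfg$params$T0),
               tolerance = 1e-4)
})

test_that("identical configuration and seed reproduce spikes bit for bit", {
  cfg <- lattice_config(8, 8, v_in = 11, t_total = 30, t_transient = 2,
                        seed = 123)
  s1 <- simulate_lattice(cfg)
  s2 <- simulate_lattice(cfg)
  expect_gt(nrow(s1$spikes), 0)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$final_state, s2$final_state)
  s3 <- simulate_lattice(lattice_config(8, 8, v_in = 11, t_total = 30,
                                        t_transient = 2, seed = 124))
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("noise-free temperature stays within the energy-balance bound", {
  cfg <- lattice_config(1, 1, v_in = 12, t_total = 30, params = quiet_params())
  st <- new_lattice_state(cfg)
  p <- cfg$params
  bound <- p$T0 + 12^2 / p$R_m / (p$S_e * 1e-3)
  Tmax <- p$T0
  for (i in 1:3000) {
    st <- lattice_step(st, cfg)
    Tmax <- max(Tmax, st$T)
  }
  expect_gt(Tmax, p$T0 + 10)  # it did spike and heat up
  expect_lt(Tmax, bound)
})

test_that("uncoupled sites reproduce the single-neuristor trajectories", {
  p <- quiet_params(S_c = 0)  # thermally decoupled
  vmap <- matrix(c(10.5, 11, 11.5, 12), 2, 2)
  cfg <- lattice_config(2, 2, v_in = vmap, t_total = 40, t_transient = 2,
                        params = p)
  sim <- simulate_lattice(cfg)
  for (k in 1:4) {
    r <- (k - 1) %% 2; c <- (k - 1) %/% 2
    one <- simulate_lattice(lattice_config(1, 1, v_in = vmap[r + 1, c + 1],
                                           t_total = 40, t_transient = 2,
                                           params = p))
    got <- sim$spikes[sim$spikes$row == r & sim$spikes$col == c, ]
    expect_equal(got$t_ns, one$spikes$t_ns)
    expect_equal(got$peak_mA, one$spikes$peak_mA, tolerance = 1e-12)
  }
})

test_that("compiled integrator agrees with the R reference stepper", {
  # pre-spike charging phase: trajectories must agree to rounding error
  for (dims in list(c(1, 1), c(3, 2))) {
    cfg <- lattice_config(dims[1], dims[2], v_in = 10.5, t_total = 2,
                          t_transient = 0, params = quiet_params())
    sim <- simulate_lattice(cfg)
    st <- new_lattice_state(cfg)
    for (i in seq_len(200)) st <- lattice_step(st, cfg)
    expect_equal(sim$final_state$V, st$V, tolerance = 1e-9)
    expect_equal(sim$final_state$T, st$T, tolerance = 1e-9)
    expect_equal(sim$final_state$delta, st$delta)
  }
  # across a full spike (branch reversals included) agreement stays tight
  cfg <- lattice_config(1, 1, v_in = 12, t_total = 8, t_transient = 0,
                        params = quiet_params())
  sim <- simulate_lattice(cfg)
  st <- new_lattice_state(cfg)
  for (i in seq_len(800)) st <- lattice_step(st, cfg)
  expect_equal(sim$final_state$T, st$T, tolerance = 1e-6)
  expect_equal(sim$final_state$delta, st$delta)
})

test_that("rectangular lattices are supported end to end", {
  cfg <- lattice_config(3, 5, v_in = 11, t_total = 20, t_transient = 2,
                        seed = 5)
  sim <- simulate_lattice(cfg)
  expect_equal(sim$n_rows, 3)
  expect_equal(sim$n_cols, 5)
  expect_true(all(sim$spikes$row >= 0 & sim$spikes$row < 3))
  expect_true(all(sim$spikes$col >= 0 & sim$spikes$col < 5))
  expect_true(!is.unsorted(sim$spikes$t_ns))
})

test_that("spike events round-trip through the CSV interface", {
  cfg <- lattice_config(4, 4, v_in = 11, t_total = 20, t_transient = 2,
                        seed = 9)
  sim <- simulate_lattice(cfg)
  path <- tempfile(fileext = ".csv")
  write_spikes(sim, path)
  expect_equal(readLines(path, n = 1), "row,col,t_ns,peak_mA")
  back <- read_spikes(path)
  expect_equal(back$row, sim$spikes$row)
  expect_equal(back$t_ns, sim$spikes$t_ns)
})
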