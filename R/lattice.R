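#' Configuration of a lattice simulation
#'
#' Describes one simulation of an `n_rows x n_cols` array of identical
#' thermal neuristors: per-site input voltages, device constants, the
#' Euler-Maruyama step, total and transient durations, spike-detection
#' settings and the RNG seed. Times are given in the externally used units
#' (`dt` in ns, durations in us); the integrator converts to SI internally.
#'
#' @param n_rows,n_cols lattice dimensions (positive integers); rectangular
#'   grids are supported.
#' @param v_in input voltage (V): a scalar broadcast to every site, or an
#'   `n_rows x n_cols` matrix.
#' @param params a [device_params()].
#' @param dt integration step (ns), default 10.
#' @param t_total simulated duration (us).
#' @param t_transient discarded warm-up (us), default 2 (several insulating
#'   RC times); spikes before this are not reported.
#' @param seed integer RNG seed; identical configurations and seeds give
#'   bit-identical results.
#' @param record `"spikes"` (default) or `"currents"` to additionally keep
#'   the dense per-site current traces of the recording window.
#' @param spike_threshold minimum peak current (mA) for a local maximum to
#'   count as a spike, default 1 (between the insulating ~0.2 mA and
#'   metallic several-mA current scales).
#' @param min_separation refractory separation between accepted spikes at
#'   one site (ns), default 200 (about the metallic RC time).
#' @param deadband hysteresis-reversal deadband (K), see [update_branch()]; default 0.25.
#' @param trace_stride keep every `trace_stride`-th sample when recording
#'   current traces.
#'
#' @return An object of class `lattice_config`.
#' @export
lattice_config <- function(n_rows, n_cols = n_rows, v_in, params = device_params(),
                           dt = 10, t_total = 100, t_transient = 2, seed = 1,
                           record = c("spikes", "currents"),
                           spike_threshold = 1, min_separation = 200,
                           deadband = 0.25, trace_stride = 1L) {
  record <- match.arg(record)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1 || n_cols < 1) stop("lattice dimensions must be positive")
  if (is.matrix(v_in)) {
    if (!all(dim(v_in) == c(n_rows, n_cols)))
      stop("v_in matrix must be ", n_rows, " x ", n_cols)
  } else {
    if (length(v_in) != 1L) stop("v_in must be a scalar or a matrix")
    v_in <- matrix(v_in, n_rows, n_cols)
  }
  if (any(!is.finite(v_in)) || any(v_in < 0)) stop("v_in must be finite and >= 0")
  if (dt <= 0) stop("dt must be positive")
  if (t_total < t_transient || t_transient < 0)
    stop("need t_total >= t_transient >= 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, v_in = v_in,
                 params = params, dt = dt, t_total = t_total,
                 t_transient = t_transient, seed = as.integer(seed),
                 record = record, spike_threshold = spike_threshold,
                 min_separation = min_separation, deadband = deadband,
                 trace_stride = as.integer(trace_stride)),
            class = "lattice_config")
}

#' Discrete Laplacian with zero-flux boundaries
#'
#' Nearest-neighbour (von Neumann) Laplacian of a field on the lattice:
#' each interior site receives the sum of the four neighbour differences;
#' at edges and corners the missing neighbours contribute nothing (no heat
#' flows past the array boundary).
#'
#' @param T a numeric matrix (e.g. the temperature field, K).
#' @return A matrix of the same shape.
#' @export
lattice_laplacian <- function(T) {
  stopifnot(is.matrix(T))
  nr <- nrow(T); nc <- ncol(T)
  s <- matrix(0, nr, nc)
  if (nr > 1) {
    s[-nr, ] <- s[-nr, ] + T[-1, , drop = FALSE] - T[-nr, , drop = FALSE]
    s[-1, ] <- s[-1, ] + T[-nr, , drop = FALSE] - T[-1, , drop = FALSE]
  }
  if (nc > 1) {
    s[, -nc] <- s[, -nc] + T[, -1, drop = FALSE] - T[, -nc, drop = FALSE]
    s[, -1] <- s[, -1] + T[, -nc, drop = FALSE] - T[, -1, drop = FALSE]
  }
  s
}

#' Initial lattice state
#'
#' The standard cold start: capacitors discharged (`V = 0`), every site at
#' ambient temperature, virgin major heating branch.
#'
#' @param cfg a [lattice_config()].
#' @return A list with matrices `V` (V), `T` (K), per-site hysteresis fields
#'   `delta`, `T_r`, `T_pr`, `T_ext`, and the current time `t_ns`.
#' @export
new_lattice_state <- function(cfg) {
  nr <- cfg$n_rows; nc <- cfg$n_cols
  T0 <- cfg$params$T0
  list(V = matrix(0, nr, nc), T = matrix(T0, nr, nc),
       delta = matrix(1, nr, nc), T_r = matrix(250, nr, nc),
       T_pr = matrix(0, nr, nc), T_ext = matrix(T0, nr, nc),
       t_ns = 0)
}

#' One Euler-Maruyama step of the lattice dynamics (reference implementation)
#'
#' Advances the coupled electro-thermal dynamics by one step `dt`:
#' the capacitor voltage follows
#' `C dV/dt = V_in/R_load - V (1/R + 1/R_load)` and the temperature
#' `C_th dT/dt = V^2/R - S_e (T - T0) + S_c lap(T) + sigma eta(t)`,
#' with `R` the hysteretic VO2 resistance at the current state. Noise enters
#' the temperature equation only, as `(sigma/C_th) sqrt(dt) xi` with `xi`
#' standard normal. The hysteresis branch is updated after the temperature
#' update. This pure-R stepper mirrors the compiled integrator used by
#' [simulate_lattice()] and serves as its cross-check.
#'
#' @param state a lattice state as returned by [new_lattice_state()] or a
#'   previous `lattice_step()`.
#' @param cfg a [lattice_config()].
#' @param xi optional matrix of standard-normal draws (one per site); if
#'   `NULL` and `sigma > 0`, drawn from the current RNG state.
#' @return The updated state.
#' @export
lattice_step <- function(state, cfg, xi = NULL) {
  p <- params_si(cfg$params)
  dt <- cfg$dt * 1e-9
  V <- state$V; T <- state$T
  F <- hyst_F(as.vector(T), as.vector(state$delta), as.vector(state$T_r),
              as.vector(state$T_pr), p$w, p$T_c, p$beta, p$gamma)
  R <- matrix(vo2_R_vec(as.vector(T), F, p$logR0, p$E_a, p$R_m),
              nrow(T), ncol(T))
  lap <- lattice_laplacian(T)
  Vn <- V + (dt / p$C) * (cfg$v_in / p$R_load - V * (1 / R + 1 / p$R_load))
  Tn <- T + (dt / p$C_th_eff) * (V^2 / R - p$S_e * (T - p$T0) + p$S_c * lap)
  if (p$sigma > 0) {
    if (is.null(xi)) xi <- matrix(stats::rnorm(length(T)), nrow(T), ncol(T))
    Tn <- Tn + (p$sigma / p$C_th_eff) * sqrt(dt) * xi
  }
  if (any(!is.finite(Vn)) || any(!is.finite(Tn))) {
    k <- which(!is.finite(Vn) | !is.finite(Tn))[1]
    stop(sprintf("simulation diverged at site (row %d, col %d), t = %g ns",
                 (k - 1) %% nrow(T), (k - 1) %/% nrow(T), state$t_ns))
  }

  # branch update with deadband, vectorised
  delta <- state$delta; T_r <- state$T_r; T_pr <- state$T_pr; T_ext <- state$T_ext
  heat <- delta > 0
  adv <- (heat & Tn >= T_ext) | (!heat & Tn <= T_ext)
  T_ext[adv] <- Tn[adv]
  flip <- !adv & abs(T_ext - Tn) > cfg$deadband
  if (any(flip)) {
    anchor <- anchor_clamp(T_ext[flip], cfg$params)
    Frev <- hyst_F(anchor, delta[flip], T_r[flip], T_pr[flip],
                   p$w, p$T_c, p$beta, p$gamma)
    nd <- -delta[flip]
    T_r[flip] <- anchor
    T_pr[flip] <- reversal_T_pr(Frev, nd, anchor, cfg$params)
    delta[flip] <- nd
    T_ext[flip] <- Tn[flip]
  }
  list(V = Vn, T = Tn, delta = delta, T_r = T_r, T_pr = T_pr, T_ext = T_ext,
       t_ns = state$t_ns + cfg$dt)
}

#' Simulate a thermal neuristor lattice
#'
#' Integrates the coupled electro-thermal dynamics from the standard cold
#' start ([new_lattice_state()]) for `t_total` microseconds at step `dt`,
#' with per-site Gaussian thermal noise, streaming spike detection (strict
#' local maxima of the per-site current `I = V/R` above the threshold, with
#' a refractory separation) and optional dense current traces. Events in the
#' first `t_transient` microseconds are discarded; reported spike times are
#' relative to the start of the recording window.
#'
#' @param cfg a [lattice_config()].
#' @return An object of class `neuristor_sim` with elements
#'   `spikes` (data frame `row`, `col` 0-based, `t_ns`, `peak_mA`,
#'   time-sorted), `n_rows`, `n_cols`, `duration_us` (recorded window),
#'   `final_state`, and, when `record = "currents"`, `traces`
#'   (time x site matrix, mA) and `trace_t_ns`.
#' @examples
#' cfg <- lattice_config(1, 1, v_in = 12, t_total = 20,
#'                       params = device_params(sigma = 0))
#' sim <- simulate_lattice(cfg)
#' sim
#' @export
simulate_lattice <- function(cfg) {
  stopifnot(inherits(cfg, "lattice_config"))
  p <- params_si(cfg$params)
  dt <- cfg$dt * 1e-9
  n_steps <- as.integer(round(cfg$t_total * 1e-6 / dt))
  record_from <- cfg$t_transient * 1e-6
  set.seed(cfg$seed)
  res <- cpp_simulate_lattice(cfg$v_in, p, dt, n_steps, record_from,
                              cfg$spike_threshold * 1e-3,
                              cfg$min_separation * 1e-9,
                              cfg$deadband,
                              cfg$record == "currents", cfg$trace_stride)
  # times are integer multiples of dt; rounding removes float residue so
  # they survive text round-trips and bin-edge arithmetic exactly
  spikes <- data.frame(row = res$row, col = res$col,
                       t_ns = round((res$t - record_from) * 1e9, 3),
                       peak_mA = res$peak * 1e3)
  out <- list(spikes = spikes, n_rows = cfg$n_rows, n_cols = cfg$n_cols,
              duration_us = cfg$t_total - cfg$t_transient,
              config = cfg,
              final_state = list(V = res$V, T = res$T, delta = res$delta,
                                 T_r = res$T_r, T_pr = res$T_pr,
                                 T_ext = res$T_ext))
  if (cfg$record == "currents") {
    out$traces <- res$traces * 1e3
    out$trace_t_ns <- round((res$trace_t - record_from) * 1e9, 3)
  }
  structure(out, class = "neuristor_sim")
}

#' @export
print.neuristor_sim <- function(x, ...) {
  n_sites <- x$n_rows * x$n_cols
  cat(sprintf("thermal neuristor simulation: %d x %d lattice, %.3g us recorded\n",
              x$n_rows, x$n_cols, x$duration_us))
  cat(sprintf("  %d spikes (%.4g spikes/site/us)\n", nrow(x$spikes),
              nrow(x$spikes) / (n_sites * x$duration_us)))
  invisible(x)
}

#' Write spike events to CSV
#'
#' Columns `row,col,t_ns,peak_mA` with 0-based site indices and times in ns
#' relative to the start of the recording window.
#'
#' @param sim a `neuristor_sim` or a spike data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(sim, path) {
  spikes <- if (inherits(sim, "neuristor_sim")) sim$spikes else sim
  utils::write.csv(spikes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spike events from CSV
#'
#' @param path a CSV written by [write_spikes()].
#' @return A spike data frame (`row`, `col`, `t_ns`, `peak_mA`).
#' @export
read_spikes <- function(path) {
  utils::read.csv(path, colClasses = c(row = "integer", col = "integer",
                                       t_ns = "numeric", peak_mA = "numeric"))
}
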