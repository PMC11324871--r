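#' Order parameters of a spike train
#'
#' Two summary statistics of collective activity on the lattice:
#' the mean firing rate (spikes per site per microsecond) and a population
#' spike-time coherence in `[0, 1]`. For the coherence, each site's spike
#' train is binned into `bin_ns` windows as a binary indicator `a_i(t)`;
#' the coherence is `Var_t(A(t)) / mean_i Var_t(a_i(t))` with `A(t)` the
#' population mean, i.e. the classical variance-ratio synchrony measure:
#' 1 when all sites spike in identical bins, of order `1/n_sites` for
#' independent trains, and defined as 0 when there are no spikes.
#'
#' @param spikes a spike data frame (`row`, `col`, `t_ns`).
#' @param n_rows,n_cols lattice shape.
#' @param duration_us duration of the recording window (us).
#' @param bin_ns coherence bin length (ns), default 400.
#' @return A list with `firing_rate` and `synchrony`.
#' @export
order_parameters <- function(spikes, n_rows, n_cols, duration_us, bin_ns = 400) {
  stopifnot(duration_us > 0)
  n_sites <- n_rows * n_cols
  rate <- nrow(spikes) / (n_sites * duration_us)
  if (!nrow(spikes)) return(list(firing_rate = 0, synchrony = 0))
  n_windows <- ceiling(duration_us * 1e3 / bin_ns)
  occ <- coarse_grain(spikes, n_rows, n_cols, bin_ns, n_windows)
  a <- matrix(as.numeric(occ > 0), n_sites, n_windows)  # site x bin indicator
  A <- colMeans(a)
  var_pop <- function(x) mean((x - mean(x))^2)
  num <- var_pop(A)
  den <- mean(apply(a, 1, var_pop))
  sync <- if (den == 0) 1 else min(1, num / den)
  list(firing_rate = rate, synchrony = sync)
}

#' Classify the dynamical phase of a lattice operating point
#'
#' A pure function of the order parameters and the avalanche power-law fit:
#' `quiescent` when the firing rate is below `rate_eps`; otherwise `rigid`
#' when the synchrony is at least `sync_hi` (collective spiking in unison);
#' otherwise `LRO-candidate` when the avalanche-size histogram admits a
#' successful power-law fit with `r^2 >= 0.98` spanning at least two decades
#' (the long-range-order signature); otherwise `uncorrelated`.
#'
#' @param firing_rate spikes per site per us.
#' @param synchrony population coherence in `[0, 1]`.
#' @param fit a [fit_power_law()] result, or `NULL`.
#' @param rate_eps quiescence threshold (spikes/site/us), default 1e-3.
#' @param sync_hi rigid-phase coherence threshold, default 0.8.
#' @return One of `"quiescent"`, `"rigid"`, `"LRO-candidate"`,
#'   `"uncorrelated"`.
#' @export
classify_phase <- function(firing_rate, synchrony, fit = NULL,
                           rate_eps = 1e-3, sync_hi = 0.8) {
  if (firing_rate < rate_eps) return("quiescent")
  if (synchrony >= sync_hi) return("rigid")
  if (!is.null(fit) && isTRUE(fit$success) && fit$r_squared >= 0.98 &&
      log10(fit$fit_range[2] / fit$fit_range[1]) >= 2)
    return("LRO-candidate")
  "uncorrelated"
}

#' Sweep input voltage and relative thermal capacitance
#'
#' Runs one independently seeded simulation per grid point of
#' `v_in x cth_scale`, computes the order parameters and the avalanche
#' power-law fit, and classifies the phase of each point. Points are
#' mutually independent; results do not depend on execution order. Failures
#' at individual points are recorded (`label = "error"`) and the sweep
#' continues.
#'
#' @param v_in input voltages (V) to sweep.
#' @param cth_scale relative thermal capacitances to sweep, default 1.
#' @param n_rows,n_cols lattice shape, default 32 x 32.
#' @param t_total,t_transient durations (us) per point.
#' @param params base [device_params()]; `cth_scale` is overridden per point.
#' @param seed master seed; each grid point derives its own sub-seed.
#' @param window_ns avalanche/coherence bin (ns), default 400.
#' @param spatial_reach avalanche spatial radius, default 1.
#' @param rate_eps,sync_hi classification thresholds, see [classify_phase()].
#' @param min_count power-law tail-exclusion count, see [fit_power_law()].
#' @param verbose print one line per grid point.
#' @return A data frame of class `phase_sweep` with columns `v_in`,
#'   `cth_scale`, `firing_rate`, `synchrony`, `pl_exponent` (absolute value,
#'   capped at 6), `pl_r2`, `label`, in grid order (`v_in` varying fastest).
#' @export
phase_sweep <- function(v_in, cth_scale = 1, n_rows = 32, n_cols = n_rows,
                        t_total = 500, t_transient = 2,
                        params = device_params(), seed = 1, window_ns = 400,
                        spatial_reach = 1, rate_eps = 1e-3, sync_hi = 0.8,
                        min_count = 10, verbose = FALSE) {
  grid <- expand.grid(v_in = v_in, cth_scale = cth_scale,
                      KEEP.OUT.ATTRS = FALSE)
  if (!nrow(grid)) stop("sweep grid is empty")
  res <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    p_i <- params
    p_i$cth_scale <- grid$cth_scale[i]
    seed_i <- (seed + 1009L * i) %% 2147483647L
    row <- data.frame(v_in = grid$v_in[i], cth_scale = grid$cth_scale[i],
                      firing_rate = NA_real_, synchrony = NA_real_,
                      pl_exponent = NA_real_, pl_r2 = NA_real_,
                      label = "error", stringsAsFactors = FALSE)
    ok <- try({
      cfg <- lattice_config(n_rows, n_cols, v_in = grid$v_in[i], params = p_i,
                            t_total = t_total, t_transient = t_transient,
                            seed = seed_i)
      sim <- simulate_lattice(cfg)
      op <- order_parameters(sim$spikes, n_rows, n_cols, sim$duration_us,
                             window_ns)
      fit <- NULL
      if (nrow(sim$spikes)) {
        av <- avalanches(sim, window_ns, spatial_reach)
        fit <- fit_power_law(size_histogram(av$sizes), min_count = min_count)
      }
      row$firing_rate <- op$firing_rate
      row$synchrony <- op$synchrony
      if (!is.null(fit) && fit$success) {
        row$pl_exponent <- min(fit$exponent, 6)  # cap outliers for rendering
        row$pl_r2 <- fit$r_squared
      }
      row$label <- classify_phase(op$firing_rate, op$synchrony, fit,
                                  rate_eps, sync_hi)
    }, silent = TRUE)
    if (inherits(ok, "try-error")) row$label <- "error"
    if (verbose)
      message(sprintf("v_in = %g V, cth_scale = %g -> %s (rate %.3g, sync %.3g)",
                      row$v_in, row$cth_scale, row$label,
                      row$firing_rate, row$synchrony))
    res[[i]] <- row
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("phase_sweep", "data.frame")
  out
}
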