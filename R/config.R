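#' Aggregate run configuration
#'
#' Collects every tunable of a full analysis run -- device constants,
#' lattice shape and input voltage, integration and transient durations,
#' avalanche and classification settings, reservoir hyperparameters and the
#' master seed -- into one validated, serialisable object. Times are in the
#' externally used units (ns for steps and windows, us for durations).
#'
#' @param params a [device_params()].
#' @param n_rows,n_cols lattice shape.
#' @param v_in scalar input voltage (V).
#' @param dt integration step (ns).
#' @param t_total,t_transient durations (us).
#' @param window_ns avalanche temporal window (ns).
#' @param spatial_reach avalanche spatial radius (sites).
#' @param spike_threshold,min_separation spike detection (mA, ns).
#' @param deadband hysteresis reversal deadband (K).
#' @param rate_eps,sync_hi phase-classification thresholds.
#' @param min_count power-law tail-exclusion count.
#' @param v_lo,v_hi reservoir encoder anchors (V).
#' @param rc_t_sim,rc_bin_ns reservoir duration (us) and feature bin (ns).
#' @param epochs,lr,batch_size readout training hyperparameters.
#' @param seed master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(params = device_params(), n_rows = 16, n_cols = 16,
                       v_in = 11, dt = 10, t_total = 200, t_transient = 2,
                       window_ns = 400, spatial_reach = 1,
                       spike_threshold = 1, min_separation = 200,
                       deadband = 0.25, rate_eps = 1e-3, sync_hi = 0.8,
                       min_count = 10, v_lo = 10.5, v_hi = 12.2,
                       rc_t_sim = 10, rc_bin_ns = 500, epochs = 20,
                       lr = 1e-3, batch_size = 128, seed = 1) {
  cfg <- list(params = params, n_rows = as.integer(n_rows),
              n_cols = as.integer(n_cols), v_in = v_in, dt = dt,
              t_total = t_total, t_transient = t_transient,
              window_ns = window_ns, spatial_reach = as.integer(spatial_reach),
              spike_threshold = spike_threshold,
              min_separation = min_separation, deadband = deadband,
              rate_eps = rate_eps, sync_hi = sync_hi,
              min_count = as.integer(min_count), v_lo = v_lo, v_hi = v_hi,
              rc_t_sim = rc_t_sim, rc_bin_ns = rc_bin_ns,
              epochs = as.integer(epochs), lr = lr,
              batch_size = as.integer(batch_size), seed = as.integer(seed))
  if (cfg$t_total < cfg$t_transient || cfg$t_transient < 0)
    stop("need t_total >= t_transient >= 0")
  if (cfg$dt <= 0 || cfg$window_ns <= 0) stop("dt and window_ns must be positive")
  if (cfg$v_hi <= cfg$v_lo) stop("v_hi must exceed v_lo")
  structure(cfg, class = "run_config")
}

#' Write a run configuration as flat key/value text
#'
#' Sectioned INI-style plain text (`[device]` for the device constants,
#' `[run]` for everything else), one `key = value` per line; numbers are
#' written at full precision so that load -> save -> load is the identity.
#'
#' @param cfg a [run_config()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  fmt <- function(v) {
    if (is.integer(v)) as.character(v) else format(v, digits = 17)
  }
  lines <- c("[device]",
             vapply(names(unclass(cfg$params)), function(nm)
               paste(nm, "=", fmt(cfg$params[[nm]])), character(1)),
             "", "[run]",
             vapply(setdiff(names(cfg), "params"), function(nm)
               paste(nm, "=", fmt(cfg[[nm]])), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#'
#' @param path config file.
#' @return A [run_config()] object.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  section <- ""
  dev <- list(); run <- list()
  for (ln in lines) {
    if (startsWith(ln, "[")) { section <- gsub("\\[|\\]", "", ln); next }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1]); val <- as.numeric(trimws(kv[2]))
    if (section == "device") dev[[key]] <- val else run[[key]] <- val
  }
  run$params <- do.call(device_params, dev)
  do.call(run_config, run)
}

# Deterministic FNV-1a hash of the serialised config, for provenance logs.
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  write_run_config(cfg, tmp)
  bytes <- utf8ToInt(paste(readLines(tmp), collapse = "\n"))
  xor32 <- function(a, b)  # 32-bit xor without overflowing R integers
    bitwXor(a %% 65536, b %% 65536) + 65536 * bitwXor(a %/% 65536, b %/% 65536)
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime, kept exact in doubles
    lo <- ((h %% 65536) * 16777619) %% 4294967296
    hi <- ((((h %/% 65536) * 16777619) %% 65536) * 65536) %% 4294967296
    h <- (lo + hi) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
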