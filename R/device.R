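#' Device constants for a VO2 thermal neuristor
#'
#' Bundles the electrical, thermal and hysteresis constants of a single
#' thermal neuristor: a thin VO2 film in series with a load resistor, with a
#' parasitic capacitance across the film. Defaults are the calibrated values
#' used throughout the package (fitted against measured devices); all fields
#' are strictly positive.
#'
#' @param C capacitance across the VO2 film (pF).
#' @param R_load series load resistance (kOhm).
#' @param C_th thermal capacitance of one neuristor (pJ/K).
#' @param cth_scale dimensionless multiplier on `C_th`; phase diagrams sweep
#'   this "relative thermal capacitance" while `C_th` itself stays at its
#'   experimentally estimated value.
#' @param S_e thermal conductance from a neuristor to the environment (mW/K).
#' @param S_c thermal conductance between adjacent neuristors (uW/K).
#' @param T0 ambient temperature (K).
#' @param sigma thermal noise strength in calibrated noise units (one unit =
#'   0.01 uJ s^-1/2, i.e. stationary temperature fluctuations of ~0.07 K at
#'   the default thermal constants); enters the temperature equation as
#'   Gaussian white noise of intensity `sigma`. See the methods vignette for
#'   how this unit was fixed.
#' @param R0 insulating resistance prefactor (mOhm).
#' @param E_a activation energy of the insulating phase (K).
#' @param R_m metallic-state resistance (Ohm).
#' @param w width of the hysteresis loop (K).
#' @param T_c centre of the hysteresis loop (K).
#' @param beta sharpness of the transition (1/K).
#' @param gamma dimensionless shape parameter of the reversal-memory term.
#'
#' @return An object of class `device_params` (a named list).
#' @examples
#' p <- device_params()
#' time_constants(p)
#' @export
device_params <- function(C = 145, R_load = 12, C_th = 49.6, cth_scale = 1,
                          S_e = 0.201, S_c = 4.11, T0 = 325, sigma = 1,
                          R0 = 5.36, E_a = 5220, R_m = 1286, w = 7.19,
                          T_c = 332.8, beta = 0.253, gamma = 0.956) {
  p <- list(C = C, R_load = R_load, C_th = C_th, cth_scale = cth_scale,
            S_e = S_e, S_c = S_c, T0 = T0, sigma = sigma, R0 = R0,
            E_a = E_a, R_m = R_m, w = w, T_c = T_c, beta = beta,
            gamma = gamma)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("device parameter '", nm, "' must be a finite numeric scalar")
  }
  # sigma = 0 (noise off) and S_c = 0 (thermally decoupled sites) may be zero
  pos <- setdiff(names(p), c("sigma", "S_c"))
  bad <- pos[vapply(p[pos], function(v) v <= 0, logical(1))]
  if (length(bad)) stop("device parameters must be strictly positive: ",
                        paste(bad, collapse = ", "))
  if (p$sigma < 0) stop("sigma must be non-negative")
  if (p$S_c < 0) stop("S_c must be non-negative")
  structure(p, class = "device_params")
}

#' @export
print.device_params <- function(x, ...) {
  units <- c(C = "pF", R_load = "kOhm", C_th = "pJ/K", cth_scale = "",
             S_e = "mW/K", S_c = "uW/K", T0 = "K", sigma = "noise units",
             R0 = "mOhm", E_a = "K", R_m = "Ohm", w = "K", T_c = "K",
             beta = "1/K", gamma = "")
  cat("VO2 thermal neuristor parameters:\n")
  for (nm in names(units))
    cat(sprintf("  %-9s %10g %s\n", nm, x[[nm]], units[[nm]]))
  invisible(x)
}

# One noise unit in J s^-1/2. The noise strength is the one constant whose
# printed unit is inconsistent with the reported dynamics (taken literally as
# uJ s^-1/2 it yields ~7 K stationary temperature fluctuations, as wide as
# the hysteresis loop, and no phase structure survives); the unit is
# calibrated once so that sigma = 1 reproduces the reported phase sequence.
# See the methods vignette.
SIGMA_UNIT <- 1e-8

# Convert the user-facing table units to SI once, for the integrator and the
# scalar device functions. This is the single place units are normalised.
params_si <- function(p) {
  stopifnot(inherits(p, "device_params"))
  list(C = p$C * 1e-12,                       # F
       R_load = p$R_load * 1e3,               # Ohm
       C_th_eff = p$C_th * 1e-12 * p$cth_scale, # J/K
       S_e = p$S_e * 1e-3,                    # W/K
       S_c = p$S_c * 1e-6,                    # W/K
       T0 = p$T0,                             # K
       sigma = p$sigma * SIGMA_UNIT,          # J s^-1/2
       logR0 = log(p$R0 * 1e-3),              # log Ohm
       E_a = p$E_a, R_m = p$R_m,
       w = p$w, T_c = p$T_c, beta = p$beta, gamma = p$gamma,
       T_r_virgin = 250)
}

#' Hysteresis memory state of one VO2 film
#'
#' The VO2 resistance depends not only on temperature but on the film's
#' thermal history: whether temperature was last rising (`delta = +1`,
#' heating branch) or falling (`delta = -1`, cooling branch), and the
#' reversal temperature `T_r` at which the direction last changed. The
#' insulating fraction cached at the most recent reversal
#' (`F_at_reversal`) fixes the offset `T_pr` of the reversal-memory term, so
#' that each branch carries one level of memory of the last reversal.
#'
#' The default state is the *virgin* major heating branch: no reversal has
#' occurred, the memory term is identically zero (`T_pr = 0`) and the
#' resistance follows the pure major-loop curve.
#'
#' @param delta branch direction, `+1` (heating) or `-1` (cooling).
#' @param T_r reversal temperature (K) of the most recent branch flip.
#' @param F_at_reversal insulating fraction in `[0, 1]` evaluated with the
#'   pre-reversal state at `T_r`, or `NULL` for the virgin major branch.
#' @param params [device_params()] used to derive the memory offset `T_pr`.
#' @param T_ext running temperature extremum (K) since the last reversal,
#'   used by [update_branch()]'s deadband logic; `NA` until first update.
#'
#' @return An object of class `hysteresis_state`.
#' @examples
#' hs <- hysteresis_state()                 # virgin heating branch
#' vo2_resistance(300, hs, device_params())
#' @export
hysteresis_state <- function(delta = 1, T_r = 250, F_at_reversal = NULL,
                             params = device_params(), T_ext = NA_real_) {
  if (!delta %in% c(-1, 1)) stop("delta must be +1 or -1")
  if (!is.finite(T_r) || T_r <= 0) stop("T_r must be a positive temperature")
  T_anchor <- anchor_clamp(T_r, params)
  if (is.null(F_at_reversal)) {
    # virgin / major branch: memory term off
    T_pr <- 0
    F_at_reversal <- if (delta > 0) 1 else 0
  } else {
    if (F_at_reversal < 0 || F_at_reversal > 1)
      stop("F_at_reversal must lie in [0, 1]")
    T_pr <- reversal_T_pr(F_at_reversal, delta, T_anchor, params)
  }
  structure(list(delta = delta, T_r = T_r, T_anchor = T_anchor,
                 F_at_reversal = F_at_reversal,
                 T_pr = T_pr, T_ext = T_ext, T_prev = T_ext),
            class = "hysteresis_state")
}

#' @export
print.hysteresis_state <- function(x, ...) {
  br <- if (x$delta > 0) "heating" else "cooling"
  cat(sprintf("hysteresis state: %s branch, T_r = %.3f K, F(T_r) = %.4f, T_pr = %.4f K\n",
              br, x$T_r, x$F_at_reversal, x$T_pr))
  invisible(x)
}

# The reversal-memory term encodes the frozen insulating/metallic domain
# mixture at the reversal point, which only exists inside the transition
# window. The memory anchor therefore saturates at the window edges
# T_c +/- (w/2 + 2/beta): a reversal further out carries no additional
# information, and an unbounded anchor would make |T_pr| grow with the
# post-spike temperature overshoot and invert the loop. Mirrored in the
# compiled integrator.
anchor_clamp <- function(T, params) {
  half <- params$w / 2 + 2 / params$beta
  pmin(pmax(T, params$T_c - half), params$T_c + half)
}

reversal_T_pr <- function(F_rev, delta_new, T_r, params) {
  delta_new * params$w / 2 + params$T_c -
    (2 * F_rev - 1) / params$beta - T_r
}

# Vectorised insulating fraction; `delta`, `T_r`, `T_pr` recycle against `T`.
# T_pr == 0 encodes the pure major branch (memory term off).
hyst_F <- function(T, delta, T_r, T_pr, w, T_c, beta, gamma) {
  shift <- numeric(length(T))
  mem <- rep_len(T_pr != 0, length(T))
  if (any(mem)) {
    Tp <- rep_len(T_pr, length(T))[mem]
    x <- (T[mem] - rep_len(T_r, length(T))[mem]) / Tp
    P <- 0.5 * (1 - sin(gamma * x)) * (1 + tanh(pi^2 - 2 * pi * x))
    P <- pmin(pmax(P, 0), 1)  # full offset near the reversal, none far away
    shift[mem] <- Tp * P
  }
  0.5 + 0.5 * tanh(beta * (rep_len(delta, length(T)) * w / 2 + T_c - (T + shift)))
}

#' Insulating fraction F(T) of the hysteretic transition
#'
#' The fraction interpolating between the insulating (`F = 1`) and metallic
#' (`F = 0`) limits of the VO2 film, on the branch described by `hs`. On the
#' major heating branch it crosses 1/2 at `T_c + w/2`; on the major cooling
#' branch at `T_c - w/2`.
#'
#' @param T temperature(s) in kelvin.
#' @param hs a [hysteresis_state()].
#' @param params a [device_params()].
#' @return Numeric vector of values in `[0, 1]`.
#' @export
hysteresis_fraction <- function(T, hs, params = device_params()) {
  stopifnot(inherits(hs, "hysteresis_state"))
  if (any(!is.finite(T))) stop("temperature must be finite")
  hyst_F(T, hs$delta, hs$T_anchor, hs$T_pr, params$w, params$T_c,
         params$beta, params$gamma)
}

# log-space guarded R(T); T in K, result in Ohm; F may be 0.
vo2_R_vec <- function(T, F, logR0_si, E_a, R_m) {
  l <- logR0_si + E_a / T + log(F)       # log(0) = -Inf -> exp = 0
  l <- pmin(l, 700)
  exp(l) + R_m
}

#' Hysteretic VO2 resistance
#'
#' Evaluates `R(T) = R0 exp(E_a / T) F(T) + R_m` with the insulating fraction
#' `F` of [hysteresis_fraction()]. The exponential is evaluated in log space
#' so low temperatures cannot overflow. `R` is bounded below by the metallic
#' resistance `R_m` and approaches it as `F -> 0`.
#'
#' @inheritParams hysteresis_fraction
#' @return Resistance(s) in Ohm.
#' @examples
#' p <- device_params()
#' vo2_resistance(300, hysteresis_state(), p)   # ~ 1.94e5 Ohm, insulating
#' @export
vo2_resistance <- function(T, hs, params = device_params()) {
  if (any(!is.finite(T)) || any(T <= 0))
    stop("temperature must be finite and positive")
  F <- hysteresis_fraction(T, hs, params)
  psi <- params_si(params)
  vo2_R_vec(T, F, psi$logR0, psi$E_a, psi$R_m)
}

#' Update the hysteresis branch after a temperature move
#'
#' Tracks the running temperature extremum since the last reversal and flips
#' the branch only when temperature has retreated from that extremum by more
#' than `deadband`. This suppresses spurious reversals from per-step noise
#' jitter while preserving genuine heating/cooling turnarounds. At a flip the
#' insulating fraction is evaluated once with the pre-flip state at the
#' extremal temperature and cached as the new `F_at_reversal`.
#'
#' @param hs a [hysteresis_state()].
#' @param T_new the temperature (K) after the latest integration step.
#' @param deadband reversal deadband (K); default 0.25 (a few per-step noise
#'   increments at the default noise strength, far below genuine
#'   heating/cooling excursions).
#' @param params a [device_params()].
#' @return The updated `hysteresis_state`.
#' @export
update_branch <- function(hs, T_new, deadband = 0.25, params = device_params()) {
  stopifnot(inherits(hs, "hysteresis_state"))
  if (!is.finite(T_new)) stop("T_new must be finite")
  if (is.na(hs$T_ext)) hs$T_ext <- T_new
  if (hs$delta > 0) {
    if (T_new >= hs$T_ext) {
      hs$T_ext <- T_new
    } else if (hs$T_ext - T_new > deadband) {
      anchor <- anchor_clamp(hs$T_ext, params)
      Frev <- hysteresis_fraction(anchor, hs, params)
      hs$delta <- -1
      hs$T_r <- hs$T_ext
      hs$T_anchor <- anchor
      hs$F_at_reversal <- Frev
      hs$T_pr <- reversal_T_pr(Frev, -1, anchor, params)
      hs$T_ext <- T_new
    }
  } else {
    if (T_new <= hs$T_ext) {
      hs$T_ext <- T_new
    } else if (T_new - hs$T_ext > deadband) {
      anchor <- anchor_clamp(hs$T_ext, params)
      Frev <- hysteresis_fraction(anchor, hs, params)
      hs$delta <- 1
      hs$T_r <- hs$T_ext
      hs$T_anchor <- anchor
      hs$F_at_reversal <- Frev
      hs$T_pr <- reversal_T_pr(Frev, 1, anchor, params)
      hs$T_ext <- T_new
    }
  }
  hs$T_prev <- T_new
  hs
}

#' Characteristic time scales of a thermal neuristor
#'
#' Three RC-type time constants govern the dynamics: the metallic electrical
#' time `tau_met = R_m C`, the thermal relaxation time
#' `tau_th = C_th / (S_c + S_e)` (with `C_th` scaled by `cth_scale`), and the
#' insulating electrical time `tau_ins = R_ins(T0) C`, where `R_ins(T0)` is
#' the insulating-branch resistance at ambient temperature (`F = 1`). Their
#' separation (`tau_met < tau_th << tau_ins`) is what lets the slow charging
#' dynamics act as a memory for the fast spiking dynamics.
#'
#' @param params a [device_params()].
#' @return Named numeric vector `c(tau_met_ns, tau_th_ns, tau_ins_ns)` in
#'   nanoseconds.
#' @examples
#' time_constants(device_params())  # ~ 187 ns, 242 ns, 7.5e3 ns
#' @export
time_constants <- function(params = device_params()) {
  psi <- params_si(params)
  tau_met <- psi$R_m * psi$C
  tau_th <- psi$C_th_eff / (psi$S_c + psi$S_e)
  R_ins <- vo2_R_vec(psi$T0, 1, psi$logR0, psi$E_a, psi$R_m)
  tau_ins <- R_ins * psi$C
  c(tau_met_ns = tau_met * 1e9, tau_th_ns = tau_th * 1e9,
    tau_ins_ns = tau_ins * 1e9)
}
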