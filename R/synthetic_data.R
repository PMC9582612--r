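# Seeded generator of benchtop-like and in-vivo-like measurement sets.
# Every dataset is a deterministic function of (spec, preset, seed), and
# generator-truth parameters travel with the data (attribute "truth") so
# downstream fits always have a recovery target.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Medium resistivity (Ohm m): phosphate-buffered saline vs cortical tissue.
medium_resistivity <- function(medium) {
  switch(medium, benchtop_saline = 0.7, in_vivo = 3.0,
         stop("unknown medium: ", medium))
}

#' Material preset for the synthetic-data generator
#'
#' Bundles the impedance-diameter scaling (`Zimag = alpha * D^d1`), the
#' electrolysis windows, the in-vivo impedance offset and the
#' generator-truth excitation-model parameters for one contact material.
#' Exponent defaults follow the reported material trends (`d1` near -1.67
#' for PtNR and -1.61 for planar Pt; pulse-width exponent near 0.9 for
#' PtNR, 0.8 for PEDOT and 1.1 for planar Pt; in-vivo impedance exponent
#' 1.08 for insertion-type and 1.04 for surface electrodes); scales with
#' no reported value are fixed at benchtop-plausible magnitudes.
#'
#' @param material One of the materials accepted by [electrode_spec()].
#' @return A list of class `"material_preset"` with fields `alpha` (Ohm
#'   m^-d1), `d1`, `n_dl`, `window_bench` / `window_invivo`
#'   ([electrolysis_window()], three-contact convention),
#'   `two_contact_widening`, `invivo_impedance_multiplier`, `k_true`
#'   ([safety_params()] benchtop truth) and `k6_invivo`.
#' @export
material_preset <- function(material = c("PtNR", "planar_Pt", "PEDOT",
                                         "clinical_depth", "sEEG",
                                         "strip")) {
  material <- match.arg(material)
  base <- list(
    PtNR = list(alpha = 6.6e-4, d1 = -1.67, n_dl = 0.92,
                win = c(-0.60, 0.80), a = 0.30, b = 1.0e-5,
                k2 = 1.00, k4 = 0.90, k6_invivo = 1.08),
    planar_Pt = list(alpha = 4.4e-3, d1 = -1.61, n_dl = 0.85,
                     win = c(-0.65, 0.85), a = 0.35, b = 2.0e-5,
                     k2 = 1.05, k4 = 1.10, k6_invivo = 1.08),
    PEDOT = list(alpha = 8.0e-4, d1 = -1.60, n_dl = 0.94,
                 win = c(-0.70, 0.70), a = 0.28, b = 1.2e-5,
                 k2 = 0.95, k4 = 0.80, k6_invivo = 1.08),
    clinical_depth = list(alpha = 2.0e-3, d1 = -1.60, n_dl = 0.88,
                          win = c(-0.60, 0.80), a = 0.32, b = 1.5e-5,
                          k2 = 1.00, k4 = 1.00, k6_invivo = 1.08),
    sEEG = list(alpha = 2.2e-3, d1 = -1.60, n_dl = 0.88,
                win = c(-0.60, 0.80), a = 0.32, b = 1.5e-5,
                k2 = 1.00, k4 = 1.00, k6_invivo = 1.08),
    strip = list(alpha = 1.8e-3, d1 = -1.60, n_dl = 0.90,
                 win = c(-0.60, 0.80), a = 0.32, b = 1.5e-5,
                 k2 = 1.00, k4 = 1.00, k6_invivo = 1.04)
  )[[material]]
  wb <- electrolysis_window(base$win[1], base$win[2])
  wi <- electrolysis_window(1.25 * base$win[1], 1.25 * base$win[2])
  structure(list(
    material = material,
    alpha = base$alpha, d1 = base$d1, n_dl = base$n_dl,
    window_bench = wb, window_invivo = wi,
    two_contact_widening = 1.6,
    invivo_impedance_multiplier = 2.0,
    k_true = safety_params(base$a, base$b, base$k2, base$k4, 1.0),
    k6_invivo = base$k6_invivo
  ), class = "material_preset")
}

#' Empirical geometric-correction-factor table
#'
#' Trend-faithful generator table for `G(D, S)` (1/m): `G` grows as the
#' contact diameter shrinks (current crowds into a smaller volume) and
#' falls as the edge-to-edge separation grows (current spreads through a
#' larger volume).
#'
#' @param diameter_m Contact diameter (m).
#' @param separation_factor Edge-to-edge separation as a multiple of the
#'   diameter.
#' @return Geometric correction factor `G` (1/m).
#' @export
geometric_factor_table <- function(diameter_m, separation_factor) {
  stopifnot(all(diameter_m > 0), all(separation_factor >= 1))
  (2 * pi / diameter_m) * (1 + 0.6 / separation_factor)
}

# Generator-truth 10 kHz reactance for a spec/preset pair (with jitter).
target_reactance <- function(spec, preset, jitter = 1) {
  z <- preset$alpha * spec$diameter_m^preset$d1 * jitter
  if (spec$medium == "in_vivo") z <- z * preset$invivo_impedance_multiplier
  z
}

#' Build an equivalent circuit for an electrode specification
#'
#' Sizes the interface CPE so the reactance magnitude at 10 kHz equals
#' `alpha * D^d1` (times a small seeded log-normal jitter), with the
#' in-vivo medium multiplying the interface impedance by the preset
#' offset. The spreading resistance follows `R = rho * G(D, S) / (4 pi)`
#' with `G` from [geometric_factor_table()].
#'
#' @param spec An [electrode_spec()].
#' @param preset A [material_preset()]; defaults to the preset of
#'   `spec$material`.
#' @param seed Integer seed controlling the jitter.
#' @return A [circuit_params()] with attribute `"truth"` (list with the
#'   target 10 kHz reactance and the spreading resistance).
#' @export
make_electrode <- function(spec, preset = material_preset(spec$material),
                           seed = 1L) {
  stopifnot(inherits(spec, "electrode_spec"),
            inherits(preset, "material_preset"))
  with_seed(seed, {
    jitter <- stats::rlnorm(1, 0, 0.02)
    z10k <- target_reactance(spec, preset, jitter)
    f0 <- 1e4
    n <- preset$n_dl
    # |Im Z_cpe|(f0) = sin(n pi/2) / (q (2 pi f0)^n)
    q_dl <- sin(n * pi / 2) / (z10k * (2 * pi * f0)^n)
    r_ct <- 200 * z10k
    iface <- interface_params(q_dl = q_dl, n_dl = n, r_ct = r_ct)
    rho <- medium_resistivity(spec$medium)
    g <- geometric_factor_table(spec$diameter_m, spec$separation_factor)
    r_spread <- rho * g / (4 * pi)
    med <- medium_params(r_spread = r_spread, r_ex = 0.3 * r_spread,
                         r_in = 0.6 * r_spread, c_in = 1e-8, r_lead = 20)
    out <- circuit_params(working = iface, counter = iface, medium = med)
    attr(out, "truth") <- list(z_imag_10k = z10k, r_spread = r_spread,
                               jitter = jitter)
    out
  })
}

# Apply magnitude/phase noise to a complex impedance vector.
perturb_spectrum <- function(z, noise) {
  if (noise$z_mag_rel_sd == 0 && noise$phase_sd_deg == 0) return(z)
  mag <- Mod(z) * stats::rlnorm(length(z), 0, noise$z_mag_rel_sd)
  ph <- Arg(z) + stats::rnorm(length(z), 0, noise$phase_sd_deg * pi / 180)
  complex(modulus = mag, argument = ph)
}

#' Generate a set of impedance spectra for one electrode
#'
#' Forward-simulates [configuration_spectrum()] for each requested wiring
#' configuration and applies the measurement-noise model.
#'
#' @param spec An [electrode_spec()].
#' @param preset A [material_preset()].
#' @param configs Character vector of configurations.
#' @param freqs Frequencies (Hz), ascending.
#' @param noise A [noise_spec()]; its seed drives both the electrode
#'   jitter and the measurement noise.
#' @return Named list of [eis_spectrum()] objects with attribute
#'   `"truth"` (the noise-free electrode).
#' @export
generate_eis_dataset <- function(spec, preset = material_preset(spec$material),
                                 configs = c("two_contact", "three_contact",
                                             "four_contact"),
                                 freqs = 10^seq(0, 5, length.out = 51),
                                 noise = noise_spec()) {
  if (length(configs) == 0) stop("configs must be non-empty")
  stopifnot(all(configs %in% c("two_contact", "three_contact",
                               "four_contact")))
  p <- make_electrode(spec, preset, seed = noise$seed)
  out <- with_seed(noise$seed + 1L, {
    lapply(configs, function(cfg) {
      s <- configuration_spectrum(p, cfg, freqs, meta = spec)
      eis_spectrum(freqs, perturb_spectrum(s$z, noise), config = cfg,
                   meta = spec)
    })
  })
  names(out) <- configs
  attr(out, "truth") <- list(circuit = p,
                             z_imag_10k = attr(p, "truth")$z_imag_10k)
  out
}

# Electrolysis window used by the generator for a given configuration.
generator_window <- function(spec, preset, config) {
  w <- if (spec$medium == "in_vivo") preset$window_invivo else
    preset$window_bench
  if (config == "two_contact") {
    w <- electrolysis_window(w$e_mc * preset$two_contact_widening,
                             w$e_ma * preset$two_contact_widening)
  }
  w
}

#' Generate a cyclic voltammetry sweep
#'
#' Capacitive baseline (`I = C_eff * scan_rate`) plus sharp exponential
#' electrolysis onsets outside the preset window. The window widens for
#' two-contact sweeps (the drop splits over both interfaces) and in vivo.
#'
#' @param spec An [electrode_spec()].
#' @param preset A [material_preset()].
#' @param scan_rate Scan rate (V/s); 0.2 V/s default.
#' @param v_range Length-2 sweep limits (V). The default (`NULL`) scans
#'   to 1.55 times each window edge, the usual practice of sweeping
#'   modestly past the expected onsets so the capacitive baseline region
#'   stays clear of them.
#' @param noise A [noise_spec()].
#' @param config `"two_contact"` or `"three_contact"`.
#' @param dv Potential sampling step (V).
#' @return A [cv_sweep()] with attribute `"truth"` (the generator window).
#'   If `v_range` does not span the window, attribute `"window_spanned"`
#'   is `FALSE`.
#' @export
generate_cv <- function(spec, preset = material_preset(spec$material),
                        scan_rate = 0.2, v_range = NULL,
                        noise = noise_spec(),
                        config = c("two_contact", "three_contact"),
                        dv = 0.002) {
  config <- match.arg(config)
  win <- generator_window(spec, preset, config)
  if (is.null(v_range)) v_range <- 1.55 * c(win$e_mc, win$e_ma)
  stopifnot(scan_rate > 0, length(v_range) == 2, v_range[1] < 0,
            v_range[2] > 0)
  p <- make_electrode(spec, preset, seed = noise$seed)
  # effective double-layer capacitance at ~1 Hz equivalent
  c_eff <- p$working$q_dl * (2 * pi)^(p$working$n_dl - 1)
  i_base <- c_eff * scan_rate
  beta <- 100  # 1/V; sharp "unrestricted increase" onset
  # triangular sweep 0 -> vmax -> vmin -> 0
  up1 <- seq(0, v_range[2], by = dv)
  down <- seq(v_range[2], v_range[1], by = -dv)
  up2 <- seq(v_range[1], 0, by = dv)
  v <- c(up1, down[-1], up2[-1])
  dir <- c(rep(1, length(up1)), rep(-1, length(down) - 1),
           rep(1, length(up2) - 1))
  i_el <- ifelse(v > win$e_ma, i_base * (exp(beta * (v - win$e_ma)) - 1), 0) -
    ifelse(v < win$e_mc, i_base * (exp(-beta * (v - win$e_mc)) - 1), 0)
  i <- dir * i_base + i_el
  i <- with_seed(noise$seed + 2L,
                 i * (1 + stats::rnorm(length(i), 0, noise$v_rel_sd)))
  out <- cv_sweep(v, i, scan_rate = scan_rate, config = config, meta = spec)
  attr(out, "truth") <- win
  attr(out, "window_spanned") <- v_range[1] < win$e_mc && v_range[2] > win$e_ma
  out
}

# Normalized charging profile of the embedded cathodal polarization:
# near-linear early (so back-extrapolation isolates the access step) with
# the sub-linear build-up of a Faradaic-loaded interface.
charging_profile <- function(x, curvature = 3) {
  log1p(curvature * x) / log1p(curvature)
}

#' Generate square-pulse voltage transients with known excitation
#'
#' For every (current, pulse width) pair the cathodal polarization
#' embedded in the waveform equals the generator-truth excitation model
#' `V = a ln(b I^k2 t^k4 |Zimag|^k6 + 1)` evaluated at the electrode's
#' 10 kHz reactance, on top of an instantaneous access step
#' `R_access * I`.
#'
#' @param spec An [electrode_spec()].
#' @param preset A [material_preset()]; the in-vivo medium switches the
#'   impedance exponent from the benchtop truth to `preset$k6_invivo`.
#' @param currents Injected current amplitudes (A).
#' @param pulse_widths Per-phase pulse widths (s).
#' @param noise A [noise_spec()].
#' @param n_samples Samples per phase.
#' @return List of [voltage_transient()] objects, each with attribute
#'   `"truth"` (`v_elec`, `v_access`, `z_imag`); the list carries the
#'   truth [safety_params()] and reactance as attributes.
#' @export
generate_transient_dataset <- function(spec,
                                       preset = material_preset(spec$material),
                                       currents, pulse_widths,
                                       noise = noise_spec(),
                                       n_samples = 200L) {
  stopifnot(length(currents) >= 1, length(pulse_widths) >= 1,
            all(currents > 0), all(pulse_widths > 0))
  p <- make_electrode(spec, preset, seed = noise$seed)
  z10k <- attr(p, "truth")$z_imag_10k
  kt <- preset$k_true
  k6 <- if (spec$medium == "in_vivo") preset$k6_invivo else kt$k6
  truth_params <- safety_params(kt$a, kt$b, kt$k2, kt$k4, k6,
                                unit_convention = kt$unit_convention)
  r_access <- p$medium$r_lead + p$medium$r_spread
  grid <- expand.grid(i_inj = currents, t_pw = pulse_widths,
                      KEEP.OUT.ATTRS = FALSE)
  out <- with_seed(noise$seed + 3L, {
    lapply(seq_len(nrow(grid)), function(j) {
      i_inj <- grid$i_inj[j]; t_pw <- grid$t_pw[j]
      v_elec <- predict_velec(truth_params, i_inj, t_pw, z10k)
      v_acc <- r_access * i_inj
      dt <- t_pw / n_samples
      t <- seq(0, 2 * t_pw, by = dt)
      x_c <- pmin(t / t_pw, 1)
      x_a <- pmax(0, pmin((t - t_pw) / t_pw, 1))
      v <- ifelse(t < t_pw,
                  -(v_acc + v_elec * charging_profile(x_c)),
                  v_acc - v_elec * (1 - 2 * charging_profile(x_a)))
      v[1] <- 0
      v <- v * (1 + stats::rnorm(length(v), 0, noise$v_rel_sd))
      vt <- voltage_transient(t, v, stim_pulse(i_inj, t_pw))
      attr(vt, "truth") <- list(v_elec = v_elec, v_access = v_acc,
                                z_imag = z10k)
      vt
    })
  })
  attr(out, "truth_params") <- truth_params
  attr(out, "z_imag_10k") <- z10k
  out
}

#' Generate cathodal-excitation records directly from the model truth
#'
#' Convenience generator used by parameter-recovery studies: evaluates
#' the generator-truth excitation model on a (current x pulse width x
#' reactance) grid and applies multiplicative noise to the excitations.
#'
#' @param truth A [safety_params()] truth.
#' @param currents Currents (A).
#' @param pulse_widths Pulse widths (s).
#' @param z_values Reactance magnitudes (Ohm).
#' @param rel_sd Multiplicative noise sd on the excitations.
#' @param seed Integer seed.
#' @return Data frame with columns `i_inj`, `t_pw`, `z_imag`, `v_elec`
#'   and attribute `"truth"`.
#' @export
generate_excitation_grid <- function(truth, currents, pulse_widths,
                                     z_values, rel_sd = 0.01, seed = 1L) {
  stopifnot(inherits(truth, "safety_params"))
  g <- expand.grid(i_inj = currents, t_pw = pulse_widths, z_imag = z_values,
                   KEEP.OUT.ATTRS = FALSE)
  v <- predict_velec(truth, g$i_inj, g$t_pw, g$z_imag)
  g$v_elec <- with_seed(seed, v * (1 + stats::rnorm(length(v), 0, rel_sd)))
  attr(g, "truth") <- truth
  g
}

#' Generate a resistivity-resistance calibration series
#'
#' `R_i = rho_i * g_true / (4 pi) * (1 + eps_i)`, the series from which
#' the geometric correction factor is recovered as 4 pi times the slope.
#'
#' @param g_true True geometric factor (1/m).
#' @param rho_values Resistivities (Ohm m), at least 3.
#' @param noise A [noise_spec()]; `v_rel_sd` scales the relative error.
#' @return Data frame with columns `resistivity_ohm_m`, `resistance_ohm`.
#' @export
generate_rho_r_series <- function(g_true, rho_values,
                                  noise = noise_spec()) {
  stopifnot(g_true > 0, length(rho_values) >= 3, all(rho_values > 0))
  eps <- with_seed(noise$seed + 4L,
                   stats::rnorm(length(rho_values), 0, noise$v_rel_sd))
  data.frame(resistivity_ohm_m = rho_values,
             resistance_ohm = rho_values * g_true / (4 * pi) * (1 + eps))
}
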