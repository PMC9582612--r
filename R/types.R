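#' Interface (electrode-electrolyte) circuit parameters
#'
#' Lumped description of one electrode-electrolyte interface: a
#' constant-phase-element (CPE) double layer in parallel with a Faradaic
#' branch made of a charge-transfer resistance in series with a Faradaic
#' pseudo-capacitance CPE.
#'
#' @param q_dl CPE coefficient of the double layer (S s^n).
#' @param n_dl CPE exponent of the double layer, in (0, 1].
#' @param r_ct Charge-transfer resistance (Ohm).
#' @param q_f CPE coefficient of the Faradaic pseudo-capacitance (S s^n);
#'   `0` reduces the Faradaic branch to `r_ct` alone.
#' @param n_f CPE exponent of the Faradaic branch, in (0, 1].
#' @param faradaic_nonlinearity Optional exponential coefficient (1/V) for
#'   bias-dependent Faradaic conduction; `0` (default) keeps the branch
#'   linear.
#' @return An object of class `"interface_params"`.
#' @export
interface_params <- function(q_dl, n_dl, r_ct, q_f = 0, n_f = 0.8,
                             faradaic_nonlinearity = 0) {
  stopifnot(is.numeric(q_dl), length(q_dl) == 1L, q_dl > 0)
  stopifnot(is.numeric(n_dl), n_dl > 0, n_dl <= 1)
  stopifnot(is.numeric(r_ct), r_ct > 0)
  stopifnot(is.numeric(q_f), q_f >= 0)
  stopifnot(is.numeric(n_f), n_f > 0, n_f <= 1)
  stopifnot(is.numeric(faradaic_nonlinearity), faradaic_nonlinearity >= 0)
  structure(
    list(q_dl = q_dl, n_dl = n_dl, r_ct = r_ct, q_f = q_f, n_f = n_f,
         faradaic_nonlinearity = faradaic_nonlinearity),
    class = "interface_params"
  )
}

#' Medium (spreading + bulk tissue) circuit parameters
#'
#' Series combination of lead resistance, spreading resistance and the bulk
#' tissue network: extracellular resistance in parallel with the
#' intracellular resistance-capacitance path.
#'
#' @param r_spread Spreading resistance from current crowding near the
#'   contact (Ohm).
#' @param r_ex Extracellular (bulk) resistance (Ohm).
#' @param r_in Intracellular resistance (Ohm).
#' @param c_in Intracellular membrane capacitance (F); `0` opens the
#'   intracellular branch.
#' @param r_lead Series lead / connection resistance (Ohm).
#' @return An object of class `"medium_params"`.
#' @export
medium_params <- function(r_spread, r_ex, r_in = 0, c_in = 0, r_lead = 0) {
  vals <- c(r_spread = r_spread, r_ex = r_ex, r_in = r_in,
            c_in = c_in, r_lead = r_lead)
  stopifnot(is.numeric(vals), all(vals >= 0))
  structure(as.list(vals), class = "medium_params")
}

#' Full two-contact circuit parameters
#'
#' @param working [interface_params()] of the current-injecting contact.
#' @param counter [interface_params()] of the current-return contact.
#' @param medium [medium_params()] of the surrounding electrolyte / tissue.
#' @return An object of class `"circuit_params"`.
#' @export
circuit_params <- function(working, counter, medium) {
  stopifnot(inherits(working, "interface_params"),
            inherits(counter, "interface_params"),
            inherits(medium, "medium_params"))
  structure(list(working = working, counter = counter, medium = medium),
            class = "circuit_params")
}

#' Biphasic square stimulation pulse
#'
#' Cathodal-first, charge-balanced biphasic symmetric square pulse.
#'
#' @param i_inj Current amplitude (A, magnitude).
#' @param t_pw Per-phase pulse width (s).
#' @param interphase_gap Gap between the cathodal and anodal phase (s).
#' @return An object of class `"stim_pulse"`.
#' @export
stim_pulse <- function(i_inj, t_pw, interphase_gap = 0) {
  stopifnot(is.numeric(i_inj), i_inj > 0,
            is.numeric(t_pw), t_pw > 0,
            is.numeric(interphase_gap), interphase_gap >= 0)
  structure(list(i_inj = i_inj, t_pw = t_pw, shape = "biphasic_symmetric",
                 interphase_gap = interphase_gap),
            class = "stim_pulse")
}

#' Electrode contact-pair specification
#'
#' Identity and geometry of a bipolar contact pair: material, contact
#' diameter `D`, edge-to-edge separation expressed as a multiple of `D`,
#' and the surrounding medium.
#'
#' @param material One of `"PtNR"`, `"planar_Pt"`, `"PEDOT"`,
#'   `"clinical_depth"`, `"sEEG"`, `"strip"`.
#' @param diameter_m Contact diameter `D` (m).
#' @param separation_factor Edge-to-edge separation `S` as a multiple of
#'   `D`; the study design uses 1.5, 2, 3, 4 or 5.
#' @param medium `"benchtop_saline"` or `"in_vivo"`.
#' @return An object of class `"electrode_spec"`.
#' @export
electrode_spec <- function(material = c("PtNR", "planar_Pt", "PEDOT",
                                        "clinical_depth", "sEEG", "strip"),
                           diameter_m, separation_factor = 1.5,
                           medium = c("benchtop_saline", "in_vivo")) {
  material <- match.arg(material)
  medium <- match.arg(medium)
  stopifnot(is.numeric(diameter_m), diameter_m > 0,
            is.numeric(separation_factor), separation_factor >= 1)
  structure(list(material = material, diameter_m = diameter_m,
                 separation_factor = separation_factor, medium = medium),
            class = "electrode_spec")
}

#' Electrochemical impedance spectrum
#'
#' @param freqs Frequencies (Hz), strictly ascending and positive.
#' @param z Complex impedance values (Ohm), same length as `freqs`.
#' @param config Measurement configuration: `"two_contact"`,
#'   `"three_contact"` or `"four_contact"`.
#' @param meta Optional [electrode_spec()].
#' @return An object of class `"eis_spectrum"`.
#' @export
eis_spectrum <- function(freqs, z,
                         config = c("two_contact", "three_contact",
                                    "four_contact"),
                         meta = NULL) {
  config <- match.arg(config)
  stopifnot(is.numeric(freqs), all(freqs > 0), !is.unsorted(freqs, strictly = TRUE))
  stopifnot(is.complex(z) || is.numeric(z), length(z) == length(freqs))
  structure(list(freqs = as.numeric(freqs), z = as.complex(z),
                 config = config, meta = meta),
            class = "eis_spectrum")
}

#' @export
print.eis_spectrum <- function(x, ...) {
  cat(sprintf("<eis_spectrum> %s, %d frequencies [%.3g, %.3g] Hz\n",
              x$config, length(x$freqs), min(x$freqs), max(x$freqs)))
  invisible(x)
}

#' Cyclic voltammetry sweep
#'
#' @param v Applied potential samples (V).
#' @param i Measured current (A), same length as `v`.
#' @param scan_rate Potential scan rate (V/s).
#' @param config `"two_contact"` or `"three_contact"`.
#' @param meta Optional [electrode_spec()].
#' @return An object of class `"cv_sweep"`.
#' @export
cv_sweep <- function(v, i, scan_rate,
                     config = c("two_contact", "three_contact"),
                     meta = NULL) {
  config <- match.arg(config)
  stopifnot(is.numeric(v), is.numeric(i), length(v) == length(i),
            is.numeric(scan_rate), scan_rate > 0)
  structure(list(v = v, i = i, scan_rate = scan_rate, config = config,
                 meta = meta),
            class = "cv_sweep")
}

#' Voltage transient record
#'
#' @param t Sample times (s), uniform grid starting at 0.
#' @param v Measured total potential (V, signed; cathodal phase negative).
#' @param pulse [stim_pulse()] that produced the record.
#' @return An object of class `"voltage_transient"`.
#' @export
voltage_transient <- function(t, v, pulse) {
  stopifnot(is.numeric(t), is.numeric(v), length(t) == length(v),
            inherits(pulse, "stim_pulse"))
  if (abs(t[1]) > .Machine$double.eps) stop("time grid must start at 0")
  dt <- diff(t)
  if (length(dt) && max(abs(dt - dt[1])) > 1e-9 * dt[1])
    stop("time grid must be uniform")
  structure(list(t = t, v = v, pulse = pulse), class = "voltage_transient")
}

#' Electrolysis (water) window
#'
#' Cathodal and anodal safety potentials between which charge injection is
#' free of irreversible electrolysis. Signed convention: `e_mc < 0 < e_ma`.
#' An arm for which no onset was found within the scanned range is `NA`
#' (open window on that side).
#'
#' @param e_mc Cathodal threshold (V, negative) or `NA`.
#' @param e_ma Anodal threshold (V, positive) or `NA`.
#' @param method_meta Optional list of detector settings used.
#' @return An object of class `"electrolysis_window"`.
#' @export
electrolysis_window <- function(e_mc, e_ma, method_meta = NULL) {
  stopifnot(is.na(e_mc) || (is.numeric(e_mc) && e_mc < 0))
  stopifnot(is.na(e_ma) || (is.numeric(e_ma) && e_ma > 0))
  structure(list(e_mc = as.numeric(e_mc), e_ma = as.numeric(e_ma),
                 method_meta = method_meta),
            class = "electrolysis_window")
}

#' @export
print.electrolysis_window <- function(x, ...) {
  fmt <- function(v, side) if (is.na(v)) sprintf("open (%s)", side) else sprintf("%+.3f V", v)
  cat(sprintf("<electrolysis_window> E_mc = %s, E_ma = %s\n",
              fmt(x$e_mc, "cathodal"), fmt(x$e_ma, "anodal")))
  invisible(x)
}

#' Fitted safety-model parameters
#'
#' Parameters of the cathodal-excitation model
#' `V_elec = a * ln(b * |I|^k2 * t_pw^k4 * |Z_imag|^k6 + 1)` in magnitude
#' convention. `b` is dimensionful; `unit_convention` records the scales
#' (A, s, Ohm) the raw inputs are divided by before entering the model, so
#' the same parameter set is meaningful under any stated convention.
#'
#' @param a Excitation scale (V).
#' @param b Composite rate constant under `unit_convention`.
#' @param k2,k4,k6 Exponents of current, pulse width and reactance.
#' @param unit_convention Named list with elements `i_scale` (A), `t_scale`
#'   (s) and `z_scale` (Ohm). Default: microamp / microsecond / kiloohm.
#' @param adj_r2 Adjusted R-squared of the fit (or `NA`).
#' @return An object of class `"safety_params"`.
#' @export
safety_params <- function(a, b, k2, k4, k6,
                          unit_convention = default_unit_convention(),
                          adj_r2 = NA_real_) {
  stopifnot(a > 0, b > 0, k2 > 0, k4 > 0, k6 > 0)
  stopifnot(is.list(unit_convention),
            all(c("i_scale", "t_scale", "z_scale") %in% names(unit_convention)))
  structure(list(a = a, b = b, k2 = k2, k4 = k4, k6 = k6,
                 unit_convention = unit_convention, adj_r2 = adj_r2),
            class = "safety_params")
}

#' @export
print.safety_params <- function(x, ...) {
  cat(sprintf(paste0("<safety_params> a = %.4g V, b = %.4g, k2 = %.3f, ",
                     "k4 = %.3f, k6 = %.3f (adj R2 = %.4f)\n"),
              x$a, x$b, x$k2, x$k4, x$k6, x$adj_r2))
  cat(sprintf("  unit convention: I / %.3g A, t / %.3g s, Z / %.3g Ohm\n",
              x$unit_convention$i_scale, x$unit_convention$t_scale,
              x$unit_convention$z_scale))
  invisible(x)
}

#' Default fitting unit convention (microamp, microsecond, kiloohm)
#'
#' @return Named list with `i_scale`, `t_scale`, `z_scale`.
#' @export
default_unit_convention <- function() {
  list(i_scale = 1e-6, t_scale = 1e-6, z_scale = 1e3)
}

#' Measurement noise specification
#'
#' @param z_mag_rel_sd Multiplicative log-normal sd on impedance magnitude.
#' @param phase_sd_deg Additive sd on impedance phase (degrees).
#' @param v_rel_sd Multiplicative sd on transient / CV samples.
#' @param seed Integer RNG seed.
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(z_mag_rel_sd = 0.01, phase_sd_deg = 1,
                       v_rel_sd = 0.01, seed = 1L) {
  stopifnot(z_mag_rel_sd >= 0, phase_sd_deg >= 0, v_rel_sd >= 0)
  structure(list(z_mag_rel_sd = z_mag_rel_sd, phase_sd_deg = phase_sd_deg,
                 v_rel_sd = v_rel_sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Noise-free measurement specification
#' @return A [noise_spec()] with all standard deviations zero.
#' @export
noise_free <- function(seed = 1L) noise_spec(0, 0, 0, seed = seed)
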