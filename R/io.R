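# CSV dialects for the three measurement record types plus the rho-R
# calibration series, each with a JSON metadata sidecar (<file>.json).

sidecar_path <- function(path) sub("\\.csv$", ".json", path)

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) return(NULL)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

spec_meta <- function(meta) {
  if (is.null(meta)) NULL else unclass(meta)
}

meta_spec <- function(m) {
  if (is.null(m) || is.null(m$material)) return(NULL)
  electrode_spec(m$material, m$diameter_m, m$separation_factor, m$medium)
}

#' Write / read an impedance spectrum as CSV + JSON sidecar
#'
#' Columns `freq_hz`, `z_real_ohm`, `z_imag_ohm`; the sidecar records the
#' configuration and electrode-spec fields.
#'
#' @param s An [eis_spectrum()].
#' @param path CSV file path.
#' @return `write_eis_csv`: the path, invisibly. `read_eis_csv`: an
#'   [eis_spectrum()].
#' @export
write_eis_csv <- function(s, path) {
  stopifnot(inherits(s, "eis_spectrum"))
  utils::write.csv(data.frame(freq_hz = s$freqs, z_real_ohm = Re(s$z),
                              z_imag_ohm = Im(s$z)),
                   path, row.names = FALSE)
  write_sidecar(path, list(config = s$config, electrode = spec_meta(s$meta)))
  invisible(path)
}

#' @rdname write_eis_csv
#' @export
read_eis_csv <- function(path) {
  d <- utils::read.csv(path)
  m <- read_sidecar(path)
  eis_spectrum(d$freq_hz, complex(real = d$z_real_ohm,
                                  imaginary = d$z_imag_ohm),
               config = if (is.null(m$config)) "two_contact" else m$config,
               meta = meta_spec(m$electrode))
}

#' Write / read a voltage transient as CSV + JSON sidecar
#'
#' Columns `time_s`, `voltage_v`; the sidecar records `i_inj_a` and
#' `t_pw_s`.
#'
#' @param vt A [voltage_transient()].
#' @param path CSV file path.
#' @return `write_transient_csv`: the path, invisibly.
#'   `read_transient_csv`: a [voltage_transient()].
#' @export
write_transient_csv <- function(vt, path) {
  stopifnot(inherits(vt, "voltage_transient"))
  utils::write.csv(data.frame(time_s = vt$t, voltage_v = vt$v),
                   path, row.names = FALSE)
  write_sidecar(path, list(i_inj_a = vt$pulse$i_inj,
                           t_pw_s = vt$pulse$t_pw,
                           interphase_gap_s = vt$pulse$interphase_gap))
  invisible(path)
}

#' @rdname write_transient_csv
#' @export
read_transient_csv <- function(path) {
  d <- utils::read.csv(path)
  m <- read_sidecar(path)
  if (is.null(m)) stop("transient sidecar (i_inj_a, t_pw_s) missing: ",
                       sidecar_path(path))
  gap <- if (is.null(m$interphase_gap_s)) 0 else m$interphase_gap_s
  voltage_transient(d$time_s, d$voltage_v,
                    stim_pulse(m$i_inj_a, m$t_pw_s, gap))
}

#' Write / read a cyclic voltammetry sweep as CSV + JSON sidecar
#'
#' Columns `potential_v`, `current_a`; the sidecar records
#' `scan_rate_v_per_s` and the configuration.
#'
#' @param cv A [cv_sweep()].
#' @param path CSV file path.
#' @return `write_cv_csv`: the path, invisibly. `read_cv_csv`: a
#'   [cv_sweep()].
#' @export
write_cv_csv <- function(cv, path) {
  stopifnot(inherits(cv, "cv_sweep"))
  utils::write.csv(data.frame(potential_v = cv$v, current_a = cv$i),
                   path, row.names = FALSE)
  write_sidecar(path, list(scan_rate_v_per_s = cv$scan_rate,
                           config = cv$config,
                           electrode = spec_meta(cv$meta)))
  invisible(path)
}

#' @rdname write_cv_csv
#' @export
read_cv_csv <- function(path) {
  d <- utils::read.csv(path)
  m <- read_sidecar(path)
  if (is.null(m)) stop("CV sidecar (scan_rate_v_per_s) missing: ",
                       sidecar_path(path))
  cv_sweep(d$potential_v, d$current_a, scan_rate = m$scan_rate_v_per_s,
           config = if (is.null(m$config)) "two_contact" else m$config,
           meta = meta_spec(m$electrode))
}

#' Write / read a resistivity-resistance calibration series
#'
#' Columns `resistivity_ohm_m`, `resistance_ohm`.
#'
#' @param series Data frame as from [generate_rho_r_series()].
#' @param path CSV file path.
#' @return `write_rho_r_csv`: the path, invisibly. `read_rho_r_csv`: a
#'   data frame.
#' @export
write_rho_r_csv <- function(series, path) {
  stopifnot(all(c("resistivity_ohm_m", "resistance_ohm") %in%
                  names(series)))
  utils::write.csv(series[c("resistivity_ohm_m", "resistance_ohm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rho_r_csv
#' @export
read_rho_r_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("resistivity_ohm_m", "resistance_ohm") %in% names(d)))
  d
}
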