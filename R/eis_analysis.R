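#' Delineate the interface impedance from 3- and 4-contact spectra
#'
#' Pointwise complex subtraction of the 4-contact (medium-only) spectrum
#' from the 3-contact spectrum isolates the electrochemical interface at
#' the working contact. Non-identical frequency grids are resampled onto
#' the common log-frequency grid (real and imaginary parts interpolated
#' linearly in log f).
#'
#' @param z3 Three-contact [eis_spectrum()].
#' @param z4 Four-contact [eis_spectrum()].
#' @return An [eis_spectrum()] of the working interface (tagged
#'   `three_contact` since it derives from that measurement).
#' @export
delineate_interface <- function(z3, z4) {
  stopifnot(inherits(z3, "eis_spectrum"), inherits(z4, "eis_spectrum"))
  if (length(z3$freqs) == length(z4$freqs) &&
      all(abs(z3$freqs - z4$freqs) <= 1e-9 * z3$freqs)) {
    return(eis_spectrum(z3$freqs, z3$z - z4$z, config = z3$config,
                        meta = z3$meta))
  }
  lo <- max(min(z3$freqs), min(z4$freqs))
  hi <- min(max(z3$freqs), max(z4$freqs))
  if (lo >= hi) stop("frequency ranges of the two spectra do not overlap")
  keep <- z3$freqs >= lo & z3$freqs <= hi
  f <- z3$freqs[keep]
  interp <- function(s, part) {
    stats::approx(log(s$freqs), part(s$z), xout = log(f))$y
  }
  z4i <- complex(real = interp(z4, Re), imaginary = interp(z4, Im))
  eis_spectrum(f, z3$z[keep] - z4i, config = z3$config, meta = z3$meta)
}

#' Reactance magnitude at a frequency
#'
#' `|Im Z|` at frequency `f`, interpolated linearly in log-frequency
#' (impedance spectra are near power-law in f); exact at grid points. No
#' extrapolation outside the measured range.
#'
#' @param s An [eis_spectrum()].
#' @param f Frequency (Hz) inside the measured range.
#' @return Reactance magnitude (Ohm).
#' @export
reactance_at <- function(s, f = 1e4) {
  stopifnot(inherits(s, "eis_spectrum"), length(f) == 1, f > 0)
  if (f < min(s$freqs) || f > max(s$freqs))
    stop(sprintf("f = %g Hz outside measured range [%g, %g] Hz",
                 f, min(s$freqs), max(s$freqs)))
  stats::approx(log(s$freqs), abs(Im(s$z)), xout = log(f))$y
}

#' Fit the impedance-diameter power law
#'
#' Least-squares line in log-log space for `Zimag = alpha * D^d1`:
#' `alpha = exp(intercept)`, `d1 = slope`.
#'
#' @param diameters Contact diameters (m), at least 3 distinct values.
#' @param reactances Reactance magnitudes (Ohm), positive.
#' @return List of class `"scaling_params"` with `alpha`, `d1`, `r2`.
#' @export
fit_impedance_scaling <- function(diameters, reactances) {
  stopifnot(length(diameters) == length(reactances))
  if (length(unique(diameters)) < 3)
    stop("need at least 3 distinct diameters")
  if (any(reactances <= 0) || any(diameters <= 0))
    stop("diameters and reactances must be positive")
  fit <- stats::lm(log(reactances) ~ log(diameters))
  # noiseless round trips fit perfectly; the summary warning about an
  # "essentially perfect fit" is expected there
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(alpha = exp(unname(stats::coef(fit)[1])),
                 d1 = unname(stats::coef(fit)[2]),
                 r2 = r2),
            class = "scaling_params")
}

#' @export
print.scaling_params <- function(x, ...) {
  cat(sprintf("<scaling_params> Zimag = %.4g * D^(%.3f)  (R2 = %.4f)\n",
              x$alpha, x$d1, x$r2))
  invisible(x)
}

#' Corner frequency of a spectrum
#'
#' Lowest frequency at which the phase rises through -45 degrees, i.e.
#' where the series resistive elements of the medium start to dominate
#' the capacitive interface. Log-interpolated between grid points.
#'
#' @param s An [eis_spectrum()].
#' @return Corner frequency (Hz), or `NA` with attribute `"diagnostic"`
#'   when the phase never crosses -45 degrees within the grid.
#' @export
corner_frequency <- function(s) {
  stopifnot(inherits(s, "eis_spectrum"))
  ph <- Arg(s$z) * 180 / pi
  below <- ph < -45
  cross <- which(below[-length(ph)] & !below[-1])
  if (length(cross) == 0) {
    out <- NA_real_
    attr(out, "diagnostic") <- sprintf(
      "phase in [%.1f, %.1f] deg never rises through -45 deg",
      min(ph), max(ph))
    return(out)
  }
  j <- cross[1]
  w <- (-45 - ph[j]) / (ph[j + 1] - ph[j])
  exp(log(s$freqs[j]) + w * (log(s$freqs[j + 1]) - log(s$freqs[j])))
}

# model spectrum for fit_circuit under a given configuration
circuit_model_z <- function(theta, freqs, config, symmetric = TRUE) {
  med <- medium_params(r_spread = exp(theta[["log_r_series"]]),
                       r_ex = exp(theta[["log_r_ex"]]),
                       r_in = 0,
                       c_in = exp(theta[["log_c_in"]]), r_lead = 0)
  z <- medium_impedance(med, freqs)
  if (config %in% c("three_contact", "two_contact")) {
    iface <- interface_params(q_dl = exp(theta[["log_q_dl"]]),
                              n_dl = theta[["n_dl"]],
                              r_ct = exp(theta[["log_r_ct"]]))
    zi <- interface_impedance(iface, freqs)
    z <- z + zi * if (config == "two_contact" && symmetric) 2 else 1
  }
  z
}

#' Fit the equivalent circuit to a measured spectrum
#'
#' Complex nonlinear least squares (stacked real and imaginary residuals
#' weighted by `1/|Z|`) of the sub-circuit seen by the named
#' configuration: medium only for `four_contact`; working interface plus
#' medium for `three_contact`; both (assumed symmetric) interfaces plus
#' medium for `two_contact`. The Faradaic pseudo-capacitance is not
#' fitted (it only shapes frequencies below the usual measurement band);
#' the lead resistance is absorbed into the reported spreading
#' resistance, which is therefore the total series resistance. The bulk
#' tissue arc is identifiable from a spectrum only up to its canonical
#' form, so the fit pins the intracellular resistance at zero and
#' returns the equivalent `r_ex` / `c_in` pair reproducing the same
#' one-pole response.
#'
#' @param s An [eis_spectrum()] with at least 10 frequencies spanning 3
#'   decades.
#' @param config Configuration to fit; defaults to `s$config`.
#' @return A [circuit_params()] with attributes `"fit"` (residual norm,
#'   convergence info) and `"insensitive"` (names of parameters pinned
#'   at a search bound, if any).
#' @export
fit_circuit <- function(s, config = s$config) {
  stopifnot(inherits(s, "eis_spectrum"))
  f <- s$freqs
  if (length(f) < 10 || log10(max(f) / min(f)) < 3)
    stop("need >= 10 frequencies spanning >= 3 decades")
  z_obs <- s$z
  w <- 1 / Mod(z_obs)

  r_hi <- Re(z_obs)[which.max(f)]           # high-f series plateau
  with_iface <- config %in% c("three_contact", "two_contact")
  base0 <- c(log_r_series = log(max(r_hi * 0.8, 1e-3)),
             log_r_ex = log(max(r_hi * 0.2, 1e-3)),
             log_c_in = log(1e-8))
  lower <- c(log_r_series = log(1e-6), log_r_ex = log(1e-6),
             log_c_in = log(1e-15))
  upper <- c(log_r_series = log(1e9), log_r_ex = log(1e9),
             log_c_in = log(1))
  starts <- list(base0)
  if (with_iface) {
    lower <- c(lower, log_q_dl = log(1e-15), n_dl = 0.05,
               log_r_ct = log(1e-3))
    upper <- c(upper, log_q_dl = log(1), n_dl = 1, log_r_ct = log(1e12))
    # data-driven initialization: the mid-band reactance slope in log-log
    # gives the CPE exponent, its level the coefficient, and the low-f
    # plateau (in excess of the series plateau) the charge-transfer R
    mid <- f >= 10 * min(f) & f <= max(f) / 10 & abs(Im(z_obs)) > 0
    n_est <- if (sum(mid) >= 3)
      -unname(stats::coef(stats::lm(log(abs(Im(z_obs[mid]))) ~
                                      log(f[mid])))[2]) else 0.9
    n_est <- min(max(n_est, 0.3), 0.98)
    f_ref <- exp(stats::median(log(f[mid])))
    im_ref <- exp(stats::approx(log(f), log(pmax(abs(Im(z_obs)), 1e-12)),
                                xout = log(f_ref))$y)
    r_ct0 <- max(Mod(z_obs)[which.min(f)] - r_hi, r_hi * 0.1, 1e-3)
    starts <- lapply(unique(pmin(pmax(n_est + c(0, -0.1, 0.1), 0.3),
                                 0.99)), function(n0) {
      c(base0,
        log_q_dl = log(sin(n0 * pi / 2) / (im_ref * (2 * pi * f_ref)^n0)),
        n_dl = n0,
        log_r_ct = log(r_ct0))
    })
  }
  resid_fn <- function(theta) {
    names(theta) <- names(starts[[1]])
    zm <- circuit_model_z(theta, f, config)
    c(w * (Re(zm) - Re(z_obs)), w * (Im(zm) - Im(z_obs)))
  }
  fit <- NULL
  for (th0 in starts) {
    cand <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(cand) || cand$info %in% c(0, 9)) next
    if (is.null(fit) || sum(cand$fvec^2) < sum(fit$fvec^2)) fit <- cand
  }
  if (is.null(fit))
    stop("circuit fit did not converge from any start")
  th <- fit$par
  names(th) <- names(starts[[1]])
  # a parameter is insensitive when the residuals barely depend on it
  # (flat Jacobian column) or it sits pinned at a search bound
  sens <- diag(fit$hessian)
  flat <- names(th)[sens < 1e-8 * max(sens)]
  at_bound <- names(th)[abs(th - lower) < 1e-6 | abs(th - upper) < 1e-6]
  at_bound <- union(at_bound, flat)
  med <- medium_params(r_spread = exp(th[["log_r_series"]]),
                       r_ex = exp(th[["log_r_ex"]]),
                       r_in = 0, c_in = exp(th[["log_c_in"]]))
  iface <- if (config == "four_contact")
    interface_params(q_dl = 1e-6, n_dl = 0.9, r_ct = 1e9) else
    interface_params(q_dl = exp(th[["log_q_dl"]]), n_dl = th[["n_dl"]],
                     r_ct = exp(th[["log_r_ct"]]))
  out <- circuit_params(working = iface, counter = iface, medium = med)
  attr(out, "fit") <- list(residual_norm = sqrt(sum(fit$fvec^2)),
                           info = fit$info, config = config)
  attr(out, "insensitive") <- at_bound
  out
}
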