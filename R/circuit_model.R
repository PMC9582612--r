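#' Constant-phase-element impedance
#'
#' Impedance of a CPE, `Z = 1 / (q * (j * 2 * pi * f)^n)`. `n = 1` is an
#' ideal capacitor of capacitance `q`; `n = 0` a resistor of `1/q`. The
#' phase is `-n * 90` degrees at every frequency.
#'
#' @param q CPE coefficient (S s^n), positive.
#' @param n CPE exponent in \[0, 1\].
#' @param f Frequency (Hz), positive; vectorized.
#' @return Complex impedance (Ohm), same length as `f`.
#' @export
cpe_impedance <- function(q, n, f) {
  if (!is.numeric(q) || q <= 0) stop("CPE coefficient q must be positive")
  if (!is.numeric(n) || n < 0 || n > 1) stop("CPE exponent n must be in [0, 1]")
  if (any(f <= 0)) stop("frequency must be positive")
  1 / (q * complex(modulus = (2 * pi * f)^n, argument = n * pi / 2))
}

#' Electrode-interface impedance
#'
#' Double-layer CPE in parallel with the Faradaic branch (charge-transfer
#' resistance in series with the Faradaic pseudo-capacitance CPE). With
#' `q_f = 0` the Faradaic branch is the charge-transfer resistance alone.
#'
#' @param p An [interface_params()] object.
#' @param f Frequency (Hz), positive; vectorized.
#' @return Complex impedance (Ohm).
#' @export
interface_impedance <- function(p, f) {
  stopifnot(inherits(p, "interface_params"))
  if (any(f <= 0)) stop("frequency must be positive")
  z_dl <- cpe_impedance(p$q_dl, p$n_dl, f)
  z_far <- if (p$q_f > 0) p$r_ct + cpe_impedance(p$q_f, p$n_f, f) else
    complex(real = rep(p$r_ct, length(f)))
  (z_dl * z_far) / (z_dl + z_far)
}

#' Medium impedance (lead + spreading + bulk tissue)
#'
#' `r_lead + r_spread + (r_ex || (r_in + 1/(j 2 pi f c_in)))`. With
#' `c_in = 0` the intracellular branch is open and the bulk term is
#' `r_ex` alone.
#'
#' @param p A [medium_params()] object.
#' @param f Frequency (Hz), positive; vectorized.
#' @return Complex impedance (Ohm).
#' @export
medium_impedance <- function(p, f) {
  stopifnot(inherits(p, "medium_params"))
  if (any(f <= 0)) stop("frequency must be positive")
  series <- p$r_lead + p$r_spread
  if (p$c_in <= 0 || p$r_ex <= 0) {
    return(complex(real = rep(series + p$r_ex, length(f))))
  }
  z_in <- p$r_in + 1 / (1i * 2 * pi * f * p$c_in)
  series + (p$r_ex * z_in) / (p$r_ex + z_in)
}

#' Impedance spectrum of a measurement configuration
#'
#' Composes the sub-circuit seen by each wiring scheme: the 4-contact
#' measurement sees the medium alone, the 3-contact adds the working
#' interface, and the 2-contact adds both the working and the counter
#' interface.
#'
#' @param p A [circuit_params()] object.
#' @param config `"two_contact"`, `"three_contact"` or `"four_contact"`.
#' @param freqs Frequencies (Hz), strictly ascending.
#' @param meta Optional [electrode_spec()] attached to the result.
#' @return An [eis_spectrum()].
#' @export
configuration_spectrum <- function(p, config = c("two_contact",
                                                 "three_contact",
                                                 "four_contact"),
                                   freqs, meta = NULL) {
  stopifnot(inherits(p, "circuit_params"))
  config <- match.arg(config)
  z <- medium_impedance(p$medium, freqs)
  if (config %in% c("three_contact", "two_contact"))
    z <- z + interface_impedance(p$working, freqs)
  if (config == "two_contact")
    z <- z + interface_impedance(p$counter, freqs)
  eis_spectrum(freqs, z, config = config, meta = meta)
}
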