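# Shared fixtures and independent oracles. The oracle implementations
# deliberately use a different computational route (principal-branch
# complex powers, explicit series/parallel reduction) than the package.

default_freqs <- function(n = 41, lo = 0, hi = 5) {
  10^seq(lo, hi, length.out = n)
}

# brute-force CPE impedance via principal-branch complex exponentiation
oracle_cpe <- function(q, n, f) 1 / (q * (2i * pi * f)^n)

# brute-force interface: explicit parallel reduction
oracle_interface <- function(p, f) {
  z_dl <- oracle_cpe(p$q_dl, p$n_dl, f)
  z_far <- if (p$q_f > 0) p$r_ct + oracle_cpe(p$q_f, p$n_f, f) else
    p$r_ct + 0i
  1 / (1 / z_dl + 1 / z_far)
}

oracle_medium <- function(p, f) {
  z_in <- if (p$c_in > 0) p$r_in + 1 / (2i * pi * f * p$c_in) else Inf
  z_bulk <- if (p$c_in > 0) 1 / (1 / p$r_ex + 1 / z_in) else p$r_ex
  p$r_lead + p$r_spread + z_bulk
}

# a representative interface / medium / circuit used across tests
fixture_interface <- function() {
  interface_params(q_dl = 1e-5, n_dl = 0.9, r_ct = 1e6, q_f = 1e-6,
                   n_f = 0.8)
}

fixture_medium <- function() {
  medium_params(r_spread = 1500, r_ex = 500, r_in = 900, c_in = 1e-8,
                r_lead = 20)
}

fixture_circuit <- function() {
  circuit_params(fixture_interface(), fixture_interface(),
                 fixture_medium())
}

# random valid safety params for property-style sweeps
random_safety_params <- function() {
  safety_params(a = runif(1, 0.1, 1), b = 10^runif(1, -4, 0),
                k2 = runif(1, 0.5, 1.5), k4 = runif(1, 0.5, 1.5),
                k6 = runif(1, 0.5, 1.5))
}

extraction_records <- function(vts) {
  z <- attr(vts, "z_imag_10k")
  do.call(rbind, lapply(vts, function(vt) {
    ft <- extract_cathodal_excitation(vt)
    data.frame(i_inj = vt$pulse$i_inj, t_pw = vt$pulse$t_pw, z_imag = z,
               v_elec = ft$v_elec)
  }))
}
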