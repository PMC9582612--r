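test_that("electrode construction is deterministic under a seed", {
  spec <- electrode_spec("PtNR", 100e-6)
  p1 <- make_electrode(spec, seed = 42)
  p2 <- make_electrode(spec, seed = 42)
  expect_identical(p1, p2)
  p3 <- make_electrode(spec, seed = 43)
  expect_false(identical(p1$working$q_dl, p3$working$q_dl))
})

test_that("reactance scales with diameter by the preset power law", {
  pre <- material_preset("PtNR")
  z100 <- attr(make_electrode(electrode_spec("PtNR", 100e-6), pre,
                              seed = 5), "truth")$z_imag_10k
  z200 <- attr(make_electrode(electrode_spec("PtNR", 200e-6), pre,
                              seed = 5), "truth")$z_imag_10k
  # ratio 2^1.67 ~ 3.18, within the 2% log-normal jitter of two draws
  expect_equal(z100 / z200, 2^1.67, tolerance = 0.1)
  # the realized spectrum carries the target reactance at 10 kHz (the
  # Faradaic branch shifts it by well under a percent)
  p <- make_electrode(electrode_spec("PtNR", 100e-6), pre, seed = 5)
  expect_equal(abs(Im(interface_impedance(p$working, 1e4))), z100,
               tolerance = 5e-3)
})

test_that("the in-vivo medium raises the impedance at every frequency", {
  f <- default_freqs()
  zb <- configuration_spectrum(
    make_electrode(electrode_spec("PtNR", 100e-6), seed = 3),
    "two_contact", f)
  zi <- configuration_spectrum(
    make_electrode(electrode_spec("PtNR", 100e-6, medium = "in_vivo"),
                   seed = 3), "two_contact", f)
  expect_true(all(Mod(zi$z) > Mod(zb$z)))
})

test_that("noise-free EIS generation reproduces the forward model", {
  spec <- electrode_spec("PtNR", 200e-6)
  ds <- generate_eis_dataset(spec, configs = "three_contact",
                             noise = noise_free(seed = 9))
  p <- make_electrode(spec, seed = 9)
  ref <- configuration_spectrum(p, "three_contact", ds$three_contact$freqs)
  expect_equal(ds$three_contact$z, ref$z, tolerance = 1e-14)
})

test_that("EIS generation is seed-reproducible and seed-sensitive", {
  spec <- electrode_spec("PtNR", 100e-6)
  d1 <- generate_eis_dataset(spec, noise = noise_spec(seed = 1))
  d2 <- generate_eis_dataset(spec, noise = noise_spec(seed = 1))
  d3 <- generate_eis_dataset(spec, noise = noise_spec(seed = 2))
  expect_identical(d1$two_contact$z, d2$two_contact$z)
  expect_false(identical(d1$two_contact$z, d3$two_contact$z))
  expect_error(generate_eis_dataset(spec, configs = character(0)),
               "non-empty")
})

test_that("generated 3c minus 4c recovers the working interface", {
  spec <- electrode_spec("PtNR", 200e-6)
  noise <- noise_spec(z_mag_rel_sd = 0.01, phase_sd_deg = 0, seed = 4)
  ds <- generate_eis_dataset(spec, configs = c("three_contact",
                                               "four_contact"),
                             noise = noise)
  iface <- delineate_interface(ds$three_contact, ds$four_contact)
  truth <- interface_impedance(attr(ds, "truth")$circuit$working,
                               iface$freqs)
  # both spectra carry 1% magnitude noise; allow 2 noise sd on the
  # larger of the two measured magnitudes
  z3 <- Mod(configuration_spectrum(attr(ds, "truth")$circuit,
                                   "three_contact", iface$freqs)$z)
  expect_true(all(Mod(iface$z - truth) <= 2 * sqrt(2) * 0.01 * z3 + 1e-9))
})

test_that("CV baseline current is proportional to the scan rate", {
  spec <- electrode_spec("PtNR", 200e-6)
  base_level <- function(sr) {
    cv <- generate_cv(spec, scan_rate = sr, noise = noise_free(),
                      config = "three_contact")
    stats::median(abs(cv$i[abs(cv$v) < 0.2]))
  }
  expect_equal(base_level(0.4) / base_level(0.2), 2, tolerance = 1e-9)
})

test_that("a sweep confined inside the window shows only the baseline", {
  spec <- electrode_spec("PtNR", 200e-6)
  cv <- generate_cv(spec, v_range = c(-0.3, 0.3), noise = noise_free(),
                    config = "three_contact")
  expect_false(attr(cv, "window_spanned"))
  expect_equal(max(abs(cv$i)), stats::median(abs(cv$i)), tolerance = 1e-9)
})

test_that("the CV round trip recovers the generator window", {
  spec <- electrode_spec("PtNR", 200e-6)
  cv <- generate_cv(spec, noise = noise_free(), config = "three_contact")
  w <- detect_electrolysis_window(cv)
  truth <- attr(cv, "truth")
  expect_equal(w$e_mc, truth$e_mc, tolerance = 0.025 / abs(truth$e_mc))
  expect_equal(w$e_ma, truth$e_ma, tolerance = 0.025 / truth$e_ma)
})

test_that("embedded excitation vanishes at negligible current", {
  vts <- generate_transient_dataset(electrode_spec("PtNR", 200e-6),
                                    currents = 1e-9,
                                    pulse_widths = 1e-4,
                                    noise = noise_free())
  expect_lt(attr(vts[[1]], "truth")$v_elec, 1e-6)
})

test_that("embedded excitation increases with current at fixed t_pw", {
  vts <- generate_transient_dataset(electrode_spec("PtNR", 200e-6),
                                    currents = c(1, 3, 10, 30) * 1e-5,
                                    pulse_widths = 2e-4,
                                    noise = noise_free())
  v <- vapply(vts, function(x) attr(x, "truth")$v_elec, 0)
  expect_true(all(diff(v) > 0))
})

test_that("excitation extraction round-trips the generator truth", {
  vts <- generate_transient_dataset(
    electrode_spec("PtNR", 100e-6),
    currents = c(2, 10, 40) * 1e-5,
    pulse_widths = c(1, 4, 10) * 1e-4, noise = noise_free())
  for (vt in vts) {
    truth <- attr(vt, "truth")
    ft <- extract_cathodal_excitation(vt)
    expect_equal(ft$v_elec, truth$v_elec, tolerance = 0.01)
    expect_equal(ft$v_access, truth$v_access, tolerance = 0.05)
  }
})

test_that("rho-R series round-trips and scales with the true factor", {
  rho <- seq(0.1, 1, length.out = 8)
  tb <- generate_rho_r_series(2000, rho, noise = noise_free())
  g <- fit_geometric_factor(tb$resistivity_ohm_m, tb$resistance_ohm)
  expect_equal(g$g, 2000, tolerance = 1e-12)
  tb2 <- generate_rho_r_series(4000, rho, noise = noise_free())
  expect_equal(tb2$resistance_ohm, 2 * tb$resistance_ohm,
               tolerance = 1e-12)
})

test_that("geometric factor recovery stays within 3% at 1% noise", {
  errs <- vapply(1:100, function(s) {
    tb <- generate_rho_r_series(2000, seq(0.1, 1, length.out = 8),
                                noise = noise_spec(v_rel_sd = 0.01,
                                                   seed = s))
    abs(fit_geometric_factor(tb$resistivity_ohm_m,
                             tb$resistance_ohm)$g - 2000) / 2000
  }, 0)
  expect_lt(max(errs), 0.03)
})
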