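test_that("delineation subtracts pointwise on identical grids", {
  f <- default_freqs()
  p <- fixture_circuit()
  s3 <- configuration_spectrum(p, "three_contact", f)
  s4 <- configuration_spectrum(p, "four_contact", f)
  zero4 <- eis_spectrum(f, complex(real = rep(0, length(f)) + 1e-30),
                        config = "four_contact")
  expect_equal(delineate_interface(s3, zero4)$z, s3$z, tolerance = 1e-12)
  same <- delineate_interface(s3, s3)
  expect_true(all(Mod(same$z) < 1e-12 * Mod(s3$z)))
  expect_equal(delineate_interface(s3, s4)$z,
               interface_impedance(p$working, f), tolerance = 1e-12)
})

test_that("delineation resamples overlapping grids and rejects disjoint", {
  p <- fixture_circuit()
  s3 <- configuration_spectrum(p, "three_contact",
                               10^seq(0.5, 4.5, length.out = 37))
  s4 <- configuration_spectrum(p, "four_contact",
                               10^seq(0, 5, length.out = 51))
  iface <- delineate_interface(s3, s4)
  truth <- interface_impedance(p$working, iface$freqs)
  # interpolation error of the smooth medium spectrum stays below 0.5%
  # of the measured 3-contact magnitude
  z3_mag <- Mod(configuration_spectrum(p, "three_contact",
                                       iface$freqs)$z)
  expect_lt(max(Mod(iface$z - truth) / z3_mag), 0.005)
  s_hi <- configuration_spectrum(p, "four_contact", c(1e6, 1e7))
  expect_error(delineate_interface(s3, s_hi), "overlap")
})

test_that("reactance read-out is exact on grid points and interpolates", {
  f <- default_freqs()
  # ideal 1 uF capacitor: |Im Z| at 10 kHz is 1/(2 pi 1e4 1e-6)
  zc <- cpe_impedance(1e-6, 1, f)
  s <- eis_spectrum(f, zc, config = "three_contact")
  expect_equal(reactance_at(s, 1e4), 1 / (2 * pi * 1e4 * 1e-6),
               tolerance = 1e-9)
  expect_equal(reactance_at(s, f[17]), abs(Im(zc[17])), tolerance = 1e-12)
  # off-grid point of a power-law spectrum vs a dense-grid oracle, on
  # the usual 10-points-per-decade instrument grid
  grid10 <- 10^seq(0, 5, length.out = 51)
  coarse <- eis_spectrum(grid10, cpe_impedance(1e-6, 0.85, grid10),
                         config = "three_contact")
  f_q <- 10^3.25
  expect_equal(reactance_at(coarse, f_q),
               abs(Im(cpe_impedance(1e-6, 0.85, f_q))), tolerance = 0.005)
  expect_error(reactance_at(coarse, 1e7), "outside")
})

test_that("impedance-diameter scaling recovers the power law", {
  d <- c(30, 50, 100, 200, 400) * 1e-6
  z <- 6.6e-4 * d^-1.67
  fit <- fit_impedance_scaling(d, z)
  expect_equal(fit$alpha, 6.6e-4, tolerance = 1e-9)
  expect_equal(fit$d1, -1.67, tolerance = 1e-9)
  # constant reactance: flat exponent
  expect_equal(fit_impedance_scaling(d, rep(100, 5))$d1, 0,
               tolerance = 1e-12)
  expect_error(fit_impedance_scaling(d[1:2], z[1:2]), "3 distinct")
  expect_error(fit_impedance_scaling(d, -z), "positive")
})

test_that("scaling fit is scale-equivariant in the reactances", {
  d <- c(30, 50, 100, 200) * 1e-6
  set.seed(1)
  z <- 6.6e-4 * d^-1.67 * exp(rnorm(4, 0, 0.05))
  f1 <- fit_impedance_scaling(d, z)
  f2 <- fit_impedance_scaling(d, 7 * z)
  expect_equal(f2$alpha / f1$alpha, 7, tolerance = 1e-9)
  expect_equal(f2$d1, f1$d1, tolerance = 1e-12)
})

test_that("d1 recovery stays within 0.05 at 1% reactance noise", {
  d <- c(30, 50, 100, 200) * 1e-6
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    z <- 6.6e-4 * d^-1.67 * (1 + rnorm(4, 0, 0.01))
    abs(fit_impedance_scaling(d, z)$d1 - (-1.67))
  }, 0)
  expect_lt(max(errs), 0.05)
})

test_that("corner frequency matches the series-RC closed form", {
  f <- 10^seq(0, 5, length.out = 201)
  z <- 1000 + 1 / (2i * pi * f * 1e-6)
  s <- eis_spectrum(f, z, config = "three_contact")
  expect_equal(corner_frequency(s), 1 / (2 * pi * 1000 * 1e-6),
               tolerance = 0.01)
  flat <- eis_spectrum(f, complex(real = rep(500, length(f))),
                       config = "four_contact")
  fc <- corner_frequency(flat)
  expect_true(is.na(fc))
  expect_match(attr(fc, "diagnostic"), "-45")
})

test_that("planar Pt shows a higher corner frequency than PtNR", {
  f <- default_freqs(61)
  corner_of <- function(material) {
    p <- make_electrode(electrode_spec(material, 200e-6), seed = 2)
    corner_frequency(configuration_spectrum(p, "three_contact", f))
  }
  expect_gt(corner_of("planar_Pt"), corner_of("PtNR"))
})

test_that("circuit fitting round-trips a noiseless 4-contact spectrum", {
  med <- medium_params(r_spread = 2000, r_ex = 800, r_in = 0, c_in = 1e-8)
  ifc <- fixture_interface()
  p <- circuit_params(ifc, ifc, med)
  s4 <- configuration_spectrum(p, "four_contact", default_freqs())
  fit <- fit_circuit(s4)
  expect_equal(fit$medium$r_spread, 2000, tolerance = 1e-3)
  expect_equal(fit$medium$r_ex, 800, tolerance = 1e-3)
  expect_equal(fit$medium$c_in, 1e-8, tolerance = 1e-3)
})

test_that("circuit fitting round-trips a noiseless 3-contact spectrum", {
  med <- medium_params(r_spread = 2000, r_ex = 800, r_in = 0, c_in = 1e-8)
  ifc <- interface_params(q_dl = 4e-8, n_dl = 0.92, r_ct = 2e5)
  p <- circuit_params(ifc, ifc, med)
  s3 <- configuration_spectrum(p, "three_contact", default_freqs())
  fit <- fit_circuit(s3)
  expect_equal(fit$working$q_dl, 4e-8, tolerance = 1e-6)
  expect_equal(fit$working$n_dl, 0.92, tolerance = 1e-6)
  expect_equal(fit$working$r_ct, 2e5, tolerance = 1e-6)
})

test_that("a purely resistive spectrum flags insensitive elements", {
  f <- default_freqs()
  s <- eis_spectrum(f, complex(real = rep(1500, length(f))),
                    config = "four_contact")
  fit <- fit_circuit(s)
  dc <- fit$medium$r_spread + fit$medium$r_ex
  expect_equal(dc, 1500, tolerance = 1e-3)
  expect_true(length(attr(fit, "insensitive")) > 0)
})

test_that("interface elements are recovered within 5% at 1% noise", {
  spec <- electrode_spec("PtNR", 200e-6)
  errs <- sapply(1:50, function(s) {
    ds <- generate_eis_dataset(spec, configs = "three_contact",
                               noise = noise_spec(seed = s))
    tr <- attr(ds, "truth")$circuit$working
    ft <- fit_circuit(ds$three_contact)$working
    c(abs(ft$q_dl - tr$q_dl) / tr$q_dl,
      abs(ft$n_dl - tr$n_dl) / tr$n_dl)
  })
  expect_lt(max(errs), 0.05)
})
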