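# The cathodal-excitation model and its inverse. All public functions
# take SI inputs (A, s, Ohm); internally the factors are divided by the
# scales in the parameter object's unit_convention (microamp /
# microsecond / kiloohm by default) because the composite rate constant b
# is dimensionful and must be quoted under a stated convention.

scale_factors <- function(p, i_inj, t_pw, z_imag) {
  uc <- p$unit_convention
  list(i = i_inj / uc$i_scale, t = t_pw / uc$t_scale, z = z_imag / uc$z_scale)
}

#' Predict the cathodal excitation
#'
#' `V_elec = a * ln(b * |I|^k2 * t_pw^k4 * |Zimag|^k6 + 1)` in magnitude
#' convention (cathodal potentials are negative at the instrument; the
#' model fits and reports magnitudes). Zero whenever any factor is zero.
#'
#' @param p A [safety_params()] object.
#' @param i_inj Injected current magnitude (A); vectorized.
#' @param t_pw Pulse width (s); vectorized.
#' @param z_imag Reactance magnitude at the principal frequency (Ohm);
#'   vectorized.
#' @return Excitation magnitude (V).
#' @export
predict_velec <- function(p, i_inj, t_pw, z_imag) {
  stopifnot(inherits(p, "safety_params"))
  if (any(i_inj < 0) || any(t_pw < 0) || any(z_imag < 0))
    stop("factors must be non-negative")
  s <- scale_factors(p, i_inj, t_pw, z_imag)
  p$a * log1p(p$b * s$i^p$k2 * s$t^p$k4 * s$z^p$k6)
}

#' Invert the excitation model to the current limit
#'
#' Closed-form inverse of the excitation model at the cathodal threshold:
#' `|I_limit| = [ (e^(E_mc/a) - 1) / (b * t_pw^k4 * |Zimag|^k6) ]^(1/k2)`.
#'
#' @param p A [safety_params()] object.
#' @param e_mc Cathodal threshold magnitude (V), non-negative.
#' @param t_pw Pulse width (s), positive.
#' @param z_imag Reactance magnitude (Ohm), positive.
#' @return Limiting current (A).
#' @export
invert_ilimit <- function(p, e_mc, t_pw, z_imag) {
  stopifnot(inherits(p, "safety_params"))
  if (any(e_mc < 0)) stop("e_mc must be a non-negative magnitude")
  if (any(t_pw <= 0) || any(z_imag <= 0))
    stop("t_pw and z_imag must be positive")
  s <- scale_factors(p, 0, t_pw, z_imag)
  i_scaled <- (expm1(e_mc / p$a) / (p$b * s$t^p$k4 * s$z^p$k6))^(1 / p$k2)
  i_scaled * p$unit_convention$i_scale
}

#' Current limit as a function of contact diameter
#'
#' Substitutes the impedance-diameter power law `Zimag = alpha * D^d1`
#' into the current-limit inverse, so the limit follows directly from
#' contact diameter. Implemented as the literal substitution into
#' [invert_ilimit()], guaranteeing consistency of the two expressions.
#'
#' @param p A [safety_params()] object.
#' @param scaling A `"scaling_params"` fit from
#'   [fit_impedance_scaling()] (or a list with `alpha`, `d1`).
#' @param e_mc Cathodal threshold magnitude (V).
#' @param t_pw Pulse width (s).
#' @param diameter Contact diameter (m), positive.
#' @return Limiting current (A).
#' @export
ilimit_vs_diameter <- function(p, scaling, e_mc, t_pw, diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  invert_ilimit(p, e_mc, t_pw, scaling$alpha * diameter^scaling$d1)
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - R^2) * (N - 1) / (N - n_params - 1)`.
#'
#' @param obs Observed values.
#' @param pred Predicted values, same length.
#' @param n_params Number of fitted parameters.
#' @return Adjusted R-squared.
#' @export
adjusted_r2 <- function(obs, pred, n_params) {
  n <- length(obs)
  if (length(pred) != n) stop("obs and pred must have equal length")
  if (n <= n_params + 1) stop("need more observations than parameters + 1")
  ss_res <- sum((obs - pred)^2)
  ss_tot <- sum((obs - mean(obs))^2)
  r2 <- 1 - ss_res / ss_tot
  1 - (1 - r2) * (n - 1) / (n - n_params - 1)
}

#' Fit a single-factor excitation model
#'
#' Magnitude fit of `V = ln(k_scale * x^k_exp + 1)` for one factor
#' (current, pulse width or reactance), with the factor expressed under
#' the stated unit convention. Initialization comes from the
#' log-linearization `log(e^V - 1) = ln(k_scale) + k_exp * log(x)`.
#'
#' @param factor `"current"`, `"pulse_width"` or `"impedance"`.
#' @param x Factor values (SI units), positive; at least 5.
#' @param v Excitation magnitudes (V), non-negative.
#' @param unit_convention Scales applied to `x` (see
#'   [default_unit_convention()]).
#' @return List of class `"single_factor_params"` with `factor`,
#'   `k_scale`, `k_exp`, `adj_r2`, and flags `degenerate` /
#'   `at_bound`.
#' @export
fit_single_factor <- function(factor = c("current", "pulse_width",
                                         "impedance"),
                              x, v,
                              unit_convention = default_unit_convention()) {
  factor <- match.arg(factor)
  if (length(x) < 5) stop("need at least 5 points")
  if (any(x <= 0)) stop("factor values must be positive")
  if (any(v < 0)) stop("excitations must be non-negative magnitudes")
  scale <- switch(factor, current = unit_convention$i_scale,
                  pulse_width = unit_convention$t_scale,
                  impedance = unit_convention$z_scale)
  xs <- x / scale
  if (all(v == 0)) {
    return(structure(list(factor = factor, k_scale = 0, k_exp = 1,
                          adj_r2 = NA_real_, degenerate = TRUE,
                          at_bound = FALSE),
                     class = "single_factor_params"))
  }
  pos <- expm1(v) > 0
  init <- if (sum(pos) >= 2) {
    cf <- stats::coef(stats::lm(log(expm1(v[pos])) ~ log(xs[pos])))
    c(log_k = unname(cf[1]), k_exp = min(max(unname(cf[2]), 0.05), 3))
  } else c(log_k = 0, k_exp = 1)
  resid_fn <- function(th) v - log1p(exp(th[1]) * xs^th[2])
  fit <- minpack.lm::nls.lm(par = init, fn = resid_fn,
                            lower = c(-40, 1e-3), upper = c(20, 3),
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200))
  if (fit$info %in% c(0, 5, 9))
    stop(sprintf("single-factor fit did not converge (residual norm %.3g)",
                 sqrt(sum(fit$fvec^2))))
  k_exp <- unname(fit$par[2])
  pred <- log1p(exp(fit$par[1]) * xs^k_exp)
  structure(list(factor = factor, k_scale = exp(unname(fit$par[1])),
                 k_exp = k_exp,
                 adj_r2 = adjusted_r2(v, pred, 2),
                 degenerate = FALSE,
                 at_bound = k_exp >= 3 - 1e-6 || k_exp <= 1e-3 + 1e-6),
            class = "single_factor_params")
}

velec_eval <- function(a, b, k2, k4, k6, si, st, sz) {
  a * log1p(b * si^k2 * st^k4 * sz^k6)
}

#' Fit the full cathodal-excitation model
#'
#' Nonlinear least squares of
#' `V = a * ln(b * |I|^k2 * t_pw^k4 * |Zimag|^k6 + 1)` over records of
#' (current, pulse width, reactance, excitation). Exponents are bounded
#' to (0, 3]. Initialization: exponents from single-factor fits, `a`
#' from `max(v)/ln(10)`, and `b` multi-started over a decade grid
#' (1e-6 to 1e2) to escape the flat region of `ln(1 + x)`; the best
#' adjusted R-squared wins, ties broken by the smallest parameter norm.
#'
#' @param records Data frame with columns `i_inj` (A), `t_pw` (s),
#'   `z_imag` (Ohm), `v_elec` (V magnitude); at least 10 rows with at
#'   least 2 distinct values in each non-fixed factor.
#' @param unit_convention Scales recorded in the result (see
#'   [default_unit_convention()]).
#' @param fixed Optional named numeric vector freezing parameters, e.g.
#'   `c(k6 = 1)` when the reactance did not vary.
#' @param weighting `"proportional"` (default) weights residuals by the
#'   inverse excitation, matching the multiplicative error structure of
#'   transient measurements and giving the curvature-informative
#'   small-excitation records their statistical due; `"none"` fits
#'   absolute residuals.
#' @return A [safety_params()] with the adjusted R-squared of the fit.
#' @export
fit_full_model <- function(records,
                           unit_convention = default_unit_convention(),
                           fixed = NULL,
                           weighting = c("proportional", "none")) {
  weighting <- match.arg(weighting)
  need <- c("i_inj", "t_pw", "z_imag", "v_elec")
  if (!all(need %in% names(records)))
    stop("records must have columns ", paste(need, collapse = ", "))
  if (nrow(records) < 10) stop("need at least 10 records")
  fixed <- if (is.null(fixed)) numeric(0) else fixed
  chk <- c(i_inj = "k2", t_pw = "k4", z_imag = "k6")
  for (j in seq_along(chk)) {
    if (length(unique(records[[names(chk)[j]]])) < 2 &&
        !(chk[[j]] %in% names(fixed)))
      stop(sprintf("factor %s is constant; fix %s or vary it",
                   names(chk)[j], chk[[j]]))
  }
  si <- records$i_inj / unit_convention$i_scale
  st <- records$t_pw / unit_convention$t_scale
  sz <- records$z_imag / unit_convention$z_scale
  v <- records$v_elec

  sf_exp <- function(factor, x) {
    ex <- tryCatch(fit_single_factor(factor, x, v, unit_convention)$k_exp,
                   error = function(e) 1)
    min(max(ex, 0.1), 3)
  }
  k2_0 <- if ("k2" %in% names(fixed)) fixed[["k2"]] else
    sf_exp("current", records$i_inj)
  k4_0 <- if ("k4" %in% names(fixed)) fixed[["k4"]] else
    sf_exp("pulse_width", records$t_pw)
  k6_0 <- if ("k6" %in% names(fixed)) fixed[["k6"]] else
    if (length(unique(sz)) < 2) 1 else sf_exp("impedance", records$z_imag)
  a_0 <- max(v) / log(10)

  free <- setdiff(c("a", "b", "k2", "k4", "k6"), names(fixed))
  pack <- function(a, b, k2, k4, k6) {
    full <- c(a = log(a), b = log(b), k2 = k2, k4 = k4, k6 = k6)
    full[free]
  }
  unpack <- function(th) {
    get1 <- function(nm, trans = identity)
      if (nm %in% names(fixed)) fixed[[nm]] else
        trans(th[[match(nm, free)]])
    list(a = get1("a", exp), b = get1("b", exp), k2 = get1("k2"),
         k4 = get1("k4"), k6 = get1("k6"))
  }
  lower_full <- c(a = log(1e-6), b = log(1e-12), k2 = 1e-3, k4 = 1e-3,
                  k6 = 1e-3)
  upper_full <- c(a = log(1e3), b = log(1e6), k2 = 3, k4 = 3, k6 = 3)
  wts <- if (weighting == "proportional")
    1 / pmax(v, 0.05 * max(v)) else rep(1, length(v))
  resid_fn <- function(th) {
    q <- unpack(th)
    wts * (v - velec_eval(q$a, q$b, q$k2, q$k4, q$k6, si, st, sz))
  }
  best <- NULL
  for (b_0 in 10^seq(-6, 2, by = 1)) {
    th0 <- pack(a_0, b_0, k2_0, k4_0, k6_0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         lower = lower_full[free], upper = upper_full[free],
                         control = minpack.lm::nls.lm.control(maxiter = 400)),
      error = function(e) NULL)
    if (is.null(fit) || fit$info %in% c(0, 9)) next
    ss <- sum(fit$fvec^2)
    norm <- sum(fit$par^2)
    if (is.null(best) || ss < best$ss * (1 - 1e-12) ||
        (abs(ss - best$ss) <= 1e-12 * max(ss, best$ss) &&
         norm < best$norm)) {
      best <- list(fit = fit, ss = ss, norm = norm)
    }
  }
  if (is.null(best)) stop("full-model fit did not converge from any start")
  q <- unpack(best$fit$par)
  pred <- velec_eval(q$a, q$b, q$k2, q$k4, q$k6, si, st, sz)
  safety_params(q$a, q$b, q$k2, q$k4, q$k6,
                unit_convention = unit_convention,
                adj_r2 = adjusted_r2(v, pred, length(free)))
}

#' Transfer a benchtop calibration to in-vivo data, refitting only k6
#'
#' The excitation scale, rate constant and the current / pulse-width
#' exponents are intrinsic to the electrode and are kept from the
#' benchtop calibration; only the impedance exponent `k6` is refit on
#' the held-out records (1-D least squares). Reports the coefficient of
#' determination of predicted vs observed excitations and a paired
#' t-test p-value between them.
#'
#' @param p_bench Benchtop-calibrated [safety_params()].
#' @param records Held-out records (>= 8 rows) with measured `z_imag`,
#'   same columns as [fit_full_model()].
#' @return List with `k6_refit`, `r2`, `t_test_p`, `params` (the
#'   transferred [safety_params()]) and `predicted`.
#' @export
holdout_transfer <- function(p_bench, records) {
  stopifnot(inherits(p_bench, "safety_params"))
  if (nrow(records) < 8) stop("need at least 8 held-out records")
  sse <- function(k6) {
    p <- safety_params(p_bench$a, p_bench$b, p_bench$k2, p_bench$k4, k6,
                       unit_convention = p_bench$unit_convention)
    sum((records$v_elec -
           predict_velec(p, records$i_inj, records$t_pw,
                         records$z_imag))^2)
  }
  k6_refit <- stats::optimize(sse, interval = c(1e-3, 3),
                              tol = 1e-10)$minimum
  p_out <- safety_params(p_bench$a, p_bench$b, p_bench$k2, p_bench$k4,
                         k6_refit,
                         unit_convention = p_bench$unit_convention)
  pred <- predict_velec(p_out, records$i_inj, records$t_pw,
                        records$z_imag)
  obs <- records$v_elec
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  d <- obs - pred
  # differences below numerical resolution are identical by any test
  t_p <- if (max(abs(d)) < 1e-6 * max(abs(obs))) 1 else
    stats::t.test(obs, pred, paired = TRUE)$p.value
  list(k6_refit = k6_refit, r2 = r2, t_test_p = t_p, params = p_out,
       predicted = pred)
}

#' Shannon charge-density safety limit
#'
#' The empirical boundary `log10(Dq) = k - log10(Q)` with `Dq` the charge
#' density per phase (uC/cm^2/ph) and `Q` the charge per phase (uC/ph)
#' solves, for a circular contact of area `A` (cm^2), to
#' `Q = sqrt(A * 10^k)`; the current limit is `Q / t_pw`.
#'
#' @param diameter Contact diameter (m), positive.
#' @param t_pw Pulse width (s), positive.
#' @param k Shannon constant (default 1.8).
#' @return List of class `"shannon_result"` with `k`, `area_cm2`,
#'   `q_per_phase` (uC), `charge_density` (uC/cm^2), `i_limit_a` (A).
#' @export
shannon_limit <- function(diameter, t_pw, k = 1.8) {
  if (any(diameter <= 0) || any(t_pw <= 0))
    stop("diameter and t_pw must be positive")
  area_cm2 <- pi * (diameter * 100 / 2)^2
  q_uc <- sqrt(area_cm2 * 10^k)
  structure(list(k = k, area_cm2 = area_cm2, q_per_phase = q_uc,
                 charge_density = q_uc / area_cm2,
                 i_limit_a = q_uc * 1e-6 / t_pw),
            class = "shannon_result")
}

#' @export
print.shannon_result <- function(x, ...) {
  cat(sprintf(paste0("<shannon_result> k = %.2f: Q = %.4g uC/ph, ",
                     "density = %.4g uC/cm2/ph, I = %.4g mA\n"),
              x$k, x$q_per_phase, x$charge_density, x$i_limit_a * 1e3))
  invisible(x)
}

#' Electric field across a layer
#'
#' Field magnitude `V / d` (V/m) — the back-of-envelope scale separating
#' the double-layer field from the tissue field in the current-crowding
#' region.
#'
#' @param voltage Potential drop (V).
#' @param thickness Layer thickness (m), positive.
#' @return Field (V/m).
#' @export
electric_field <- function(voltage, thickness) {
  if (any(thickness <= 0)) stop("thickness must be positive")
  voltage / thickness
}
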