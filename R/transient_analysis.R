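#' Extract access voltage and cathodal excitation from a transient
#'
#' The measured transient is the sum of an instantaneous ohmic access
#' step (series spreading + lead + bulk resistance) and the slow
#' polarization of the electrochemical interface. The access step is
#' estimated by back-extrapolating a line fit of `|v|` over the first
#' tenth of the cathodal phase to `t = 0+`; the cathodal excitation is
#' the end-of-phase polarization minus that step.
#'
#' @param vt A [voltage_transient()] with at least 20 samples in the
#'   cathodal phase.
#' @return List of class `"transient_features"` with `v_access` (V),
#'   `v_elec` (V), `pulse`, and `clamped` (`TRUE` when a negative
#'   estimate was clamped to zero).
#' @export
extract_cathodal_excitation <- function(vt) {
  stopifnot(inherits(vt, "voltage_transient"))
  t_pw <- vt$pulse$t_pw
  if (max(vt$t) < t_pw)
    stop("record does not cover the cathodal phase boundary")
  in_phase <- vt$t < t_pw * (1 - 1e-9)
  if (sum(in_phase) < 20)
    stop("need >= 20 samples in the cathodal phase")
  sel <- vt$t > 0 & vt$t <= t_pw / 10
  if (sum(sel) < 2)
    stop("need >= 2 samples in (0, t_pw/10] to estimate the access step")
  fit <- stats::lm(abs(vt$v[sel]) ~ vt$t[sel])
  v_access <- unname(stats::coef(fit)[1])
  v_end <- abs(vt$v[max(which(in_phase))])
  clamped <- FALSE
  if (v_access < 0) { v_access <- 0; clamped <- TRUE }
  v_elec <- v_end - v_access
  if (v_elec < 0) { v_elec <- 0; clamped <- TRUE }
  structure(list(v_access = v_access, v_elec = v_elec, pulse = vt$pulse,
                 clamped = clamped),
            class = "transient_features")
}

#' Maximum safe injection current by bisection
#'
#' Finds the current at which the cathodal excitation reaches the
#' cathodal electrolysis threshold `|E_mc|`. The provider may be a
#' measured-transient interpolator or a forward model; monotonicity of
#' the excitation in the current is verified on the bracket.
#'
#' @param provider Function `(i_inj, t_pw) -> v_elec magnitude (V)`.
#' @param window An [electrolysis_window()] with a finite cathodal arm.
#' @param t_pw Pulse width (s) passed through to the provider.
#' @param bracket Length-2 current bracket (A) straddling the limit.
#' @param tol Voltage tolerance (V) on the excitation (default 1 mV).
#' @param max_iter Iteration cap (default 60).
#' @return The limiting current `I_max` (A), with attribute
#'   `"iterations"`.
#' @export
find_imax <- function(provider, window, t_pw, bracket, tol = 1e-3,
                      max_iter = 60L) {
  stopifnot(is.function(provider), inherits(window, "electrolysis_window"))
  if (is.na(window$e_mc)) stop("window has no cathodal threshold")
  target <- abs(window$e_mc)
  lo <- min(bracket); hi <- max(bracket)
  stopifnot(lo > 0, hi > lo)
  v_lo <- provider(lo, t_pw); v_hi <- provider(hi, t_pw)
  if (v_lo >= v_hi)
    stop("excitation is not increasing over the bracket")
  if (v_lo > target || v_hi < target)
    stop(sprintf(paste0("bracket does not straddle |E_mc| = %.4g V: ",
                        "v_elec(%.3g A) = %.4g V, v_elec(%.3g A) = %.4g V"),
                 target, lo, v_lo, hi, v_hi))
  it <- 0L
  repeat {
    mid <- sqrt(lo * hi)   # bisect in log-current (spans decades)
    v_mid <- provider(mid, t_pw)
    it <- it + 1L
    if (abs(v_mid - target) < tol || it >= max_iter) break
    if (v_mid < target) lo <- mid else hi <- mid
  }
  structure(mid, iterations = it)
}
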