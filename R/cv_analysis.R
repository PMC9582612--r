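#' Detect the electrolysis (water) window from a CV sweep
#'
#' The onset of irreversible electrolysis appears in a cyclic
#' voltammogram as a sudden, sustained increase of the current beyond the
#' capacitive baseline. The baseline envelope is estimated from the
#' central `baseline_band` fraction of the potential range; each arm's
#' threshold is the lowest potential magnitude at which the current
#' exceeds `onset_ratio` times that envelope and keeps growing for the
#' remainder of the arm. The criterion is ratio-based, so it is invariant
#' to uniform current scaling. Forward and reverse sweep passes are
#' pooled by potential before detection.
#'
#' @param cv A [cv_sweep()] spanning both polarities with at least 100
#'   samples.
#' @param baseline_band Central fraction of the potential range used for
#'   the baseline envelope (default 0.4).
#' @param onset_ratio Multiplier over the baseline envelope marking the
#'   onset (default 3).
#' @return An [electrolysis_window()]; an arm with no onset inside the
#'   scanned range is returned as `NA` (open window on that side), with
#'   the detector settings in `method_meta`.
#' @export
detect_electrolysis_window <- function(cv, baseline_band = 0.4,
                                       onset_ratio = 3) {
  stopifnot(inherits(cv, "cv_sweep"))
  if (length(cv$v) < 100) stop("need at least 100 samples")
  if (min(cv$v) >= 0 || max(cv$v) <= 0)
    stop("sweep must span both polarities")
  v_mid <- (max(cv$v) + min(cv$v)) / 2
  half_band <- baseline_band / 2 * (max(cv$v) - min(cv$v))
  in_band <- abs(cv$v - v_mid) <= half_band
  baseline <- max(abs(cv$i[in_band]))
  thresh <- onset_ratio * baseline

  find_onset <- function(sign_arm) {
    sel <- sign_arm * cv$v > 0
    ord <- order(sign_arm * cv$v[sel])
    v_arm <- (sign_arm * cv$v[sel])[ord]      # increasing magnitude
    i_arm <- abs(cv$i[sel])[ord]
    # pool forward/reverse passes on a monotone potential grid
    agg <- tapply(i_arm, round(v_arm, 6), mean)
    v_u <- as.numeric(names(agg))
    i_u <- as.numeric(agg)
    above <- i_u > thresh
    if (!any(above)) return(NA_real_)
    # sustained growth: from the onset on, |i| never falls back by > 5%
    run_max_rev <- rev(cummin(rev(i_u)))
    sustained <- above & (run_max_rev >= 0.95 * i_u | seq_along(i_u) ==
                            length(i_u))
    cand <- which(above & sustained)
    if (length(cand) == 0) return(NA_real_)
    j <- cand[1]
    if (j == 1) return(sign_arm * v_u[1])
    # interpolate the crossing of the threshold between grid points
    w <- (thresh - i_u[j - 1]) / (i_u[j] - i_u[j - 1])
    w <- min(max(w, 0), 1)
    sign_arm * (v_u[j - 1] + w * (v_u[j] - v_u[j - 1]))
  }
  e_ma <- find_onset(1)
  e_mc <- find_onset(-1)
  electrolysis_window(e_mc, e_ma,
                      method_meta = list(baseline_band = baseline_band,
                                         onset_ratio = onset_ratio,
                                         baseline_envelope = baseline,
                                         config = cv$config))
}
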