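#' Estimate the geometric correction factor from a resistivity series
#'
#' The 4-contact resistance of a contact pair in a medium of resistivity
#' `rho` is `R = rho * G / (4 pi)`, so `G / (4 pi)` is the slope of the
#' measured rho-R line. The regression runs through the origin (the
#' relation has no offset); an intercept can be enabled to diagnose
#' electrode-polarization leakage into the 4-contact measurement.
#'
#' @param rho Resistivities (Ohm m), at least 3 positive values.
#' @param r Measured resistances (Ohm), positive.
#' @param intercept Include an intercept term (diagnostic only).
#' @return List of class `"geometric_factor"` with `g` (1/m),
#'   `slope_se`, `n_points`, and `intercept` when requested.
#' @export
fit_geometric_factor <- function(rho, r, intercept = FALSE) {
  if (length(rho) < 3 || length(r) != length(rho))
    stop("need >= 3 matched (rho, R) points")
  if (any(rho <= 0) || any(r <= 0))
    stop("resistivities and resistances must be positive")
  fit <- if (intercept) stats::lm(r ~ rho) else stats::lm(r ~ 0 + rho)
  sm <- suppressWarnings(summary(fit))  # exact series fit perfectly
  slope_row <- if (intercept) 2 else 1
  structure(list(g = 4 * pi * unname(stats::coef(fit)[slope_row]),
                 slope_se = 4 * pi * sm$coefficients[slope_row, 2],
                 n_points = length(rho),
                 intercept = if (intercept)
                   unname(stats::coef(fit)[1]) else NULL),
            class = "geometric_factor")
}

#' @export
print.geometric_factor <- function(x, ...) {
  cat(sprintf("<geometric_factor> G = %.4g 1/m (se %.2g, n = %d)\n",
              x$g, x$slope_se, x$n_points))
  invisible(x)
}

#' Convert conductivity to resistivity
#'
#' @param sigma Conductivity (S/m), positive.
#' @return Resistivity (Ohm m), `1/sigma`.
#' @export
conductivity_to_resistivity <- function(sigma) {
  if (any(sigma <= 0)) stop("conductivity must be positive")
  1 / sigma
}
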