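#' Convert a dissociation constant to pKd
#'
#' Docking scores throughout this package are expressed as pKd, the negative
#' base-10 logarithm of the dissociation constant Kd in mol/L. A Kd of
#' 3e-6 mol/L (3 uM) corresponds to a pKd of 5.52, the default edge-retention
#' threshold for biomarker-target interaction networks.
#'
#' @param kd Dissociation constant(s) in mol/L. Must be strictly positive.
#' @return Numeric vector of pKd values, \code{-log10(kd)}.
#' @seealso [kd_from_pkd()] for the inverse.
#' @examples
#' pkd_from_kd(3e-6)  # 5.52 (2 dp)
#' @export
pkd_from_kd <- function(kd) {
  if (!is.numeric(kd) || length(kd) == 0) {
    stop("`kd` must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(kd) | kd <= 0
  if (any(bad)) {
    stop(sprintf(
      "`kd` must be positive and finite; offending value(s): %s",
      paste(format(kd[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  -log10(kd)
}

#' Convert a pKd value to a dissociation constant
#'
#' @param pkd pKd value(s); must be finite.
#' @return Dissociation constant(s) in mol/L, \code{10^(-pkd)}.
#' @seealso [pkd_from_kd()]
#' @examples
#' kd_from_pkd(5.52)  # ~3 uM
#' @export
kd_from_pkd <- function(pkd) {
  if (!is.numeric(pkd) || length(pkd) == 0) {
    stop("`pkd` must be a non-empty numeric vector", call. = FALSE)
  }
  bad <- !is.finite(pkd)
  if (any(bad)) {
    stop(sprintf(
      "`pkd` must be finite; offending value(s): %s",
      paste(format(pkd[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  10^(-pkd)
}

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed network summaries in this
#' field use conventional half-up rounding (e.g. 232/13 -> 17.85), so reported
#' means go through this helper.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}
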