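#' Concentration proxy of a phase field
#'
#' `c = (1 - phi) / 2`: a crude dimensionless proxy for molecular collagen
#' concentration, with `c < 1/2` marking protomer-occupied (low-density)
#' regions and `c >= 1/2` dense fibrillar regions.
#'
#' @param field A [phase_field()].
#' @return A numeric matrix.
#' @export
concentration <- function(field) {
  stopifnot(inherits(field, "phase_field"))
  (1 - field$values) / 2
}

#' Protomer availability
#'
#' Integral of the concentration proxy over the in-mask region where
#' `c < 1/2`: an estimate of the relative amount of free (protomeric)
#' collagen still available in the extracellular space. Falls as protomer
#' is incorporated into fibrils.
#'
#' @param field A [phase_field()].
#' @param mask Optional [domain_mask()].
#' @return Scalar, in units of `c * dx^2`.
#' @export
protomer_availability <- function(field, mask = NULL) {
  cc <- concentration(field)
  inside <- if (is.null(mask)) TRUE & array(TRUE, dim(cc)) else mask$mask
  sum(cc[inside & cc < 0.5]) * field$grid$dx^2
}

#' Crystallized area fraction
#'
#' Fraction of in-mask pixels in the fibrillar class (`c >= 1/2`).
#'
#' @inheritParams protomer_availability
#' @return Scalar in `[0, 1]`.
#' @export
crystallized_fraction <- function(field, mask = NULL) {
  cc <- concentration(field)
  inside <- if (is.null(mask)) array(TRUE, dim(cc)) else mask$mask
  mean(cc[inside] >= 0.5)
}

#' Concentration integral over the fibrillar region
#'
#' Companion of [protomer_availability()]: the integral of `c` over the
#' in-mask region with `c >= 1/2`. By construction
#' `protomer_availability + fibril_mass` equals the integral of `c` over the
#' whole mask.
#'
#' @inheritParams protomer_availability
#' @return Scalar, in units of `c * dx^2`.
#' @export
fibril_mass <- function(field, mask = NULL) {
  cc <- concentration(field)
  inside <- if (is.null(mask)) array(TRUE, dim(cc)) else mask$mask
  sum(cc[inside & cc >= 0.5]) * field$grid$dx^2
}

#' Write an observable series to CSV
#'
#' @param trajectory A `pfc_trajectory` from [pfc_run()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_series <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "pfc_trajectory"))
  readr::write_csv(trajectory$series, path)
  invisible(path)
}
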