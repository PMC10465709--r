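#' Phase field container
#'
#' A scalar order-parameter field on a regular grid. By convention
#' `phi = -1` marks dense fibrillar collagen and `phi = +1` protomer-rich
#' extracellular medium; `c = (1 - phi) / 2` is the concentration proxy.
#'
#' @param values Numeric matrix of field values.
#' @param grid The [grid_spec()] the field lives on.
#' @param time Simulation time attached to the snapshot (dimensionless).
#' @return A `phase_field` object.
#' @export
phase_field <- function(values, grid, time = 0) {
  stopifnot(is.matrix(values), inherits(grid, "grid_spec"))
  if (nrow(values) != grid$nx || ncol(values) != grid$ny) {
    abort("field dimensions do not match the grid.")
  }
  if (!all(is.finite(values))) abort("field contains non-finite values.")
  structure(list(values = values, grid = grid, time = time),
            class = "phase_field")
}

#' @export
print.phase_field <- function(x, ...) {
  v <- x$values
  cat(sprintf("<phase_field> %d x %d, t = %g, range [%.3f, %.3f], mean %.4f\n",
              nrow(v), ncol(v), x$time, min(v), max(v), mean(v)))
  invisible(x)
}

#' Sample a Gaussian-random-field initial condition
#'
#' Constructs the initial phase field: a uniform mean `phi0` plus a small
#' spatially correlated fluctuation, generated by spectrally filtering
#' seeded white noise with a Gaussian kernel so the fluctuation
#' autocorrelation is `m2 * exp(-x^2 / lam^2)` (e-folding length `lam`).
#' The in-mask sample variance is rescaled to exactly `m2` and the in-mask
#' sample mean shifted to exactly `phi0`; outside the mask the field is
#' held at `phi0`.
#'
#' @param grid A [grid_spec()].
#' @param mask Optional [domain_mask()]; `NULL` means the full periodic
#'   rectangle.
#' @param phi0 Mean phase field, `|phi0| < 1`.
#' @param m2 Variance of the initial fluctuation (>= 0).
#' @param lam Correlation length. Interpreted in grid units (pixels) when
#'   `lam_units = "grid"` (the default), or in the units of `grid$dx` when
#'   `"physical"`.
#' @param seed Integer seed.
#' @param lam_units `"grid"` or `"physical"`.
#' @return A [phase_field()] at `time = 0`.
#' @examples
#' f <- sample_grf(grid_spec(64, 64), phi0 = 0.4, m2 = 0.01, lam = 5, seed = 1)
#' mean(f$values)  # exactly 0.4
#' @export
sample_grf <- function(grid, mask = NULL, phi0 = 0.4, m2 = 0.01, lam = 10,
                       seed = 1, lam_units = c("grid", "physical")) {
  stopifnot(inherits(grid, "grid_spec"))
  lam_units <- match.arg(lam_units)
  if (abs(phi0) >= 1) abort("`phi0` must satisfy |phi0| < 1.")
  if (m2 < 0 || lam < 0) abort("`m2` and `lam` must be non-negative.")
  inside <- if (is.null(mask)) matrix(TRUE, grid$nx, grid$ny) else mask$mask
  if (m2 == 0) {
    return(phase_field(matrix(phi0, grid$nx, grid$ny), grid))
  }
  if (sum(inside) < 2) abort("mask has fewer than 2 pixels; variance undefined.")
  lam_phys <- if (lam_units == "grid") lam * grid$dx else lam
  k2 <- spectral_k2(grid)
  noise <- withr::with_seed(seed, matrix(rnorm(grid$nx * grid$ny), grid$nx))
  f <- if (lam_phys > 0) {
    # power spectrum ~ exp(-k^2 lam^2 / 4)  <=>  autocorr ~ exp(-x^2 / lam^2)
    Re(fft(exp(-k2 * lam_phys^2 / 8) * fft(noise), inverse = TRUE)) /
      length(noise)
  } else {
    noise
  }
  f <- f - mean(f[inside])
  f <- f * sqrt(m2 / var(as.vector(f[inside])))
  vals <- matrix(phi0, grid$nx, grid$ny)
  vals[inside] <- phi0 + f[inside] - mean(f[inside])
  phase_field(vals, grid)
}
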