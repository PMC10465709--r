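#' Generate a synthetic inter-cellular-space domain mask
#'
#' Produces a star-convex "blobby" domain emulating the irregular lobed
#' outlines of inter-cellular spaces seen in tendon cross-sections. The
#' boundary radius is a seeded random Fourier series in the polar angle,
#' `R(theta) = mean_radius * (1 + boundary_roughness * s(theta))` with
#' `max |s| = 1`, rasterized by center-of-pixel inclusion, so the pixel area
#' always lies between the areas of the inscribed and circumscribed disks.
#'
#' @param grid A [grid_spec()]; the blob is centered on the grid.
#' @param mean_radius Mean boundary radius, in the units of `grid$dx`.
#' @param boundary_roughness Relative amplitude of the radial perturbation,
#'   in `[0, 1)`. `0` gives a discrete disk.
#' @param n_modes Number of angular Fourier modes in the perturbation.
#' @param seed Integer seed; the same seed reproduces the mask exactly.
#' @param smooth_width Passed to [domain_mask()].
#' @return A [domain_mask()].
#' @examples
#' m <- gen_domain_mask(grid_spec(64, 64, dx = 10), mean_radius = 200, seed = 1)
#' sum(m$mask)
#' @export
gen_domain_mask <- function(grid, mean_radius,
                            boundary_roughness = 0.15, n_modes = 8,
                            seed = 1, smooth_width = 2) {
  stopifnot(inherits(grid, "grid_spec"))
  if (boundary_roughness < 0 || boundary_roughness >= 1) {
    abort("`boundary_roughness` must be in [0, 1).")
  }
  rmax <- mean_radius * (1 + boundary_roughness)
  half <- (min(grid$nx, grid$ny) / 2 - 1.5) * grid$dx
  if (rmax >= half) {
    abort(sprintf(
      "domain (max radius %.4g) does not fit inside the grid (half-width %.4g).",
      rmax, half))
  }
  xc <- ((1:grid$nx) - 0.5 - grid$nx / 2) * grid$dx
  yc <- ((1:grid$ny) - 0.5 - grid$ny / 2) * grid$dx
  rr <- outer(xc, yc, function(a, b) sqrt(a^2 + b^2))
  th <- outer(xc, yc, function(a, b) atan2(b, a))
  if (boundary_roughness > 0 && n_modes > 0) {
    co <- withr::with_seed(seed, list(a = rnorm(n_modes), b = rnorm(n_modes)))
    s <- matrix(0, grid$nx, grid$ny)
    for (k in seq_len(n_modes)) {
      s <- s + co$a[k] * cos(k * th) + co$b[k] * sin(k * th)
    }
    s <- s / max(abs(s))
  } else {
    s <- matrix(0, grid$nx, grid$ny)
  }
  mask <- rr <= mean_radius * (1 + boundary_roughness * s)
  domain_mask(mask, grid, smooth_width = smooth_width)
}
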