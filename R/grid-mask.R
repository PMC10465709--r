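#' Regular simulation grid
#'
#' Defines the isotropic pixel grid on which phase fields and domain masks
#' live. `dx` is the physical (or dimensionless) size of one pixel; the grid
#' spans `nx * dx` by `ny * dx`. Pixel centers sit at `(i - 1/2) * dx`.
#'
#' @param nx,ny Number of pixels in each direction (at least 16).
#' @param dx Pixel size (nm, or dimensionless units), strictly positive.
#' @return A `grid_spec` object.
#' @examples
#' grid_spec(128, 128, dx = 10)
#' @export
grid_spec <- function(nx, ny = nx, dx = 1) {
  if (!is.numeric(nx) || !is.numeric(ny) || nx < 16 || ny < 16 ||
      nx != round(nx) || ny != round(ny)) {
    abort("`nx` and `ny` must be integers >= 16.")
  }
  if (!is.numeric(dx) || length(dx) != 1L || dx <= 0) {
    abort("`dx` must be a single positive number.")
  }
  structure(list(nx = as.integer(nx), ny = as.integer(ny), dx = as.numeric(dx)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d pixels, dx = %g (width %g x %g)\n",
              x$nx, x$ny, x$dx, x$nx * x$dx, x$ny * x$dx))
  invisible(x)
}

#' Irregular domain mask
#'
#' Wraps a binary indicator of the inter-cellular space together with its
#' grid and a smoothed indicator `psi` in `[0, 1]` (tanh profile across the
#' boundary, clamped to exactly 0/1 outside the interface band). `psi` acts
#' as the spatially varying mobility in masked simulations, so the domain
#' boundary is impermeable up to the smoothing width.
#'
#' @param mask Logical (or 0/1) matrix with `TRUE` inside the domain.
#' @param grid A [grid_spec()] whose dimensions match `mask`.
#' @param smooth_width Interface half-width of the tanh profile, in pixels.
#' @return A `domain_mask` object with elements `mask`, `grid`, `psi`.
#' @export
domain_mask <- function(mask, grid, smooth_width = 2) {
  if (is.numeric(mask)) mask <- mask > 0
  if (!is.logical(mask) || !is.matrix(mask)) {
    abort("`mask` must be a logical matrix.")
  }
  stopifnot(inherits(grid, "grid_spec"))
  if (nrow(mask) != grid$nx || ncol(mask) != grid$ny) {
    abort(sprintf("mask is %d x %d but grid is %d x %d.",
                  nrow(mask), ncol(mask), grid$nx, grid$ny))
  }
  if (!any(mask)) abort("mask is empty (no interior pixels).")
  if (any(mask[1, ]) || any(mask[nrow(mask), ]) ||
      any(mask[, 1]) || any(mask[, ncol(mask)])) {
    abort("mask touches the grid border; no room for the boundary treatment.")
  }
  psi <- smooth_indicator(mask, smooth_width)
  structure(list(mask = mask, grid = grid, psi = psi,
                 smooth_width = smooth_width),
            class = "domain_mask")
}

# tanh profile of the signed Euclidean distance to the mask boundary,
# clamped to {0, 1} outside the interface band so the far field carries
# exactly zero mobility (no slow leak through the tanh tails).
smooth_indicator <- function(mask, width = 2) {
  d_in <- EBImage::distmap(matrix(as.numeric(mask), nrow(mask)))
  d_out <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask)))
  psi <- 0.5 * (1 + tanh((d_in - d_out) / width))
  psi[psi < 0.005] <- 0
  psi[psi > 0.995] <- 1
  psi
}

#' @export
print.domain_mask <- function(x, ...) {
  cat(sprintf("<domain_mask> %d / %d pixels inside (%.1f%%), dx = %g\n",
              sum(x$mask), length(x$mask), 100 * mean(x$mask), x$grid$dx))
  invisible(x)
}

#' Read and write domain masks as 8-bit PNG with a sidecar scale file
#'
#' Masks are stored as grayscale PNG (0 = outside, 255 = inside) plus a YAML
#' sidecar `<path>.yml` recording the pixel size `dx` (and the smoothing
#' width), so a mask round-trips with its physical scale.
#'
#' @param x A `domain_mask`.
#' @param path PNG file path.
#' @return `write_mask` returns `path` invisibly; `read_mask` returns a
#'   `domain_mask`.
#' @export
write_mask <- function(x, path) {
  stopifnot(inherits(x, "domain_mask"))
  png::writePNG(t(matrix(as.numeric(x$mask), nrow(x$mask))), path)
  yaml::write_yaml(list(dx = x$grid$dx, smooth_width = x$smooth_width),
                   paste0(path, ".yml"))
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  m <- t(img) > 0.5
  domain_mask(m, grid_spec(nrow(m), ncol(m), dx = meta$dx),
              smooth_width = meta$smooth_width %||% 2)
}
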