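#' Fibril center point set
#'
#' A tibble of fibril cross-section centers in physical units, from either
#' simulation detection or manual micrograph annotation.
#'
#' @param points Data frame with numeric columns `x_nm`, `y_nm`.
#' @param source `"simulation"` or `"annotation"`.
#' @return A `fibril_set` (tibble subclass).
#' @export
fibril_set <- function(points, source = c("simulation", "annotation")) {
  source <- match.arg(source)
  pts <- as_tibble(points)
  if (!all(c("x_nm", "y_nm") %in% names(pts))) {
    abort("`points` must have columns x_nm and y_nm.")
  }
  if (!is.numeric(pts$x_nm) || !is.numeric(pts$y_nm) ||
      anyNA(pts$x_nm) || anyNA(pts$y_nm)) {
    abort("x_nm and y_nm must be numeric and non-missing.")
  }
  dup <- duplicated(pts[, c("x_nm", "y_nm")])
  if (any(dup)) {
    abort(sprintf("duplicate points at rows: %s.",
                  paste(which(dup), collapse = ", ")))
  }
  structure(pts[, c("x_nm", "y_nm")],
            source = source,
            class = c("fibril_set", class(pts)))
}

#' Detect fibril centers in a phase field
#'
#' Labels connected components of the fibrillar region (`c >= 1/2`),
#' discards components smaller than `min_area`, and returns
#' the concentration-weighted centroid of each remaining component. The
#' default `min_area` is a quarter of the area of a disk of radius one
#' quarter of the one-mode lattice constant `4 pi / (sqrt(3) qstar)`, which
#' rejects boundary slivers but keeps genuine fibril cross-sections.
#'
#' @param field A [phase_field()] at or near equilibrium.
#' @param mask Optional [domain_mask()].
#' @param min_area Minimum component area, in `dx^2` units; `NULL` for the
#'   default above.
#' @param qstar Pattern wavenumber used for the default `min_area`.
#' @return A [fibril_set()] (possibly empty) with coordinates in the units
#'   of `grid$dx`.
#' @export
detect_fibrils <- function(field, mask = NULL, min_area = NULL, qstar = 1) {
  stopifnot(inherits(field, "phase_field"))
  cc <- concentration(field)
  dx <- field$grid$dx
  if (is.null(min_area)) {
    a <- 4 * pi / (sqrt(3) * qstar)
    min_area <- 0.25 * pi * (a / 4)^2
  }
  # label the crystallized set on the full grid: outside a masked domain the
  # field is frozen below the fibrillar threshold, and clipping with the
  # binary mask would cut boundary-row fibrils into spurious fragments
  bw <- matrix(as.numeric(cc >= 0.5), nrow(cc))
  lab <- EBImage::bwlabel(bw)
  nlab <- max(lab)
  if (nlab == 0) {
    return(fibril_set(tibble(x_nm = numeric(), y_nm = numeric())))
  }
  idx <- which(lab > 0)
  l <- lab[idx]
  w <- cc[idx]
  ri <- (idx - 1) %% nrow(cc) + 1
  ci <- (idx - 1) %/% nrow(cc) + 1
  area <- tabulate(l, nlab) * dx^2
  wsum <- vapply(split(w, l), sum, 0)
  xs <- vapply(split(w * (ri - 0.5) * dx, l), sum, 0) / wsum
  ys <- vapply(split(w * (ci - 0.5) * dx, l), sum, 0) / wsum
  keep <- area >= min_area
  if (!is.null(mask)) {
    # drop anything centered beyond the smoothed domain boundary
    pi_ <- pmin(pmax(round(xs / dx + 0.5), 1L), nrow(cc))
    pj <- pmin(pmax(round(ys / dx + 0.5), 1L), ncol(cc))
    keep <- keep & mask$psi[cbind(pi_, pj)] > 0
  }
  fibril_set(tibble(x_nm = xs[keep], y_nm = ys[keep]))
}

# simple 8-neighborhood local-maximum detector; retained as an independent
# cross-check of the component-centroid detector
detect_fibrils_maxima <- function(field) {
  cc <- concentration(field)
  n <- nrow(cc); m <- ncol(cc)
  core <- cc[2:(n - 1), 2:(m - 1)]
  ismax <- core >= 0.5
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    ismax <- ismax & (core > cc[2:(n - 1) + di, 2:(m - 1) + dj] |
                        (core == cc[2:(n - 1) + di, 2:(m - 1) + dj] &
                           (di > 0 | (di == 0 & dj > 0))))
  }
  which(ismax, arr.ind = TRUE) + 1L
}

#' Read and write fibril point lists
#'
#' Point lists are CSVs with (at least) the numeric columns `x_nm`, `y_nm`;
#' extra annotation columns are ignored on read. Malformed numeric cells
#' and duplicated points are rejected with the offending line numbers.
#'
#' @param path CSV path.
#' @param fibrils A [fibril_set()].
#' @return `read_points` returns a [fibril_set()] with
#'   `source = "annotation"`; `write_points` returns `path` invisibly.
#' @export
read_points <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!all(c("x_nm", "y_nm") %in% names(raw))) {
    abort(sprintf("%s: expected header columns x_nm,y_nm.", path))
  }
  xs <- suppressWarnings(as.numeric(raw$x_nm))
  ys <- suppressWarnings(as.numeric(raw$y_nm))
  bad <- which(is.na(xs) | is.na(ys))
  if (length(bad)) {
    abort(sprintf("%s: non-numeric coordinate on line(s) %s.",
                  path, paste(bad + 1L, collapse = ", ")))
  }
  dup <- which(duplicated(cbind(xs, ys)))
  if (length(dup)) {
    abort(sprintf("%s: duplicate point(s) on line(s) %s.",
                  path, paste(dup + 1L, collapse = ", ")))
  }
  fibril_set(tibble(x_nm = xs, y_nm = ys), source = "annotation")
}

#' @rdname read_points
#' @export
write_points <- function(fibrils, path) {
  stopifnot(inherits(fibrils, "fibril_set"))
  readr::write_csv(as_tibble(fibrils)[, c("x_nm", "y_nm")], path)
  invisible(path)
}
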