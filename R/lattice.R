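#' Exhaustive reference triangulation and defect analysis
#'
#' Brute-force Delaunay analysis by the empty-circumcircle definition: every
#' triple of points is tested for an empty circumcircle, Delaunay edges are
#' collected from the accepted triangles, edges longer than
#' `prune_factor` times the median edge length are removed, and a point is
#' peripheral iff it touches an edge bounding at most one surviving
#' triangle. This is `O(n^3)`-`O(n^4)` and intended as an independent oracle
#' for small point sets (`n <= 200`), entirely separate from the
#' `deldir`-based production pipeline in [defect_report()].
#'
#' @param points A data frame with columns `x_nm`, `y_nm` (or a
#'   [fibril_set()]).
#' @param prune_factor Edges longer than `prune_factor * median(edge length)`
#'   are dropped before neighbor counting.
#' @return A list with `edges` (tibble `i`, `j`, `length_nm` of the pruned
#'   graph), `neighbor_count` (integer per point), `interior` (logical per
#'   point).
#' @export
reference_triangulation <- function(points, prune_factor = 1.8) {
  pts <- as.data.frame(points)[, c("x_nm", "y_nm")]
  n <- nrow(pts)
  if (n < 3) abort("need at least 3 points.")
  if (n > 250) abort("reference_triangulation is an exhaustive oracle; use n <= 250.")
  x <- pts$x_nm
  y <- pts$y_nm
  scale <- max(diff(range(x)), diff(range(y)))
  tri <- t(utils::combn(n, 3L))
  x1 <- x[tri[, 1]]; y1 <- y[tri[, 1]]
  x2 <- x[tri[, 2]]; y2 <- y[tri[, 2]]
  x3 <- x[tri[, 3]]; y3 <- y[tri[, 3]]
  # signed twice-area; exactly collinear triples carry no triangle
  orient <- (x2 - x1) * (y3 - y1) - (y2 - y1) * (x3 - x1)
  ok <- abs(orient) > 1e-12 * scale^2
  # incircle determinant predicate (well-conditioned even for the huge
  # circumcircles of near-collinear boundary triples): D lies strictly
  # inside the circumcircle of the CCW triangle ABC iff det > 0
  tol <- 1e-12 * scale^4
  keep <- logical(nrow(tri))
  idx <- which(ok)
  chunk <- 5000L
  for (start in seq(1L, length(idx), by = chunk)) {
    ii <- idx[start:min(start + chunk - 1L, length(idx))]
    adx <- outer(x1[ii], x, `-`); ady <- outer(y1[ii], y, `-`)
    bdx <- outer(x2[ii], x, `-`); bdy <- outer(y2[ii], y, `-`)
    cdx <- outer(x3[ii], x, `-`); cdy <- outer(y3[ii], y, `-`)
    ad2 <- adx^2 + ady^2; bd2 <- bdx^2 + bdy^2; cd2 <- cdx^2 + cdy^2
    det <- adx * (bdy * cd2 - bd2 * cdy) -
      ady * (bdx * cd2 - bd2 * cdx) +
      ad2 * (bdx * cdy - bdy * cdx)
    inside <- det * sign(orient[ii]) > tol
    keep[ii] <- rowSums(inside) == 0L
  }
  tri <- tri[keep, , drop = FALSE]
  if (nrow(tri) == 0L) {
    return(list(edges = tibble(i = integer(), j = integer(),
                               length_nm = numeric()),
                neighbor_count = rep(0L, n), interior = rep(FALSE, n)))
  }
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- unique(e)
  len <- sqrt((x[e[, 1]] - x[e[, 2]])^2 + (y[e[, 1]] - y[e[, 2]])^2)
  cut <- prune_factor * median(len)
  alive <- len <= cut
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  alive_keys <- ekey(e[alive, 1], e[alive, 2])
  tri_keys <- cbind(ekey(tri[, 1], tri[, 2]),
                    ekey(tri[, 2], tri[, 3]),
                    ekey(tri[, 1], tri[, 3]))
  tri_ok <- matrix(tri_keys %in% alive_keys, nrow(tri)) |> rowSums() == 3L
  edge_tri_count <- table(factor(as.vector(tri_keys[tri_ok, , drop = FALSE]),
                                 levels = alive_keys))
  boundary_keys <- names(edge_tri_count)[edge_tri_count <= 1L]
  ei <- e[alive, 1]; ej <- e[alive, 2]
  deg <- tabulate(c(ei, ej), nbins = n)
  on_boundary <- rep(FALSE, n)
  if (length(boundary_keys)) {
    bk <- do.call(rbind, strsplit(boundary_keys, " "))
    on_boundary[as.integer(bk)] <- TRUE
  }
  interior <- deg > 0L & !on_boundary
  list(edges = tibble(i = ei, j = ej, length_nm = len[alive]),
       neighbor_count = as.integer(deg), interior = interior)
}

#' Generate a jittered triangular (hexagonal-packing) lattice
#'
#' Builds the ideal triangular lattice of fibril centers with the given
#' nearest-neighbor spacing, clips it to a square of side `extent`, and
#' perturbs every position with seeded isotropic Gaussian jitter. Ground
#' truth (per-point neighbor counts and interior flags) is computed at
#' generation time with the exhaustive [reference_triangulation()] oracle,
#' not with the production pipeline.
#'
#' @param spacing Nearest-neighbor distance, nm.
#' @param extent Side of the clipping square, nm (at least `4 * spacing`).
#' @param jitter_sd Standard deviation of the positional jitter, nm. A
#'   deterministic tie-breaking jitter of 0.0001 nm is always applied so
#'   the ideal lattice's exactly cocircular configurations cannot produce
#'   triangulation ties.
#' @param seed Integer seed.
#' @param prune_factor Passed to the ground-truth oracle.
#' @return A `planted_lattice`: list with `points` (tibble `x_nm`, `y_nm`),
#'   `truth` (points plus `neighbor_count`, `interior`), `defects` (tibble of
#'   planted defects), `spacing`.
#' @examples
#' lat <- gen_hex_lattice(spacing = 60, extent = 360, jitter_sd = 0, seed = 1)
#' table(lat$truth$neighbor_count[lat$truth$interior])
#' @export
gen_hex_lattice <- function(spacing, extent, jitter_sd = 0, seed = 1,
                            prune_factor = 1.8) {
  if (spacing <= 0) abort("`spacing` must be positive.")
  if (extent < 4 * spacing) abort("`extent` must be at least 4 * spacing.")
  if (jitter_sd < 0) abort("`jitter_sd` must be non-negative.")
  rowh <- spacing * sqrt(3) / 2
  jrow <- 0:floor(extent / rowh)
  # parallelogram patch spanned by the lattice vectors (rows shift by half a
  # spacing each row): every boundary point is then a convex-hull point, so
  # the clip introduces no spurious interior under-coordination
  pts <- purrr::map_dfr(jrow, function(j) {
    off <- j * spacing / 2
    xs <- seq(off, off + extent, by = spacing)
    tibble(x_nm = xs, y_nm = j * rowh)
  })
  # a deterministic sub-nanometer displacement always breaks the exact
  # cocircularity of the ideal lattice, so every triangulation (library or
  # exhaustive oracle) resolves ties identically
  sd_eff <- max(jitter_sd, 1e-4)
  pts <- withr::with_seed(seed, {
    dplyr::mutate(pts,
                  x_nm = .data$x_nm + rnorm(dplyr::n(), sd = sd_eff),
                  y_nm = .data$y_nm + rnorm(dplyr::n(), sd = sd_eff))
  })
  new_planted_lattice(pts, spacing,
                      defects = tibble(type = character(),
                                       x_nm = numeric(), y_nm = numeric()),
                      prune_factor = prune_factor)
}

new_planted_lattice <- function(points, spacing, defects, prune_factor = 1.8) {
  ref <- reference_triangulation(points, prune_factor = prune_factor)
  structure(list(
    points = as_tibble(points),
    truth = dplyr::mutate(as_tibble(points),
                          neighbor_count = ref$neighbor_count,
                          interior = ref$interior),
    defects = defects,
    spacing = spacing,
    prune_factor = prune_factor
  ), class = "planted_lattice")
}

#' @export
print.planted_lattice <- function(x, ...) {
  cat(sprintf("<planted_lattice> %d points, spacing %g nm, %d planted defects\n",
              nrow(x$points), x$spacing, nrow(x$defects)))
  invisible(x)
}

#' Plant point defects into a lattice
#'
#' Removes `vacancies` randomly chosen interior points, inserts
#' `interstitials` extra points at centers of randomly chosen interior
#' lattice cells (triangle centroids), and carves a circular void of radius
#' `void_radius` around a randomly chosen interior point. Ground truth is
#' recomputed from scratch with the exhaustive oracle.
#'
#' @param lattice A `planted_lattice` from [gen_hex_lattice()].
#' @param vacancies,interstitials Counts of point defects to plant.
#' @param void_radius Radius of the void, nm (0 for none).
#' @param seed Integer seed.
#' @return A new `planted_lattice` with updated points, truth and defect log.
#' @export
plant_defects <- function(lattice, vacancies = 0, interstitials = 0,
                          void_radius = 0, seed = 1) {
  stopifnot(inherits(lattice, "planted_lattice"))
  pts <- lattice$points
  truth <- lattice$truth
  interior_idx <- which(truth$interior)
  if (vacancies >= length(interior_idx)) {
    abort("requested vacancies must be fewer than the interior point count.")
  }
  defects <- lattice$defects
  withr::with_seed(seed, {
    if (vacancies > 0) {
      rm_idx <- sample(interior_idx, vacancies)
      defects <- dplyr::bind_rows(defects,
        tibble(type = "vacancy", x_nm = pts$x_nm[rm_idx], y_nm = pts$y_nm[rm_idx]))
      pts <- pts[-rm_idx, ]
    }
    if (interstitials > 0) {
      ref <- reference_triangulation(pts, lattice$prune_factor)
      cand <- which(ref$interior)
      if (length(cand) < interstitials) abort("not enough interior cells for interstitials.")
      pick <- sample(cand, interstitials)
      # centroid of the lattice cell up-right of the picked site: the
      # honeycomb hole of the ideal triangular lattice
      newx <- pts$x_nm[pick] + lattice$spacing / 2 + rnorm(interstitials, sd = 1e-4)
      newy <- pts$y_nm[pick] + lattice$spacing / (2 * sqrt(3)) +
        rnorm(interstitials, sd = 1e-4)
      defects <- dplyr::bind_rows(defects,
        tibble(type = "interstitial", x_nm = newx, y_nm = newy))
      pts <- dplyr::bind_rows(pts, tibble(x_nm = newx, y_nm = newy))
    }
    if (void_radius > 0) {
      ref <- reference_triangulation(pts, lattice$prune_factor)
      cand <- which(ref$interior)
      ctr <- cand[sample(length(cand), 1)]
      cx <- pts$x_nm[ctr]; cy <- pts$y_nm[ctr]
      gone <- (pts$x_nm - cx)^2 + (pts$y_nm - cy)^2 <= void_radius^2
      if (all(gone)) abort("void would cover the entire lattice.")
      defects <- dplyr::bind_rows(defects,
        tibble(type = "void", x_nm = cx, y_nm = cy))
      pts <- pts[!gone, ]
    }
  })
  new_planted_lattice(pts, lattice$spacing, defects,
                      prune_factor = lattice$prune_factor)
}
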