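#' Pruned Delaunay triangulation of fibril centers
#'
#' Delaunay-triangulates the points and removes edges longer than
#' `prune_factor` times the median edge length, which suppresses spurious
#' adjacencies across voids and boundary concavities. The default 1.8
#' sits safely between the population of genuine lattice edges (within
#' ~1.3x the median even for strongly jittered packings) and the
#' shortest spurious chords (2x the median, from skipped points on flat
#' boundary runs), so the cut never lands on a tie.
#'
#' @param fibrils A [fibril_set()] or data frame with `x_nm`, `y_nm`.
#' @param prune_factor Pruning multiple of the median edge length.
#' @return A tibble of surviving edges (`i`, `j`, `length_nm`), with the
#'   full triangle index matrix attached as attribute `"triangles"` and the
#'   point count as `"n_points"`.
#' @export
triangulate_fibrils <- function(fibrils, prune_factor = 1.8) {
  pts <- as.data.frame(fibrils)[, c("x_nm", "y_nm")]
  n <- nrow(pts)
  if (n < 3) abort("need at least 3 points to triangulate.")
  rng <- range(c(diff(range(pts$x_nm)), diff(range(pts$y_nm))))
  dl <- tryCatch(
    deldir::deldir(pts$x_nm, pts$y_nm, suppressMsge = TRUE),
    error = function(e) abort(paste0("triangulation failed (collinear points?): ",
                                     conditionMessage(e))))
  sg <- dl$delsgs
  if (is.null(sg) || nrow(sg) == 0) abort("degenerate point set: no Delaunay edges.")
  len <- sqrt((sg$x1 - sg$x2)^2 + (sg$y1 - sg$y2)^2)
  alive <- len <= prune_factor * median(len)
  edges <- tibble(i = pmin(sg$ind1, sg$ind2)[alive],
                  j = pmax(sg$ind1, sg$ind2)[alive],
                  length_nm = len[alive])
  tri <- deldir::triMat(dl)
  if (!is.matrix(tri)) tri <- matrix(tri, ncol = 3)
  attr(edges, "triangles") <- tri
  attr(edges, "n_points") <- n
  edges
}

edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j))

#' Classify interior versus peripheral fibrils
#'
#' A fibril is peripheral iff it lies on the boundary of the pruned
#' triangulation: it touches an edge that bounds at most one surviving
#' triangle (a triangle survives when all three of its edges survive
#' pruning), or it has no surviving edges at all. All other fibrils are
#' interior. On convex, void-free bundles this coincides with the convex
#' hull rule.
#'
#' @param fibrils A [fibril_set()] (used for the point count).
#' @param edges Pruned edge tibble from [triangulate_fibrils()].
#' @return Logical vector, `TRUE` for interior points.
#' @export
classify_interior <- function(fibrils, edges) {
  n <- attr(edges, "n_points") %||% nrow(as.data.frame(fibrils))
  tri <- attr(edges, "triangles")
  if (is.null(tri)) abort("`edges` must come from triangulate_fibrils().")
  alive_keys <- edge_key(edges$i, edges$j)
  tri_keys <- cbind(edge_key(tri[, 1], tri[, 2]),
                    edge_key(tri[, 2], tri[, 3]),
                    edge_key(tri[, 1], tri[, 3]))
  tri_ok <- rowSums(matrix(tri_keys %in% alive_keys, nrow(tri))) == 3L
  cnt <- table(factor(as.vector(tri_keys[tri_ok, , drop = FALSE]),
                      levels = alive_keys))
  boundary_keys <- names(cnt)[cnt <= 1L]
  on_boundary <- rep(FALSE, n)
  if (length(boundary_keys)) {
    bk <- do.call(rbind, strsplit(boundary_keys, " "))
    on_boundary[as.integer(bk)] <- TRUE
  }
  deg <- neighbor_counts(edges)
  deg > 0L & !on_boundary
}

#' Per-fibril neighbor counts
#'
#' Vertex degrees of the pruned Delaunay graph.
#'
#' @param edges Pruned edge tibble from [triangulate_fibrils()].
#' @param n_points Number of points; taken from the edge attributes when
#'   omitted.
#' @return Integer vector of neighbor counts.
#' @export
neighbor_counts <- function(edges, n_points = NULL) {
  n <- n_points %||% attr(edges, "n_points")
  if (is.null(n)) n <- max(edges$i, edges$j)
  tabulate(c(edges$i, edges$j), nbins = n)
}

#' Defect analysis of a fibril point pattern
#'
#' The full defect-quantification pipeline: pruned Delaunay triangulation,
#' periphery exclusion, neighbor counts, disclination labels (`five` red,
#' `seven` blue, `six` clear, `other` gray in the conventional coloring),
#' and the defect proportion `d` = fraction of interior fibrils whose
#' neighbor count differs from six.
#'
#' @param fibrils A [fibril_set()] or data frame with `x_nm`, `y_nm`.
#' @param prune_factor Passed to [triangulate_fibrils()].
#' @return A `defect_report`: list with `points` (tibble `x_nm`, `y_nm`,
#'   `neighbor_count`, `interior`, `label`), `edges`, `defect_proportion`,
#'   `median_edge_nm` (median over edges joining two interior fibrils),
#'   `edge_lengths_nm` (those same lengths), `n_interior`.
#' @examples
#' lat <- gen_hex_lattice(spacing = 60, extent = 360, seed = 1)
#' rep <- defect_report(lat$points)
#' rep$defect_proportion  # 0 for a perfect lattice
#' @export
defect_report <- function(fibrils, prune_factor = 1.8) {
  pts <- as_tibble(as.data.frame(fibrils)[, c("x_nm", "y_nm")])
  edges <- triangulate_fibrils(pts, prune_factor)
  interior <- classify_interior(pts, edges)
  counts <- neighbor_counts(edges, nrow(pts))
  label <- dplyr::case_when(
    !interior ~ "peripheral",
    counts == 5L ~ "five",
    counts == 6L ~ "six",
    counts == 7L ~ "seven",
    TRUE ~ "other"
  )
  n_int <- sum(interior)
  d <- if (n_int > 0) mean(counts[interior] != 6L) else NA_real_
  if (n_int == 0) warn("no interior fibrils: defect proportion is undefined.")
  int_edges <- edges$length_nm[interior[edges$i] & interior[edges$j]]
  structure(list(
    points = dplyr::mutate(pts, neighbor_count = counts, interior = interior,
                           label = label),
    edges = edges,
    defect_proportion = d,
    median_edge_nm = if (length(int_edges)) median(int_edges) else NA_real_,
    edge_lengths_nm = int_edges,
    n_interior = n_int,
    prune_factor = prune_factor
  ), class = "defect_report")
}

#' @export
print.defect_report <- function(x, ...) {
  cat(sprintf(paste0("<defect_report> %d fibrils (%d interior), d = %.3f, ",
                     "median edge %.2f nm\n"),
              nrow(x$points), x$n_interior, x$defect_proportion,
              x$median_edge_nm))
  invisible(x)
}

#' @method tidy defect_report
#' @export
tidy.defect_report <- function(x, ...) x$points

#' @method glance defect_report
#' @export
glance.defect_report <- function(x, ...) {
  tibble(
    n_fibrils = nrow(x$points),
    n_interior = x$n_interior,
    defect_proportion = x$defect_proportion,
    median_edge_nm = x$median_edge_nm,
    prop_five = mean(x$points$label == "five"),
    prop_seven = mean(x$points$label == "seven")
  )
}

#' Normalized defect distributions
#'
#' Edge-length and neighbor-count distributions of the interior of a
#' [defect_report()], normalized to unit mass.
#'
#' @param report A `defect_report`.
#' @param binwidth Edge-length bin width in nm; default a twentieth of the
#'   median edge length.
#' @return A list with `edge_lengths` (tibble `mid`, `density`, unit mass
#'   when multiplied by the bin width), `neighbor_counts` (tibble `count`,
#'   `prop` summing to 1 over interior fibrils), and `median_edge_nm`.
#' @export
defect_distributions <- function(report, binwidth = NULL) {
  stopifnot(inherits(report, "defect_report"))
  el <- report$edge_lengths_nm
  if (!length(el)) abort("report has no interior edges.")
  if (is.null(binwidth)) binwidth <- median(el) / 20
  breaks <- seq(floor(min(el) / binwidth) * binwidth,
                max(el) + binwidth, by = binwidth)
  h <- graphics::hist(el, breaks = breaks, plot = FALSE)
  counts <- report$points$neighbor_count[report$points$interior]
  nc <- as.data.frame(table(count = counts), stringsAsFactors = FALSE)
  list(
    edge_lengths = tibble(mid = h$mids, density = h$density),
    neighbor_counts = tibble(count = as.integer(nc$count),
                             prop = nc$Freq / sum(nc$Freq)),
    median_edge_nm = report$median_edge_nm
  )
}
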