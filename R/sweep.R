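# deterministic per-cell seed expansion: a small multiplicative hash of the
# base seed and the cell indices, kept below 2^31
derive_seed <- function(seed0, ...) {
  h <- as.numeric(seed0) %% 2147483629
  for (v in c(...)) h <- (h * 31 + as.numeric(v) + 1) %% 2147483629
  as.integer(h + 1)
}

#' Parameter sweep over destabilization strength and mean phase field
#'
#' Runs the full simulate-detect-analyze pipeline over the grid of
#' `(r, phi0)` combinations, with `n_reps` independently seeded initial
#' conditions per cell. Per-cell seeds are derived deterministically from
#' `seed0`, so the whole sweep is reproducible and cells are independent.
#' Individual cell failures are recorded, not fatal.
#'
#' @param r_values,phi0_values Numeric vectors defining the sweep grid.
#' @param grid A [grid_spec()].
#' @param mask Optional [domain_mask()] (or `NULL` for periodic runs).
#' @param base_params A [pfc_params()]; its `r` and `phi0` are overridden
#'   cell by cell.
#' @param n_reps Replicate initial conditions per cell.
#' @param m2,lam Initial-condition parameters passed to [sample_grf()].
#' @param seed0 Base seed.
#' @return A `pfc_sweep` tibble with one row per (r, phi0, rep):
#'   `crystallized_fraction`, `defect_proportion`, `median_edge_nm`,
#'   `n_fibrils`, `failed`, and list-columns `edge_lengths` and
#'   `neighbor_counts` for pooling.
#' @export
run_sweep <- function(r_values, phi0_values, grid, mask = NULL,
                      base_params = pfc_params(), n_reps = 1,
                      m2 = 0.01, lam = 10, seed0 = 1) {
  if (!length(r_values) || !length(phi0_values)) {
    abort("sweep grid must be non-empty.")
  }
  cells <- tidyr::expand_grid(
    ri = seq_along(r_values), pi_ = seq_along(phi0_values),
    rep = seq_len(n_reps))
  rows <- purrr::pmap(cells, function(ri, pi_, rep) {
    r <- r_values[ri]; phi0 <- phi0_values[pi_]
    seed <- derive_seed(seed0, ri, pi_, rep)
    p <- base_params
    p$r <- r; p$phi0 <- phi0
    out <- tibble(r = r, phi0 = phi0, rep = rep, seed = seed,
                  crystallized_fraction = NA_real_,
                  defect_proportion = NA_real_,
                  median_edge_nm = NA_real_, n_fibrils = NA_integer_,
                  edge_lengths = list(numeric()),
                  neighbor_counts = list(integer()),
                  failed = TRUE, error = NA_character_)
    tryCatch({
      ic <- sample_grf(grid, mask, phi0 = phi0, m2 = m2, lam = lam, seed = seed)
      tr <- pfc_run(ic, mask, p, keep_fields = "none")
      out$crystallized_fraction <- tail(tr$series$crystallized_fraction, 1)
      fs <- detect_fibrils(tr$final, mask, qstar = p$qstar)
      out$n_fibrils <- nrow(fs)
      if (nrow(fs) >= 10) {
        repo <- defect_report(fs)
        out$defect_proportion <- repo$defect_proportion
        out$median_edge_nm <- repo$median_edge_nm
        out$edge_lengths <- list(repo$edge_lengths_nm)
        out$neighbor_counts <-
          list(repo$points$neighbor_count[repo$points$interior])
      }
      out$failed <- FALSE
      out
    }, error = function(e) {
      out$error <- conditionMessage(e)
      out
    })
  })
  res <- dplyr::bind_rows(rows)
  class(res) <- c("pfc_sweep", class(res))
  res
}

#' Pool sweep distributions
#'
#' Pools the per-run edge-length or neighbor-count samples of a sweep into
#' normalized distributions, per `(r, phi0)` cell or overall.
#'
#' @param sweep A `pfc_sweep` from [run_sweep()].
#' @param what `"edge_lengths"` or `"neighbor_counts"`.
#' @param by `"cell"` (per (r, phi0) combination) or `"overall"`.
#' @param binwidth Bin width for edge lengths (default: pooled median / 20).
#' @return For edge lengths, a tibble of `mid`, `density` (unit mass per
#'   group) plus grouping columns and `median_nm`; for neighbor counts, a
#'   tibble of `count`, `prop` plus grouping columns.
#' @export
aggregate_sweep <- function(sweep, what = c("edge_lengths", "neighbor_counts"),
                            by = c("cell", "overall"), binwidth = NULL) {
  what <- match.arg(what)
  by <- match.arg(by)
  ok <- !sweep$failed
  if (!any(ok)) abort("no successful sweep cells to aggregate.")
  sw <- sweep[ok, ]
  groups <- if (by == "cell") dplyr::group_by(sw, .data$r, .data$phi0) else
    dplyr::group_by(sw)
  if (what == "neighbor_counts") {
    return(dplyr::reframe(groups, {
      v <- unlist(.data$neighbor_counts)
      tb <- table(v)
      tibble(count = as.integer(names(tb)), prop = as.numeric(tb) / length(v))
    }))
  }
  all_el <- unlist(sw$edge_lengths)
  if (!length(all_el)) abort("no edge-length samples in the sweep.")
  if (is.null(binwidth)) binwidth <- median(all_el) / 20
  breaks <- seq(floor(min(all_el) / binwidth) * binwidth,
                max(all_el) + binwidth, by = binwidth)
  dplyr::reframe(groups, {
    v <- unlist(.data$edge_lengths)
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    tibble(mid = h$mids, density = h$density, median_nm = median(v))
  })
}
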