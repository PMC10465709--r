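# the five developmental time-point columns, in order
timepoint_cols <- function(table) {
  missing_tp <- setdiff(TIMEPOINTS, names(table))
  if (length(missing_tp)) {
    abort(sprintf("abundance table is missing time-point column(s): %s.",
                  paste(missing_tp, collapse = ", ")))
  }
  TIMEPOINTS
}

check_abundance <- function(table) {
  tp <- timepoint_cols(table)
  vals <- as.matrix(table[tp])
  if (!is.numeric(vals)) abort("time-point columns must be numeric.")
  if (any(vals <= 0, na.rm = TRUE)) {
    abort("abundances must be positive where present.")
  }
  invisible(tp)
}

#' Keep only proteins quantified at every time point
#'
#' Complete-case filter across the five developmental time points: proteins
#' with one or more missing values are excluded. Row order and any extra
#' annotation columns are preserved. Idempotent.
#'
#' @param table An abundance data frame with columns `E12.5` ... `E14.5`
#'   (plus any identifier/annotation columns).
#' @return The filtered tibble (possibly empty).
#' @examples
#' tab <- gen_abundance_table(20, missing_rate = 0.3, seed = 1)
#' nrow(filter_complete(tab))
#' @export
filter_complete <- function(table) {
  tp <- check_abundance(table)
  as_tibble(table)[complete.cases(as.matrix(table[tp])), ]
}

#' Log2 fold change relative to E12.5
#'
#' Normalizes each protein's trajectory to its E12.5 abundance:
#' `value(t) = log2(a_t / a_E12.5)`, so the E12.5 column is identically 0.
#' The table must be complete-case (apply [filter_complete()] first).
#'
#' @param table A complete-case abundance table.
#' @return A tibble with the same identifier/annotation columns and the five
#'   time-point columns holding log2 fold changes.
#' @examples
#' tab <- tibble::tibble(protein = "Col1a1", E12.5 = 10, E13.0 = 20,
#'                       E13.5 = 40, E14.0 = 20, E14.5 = 10)
#' log2_fold_change(tab)  # 0 1 2 1 0
#' @export
log2_fold_change <- function(table) {
  tp <- timepoint_cols(table)
  vals <- as.matrix(table[tp])
  if (!is.numeric(vals)) abort("time-point columns must be numeric.")
  if (anyNA(vals)) {
    abort("table has missing values; apply filter_complete() first.")
  }
  ref <- vals[, "E12.5"]
  bad <- which(!(ref > 0))
  if (length(bad)) {
    ids <- if ("protein" %in% names(table)) table$protein[bad] else bad
    abort(sprintf("non-positive E12.5 reference abundance for: %s.",
                  paste(ids, collapse = ", ")))
  }
  if (any(vals <= 0)) abort("abundances must be positive.")
  fc <- log2(vals / ref)
  out <- as_tibble(table)
  out[tp] <- as_tibble(as.data.frame(fc))
  out
}

#' Peak time point of each fold-change trajectory
#'
#' The time point at which each protein's trajectory is maximal; ties are
#' broken toward the earliest time point (so an all-flat trajectory peaks
#' at E12.5).
#'
#' @param fc A fold-change (or abundance) table with the five time-point
#'   columns, complete-case.
#' @return A tibble with the identifier columns of `fc` plus `peak`, a
#'   factor over the five time points.
#' @export
peak_timepoint <- function(fc) {
  tp <- timepoint_cols(fc)
  vals <- as.matrix(fc[tp])
  if (anyNA(vals)) abort("table has missing values; apply filter_complete() first.")
  idx <- apply(vals, 1L, which.max)  # which.max breaks ties to the first
  out <- as_tibble(fc)[, setdiff(names(fc), tp), drop = FALSE]
  out$peak <- factor(TIMEPOINTS[idx], levels = TIMEPOINTS)
  out
}

#' Long-format fold-change export
#'
#' Pivots a fold-change table to heatmap-ready long format (one row per
#' protein and time point), optionally joining a two-column annotation
#' table (`protein`, `category`).
#'
#' @param fc A fold-change table from [log2_fold_change()].
#' @param annotation Optional data frame with columns `protein`, `category`.
#' @return A tibble `protein`, `timepoint`, `log2fc` (and `category`).
#' @export
fold_change_long <- function(fc, annotation = NULL) {
  tp <- timepoint_cols(fc)
  long <- tidyr::pivot_longer(as_tibble(fc), dplyr::all_of(tp),
                              names_to = "timepoint", values_to = "log2fc")
  long$timepoint <- factor(long$timepoint, levels = TIMEPOINTS)
  if (!is.null(annotation)) {
    stopifnot(all(c("protein", "category") %in% names(annotation)))
    long <- dplyr::left_join(long, as_tibble(annotation), by = "protein")
  }
  long
}

#' Read and write abundance tables
#'
#' CSV layout: first column the protein identifier, then the five time-point
#' columns `E12.5,E13.0,E13.5,E14.0,E14.5`; empty cells are missing values.
#' Extra columns are carried through.
#'
#' @param path CSV path.
#' @param table An abundance (or fold-change) table.
#' @return `read_abundance` returns a tibble; `write_abundance` returns
#'   `path` invisibly.
#' @export
read_abundance <- function(path) {
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_abundance(tab)
  tab
}

#' @rdname read_abundance
#' @export
write_abundance <- function(table, path) {
  readr::write_csv(as_tibble(table), path, na = "")
  invisible(path)
}
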