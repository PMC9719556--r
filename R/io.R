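#' Read a single-column fluorescence CSV export
#'
#' Reads the per-sample CSV exports of gated fluorescence area values (one
#' numeric column, header optional) produced by flow-cytometry software.
#'
#' @param path Path to the CSV file.
#' @param ... Metadata passed to [fluorescence_sample()] (`clone_id`,
#'   `stage`, `female_peak`, `n_individuals`).
#' @return A [fluorescence_sample()].
#' @export
read_fluorescence_csv <- function(path, ...) {
  first <- readLines(path, n = 1)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, ",")[[1]][1])))
  d <- readr::read_csv(path, col_names = has_header, show_col_types = FALSE,
                       progress = FALSE)
  if (ncol(d) != 1) abort("Expected a single-column fluorescence CSV.")
  fluorescence_sample(d[[1]], ...)
}

#' Write fluorescence events as a single-column CSV
#'
#' @param sample A [fluorescence_sample()] or numeric vector.
#' @param path Output path.
#' @param header Column name to write (`NULL` for no header line).
#' @return `path`, invisibly.
#' @export
write_fluorescence_csv <- function(sample, path, header = "YL2.A") {
  x <- sample_events(sample)
  d <- tibble(!!(header %||% "x") := x)
  readr::write_csv(d, path, col_names = !is.null(header), progress = FALSE)
  invisible(path)
}

#' Read a sample sheet
#'
#' The sample sheet is a TSV with one row per flow-cytometry sample and
#' columns `file` (events CSV, relative to the sheet's directory), `clone_id`,
#' `stage`, `n_males`, and optionally `female_peak`.
#'
#' @param path Path to the TSV.
#' @return A tibble with absolute file paths.
#' @export
read_sample_sheet <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("file", "clone_id", "stage", "n_males")
  if (!all(need %in% names(d))) {
    abort(paste("Sample sheet must have columns:", paste(need, collapse = ", ")))
  }
  d$file <- ifelse(file.exists(d$file), d$file,
                   file.path(dirname(path), d$file))
  d
}

#' Read and write class-frequency tables
#'
#' Class tables are TSVs with columns `clone_id` (optional on read),
#' `class_k` and `frequency` (or `proportion`).
#'
#' @param x A data frame to write.
#' @param path File path.
#' @return The tibble read, or `path` invisibly for the writer.
#' @export
read_class_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("proportion" %in% names(d) && !"frequency" %in% names(d)) {
    d <- rename(d, frequency = proportion)
  }
  if (!all(c("class_k", "frequency") %in% names(d))) {
    abort("Class table needs `class_k` and `frequency` columns.")
  }
  d
}

#' @rdname read_class_table
#' @export
write_class_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Serialise a grid fit
#'
#' Writes the RMSE surface as TSV and the best-fit summary as JSON, the
#' machine-readable forms of a [grid_fit()] result.
#'
#' @param fit An `ise_fit`.
#' @param surface_path,summary_path Output paths (either may be `NULL` to
#'   skip).
#' @return `fit`, invisibly.
#' @export
write_fit <- function(fit, surface_path = NULL, summary_path = NULL) {
  stopifnot(inherits(fit, "ise_fit"))
  if (!is.null(surface_path)) {
    readr::write_tsv(fit$surface, surface_path, progress = FALSE)
  }
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      list(n_ise = fit$n_ise, best_tb = fit$best_tb, best_cb = fit$best_cb,
           best_rmse = fit$best_rmse, grid_step = fit$grid_step,
           n_grid = nrow(fit$surface)),
      summary_path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(fit)
}
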