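#' Pipeline configuration
#'
#' Bundles the tunables of [run_pipeline()]: grid resolution for the
#' parameter search, mixture-fitting settings, the female-peak CV exclusion
#' cutoff, and the root seed from which all randomness is derived.
#'
#' @param grid_step Grid spacing of the (tb, cb) search (default 0.05).
#' @param g_min,g_max,family,tol,max_iter Mixture settings, see
#'   [fit_finite_mixture()].
#' @param window Component-to-class matching window, see
#'   [assign_components_to_classes()].
#' @param cv_cutoff Female-peak CV exclusion threshold in percent
#'   (default 3.5).
#' @param seed Root seed.
#' @param verbose Print progress messages?
#' @return A list of class `run_config`.
#' @export
run_config <- function(grid_step = 0.05, g_min = 3, g_max = 8,
                       family = "skew_normal", tol = 1e-5, max_iter = 1000,
                       window = 0.05, cv_cutoff = 3.5, seed = 1,
                       verbose = FALSE) {
  stopifnot(cv_cutoff > 0)
  structure(
    list(grid_step = grid_step, g_min = g_min, g_max = g_max, family = family,
         tol = tol, max_iter = max_iter, window = window,
         cv_cutoff = cv_cutoff, seed = as.integer(seed), verbose = verbose),
    class = "run_config"
  )
}

pipeline_log <- function(lines, config) {
  if (isTRUE(config$verbose)) message(paste(lines, collapse = "\n"))
  lines
}

#' Run the full transmission-analysis pipeline
#'
#' Orchestrates the analysis end to end: quality control of each sample via
#' the female internal-standard CV, finite-mixture decomposition into
#' genome-size class proportions, per-clone averaging of replicate
#' frequencies, grid-search estimation of transmission and cosegregation
#' bias, observed/expected tables against the unbiased expectation, and
#' replicated G-tests per clone and stage. QC-excluded samples are reported,
#' never silently dropped. Re-running with an identical configuration
#' reproduces all numeric outputs.
#'
#' @param samples A named list of [fluorescence_sample()] objects, or the
#'   path to a sample-sheet TSV (see [read_sample_sheet()]).
#' @param karyotypes A single [ise_karyotype()], or a named list of them
#'   keyed by `clone_id`.
#' @param out_dir Output directory (created if needed); `NULL` to skip
#'   writing files.
#' @param config A [run_config()].
#' @return A list (invisibly if `out_dir` is set): `qc`, `class_tables`
#'   (per-sample tibble), `frequencies` (per clone), `fits` (tibble +
#'   `fit_objects`), `oe` (per clone), `gtests` (per clone x stage), `log`.
#' @export
run_pipeline <- function(samples, karyotypes, out_dir = NULL,
                         config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- c(sprintf("iseseg %s pipeline run, seed %d, %s",
                         as.character(utils::packageVersion("iseseg")),
                         config$seed, format(Sys.time(), "%Y-%m-%d %H:%M:%S")))

  if (is.character(samples)) {
    sheet <- read_sample_sheet(samples)
    samples <- purrr::pmap(sheet, function(file, clone_id, stage, n_males, ...) {
      extra <- list(...)
      read_fluorescence_csv(file, clone_id = clone_id, stage = stage,
                            n_individuals = n_males,
                            female_peak = extra$female_peak %||% NA_real_)
    })
    names(samples) <- paste0(sheet$clone_id, "_", sheet$stage, "_",
                             seq_len(nrow(sheet)))
  }
  stopifnot(length(samples) >= 1)
  if (is.null(names(samples)) || anyNA(names(samples)) || any(names(samples) == "")) {
    names(samples) <- paste0("sample", seq_along(samples))
  }
  samples <- purrr::map(samples, function(s) {
    if (!is.finite(s$female_peak)) s$female_peak <- estimate_female_peak(s)
    s
  })
  if (inherits(karyotypes, "ise_karyotype")) {
    ids <- unique(vapply(samples, function(s) s$clone_id, character(1)))
    karyotypes <- setNames(rep(list(karyotypes), length(ids)), ids)
  }

  # --- QC on the female internal-standard peak ---------------------------
  qc <- purrr::imap_dfr(samples, function(s, id) {
    mutate(qc_cv(s, cutoff = config$cv_cutoff),
           sample_id = id, clone_id = s$clone_id, stage = s$stage,
           .before = 1)
  })
  log_lines <- c(log_lines, pipeline_log(sprintf(
    "QC: %d/%d samples pass the %.1f%% female-peak CV cutoff",
    sum(!qc$excluded), nrow(qc), config$cv_cutoff), config))
  if (any(qc$excluded)) {
    log_lines <- c(log_lines, paste("excluded:", paste(
      qc$sample_id[qc$excluded], sprintf("(CV %.2f%%)",
                                         qc$cv_percent[qc$excluded]),
      collapse = ", ")))
  }
  kept <- samples[qc$sample_id[!qc$excluded]]
  if (length(kept) == 0) abort("Every sample failed QC; nothing to analyse.")

  # --- mixture decomposition into class proportions ----------------------
  class_tables <- purrr::imap_dfr(kept, function(s, id) {
    ky <- karyotypes[[s$clone_id]]
    if (is.null(ky)) abort(sprintf("No karyotype supplied for clone %s.", s$clone_id))
    dec <- decompose_sample(s, ky, window = config$window,
                            g_min = config$g_min, g_max = config$g_max,
                            family = config$family, tol = config$tol,
                            max_iter = config$max_iter, seed = config$seed)
    mutate(select(dec$classes, class_k, proportion, mean_fluorescence),
           sample_id = id, clone_id = s$clone_id, stage = s$stage,
           n_males = s$n_individuals, .before = 1)
  })

  # --- per-clone frequencies (mean over replicate samples) ---------------
  frequencies <- class_tables %>%
    group_by(clone_id, class_k) %>%
    summarise(frequency = mean(proportion), .groups = "drop_last") %>%
    mutate(frequency = frequency / sum(frequency)) %>%
    ungroup()

  # --- grid fit + O/E per clone ------------------------------------------
  fit_objects <- purrr::map(split(frequencies, frequencies$clone_id),
                            function(d) grid_fit(d[, c("class_k", "frequency")],
                                                 grid_step = config$grid_step))
  fits <- purrr::imap_dfr(fit_objects, function(f, id) {
    mutate(glance(f), clone_id = id, .before = 1)
  })
  oe <- purrr::imap_dfr(split(frequencies, frequencies$clone_id), function(d, id) {
    mutate(oe_ratios(d[, c("class_k", "frequency")],
                     unbiased_distribution(nrow(d) - 1)),
           clone_id = id, .before = 1)
  })

  # --- replicated G-tests per clone x stage ------------------------------
  gtests <- class_tables %>%
    group_by(clone_id, stage) %>%
    dplyr::group_map(function(d, key) {
      reps <- split(d, d$sample_id)
      counts <- purrr::imap(reps, function(r, id) {
        reconstruct_counts(r$n_males[1], r[, c("class_k", "proportion")])
      })
      expected <- unbiased_distribution(length(counts[[1]]$count) - 1)$frequency
      res <- if (length(counts) >= 2) {
        repeated_g_test(counts, expected)
      } else {
        g_test(counts[[1]], expected)
      }
      mutate(res, clone_id = key$clone_id, stage = key$stage, .before = 1)
    }) %>% bind_rows()

  result <- list(qc = qc, class_tables = class_tables,
                 frequencies = frequencies, fits = fits,
                 fit_objects = fit_objects, oe = oe, gtests = gtests,
                 log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "classes"), recursive = TRUE,
               showWarnings = FALSE)
    readr::write_tsv(qc, file.path(out_dir, "qc.tsv"), progress = FALSE)
    for (id in unique(class_tables$sample_id)) {
      write_class_table(dplyr::filter(class_tables, sample_id == id),
                        file.path(out_dir, "classes", paste0(id, ".tsv")))
    }
    readr::write_tsv(frequencies, file.path(out_dir, "frequencies.tsv"),
                     progress = FALSE)
    readr::write_tsv(fits, file.path(out_dir, "fits.tsv"), progress = FALSE)
    jsonlite::write_json(fits, file.path(out_dir, "fits.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    for (id in names(fit_objects)) {
      write_fit(fit_objects[[id]],
                surface_path = file.path(out_dir,
                                         paste0("surface_", id, ".tsv")))
    }
    readr::write_tsv(oe, file.path(out_dir, "oe.tsv"), progress = FALSE)
    jsonlite::write_json(gtests, file.path(out_dir, "gtests.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
    return(invisible(result))
  }
  result
}
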