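# End-to-end orchestration: read -> cluster (or import) -> merge ->
# categorize -> transfer -> write -> evaluate.

#' Run the full identification-transfer pipeline
#'
#' Takes in-memory tibbles (or paths via the reader functions), clusters
#' the spectra at the requested stringency ladder (or imports external
#' cluster-assignment files), and for every threshold merges, categorizes
#' and transfers. Exactly one of internal clustering (`spectra`) and
#' imported clusters (`cluster_dir` / `assignments`) must be active.
#'
#' @param psms PSM tibble ([read_psm_table()] or `generate_dataset()$psms`).
#' @param spectra Spectrum tibble; required for internal clustering.
#' @param assignments Named list of assignment tibbles (one per threshold
#'   label), as produced by [cluster_spectra()]; alternative to `spectra`.
#' @param cluster_dir Directory of `<stem>.<label>.tsv` cluster files to
#'   import; alternative to `spectra` and `assignments`.
#' @param thresholds Named numeric ladder, default [default_thresholds()].
#' @param params A [cluster_params()].
#' @param output_dir Optional; when given, per-threshold transfer tables,
#'   summaries and a JSON run manifest are written there.
#' @param require_equal_mod_counts Passed to [categorize_clusters()].
#' @return List of class `ms2transfer_run`: `tables` (named list of
#'   transfer tables per threshold), `summaries`, `category_counts`,
#'   `ambiguous`, `manifest`.
#' @export
run_pipeline <- function(psms, spectra = NULL, assignments = NULL,
                         cluster_dir = NULL,
                         thresholds = default_thresholds(),
                         params = cluster_params(),
                         output_dir = NULL,
                         require_equal_mod_counts = TRUE) {
  sources <- c(!is.null(spectra), !is.null(assignments), !is.null(cluster_dir))
  if (sum(sources) != 1) {
    stop("exactly one of spectra (internal clustering), assignments, ",
         "or cluster_dir (imported clusters) must be given")
  }
  if (!is.null(cluster_dir)) {
    files <- list.files(cluster_dir, pattern = "\\.tsv$", full.names = TRUE)
    if (length(files) == 0) stop("no .tsv cluster files in ", cluster_dir)
    assignments <- lapply(files, read_cluster_assignments)
    names(assignments) <- vapply(assignments, attr, character(1),
                                 "threshold_label")
  }
  if (!is.null(spectra)) {
    assignments <- cluster_spectra(spectra, thresholds, params)
  }
  all_scans <- if (!is.null(spectra)) {
    spectra[, c("raw_file", "scan_number")]
  } else NULL
  tables <- lapply(assignments, function(asg) {
    merge_tables(psms, asg, all_scans) |>
      categorize_clusters(require_equal_mod_counts) |>
      transfer_identifications()
  })
  summaries <- lapply(tables, summarize_transfers)
  counts <- lapply(tables, category_counts)
  ambiguous <- dplyr::bind_rows(lapply(tables, ambiguous_cluster_fraction))
  manifest <- list(
    package = "ms2transfer",
    version = as.character(utils::packageVersion("ms2transfer")),
    timestamp = format(Sys.time(), tz = "UTC"),
    thresholds = as.list(vapply(names(assignments), function(x) x, character(1))),
    n_scans = if (!is.null(spectra)) nrow(spectra) else nrow(psms),
    n_psms_identified = sum(psms$is_identified),
    params = unclass(params)
  )
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    for (lab in names(tables)) {
      write_transfer_table(tables[[lab]],
                           file.path(output_dir, paste0("transfers.", lab, ".txt")))
      readr::write_tsv(summaries[[lab]],
                       file.path(output_dir, paste0("summary.", lab, ".tsv")),
                       progress = FALSE)
    }
    readr::write_tsv(ambiguous, file.path(output_dir, "ambiguous_fraction.tsv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  structure(list(tables = tables, summaries = summaries,
                 category_counts = counts, ambiguous = ambiguous,
                 manifest = manifest),
            class = "ms2transfer_run")
}

#' Run the masking evaluation across the threshold ladder
#'
#' Masks a fraction of the identifications, reruns the transfer pipeline
#' on the masked tables with the *same* cluster assignments, and reports
#' precision/recall/FDR per threshold.
#'
#' @inheritParams run_pipeline
#' @param fraction Masking fraction in (0, 1].
#' @param seed Seed for the masking draw.
#' @param strict Judge correctness on the modified sequence too.
#' @return Tibble with one `masking_report` row per threshold.
#' @export
run_masking <- function(psms, spectra = NULL, assignments = NULL,
                        fraction = 0.1, seed = 1L,
                        thresholds = default_thresholds(),
                        params = cluster_params(), strict = FALSE,
                        require_equal_mod_counts = TRUE) {
  masked <- mask_identifications(psms, fraction, seed)
  if (is.null(assignments)) {
    if (is.null(spectra)) stop("need spectra or assignments")
    assignments <- cluster_spectra(spectra, thresholds, params)
  }
  all_scans <- if (!is.null(spectra)) spectra[, c("raw_file", "scan_number")] else NULL
  reports <- lapply(assignments, function(asg) {
    tbl <- merge_tables(masked$psms, asg, all_scans) |>
      categorize_clusters(require_equal_mod_counts) |>
      transfer_identifications()
    precision_recall(tbl, masked$truth, strict = strict) |>
      dplyr::mutate(mask_fraction = fraction, seed = seed)
  })
  structure(dplyr::bind_rows(reports),
            class = c("masking_report", "tbl_df", "tbl", "data.frame"))
}

#' @export
print.ms2transfer_run <- function(x, ...) {
  cat("<ms2transfer_run> ", length(x$tables), " threshold(s): ",
      paste(names(x$tables), collapse = ", "), "\n", sep = "")
  glob <- x$summaries[[1]]
  glob <- glob[glob$batch_id == "(all)", ]
  cat("  scans: ", glob$n_scans, ", direct: ", glob$n_direct,
      " (first threshold: +", glob$n_transferred, " transferred, ",
      sprintf("%.1f%%", glob$psm_gain_percent), ")\n", sep = "")
  invisible(x)
}
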