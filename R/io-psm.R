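# PSM table (msms.txt dialect) reading and writing.

#' Column-name dialect for PSM tables
#'
#' Maps the internal column names to the header names used on disk. Defaults
#' are the MaxQuant msms.txt / msmsScans.txt conventions. `reporter_prefix`
#' is the stem of the per-channel reporter columns, completed with the
#' channel index (1-based).
#'
#' @param raw_file,scan_number,sequence,modified_sequence,proteins,score,pep
#'   Header names of the corresponding columns.
#' @param reporter_prefix Stem of the reporter intensity columns, e.g.
#'   `"Reporter intensity corrected "` giving
#'   `"Reporter intensity corrected 1"` etc.
#' @return A named list of class `psm_dialect`.
#' @export
psm_dialect <- function(raw_file = "Raw file",
                        scan_number = "Scan number",
                        sequence = "Sequence",
                        modified_sequence = "Modified sequence",
                        proteins = "Proteins",
                        score = "Score",
                        pep = "PEP",
                        reporter_prefix = "Reporter intensity corrected ") {
  structure(list(raw_file = raw_file, scan_number = scan_number,
                 sequence = sequence, modified_sequence = modified_sequence,
                 proteins = proteins, score = score, pep = pep,
                 reporter_prefix = reporter_prefix),
            class = "psm_dialect")
}

# raw-file labels are matched across tools by basename without extension
normalize_raw_file <- function(x) {
  sub("\\.(raw|RAW|mzML|mzml|mzXML|mgf|MGF|d)$", "", basename(x))
}

#' Read a search-engine PSM table
#'
#' Reads a tab-separated MaxQuant-style table (msms.txt or msmsScans.txt
#' dialect; one row per MS2 scan identification attempt) into a tidy PSM
#' tibble. Rows without a sequence are retained as unidentified scans.
#' Decoy (`REV__`/`"+"` reverse marker) and contaminant (`CON__`) rows are
#' flagged; they are parsed but never act as transfer donors downstream.
#' When a scan carries several rows, only the best-scoring one is kept.
#'
#' @param path Path to the tab-separated file.
#' @param dialect A [psm_dialect()].
#' @param plex_size Number of reporter channels expected; reporter columns
#'   beyond those present are filled with `NA`.
#' @return A tibble with columns `raw_file`, `scan_number`, `batch_id`,
#'   `sequence`, `modified_sequence`, `proteins`, `score`, `pep`,
#'   `is_decoy`, `is_contaminant`, `is_identified` and `reporter_1` ..
#'   `reporter_<plex_size>`.
#' @export
read_psm_table <- function(path, dialect = psm_dialect(), plex_size = 10) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  required <- c("raw_file", "scan_number", "sequence", "modified_sequence",
                "proteins", "score")
  for (key in required) {
    if (!dialect[[key]] %in% names(raw)) {
      stop("required column missing from ", path, ": '", dialect[[key]], "'")
    }
  }
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & col != "" & col != "NA" & is.na(x))
    if (length(bad) > 0) {
      stop("unparsable ", what, " in ", path, " at data line ", bad[1],
           ": '", col[bad[1]], "'")
    }
    x[col == "" | col == "NA"] <- NA_real_
    x
  }
  out <- tibble::tibble(
    raw_file = normalize_raw_file(raw[[dialect$raw_file]]),
    scan_number = as.integer(num(raw[[dialect$scan_number]], "scan number")),
    sequence = toupper(trimws(raw[[dialect$sequence]])),
    modified_sequence = trimws(raw[[dialect$modified_sequence]]),
    proteins = raw[[dialect$proteins]],
    score = num(raw[[dialect$score]], "score")
  )
  out$pep <- if (dialect$pep %in% names(raw)) num(raw[[dialect$pep]], "PEP") else NA_real_
  rev_col <- if ("Reverse" %in% names(raw)) raw[["Reverse"]] == "+" else FALSE
  out$is_decoy <- grepl("REV__", out$proteins, fixed = TRUE) | rev_col
  out$is_contaminant <- grepl("CON__", out$proteins, fixed = TRUE)
  out$is_identified <- !is.na(out$sequence) & out$sequence != ""
  out$sequence[!out$is_identified] <- NA_character_
  out$modified_sequence[out$modified_sequence == ""] <- NA_character_
  out$proteins[out$proteins == ""] <- NA_character_
  for (i in seq_len(plex_size)) {
    col <- paste0(dialect$reporter_prefix, i)
    out[[paste0("reporter_", i)]] <-
      if (col %in% names(raw)) num(raw[[col]], col) else NA_real_
  }
  out <- dplyr::mutate(out, batch_id = .data$raw_file, .after = "scan_number")
  best_psm_per_scan(out)
}

#' Keep the best-scoring PSM per scan
#'
#' @param psms PSM tibble.
#' @return Tibble with at most one row per (`raw_file`, `scan_number`),
#'   the highest `score` retained (ties by row order).
#' @export
best_psm_per_scan <- function(psms) {
  psms |>
    dplyr::arrange(.data$raw_file, .data$scan_number,
                   dplyr::desc(!is.na(.data$score)), dplyr::desc(.data$score)) |>
    dplyr::distinct(.data$raw_file, .data$scan_number, .keep_all = TRUE)
}

#' Write a PSM tibble back to the msms.txt dialect
#'
#' Inverse of [read_psm_table()]: internal columns are renamed to the
#' dialect's header names and written tab-separated.
#'
#' @param psms PSM tibble as returned by [read_psm_table()].
#' @param path Output path.
#' @param dialect A [psm_dialect()].
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path, dialect = psm_dialect()) {
  rep_cols <- grep("^reporter_[0-9]+$", names(psms), value = TRUE)
  out <- tibble::tibble(
    !!dialect$raw_file := psms$raw_file,
    !!dialect$scan_number := psms$scan_number,
    !!dialect$sequence := ifelse(is.na(psms$sequence), "", psms$sequence),
    !!dialect$modified_sequence :=
      ifelse(is.na(psms$modified_sequence), "", psms$modified_sequence),
    !!dialect$proteins := ifelse(is.na(psms$proteins), "", psms$proteins),
    !!dialect$score := psms$score,
    !!dialect$pep := psms$pep
  )
  for (col in rep_cols) {
    i <- sub("^reporter_", "", col)
    out[[paste0(dialect$reporter_prefix, i)]] <- psms[[col]]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
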