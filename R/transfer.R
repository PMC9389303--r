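# The transfer pipeline core: merge cluster assignments with PSM tables,
# categorize clusters into the six classes (a)-(f), and transfer
# identifications inside transferable and PTM-isomeric clusters.

CATEGORY_LETTERS <- c(singleton = "a", unanimous = "b",
                      fully_unidentified = "c", ambiguous = "d",
                      transferable = "e", ptm_isomeric = "f")

#' Merge a cluster assignment with a PSM table
#'
#' Produces one row per MS2 scan: the PSM fields (when a retained PSM
#' exists for the scan) joined with the scan's cluster id. Scans missing
#' from the assignment get fresh singleton cluster ids. A scan is a
#' "direct" identification iff it carries a retained, FDR-filtered target
#' PSM; decoy and contaminant PSMs are kept in the table but treated as
#' unidentified for all transfer decisions.
#'
#' @param psms PSM tibble ([read_psm_table()]).
#' @param assignment Cluster-assignment tibble
#'   ([read_cluster_assignments()] or one element of [cluster_spectra()]).
#' @param all_scans Optional tibble `raw_file`, `scan_number` enumerating
#'   every MS2 scan (e.g. from the spectrum tibble). Defaults to the union
#'   of scans in `psms` and `assignment`; PSMs for scans absent from
#'   `all_scans` are included with a warning.
#' @return A merged tibble with `cluster_id`, `identification_type`
#'   (`"direct"`/`"none"`) and all PSM columns; attribute
#'   `threshold_label` is carried over from the assignment.
#' @export
merge_tables <- function(psms, assignment, all_scans = NULL) {
  keys_psm <- psms[, c("raw_file", "scan_number")]
  if (is.null(all_scans)) {
    all_scans <- dplyr::distinct(
      dplyr::bind_rows(keys_psm, assignment[, c("raw_file", "scan_number")])
    )
  } else {
    all_scans <- dplyr::distinct(all_scans[, c("raw_file", "scan_number")])
    extra <- dplyr::anti_join(keys_psm, all_scans,
                              by = c("raw_file", "scan_number"))
    if (nrow(extra) > 0) {
      warning(nrow(extra), " PSM scan(s) absent from the scan list; ",
              "included anyway (the PSM table is authoritative)")
      all_scans <- dplyr::bind_rows(all_scans, extra)
    }
  }
  merged <- all_scans |>
    dplyr::left_join(psms, by = c("raw_file", "scan_number")) |>
    dplyr::left_join(assignment, by = c("raw_file", "scan_number"))
  if (!"batch_id" %in% names(merged)) merged$batch_id <- merged$raw_file
  merged$batch_id[is.na(merged$batch_id)] <- merged$raw_file[is.na(merged$batch_id)]
  if (!"is_identified" %in% names(merged)) merged$is_identified <- FALSE
  merged$is_identified[is.na(merged$is_identified)] <- FALSE
  for (flag in c("is_decoy", "is_contaminant")) {
    if (!flag %in% names(merged)) merged[[flag]] <- FALSE
    merged[[flag]][is.na(merged[[flag]])] <- FALSE
  }
  # fresh singleton ids for scans the clusterer never saw
  miss <- is.na(merged$cluster_id)
  base_id <- if (all(miss)) 0L else max(merged$cluster_id, na.rm = TRUE)
  merged$cluster_id[miss] <- base_id + seq_len(sum(miss))
  merged$identification_type <- ifelse(
    merged$is_identified & !merged$is_decoy & !merged$is_contaminant,
    "direct", "none")
  merged <- dplyr::arrange(merged, .data$raw_file, .data$scan_number)
  attr(merged, "threshold_label") <- attr(assignment, "threshold_label")
  merged
}

categorize_one <- function(n_rows, direct_unmod, direct_mod,
                           n_unidentified, require_equal_mod_counts) {
  if (n_rows == 1) return("singleton")
  if (length(direct_unmod) == 0) return("fully_unidentified")
  if (dplyr::n_distinct(direct_unmod) >= 2) return("ambiguous")
  n_mod <- dplyr::n_distinct(direct_mod)
  if (n_unidentified == 0) return("unanimous")
  if (n_mod == 1) return("transferable")
  # >= 2 modified forms of one unmodified sequence: PTM-isomeric, provided
  # the donors agree on per-type modification counts (else the cluster is
  # not confidently one analyte and is demoted to ambiguous)
  if (require_equal_mod_counts) {
    sig <- vapply(unique(direct_mod), function(ms) {
      tab <- table(parse_modified_sequence(ms)$mods$name)
      paste(sort(paste0(names(tab), ":", tab)), collapse = ";")
    }, character(1))
    if (dplyr::n_distinct(sig) > 1) return("ambiguous")
  }
  "ptm_isomeric"
}

#' Categorize clusters by the identity of their members
#'
#' Assigns every cluster one of the six classes:
#' (a) `singleton` — one spectrum; (b) `unanimous` — all members directly
#' identified with one unmodified sequence; (c) `fully_unidentified`;
#' (d) `ambiguous` — direct identifications with >= 2 distinct unmodified
#' sequences; (e) `transferable` — one modified sequence among the direct
#' identifications plus unidentified members; (f) `ptm_isomeric` — one
#' unmodified sequence, >= 2 modification-site variants, plus unidentified
#' members. Fully identified clusters whose members differ only in
#' modification sites have no acceptors and are counted `unanimous` (the
#' `ptm_variants` column marks them).
#'
#' @param merged Merged tibble from [merge_tables()].
#' @param require_equal_mod_counts When `TRUE` (default), clusters whose
#'   donors disagree on per-type modification counts (e.g. singly vs doubly
#'   phosphorylated) are demoted to `ambiguous` rather than `ptm_isomeric`.
#' @return `merged` with columns `cluster_category`, `category_letter`
#'   (a-f) and `ptm_variants` added.
#' @export
categorize_clusters <- function(merged, require_equal_mod_counts = TRUE) {
  merged$cluster_category <- NULL
  merged$category_letter <- NULL
  info <- merged |>
    dplyr::mutate(.direct = .data$identification_type == "direct") |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(
      .n = dplyr::n(),
      .n_unid = sum(!.data$.direct),
      .unmod = list(.data$sequence[.data$.direct]),
      .mod = list(.data$modified_sequence[.data$.direct]),
      .groups = "drop"
    )
  info$cluster_category <- purrr::pmap_chr(
    list(info$.n, info$.unmod, info$.mod, info$.n_unid),
    function(n, unmod, mod, n_unid) {
      categorize_one(n, unmod, mod, n_unid, require_equal_mod_counts)
    })
  info$ptm_variants <- purrr::map2_lgl(info$.mod, info$cluster_category,
    function(mod, cat) {
      cat %in% c("unanimous", "ptm_isomeric") && dplyr::n_distinct(mod) > 1
    })
  out <- merged |>
    dplyr::left_join(
      info[, c("cluster_id", "cluster_category", "ptm_variants")],
      by = "cluster_id") |>
    dplyr::mutate(category_letter = unname(CATEGORY_LETTERS[.data$cluster_category]))
  attr(out, "threshold_label") <- attr(merged, "threshold_label")
  out
}

#' Transfer identifications within transferable and PTM-isomeric clusters
#'
#' In class (e) clusters every unidentified member (acceptor) receives the
#' donors' shared modified and unmodified sequence plus the protein
#' identifiers of the highest-scoring donor, with
#' `identification_type = "transfer"`. In class (f) clusters no single
#' modified sequence exists, so acceptors receive the unmodified sequence,
#' the proteins, and a rendered localization flag (see
#' [build_localization_flag()]) in `transferred_sequence`. Classes (a)-(d)
#' are untouched, and direct identifications are never altered. The
#' operation is idempotent.
#'
#' @param merged Merged tibble; categorized with [categorize_clusters()]
#'   first if the category columns are absent.
#' @inheritParams categorize_clusters
#' @return The table with transfers applied and column
#'   `transferred_sequence` (the transferred modified sequence for class e,
#'   the localization flag for class f, `NA` elsewhere), classed
#'   `transfer_tbl`.
#' @export
transfer_identifications <- function(merged, require_equal_mod_counts = TRUE) {
  if (!"cluster_category" %in% names(merged)) {
    merged <- categorize_clusters(merged, require_equal_mod_counts)
  }
  if (!"transferred_sequence" %in% names(merged)) {
    merged$transferred_sequence <- NA_character_
  }
  donors <- merged |>
    dplyr::filter(.data$identification_type == "direct",
                  .data$cluster_category %in% c("transferable", "ptm_isomeric")) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::arrange(dplyr::desc(.data$score), .by_group = TRUE) |>
    dplyr::summarise(
      donor_sequence = .data$sequence[1],
      donor_modified = .data$modified_sequence[1],
      donor_proteins = .data$proteins[1],
      donor_all_modified = list(unique(.data$modified_sequence)),
      .groups = "drop"
    )
  acceptors <- which(merged$identification_type == "none" &
                       merged$cluster_category %in% c("transferable", "ptm_isomeric"))
  if (length(acceptors) > 0) {
    idx <- match(merged$cluster_id[acceptors], donors$cluster_id)
    take <- !is.na(idx)
    acceptors <- acceptors[take]
    idx <- idx[take]
    merged$sequence[acceptors] <- donors$donor_sequence[idx]
    merged$proteins[acceptors] <- donors$donor_proteins[idx]
    is_e <- merged$cluster_category[acceptors] == "transferable"
    merged$modified_sequence[acceptors][is_e] <- donors$donor_modified[idx][is_e]
    merged$transferred_sequence[acceptors][is_e] <- donors$donor_modified[idx][is_e]
    if (any(!is_e)) {
      flags <- vapply(donors$donor_all_modified[idx[!is_e]], function(ms) {
        build_localization_flag(ms)$text
      }, character(1))
      merged$transferred_sequence[acceptors][!is_e] <- flags
    }
    merged$identification_type[acceptors] <- "transfer"
    merged$is_identified[acceptors] <- TRUE
  }
  class(merged) <- unique(c("transfer_tbl", class(merged)))
  merged
}

#' Summarize transfers per batch
#'
#' @param table Transfer table from [transfer_identifications()].
#' @return Tibble with one row per batch plus a `"(all)"` total row:
#'   direct and transferred PSM counts, the percentage gain, and distinct
#'   unmodified-peptide and leading-protein counts.
#' @export
summarize_transfers <- function(table) {
  one <- function(rows, label) {
    direct <- sum(rows$identification_type == "direct")
    transferred <- sum(rows$identification_type == "transfer")
    tibble::tibble(
      batch_id = label,
      n_scans = nrow(rows),
      n_direct = direct,
      n_transferred = transferred,
      psm_gain_percent = if (direct > 0) 100 * transferred / direct else NA_real_,
      n_peptides = dplyr::n_distinct(rows$sequence[rows$identification_type != "none"]),
      n_proteins = dplyr::n_distinct(
        leading_protein(rows$proteins[rows$identification_type != "none"]))
    )
  }
  per_batch <- table |>
    dplyr::group_by(.data$batch_id) |>
    dplyr::group_map(function(rows, key) one(rows, key$batch_id)) |>
    dplyr::bind_rows()
  dplyr::bind_rows(per_batch, one(table, "(all)"))
}

#' Per-category cluster counts
#'
#' @param table Categorized merged tibble.
#' @return Tibble `cluster_category`, `category_letter`, `n_clusters`,
#'   `n_scans`, covering all six classes (zero-filled).
#' @export
category_counts <- function(table) {
  counts <- table |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(cluster_category = .data$cluster_category[1],
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::group_by(.data$cluster_category) |>
    dplyr::summarise(n_clusters = dplyr::n(), n_scans = sum(.data$n),
                     .groups = "drop")
  tibble::tibble(cluster_category = names(CATEGORY_LETTERS),
                 category_letter = unname(CATEGORY_LETTERS)) |>
    dplyr::left_join(counts, by = "cluster_category") |>
    dplyr::mutate(n_clusters = dplyr::coalesce(.data$n_clusters, 0L),
                  n_scans = dplyr::coalesce(.data$n_scans, 0L))
}

leading_protein <- function(proteins) {
  vapply(proteins, function(p) {
    if (is.na(p)) NA_character_ else strsplit(p, ";", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
}

#' Write the augmented transfer table
#'
#' Writes a tab-separated file resembling the input PSM table with the
#' added columns `Cluster ID`, `Cluster category` (letter and name),
#' `Identification type` (`direct`/`transfer`, empty for unidentified
#' scans) and `Transferred modified sequence` (the modified sequence or,
#' for PTM-isomeric clusters, the localization flag).
#'
#' @param table Transfer table.
#' @param path Output path.
#' @param dialect A [psm_dialect()].
#' @return `path`, invisibly.
#' @export
write_transfer_table <- function(table, path, dialect = psm_dialect()) {
  rep_cols <- grep("^reporter_[0-9]+$", names(table), value = TRUE)
  blank <- function(x) ifelse(is.na(x), "", x)
  out <- tibble::tibble(
    !!dialect$raw_file := table$raw_file,
    !!dialect$scan_number := table$scan_number,
    !!dialect$sequence := blank(table$sequence),
    !!dialect$modified_sequence := blank(table$modified_sequence),
    !!dialect$proteins := blank(table$proteins),
    !!dialect$score := table$score,
    !!dialect$pep := table$pep
  )
  for (col in rep_cols) {
    i <- sub("^reporter_", "", col)
    out[[paste0(dialect$reporter_prefix, i)]] <- table[[col]]
  }
  out[["Cluster ID"]] <- table$cluster_id
  out[["Cluster category"]] <- paste0(table$category_letter, ":",
                                      table$cluster_category)
  out[["Identification type"]] <- ifelse(table$identification_type == "none",
                                         "", table$identification_type)
  out[["Transferred modified sequence"]] <- blank(table$transferred_sequence)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
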