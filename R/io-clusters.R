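# Cluster-assignment files: "raw_file<TAB>scan_number<TAB>cluster_id",
# blank lines permitted between clusters, one file per stringency threshold
# (threshold label in the filename suffix, e.g. clusters.p10.tsv).

#' Read a cluster-assignment file
#'
#' @param path Tab-separated file with lines
#'   `raw_file<TAB>scan_number<TAB>cluster_id`; blank lines are ignored.
#' @param threshold_label Stringency label (e.g. `"p10"`); when `NULL` it is
#'   taken from the filename suffix `.<label>.tsv` if present.
#' @return A tibble `raw_file`, `scan_number`, `cluster_id` (dense positive
#'   integers, renumbered in file order) with attribute `threshold_label`.
#' @export
read_cluster_assignments <- function(path, threshold_label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(threshold_label)) {
    m <- regmatches(basename(path), regexpr("\\.([a-zA-Z0-9]+)\\.tsv$", basename(path)))
    threshold_label <- if (length(m) == 1) sub("^\\.", "", sub("\\.tsv$", "", m)) else NA_character_
  }
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) {
    out <- tibble::tibble(raw_file = character(0), scan_number = integer(0),
                          cluster_id = integer(0))
    attr(out, "threshold_label") <- threshold_label
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3)) {
    stop("malformed cluster-assignment line in ", path, ": '",
         lines[which(lengths(parts) < 3)[1]], "'")
  }
  out <- tibble::tibble(
    raw_file = normalize_raw_file(vapply(parts, `[[`, character(1), 1)),
    scan_number = as.integer(vapply(parts, `[[`, character(1), 2)),
    cluster_id = as.integer(factor(vapply(parts, `[[`, character(1), 3),
                                   levels = unique(vapply(parts, `[[`, character(1), 3))))
  )
  dup <- duplicated(out[, c("raw_file", "scan_number")])
  if (any(dup)) {
    stop("duplicate (raw file, scan) in ", path, ": ",
         out$raw_file[dup][1], " scan ", out$scan_number[dup][1],
         " — ambiguous assignment")
  }
  attr(out, "threshold_label") <- threshold_label
  out
}

#' Write a cluster assignment
#'
#' Clusters are written as blank-line-separated blocks in ascending
#' `cluster_id` order.
#'
#' @param assignment Tibble `raw_file`, `scan_number`, `cluster_id`.
#' @param path Output path (conventionally `<stem>.<label>.tsv`).
#' @return `path`, invisibly.
#' @export
write_cluster_assignments <- function(assignment, path) {
  blocks <- assignment |>
    dplyr::arrange(.data$cluster_id, .data$raw_file, .data$scan_number) |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::group_map(function(rows, key) {
      paste(sprintf("%s\t%d\t%d", rows$raw_file, rows$scan_number,
                    key$cluster_id), collapse = "\n")
    })
  readr::write_lines(paste(unlist(blocks), collapse = "\n\n"), path)
  invisible(path)
}
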