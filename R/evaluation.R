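# Validation machinery: masking-based precision/recall/FDR, the
# ambiguous-cluster FDR proxy, cumulative batch-presence curves, and the
# reporter-ion ratio agreement check.

#' Mask a fraction of identifications
#'
#' Per raw file, `round(fraction * n_identified)` retained target
#' identifications are chosen uniformly at random (seeded) and hidden:
#' `is_identified` becomes `FALSE` and the sequence fields are cleared, so
#' the scans become transfer acceptors whose ground truth is known.
#'
#' @param psms PSM tibble.
#' @param fraction Fraction in (0, 1] of identified PSMs to mask per file.
#' @param seed Integer seed; the sampling is deterministic given it.
#' @return List with `psms` (the masked table) and `truth` (tibble
#'   `raw_file`, `scan_number`, `sequence`, `modified_sequence`,
#'   `proteins` of the masked scans).
#' @export
mask_identifications <- function(psms, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must be in (0, 1]")
  }
  eligible <- which(psms$is_identified & !psms$is_decoy & !psms$is_contaminant)
  rng <- local_rng(seed)
  masked_idx <- unlist(lapply(split(eligible, psms$raw_file[eligible]),
                              function(idx) {
    k <- round(fraction * length(idx))
    if (k == 0) integer(0) else sort(sample_int(rng, idx, k))
  }), use.names = FALSE)
  truth <- psms[masked_idx, c("raw_file", "scan_number", "sequence",
                              "modified_sequence", "proteins")]
  out <- psms
  out$is_identified[masked_idx] <- FALSE
  out$sequence[masked_idx] <- NA_character_
  out$modified_sequence[masked_idx] <- NA_character_
  out$proteins[masked_idx] <- NA_character_
  out$score[masked_idx] <- NA_real_
  out$pep[masked_idx] <- NA_real_
  list(psms = out, truth = dplyr::arrange(truth, .data$raw_file,
                                          .data$scan_number))
}

# self-contained RNG so masking/generation never disturb the caller's
# random-number stream
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  env
}

with_rng <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
  })
  expr
}

sample_int <- function(rng, x, k) with_rng(rng, sample(x, k))
rng_runif <- function(rng, n, ...) with_rng(rng, stats::runif(n, ...))
rng_rnorm <- function(rng, n, ...) with_rng(rng, stats::rnorm(n, ...))

#' Masking precision, recall and FDR
#'
#' A transfer onto a masked scan is correct iff the transferred unmodified
#' sequence equals the ground truth (strict mode additionally requires the
#' modified sequence to match, which PTM-isomeric flag transfers cannot).
#' Precision is correct transfers over all verifiable transfers, recall is
#' correct transfers over all masked scans, and FDR is `1 - precision`
#' exactly. Transfers onto scans that were never identified have no ground
#' truth and are excluded from both numerator and denominator.
#'
#' @param transfers Transfer table computed from the masked dataset.
#' @param truth Ground-truth tibble from [mask_identifications()].
#' @param strict Require the modified sequence to match as well.
#' @return One-row tibble (`masking_report`): `threshold_label`,
#'   `n_masked`, `n_transferred_to_masked`, `n_correct`, `precision`,
#'   `recall`, `fdr`, `degenerate` (`TRUE` when no verifiable transfer
#'   exists and precision defaults to 1).
#' @export
precision_recall <- function(transfers, truth, strict = FALSE) {
  if (nrow(truth) == 0) stop("no masked scans: ground truth is empty")
  onto_masked <- transfers |>
    dplyr::filter(.data$identification_type == "transfer") |>
    dplyr::inner_join(truth, by = c("raw_file", "scan_number"),
                      suffix = c("", ".truth"))
  correct <- onto_masked$sequence == onto_masked$sequence.truth
  if (strict) {
    correct <- correct & !is.na(onto_masked$modified_sequence) &
      onto_masked$modified_sequence == onto_masked$modified_sequence.truth
  }
  n_t <- nrow(onto_masked)
  n_c <- sum(correct, na.rm = TRUE)
  degenerate <- n_t == 0
  precision <- if (degenerate) 1 else n_c / n_t
  tibble::tibble(
    threshold_label = attr(transfers, "threshold_label") %||% NA_character_,
    n_masked = nrow(truth),
    n_transferred_to_masked = n_t,
    n_correct = n_c,
    precision = precision,
    recall = n_c / nrow(truth),
    fdr = 1 - precision,
    degenerate = degenerate
  ) |> structure(class = c("masking_report", "tbl_df", "tbl", "data.frame"))
}

#' Fraction of multi-spectrum clusters that are ambiguous
#'
#' The share of clusters of size > 1 whose direct identifications disagree
#' on the unmodified sequence. Because such clusters are discarded for
#' transfer, this fraction serves as a proxy for the transfer FDR without
#' requiring a masking experiment.
#'
#' @param table Categorized merged tibble.
#' @return One-row tibble: `n_multi` (clusters of size > 1),
#'   `n_ambiguous`, `fraction` (0 with `degenerate = TRUE` when no
#'   multi-spectrum cluster exists).
#' @export
ambiguous_cluster_fraction <- function(table) {
  per_cluster <- table |>
    dplyr::group_by(.data$cluster_id) |>
    dplyr::summarise(n = dplyr::n(),
                     cat = .data$cluster_category[1], .groups = "drop")
  multi <- per_cluster[per_cluster$n > 1, ]
  n_multi <- nrow(multi)
  n_amb <- sum(multi$cat == "ambiguous")
  tibble::tibble(
    threshold_label = attr(table, "threshold_label") %||% NA_character_,
    n_multi = n_multi,
    n_ambiguous = n_amb,
    fraction = if (n_multi == 0) 0 else n_amb / n_multi,
    degenerate = n_multi == 0
  )
}

#' Cumulative batch-presence curve
#'
#' For every `n` from 1 to the number of batches, the number of entities
#' (unmodified peptides or leading proteins) identified in at least `n`
#' batches. Transfers can be included to show the missing-value reduction.
#'
#' @param table Merged (or transfer) tibble carrying `batch_id`.
#' @param level `"peptide"` (unmodified sequence) or `"protein"` (leading
#'   protein identifier).
#' @param include_transfers Count transferred identifications as presence.
#' @return Tibble (`presence_curve`): `n_batches`, `count`, plus `level`
#'   and `include_transfers` columns.
#' @export
batch_presence_curve <- function(table, level = c("peptide", "protein"),
                                 include_transfers = TRUE) {
  level <- match.arg(level)
  types <- if (include_transfers) c("direct", "transfer") else "direct"
  rows <- table[table$identification_type %in% types, ]
  entity <- if (level == "peptide") rows$sequence else leading_protein(rows$proteins)
  keep <- !is.na(entity)
  n_batches_total <- dplyr::n_distinct(table$batch_id)
  presence <- tibble::tibble(entity = entity[keep],
                             batch_id = rows$batch_id[keep]) |>
    dplyr::distinct() |>
    dplyr::count(.data$entity, name = "n_present")
  counts <- vapply(seq_len(n_batches_total), function(n) {
    sum(presence$n_present >= n)
  }, integer(1))
  tibble::tibble(n_batches = seq_len(n_batches_total), count = counts,
                 level = level, include_transfers = include_transfers) |>
    structure(class = c("presence_curve", "tbl_df", "tbl", "data.frame"))
}

#' Reporter-ion ratio agreement of transferred PSMs
#'
#' Sanity check that a transferred identification quantifies like its
#' protein: for each PSM, the Pearson correlation between its log reporter
#' ratios (each channel over the reference/bridge channel) and the
#' per-protein median log-ratio vector of the *other* direct PSMs of the
#' same protein in the same batch. Comparable correlations for direct
#' PSMs provide the baseline. Proteins with fewer than two direct PSMs in
#' a batch, and PSMs with degenerate (constant or non-positive) reporter
#' vectors, are skipped and counted.
#'
#' @param table Transfer table with `reporter_*` columns.
#' @param reference_channel Index of the bridge channel (default: the last
#'   reporter column).
#' @return Tibble with one row per evaluated PSM: `raw_file`,
#'   `scan_number`, `batch_id`, `protein`, `identification_type`,
#'   `correlation`; attribute `n_skipped` counts the skipped PSMs.
#' @export
reporter_ratio_agreement <- function(table, reference_channel = NULL) {
  rep_cols <- grep("^reporter_[0-9]+$", names(table), value = TRUE)
  if (length(rep_cols) < 3) stop("need at least 3 reporter channels")
  rep_cols <- rep_cols[order(as.integer(sub("^reporter_", "", rep_cols)))]
  if (is.null(reference_channel)) reference_channel <- length(rep_cols)
  mat <- as.matrix(table[, rep_cols])
  ok_vec <- rowSums(is.na(mat) | mat <= 0) == 0
  logratio <- log2(mat / mat[, reference_channel])
  logratio <- logratio[, -reference_channel, drop = FALSE]
  idx <- which(table$identification_type %in% c("direct", "transfer") & ok_vec &
                 !is.na(table$proteins))
  prot <- leading_protein(table$proteins[idx])
  batch <- table$batch_id[idx]
  direct <- table$identification_type[idx] == "direct"
  n_skipped <- 0L
  res <- vector("list", length(idx))
  groups <- split(seq_along(idx), paste(batch, prot, sep = "\r"))
  for (g in groups) {
    d <- g[direct[g]]
    for (i in g) {
      others <- setdiff(d, i)
      if (length(others) < 2) {
        n_skipped <- n_skipped + 1L
        next
      }
      ref_vec <- apply(logratio[idx[others], , drop = FALSE], 2, stats::median)
      own <- logratio[idx[i], ]
      if (stats::sd(own) == 0 || stats::sd(ref_vec) == 0) {
        n_skipped <- n_skipped + 1L
        next
      }
      res[[i]] <- tibble::tibble(
        raw_file = table$raw_file[idx[i]],
        scan_number = table$scan_number[idx[i]],
        batch_id = batch[i],
        protein = prot[i],
        identification_type = if (direct[i]) "direct" else "transfer",
        correlation = stats::cor(own, ref_vec)
      )
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "n_skipped") <- n_skipped
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
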