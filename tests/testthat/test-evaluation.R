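test_that("masking rounds per file, partitions, and is seed-deterministic", {
  psms <- dplyr::bind_rows(
    make_psms("f1", 1:10, "AAAK", "AAAK", "P1", 50),
    make_psms("f1", 11:12),
    make_psms("f2", 1:4, "CCCK", "CCCK", "P2", 60))
  m <- mask_identifications(psms, 0.5, seed = 7)
  expect_equal(sum(m$truth$raw_file == "f1"), 5) # round(0.5 * 10)
  expect_equal(sum(m$truth$raw_file == "f2"), 2)
  expect_equal(sum(m$psms$is_identified), 14 - 7)
  # same seed -> same masked set; different seed differs
  m2 <- mask_identifications(psms, 0.5, seed = 7)
  expect_identical(m$truth, m2$truth)
  # masked + still-identified = original identified set (partition)
  still <- m$psms[m$psms$is_identified, c("raw_file", "scan_number")]
  orig <- psms[psms$is_identified, c("raw_file", "scan_number")]
  expect_equal(dplyr::arrange(dplyr::bind_rows(
    still, m$truth[, c("raw_file", "scan_number")]), raw_file, scan_number),
    dplyr::arrange(orig, raw_file, scan_number))
  expect_error(mask_identifications(psms, 0), "fraction")
  expect_error(mask_identifications(psms, 1.2), "fraction")
})

test_that("precision/recall/FDR follow the printed formulas", {
  # 5 masked, 4 transfers onto masked scans, 3 correct:
  # precision 0.75, recall 0.6, FDR 0.25
  truth <- tibble::tibble(raw_file = "f", scan_number = 1:5,
                          sequence = "AAAK", modified_sequence = "AAAK",
                          proteins = "P1")
  transfers <- tibble::tibble(
    raw_file = "f", scan_number = c(1:4, 99L),
    sequence = c("AAAK", "AAAK", "AAAK", "CCCK", "DDDK"),
    modified_sequence = NA_character_,
    identification_type = "transfer")
  r <- precision_recall(transfers, truth)
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.6)
  expect_equal(r$fdr, 0.25)
  expect_identical(r$fdr + r$precision, 1) # exact identity
  # the transfer onto scan 99 (never identified) was excluded
  expect_equal(r$n_transferred_to_masked, 4)
  # all correct -> fdr exactly 0
  all_ok <- transfers[1:3, ]
  expect_identical(precision_recall(all_ok, truth)$fdr, 0)
  expect_error(precision_recall(transfers, truth[0, ]), "masked")
})

test_that("pooled metrics equal per-peptide micro-average tallies", {
  # independent oracle: per-peptide TP/FP/FN tables summed by brute force
  d <- generate_dataset(synthetic_config(n_peptides = 50, seed = 17))
  masked <- mask_identifications(d$psms, 0.2, seed = 18)
  asg <- cluster_spectra(d$spectra, c(p5 = 5))
  tbl <- merge_tables(masked$psms, asg$p5,
                      d$spectra[, c("raw_file", "scan_number")]) |>
    categorize_clusters() |> transfer_identifications()
  rep <- precision_recall(tbl, masked$truth)

  joined <- dplyr::inner_join(
    tbl[tbl$identification_type == "transfer",
        c("raw_file", "scan_number", "sequence")],
    masked$truth, by = c("raw_file", "scan_number"), suffix = c("", ".t"))
  peptides <- union(masked$truth$sequence, joined$sequence)
  tp <- fp <- fn <- 0
  for (pep in peptides) {
    tp_i <- sum(joined$sequence == pep & joined$sequence.t == pep)
    fp_i <- sum(joined$sequence == pep & joined$sequence.t != pep)
    n_masked_i <- sum(masked$truth$sequence == pep)
    tp <- tp + tp_i
    fp <- fp + fp_i
    fn <- fn + (n_masked_i - tp_i)
  }
  expect_gt(tp, 0)
  expect_identical(rep$precision, tp / (tp + fp))
  expect_identical(rep$recall, tp / (tp + fn))
  expect_identical(rep$fdr, 1 - tp / (tp + fp))
})

test_that("ambiguous-cluster fraction counts multi-spectrum clusters", {
  mk <- function(ids, cats) {
    tibble::tibble(cluster_id = ids, cluster_category = cats)
  }
  # 1 ambiguous among 50 multi-spectrum clusters -> 0.02
  tbl <- mk(rep(1:50, each = 2),
            rep(c("ambiguous", rep("unanimous", 49)), each = 2))
  r <- ambiguous_cluster_fraction(tbl)
  expect_equal(r$fraction, 0.02)
  expect_false(r$degenerate)
  # all singletons -> 0 with the degenerate flag
  r0 <- ambiguous_cluster_fraction(mk(1:5, rep("singleton", 5)))
  expect_equal(r0$fraction, 0)
  expect_true(r0$degenerate)
})

test_that("planted look-alike rate is recovered by the ambiguous fraction", {
  cfg <- synthetic_config(n_peptides = 120, lookalike_pair_fraction = 0.25,
                          lookalike_scans_per_batch = 2,
                          lookalike_n_batches = 3,
                          per_batch_identification_prob = 0.9, seed = 31)
  d <- generate_dataset(cfg)
  n_pairs <- sum(d$analytes$is_lookalike)
  asg <- cluster_spectra(d$spectra, c(p5 = 5))
  tbl <- merge_tables(d$psms, asg$p5,
                      d$spectra[, c("raw_file", "scan_number")]) |>
    categorize_clusters()
  r <- ambiguous_cluster_fraction(tbl)
  # with near-certain identification every look-alike pair that clusters
  # is ambiguous; expect the planted rate within binomial error
  planted <- n_pairs / r$n_multi
  expect_gt(r$fraction, planted * 0.6)
  expect_lt(r$fraction, planted * 1.4)
})

test_that("presence curves are monotone and match ground truth", {
  # a peptide seen in batches {1,2} of 3 contributes to counts 1 and 2 only
  tbl <- tibble::tibble(
    batch_id = c("b1", "b2", "b3", "b1"),
    sequence = c("AAAK", "AAAK", "CCCK", "DDDK"),
    proteins = c("P1", "P1", "P2", "P3"),
    identification_type = c("direct", "transfer", "direct", "direct"))
  with_t <- batch_presence_curve(tbl, "peptide", include_transfers = TRUE)
  no_t <- batch_presence_curve(tbl, "peptide", include_transfers = FALSE)
  expect_equal(with_t$count, c(3L, 1L, 0L))
  expect_equal(no_t$count, c(3L, 0L, 0L))
  expect_true(all(diff(with_t$count) <= 0)) # non-increasing in n
  expect_true(all(with_t$count >= no_t$count)) # transfers never decrease
  # exact match with generator ground truth on a noiseless dataset
  cfg <- synthetic_config(n_peptides = 40, per_batch_identification_prob = 1,
                          dropout_prob = 0, mz_jitter_sd = 0,
                          isomer_pair_fraction = 0, seed = 23)
  d <- generate_dataset(cfg)
  asg <- cluster_spectra(d$spectra, c(p10 = 10))
  tbl2 <- merge_tables(d$psms, asg$p10,
                       d$spectra[, c("raw_file", "scan_number")]) |>
    categorize_clusters() |> transfer_identifications()
  curve <- batch_presence_curve(tbl2, "peptide")
  want <- d$truth |>
    dplyr::distinct(sequence, raw_file) |>
    dplyr::count(sequence)
  expect_equal(curve$count,
               vapply(1:3, function(n) sum(want$n >= n), integer(1)))
  expect_equal(curve$count[1], dplyr::n_distinct(d$truth$sequence))
})

test_that("transferred PSMs quantify like their protein", {
  d <- generate_dataset(synthetic_config(n_peptides = 60, seed = 41,
                                         per_batch_identification_prob = 0.7))
  asg <- cluster_spectra(d$spectra, c(p10 = 10))
  tbl <- merge_tables(d$psms, asg$p10,
                      d$spectra[, c("raw_file", "scan_number")]) |>
    categorize_clusters() |> transfer_identifications()
  # transfers need reporter values: take them from the spectra
  rep_mat <- do.call(rbind, d$spectra$reporter)
  key <- paste(d$spectra$raw_file, d$spectra$scan_number)
  idx <- match(paste(tbl$raw_file, tbl$scan_number), key)
  for (i in 1:10) tbl[[paste0("reporter_", i)]] <- rep_mat[idx, i]
  agree <- reporter_ratio_agreement(tbl)
  expect_true(all(c("direct", "transfer") %in% agree$identification_type))
  med_transfer <- stats::median(agree$correlation[
    agree$identification_type == "transfer"])
  expect_gt(med_transfer, 0.8)
  # shuffled-protein control: correlations collapse
  shuf <- tbl
  set.seed(5)
  prot_rows <- !is.na(shuf$proteins)
  shuf$proteins[prot_rows] <- sample(shuf$proteins[prot_rows])
  agree_shuf <- reporter_ratio_agreement(shuf)
  expect_gt(med_transfer, stats::median(agree_shuf$correlation) + 0.3)
  # exactly proportional vectors give correlation 1
  base <- make_psms("b", 1:3, "AAAK", "AAAK", "P1", 50)
  base$identification_type <- c("direct", "direct", "transfer")
  pat <- c(1, 2, 4, 8, 1, 2, 4, 8, 1, 1)
  for (i in 1:10) base[[paste0("reporter_", i)]] <- pat[i] * c(1, 2, 3)
  r <- reporter_ratio_agreement(base)
  expect_equal(r$correlation[r$identification_type == "transfer"], 1)
  # all-equal channels: ratios constant -> skipped with a count
  flat <- base
  for (i in 1:10) flat[[paste0("reporter_", i)]] <- c(5, 5, 5)
  r2 <- reporter_ratio_agreement(flat)
  expect_equal(nrow(r2), 0)
  expect_gt(attr(r2, "n_skipped"), 0)
})
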