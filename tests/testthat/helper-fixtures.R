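# Shared fixtures and independent oracles.

# The worked five-spectrum PTM-isomeric cluster: three direct
# identifications of RASPSPRAA differing in the phospho site (positions 3
# and 5), two unidentified spectra, all in cluster 75 across three runs.
table1_psms <- function() {
  tibble::tibble(
    raw_file = c("rawfile1", "rawfile1", "rawfile1", "rawfile2", "rawfile3"),
    scan_number = c(5582L, 5588L, 5602L, 6025L, 6033L),
    batch_id = raw_file,
    sequence = c("RASPSPRAA", "RASPSPRAA", NA, "RASPSPRAA", NA),
    modified_sequence = c("RApSPSPRAA", "RASPpSPRAA", NA, "RApSPSPRAA", NA),
    proteins = ifelse(is.na(sequence), NA,
                      "Serine/arginine repetitive matrix protein 1"),
    score = c(120, 110, NA, 100, NA),
    pep = c(1e-3, 1e-3, NA, 1e-3, NA),
    is_decoy = FALSE, is_contaminant = FALSE,
    is_identified = !is.na(sequence)
  )
}

table1_assignment <- function() {
  p <- table1_psms()
  tibble::tibble(raw_file = p$raw_file, scan_number = p$scan_number,
                 cluster_id = 75L)
}

# a minimal identified/unidentified PSM tibble builder for transfer tests
make_psms <- function(raw_file, scan_number, sequence = NA,
                      modified_sequence = NA, proteins = NA, score = NA) {
  n <- length(scan_number)
  tibble::tibble(
    raw_file = rep_len(raw_file, n),
    scan_number = as.integer(scan_number),
    batch_id = rep_len(raw_file, n),
    sequence = rep_len(sequence, n),
    modified_sequence = rep_len(modified_sequence, n),
    proteins = rep_len(proteins, n),
    score = as.numeric(rep_len(score, n)),
    pep = NA_real_,
    is_decoy = FALSE, is_contaminant = FALSE,
    is_identified = !is.na(rep_len(sequence, n))
  )
}

# spectrum tibble from explicit peak lists (shared precursor so that all
# spectra fall into one comparison partition unless told otherwise)
make_spectra <- function(peak_sets, raw_file = "run1", scan_number = NULL,
                         precursor_mz = 500.25, precursor_charge = 2L) {
  n <- length(peak_sets)
  if (is.null(scan_number)) scan_number <- seq_len(n)
  tibble::tibble(
    raw_file = rep_len(raw_file, n),
    scan_number = as.integer(scan_number),
    batch_id = rep_len(raw_file, n),
    precursor_mz = rep_len(precursor_mz, n),
    precursor_charge = as.integer(rep_len(precursor_charge, n)),
    retention_time = NA_real_,
    peaks = lapply(peak_sets, function(mz) {
      tibble::tibble(mz = sort(mz), intensity = rep(100, length(mz)))
    }),
    reporter = rep(list(rep(0, 10)), n),
    n_peaks = lengths(peak_sets)
  )
}

# peak m/z values hitting exactly the given integer bins (bin width 0.02)
peaks_for_bins <- function(bins, bin_width = 0.02) {
  (bins + 0.5) * bin_width
}

# Independent complete-linkage oracle: greedy agglomeration at a single
# threshold with the linkage value recomputed from scratch over all cross
# pairs at every step (no Lance-Williams update), ties broken by the
# lexicographic item-rank pair. Returns cluster labels (representative
# item index per item).
oracle_complete_linkage <- function(score, ranks, threshold) {
  clusters <- as.list(seq_len(nrow(score)))
  repeat {
    m <- length(clusters)
    if (m == 1) break
    best <- -Inf
    bi <- bj <- 0L
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        v <- min(score[clusters[[i]], clusters[[j]]])
        rep_i <- min(ranks[clusters[[i]]])
        rep_j <- min(ranks[clusters[[j]]])
        cur <- sort(c(rep_i, rep_j))
        better <- v > best
        if (!better && v == best) {
          old <- sort(c(min(ranks[clusters[[bi]]]), min(ranks[clusters[[bj]]])))
          better <- cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2])
        }
        if (better) {
          best <- v
          bi <- i
          bj <- j
        }
      }
    }
    if (best < threshold) break
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  labels <- integer(nrow(score))
  for (cl in clusters) labels[cl] <- min(cl)
  labels
}

# partition equality up to relabelling
same_partition <- function(a, b) {
  identical(as.integer(factor(a, levels = unique(a))),
            as.integer(factor(b, levels = unique(b))))
}

# closed-form hypergeometric upper-tail -log10 p computed directly from
# lchoose sums, independent of stats::phyper
neglog_hyper_tail <- function(s, ka, kb, B) {
  terms <- vapply(s:min(ka, kb), function(x) {
    lchoose(ka, x) + lchoose(B - ka, kb - x) - lchoose(B, kb)
  }, numeric(1))
  m <- max(terms)
  -(m + log(sum(exp(terms - m)))) / log(10)
}
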