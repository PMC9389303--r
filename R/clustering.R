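# Complete-linkage spectrum clustering at -log10(p-value) stringency
# thresholds. Spectra are reduced to sets of integer fragment bins; pair
# similarity is the hypergeometric tail probability of the observed number
# of shared bins under an independence null; agglomeration is plain
# complete linkage, cut at each requested threshold from one dendrogram.

#' Default stringency threshold ladder
#'
#' The six default cutoffs on -log10(p-value): p5 (loosest) through p30
#' (strictest).
#'
#' @return Named numeric vector `c(p5 = 5, ..., p30 = 30)`.
#' @export
default_thresholds <- function() {
  c(p5 = 5, p10 = 10, p15 = 15, p20 = 20, p25 = 25, p30 = 30)
}

#' Clustering parameters
#'
#' @param bin_width Fragment bin width in Th.
#' @param top_k Number of most intense peaks retained per spectrum.
#' @param reporter_range m/z window (Th) excluded from binning; TMT reporter
#'   ions are shared by all spectra and carry no identity signal.
#' @param fragment_range m/z range (Th) assumed available to fragments; its
#'   width divided by `bin_width` is the null model's number of bins.
#' @param precursor_tol_ppm Precursor-mass tolerance (ppm) for the
#'   single-linkage mass windows inside which spectra are compared.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(bin_width = 0.02, top_k = 40,
                           reporter_range = c(125, 135),
                           fragment_range = c(100, 1800),
                           precursor_tol_ppm = 10) {
  stopifnot(bin_width > 0, top_k >= 1,
            fragment_range[2] > fragment_range[1], precursor_tol_ppm > 0)
  structure(list(bin_width = bin_width, top_k = top_k,
                 reporter_range = reporter_range,
                 fragment_range = fragment_range,
                 precursor_tol_ppm = precursor_tol_ppm,
                 n_bins = floor(diff(fragment_range) / bin_width)),
            class = "cluster_params")
}

#' Reduce a peak list to fragment bins
#'
#' Keeps the `top_k` most intense peaks outside the reporter region and
#' maps them to integer bins `floor(mz / bin_width)`. The result is a set:
#' duplicates are collapsed and peak input order is irrelevant.
#'
#' @param peaks Tibble with `mz`, `intensity`.
#' @param params A [cluster_params()].
#' @return Sorted integer vector of bin indices (possibly fewer than
#'   `top_k` after deduplication).
#' @export
bin_spectrum <- function(peaks, params = cluster_params()) {
  if (nrow(peaks) == 0) stop("cannot bin an empty spectrum")
  keep <- peaks$mz < params$reporter_range[1] | peaks$mz > params$reporter_range[2]
  keep <- keep & peaks$mz >= params$fragment_range[1] &
    peaks$mz <= params$fragment_range[2]
  pk <- peaks[keep, , drop = FALSE]
  if (nrow(pk) == 0) return(integer(0))
  o <- order(pk$intensity, pk$mz, decreasing = TRUE)
  top <- pk[o[seq_len(min(params$top_k, nrow(pk)))], ]
  sort(unique(as.integer(floor(top$mz / params$bin_width))))
}

#' -log10 p-value for the bin overlap of two spectra
#'
#' Under the null that spectrum `a`'s `|a|` bins are an independent uniform
#' draw from `n_bins` available bins, the number shared with `b`'s bins is
#' hypergeometric; the score is `-log10 P(shared >= observed)`. Symmetric,
#' zero for disjoint sets, monotone increasing in the overlap.
#'
#' @param bins_a,bins_b Integer bin sets from [bin_spectrum()].
#' @param n_bins Total number of available bins in the null model.
#' @return Non-negative number; `Inf` never occurs (log-scale tail).
#' @export
pair_neglog_pvalue <- function(bins_a, bins_b, n_bins) {
  s <- length(intersect(bins_a, bins_b))
  if (s == 0) return(0)
  ka <- length(bins_a)
  kb <- length(bins_b)
  stopifnot(n_bins >= max(ka, kb))
  lp <- stats::phyper(s - 1, ka, n_bins - ka, kb,
                      lower.tail = FALSE, log.p = TRUE)
  max(0, -lp / log(10))
}

# single-linkage chaining of precursor masses: sort, cut where the gap to
# the previous mass exceeds tol_ppm of the midpoint
chain_masses <- function(mass, tol_ppm) {
  o <- order(mass)
  gaps <- diff(mass[o])
  lim <- tol_ppm * 1e-6 * mass[o][-1]
  grp_sorted <- cumsum(c(1, as.integer(gaps > lim)))
  grp <- integer(length(mass))
  grp[o] <- grp_sorted
  grp
}

# complete-linkage agglomeration over a symmetric score matrix (higher =
# more similar). Merges best pair first; ties broken by the lexicographic
# (raw_file, scan) order of cluster representatives encoded in `ord` (the
# rank of each item). Returns the merge list: for each merge, the member
# indices of the resulting cluster and the linkage score (min cross-pair).
agglomerate <- function(score, ord) {
  n <- nrow(score)
  clusters <- as.list(seq_len(n))
  reps <- ord # representative rank per active cluster
  link <- score # complete-linkage score between active clusters
  merges <- list()
  while (length(clusters) > 1) {
    m <- length(clusters)
    best <- -Inf
    bi <- bj <- 0L
    for (i in seq_len(m - 1)) {
      for (j in (i + 1):m) {
        v <- link[i, j]
        better <- v > best
        if (!better && v == best) {
          # tie: prefer the pair whose sorted representative ranks are
          # lexicographically smallest
          cur <- sort(c(reps[i], reps[j]))
          old <- sort(c(reps[bi], reps[bj]))
          better <- cur[1] < old[1] || (cur[1] == old[1] && cur[2] < old[2])
        }
        if (better) {
          best <- v
          bi <- i
          bj <- j
        }
      }
    }
    merged <- c(clusters[[bi]], clusters[[bj]])
    new_link <- pmin(link[bi, ], link[bj, ])[-c(bi, bj)]
    keep <- setdiff(seq_len(m), c(bi, bj))
    clusters <- c(clusters[keep], list(merged))
    reps <- c(reps[keep], min(reps[bi], reps[bj]))
    link <- link[keep, keep, drop = FALSE]
    link <- rbind(cbind(link, new_link), c(new_link, 0))
    merges[[length(merges) + 1]] <- list(members = merged, height = best)
  }
  merges
}

# cut a merge list at a threshold: apply merges with height >= t in order
cut_merges <- function(merges, n, t) {
  labels <- seq_len(n)
  for (m in merges) {
    if (m$height >= t) {
      labels[m$members] <- min(labels[m$members])
    }
  }
  labels
}

#' Cluster spectra at a ladder of stringency thresholds
#'
#' Spectra are partitioned by precursor charge and chained precursor-mass
#' windows, scored pairwise by [pair_neglog_pvalue()], and agglomerated by
#' complete linkage; one dendrogram per partition is cut at every
#' threshold, which guarantees that stricter partitions refine looser ones.
#' Spectra with unknown charge form their own charge stratum; spectra with
#' no usable peaks become singletons at every threshold.
#'
#' @param spectra Spectrum tibble (see [read_mgf()]).
#' @param thresholds Named numeric vector of -log10(p-value) cutoffs
#'   (default [default_thresholds()]).
#' @param params A [cluster_params()].
#' @return Named list (one element per threshold label) of assignment
#'   tibbles `raw_file`, `scan_number`, `cluster_id` with dense ids ordered
#'   by first appearance; each carries attribute `threshold_label`.
#' @export
cluster_spectra <- function(spectra, thresholds = default_thresholds(),
                            params = cluster_params()) {
  stopifnot(length(thresholds) >= 1)
  if (is.null(names(thresholds))) {
    names(thresholds) <- paste0("p", thresholds)
  }
  n <- nrow(spectra)
  keys <- spectra[, c("raw_file", "scan_number")]
  if (n == 0) {
    return(purrr::map(as.list(thresholds), function(t) {
      out <- tibble::tibble(raw_file = character(0), scan_number = integer(0),
                            cluster_id = integer(0))
      out
    }) |> purrr::imap(function(x, lab) `attr<-`(x, "threshold_label", lab)))
  }
  bins <- purrr::map(spectra$peaks, function(p) {
    if (nrow(p) == 0) integer(0) else bin_spectrum(p, params)
  })
  usable <- lengths(bins) > 0
  mass <- (spectra$precursor_mz - PROTON_MASS) *
    ifelse(is.na(spectra$precursor_charge), 2L, spectra$precursor_charge)
  charge_key <- ifelse(is.na(spectra$precursor_charge), 0L,
                       spectra$precursor_charge)
  ord <- order(keys$raw_file, keys$scan_number)
  rank_of <- integer(n)
  rank_of[ord] <- seq_len(n)

  # global labels per threshold, initialised to self (singletons)
  labels <- matrix(rep(seq_len(n), length(thresholds)), nrow = n)
  idx_usable <- which(usable & !is.na(mass))
  if (length(idx_usable) > 1) {
    parts <- split(
      idx_usable,
      paste(charge_key[idx_usable], chain_masses(mass[idx_usable], params$precursor_tol_ppm))
    )
    for (part in parts) {
      m <- length(part)
      if (m < 2) next
      score <- matrix(0, m, m)
      for (i in seq_len(m - 1)) {
        for (j in (i + 1):m) {
          score[i, j] <- score[j, i] <-
            pair_neglog_pvalue(bins[[part[i]]], bins[[part[j]]], params$n_bins)
        }
      }
      merges <- agglomerate(score, rank_of[part])
      for (k in seq_along(thresholds)) {
        loc <- cut_merges(merges, m, thresholds[k])
        labels[part, k] <- part[loc]
      }
    }
  }
  res <- lapply(seq_along(thresholds), function(k) {
    lab <- labels[, k]
    # dense ids ordered by the first (raw_file, scan) appearance
    first_rank <- tapply(rank_of, lab, min)
    dense_of_group <- rank(first_rank)
    dense <- as.integer(dense_of_group[as.character(lab)])
    out <- tibble::tibble(raw_file = keys$raw_file,
                          scan_number = keys$scan_number,
                          cluster_id = dense)
    attr(out, "threshold_label") <- names(thresholds)[k]
    out
  })
  names(res) <- names(thresholds)
  res
}
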