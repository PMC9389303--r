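# Synthetic multi-batch TMT-like datasets with ground truth: theoretical
# b/y fragment templates per peptide, per-batch noisy spectrum instances,
# reporter patterns per protein, and msms.txt-style PSM tables.

#' Configuration for the synthetic dataset generator
#'
#' The defaults describe the study conditions used throughout the test
#' suite: three TMT10 batches measured as one raw file each, two MS2 scans
#' per peptide per batch, and a 60% chance that any single scan is
#' identified by the search engine.
#'
#' @param n_batches Number of TMT batches (one raw file per batch).
#' @param n_peptides Number of base peptide analytes.
#' @param peptides_per_protein Peptides mapped to each synthetic protein.
#' @param scans_per_batch MS2 scans per analyte per batch.
#' @param phospho_fraction Fraction of peptides carrying one phospho site.
#' @param isomer_pair_fraction Fraction of peptides that get a positional
#'   phospho-isomer partner analyte (same unmodified sequence, shifted
#'   site; same protein).
#' @param lookalike_pair_fraction Fraction of peptides that get a
#'   look-alike partner: a different sequence (two adjacent residues
#'   swapped, hence identical precursor mass and mostly shared fragments)
#'   on a different protein, planting cluster-level ambiguity.
#' @param lookalike_scans_per_batch MS2 scans per look-alike partner per
#'   batch it occurs in (rare-analyte regime by default).
#' @param lookalike_n_batches Number of batches (from the first) in which a
#'   look-alike partner occurs; sporadically observed low-abundance
#'   co-eluting analytes are the realistic source of misclustered spectra,
#'   so the default is 1.
#' @param per_batch_identification_prob Probability that a scan is
#'   identified.
#' @param dropout_prob Per-fragment peak dropout probability.
#' @param mz_jitter_sd Gaussian m/z jitter sd in Th.
#' @param intensity_noise_sd Log-normal intensity noise sd (natural log).
#' @param plex_size Number of reporter channels (>= 2); the last channel
#'   is the bridge/reference.
#' @param reporter_pattern_sd Per-protein channel log-pattern sd.
#' @param reporter_noise_sd Per-PSM reporter log-noise sd.
#' @param peptide_length_range Residue-count range of generated peptides.
#' @param seed Integer seed; everything is deterministic given it.
#' @return List of class `synthetic_config`.
#' @export
synthetic_config <- function(n_batches = 3,
                             n_peptides = 200,
                             peptides_per_protein = 4,
                             scans_per_batch = 2,
                             phospho_fraction = 0.3,
                             isomer_pair_fraction = 0.05,
                             lookalike_pair_fraction = 0,
                             lookalike_scans_per_batch = 1,
                             lookalike_n_batches = 1,
                             per_batch_identification_prob = 0.6,
                             dropout_prob = 0.05,
                             mz_jitter_sd = 0.003,
                             intensity_noise_sd = 0.2,
                             plex_size = 10,
                             reporter_pattern_sd = 1,
                             reporter_noise_sd = 0.2,
                             peptide_length_range = c(8, 14),
                             seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("phospho_fraction", "isomer_pair_fraction",
             "lookalike_pair_fraction", "per_batch_identification_prob",
             "dropout_prob")
  for (p in probs) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must be in [0, 1]")
  }
  if (cfg$isomer_pair_fraction > 0 && cfg$phospho_fraction == 0) {
    stop("isomer pairs require phospho_fraction > 0")
  }
  stopifnot(n_batches >= 1, plex_size >= 2, n_peptides >= 1)
  structure(cfg, class = "synthetic_config")
}

AA_POOL <- c("A", "D", "E", "F", "G", "H", "K", "L", "N", "P", "Q", "R",
             "S", "T", "V", "W", "Y")

random_peptide <- function(rng, len) {
  paste(with_rng(rng, sample(AA_POOL, len, replace = TRUE)), collapse = "")
}

# render a modified sequence in the lowercase-prefix dialect, e.g. RApSPS...
render_prefix_dialect <- function(sequence, mods) {
  if (is.null(mods) || nrow(mods) == 0) return(sequence)
  res <- strsplit(sequence, "")[[1]]
  code_of <- c(Phospho = "p", Oxidation = "ox", Acetyl = "ac")
  for (k in seq_len(nrow(mods))) {
    res[mods$position[k]] <- paste0(code_of[[mods$name[k]]], res[mods$position[k]])
  }
  paste(res, collapse = "")
}

#' Generate a synthetic multi-batch dataset
#'
#' Builds the analyte panel (peptides, phospho forms, isomer partners,
#' look-alike partners, protein assignments), then per batch emits noisy
#' spectrum instances of each analyte's theoretical singly charged b/y
#' fragment template plus TMT reporter peaks drawn from the protein's
#' channel pattern, and a PSM table in which each scan is identified with
#' the configured probability.
#'
#' @param config A [synthetic_config()].
#' @return List with tibbles `spectra` (spectrum tibble as from
#'   [read_mgf()]), `psms` (PSM tibble as from [read_psm_table()]),
#'   `truth` (per-scan ground truth: `raw_file`, `scan_number`,
#'   `sequence`, `modified_sequence`, `proteins`, `analyte_id`,
#'   `is_lookalike`), `analytes` (the panel) and the `config`.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  rng <- local_rng(config$seed)
  lens <- config$peptide_length_range
  # --- base peptides (unique sequences) ---
  seqs <- character(0)
  while (length(seqs) < config$n_peptides) {
    need <- config$n_peptides - length(seqs)
    new <- vapply(seq_len(need), function(i) {
      random_peptide(rng, with_rng(rng, sample(lens[1]:lens[2], 1)))
    }, character(1))
    seqs <- unique(c(seqs, new))
  }
  n <- config$n_peptides
  protein <- sprintf("SYNPROT%04d", ceiling(seq_len(n) / config$peptides_per_protein))
  n_phos <- round(config$phospho_fraction * n)
  phospho_idx <- if (n_phos > 0) sort(sample_int(rng, seq_len(n), n_phos)) else integer(0)

  # ensure phospho peptides have two STY sites so isomer partners exist
  ensure_sty <- function(s, k) {
    res <- strsplit(s, "")[[1]]
    sty <- which(res %in% c("S", "T", "Y"))
    while (length(sty) < k) {
      pos <- with_rng(rng, sample(setdiff(seq_along(res), sty), 1))
      res[pos] <- "S"
      sty <- which(res %in% c("S", "T", "Y"))
    }
    paste(res, collapse = "")
  }
  n_iso <- round(config$isomer_pair_fraction * n)
  iso_idx <- if (n_iso > 0) phospho_idx[sort(sample_int(rng, seq_along(phospho_idx),
                                                        min(n_iso, length(phospho_idx))))]
             else integer(0)
  for (i in phospho_idx) {
    seqs[i] <- ensure_sty(seqs[i], if (i %in% iso_idx) 2 else 1)
  }

  analytes <- tibble::tibble(
    analyte_id = seq_len(n), sequence = seqs, protein = protein,
    phospho_pos = NA_integer_, is_lookalike = FALSE,
    scans_per_batch = config$scans_per_batch,
    n_batches_present = config$n_batches
  )
  for (i in phospho_idx) {
    sty <- which(strsplit(seqs[i], "")[[1]] %in% c("S", "T", "Y"))
    analytes$phospho_pos[i] <- sty[with_rng(rng, sample(length(sty), 1))]
  }
  # isomer partners: same sequence, phospho on a different STY site
  extra <- list()
  for (i in iso_idx) {
    sty <- which(strsplit(seqs[i], "")[[1]] %in% c("S", "T", "Y"))
    alt <- setdiff(sty, analytes$phospho_pos[i])
    extra[[length(extra) + 1]] <- tibble::tibble(
      analyte_id = NA_integer_, sequence = seqs[i], protein = protein[i],
      phospho_pos = alt[with_rng(rng, sample(length(alt), 1))],
      is_lookalike = FALSE, scans_per_batch = config$scans_per_batch,
      n_batches_present = config$n_batches)
  }
  # look-alike partners: adjacent-residue swap, different protein
  n_look <- round(config$lookalike_pair_fraction * n)
  look_idx <- if (n_look > 0) sort(sample_int(rng, seq_len(n), n_look)) else integer(0)
  for (i in look_idx) {
    res <- strsplit(seqs[i], "")[[1]]
    cand <- which(res[-length(res)] != res[-1])
    cand <- cand[cand > 1 & cand < length(res) - 1]
    if (length(cand) == 0) next
    sw <- cand[with_rng(rng, sample(length(cand), 1))]
    res[c(sw, sw + 1)] <- res[c(sw + 1, sw)]
    partner <- paste(res, collapse = "")
    if (partner %in% c(seqs, vapply(extra, function(e) e$sequence, character(1)))) next
    partner_pp <- NA_integer_
    if (!is.na(analytes$phospho_pos[i])) {
      sty <- which(res %in% c("S", "T", "Y"))
      partner_pp <- if (analytes$phospho_pos[i] %in% sty) analytes$phospho_pos[i]
                    else sty[with_rng(rng, sample(length(sty), 1))]
    }
    extra[[length(extra) + 1]] <- tibble::tibble(
      analyte_id = NA_integer_, sequence = partner,
      protein = sprintf("SYNLOOK%04d", i),
      phospho_pos = partner_pp, is_lookalike = TRUE,
      scans_per_batch = config$lookalike_scans_per_batch,
      n_batches_present = min(config$lookalike_n_batches, config$n_batches))
  }
  if (length(extra) > 0) analytes <- dplyr::bind_rows(analytes, extra)
  analytes$analyte_id <- seq_len(nrow(analytes))
  analytes$modified_sequence <- purrr::pmap_chr(
    list(analytes$sequence, analytes$phospho_pos),
    function(s, pp) {
      if (is.na(pp)) s else render_prefix_dialect(
        s, tibble::tibble(position = pp, name = "Phospho"))
    })

  # --- per-analyte fragment templates and base intensities ---
  templates <- purrr::pmap(list(analytes$sequence, analytes$phospho_pos),
    function(s, pp) {
      mods <- if (is.na(pp)) NULL else tibble::tibble(position = pp, name = "Phospho")
      mz <- fragment_mz(s, mods)
      base <- 1e4 * rng_runif(rng, length(mz), 0.2, 1)
      list(mz = mz, base = base,
           mass = peptide_mass(s, mods))
    })
  # per-protein reporter channel pattern (log2 space, bridge channel 0)
  prots <- unique(analytes$protein)
  pattern <- matrix(rng_rnorm(rng, length(prots) * config$plex_size,
                              sd = config$reporter_pattern_sd),
                    nrow = length(prots))
  pattern[, config$plex_size] <- 0
  rownames(pattern) <- prots

  # --- emit scans ---
  rows <- list()
  for (b in seq_len(config$n_batches)) {
    raw_file <- sprintf("batch%02d", b)
    scan <- 0L
    for (a in seq_len(nrow(analytes))) {
      if (b > analytes$n_batches_present[a]) next
      tpl <- templates[[a]]
      for (r in seq_len(analytes$scans_per_batch[a])) {
        scan <- scan + 1L
        keep <- rng_runif(rng, length(tpl$mz)) >= config$dropout_prob
        if (!any(keep)) keep[1] <- TRUE
        mz <- tpl$mz[keep] + rng_rnorm(rng, sum(keep), sd = config$mz_jitter_sd)
        int <- tpl$base[keep] *
          exp(rng_rnorm(rng, sum(keep), sd = config$intensity_noise_sd))
        reporter <- 1e5 * 2^pattern[analytes$protein[a], ] *
          exp(rng_rnorm(rng, config$plex_size, sd = config$reporter_noise_sd))
        identified <- rng_runif(rng, 1) < config$per_batch_identification_prob
        rows[[length(rows) + 1]] <- list(
          raw_file = raw_file, scan_number = scan, analyte = a,
          mz = mz, intensity = int, reporter = reporter,
          mass = tpl$mass, identified = identified,
          score = 50 + 100 * rng_runif(rng, 1))
      }
    }
  }
  reporter_names <- paste0("reporter_", seq_len(config$plex_size))
  spectra <- new_spectrum_tbl(
    raw_file = vapply(rows, `[[`, character(1), "raw_file"),
    scan_number = vapply(rows, `[[`, integer(1), "scan_number"),
    precursor_mz = vapply(rows, function(r) r$mass / 2 + PROTON_MASS, numeric(1)),
    precursor_charge = rep(2L, length(rows)),
    retention_time = rep(NA_real_, length(rows)),
    peaks = purrr::map(rows, function(r) {
      o <- order(r$mz)
      tibble::tibble(mz = r$mz[o], intensity = r$intensity[o])
    }),
    reporter = purrr::map(rows, "reporter")
  )
  a_of <- vapply(rows, `[[`, integer(1), "analyte")
  identified <- vapply(rows, `[[`, logical(1), "identified")
  psms <- tibble::tibble(
    raw_file = spectra$raw_file,
    scan_number = spectra$scan_number,
    batch_id = spectra$raw_file,
    sequence = ifelse(identified, analytes$sequence[a_of], NA_character_),
    modified_sequence = ifelse(identified, analytes$modified_sequence[a_of],
                               NA_character_),
    proteins = ifelse(identified, analytes$protein[a_of], NA_character_),
    score = ifelse(identified, vapply(rows, `[[`, numeric(1), "score"), NA_real_),
    pep = ifelse(identified, 0.001, NA_real_),
    is_decoy = FALSE, is_contaminant = FALSE,
    is_identified = identified
  )
  rep_mat <- do.call(rbind, spectra$reporter)
  for (i in seq_len(config$plex_size)) psms[[reporter_names[i]]] <- rep_mat[, i]
  truth <- tibble::tibble(
    raw_file = spectra$raw_file, scan_number = spectra$scan_number,
    sequence = analytes$sequence[a_of],
    modified_sequence = analytes$modified_sequence[a_of],
    proteins = analytes$protein[a_of],
    analyte_id = a_of,
    is_lookalike = analytes$is_lookalike[a_of]
  )
  list(spectra = spectra, psms = psms, truth = truth, analytes = analytes,
       config = config)
}

#' Write a synthetic dataset to disk
#'
#' One MGF per batch, a combined msms.txt-dialect PSM table, and a
#' ground-truth TSV.
#'
#' @param dataset Result of [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rf in unique(dataset$spectra$raw_file)) {
    sub <- dataset$spectra[dataset$spectra$raw_file == rf, ]
    # include the reporter peaks so MGF round trips carry quantification
    sub$peaks <- purrr::map2(sub$peaks, sub$reporter, function(p, rep) {
      dplyr::arrange(dplyr::bind_rows(
        p, tibble::tibble(mz = tmt10_reporter_mz[seq_along(rep)],
                          intensity = rep)), .data$mz)
    })
    write_mgf(sub, file.path(dir, paste0(rf, ".mgf")))
  }
  write_psm_table(dataset$psms, file.path(dir, "msms.txt"))
  readr::write_tsv(dataset$truth, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
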