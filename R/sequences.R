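# Residue masses, modified-sequence parsing and localization flags.

#' Monoisotopic residue masses
#'
#' Named vector of monoisotopic masses (Da) of the 20 amino-acid residues
#' (i.e. amino acid minus water), as used for theoretical b/y fragment ions.
#'
#' @format Named numeric vector, names are one-letter residue codes.
#' @export
residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.00727646688
WATER_MASS <- 18.0105646863

# modification name -> monoisotopic mass shift (Da); lowercase short codes
# are the inline-token dialect (e.g. "pS" = phospho-serine)
MOD_MASSES <- c(Phospho = 79.96633, Oxidation = 15.99491, Acetyl = 42.01057)
MOD_CODES <- c(p = "Phospho", ph = "Phospho", ox = "Oxidation", ac = "Acetyl")
# residues a modification may sit on (used to validate flag positions);
# types not listed here are accepted on any residue
MOD_TARGETS <- list(Phospho = c("S", "T", "Y"), Oxidation = "M")

#' Parse a modified peptide sequence
#'
#' Understands two common dialects and mixtures of them:
#' * lowercase tokens prefixed to the modified residue, e.g. `"RApSPSPRAA"`
#'   (`p` = phospho, `ox` = oxidation, `ac` = acetyl);
#' * MaxQuant-style parenthesised tokens following the residue, possibly with
#'   nested parentheses, e.g. `"RAS(Phospho (STY))PSPRAA"` or `"M(ox)PEPTIDE"`.
#'
#' Leading/trailing underscores (MaxQuant framing) are stripped. A
#' parenthesised token before the first residue is taken as an N-terminal
#' modification and attached to position 1.
#'
#' @param modified_sequence Character scalar.
#' @return A list with elements `sequence` (the unmodified uppercase
#'   sequence) and `mods`, a tibble with columns `position` (1-based residue
#'   index) and `name` (normalized modification name).
#' @export
parse_modified_sequence <- function(modified_sequence) {
  stopifnot(is.character(modified_sequence), length(modified_sequence) == 1)
  s <- gsub("^_+|_+$", "", modified_sequence)
  chars <- strsplit(s, "")[[1]]
  seq_chars <- character(0)
  pos <- integer(0)
  name <- character(0)
  i <- 1L
  pending <- NULL # lowercase token awaiting its residue
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "(") {
      depth <- 1L
      j <- i + 1L
      while (j <= length(chars) && depth > 0L) {
        if (chars[j] == "(") depth <- depth + 1L
        if (chars[j] == ")") depth <- depth - 1L
        j <- j + 1L
      }
      if (depth > 0L) stop("unbalanced parentheses in modified sequence: ", modified_sequence)
      token <- paste(chars[(i + 1L):(j - 2L)], collapse = "")
      pos <- c(pos, max(1L, length(seq_chars)))
      name <- c(name, normalize_mod_name(token))
      i <- j
    } else if (ch %in% letters) {
      run <- ch
      while (i + 1L <= length(chars) && chars[i + 1L] %in% letters) {
        i <- i + 1L
        run <- paste0(run, chars[i])
      }
      pending <- run
      i <- i + 1L
    } else if (ch %in% LETTERS) {
      seq_chars <- c(seq_chars, ch)
      if (!is.null(pending)) {
        pos <- c(pos, length(seq_chars))
        name <- c(name, normalize_mod_name(pending))
        pending <- NULL
      }
      i <- i + 1L
    } else {
      i <- i + 1L # ignore stray characters (digits, dots in framed forms)
    }
  }
  if (!is.null(pending)) stop("dangling modification token in: ", modified_sequence)
  list(sequence = paste(seq_chars, collapse = ""),
       mods = tibble::tibble(position = pos, name = name))
}

normalize_mod_name <- function(token) {
  token <- trimws(token)
  low <- tolower(token)
  if (low %in% names(MOD_CODES)) return(unname(MOD_CODES[[low]]))
  # MaxQuant long form e.g. "Phospho (STY)", "Oxidation (M)"
  head_word <- sub("\\s*\\(.*$", "", token)
  if (head_word %in% names(MOD_MASSES)) return(head_word)
  token
}

#' Strip modification tokens from a modified sequence
#'
#' @param modified_sequence Character vector.
#' @return Character vector of unmodified uppercase sequences.
#' @export
strip_modifications <- function(modified_sequence) {
  vapply(modified_sequence, function(x) {
    if (is.na(x) || x == "") return(NA_character_)
    parse_modified_sequence(x)$sequence
  }, character(1), USE.NAMES = FALSE)
}

#' Theoretical singly charged b/y fragment m/z values
#'
#' @param sequence Unmodified uppercase sequence.
#' @param mods Optional tibble with `position`, `name` as produced by
#'   [parse_modified_sequence()]; modification masses are added to the
#'   affected residues before fragment masses are computed.
#' @return Numeric vector of b1..b(n-1) and y1..y(n-1) m/z values (charge 1).
#' @export
fragment_mz <- function(sequence, mods = NULL) {
  res <- strsplit(sequence, "")[[1]]
  if (!all(res %in% names(residue_masses))) {
    stop("unknown residue in sequence: ", sequence)
  }
  m <- unname(residue_masses[res])
  if (!is.null(mods) && nrow(mods) > 0) {
    for (k in seq_len(nrow(mods))) {
      nm <- mods$name[k]
      if (!nm %in% names(MOD_MASSES)) stop("unknown modification: ", nm)
      m[mods$position[k]] <- m[mods$position[k]] + MOD_MASSES[[nm]]
    }
  }
  n <- length(m)
  if (n < 2) return(numeric(0))
  b <- cumsum(m)[seq_len(n - 1)] + PROTON_MASS
  y <- rev(cumsum(rev(m))[seq_len(n - 1)]) + WATER_MASS + PROTON_MASS
  c(b, rev(y))
}

#' Neutral peptide mass
#'
#' @inheritParams fragment_mz
#' @return Monoisotopic neutral mass in Da.
#' @export
peptide_mass <- function(sequence, mods = NULL) {
  res <- strsplit(sequence, "")[[1]]
  m <- sum(residue_masses[res]) + WATER_MASS
  if (!is.null(mods) && nrow(mods) > 0) m <- m + sum(MOD_MASSES[mods$name])
  unname(m)
}

#' Build a localization flag from positional modification isomers
#'
#' Summarises a set of modified sequences that agree on the unmodified
#' sequence and per-type modification counts but differ in the modified
#' positions. The rendered flag lists the shared sequence, the total
#' modification count, and the union of observed sites, e.g.
#' `"RASPSPRAA.1.p3/p5"` for a singly phosphorylated peptide observed on
#' sites 3 and 5. Phosphorylation sites use the `p` prefix; other
#' modification types use a `mod` prefix.
#'
#' @param modified_sequences Character vector (length >= 1) of modified
#'   sequences in any dialect understood by [parse_modified_sequence()].
#' @return A list of class `localization_flag` with elements
#'   `base_sequence`, `n_mods`, `positions` (named list per modification
#'   type, ascending) and `text` (the rendered flag).
#' @export
build_localization_flag <- function(modified_sequences) {
  stopifnot(length(modified_sequences) >= 1)
  parsed <- lapply(modified_sequences, parse_modified_sequence)
  base <- unique(vapply(parsed, `[[`, character(1), "sequence"))
  if (length(base) != 1) {
    stop("modified sequences do not share one unmodified sequence: ",
         paste(base, collapse = ", "))
  }
  count_sig <- function(p) {
    tab <- table(p$mods$name)
    paste(sort(paste0(names(tab), ":", tab)), collapse = ";")
  }
  sigs <- unique(vapply(parsed, count_sig, character(1)))
  if (length(sigs) != 1) {
    stop("modified sequences differ in modification counts; ",
         "such clusters must be categorized as ambiguous, not PTM-isomeric")
  }
  all_mods <- dplyr::bind_rows(lapply(parsed, `[[`, "mods"))
  n_mods <- nrow(parsed[[1]]$mods)
  base_res <- strsplit(base, "")[[1]]
  positions <- list()
  for (nm in sort(unique(all_mods$name))) {
    p <- sort(unique(all_mods$position[all_mods$name == nm]))
    bad <- p[!base_res[p] %in% MOD_TARGETS[[nm]]]
    if (nm %in% names(MOD_TARGETS) && length(bad) > 0) {
      stop("position ", paste(bad, collapse = ","), " of ", base,
           " cannot carry ", nm)
    }
    positions[[nm]] <- p
  }
  prefix <- function(nm) if (nm == "Phospho") "p" else "mod"
  segs <- unlist(lapply(names(positions), function(nm) {
    paste0(prefix(nm), positions[[nm]])
  }))
  structure(
    list(base_sequence = base, n_mods = n_mods, positions = positions,
         text = paste0(base, ".", n_mods, ".", paste(segs, collapse = "/"))),
    class = "localization_flag"
  )
}

#' @export
format.localization_flag <- function(x, ...) x$text

#' @export
print.localization_flag <- function(x, ...) {
  cat("<localization_flag> ", x$text, "\n", sep = "")
  invisible(x)
}
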