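# MS2 spectrum reading: MGF and mzML, plus reporter-ion extraction.

#' Default TMT10 reporter ion m/z values
#'
#' The ten HCD reporter masses of the TMT10plex reagents, in Th.
#'
#' @export
tmt10_reporter_mz <- c(
  126.127726, 127.124761, 127.131081, 128.128116, 128.134436,
  129.131471, 129.137790, 130.134825, 130.141145, 131.138180
)

new_spectrum_tbl <- function(raw_file, scan_number, precursor_mz,
                             precursor_charge, retention_time, peaks,
                             reporter) {
  tibble::tibble(
    raw_file = raw_file,
    scan_number = as.integer(scan_number),
    batch_id = raw_file,
    precursor_mz = precursor_mz,
    precursor_charge = as.integer(precursor_charge),
    retention_time = retention_time,
    peaks = peaks,
    reporter = reporter,
    n_peaks = vapply(peaks, nrow, integer(1))
  )
}

#' Extract reporter intensities from a peak list
#'
#' For each configured reporter m/z, the summed intensity of peaks within
#' `tol` Th of it.
#'
#' @param peaks Tibble with `mz`, `intensity`.
#' @param reporter_mz Reporter ion m/z values (default TMT10).
#' @param tol Half-window in Th.
#' @return Numeric vector, one entry per reporter channel.
#' @export
extract_reporter_intensities <- function(peaks, reporter_mz = tmt10_reporter_mz,
                                         tol = 0.003) {
  vapply(reporter_mz, function(m) {
    sum(peaks$intensity[abs(peaks$mz - m) <= tol])
  }, numeric(1))
}

#' Read MS2 spectra from an MGF file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `TITLE` lines of the form
#' `...scan=N...` or a `SCANS=` line provide the scan number; blocks without
#' either get sequential numbers. Peaks are sorted ascending by m/z.
#' Reporter intensities are extracted from the reporter m/z windows.
#'
#' @param path MGF file path.
#' @param reporter_mz,reporter_tol Passed to
#'   [extract_reporter_intensities()].
#' @return Spectrum tibble: `raw_file`, `scan_number`, `batch_id`,
#'   `precursor_mz`, `precursor_charge` (NA when absent), `retention_time`
#'   (minutes, NA when absent), `peaks` (list of tibbles), `reporter` (list
#'   of numeric vectors), `n_peaks`.
#' @export
read_mgf <- function(path, reporter_mz = tmt10_reporter_mz,
                     reporter_tol = 0.003) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readr::read_lines(path, progress = FALSE)
  raw_file <- normalize_raw_file(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("unbalanced BEGIN/END IONS in ", path)
  recs <- purrr::map2(starts, ends, function(s, e) {
    block <- lines[(s + 1):(e - 1)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    get <- function(k) if (k %in% keys) vals[match(k, keys)] else NA_character_
    scan <- NA_integer_
    if (!is.na(get("SCANS"))) scan <- as.integer(get("SCANS"))
    title <- get("TITLE")
    if (is.na(scan) && !is.na(title) && grepl("scan=", title)) {
      scan <- as.integer(sub(".*scan=([0-9]+).*", "\\1", title))
    }
    pep_mz <- if (!is.na(get("PEPMASS"))) {
      as.numeric(strsplit(get("PEPMASS"), "\\s+")[[1]][1])
    } else NA_real_
    charge <- if (!is.na(get("CHARGE"))) {
      as.integer(sub("[+-]$", "", get("CHARGE")))
    } else NA_integer_
    rt <- if (!is.na(get("RTINSECONDS"))) as.numeric(get("RTINSECONDS")) / 60 else NA_real_
    pk_lines <- block[!is_kv & grepl("^[0-9]", block)]
    if (length(pk_lines) > 0) {
      mat <- do.call(rbind, lapply(strsplit(pk_lines, "\\s+"), function(x) {
        as.numeric(x[1:2])
      }))
      o <- order(mat[, 1])
      peaks <- tibble::tibble(mz = mat[o, 1], intensity = mat[o, 2])
    } else {
      peaks <- tibble::tibble(mz = numeric(0), intensity = numeric(0))
    }
    list(scan = scan, pep_mz = pep_mz, charge = charge, rt = rt, peaks = peaks)
  })
  scans <- vapply(recs, `[[`, integer(1), "scan")
  scans[is.na(scans)] <- seq_along(scans)[is.na(scans)]
  new_spectrum_tbl(
    raw_file = rep(raw_file, length(recs)),
    scan_number = scans,
    precursor_mz = vapply(recs, `[[`, numeric(1), "pep_mz"),
    precursor_charge = vapply(recs, `[[`, integer(1), "charge"),
    retention_time = vapply(recs, `[[`, numeric(1), "rt"),
    peaks = purrr::map(recs, "peaks"),
    reporter = purrr::map(recs, function(r) {
      extract_reporter_intensities(r$peaks, reporter_mz, reporter_tol)
    })
  )
}

#' Write spectra to an MGF file
#'
#' @param spectra Spectrum tibble (see [read_mgf()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  blocks <- purrr::pmap_chr(
    list(spectra$scan_number, spectra$precursor_mz, spectra$precursor_charge,
         spectra$retention_time, spectra$peaks),
    function(scan, mz, z, rt, peaks) {
      hdr <- c("BEGIN IONS",
               sprintf("TITLE=scan=%d", scan),
               sprintf("SCANS=%d", scan),
               if (!is.na(mz)) sprintf("PEPMASS=%.6f", mz),
               if (!is.na(z)) sprintf("CHARGE=%d+", z),
               if (!is.na(rt)) sprintf("RTINSECONDS=%.3f", rt * 60))
      pk <- sprintf("%.6f %.4f", peaks$mz, peaks$intensity)
      paste(c(hdr, pk, "END IONS"), collapse = "\n")
    })
  readr::write_lines(paste(blocks, collapse = "\n\n"), path)
  invisible(path)
}

#' Read MS2 spectra from an mzML file
#'
#' Uses \pkg{mzR}. Non-MS2 scans are skipped with a single warning giving
#' their count. Scan numbers are taken from the `scan=` field of the
#' spectrum id, falling back to the acquisition number.
#'
#' @inheritParams read_mgf
#' @param path mzML file path.
#' @return Spectrum tibble as for [read_mgf()].
#' @export
read_mzml <- function(path, reporter_mz = tmt10_reporter_mz,
                      reporter_tol = 0.003) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("reading mzML requires the mzR package")
  }
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle))
  hdr <- suppressWarnings(mzR::header(handle))
  keep <- which(hdr$msLevel == 2)
  n_skipped <- nrow(hdr) - length(keep)
  if (n_skipped > 0) {
    warning(n_skipped, " non-MS2 scan(s) skipped in ", basename(path))
  }
  scan_from_id <- function(id, fallback) {
    hit <- grepl("scan=[0-9]+", id)
    out <- ifelse(hit, suppressWarnings(as.integer(sub(".*scan=([0-9]+).*", "\\1", id))),
                  NA_integer_)
    ifelse(is.na(out), fallback, out)
  }
  peaks_list <- lapply(keep, function(i) {
    p <- suppressWarnings(mzR::peaks(handle, i))
    if (is.null(p) || nrow(p) == 0) {
      return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
    }
    o <- order(p[, 1])
    tibble::tibble(mz = p[o, 1], intensity = p[o, 2])
  })
  charge <- hdr$precursorCharge[keep]
  charge[!is.na(charge) & charge <= 0] <- NA_integer_
  new_spectrum_tbl(
    raw_file = rep(normalize_raw_file(path), length(keep)),
    scan_number = scan_from_id(hdr$spectrumId[keep], hdr$acquisitionNum[keep]),
    precursor_mz = hdr$precursorMZ[keep],
    precursor_charge = charge,
    retention_time = ifelse(is.na(hdr$retentionTime[keep]), NA_real_,
                            hdr$retentionTime[keep] / 60),
    peaks = peaks_list,
    reporter = lapply(peaks_list, extract_reporter_intensities,
                      reporter_mz = reporter_mz, tol = reporter_tol)
  )
}
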