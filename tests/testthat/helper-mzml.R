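# Synthetic mzML fixture writer (test plumbing only: mzML *writing* is
# outside the package's scope). Emits a minimal uncompressed 64-bit mzML
# with MS2 spectra carrying scan numbers 101, 102, ...

write_tiny_mzml <- function(path, n_scans = 5) {
  enc64 <- function(x) {
    jsonlite::base64_enc(writeBin(as.double(x), raw(), size = 8,
                                  endian = "little"))
  }
  one <- function(i, scan, premz, z, mz, int) {
    sprintf(paste0(
      '<spectrum index="%d" id="controllerType=0 controllerNumber=1 scan=%d" defaultArrayLength="%d">\n',
      '<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="2"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000580" name="MSn spectrum" value=""/>\n',
      '<precursorList count="1"><precursor><selectedIonList count="1"><selectedIon>\n',
      '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%f"/>\n',
      '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>\n',
      '</selectedIon></selectedIonList></precursor></precursorList>\n',
      '<binaryDataArrayList count="2">\n',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/><binary>%s</binary></binaryDataArray>\n',
      '<binaryDataArray encodedLength="%d"><cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/><binary>%s</binary></binaryDataArray>\n',
      '</binaryDataArrayList></spectrum>'),
      i, scan, length(mz), premz, z,
      nchar(enc64(mz)), enc64(mz), nchar(enc64(int)), enc64(int))
  }
  body <- paste(vapply(seq_len(n_scans), function(k) {
    one(k - 1L, 100L + k, 500.25, 2L, c(120.5, 230.1, 340.7),
        c(10, 20, 5) * k)
  }, character(1)), collapse = "\n")
  doc <- sprintf(paste0(
    '<?xml version="1.0" encoding="utf-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">\n',
    '<cvList count="1"><cv id="MS" fullName="PSI-MS" URI="x"/></cvList>\n',
    '<run id="r1"><spectrumList count="%d" defaultDataProcessingRef="dp1">\n%s\n',
    '</spectrumList></run></mzML>'), n_scans, body)
  writeLines(doc, path)
  invisible(path)
}
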