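Package: ms2transfer
Title: Spectrum-Clustering-Based Transfer of Peptide Identifications Across
    Isobaric-Labeling Batches
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters MS2 fragment spectra across multiplexed isobaric-labeling
    (TMT) batches by complete-linkage agglomeration at a ladder of
    -log10(p-value) stringency thresholds, categorizes the resulting clusters
    by the identity of their member peptide-spectrum matches, and transfers
    identifications from identified to unidentified spectra within
    transferable and PTM-isomeric clusters, reducing missing values across
    batches. Includes readers and writers for MaxQuant-style PSM tables, MGF
    and mzML spectra, and cluster-assignment files; a masking-based
    precision/recall/FDR evaluation; the ambiguous-cluster FDR proxy;
    cumulative batch-presence curves; a reporter-ion ratio agreement check;
    and a synthetic multi-batch dataset generator with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    mzR,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
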