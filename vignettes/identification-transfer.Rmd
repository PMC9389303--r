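---
title: "Transferring peptide identifications across TMT batches by spectrum clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transferring peptide identifications across TMT batches by spectrum clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiplexed isobaric-labeling (TMT) studies measure cohorts as a series of
batches. A peptide that is fragmented in every batch is frequently
*identified* by the search engine in only some of them — identical precursors
yield near-identical MS2 spectra, but stochastic differences push some below
the identification threshold. The result is a missing-value pattern that
grows with the number of batches, even though the quantitative evidence (the
reporter ions) is present in every batch.

`ms2transfer` exploits the redundancy directly: MS2 spectra are clustered
across batches by fragment similarity, and within suitable clusters the
identification is transferred from identified ("donor") to unidentified
("acceptor") spectra. Because reporter ions live in the same MS2 scan, a
transferred identification immediately yields a quantification in the batch
where it was missing.

```{r}
library(ms2transfer)
library(dplyr)
```

## Clustering model

Each spectrum is reduced to the set of integer fragment bins
(`floor(mz / bin_width)`, default width 0.02 Th) occupied by its `top_k`
(default 40) most intense peaks. The reporter region (125–135 Th) is
excluded: every TMT spectrum carries those ions, so they hold no identity
signal. For two binned spectra with $k_a$ and $k_b$ bins sharing $s$ of $B$
available bins, the similarity score is the hypergeometric upper tail

$$-\log_{10} P(S \ge s), \qquad S \sim
  \mathrm{Hypergeom}(B, k_a, k_b),$$

i.e. the surprise of the observed overlap under an independence null. $B$ is
the fragment m/z range (default 100–1800 Th) divided by the bin width.
Spectra are compared only within partitions of equal precursor charge and
chained precursor-mass windows (single-linkage chaining at 10 ppm, so
near-boundary pairs are still compared; hard bin edges would split them
arbitrarily). Spectra of unknown charge are compared among themselves: a
scan must end up in exactly one cluster, which rules out entering several
charge partitions at once.

Within each partition, clusters grow by **complete-linkage agglomeration**:
two clusters merge only while *every* cross-pair meets the stringency
threshold. One dendrogram is built per partition and cut at each threshold
of the ladder p5, p10, …, p30 (cutoffs 5–30 on the $-\log_{10} p$ scale),
which guarantees that stricter partitions refine looser ones. Ties in the
merge order are broken by the lexicographic (raw file, scan number) order
of the cluster representatives, making the whole procedure deterministic.
The p-value model here is deliberately simple — the pipeline only consumes
cluster assignments, and assignments from an external spectrum clusterer
can be imported as `raw_file TAB scan TAB cluster_id` files to replace it.

The suite verifies agglomeration against a from-scratch enumerating
implementation on random sets of up to 12 spectra, checks the
all-cross-pairs certificate on emitted clusters, and asserts the nesting of
the threshold ladder.

## Cluster categories and transfer

Clusters are categorized by the identities of their members:

| class | name | definition |
|---|---|---|
| a | singleton | one spectrum |
| b | unanimous | all members identified, one unmodified sequence |
| c | fully unidentified | no identified member |
| d | ambiguous | identified members disagree on the unmodified sequence |
| e | transferable | one modified sequence among donors + unidentified members |
| f | PTM-isomeric | one unmodified sequence, ≥ 2 modification-site variants, + unidentified members |

Only classes (e) and (f) transfer. In class (e) the acceptors receive the
donors' modified and unmodified sequence and the protein identifiers of the
highest-scoring donor. In class (f) the localization is genuinely ambiguous,
so no single modified sequence is transferred; acceptors receive the
unmodified sequence plus a *localization flag* listing the modification
count and the union of observed sites:

```{r}
build_localization_flag(c("RApSPSPRAA", "RASPpSPRAA"))
```

Two judgement calls were open and are decided as follows. Clusters whose
donors carry *different modification counts* (say singly and doubly
phosphorylated forms) are demoted to ambiguous rather than treated as
PTM-isomeric — the flag format assumes one shared count, and transferring
across different stoichiometries would assert more than the evidence shows
(`require_equal_mod_counts = FALSE` restores the permissive behaviour).
Fully identified clusters that differ only in modification sites have no
acceptors; they are counted as unanimous, with a `ptm_variants` marker,
since no transfer decision depends on the distinction. Decoy and
contaminant PSMs are parsed but never donate.

Direct identifications are never altered by transfer, transfers never
originate from classes a–d, and the operation is idempotent; all three are
asserted property-style over randomized tables.

## Masking evaluation and the ambiguity proxy

To measure error rates without external ground truth, a fraction (5–50%) of
the identified spectra *per raw file* is masked — the identification is
hidden and the scan becomes an ordinary acceptor. Treating re-identification
as multi-class classification with one class per peptide sequence,

$$\text{Precision} = \frac{\sum \text{correct transfers}}{\sum \text{transfers}},
\qquad \text{Recall} = \frac{\sum \text{correct transfers}}{\sum \text{masked spectra}},
\qquad \text{FDR} = 1 - \text{Precision},$$

micro-averaged over classes (the package computes the pooled ratios; the
test suite checks them against an independent per-class tally). Correctness
is judged on the unmodified sequence — PTM-isomeric transfers deliberately
leave the site open — with a strict mode available that also requires the
modified sequence to match. Transfers onto scans that never had an
identification are unverifiable and are excluded from both the numerator
and the denominator of precision; reports carry the counts so this choice
is visible.

Independently, the fraction of multi-spectrum clusters that are *ambiguous*
(class d) proxies the transfer FDR: it flags the same failure mode —
spectra of different peptides landing in one cluster — without requiring a
masking run.

## What the synthetic generator emulates

`generate_dataset()` builds a multi-batch TMT10 study from first
principles: random tryptic-like peptides (8–14 residues), singly charged
b/y fragment templates from monoisotopic residue masses (phosphorylation
adds 79.96633 Da at the site), per-batch spectrum instances with peak
dropout, m/z jitter and log-normal intensity noise, reporter intensities
from a per-protein channel pattern with the last channel as bridge, and an
msms.txt-style PSM table in which each scan is identified with a configured
probability.

The default study conditions, used by the test suite and the acceptance
script, are: 3 batches × 2 scans per peptide per batch × 850 peptides
(≈ 5,100 scans when partner analytes are included), 60% per-scan
identification probability (a typical fraction of MS2 scans a search engine
identifies), 30% phosphopeptides, 5% planted positional-isomer pairs,
dropout 0.05, m/z jitter 0.003 Th, intensity noise 0.2 (log scale). With
two scans per batch a masked scan has five same-analyte siblings, so
near-complete recovery of masked identifications is expected and observed
(≥ 95% at p5).

Two structured perturbations plant controlled failure modes:

* **positional isomer pairs** — a second analyte with the same sequence and
  a shifted phospho site (same protein), which populates class (f);
* **look-alike pairs** — a different peptide obtained by swapping two
  adjacent residues (identical precursor mass, almost identical fragment
  set) assigned to a different protein, which populates class (d) and
  causes genuinely wrong transfers. Look-alike partners default to a single
  scan in a single batch: sporadically observed low-abundance co-eluting
  analytes are the realistic source of misclustered spectra, and this
  regime keeps the two error estimates (masking FDR and ambiguous fraction)
  on comparable footing — a partner observed in every batch is nearly
  always *identified* somewhere, which inflates ambiguity counts while
  producing almost no wrong transfer. The proxy experiment masks 50% (the
  largest fraction used in masking analyses) to maximise verifiable
  acceptors.

What the generator does **not** model: chimeric spectra, retention-time
structure, charge-state mixtures (everything is 2+), realistic fragment
intensity prediction, shared/razor peptides, and protein-level FDR
artefacts. Passing tests therefore demonstrate the correctness of the
bookkeeping and the statistical machinery under controlled conditions, not
performance on real cohort data — on real data the clustering error
structure is set by the actual spectrum clusterer used upstream.

## Numerical choices and degenerate inputs

* Scores are computed on the log scale (`phyper(..., log.p = TRUE)`), so
  identical-spectrum pairs give finite scores far above p30 rather than
  underflowing to `-log10(0)`.
* Empty spectra are retained in tables but excluded from clustering; they
  become singletons at every threshold. Scans missing from an imported
  assignment likewise become fresh singletons.
* Best-per-scan PSM selection keeps the highest score; ties keep the first
  row (stable order).
* `round(fraction × n_identified)` masked scans per raw file, sampled
  without replacement with a self-contained RNG stream, so masking never
  perturbs the caller's random state.
* Zero verifiable transfers make precision degenerate; it is reported as 1
  with `degenerate = TRUE` rather than NaN, and FDR stays `1 - precision`
  exactly.
* Reporter-ratio agreement skips proteins with fewer than two other direct
  PSMs in the batch and PSMs with constant or non-positive reporter
  vectors; skipped counts are attached to the result.

## A worked run

```{r, fig.width = 6, fig.height = 4}
d <- generate_dataset(synthetic_config(n_peptides = 120, seed = 1))
run <- run_pipeline(d$psms, spectra = d$spectra, thresholds = c(p10 = 10))
glance(run$tables$p10)
tidy(run$tables$p10)
autoplot(bind_rows(
  batch_presence_curve(run$tables$p10, "peptide", include_transfers = FALSE),
  batch_presence_curve(run$tables$p10, "peptide", include_transfers = TRUE)
) |> structure(class = c("presence_curve", "tbl_df", "tbl", "data.frame")))
```

Masking evaluation across the full ladder:

```{r}
run_masking(d$psms, spectra = d$spectra, fraction = 0.1, seed = 2) |>
  select(threshold_label, n_masked, n_correct, precision, recall, fdr)
```

## Known limitations

* The built-in p-value model is a stand-in with the right semantics
  (a $-\log_{10} p$ ladder under complete linkage), not a reimplementation
  of any particular published clusterer; absolute cluster memberships will
  differ. Import external assignments where fidelity matters.
* Localization flags are rendered for phosphorylation with the `p` prefix;
  other variable modifications use a generic `mod` prefix.
* Protein-level reporting uses the leading protein of the group; razor
  logic is out of scope.
* Site-level localization scoring of transferred PTM peptides is out of
  scope; class (f) transfers deliberately report all candidate sites.
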