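---
title: "Methods: customized splice-variant databases, ortholog peptide mapping, and isobaric quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: customized splice-variant databases, ortholog peptide mapping, and isobaric quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthosplice)
```

## The problem

Standard shotgun-proteomics searches match MS/MS spectra against a canonical
protein database, so peptides arising from noncanonical alternatively
spliced (AS) proteoforms go unidentified. `orthosplice` implements a
proteogenomic workflow around this gap:

1. **Customized database construction** — select protein-coding transcripts
   whose translation differs from every canonical sequence, discard
   candidate targets of nonsense-mediated decay (NMD), digest the surviving
   proteoforms in silico with trypsin, and append to the canonical proteome
   only those peptides that occur in no canonical sequence.
2. **Cross-species ortholog mapping** — resolve identified database entries
   to genes (UniProt idmapping), join genes across two species (NCBI
   `gene_orthologs`), and report peptides with identical sequences
   identified in both species on orthologous genes, with proteotypicity
   flags and UpSet-style intersection counts over species/tissue groups.
3. **Quantitative statistics** — isobaric (iTRAQ) reporter extraction and
   channel normalization, a paired log2-ratio one-sample t-test per
   peptide, transcripts-per-million (TPM), and qPCR relative expression by
   the 2^-ddCt method with a two-sample t-test.

## Models and conventions

### Coordinates and transcript models

All internal coordinates are 0-based half-open; GTF input/output converts
at the boundary (1-based inclusive), the standard genomics convention.
Exons are stored in transcription order, so transcript-relative positions
are strand-free downstream; on the minus strand the exon list descends in
genomic coordinates. The transcript-relative coding interval *includes the
stop codon*: `cds_end` is the exclusive end of the stop. `classify_nmd()`
can instead locate the first in-frame stop from the CDS nucleotide
sequence, which positions premature stops inside an annotated ORF
correctly; a CDS with no stop codon is kept but flagged and never treated
as an NMD candidate.

### The NMD rule

The workflow delegates NMD detection to the canonical 50-nt rule: a
transcript is a candidate when its stop codon ends more than
`junction_distance_threshold` (default 50 nt) upstream of the last
exon–exon junction. Single-exon transcripts are never candidates, since no
junction exists. The threshold is configurable because published
classifiers vary between 50 and 55 nt; 50 nt is the value used throughout
and in all tests. The rule is monotone by construction: moving a stop
strictly closer to the final junction can only change `nmd_candidate` to
`not_nmd`.

### Trypsin digestion

Cleavage occurs after K or R, and (with the default proline rule) not when
the next residue is proline. All peptides with 0..`max_missed_cleavages`
internal uncut sites are emitted and then filtered to the
`min_peptide_length`..`max_peptide_length` window. Defaults: 2 missed
cleavages, mirroring typical database-search settings, and 6–45 aa, the
practically MS-observable range. For a protein with *f* zero-missed
fragments the emitted count (length filter disabled) is exactly
$\sum_{m=0}^{M} \max(0, f - m)$, and the suite verifies the enumeration
against an independent brute-force oracle that scans boundary-position
pairs.

### Exclusivity

A peptide is *exclusive* when it is not a substring of any whole canonical
protein sequence — deliberately stricter than mere absence from the
canonical tryptic peptide set. I and L are distinct by default; a
`collapse_IL` flag treats them as identical (they are isobaric in MS).
Peptides containing `X` (from `N`-containing codons) are discarded before
the exclusivity filter. All serialized sets are ordered lexicographically
so outputs are byte-deterministic.

### Custom database and header grammar

The database holds the canonical entries plus one entry per exclusive
peptide. Peptide entries carry parent proteoform ids, gene ids, and
offsets in a stable header grammar
(`pep|<id>|parents:...|genes:...|offsets:...|taxon:<t>`) that
`read_custom_db()` parses back; the FASTA round trip reproduces the
serialized entries. The full noncanonical parent proteoform sequences are
kept in memory for proteotypicity checks but are not part of the FASTA —
the shipped database contains canonical sequences and exclusive peptides
only. After a round trip, `is_proteotypic()` falls back to peptide entries
grouped by parent, which is equivalent for peptides that are themselves
entries.

### Ortholog peptide mapping

`index_identifications()` resolves canonical accessions through the
UniProt idmapping table (`GeneID` rows; the id type is configurable because
upstream tooling does not pin it) and peptide entries through their
header-encoded genes. Unresolvable accessions are logged and skipped, but
more than 50% unresolved aborts — that pattern indicates a mismatched
idmapping file rather than sporadic gaps. One-to-many ortholog relations
are all retained, as the NCBI file is many-to-many and the workflow
prescribes no collapse. A shared peptide mapping to multiple genes within a
species is kept in the index but only reported as an orthologous hit when
proteotypic in both species — the stricter of the two defensible readings,
with the raw intersections reported separately by `intersection_report()`.

### Isobaric quantitation

Reporter peaks are matched within 100 ppm of the channel m/z (most intense
peak wins) and zeroed below 2.5% of the spectrum base peak; the threshold
is interpreted as a fraction of the base-peak intensity, since no unit is
standard, and both knobs are configurable. Channel normalization equalizes
each channel's summed intensity over all identified spectra (grand mean as
the common target). The absolute scale of the output therefore depends on
all channels jointly, but every downstream quantity — per-spectrum
cross-channel ratios and hence all test statistics — is invariant to
rescaling any single channel's raw data.

The per-peptide statistic treats the two channels of each MS2 spectrum as
paired: ratio = case/control (positive log2 means more abundant in the
disease-model channel), log2-transformed, then mean, SD (n−1 denominator),
SEM = SD/√n, t = mean/SEM with df = n−1, two-sided p from the Student t
distribution. With one usable spectrum or zero variance the row is flagged
`degenerate` with p = 1 when the mean is 0 and p = 0 otherwise — this
keeps the result table total while marking unreliable rows. No
multiple-testing correction is applied by default (a raw 5% level is the
convention here); Benjamini–Hochberg is available via `adjust = "BH"`.

TPM is $\mathrm{tpm}_i = (c_i/l_i) / \sum_j (c_j/l_j) \times 10^6$, with
all-zero counts mapping to all-zero TPM; an FPKM column is included in the
report for reference only. The 2^-ddCt computation assumes 100%
amplification efficiency, normalizes to a reference gene per sample, and
anchors to a calibrator sample whose relative quantity is 1 by
construction. Group comparisons use the Welch two-sample t-test by default
(no equal-variance assumption); a pooled-variance variant is available.

## The synthetic fixture

`generate_fixture()` emulates every external input at toy scale so the
whole pipeline is testable without downloads: two species with orthologous
genes, a canonical transcript plus AS variants per gene, canonical
proteomes with UniProt-style headers, idmapping and `gene_orthologs`
tables (including decoy rows of other id types and relationships),
identification tables for two tissue labels (CC and OB, after the brain
regions that motivated the workflow), an iTRAQ reporter table, and a qPCR
Ct table. All randomness flows from a single seed; identical seed and spec
give byte-identical files.

Design choices that the generator fixes once:

* **Proteins are built from exon blocks at the amino-acid level** and
  back-translated with one deterministic codon per residue. Each AS
  variant edits the block structure (skip an internal block, replace the
  last block, or swap in a mutually exclusive block), which guarantees a
  junction-spanning or variant-exclusive tryptic peptide per surviving
  variant.
* **Cross-species identical peptides** are planted through a shared
  mutually-exclusive-exon cassette (K + 9-residue tag + R, tag drawn from
  an alphabet without K/R/P). An exon-skip junction peptide cannot be made
  identical across species without also sharing flanking sequence, so
  genes selected for orthology planting use the MXE event.
* **NMD candidates** append an extra 3'UTR exon so the stop sits 80 nt
  upstream of the final junction — unambiguously beyond the 50-nt
  threshold. NMD labels are assigned only to variants that do not carry a
  planted peptide; a spec demanding more NMD variants than are available
  errors out rather than silently degrading.
* **The iTRAQ table** plants sign-balanced differential peptides (half at
  +lfc, half at −lfc, default lfc 1.0, noise SD 0.3, 8 spectra/peptide)
  among null peptides (60 by default), mirroring the assumption behind
  sum-equalizing normalization that most peptides are unchanged. Defaults:
  10 genes, 1 variant per gene, 20% NMD, 50% orthology planting — small
  enough for seconds-scale tests, large enough that every code path is
  exercised.

`audit_fixture()` re-derives all ground-truth labels with independent
straightforward code — a plain codon-loop translation, a boundary-scan
digestion enumerator, and brute-force substring checks — and fails naming
the affected transcript or peptide on any mismatch.

What the fixture does *not* emulate: real spectra and search-engine
scoring (identification tables are taken as given, as the search itself is
out of scope), sequence homology between the two species outside the
planted cassettes, shared exons between isoforms at the genomic level
(each transcript is laid out in its own window), isotope impurity between
reporter channels, and realistic transcript-length or abundance
distributions. Passing tests therefore demonstrate the correctness of the
algorithms under the stated model, not search-engine-level performance on
real data.

## Numerical choices and degenerate inputs

* Ties in reporter matching resolve to the most intense peak in-window.
* `filter_exclusive()` tests substring containment against a single
  separator-joined canonical blob (`|` is outside the amino-acid
  alphabet), which is exactly equivalent to per-sequence checks.
* Deterministic ordering (lexicographic by sequence, then id) everywhere a
  set is serialized; peptide entry ids are assigned in lexicographic
  sequence order, so identification tables can reference them stably.
* Zero-count TPM, zero-variance t-tests, empty ortholog tables, and empty
  exclusive sets all return well-defined results rather than erroring;
  genuinely unusable inputs (no usable spectra, nonpositive lengths,
  missing reference Ct) raise informative errors.
* Problem sizes used by the test suite and acceptance script: 1,000 random
  proteins (length ≤ 200) for the digestion oracle, 1,000 random sets for
  exclusivity, an exhaustive stop-position grid for the NMD truth table,
  100 random systems for joins/intersections, the default 10-gene fixture
  for end-to-end recovery, and 200 replicates of 5 + 5 peptides for the
  power study. These sizes give stable results in well under a minute per
  property.

## The command-line interface

A thin `Rscript` wrapper at `inst/cli/orthosplice.R` exposes
`make-fixture`, `build-db`, `orthomap`, `quant itraq|tpm|ddct`, and `run`
(the YAML-configured full pipeline, also available as `run_pipeline()`).
The pipeline validates all inputs before any stage executes, removes a
failing stage's partial outputs, and writes a manifest with input/output
checksums and row counts. Outputs are byte-identical across reruns with
the same configuration and inputs; the manifest's timestamps are the one
intentional exception.

## Known limitations

* Exclusivity is species-internal: a peptide exclusive in one species may
  occur in the other species' canonical proteome; the cross-species step
  only requires identity of identified sequences on orthologous genes.
* The one-sample t-test treats spectra as independent replicates; repeated
  measurements of the same precursor violate this mildly, as they do in
  the upstream tooling this mirrors.
* Semi-tryptic peptides and post-translational modifications are not
  modeled; the digest is fully tryptic.
* `2^-ddCt` assumes perfect doubling per cycle; efficiency calibration is
  out of scope.

## A worked example

```{r example, eval = FALSE}
d <- tempfile()
generate_fixture(fixture_spec(seed = 1), d)
audit_fixture(d)

res <- build_splice_db(
  load_gtf(file.path(d, "species_a.gtf")),
  load_fasta(file.path(d, "species_a_cds.fasta")),
  load_canonical_proteome(file.path(d, "species_a_canonical.fasta")),
  taxon = 9606)
res$db
#> <custom_db> taxon 9606: 10 canonical entries + 69 exclusive peptide entries

rec <- data.frame(spectrum_id = 1:3, peptide = "P",
                  `117` = c(100, 100, 100),
                  `118` = 100 * 2^c(1.0, 1.2, 0.8), check.names = FALSE)
peptide_ratio_test(rec)[, c("mean_log2_ratio", "t_statistic",
                            "degrees_of_freedom", "p_value")]
#>   mean_log2_ratio t_statistic degrees_of_freedom    p_value
#> 1               1    8.660254                  2 0.01307216
```
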