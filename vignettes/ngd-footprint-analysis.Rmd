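---
title: "Size-resolved footprint analysis of No-Go mRNA Decay"
author: "NGDprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Size-resolved footprint analysis of No-Go mRNA Decay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NGDprofiler)
```

# The model

When a yeast ribosome stalls irreversibly — for example on a run of CGA
codons decoded by a rare tRNA — trailing ribosomes collide with it, and the
collided state recruits an endonuclease (Cue2) that cleaves the mRNA in the
collided ribosome's A site. No-Go Decay (NGD) is this surveillance pathway.
Ribosome profiling resolves its anatomy because footprint *length* reports
ribosome *state*:

* **21-nt class** (20–22 nt): the stalled lead ribosome with an empty A
  site, waiting for a slow tRNA. Its A-site codon start is inferred from
  the 5′ end via length-dependent offsets 20:16, 21:17, 22:17.
* **28-nt class** (27–32 nt): ribosomes with occupied A sites, including
  collided ribosomes stacked behind the lead; offsets 27:16, 28:16, 29:17,
  30:17, 31:17, 32:17.
* **16-nt class** (15–17 nt): the 5′-side product of endonucleolytic
  cleavage. These fragments have no meaningful A-site offset; their **3′
  ends** mark the cut point directly.
* **Disome classes** (44–62 nt): nuclease-resistant footprints of stacked
  ribosome pairs; 60-class (57–62) and 54-class (51–54) map the lead
  ribosome's A site at offset 47, the 46-class (44–48) 3′ ends mark cuts.
* **In vitro class** (60–65 nt): fragments produced by the purified SMR
  endonuclease domain acting on collided ribosomes in vitro; 3′ ends mark
  its cut sites.

Monosome lengths 18–19 and 23–26 nt fall between classes and are left
unclassified; no interpolation is attempted.

Two geometric facts anchor everything. A collided ribosome's A site sits
**30 nt upstream** of its lead's (A-site to A-site distance of stacked
ribosomes), and the cleavage occurs **within the collided ribosome's A
site**. The package places the cut at the 5′ boundary of that codon, which
makes the spacing statistics integer-exact; a sub-codon shift is
configurable (`cutOffset`). All coordinates are 0-based half-open; a cut
point is the first nucleotide beyond the protected fragment, so "cleavage
before position x" is single-valued. 1-based coordinates appear only in
GFF3 and SAM output.

# The reporter

`buildReporter()` assembles the GFP–2A–FLAG–HIS3 reporter: GFP is released
by the 2A self-cleaving peptide before the ribosome reaches the stall, so
GFP fluorescence reports mRNA abundance rather than protein-level
surveillance. The stall insert — (CGA)×12 for NGD-CGA, (AAA)×12 for
NGD-AAA — is placed after 90 HIS3 codons. An RFP control transcript
(`buildControlTranscript()`) provides the internal normalization target.

The true plasmid sequences are not redistributed. The package generates
deterministic stand-in coding sequences of realistic lengths (GFP 717 nt,
2A 60 nt, FLAG 24 nt, HIS3 660 nt) from a fixed seed, constrained to have
no internal stops, no in-frame CGA codons, no CGACGA hexamers and no
A-runs longer than 3 nt outside the insert. Every analysis in scope
depends on reporter *geometry* (where the stall is, how far windows
reach), not on the true nucleotide sequence; the constraints make peak
positions, unique alignment and untemplated-A calls unambiguous on the
stand-in.

# The synthetic libraries

`simulateNgdLibrary()` is the package's stated world: it emits raw reads
with the library's exact adapter/UMI layout
(`[4 random nt][footprint][6 random nt][CACTCGGGCACCAAGGA…]`, truncated at
the sequencing read length) so that the trimming and alignment code paths
run end to end. Defaults:

* Lead-ribosome A sites on stall codons 2–5 of the (CGA)×12 tract,
  uniformly weighted — the observed "quadruplet" structure.
* Collided 28-class A sites exactly 30 nt upstream of a sampled lead
  site; 16-class cut points at the collided A-site codon's 5′ boundary.
* Genotype presets (`scenarioPreset()`) encode the qualitative class
  mixtures: the endonuclease deletion (`cue2 dom34 ski2`) sets the
  16-class weight to zero while leaving the 21/28-class geometry
  untouched; the helicase deletion (`slh1 dom34 ski2`) raises it.
* Uniform background at 1 read/nt of CDS over all transcripts including
  RFP, drawn from the 5′-offset classes (background is elongation, not
  cleavage).
* Per-base mismatch rate 0.001; errors are never applied to untemplated
  A tails, so poly(A) ground truth stays exact.
* Sequencing read length 51 nt (the raw libraries' length is not
  documented; it is configurable, and disome simulations default to
  100 nt because 4 + 44 + 6 nt of a disome read already exceed 51 nt,
  leaving no adapter to find).

What the generator does **not** model: ligation and PCR bias, rRNA
contamination composition, nuclease sequence preference, or sub-codon
heterogeneity of cut positions. A green round-trip test therefore
establishes that the *inference* is a correct inverse of the stated
geometry — not that the geometry exhausts real libraries.

`simulatePolyAReads()` emulates footprints of ribosomes that translated
into a premature poly(A) tail: the templated portion ends at the
polyadenylation junction and the read continues with untemplated A's.
`simulateCalibrationLibrary()` produces the start-codon metagene fixture
for offset calibration: an initiation-proximal population with AUG in the
P site (30% of reads) over uniform elongation background.

# Read processing

`trimReads()` finds the constant adapter by leftmost match with at most
one mismatch, accepting matches truncated by the read end down to a 5-nt
overlap, then strips the 6-nt UMI block before it and the 4 leading
random nucleotides. `alignFootprints()` performs ungapped all-positions
search against the small transcriptome (the original study aligned
genome-wide with a spliced aligner; re-implementing one is out of scope
and unnecessary for the method's logic — externally aligned SAM/BAM
enters through `readSam()`, which reconstructs untemplated tails from 3′
soft clips that are entirely A).

Untemplated-A semantics follow maximal templated extension: the candidate
tail is the maximal trailing run of read A's that *disagree* with the
reference; an A that matches the reference is templated. The tail is
honoured only when the templated prefix covers ≥ 15 nt; otherwise
trailing disagreements count as ordinary mismatches. Placements must keep
mismatches ≤ 10% of the templated length; more than one best-scoring
placement means the read is discarded as multimapped. One documented
consequence: when the reference itself continues with A's at a poly(A)
junction, leading tail A's become templated and the untemplated count is
deflated — the stand-in reference avoids A-runs so simulated truth is
exact, and on real data this behaviour is documented rather than guessed.

Every input read is accounted for exactly once across kept / no_adapter /
too_short / too_long / contaminant / unaligned / multimapped; the
conservation is asserted in the test suite and recorded in pipeline
manifests. UMI deduplication exists (`dedupUmis()`) but is off by
default: the library protocol describes random nucleotides, not a
deduplication step.

# Offset calibration

`calibrateOffsets()` anchors on start codons: for each read length it
builds the metagene histogram of 5′ ends in a window of [−40, +20) nt
around annotated CDS starts and takes the modal position. The dominant
initiation-proximal species is taken to have AUG in the P site, hence its
A site at `start + 3`, giving `offset = (start + 3) − modal 5′ end`. Ties
resolve to the smaller offset with a warning; lengths with fewer than 100
in-window reads fall back to the default table with a warning. The
package's generator inverts exactly this rule, and the calibration
round-trip (27–32 nt → 16/16/17/17/17/17; 20–22 nt → 16/17/17) is an
acceptance criterion.

# Peaks, spacing, occupancy, concordance

`callPeaks()` marks positions that are local maxima within ±1 nt carrying
at least 5% of the track and at least 5 calls — repository defaults
(configurable), since the source figures display tracks without a stated
peak rule; they are robust on quadruplet fixtures across seeds.
`peakSpacing()` weights each upstream/downstream peak pair by the smaller
count and reports the modal lag; under the stated geometry both the
16-vs-21 and 28-vs-21 comparisons give exactly 30 nt.

`windowedOccupancy()` computes combined 21+28-class density over the
reporter window (canonically `stallWindow(construct, 300)`: 300 nt
upstream of the insert through its end) divided by the same density over
the RFP CDS. Normalization is per-nucleotide density, not total counts —
the alternative reading of "normalized to RFP" — because it is invariant
to window and CDS length; the choice only rescales all samples jointly.

`cutSiteConcordance()` reports the fraction of the in vitro cut-point
track's weight within ±1 nt of an occupied in vivo cut position
(`minCount` ≥ 1 by default; raise it on noisy tracks). Defining anchors
by occupancy rather than by called peaks makes identical distributions
score exactly 1 and an 80:20 signal:background mixture score ≈ 0.8.

# Premature poly(A) and endonuclease-target calling

`flagPrematurePolyA()` applies the published thresholds literally: a gene
is flagged when *every* required replicate has ≥ 3 monosome-size
footprints (15–34 nt including the tail) carrying more than one
untemplated A. `shortLongRatio()` is `(n15–17 + 1) / (n20–32 + 1)`.

`callCue2Targets()` is a documented stand-in for the differential-count
package the original analysis delegated to, built from its published
components: median-of-ratios size factors; per-condition method-of-moments
dispersions (estimating within conditions avoids inflating the dispersion
of genes with true fold changes), df-weighted and shrunk in log space
toward a fitted mean–dispersion trend (prior worth 4 observations — at two
replicates per condition the gene-wise estimate carries 2 df, so the trend
dominates 2:1); per-group abundance by the moment estimator
`sum(counts)/sum(size factors)`; a Wald test using the negative-binomial
Fisher information; Benjamini–Hochberg adjustment; targets are genes with
adjusted p < 0.005 and reduced counts in the deletion. Genes with zero
counts everywhere are excluded rather than assigned p = 1, to avoid
diluting the adjustment. "Reproducible reduction" is operationalized as
the pooled test; `strict = TRUE` additionally requires every deletion
replicate below every control replicate. The test suite cross-checks the
stand-in against DESeq2 on a spiked fixture (fold-change correlation and
call agreement) and verifies type-I control and 18/20-at-8-fold power on
simulated counts.

# Screen scoring

`screenPipeline()` reproduces the reporter-SGA analysis: border strains
and colony-size outliers (< 1500 or > 6000 px, boundaries kept) are
removed; surviving replicate colonies aggregate to per-strain median GFP
and RFP (the protocol names both median and mean; median is the robust
default, mean is selectable); log2(GFP/RFP) is LOESS-normalized per plate
sequentially against column then row position (the protocol says only
"per plate"; plate artifacts are spatial, and the covariate is
configurable); Z-scores standardize each plate with the sample standard
deviation (population vs sample is not documented; at ≥ 300 strains the
difference is negligible — note the two-point standardization example in
the tests reflects the sample-sd convention). A hit has |Z| > 2.5
(strict) on a stall reporter and Z strictly inside (−2.5, 2.5) on the
matched OPT reporter.

`simulatePlatePair()` states the screen's world: 32 × 48 plates, 2 × 2
colony blocks per strain, an outermost border-block ring, strain effects
shared between the NGD and OPT plates (it is the same strain on both),
log-normal colony noise, smooth per-channel spatial gradients, and spiked
hits that shift GFP on the NGD plate only, scaled in units of the
strain-level sd of log2(GFP/RFP). With 10 spikes at 6 sd among ~300
strains the spikes inflate the plate sd, which is precisely what makes
null strains rare beyond |Z| = 2.5 and gives the pipeline ≥ 0.95
precision and recall across seeds.

# Numerical choices and degenerate inputs

* Modal ties (calibration, spacing) resolve to the smaller offset/lag
  with a warning, never silently.
* Peak calling on an all-zero track returns an empty set; spacing on an
  empty peak set is an error (there is nothing to compare).
* `windowedOccupancy()` errors on a zero control denominator rather than
  returning Inf.
* Plates with fewer than 10 strains skip LOESS (median-centring instead,
  with a warning); a zero plate sd is an error.
* A group with zero total counts in the target caller uses a half-count
  continuity floor for the fold change rather than ±Inf.
* Library generation, plate generation and the pipeline runner are
  deterministic given their seeds; manifests record seeds and versions.

# Known limitations

* The ungapped aligner targets desk-scale synthetic references; real
  genome-scale libraries should be aligned externally and imported as
  SAM/BAM (forward-strand, transcriptome-coordinate).
* The published deposited libraries are deliberately not fetched
  or re-analyzed here; the corresponding figure-level quantities that
  depend on them (the > 2-fold occupancy change and the 21/55 overlap)
  are exercised on simulated ground truth instead.
* The NB target caller is a stand-in with conservative, trend-anchored
  dispersions; it is validated against DESeq2 in the tests, not a drop-in
  replacement for it.
* The 2A peptide's biochemistry, plasmid features, and protein-level
  outputs are out of scope; the reporter model is an mRNA-coordinate
  object.

# A worked run

```{r pipeline, eval = FALSE}
res <- runPipeline(list(outdir = "ngd_run", seed = 1,
                        scenario = scenarioConfig(nReads = 50000),
                        stages = c("simulate", "align", "tracks", "ngd")))
res$spacing$cut_vs_lead$modal_spacing        # 30
res$spacing$collided_vs_lead$modal_spacing   # 30
```
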