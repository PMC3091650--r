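---
title: "Models and methods behind AluEdit"
author: "AluEdit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind AluEdit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AluEdit)
```

# Scope

`AluEdit` quantifies how the secondary-structure micro-environment, the
local sequence context and the thermodynamic stability of an adenosine in
an Alu-derived RNA duplex relate to its probability of A-to-I editing. The
package covers the whole chain from raw alignment mismatches to stratified
statistics, and ships a seeded generator that produces every input with a
known ground-truth editing model. This vignette records the models, the
parameters that matter, the numerical conventions and the design choices
that were genuinely open.

# Site calling

Input is a mismatch table (one row per RNA-to-genome alignment mismatch,
plus-strand reference bases, 0-based positions). The calling chain is

1. remove records overlapping known SNPs (`filterSNPs`);
2. keep records inside Alu intervals and re-express the mismatch type on
   the Alu strand (`intersectAlus`) — a T→C record inside a minus-strand
   Alu is an A→G edit on that Alu;
3. within each RNA, order mismatches along the transcript and call every
   maximal run of identical mismatch types of length ≥ `minCluster`
   (default 3) as editing sites (`callEditingClusters`); positions are
   unioned across RNAs;
4. emit every Alu-strand adenosine of each Alu that received at least one
   A→G call, labelled E1 (called) or E0 (control) (`assembleSiteSets`).

The cluster rule reflects ADAR hyper-editing: a single engaged duplex is
edited at many adenosines, so genuine sites co-occur on a read while
one-off mismatches (sequencing errors, unannotated variation) do not. We
interpret "consecutive" in transcript order of one alignment with no
genomic-distance cap; the fraction of called mismatches that are A→G is
reported as a QC metric, not enforced as a filter. The E0/E1 universe is
restricted to Alus with at least one call, because the folded
neighborhoods from which structure is read are constructed around edited
Alus; partner Alus without calls of their own have no structure frame in
their orientation.

# Neighborhoods

For an edited Alu, the nearest antisense Alu (edge-to-edge gap;
equidistant ties broken downstream) defines the duplex partner. The
neighborhood spans both Alus, everything between them and 200 extra
nucleotides per side, on the edited Alu's strand; same-strand
neighborhoods overlapping by strictly more than 400 bp are merged
transitively. Merging is order-independent and every assembled site falls
in exactly one merged neighborhood (both are tested properties).

# Substructure classification

A secondary structure is held as a `PairingTable`: sequence plus a
symmetric, non-crossing partner map (pseudoknots are rejected — MFOLD-type
folders never emit them). `classifySubstructures` partitions all
nucleotides into six element kinds:

* **helix** — maximal stacks of base pairs (G·T wobbles included); size in
  stacked pairs;
* **hairpin / interior / bulge / junction** — the unpaired strands of
  loops closed by one pair, two pairs (unpaired on both sides / exactly
  one side), or three and more pairs; loop elements contain only their
  unpaired strands, never the closing pairs;
* **strand** — exterior unpaired runs, dangling ends included, one element
  per maximal run.

Per-site context derives from this partition: `cePos` is the distance to
the closest edge of the site's own strand (0 = at the edge); for helix
sites it is counted in base-pair steps from the nearest helix terminus —
the paper-style phrasing "distance in nucleotides" gives no helix-specific
rule, and bp-steps make an 11-bp helix midpoint sit at cePos 5 and a 17-bp
helix Q/R-like site at cePos 5, the natural metric for stack depth. Loop
`cePos` is measured within the site's own strand, not across the whole
loop. The opposite nucleotide (`opNuc`) is the pairing partner for helix
sites; for interior-loop sites at the loop edge, the most 5' base of one
strand opposes the most 3' base of the other (and vice versa); a site
alone on its strand facing a longer strand has an `undefined` opposite;
everything else is `n/a`. Sequence neighbours up to `kMax = 30` per side
are read off the primary sequence regardless of element boundaries, with
`NA` outside the record.

The classifier is verified two ways: against hand-worked examples, and
exhaustively against an independently written brute-force
loop-decomposition oracle on every valid dot-bracket string up to 12 nt
(minimum hairpin 3, the MFOLD convention) — 538 structures, position by
position.

# Context statistics

Editing frequencies are reported per stratum with Wilson 95% score
intervals (the score interval behaves well at the small per-bin counts
that length and cePos tails produce; coverage is checked by simulation).
The **enrichment factor** of a context is its editing frequency divided by
the mean frequency of all sites of the stratum eligible for the table
(feature defined). Because the baseline is the site-share weighted mean,
enrichment factors average to 1 by construction, and
`freq / enrichment` is one shared constant per table — the package exposes
that baseline as a computed attribute rather than hard-coding any value.
Neighbour composition at offsets ±1..±30 is compared between E1 and E0
with the Pearson statistic on the 2×4 table (df = 3, no continuity
correction, zero-expectation cells contribute nothing, expected counts
below 5 flag the row). Two-proportion comparisons use the pooled-variance
z-test (equivalently the 2×2 Pearson chi-square without continuity
correction), Bonferroni correction is `min(1, p·m)`.

# Boltzmann ensemble and structural entropy

The fold ensemble of a neighborhood is the discrete list of structures
supplied to the package — exactly those folds, no re-enumeration, mirroring
an MFOLD suboptimal-folding run. Weights are

$$P_n = \frac{e^{-G_n/RT}}{\sum_m e^{-G_m/RT}}$$

with the gas constant R = 1.98717×10⁻³ kcal·mol⁻¹·K⁻¹ and T = 310.15 K by
default (37 °C, MFOLD's default folding temperature; energies are molar, so
R realises the Boltzmann constant). The computation max-shifts energies, so
adding any constant to all G_n changes nothing. Per site,
`p_i^s = Σ_n P_n · [site i is in kind s under fold n]` and the structural
entropy is `H_i = −Σ_s p_i^s ln p_i^s` (natural log, 0·ln 0 ≡ 0), ranging
from 0 (always the same substructure) through ln 2 ≈ 0.693 (an even
two-state split) to ln 6. The ground state is the minimum-energy fold,
ties broken toward the first structure listed (folders emit best-first).
Frequency-vs-entropy profiles bin sites per ground-state stratum into
equal-count bins; duplicate quantile edges are collapsed, so the common
mass of exactly-zero-entropy sites forms a single bin and strata with too
little spread are emitted unbinned with a flag.

# The synthetic-data generator

`aluEditConfig()` fixes the study conditions; the seed fully determines
every output. The generator emulates:

* **Genome** — one chromosome of random background with `nAluPairs`
  planted sense/antisense pairs of a fixed packaged 280-nt Alu-like
  consensus. Each copy diverges by 8% substitutions and 1.2% single-base
  indels (typical Alu-copy divergence; this sets the interior-loop and
  bulge density of the duplex). Intra-pair gaps are drawn from bins
  <1000 / 1000–2000 / 2000–3000 / 3000–6800 nt with weights
  0.61 / 0.22 / 0.09 / 0.08. Consecutive pairs are separated by 8000 nt so
  that each Alu's nearest antisense Alu is always its planted partner and
  neighborhoods of different pairs never merge — one pair, one duplex.
  Known-SNP positions are sprinkled at 5×10⁻⁴ per bp.
* **Fold ensembles** — the ground fold pairs the two Alu copies through
  their common consensus alignment (Watson-Crick plus G·T wobble);
  mismatched positions become interior loops, indels become bulges, the
  intervening sequence a terminal loop, flanks exterior strands.
  `nFolds − 1 = 5` alternatives each open 15% of the duplex pairs in
  windows of 2–6; their energies sit Uniform(0.3, 1.8) kcal/mol above the
  ground state, giving individual alternative weights of roughly 0.05–0.3
  and per-site entropies spread over 0–0.7 for about half of the duplex
  sites. Both neighborhood orientations are emitted (the antisense Alu is
  analysed on the mirrored structure). Energies are set by inverting the
  Boltzmann formula from target gaps, not by a physical energy model — the
  analysis consumes only weights.
* **Editing** — each Alu-strand adenosine is edited with probability
  `baseline(kind) · eff(up1) · eff(dn1) · eff(opNuc) · eff(cePos)^cePos ·
  boost(symmetric loop) · e^{−λH}`, clipped to [0, 0.95]. Defaults:
  baselines 0.044 (helix), 0.091 (interior), 0.031/0.032/0.024/0.020
  (bulge/hairpin/junction/strand); up1 T×2.2, G×0.32; dn1 G×1.5; opNuc
  C×3.5; λ = 1; cePos and symmetric-loop effects off. A multiplicative
  relative-risk model is used because the analysis reports ratio-style
  enrichments, making the multipliers the natural recoverable target.
* **Reads and noise** — edits of one Alu are emitted together on its
  simulated reads (2 per Alu), each read reporting each edited site with
  probability `sensitivity` (default 0.9), plus Poisson decoy non-editing
  mismatches (mean 0.5/read) and SNP-overlapping mismatches (mean
  0.3/read). Alus whose draw yields only one or two edited adenosines are
  re-labelled unedited: such sites could never satisfy the ≥3-cluster rule,
  and keeping them in the truth would make exact noise-free recovery
  impossible by construction rather than by analysis error. "Noise off"
  means sensitivity 1 and zero decoy, SNP-mismatch and SNP rates — note
  that with SNPs planted, a true site colliding with a known SNP is
  correctly (and irrecoverably) removed by the SNP filter.

## What passing tests do and do not show

The generator produces near-ideal duplexes: no transcription-unit
boundaries, no overlapping or nested repeats, no alignment error, uniform
background composition, binary editing labels, and fold ensembles that are
perturbations of a known ground state rather than genuine thermodynamic
re-folds. Parameter recovery on this data demonstrates that the analysis
chain measures what it claims to measure — it does not validate MFOLD's
structure predictions nor guarantee the same power on real UCSC-scale
data, where structure error and coverage bias add noise the generator does
not model.

Two quantitative consequences matter when reading recovery results.
First, the expected enrichment factor of a boosted context is *not* the
raw multiplier: the stratum baseline already contains the boosted sites,
so a ×2.2 up1=T effect implies an enrichment of about 1.85 at uniform base
composition. Recovery is therefore checked against the model-implied
enrichment computed from the generator's own per-site probabilities.
Second, conditioning the site universe on Alus with ≥3 detected edits
selects Alus with upward-fluctuating realisations, inflating absolute
frequencies in both strata by ~10% alike; stratum *contrasts* (e.g.
interior/helix) are the stable recoverable quantities, which is also why
observed frequencies should be read as relative measures.

# Problem sizes and numerical choices

The full-scale recovery experiment uses 368 Alu pairs (~50,000 Alu-strand
adenosines, matching the intended study scale), runs the entire pipeline
in a few minutes on one core, and checks the up1=T and opNuc=C enrichment
recovery and the interior/helix contrast to within 10% of the
model-implied truth, plus a strictly decreasing editing frequency across
4 equal-count entropy bins for ground-state helix sites (few wide bins
keep the per-bin intervals comparable; the zero-entropy mass occupies the
first bin). Unit and property tests use 2–10 pairs. Other conventions:
probabilities are validated to sum to 1 within 1e-6 before entropy is
taken; entropies below 1e-12 are clamped to 0; mismatch TSV and BED
interfaces are 0-based half-open on disk while interval work in memory
uses Bioconductor's 1-based `GRanges`; CT files are 1-based as the format
demands; T and U are identified on ingest.

# Known limitations

* Pseudoknots are rejected, not broken.
* No folding is performed; structures must be supplied (CT or
  dot-bracket) or simulated.
* Editing labels are binary; per-site editing levels are out of scope.
* Trans-chromosomal duplexes and Alu pairs spanning contig breaks are not
  handled.
* Multiple-testing support stops at Bonferroni.
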