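# AluEdit

Structural, sequence and thermodynamic analysis of A-to-I RNA editing in
Alu repeats.

## The problem

ADAR enzymes deaminate adenosine to inosine in double-stranded RNA; since
inosine is read as guanosine, editing shows up as A→G mismatches when RNA
sequences are aligned back to the genome. In the human transcriptome almost
all such editing falls inside Alu repeats: two nearby, oppositely oriented
Alu copies in one transcript base-pair into a long near-perfect duplex, the
ADAR substrate. Editing is highly selective, and the selectivity is only
partly explained by sequence motifs — the *micro-structure* around each
adenosine (helix vs interior loop, position within the element, the
structurally opposite base) and the thermodynamic stability of that
micro-structure matter too.

`AluEdit` implements the full analysis chain for quantifying these
determinants, for bioinformaticians studying RNA editing or RNA secondary
structure:

1. **Site calling** — mismatch tables from RNA-to-genome alignments are
   cleaned of known SNPs, intersected with Alu annotations (mismatch types
   re-expressed on the Alu strand) and filtered to clusters of ≥ 3
   consecutive identical mismatches per RNA; called adenosines form the E1
   set, all remaining Alu adenosines the E0 control set.
2. **Neighborhoods** — for each edited Alu, the nearest antisense Alu is
   found and the window spanning both plus 200 nt flanks is built;
   same-strand windows overlapping by > 400 bp are merged.
3. **Structure model** — MFOLD-style CT ensembles (or dot-bracket input)
   are parsed into validated pairing tables and every nucleotide is
   classified into one of six substructure kinds `S = {helix, interior,
   bulge, hairpin, junction, strand}`; per-site context includes the
   closest-edge position (cePos, 0 = element edge; base-pair steps within
   helices), own/opposite strand lengths, the interior-loop asymmetry, and
   the opposite nucleotide (opNuc: the pairing partner in a helix, the
   cross-strand edge base for loop-edge sites).
4. **Context statistics** — stratified editing frequencies with Wilson 95%
   intervals, enrichment factors (context frequency ÷ stratum baseline),
   per-offset 2×4 Pearson chi-square tests of neighbour composition over
   ±30 nt, two-proportion z-tests and Bonferroni correction.
5. **Thermodynamic ensemble** — Boltzmann weights
   `P_n = exp(−G_n/RT)/Z` over the supplied suboptimal folds, per-site
   substructure probabilities `p_i^s = Σ_n P_n · χ_s(i, n)`, the structural
   entropy `H_i = −Σ_s p_i^s ln p_i^s ∈ [0, ln 6]`, and editing-frequency
   vs entropy profiles stratified by ground-state kind.
6. **Synthetic data** — a seeded generator plants Alu-like inverted-repeat
   pairs in a random genome, constructs duplex fold ensembles with
   controlled Boltzmann weights, and simulates editing from a known
   multiplicative model (baseline(kind) × up1 × dn1 × opNuc effects ×
   e^{−λH}), so every stage of the pipeline is testable end to end with
   ground truth.

## Worked example

```r
library(AluEdit)

# simulate a small study: 8 Alu pairs, noise-free detection
cfg <- aluEditConfig(seed = 23, nAluPairs = 8, sensitivity = 1,
                     decoyMean = 0, snpNoiseMean = 0, snpRate = 0)
ds  <- simulateAluDataset(cfg)
res <- runPipeline(aluPipelineConfig(ds$records, ds$gen$alus, ds$gen$snps,
                                     ds$gen$genome, ds$ensembles))
res$freqByKind
```

```
      kind nSites nE1       freq      ciLow     ciHigh
1    bulge      8   0 0.00000000 0.00000000 0.32440756
2    helix    829  50 0.06031363 0.04604661 0.07863673
3 interior    105  17 0.16190476 0.10361288 0.24406217
```

Interior-loop adenosines are edited at several times the helix frequency,
recovering the planted baseline contrast (0.091 vs 0.044, amplified by the
entropy and context effects and by conditioning on detectable Alus). The
structural entropy of an individual site is equally direct:

```r
structuralEntropy(c(0.5, 0.5, 0, 0, 0, 0))
#> [1] 0.6931472     # a site split between two substructures: ln 2
```

`res$enrichment$helix$up1`, `res$neighborChi2$interior`, `res$entropy` and
`res$tissue` hold the enrichment-factor, neighbour-composition,
frequency-vs-entropy and brain/non-brain tables; with `outDir` set, all of
them are written as TSV next to a JSON report.

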