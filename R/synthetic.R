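## Fixed packaged 280-nt Alu-like consensus. Any fixed string suffices for
## the simulation; per-copy divergence is applied on top of it.
ALU_CONSENSUS <- paste0(
  "GATCTAGCGATCCTTTGACCGATCGGTTATGTTGGTCCGTAGGATATTTTATACATTAGGAAGTCTCCGC",
  "GTGGATTTGGTTGCCCGACTATCCTTCGATGATGATTGGACATCTAGTGGAGGTTTCAGGTAACTTTTTA",
  "ACCTAGTAGGGAGTTGGTGTATGAAATAAGCTGCTCTTATTCGTGAAGACCCCCTAGCTAGCTATATCAC",
  "GTAAAGAGACAGCAGACGGGGCTAGGGCAAATCAGGGGCTTGCTGGTATCGACAATCTACGGCTGCGAGA")

#' Configuration of the synthetic Alu-editing dataset generator
#'
#' Bundles every tunable of the generator with its default. The seed
#' fully determines all outputs. Defaults encode the study conditions
#' the pipeline is meant to analyse: ~280-nt Alu-like repeats planted as
#' sense/antisense pairs, inter-Alu gap lengths drawn from bins
#' `<1000 / 1000-2000 / 2000-3000 / 3000-6800` with weights
#' `0.61 / 0.22 / 0.09 / 0.08`, per-substructure baseline editing
#' probabilities `helix 0.044, interior 0.091, bulge 0.031,
#' hairpin 0.032, junction 0.024, strand 0.020`, multiplicative
#' sequence-context effects (upstream T favoured, upstream G strongly
#' disfavoured, downstream G favoured, opposite C strongly favoured) and
#' an entropy-suppression factor `exp(-lambda * H)`.
#'
#' @param seed Integer seed.
#' @param nAluPairs Number of planted sense/antisense Alu pairs.
#' @param aluLength Consensus length used (<= 280).
#' @param gapWeights Probabilities of the four inter-Alu gap bins.
#' @param gapBreaks Bin edges of the gap distribution (nt).
#' @param interPairSpacer Background nucleotides between consecutive
#'   pairs; large enough that each Alu's nearest antisense Alu is its
#'   planted partner and neighborhoods of different pairs never merge.
#' @param flank Neighborhood flank (nt).
#' @param divergence Per-base substitution rate of each Alu copy
#'   relative to consensus (drives interior-loop density of the duplex).
#' @param indelRate Per-base insertion+deletion rate (drives bulges).
#' @param nFolds Structures per neighborhood ensemble (1 ground +
#'   alternatives).
#' @param energyGapRange Range (kcal/mol) of the uniform free-energy
#'   gaps assigned to alternative folds above the ground state.
#' @param perturbFrac Fraction of duplex base pairs opened (in windows
#'   of `perturbWindow` consecutive pairs) in each alternative fold.
#' @param perturbWindow Integer range of perturbation window lengths.
#' @param baseline Named editing baseline per substructure kind.
#' @param up1Effect,dn1Effect,opNucEffect Named multiplicative effects
#'   of the 5' neighbour, 3' neighbour and opposite nucleotide.
#' @param cePosEffect Named per-step multipliers (`helix`, `interior`)
#'   applied as `effect^cePos`; 1 disables.
#' @param symmetricLoopBoost Extra multiplier for symmetric interior
#'   loops (asymmetry 0); 1 disables.
#' @param lambda Entropy suppression rate in `exp(-lambda * H)`.
#' @param snpRate Per-base density of known SNP positions.
#' @param snpNoiseMean Mean number of SNP-overlapping decoy mismatches
#'   per simulated read.
#' @param decoyMean Mean number of non-editing decoy mismatches per
#'   simulated read.
#' @param sensitivity Probability that a read reports each edited site.
#' @param readsPerAlu Simulated RNA reads per Alu.
#' @param maxProb Editing probabilities are clipped to `[0, maxProb]`.
#' @param temperature Kelvin, for ensemble weights.
#' @return A list of class `aluEditConfig`.
#' @export
aluEditConfig <- function(seed = 1L,
                          nAluPairs = 30L,
                          aluLength = 280L,
                          gapWeights = c(0.61, 0.22, 0.09, 0.08),
                          gapBreaks = c(150, 1000, 2000, 3000, 6800),
                          interPairSpacer = 8000L,
                          flank = 200L,
                          divergence = 0.08,
                          indelRate = 0.012,
                          nFolds = 6L,
                          energyGapRange = c(0.3, 1.8),
                          perturbFrac = 0.15,
                          perturbWindow = c(2L, 6L),
                          baseline = c(helix = 0.044, interior = 0.091,
                                       bulge = 0.031, hairpin = 0.032,
                                       junction = 0.024, strand = 0.020),
                          up1Effect = c(A = 1, C = 1, G = 0.32, T = 2.2),
                          dn1Effect = c(A = 1, C = 1, G = 1.5, T = 1),
                          opNucEffect = c(A = 1, C = 3.5, G = 1, T = 1),
                          cePosEffect = c(helix = 1, interior = 1),
                          symmetricLoopBoost = 1,
                          lambda = 1,
                          snpRate = 5e-4,
                          snpNoiseMean = 0.3,
                          decoyMean = 0.5,
                          sensitivity = 0.9,
                          readsPerAlu = 2L,
                          maxProb = 0.95,
                          temperature = 310.15) {
  cfg <- as.list(environment())
  stopifnot(abs(sum(cfg$gapWeights) - 1) < 1e-9,
            cfg$aluLength <= nchar(ALU_CONSENSUS),
            all(cfg$baseline >= 0 & cfg$baseline <= 1),
            cfg$nFolds >= 1L)
  class(cfg) <- "aluEditConfig"
  cfg
}

sampleOtherBase <- function(base) {
  nuc <- c("A", "C", "G", "T")
  idx <- match(base, nuc)
  nuc[(idx - 1L + sample(1:3, length(base), replace = TRUE)) %% 4L + 1L]
}

randomBases <- function(n, prob = c(0.27, 0.23, 0.23, 0.27)) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob)
}

## Mutate a consensus copy: substitutions plus single-base indels,
## keeping the alignment of consensus positions to copy positions.
mutateCopy <- function(cons, divergence, indelRate) {
  n <- length(cons)
  del <- runif(n) < indelRate / 2
  ins <- runif(n) < indelRate / 2
  subst <- runif(n) < divergence
  base <- cons
  if (any(subst)) base[subst] <- sampleOtherBase(base[subst])
  perPos <- as.integer(!del) + as.integer(ins)
  ends <- cumsum(perPos)
  consToCopy <- ifelse(del, NA_integer_, ends - as.integer(ins))
  out <- character(ends[n])
  keep <- which(!del)
  out[consToCopy[keep]] <- base[keep]
  if (any(ins)) out[ends[ins]] <- randomBases(sum(ins))
  list(seq = out, consToCopy = as.integer(consToCopy))
}

#' Generate a synthetic genome with planted Alu inverted repeats
#'
#' Builds one chromosome of random background sequence with `nAluPairs`
#' planted sense/antisense Alu-like pairs (consensus plus per-copy
#' divergence and indels), inter-Alu gaps drawn from the configured gap
#' bins, and SNP positions sampled at the configured rate. The seed
#' fully determines the output.
#'
#' @param config An [aluEditConfig()].
#' @return A list: `genome` (`DNAStringSet`, chromosome `chrS`), `alus`
#'   (`GRanges`, names `pair<i>_s` / `pair<i>_a`), `snps` (`GRanges`),
#'   `pairs` (`data.frame` of pair layout) and `truth` (per-copy
#'   alignment of consensus to copy, used by the fold generator).
#' @export
generateGenome <- function(config) {
  set.seed(config$seed)
  cons <- strsplit(substr(ALU_CONSENSUS, 1L, config$aluLength), "")[[1]]
  chunks <- list()
  aluStart <- integer(0); aluEnd <- integer(0)
  aluStrand <- character(0); aluName <- character(0)
  truth <- list()
  pairRows <- list()
  cursor <- 0L
  lead <- 600L
  chunks[[1]] <- randomBases(lead)
  cursor <- lead
  for (i in seq_len(config$nAluPairs)) {
    c1 <- mutateCopy(cons, config$divergence, config$indelRate)
    c2 <- mutateCopy(cons, config$divergence, config$indelRate)
    bin <- sample(length(config$gapWeights), 1L, prob = config$gapWeights)
    gap <- floor(runif(1, config$gapBreaks[bin], config$gapBreaks[bin + 1L]))
    s1 <- cursor + 1L
    e1 <- cursor + length(c1$seq)
    gapSeq <- randomBases(gap)
    s2 <- e1 + gap + 1L
    anti <- rev(chartr("ACGT", "TGCA", c2$seq))
    e2 <- s2 + length(anti) - 1L
    chunks[[length(chunks) + 1L]] <- c1$seq
    chunks[[length(chunks) + 1L]] <- gapSeq
    chunks[[length(chunks) + 1L]] <- anti
    chunks[[length(chunks) + 1L]] <- randomBases(config$interPairSpacer)
    cursor <- e2 + config$interPairSpacer
    aluStart <- c(aluStart, s1, s2)
    aluEnd <- c(aluEnd, e1, e2)
    aluStrand <- c(aluStrand, "+", "-")
    aluName <- c(aluName, sprintf("pair%d_s", i), sprintf("pair%d_a", i))
    truth[[sprintf("pair%d_s", i)]] <- c1
    truth[[sprintf("pair%d_a", i)]] <- c2
    pairRows[[i]] <- data.frame(pairId = i,
                                senseId = sprintf("pair%d_s", i),
                                antiId = sprintf("pair%d_a", i),
                                senseStart = s1, senseEnd = e1,
                                antiStart = s2, antiEnd = e2,
                                gap = gap)
  }
  seqStr <- paste(unlist(chunks), collapse = "")
  genome <- Biostrings::DNAStringSet(seqStr)
  names(genome) <- "chrS"
  n <- nchar(seqStr)
  alus <- GenomicRanges::GRanges(rep("chrS", length(aluStart)),
                                 IRanges::IRanges(aluStart, aluEnd),
                                 strand = aluStrand)
  names(alus) <- aluName
  GenomeInfoDb::seqlevels(alus) <- "chrS"
  GenomeInfoDb::seqlengths(alus) <- c(chrS = n)
  nSnp <- rpois(1, config$snpRate * n)
  snpPos <- sort(sample.int(n, min(nSnp, n)))
  snps <- GenomicRanges::GRanges(rep("chrS", length(snpPos)),
                                 IRanges::IRanges(snpPos, snpPos))
  if (length(snpPos))
    names(snps) <- paste0("snp_", seq_along(snpPos))
  pairs <- if (length(pairRows)) do.call(rbind, pairRows) else
    data.frame(pairId = integer(0), senseId = character(0),
               antiId = character(0), senseStart = integer(0),
               senseEnd = integer(0), antiStart = integer(0),
               antiEnd = integer(0), gap = integer(0))
  list(genome = genome,
       alus = alus,
       snps = snps,
       pairs = pairs,
       truth = truth)
}

## Duplex pairing map of one neighborhood (+ orientation), from the
## planted alignments of both copies to consensus.
duplexPairs <- function(nbLen, s1, s2, e2, c1, c2, seqChars) {
  consN <- length(c1$consToCopy)
  i <- s1 - 1L + c1$consToCopy
  j <- e2 - c2$consToCopy + 1L
  ok <- !is.na(i) & !is.na(j)
  x <- rep(NA_character_, consN)
  y <- rep(NA_character_, consN)
  x[ok] <- seqChars[i[ok]]
  yBase <- chartr("ACGT", "TGCA", seqChars[j[ok]])   # copy2 base
  y[ok] <- yBase
  canPair <- ok & (x == y | (x == "G" & y == "A") | (x == "T" & y == "C"))
  canPair[is.na(canPair)] <- FALSE
  p <- integer(nbLen)
  p[i[canPair]] <- j[canPair]
  p[j[canPair]] <- i[canPair]
  list(pairs = p, pairedCons = which(canPair), i = i, j = j)
}

mirrorPairs <- function(p) {
  n <- length(p)
  pm <- integer(n)
  idx <- which(p > 0L)
  pm[n + 1L - idx] <- n + 1L - p[idx]
  pm
}

#' Generate Boltzmann fold ensembles for the planted neighborhoods
#'
#' For every planted Alu pair, constructs the neighborhood (both Alus,
#' the intervening sequence and the flanks), builds the ground-state
#' duplex fold implied by the planted alignment (mismatched positions
#' become interior loops, indels become bulges, the intervening sequence
#' a terminal loop, the flanks exterior strands) and derives
#' `nFolds - 1` alternative folds by opening random windows of base
#' pairs. Free energies place the alternatives `energyGapRange` kcal/mol
#' above the ground state, so the Boltzmann weights are controlled
#' directly. Ensembles are emitted for both neighborhood orientations
#' (the minus-strand Alu is analysed on the mirrored structure).
#'
#' @param gen Output of [generateGenome()].
#' @param config The same [aluEditConfig()].
#' @return A named list (one element per neighborhood name, both
#'   orientations) of lists of [PairingTable-class] objects, ground
#'   state first; attribute `"layout"` holds the neighborhood `GRanges`.
#' @export
generateFoldEnsembles <- function(gen, config) {
  set.seed(config$seed + 1L)
  seqChars <- strsplit(as.character(gen$genome[[1]]), "")[[1]]
  chromLen <- length(seqChars)
  ensembles <- list()
  layout <- GenomicRanges::GRanges()
  for (r in seq_len(nrow(gen$pairs))) {
    pr <- gen$pairs[r, ]
    nbS <- max(1L, pr$senseStart - config$flank)
    nbE <- min(chromLen, pr$antiEnd + config$flank)
    nbLen <- nbE - nbS + 1L
    c1 <- gen$truth[[pr$senseId]]
    c2 <- gen$truth[[pr$antiId]]
    dp <- duplexPairs(nbLen, pr$senseStart - nbS + 1L,
                      pr$antiStart - nbS + 1L, pr$antiEnd - nbS + 1L,
                      c1, c2, seqChars[nbS:nbE])
    nbSeq <- paste(seqChars[nbS:nbE], collapse = "")
    nPaired <- length(dp$pairedCons)
    ground <- dp$pairs
    nAlt <- config$nFolds - 1L
    altPairs <- list()
    if (nAlt > 0L && nPaired > 0L) {
      target <- round(config$perturbFrac * nPaired)
      for (a in seq_len(nAlt)) {
        p <- ground
        openCons <- integer(0)
        guard <- 0L
        while (length(openCons) < target && guard < 10L * target + 20L) {
          guard <- guard + 1L
          st <- sample(dp$pairedCons, 1L)
          w <- sample(seq(config$perturbWindow[1], config$perturbWindow[2]), 1L)
          openCons <- unique(c(openCons,
                               intersect(st:(st + w - 1L), dp$pairedCons)))
        }
        ii <- dp$i[openCons]
        p[p[ii]] <- 0L
        p[ii] <- 0L
        altPairs[[a]] <- p
      }
    } else if (nAlt > 0L) {
      altPairs <- rep(list(ground), nAlt)
    }
    g1 <- -0.4 * max(nPaired, 1L)
    gaps <- if (nAlt > 0L) sort(runif(nAlt, config$energyGapRange[1],
                                      config$energyGapRange[2])) else numeric(0)
    energies <- c(g1, g1 + gaps)
    allPairs <- c(list(ground), altPairs)
    for (orient in c("+", "-")) {
      nb <- GenomicRanges::GRanges("chrS", IRanges::IRanges(nbS, nbE),
                                   strand = orient)
      nb$aluIds <- S4Vectors::List(c(pr$senseId, pr$antiId))
      nm <- neighborhoodName(nb)
      sq <- if (orient == "+") nbSeq else
        as.character(Biostrings::reverseComplement(Biostrings::DNAString(nbSeq)))
      pts <- lapply(seq_along(allPairs), function(k) {
        pp <- if (orient == "+") allPairs[[k]] else mirrorPairs(allPairs[[k]])
        PairingTable(sq, pp, energies[k], sprintf("%s#%d", nm, k))
      })
      ensembles[[nm]] <- pts
      layout <- c(layout, nb)
    }
  }
  attr(ensembles, "layout") <- layout
  ensembles
}

#' Ground-truth site contexts of the synthetic dataset
#'
#' Computes, for every Alu-strand adenosine of every planted Alu, the
#' structural and sequence context on the ground-state fold of its
#' neighborhood plus the ensemble substructure probabilities and
#' structural entropy, using the package's own classification machinery.
#'
#' @param gen Output of [generateGenome()].
#' @param ensembles Output of [generateFoldEnsembles()].
#' @param config The [aluEditConfig()].
#' @return `data.frame`: identity columns (`chrom`, `pos` 0-based,
#'   `strand`, `aluId`, `recordId`, `structPos`) plus context columns
#'   (`kind`, `cePos`, `strandLen`, `oppLen`, `asymmetry`, `opNuc`,
#'   `up1`, `dn1`, `helixFlank`, `H`, `groundKind`, `pHelix` ...).
#' @export
syntheticSiteContexts <- function(gen, ensembles, config) {
  layout <- attr(ensembles, "layout")
  seqChars <- strsplit(as.character(gen$genome[[1]]), "")[[1]]
  ids <- names(gen$alus)
  out <- vector("list", length(gen$alus))
  for (k in seq_along(gen$alus)) {
    alu <- gen$alus[k]
    strandA <- as.character(GenomicRanges::strand(alu))
    s <- GenomicRanges::start(alu); e <- GenomicRanges::end(alu)
    base <- if (strandA == "+") "A" else "T"
    gpos1 <- s - 1L + which(seqChars[s:e] == base)   # 1-based genomic
    if (!length(gpos1)) next
    hit <- which(as.character(GenomicRanges::strand(layout)) == strandA &
                 GenomicRanges::start(layout) <= s &
                 GenomicRanges::end(layout) >= e)
    nb <- layout[hit[1]]
    nm <- neighborhoodName(nb)
    ens <- ensembles[[nm]]
    structPos <- genomicToStructure(nb, gpos1 - 1L)
    maps <- lapply(ens, classifySubstructures)
    g <- which.min(vapply(ens, freeEnergy, 0))
    ann <- annotateStructurePositions(ens[[g]], maps[[g]], structPos)
    prof <- ensembleProfiles(ens, structPos, config$temperature, maps)
    out[[k]] <- cbind(data.frame(chrom = "chrS", pos = gpos1 - 1L,
                                 strand = strandA, aluId = ids[k],
                                 recordId = nm,
                                 stringsAsFactors = FALSE),
                      ann[setdiff(names(ann), "position")],
                      structPos = structPos,
                      prof[c("pHelix", "pInterior", "pBulge", "pHairpin",
                             "pJunction", "pStrand", "H", "groundKind")])
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate editing events under the multiplicative ground-truth model
#'
#' Assigns each adenosine an editing probability
#' `baseline(kind) * effect(up1) * effect(dn1) * effect(opNuc) *
#' effect(cePos) * symmetricLoopBoost * exp(-lambda * H)` (clipped to
#' `[0, maxProb]`), draws the true edited set, and emits mismatch
#' records over simulated RNA reads. Editing in Alu repeats is
#' hyper-editing-like: edits of one Alu appear together on its reads, so
#' true sites form clusters; Alus whose draw yields only one or two
#' edited adenosines (too few to ever form a reportable cluster) are
#' re-labelled unedited, keeping truth and detectability consistent.
#' Reads drop each edited site with probability `1 - sensitivity`, and
#' decoy non-editing mismatches plus SNP-overlapping mismatches are
#' added at the configured rates.
#'
#' @param contexts Site-context table from [syntheticSiteContexts()].
#' @param config The [aluEditConfig()].
#' @param genome Optional `DNAStringSet` (needed when `decoyMean > 0`).
#' @param snps Optional SNP `GRanges` (needed when `snpNoiseMean > 0`).
#' @return A list: `truth` (the context table plus `trueProb` and
#'   `edited`) and `records` (mismatch `data.frame` in the format of
#'   [readMismatchTSV()]).
#' @export
simulateEditing <- function(contexts, config, genome = NULL, snps = NULL) {
  if (!nrow(contexts)) stop("empty site-context table")
  set.seed(config$seed + 2L)
  eff <- function(tab, val) {
    m <- tab[val]
    m[is.na(m)] <- 1
    unname(m)
  }
  p <- unname(config$baseline[contexts$kind])
  p <- p * eff(config$up1Effect, contexts$up1)
  p <- p * eff(config$dn1Effect, contexts$dn1)
  p <- p * eff(config$opNucEffect, contexts$opNuc)
  ce <- unname(config$cePosEffect[contexts$kind])
  ce[is.na(ce)] <- 1
  p <- p * ce^contexts$cePos
  sym <- contexts$kind == "interior" & !is.na(contexts$asymmetry) &
    contexts$asymmetry == 0L
  p[sym] <- p[sym] * config$symmetricLoopBoost
  p <- p * exp(-config$lambda * contexts$H)
  p <- pmin(pmax(p, 0), config$maxProb)
  edited <- rbinom(length(p), 1L, p) == 1L
  ## suppress Alus with 1-2 edits: too few to form a mismatch cluster
  perAlu <- tapply(edited, contexts$aluId, sum)
  weak <- names(perAlu)[perAlu > 0 & perAlu < 3]
  edited[contexts$aluId %in% weak] <- FALSE

  truth <- contexts
  truth$trueProb <- p
  truth$edited <- edited

  seqChars <- if (!is.null(genome))
    strsplit(as.character(genome[[1]]), "")[[1]] else NULL
  snpPos <- if (!is.null(snps)) GenomicRanges::start(snps) else integer(0)

  recs <- list()
  aluIds <- unique(contexts$aluId[edited])
  aluRanges <- tapply(contexts$pos, contexts$aluId, range)
  for (id in aluIds) {
    idx <- which(contexts$aluId == id & edited)
    strandA <- contexts$strand[idx[1]]
    ref <- if (strandA == "+") "A" else "T"
    alt <- if (strandA == "+") "G" else "C"
    rng <- aluRanges[[id]]
    for (r in seq_len(config$readsPerAlu)) {
      keep <- idx[runif(length(idx)) < config$sensitivity]
      rows <- data.frame(rnaId = sprintf("%s_rna%d", id, r),
                         chrom = "chrS",
                         pos = contexts$pos[keep],
                         strand = strandA,
                         ref = ref, alt = alt,
                         tissue = sample(c("brain", "non-brain"), 1L),
                         stringsAsFactors = FALSE)
      nDecoy <- if (config$decoyMean > 0 && !is.null(seqChars))
        rpois(1, config$decoyMean) else 0L
      if (nDecoy > 0L) {
        dpos <- sample(seq(rng[1], rng[2]), nDecoy)
        dref <- seqChars[dpos + 1L]
        dalt <- sampleOtherBase(dref)
        bad <- dref == ref & dalt == alt
        dalt[bad] <- sampleOtherBase(dref[bad])
        ok <- !(dref == ref & dalt == alt) & !(dpos %in% contexts$pos[keep])
        if (any(ok))
          rows <- rbind(rows, data.frame(rnaId = rows$rnaId[1], chrom = "chrS",
                                         pos = dpos[ok], strand = strandA,
                                         ref = dref[ok], alt = dalt[ok],
                                         tissue = rows$tissue[1]))
      }
      nSnpMm <- if (config$snpNoiseMean > 0 && length(snpPos) &&
                    !is.null(seqChars)) rpois(1, config$snpNoiseMean) else 0L
      if (nSnpMm > 0L) {
        cand <- snpPos[snpPos - 1L >= rng[1] & snpPos - 1L <= rng[2]]
        if (length(cand)) {
          spos <- sample(rep(cand, 2L), min(nSnpMm, length(cand)))
          spos <- unique(spos)
          sref <- seqChars[spos]
          rows <- rbind(rows, data.frame(rnaId = rows$rnaId[1], chrom = "chrS",
                                         pos = spos - 1L, strand = strandA,
                                         ref = sref,
                                         alt = sampleOtherBase(sref),
                                         tissue = rows$tissue[1]))
        }
      }
      recs[[length(recs) + 1L]] <- rows
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else
    data.frame(rnaId = character(0), chrom = character(0), pos = integer(0),
               strand = character(0), ref = character(0), alt = character(0),
               tissue = character(0))
  records <- records[order(records$rnaId, records$pos), ]
  rownames(records) <- NULL
  list(truth = truth, records = records)
}

#' Generate a complete synthetic dataset
#'
#' Orchestrates [generateGenome()], [generateFoldEnsembles()],
#' [syntheticSiteContexts()] and [simulateEditing()] and optionally
#' writes every artifact the analysis pipeline consumes: genome FASTA,
#' Alu and SNP BED, mismatch TSV, concatenated CT ensembles, the
#' ground-truth table and a manifest JSON recording the configuration
#' and seed.
#'
#' @param config An [aluEditConfig()].
#' @param dir Optional output directory (created if missing).
#' @return A list with `gen`, `ensembles`, `contexts`, `truth`,
#'   `records` and, when written, `paths`.
#' @export
simulateAluDataset <- function(config, dir = NULL) {
  gen <- generateGenome(config)
  ensembles <- generateFoldEnsembles(gen, config)
  contexts <- syntheticSiteContexts(gen, ensembles, config)
  sim <- simulateEditing(contexts, config, gen$genome, gen$snps)
  out <- list(gen = gen, ensembles = ensembles, contexts = contexts,
              truth = sim$truth, records = sim$records)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  alus = file.path(dir, "alus.bed"),
                  snps = file.path(dir, "snps.bed"),
                  mismatches = file.path(dir, "mismatches.tsv"),
                  ensembles = file.path(dir, "ensembles.ct"),
                  truth = file.path(dir, "truth.tsv"),
                  manifest = file.path(dir, "manifest.json"))
    Biostrings::writeXStringSet(gen$genome, paths$genome)
    exportBed6(gen$alus, paths$alus)
    exportBed6(gen$snps, paths$snps)
    writeMismatchTSV(sim$records, paths$mismatches)
    writeCT(unlist(ensembles, recursive = FALSE, use.names = FALSE),
            paths$ensembles)
    write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                row.names = FALSE)
    cfg <- config
    class(cfg) <- NULL
    jsonlite::write_json(cfg, paths$manifest, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- paths
  }
  out
}

exportBed6 <- function(gr, path) {
  if (!length(gr)) {
    file.create(path)
    return(invisible(path))
  }
  nm <- names(gr)
  if (is.null(nm)) nm <- paste0("feat_", seq_along(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm,
                   score = 0L,
                   strand = as.character(GenomicRanges::strand(gr)))
  df$strand[df$strand == "*"] <- "."
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
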