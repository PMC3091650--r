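#' Pipeline run configuration
#'
#' Collects inputs and parameters for [runPipeline()]. Inputs may be
#' file paths (TSV/BED/FASTA/CT) or in-memory objects (mismatch
#' `data.frame`, `GRanges`, `DNAStringSet`, named list of
#' [PairingTable-class] ensembles keyed by neighborhood name).
#'
#' @param mismatches Mismatch table or TSV path.
#' @param alus Alu annotations (`GRanges` or BED path).
#' @param snps Known SNPs (`GRanges` or BED path); may be empty.
#' @param genome Reference (`DNAStringSet` or FASTA path).
#' @param ensembles Fold ensembles: a CT path (records named
#'   `<neighborhood>#<k>`) or a named list of `PairingTable` lists.
#' @param outDir Optional output directory for report tables.
#' @param minCluster Minimum mismatch-cluster size (default 3).
#' @param flank Neighborhood flank in nt (default 200).
#' @param mergeOverlap Same-strand overlap (bp, strict) beyond which
#'   neighborhoods merge (default 400).
#' @param temperature Kelvin for Boltzmann weights (default 310.15).
#' @param kMax Neighbour positions per side for composition tests.
#' @param entropyBins Equal-count entropy bins per stratum.
#' @param minSites Low-support threshold for enrichment contexts.
#' @return A list of class `aluPipelineConfig`.
#' @export
aluPipelineConfig <- function(mismatches, alus, snps, genome, ensembles,
                              outDir = NULL, minCluster = 3L, flank = 200L,
                              mergeOverlap = 400L, temperature = 310.15,
                              kMax = 30L, entropyBins = 10L,
                              minSites = 50L) {
  cfg <- as.list(environment())
  class(cfg) <- "aluPipelineConfig"
  cfg
}

loadEnsembles <- function(x) {
  if (is.character(x)) {
    pts <- parseCT(x)
    nm <- sub("#\\d+$", "", vapply(pts, structureId, ""))
    x <- split(pts, nm)
  }
  x
}

#' Run the full Alu-editing analysis pipeline
#'
#' Executes site calling (SNP removal, Alu intersection, mismatch
#' clustering, E1/E0 assembly), neighborhood construction (nearest
#' antisense partner, flanking, same-strand merging), per-site
#' structural annotation on the ground-state fold of each neighborhood
#' ensemble, context statistics (stratified frequencies, enrichment
#' factors, neighbour chi-square) and Boltzmann-ensemble entropy
#' profiles. Deterministic given its inputs. If `outDir` is set, the
#' result tables are written as TSV together with a JSON report and
#' manifest.
#'
#' @param config An [aluPipelineConfig()].
#' @return A list of result tables; see Details.
#' @details The returned list holds `sites` (the labelled E1/E0 table),
#'   `annotated` (per-site contexts + ensemble profile), `neighborhoods`
#'   (`GRanges`), `freqByKind`, `freqHelixLen`, `freqInteriorLen`,
#'   `freqCePosHelix`, `freqCePosInterior`, `asymmetry`, `enrichment`
#'   (nested by stratum and feature), `neighborChi2` (per stratum),
#'   `entropy` (frequency-vs-entropy bins), `tissue` (brain vs
#'   non-brain dn1 = G comparison when tissue tags are present) and `qc`.
#' @export
runPipeline <- function(config) {
  records <- config$mismatches
  if (is.character(records)) records <- readMismatchTSV(records)
  alus <- config$alus
  if (is.character(alus)) alus <- rtracklayer::import(alus)
  snps <- config$snps
  if (is.character(snps)) snps <- rtracklayer::import(snps)
  genome <- config$genome
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  ensembles <- loadEnsembles(config$ensembles)

  ## --- site calling ---
  rec <- filterSNPs(records, snps)
  rec <- intersectAlus(rec, alus)
  calls <- callEditingClusters(rec, config$minCluster)
  qc <- list(nMismatches = nrow(records),
             nAfterSNP = nrow(rec),
             nCalled = nrow(calls),
             fracAG = if (nrow(calls))
               mean(calls$refAlu == "A" & calls$altAlu == "G") else NA)
  e1 <- calls[calls$refAlu == "A" & calls$altAlu == "G", , drop = FALSE]
  if (!nrow(e1)) stop("site calling produced no A-to-G editing sites")
  memberIds <- unique(e1$aluId)
  memberAlus <- alus[aluNames(alus) %in% memberIds]
  sites <- assembleSiteSets(e1, memberAlus, genome)
  qc$nE1 <- sum(sites$label == "E1")
  qc$nE0 <- sum(sites$label == "E0")

  ## --- neighborhoods ---
  seqlens <- Biostrings::width(genome)
  names(seqlens) <- names(genome)
  nbs <- GenomicRanges::GRanges()
  for (k in seq_along(memberAlus)) {
    partner <- findPartnerAlu(memberAlus[k], alus)
    if (is.null(partner)) next
    nb <- buildNeighborhood(memberAlus[k], partner, config$flank,
                            seqlens[as.character(
                              GenomicRanges::seqnames(memberAlus[k]))])
    nbs <- c(nbs, nb)
  }
  nbs <- mergeNeighborhoods(sort(nbs), config$mergeOverlap)

  ## --- assign sites to neighborhoods (strand-aware) ---
  siteGR <- GenomicRanges::GRanges(sites$chrom,
                                   IRanges::IRanges(sites$pos + 1L,
                                                    sites$pos + 1L),
                                   strand = sites$strand)
  ov <- GenomicRanges::findOverlaps(siteGR, nbs)
  if (anyDuplicated(S4Vectors::queryHits(ov)))
    stop("a site fell into more than one merged neighborhood")
  nbOf <- rep(NA_integer_, nrow(sites))
  nbOf[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  orphan <- is.na(nbOf)
  if (any(orphan)) {
    warning(sum(orphan), " site(s) outside any neighborhood ",
            "(no antisense partner); excluded")
    sites <- sites[!orphan, , drop = FALSE]
    nbOf <- nbOf[!orphan]
  }

  ## --- structural annotation per neighborhood ---
  ann <- vector("list", length(nbs))
  recSeqs <- character(0)
  for (i in unique(nbOf)) {
    nb <- nbs[i]
    nm <- neighborhoodName(nb)
    ens <- ensembles[[nm]]
    if (is.null(ens))
      stop("annotation stage: no fold ensemble for neighborhood ", nm)
    idx <- which(nbOf == i)
    structPos <- genomicToStructure(nb, sites$pos[idx])
    maps <- lapply(ens, classifySubstructures)
    g <- which.min(vapply(ens, freeEnergy, 0))
    a <- annotateStructurePositions(ens[[g]], maps[[g]], structPos)
    prof <- ensembleProfiles(ens, structPos, config$temperature, maps)
    ann[[i]] <- cbind(sites[idx, , drop = FALSE],
                      recordId = nm, structPos = structPos,
                      a[setdiff(names(a), "position")],
                      prof[c("pHelix", "pInterior", "pBulge", "pHairpin",
                             "pJunction", "pStrand", "H", "groundKind")])
    recSeqs[nm] <- structureSequence(ens[[g]])
  }
  annotated <- do.call(rbind, ann)
  rownames(annotated) <- NULL

  ## --- statistics ---
  hx <- annotated[annotated$kind == "helix", , drop = FALSE]
  il <- annotated[annotated$kind == "interior", , drop = FALSE]
  enr <- list()
  for (st in c("helix", "interior"))
    for (f in c("up1", "dn1", "opNuc", "up1dn1", "up1dn1opNuc"))
      enr[[st]][[f]] <- tryCatch(
        enrichmentFactors(annotated, f, st, config$minSites),
        error = function(e) NULL)
  nbrMat <- neighborMatrix(recSeqs, annotated$recordId, annotated$structPos,
                           config$kMax)
  offsets <- c(-(config$kMax:1), 1:config$kMax)
  chi2 <- list(
    helix = neighborChi2(hx$label, nbrMat[annotated$kind == "helix", ,
                                          drop = FALSE], offsets),
    interior = neighborChi2(il$label, nbrMat[annotated$kind == "interior", ,
                                             drop = FALSE], offsets))

  tissue <- NULL
  if ("tissue" %in% names(annotated)) {
    t1 <- annotated[annotated$label == "E1" & annotated$kind == "helix" &
                    !is.na(annotated$tissue), , drop = FALSE]
    if (nrow(t1) && length(unique(t1$tissue)) == 2L) {
      kb <- sum(t1$tissue == "brain" & t1$dn1 == "G", na.rm = TRUE)
      nb_ <- sum(t1$tissue == "brain")
      kn <- sum(t1$tissue == "non-brain" & t1$dn1 == "G", na.rm = TRUE)
      nn <- sum(t1$tissue == "non-brain")
      tp <- twoProportionTest(kb, nb_, kn, nn)
      tissue <- data.frame(group = c("brain", "non-brain"),
                           n = c(nb_, nn), dn1G = c(kb, kn),
                           prop = tp$estimate, p.value = tp$p.value)
    }
  }

  res <- list(
    sites = sites,
    annotated = annotated,
    neighborhoods = nbs,
    freqByKind = frequencyBy(annotated, "kind"),
    freqHelixLen = frequencyBy(hx, "strandLen"),
    freqInteriorLen = frequencyBy(il, "strandLen"),
    freqCePosHelix = frequencyBy(hx, "cePos"),
    freqCePosInterior = frequencyBy(il, "cePos"),
    asymmetry = tryCatch(asymmetryProfile(annotated), error = function(e) NULL),
    enrichment = enr,
    neighborChi2 = chi2,
    entropy = entropyProfile(annotated, config$entropyBins),
    tissue = tissue,
    qc = qc)

  if (!is.null(config$outDir)) writePipelineReport(res, config)
  res
}

writePipelineReport <- function(res, config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) {
    if (!is.null(d))
      write.table(d, file.path(config$outDir, f), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  wt(res$sites, "sites.tsv")
  wt(res$annotated, "annotated_sites.tsv")
  wt(res$freqByKind, "freq_by_kind.tsv")
  wt(res$freqHelixLen, "freq_helix_length.tsv")
  wt(res$freqInteriorLen, "freq_interior_length.tsv")
  wt(res$freqCePosHelix, "freq_cepos_helix.tsv")
  wt(res$freqCePosInterior, "freq_cepos_interior.tsv")
  wt(res$asymmetry, "asymmetry_profile.tsv")
  wt(res$entropy, "entropy_profile.tsv")
  wt(res$tissue, "tissue_comparison.tsv")
  for (st in names(res$enrichment))
    for (f in names(res$enrichment[[st]]))
      wt(res$enrichment[[st]][[f]], sprintf("enrichment_%s_%s.tsv", st, f))
  for (st in names(res$neighborChi2))
    wt(res$neighborChi2[[st]], sprintf("neighbor_chi2_%s.tsv", st))
  exportBed6(res$neighborhoods, file.path(config$outDir,
                                          "neighborhoods.bed"))
  cfg <- config
  class(cfg) <- NULL
  cfg$outDir <- NULL   # analysis parameters only, not the output location
  cfg <- cfg[vapply(cfg, function(x)
    is.character(x) || is.numeric(x) || is.null(x), TRUE)]
  report <- c(res$qc, list(config = cfg))
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$outDir)
}

#' Validate pipeline inputs
#'
#' Checks formats, coordinate sanity and structure validity of the
#' configured inputs without running the pipeline. Diagnostics only:
#' always returns (a possibly empty) issue table.
#'
#' @param config An [aluPipelineConfig()].
#' @return `data.frame` with columns `input`, `issue`.
#' @export
validateInputs <- function(config) {
  issues <- list()
  note <- function(input, issue)
    issues[[length(issues) + 1L]] <<- data.frame(input = input,
                                                 issue = issue)
  chkPath <- function(x, input) {
    if (is.character(x) && !file.exists(x)) {
      note(input, paste0("file not found: ", x))
      FALSE
    } else TRUE
  }
  if (chkPath(config$mismatches, "mismatches")) {
    rec <- tryCatch({
      r <- config$mismatches
      if (is.character(r)) r <- readMismatchTSV(r)
      r
    }, error = function(e) {
      note("mismatches", conditionMessage(e))
      NULL
    })
    if (!is.null(rec) && nrow(rec) &&
        !all(rec$strand %in% c("+", "-")))
      note("mismatches", "strand values outside {+,-}")
  }
  for (what in c("alus", "snps")) {
    x <- config[[what]]
    if (is.character(x)) {
      if (!chkPath(x, what)) next
      raw <- tryCatch(read.delim(x, header = FALSE), error = function(e) NULL)
      if (!is.null(raw) && ncol(raw) >= 3 && any(raw[[3]] < raw[[2]]))
        note(what, "interval with end < start")
      x <- tryCatch(rtracklayer::import(x), error = function(e) {
        note(what, conditionMessage(e))
        NULL
      })
    }
    if (!is.null(x) && length(x) &&
        is.unsorted(order(as.character(GenomicRanges::seqnames(x)),
                          GenomicRanges::start(x))))
      note(what, "intervals not sorted")
  }
  if (chkPath(config$genome, "genome")) {
    g <- tryCatch({
      g <- config$genome
      if (is.character(g)) g <- Biostrings::readDNAStringSet(g)
      g
    }, error = function(e) {
      note("genome", conditionMessage(e))
      NULL
    })
  }
  if (chkPath(config$ensembles, "ensembles")) {
    tryCatch(loadEnsembles(config$ensembles), error = function(e)
      note("ensembles", conditionMessage(e)))
  }
  out <- if (length(issues)) do.call(rbind, issues) else
    data.frame(input = character(0), issue = character(0))
  rownames(out) <- NULL
  out
}

#' Published joint-context reference table
#'
#' Loads the packaged reference table of editing frequencies,
#' enrichment factors and site counts for the 48 joint contexts of
#' upstream neighbour, downstream neighbour and opposite nucleotide
#' reported for human Alu editing sites. Useful for checking the
#' internal consistency of the enrichment-factor definition (frequency
#' divided by a single shared baseline).
#'
#' @return `data.frame`: `up1`, `dn1`, `opNuc`, `freq`, `enrichment`,
#'   `nSites`.
#' @export
referenceJointContextTable <- function() {
  read.delim(system.file("extdata", "joint_context_reference.tsv",
                         package = "AluEdit"), stringsAsFactors = FALSE)
}
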