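mkRecords <- function(pos, ref = "A", alt = "G", rnaId = "rna1",
                      strand = "+", chrom = "chr1") {
  data.frame(rnaId = rnaId, chrom = chrom, pos = pos, strand = strand,
              ref = ref, alt = alt, stringsAsFactors = FALSE)
}

gr <- function(start0, end0, strand = "+", chrom = "chr1", name = NULL) {
  g <- GenomicRanges::GRanges(chrom,
                              IRanges::IRanges(start0 + 1L, end0),
                              strand = strand)
  if (!is.null(name)) names(g) <- name
  g
}

test_that("SNP filtering removes overlapping records and preserves order", {
  rec <- mkRecords(c(10L, 20L, 30L, 100L, 40L))
  empty <- GenomicRanges::GRanges()
  expect_identical(filterSNPs(rec, empty), rec)

  snp <- gr(100L, 101L)
  expect_equal(filterSNPs(rec, snp)$pos, c(10L, 20L, 30L, 40L))

  snps <- gr(c(19L, 20L), c(21L, 21L))
  out <- filterSNPs(mkRecords(c(10L, 20L, 30L)), snps)
  expect_equal(out$pos, c(10L, 30L))

  unsorted <- gr(c(50L, 10L), c(51L, 11L))
  expect_warning(filterSNPs(rec, unsorted), "not sorted")
})

test_that("Alu intersection annotates and re-expresses mismatch strand", {
  alus <- gr(c(100L, 1000L), c(400L, 1300L), strand = c("+", "-"),
             name = c("aluA", "aluB"))
  rec <- mkRecords(c(50L, 150L, 1100L), ref = c("A", "A", "T"),
                   alt = c("G", "G", "C"), strand = c("+", "+", "-"))
  out <- intersectAlus(rec, alus)
  expect_equal(nrow(out), 2L)                       # record outside all Alus dropped
  expect_equal(out$aluId, c("aluA", "aluB"))
  # A->G in a +strand Alu unchanged; T->C inside a -strand Alu becomes A->G
  expect_equal(out$refAlu, c("A", "A"))
  expect_equal(out$altAlu, c("G", "G"))

  over <- gr(c(100L, 120L), c(400L, 420L), name = c("first", "second"))
  expect_message(out2 <- intersectAlus(mkRecords(130L), over), "smaller start")
  expect_equal(out2$aluId, "first")
})

test_that("cluster calling keeps only runs of >= minCluster identical mismatches", {
  rec <- cbind(mkRecords(c(5L, 9L, 14L)), aluId = "a", aluStrand = "+",
               refAlu = "A", altAlu = "G")
  expect_equal(callEditingClusters(rec)$pos, c(5L, 9L, 14L))

  # run of 2, interrupted, then run of 4
  rec2 <- cbind(mkRecords(c(1L, 2L, 3L, 4L, 5L, 6L, 7L),
                          ref = c("A", "A", "C", "A", "A", "A", "A"),
                          alt = c("G", "G", "T", "G", "G", "G", "G")),
                aluId = "a", aluStrand = "+", refAlu = "A", altAlu = "G")
  expect_equal(callEditingClusters(rec2)$pos, c(4L, 5L, 6L, 7L))

  rec3 <- mkRecords(c(1L, 2L))
  rec3$aluId <- "a"; rec3$aluStrand <- "+"
  rec3$refAlu <- "A"; rec3$altAlu <- "G"
  expect_equal(nrow(callEditingClusters(rec3)), 0L)

  # minus-strand RNA: transcript order is descending genomic order
  rec4 <- cbind(mkRecords(c(10L, 20L, 30L), strand = "-",
                          ref = "T", alt = "C"),
                aluId = "a", aluStrand = "-", refAlu = "A", altAlu = "G")
  expect_equal(sort(callEditingClusters(rec4)$pos), c(10L, 20L, 30L))

  # union across RNAs by genomic coordinate
  rec5 <- rbind(mkRecords(c(1L, 2L, 3L), rnaId = "r1"),
                mkRecords(c(2L, 3L, 4L), rnaId = "r2"))
  rec5$aluId <- "a"; rec5$aluStrand <- "+"
  rec5$refAlu <- "A"; rec5$altAlu <- "G"
  expect_equal(callEditingClusters(rec5)$pos, 1:4)

  # idempotence: re-calling on records restricted to called positions
  called <- callEditingClusters(rec2)
  rec6 <- rec2[rec2$pos %in% called$pos, ]
  expect_equal(callEditingClusters(rec6)$pos, called$pos)
})

test_that("site-set assembly labels every Alu-strand adenosine", {
  genome <- Biostrings::DNAStringSet(c(chr1 = paste0(
    strrep("C", 100), "AACCAAGGACCATTAAGGCCAA", strrep("C", 100))))
  alu <- gr(100L, 122L, name = "alu1")
  aseq <- substr(as.character(genome[[1]]), 101, 122)
  nA <- lengths(regmatches(aseq, gregexpr("A", aseq)))
  e1 <- data.frame(chrom = "chr1", pos = 100L, stringsAsFactors = FALSE)
  sites <- assembleSiteSets(e1, alu, genome)
  expect_equal(nrow(sites), nA)
  expect_equal(sum(sites$label == "E1"), 1L)
  expect_equal(sum(sites$label == "E0"), nA - 1L)

  # called position at a reference C: warned about and dropped
  e1bad <- data.frame(chrom = "chr1", pos = c(100L, 102L))
  expect_warning(sites2 <- assembleSiteSets(e1bad, alu, genome),
                 "not at an Alu-strand adenosine")
  expect_equal(sum(sites2$label == "E1"), 1L)

  # minus-strand Alu: adenosines on the Alu strand are reference Ts
  aluM <- gr(100L, 122L, strand = "-", name = "aluM")
  sitesM <- assembleSiteSets(NULL, aluM, genome)
  nT <- lengths(regmatches(aseq, gregexpr("T", aseq)))
  expect_equal(nrow(sitesM), nT)
  expect_true(all(sitesM$label == "E0"))
})

test_that("toy frequency mirrors direct counting (3 E1 of 62 adenosines)", {
  set.seed(42)
  sq <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = sq))
  ch <- strsplit(sq, "")[[1]]
  apos <- which(ch == "A") - 1L
  # choose two "Alus" jointly holding 62 adenosines
  cut <- apos[62]
  alus <- gr(c(0L, 200L), c(200L, cut + 1L), name = c("x", "y"))
  nA <- sum(apos <= cut)
  e1 <- data.frame(chrom = "chr1", pos = apos[1:3])
  sites <- assembleSiteSets(e1, alus, genome)
  expect_equal(nrow(sites), nA)
  freq <- mean(sites$label == "E1")
  expect_equal(freq, 3 / nA)
})

test_that("calling is invariant under reverse-complementing the genome", {
  cfg <- aluEditConfig(seed = 31, nAluPairs = 3, sensitivity = 1,
                       decoyMean = 0, snpNoiseMean = 0, snpRate = 0)
  ds <- simulateAluDataset(cfg)
  L <- Biostrings::width(ds$gen$genome)[1]

  callOn <- function(records, alus, snps) {
    rec <- filterSNPs(records, snps)
    rec <- intersectAlus(rec, alus)
    callEditingClusters(rec)
  }
  fwd <- callOn(ds$records, ds$gen$alus, ds$gen$snps)

  # mirrored inputs
  recM <- ds$records
  recM$pos <- L - 1L - recM$pos
  recM$strand <- ifelse(recM$strand == "+", "-", "+")
  recM$ref <- chartr("ACGT", "TGCA", recM$ref)
  recM$alt <- chartr("ACGT", "TGCA", recM$alt)
  alusM <- ds$gen$alus
  st <- GenomicRanges::start(alusM); en <- GenomicRanges::end(alusM)
  alusM <- GenomicRanges::GRanges("chrS",
            IRanges::IRanges(L - en + 1L, L - st + 1L),
            strand = ifelse(as.character(GenomicRanges::strand(alusM)) == "+",
                            "-", "+"))
  names(alusM) <- names(ds$gen$alus)
  revCalls <- callOn(recM, alusM, GenomicRanges::GRanges())
  # map mirrored calls back to forward coordinates
  backPos <- sort(L - 1L - revCalls$pos)
  expect_equal(backPos, sort(fwd$pos))
})
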