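test_that("substructure classification matches the worked examples", {
  pt <- parseDotBracket(FIX_SEQ, FIX_DB)
  m <- classifySubstructures(pt)
  el <- structuralElements(m)
  pos <- positionIndex(m)

  expect_equal(sum(el$kind == "helix"), 2)
  expect_equal(sort(el$size[el$kind == "helix"]), c(2, 2))
  expect_equal(pos$kind[c(3, 4, 13, 14)], rep("interior", 4))
  expect_equal(el$size[el$kind == "interior"], 4)  # 2x2 loop
  expect_equal(pos$kind[7:10], rep("hairpin", 4))

  # bulge of length 1, unpaired on one side only
  m2 <- classifySubstructures(parseDotBracket("GGCGGTTTTCCCC", "((.((....))))"))
  el2 <- structuralElements(m2)
  expect_equal(el2$size[el2$kind == "bulge"], 1)
  expect_equal(positionIndex(m2)$oppLen[3], 0L)

  # fully unpaired record: one exterior strand of 16 nt
  m3 <- classifySubstructures(parseDotBracket(strrep("A", 16), strrep(".", 16)))
  expect_equal(structuralElements(m3)$kind, "strand")
  expect_equal(structuralElements(m3)$size, 16)

  # inter-helix exterior single strands and dangling ends are "strand"
  m4 <- classifySubstructures(parseDotBracket(
    strrep("A", 19), ".((...)).((...))..."))
  pos4 <- positionIndex(m4)
  expect_equal(pos4$kind[c(1, 9, 17, 18, 19)], rep("strand", 5))
  el4 <- structuralElements(m4)
  expect_equal(sum(el4$kind == "strand"), 3)  # each maximal run separately
})

test_that("junction loops are labelled for all their strands", {
  db <- "((.((...)).((...)).))"
  m <- classifySubstructures(parseDotBracket(strrep("A", nchar(db)), db))
  pos <- positionIndex(m)
  expect_equal(pos$kind[c(3, 11, 19)], rep("junction", 3))
  el <- structuralElements(m)
  expect_equal(el$size[el$kind == "junction"], 3)
})

test_that("site context reports kind, sizes, cePos and flanks", {
  pt <- parseDotBracket(FIX_SEQ, FIX_DB)
  m <- classifySubstructures(pt)

  ctx3 <- siteContext(pt, m, 3)
  expect_equal(ctx3$kind, "interior")
  expect_equal(ctx3$strandLen, 2L)
  expect_equal(ctx3$oppLen, 2L)
  expect_equal(ctx3$asymmetry, 0L)
  expect_equal(ctx3$cePos, 0L)
  expect_equal(ctx3$helixFlank, "upstream-only")

  ctx5 <- siteContext(pt, m, 5)
  expect_equal(ctx5$kind, "helix")
  expect_equal(ctx5$cePos, 0L)

  # 11-bp perfect helix, middle pair: cePos = 5 (bp steps to nearest end)
  h <- parseDotBracket(paste0(strrep("G", 11), "AAAA", strrep("C", 11)),
                       paste0(strrep("(", 11), "....", strrep(")", 11)))
  mh <- classifySubstructures(h)
  expect_equal(siteContext(h, mh, 6)$cePos, 5L)

  # neighbours come from the primary sequence; edges give NA
  ctx2 <- siteContext(pt, m, 2, kMax = 4)
  expect_equal(unname(ctx2$upNbr), c("G", NA, NA, NA))
  expect_equal(unname(ctx2$dnNbr), c("A", "A", "G", "G"))
  expect_error(siteContext(pt, m, 17), "outside")
})

test_that("opposite nucleotide follows the helix and loop-edge rules", {
  pt <- parseDotBracket(FIX_SEQ, FIX_DB)
  m <- classifySubstructures(pt)
  # loop-edge rule: 5'-most of own strand <-> 3'-most of other strand
  expect_equal(oppositeNucleotide(pt, m, 3),
               substr(FIX_SEQ, 14, 14))
  expect_equal(oppositeNucleotide(pt, m, 4),
               substr(FIX_SEQ, 13, 13))
  # helix: pairing partner
  expect_equal(oppositeNucleotide(pt, m, 5), substr(FIX_SEQ, 12, 12))

  # single A.C mismatch (1x1 interior loop) inside a helix -> C
  mm <- parseDotBracket("GGGACCAAAAGGCCCC", "(((.((....)).)))")
  mmap <- classifySubstructures(mm)
  expect_equal(positionIndex(mmap)$kind[4], "interior")
  expect_equal(positionIndex(mmap)$strandLen[4], 1L)
  expect_equal(positionIndex(mmap)$oppLen[4], 1L)
  expect_equal(oppositeNucleotide(mm, mmap, 4), "C")

  # own strand length 1, opposite length 3 -> undefined
  u <- parseDotBracket("GGACCCCGGTTTTCC", "((.((...))...))")
  umap <- classifySubstructures(u)
  expect_equal(positionIndex(umap)$kind[3], "interior")
  expect_equal(positionIndex(umap)$strandLen[3], 1L)
  expect_equal(positionIndex(umap)$oppLen[3], 3L)
  expect_equal(oppositeNucleotide(u, umap, 3), "undefined")
  # the opposite-strand 5' edge still maps back onto position 3's base
  expect_equal(oppositeNucleotide(u, umap, 11), substr("GGACCCCGGTTTTCC", 3, 3))

  # deep loop sites, hairpins, exterior strands: n/a
  expect_equal(oppositeNucleotide(pt, m, 8), "n/a")
})

test_that("classifier agrees with the brute-force oracle (exhaustive, n <= 9)", {
  for (n in 0:9) {
    for (db in enumDotBrackets(n)) {
      if (!nchar(db)) next
      pt <- parseDotBracket(strrep("A", n), db)
      got <- positionIndex(classifySubstructures(pt))$kind
      expect_equal(got, oracleKinds(db), info = db)
    }
  }
})

test_that("every nucleotide belongs to exactly one element", {
  set.seed(5)
  pool <- enumDotBrackets(12L)
  for (db in sample(pool, 40)) {
    m <- classifySubstructures(parseDotBracket(randomSeq(12L), db))
    el <- structuralElements(m)
    pos <- positionIndex(m)
    expect_equal(sum(el$nMembers), 12L, info = db)
    expect_true(all(pos$elementId >= 1L), info = db)
    # member counts per element match the position index
    expect_equal(unname(table(pos$elementId)[as.character(el$elementId)]),
                 unname(as.table(setNames(el$nMembers, el$elementId))),
                 ignore_attr = TRUE, info = db)
  }
})

test_that("mirror symmetry: reversing the structure preserves site geometry", {
  set.seed(6)
  pool <- enumDotBrackets(12L)
  for (db in sample(pool, 40)) {
    n <- nchar(db)
    sq <- randomSeq(n)
    pt <- parseDotBracket(sq, db)
    m <- positionIndex(classifySubstructures(pt))
    # mirrored structure: reversed sequence, mirrored pair map
    p <- basePairs(pt)
    pm <- integer(n)
    idx <- which(p > 0)
    pm[n + 1 - idx] <- n + 1 - p[idx]
    ptm <- PairingTable(paste(rev(strsplit(sq, "")[[1]]), collapse = ""), pm)
    mm <- positionIndex(classifySubstructures(ptm))
    rev_idx <- n:1
    expect_equal(mm$kind, m$kind[rev_idx], info = db)
    expect_equal(mm$cePos, m$cePos[rev_idx], info = db)
    expect_equal(mm$strandLen, m$strandLen[rev_idx], info = db)
    expect_equal(abs(mm$asymmetry), abs(m$asymmetry[rev_idx]), info = db)
  }
})

test_that("opNuc is reciprocal at interior-loop edges", {
  set.seed(7)
  pool <- enumDotBrackets(12L)
  for (db in sample(pool, 60)) {
    n <- nchar(db)
    sq <- randomSeq(n)
    pt <- parseDotBracket(sq, db)
    m <- classifySubstructures(pt)
    pos <- positionIndex(m)
    ch <- strsplit(sq, "")[[1]]
    for (u in which(pos$kind == "interior" & pos$cePos == 0L)) {
      op <- oppositeNucleotide(pt, m, u)
      if (op %in% c("n/a", "undefined")) next
      j <- if (u == pos$ownStart[u]) pos$oppEnd[u] else pos$oppStart[u]
      expect_equal(op, ch[j])
      opBack <- oppositeNucleotide(pt, m, j)
      if (!opBack %in% c("n/a", "undefined"))
        expect_equal(opBack, ch[u], info = paste(db, u))
    }
  }
})
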