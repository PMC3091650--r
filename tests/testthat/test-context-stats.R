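mkSites <- function(n, nE1, ...) {
  extra <- list(...)
  d <- data.frame(label = c(rep("E1", nE1), rep("E0", n - nE1)),
                  stringsAsFactors = FALSE)
  for (nm in names(extra)) d[[nm]] <- extra[[nm]]
  d
}

test_that("stratified frequencies count directly and carry Wilson CIs", {
  s <- mkSites(62, 3, kind = "interior")
  tab <- frequencyBy(s, "kind")
  expect_equal(tab$nSites, 62L)
  expect_equal(tab$nE1, 3L)
  expect_equal(tab$freq, 3 / 62, tolerance = 1e-12)
  expect_true(tab$ciLow <= tab$freq && tab$freq <= tab$ciHigh)

  z <- frequencyBy(mkSites(50, 0, kind = "helix"), "kind")
  expect_equal(z$freq, 0)
  expect_equal(z$ciLow, 0)

  two <- frequencyBy(rbind(mkSites(40, 4, kind = "helix"),
                           mkSites(10, 5, kind = "interior")), "kind")
  expect_equal(two$freq[two$kind == "interior"], 0.5)
})

test_that("Wilson interval covers the truth at nominal rate (n=100, p=0.05)", {
  set.seed(99)
  k <- rbinom(1000, 100, 0.05)
  ci <- wilsonCI(k, 100)
  covered <- mean(ci$low <= 0.05 & 0.05 <= ci$high)
  expect_gte(covered, 0.93)
})

test_that("asymmetry profile normalises within strand-length strata", {
  set.seed(4)
  n <- 4000
  sl <- sample(1:5, n, TRUE)
  asym <- sample(0:3, n, TRUE)
  # editing independent of asymmetry -> normalised value ~ 1 everywhere
  lab <- ifelse(runif(n) < 0.1, "E1", "E0")
  s <- data.frame(label = lab, kind = "interior", strandLen = sl,
                  asymmetry = asym)
  prof <- asymmetryProfile(s)
  expect_true(all(prof$strandLen <= 4))         # strand length 5 excluded
  expect_true(all(abs(prof$normFreq - 1) < 0.5))
  # weighted mean of normalised frequencies is exactly 1 per stratum
  for (L in 1:4) {
    p <- prof[prof$strandLen == L, ]
    expect_equal(sum(p$normFreq * p$nSites * sum(p$nE1) / sum(p$nSites)) /
                   sum(p$nE1), 1, tolerance = 1e-9)
  }
})

test_that("asymmetry profile recovers a planted symmetric-loop boost", {
  set.seed(8)
  n <- 30000
  sl <- sample(1:4, n, TRUE)
  asym <- sample(0:3, n, TRUE)
  p <- ifelse(asym == 0, 0.2, 0.1)
  s <- data.frame(label = ifelse(runif(n) < p, "E1", "E0"),
                  kind = "interior", strandLen = sl, asymmetry = asym)
  prof <- asymmetryProfile(s)
  at0 <- prof$normFreq[prof$asymmetry == 0]
  away <- prof$normFreq[prof$asymmetry != 0]
  expect_true(all(at0 / mean(away) > 1.7))
  expect_true(all(at0 / mean(away) < 2.3))
})

test_that("enrichment factors are frequency over one shared baseline", {
  set.seed(12)
  n <- 20000
  up1 <- sample(c("A", "C", "G", "T"), n, TRUE)
  # null model: editing independent of the feature
  s <- data.frame(label = ifelse(runif(n) < 0.08, "E1", "E0"),
                  kind = "helix", up1 = up1, dn1 = "A", opNuc = "T")
  tab <- enrichmentFactors(s, "up1", "helix")
  expect_true(all(abs(tab$enrichment - 1) < 0.15))
  # site-share weighted mean enrichment is exactly 1
  expect_equal(sum(tab$enrichment * tab$nSites) / sum(tab$nSites), 1,
               tolerance = 1e-12)
  # freq / enrichment is the same constant in every row
  expect_equal(tab$freq / tab$enrichment, rep(attr(tab, "baseline"), 4),
               tolerance = 1e-12)

  # planted multiplicative effect is recovered as an enrichment ratio
  p <- 0.05 * ifelse(up1 == "T", 2.2, 1)
  s2 <- data.frame(label = ifelse(runif(n) < p, "E1", "E0"),
                   kind = "helix", up1 = up1, dn1 = "A", opNuc = "T")
  tab2 <- enrichmentFactors(s2, "up1", "helix")
  ratio <- tab2$enrichment[tab2$up1 == "T"] /
    mean(tab2$enrichment[tab2$up1 %in% c("A", "C", "G")])
  expect_equal(ratio, 2.2, tolerance = 0.25)

  # sites with undefined opNuc are excluded from opNuc tables
  s2$opNuc[1:1000] <- "undefined"
  tab3 <- enrichmentFactors(s2, "opNuc", "helix")
  expect_equal(sum(tab3$nSites), n - 1000)
  expect_true(any(enrichmentFactors(s2, "up1dn1", "helix",
                                    minSites = 1e6)$lowSupport))
})

test_that("neighbour chi-square behaves like the Pearson statistic", {
  nbr <- matrix(rep(c("A", "C", "G", "T"), 10), ncol = 1,
                dimnames = list(NULL, "up1"))
  lab <- rep(c("E1", "E0"), each = 20)   # identical E1 and E0 composition
  tab <- neighborChi2(lab, nbr, offsets = -1L)
  expect_equal(tab$chi2, 0)
  expect_false(tab$flagged)

  # E1 all A, E0 all C -> chi2 = N = 20
  nbr2 <- matrix(c(rep("A", 10), rep("C", 10)), ncol = 1,
                 dimnames = list(NULL, "up1"))
  lab2 <- c(rep("E1", 10), rep("E0", 10))
  tab2 <- neighborChi2(lab2, nbr2, offsets = -1L)
  expect_equal(tab2$chi2, 20)
  expect_true(tab2$flagged)
  expect_equal(tab2$E1_A, 1)
  expect_equal(tab2$E0_C, 1)

  # invariance under swapping the E1/E0 labels
  lab3 <- ifelse(lab2 == "E1", "E0", "E1")
  expect_equal(neighborChi2(lab3, nbr2, offsets = -1L)$chi2, tab2$chi2)

  # NA neighbours (record edges) are skipped for that offset
  nbr2[1, 1] <- NA
  expect_equal(neighborChi2(lab2, nbr2, offsets = -1L)$E1_A, 1)
})

test_that("neighbour matrix reads bases off the primary sequence", {
  seqs <- c(rec1 = "ACGTACGT")
  nm <- neighborMatrix(seqs, rep("rec1", 2), c(1L, 5L), kMax = 2)
  expect_equal(unname(nm[1, c("up2", "up1", "dn1", "dn2")]),
               c(NA, NA, "C", "G"))
  expect_equal(unname(nm[2, c("up2", "up1", "dn1", "dn2")]),
               c("G", "T", "C", "G"))
})

test_that("two-proportion test matches the pooled z closed form", {
  tp <- twoProportionTest(50, 100, 50, 100)
  expect_equal(tp$p.value, 1)

  tp2 <- twoProportionTest(0, 10, 10, 10)
  expect_lt(tp2$p.value, 1e-4)

  # closed-form check
  k1 <- 30; n1 <- 200; k2 <- 50; n2 <- 220
  p1 <- k1 / n1; p2 <- k2 / n2; pp <- (k1 + k2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  tp3 <- twoProportionTest(k1, n1, k2, n2)
  expect_equal(tp3$statistic, z, tolerance = 1e-9)
  expect_equal(tp3$p.value, 2 * pnorm(-abs(z)), tolerance = 1e-9)

  expect_error(twoProportionTest(1, 0, 1, 2), "at least 1")
  expect_error(twoProportionTest(5, 4, 1, 2), "within")
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(0.013, 1), 0.013)
  expect_equal(bonferroniAdjust(0.013, 4), 0.052)
  expect_equal(bonferroniAdjust(0.5, 3), 1)
  expect_equal(bonferroniAdjust(c(0.01, 0.2), 4), c(0.04, 0.8))
  expect_error(bonferroniAdjust(c(0.1, 0.2), 1), "at least")
})
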