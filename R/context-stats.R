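#' Wilson score confidence interval for a proportion
#'
#' @param k Successes (vectorised).
#' @param n Trials.
#' @param conf Confidence level (default 0.95).
#' @return `data.frame` with `low` and `high`.
#' @export
wilsonCI <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  data.frame(low = pmax(0, centre - half), high = pmin(1, centre + half))
}

#' Editing frequency stratified by context keys
#'
#' Groups an annotated site table by the given keys and reports per
#' group the number of sites, the number of E1 calls, the editing
#' frequency and its 95% Wilson confidence interval.
#'
#' @param sites `data.frame` with a `label` column (`"E1"`/`"E0"`) and
#'   the key columns.
#' @param keys Character vector of grouping column names (e.g. `"kind"`,
#'   `"strandLen"`, `"cePos"`, `"asymmetry"`, `"helixFlank"`).
#' @param conf Confidence level for the interval.
#' @return `data.frame`: key columns, `nSites`, `nE1`, `freq`, `ciLow`,
#'   `ciHigh`.
#' @export
frequencyBy <- function(sites, keys, conf = 0.95) {
  miss <- setdiff(c("label", keys), names(sites))
  if (length(miss))
    stop("site table lacks columns: ", paste(miss, collapse = ", "))
  keep <- stats::complete.cases(sites[keys])
  sites <- sites[keep, , drop = FALSE]
  g <- interaction(sites[keys], drop = TRUE, lex.order = TRUE)
  nSites <- as.vector(table(g))
  nE1 <- as.vector(tapply(sites$label == "E1", g, sum))
  keyTab <- unique(sites[keys])
  keyTab <- keyTab[match(levels(g), interaction(keyTab, lex.order = TRUE)), ,
                   drop = FALSE]
  ci <- wilsonCI(nE1, nSites, conf)
  out <- cbind(keyTab, data.frame(nSites = nSites, nE1 = nE1,
                                  freq = nE1 / nSites,
                                  ciLow = ci$low, ciHigh = ci$high))
  o <- do.call(order, out[keys])
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Normalised editing frequency versus interior-loop asymmetry
#'
#' For interior-loop sites with own-strand length 1 to 4, tabulates the
#' editing frequency as a function of loop asymmetry (opposite minus own
#' strand length) and normalises each entry by the average editing
#' frequency of sites with the same strand length regardless of
#' asymmetry.
#'
#' @param sites Annotated site table (`kind`, `strandLen`, `asymmetry`,
#'   `label`).
#' @param maxStrandLen Largest own-strand length kept (default 4).
#' @return `data.frame`: `strandLen`, `asymmetry`, `nSites`, `nE1`,
#'   `freq`, `normFreq`.
#' @export
asymmetryProfile <- function(sites, maxStrandLen = 4L) {
  s <- sites[sites$kind == "interior" &
             sites$strandLen >= 1L & sites$strandLen <= maxStrandLen, ,
             drop = FALSE]
  tab <- frequencyBy(s, c("strandLen", "asymmetry"))
  byLen <- frequencyBy(s, "strandLen")
  tab$normFreq <- tab$freq /
    byLen$freq[match(tab$strandLen, byLen$strandLen)]
  tab
}

#' Enrichment factors for sequence contexts
#'
#' Computes, within one substructure stratum, the editing frequency of
#' each context of the chosen feature and its enrichment factor, i.e.
#' the context frequency divided by the baseline frequency. The baseline
#' is the mean editing frequency over all sites of the stratum that are
#' eligible for the table (feature fully defined), so the site-share
#' weighted mean of the enrichment factors is 1 by construction; the
#' baseline is returned as attribute `"baseline"` rather than
#' hard-coded.
#'
#' @param sites Annotated site table (`kind`, `up1`, `dn1`, `opNuc`,
#'   `label`).
#' @param feature One of `"up1"`, `"dn1"`, `"opNuc"`, `"up1dn1"`,
#'   `"up1dn1opNuc"`.
#' @param stratum Substructure stratum, `"helix"` or `"interior"`.
#' @param minSites Contexts with fewer sites are flagged `lowSupport`.
#' @return `data.frame`: context columns, `nSites`, `nE1`, `freq`,
#'   `enrichment`, `lowSupport`; attribute `baseline`.
#' @export
enrichmentFactors <- function(sites,
                              feature = c("up1", "dn1", "opNuc",
                                          "up1dn1", "up1dn1opNuc"),
                              stratum = c("helix", "interior"),
                              minSites = 50L) {
  feature <- match.arg(feature)
  stratum <- match.arg(stratum)
  cols <- switch(feature,
                 up1 = "up1", dn1 = "dn1", opNuc = "opNuc",
                 up1dn1 = c("up1", "dn1"),
                 up1dn1opNuc = c("up1", "dn1", "opNuc"))
  s <- sites[sites$kind == stratum, , drop = FALSE]
  ok <- rep(TRUE, nrow(s))
  for (cl in cols)
    ok <- ok & !is.na(s[[cl]]) & s[[cl]] %in% c("A", "C", "G", "T")
  s <- s[ok, , drop = FALSE]
  if (!nrow(s)) stop("no eligible sites in stratum '", stratum, "'")
  baseline <- mean(s$label == "E1")
  tab <- frequencyBy(s, cols)
  tab$enrichment <- tab$freq / baseline
  tab$lowSupport <- tab$nSites < minSites
  attr(tab, "baseline") <- baseline
  tab
}

#' Chi-square comparison of neighbour nucleotide composition
#'
#' For each offset, compares the nucleotide distribution at that
#' position relative to E1 sites against E0 sites with a Pearson
#' chi-square test on the 2x4 contingency table (df = 3, no continuity
#' correction). Sites whose neighbour falls outside the sequence record
#' are skipped for that offset. Rows with any expected cell below 5 are
#' flagged but the statistic is still reported.
#'
#' @param labels Character vector, `"E1"`/`"E0"`, one per site.
#' @param nbrMatrix Character matrix of neighbour bases; columns named
#'   `up30 ... up1, dn1 ... dn30` (see [neighborMatrix()]).
#' @param offsets Integer offsets to report; negative = upstream.
#' @return `data.frame`: `offset`, `chi2`, the eight nucleotide
#'   fractions (`E1_A ... E0_T`) and `flagged`.
#' @export
neighborChi2 <- function(labels, nbrMatrix,
                         offsets = c(-(30:1), 1:30)) {
  nuc <- c("A", "C", "G", "T")
  res <- lapply(offsets, function(off) {
    cn <- if (off < 0) paste0("up", -off) else paste0("dn", off)
    if (!cn %in% colnames(nbrMatrix)) return(NULL)
    b <- nbrMatrix[, cn]
    keep <- !is.na(b) & b %in% nuc
    m <- rbind(E1 = table(factor(b[keep & labels == "E1"], levels = nuc)),
               E0 = table(factor(b[keep & labels == "E0"], levels = nuc)))
    expd <- outer(rowSums(m), colSums(m)) / sum(m)
    ## Pearson statistic; cells with zero expectation contribute nothing
    nz <- expd > 0
    chi2 <- sum((m[nz] - expd[nz])^2 / expd[nz])
    fr <- sweep(m, 1, rowSums(m), "/")
    data.frame(offset = off, chi2 = chi2,
               E1_A = fr["E1", "A"], E1_C = fr["E1", "C"],
               E1_G = fr["E1", "G"], E1_T = fr["E1", "T"],
               E0_A = fr["E0", "A"], E0_C = fr["E0", "C"],
               E0_G = fr["E0", "G"], E0_T = fr["E0", "T"],
               flagged = any(expd < 5))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Neighbour-base matrix for a set of sites
#'
#' Builds the character matrix consumed by [neighborChi2()]: the bases
#' `kMax` positions 5' and 3' of each site, taken from the primary
#' sequence of the site's structure record; positions outside the record
#' are `NA`.
#'
#' @param seqs Named character vector (or `DNAStringSet`) of structure
#'   record sequences.
#' @param recordId Record name per site.
#' @param structPos 1-based position per site within its record.
#' @param kMax Neighbours per side (default 30).
#' @return Character matrix with columns `up<k>`, `dn<k>`.
#' @export
neighborMatrix <- function(seqs, recordId, structPos, kMax = 30L) {
  if (is(seqs, "XStringSet")) seqs <- as.character(seqs)
  splitSeqs <- strsplit(seqs, "")
  cols <- c(paste0("up", kMax:1), paste0("dn", 1:kMax))
  out <- matrix(NA_character_, nrow = length(recordId), ncol = length(cols),
                dimnames = list(NULL, cols))
  for (id in unique(recordId)) {
    ch <- splitSeqs[[id]]
    n <- length(ch)
    idx <- which(recordId == id)
    for (k in seq_len(kMax)) {
      u <- structPos[idx] - k
      d <- structPos[idx] + k
      out[idx, paste0("up", k)] <- ifelse(u >= 1L, ch[pmax(u, 1L)],
                                          NA_character_)
      out[idx, paste0("dn", k)] <- ifelse(d <= n, ch[pmin(d, n)],
                                          NA_character_)
    }
  }
  out
}

#' Two-proportion z-test (pooled variance, two-sided)
#'
#' Tests equality of two binomial proportions with the pooled-variance
#' z statistic, equivalent to the Pearson chi-square test on the 2x2
#' table without continuity correction.
#'
#' @param k1,n1 Successes and trials in group 1.
#' @param k2,n2 Successes and trials in group 2.
#' @return List with `estimate` (the two proportions), `statistic`
#'   (signed z) and `p.value`.
#' @export
twoProportionTest <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be at least 1")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("successes must lie within [0, n]")
  p1 <- k1 / n1
  p2 <- k2 / n2
  if (p1 == p2)
    return(list(estimate = c(p1 = p1, p2 = p2), statistic = 0,
                p.value = 1))
  ht <- suppressWarnings(
    stats::prop.test(c(k1, k2), c(n1, n2), correct = FALSE))
  z <- sign(p1 - p2) * sqrt(unname(ht$statistic))
  list(estimate = c(p1 = p1, p2 = p2), statistic = z,
       p.value = ht$p.value)
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for each p-value, with `m` at least the number of
#' p-values supplied.
#'
#' @param p Numeric vector of p-values.
#' @param m Number of tests (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroniAdjust <- function(p, m = length(p)) {
  if (m < length(p)) stop("m must be at least length(p)")
  stats::p.adjust(p, method = "bonferroni", n = m)
}
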