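## gas constant in kcal mol^-1 K^-1 (molar realisation of k_B for
## free energies quoted per mole)
GAS_CONSTANT_KCAL <- 1.98717e-3

#' Boltzmann weights of a fold ensemble
#'
#' Converts the free energies of a discrete list of suboptimal folds
#' into occupation probabilities `P_n = exp(-G_n / (R T)) / Z`. The
#' computation shifts by the minimum energy for numerical stability, so
#' adding a constant to all energies changes nothing.
#'
#' @param energies Free energies in kcal/mol (at least one, finite).
#' @param temperature Temperature in Kelvin (default 310.15, i.e. 37 C,
#'   the default folding temperature of MFOLD).
#' @return Probability vector summing to 1.
#' @examples
#' boltzmannWeights(c(-10, -10))
#' @export
boltzmannWeights <- function(energies, temperature = 310.15) {
  if (!length(energies)) stop("at least one free energy is required")
  if (any(!is.finite(energies))) stop("free energies must be finite")
  rt <- GAS_CONSTANT_KCAL * temperature
  w <- exp(-(energies - min(energies)) / rt)
  w / sum(w)
}

#' Per-site substructure probabilities
#'
#' Weighted indicator sum over an ensemble: given the substructure kind
#' a site has in each fold and the fold weights, returns the probability
#' vector over the six substructure kinds.
#'
#' @param kinds Character vector: the site's kind in each fold.
#' @param weights Fold probabilities (same length, summing to 1).
#' @return Named numeric vector over
#'   `helix, interior, bulge, hairpin, junction, strand`.
#' @export
substructureProbabilities <- function(kinds, weights) {
  if (length(kinds) != length(weights))
    stop("kinds and weights differ in length")
  bad <- setdiff(unique(kinds), SUBSTRUCTURE_KINDS)
  if (length(bad))
    stop("unknown substructure kind(s): ", paste(bad, collapse = ", "))
  p <- vapply(SUBSTRUCTURE_KINDS,
              function(s) sum(weights[kinds == s]), 0)
  p
}

#' Structural entropy of a site
#'
#' `H = -sum_s p_s log(p_s)` (natural logarithm, `0 log 0 = 0`) over the
#' substructure probability vector. A site always found in the same
#' substructure has zero structural entropy; a site split equally
#' between two substructures has `ln 2`; the maximum is `ln 6`.
#'
#' @param p Probability vector over the six substructure kinds.
#' @param tol Tolerance on `sum(p) == 1` (default 1e-6).
#' @return Entropy in nats.
#' @examples
#' structuralEntropy(c(0.5, 0.5, 0, 0, 0, 0))
#' @export
structuralEntropy <- function(p, tol = 1e-6) {
  if (any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("probabilities sum to ", sum(p), ", not 1")
  pp <- p[p > 0]
  -sum(pp * log(pp))
}

#' Ensemble profiles for a set of positions
#'
#' Classifies every fold of an ensemble, weights the folds by their
#' Boltzmann probabilities and returns, per requested position, the six
#' substructure probabilities, the structural entropy and the
#' substructure kind in the ground state (minimum-free-energy fold; ties
#' broken toward the first structure listed, matching MFOLD's best-first
#' output order). Exactly the supplied folds enter the ensemble; no
#' re-enumeration is performed.
#'
#' @param structures List of [PairingTable-class] objects over the same
#'   sequence.
#' @param positions 1-based positions to profile (default: all).
#' @param temperature Kelvin (default 310.15).
#' @param maps Optional pre-computed [SubstructureMap-class] list
#'   (matched to `structures`) to avoid re-classification.
#' @return `data.frame`: `position`, `pHelix`, `pInterior`, `pBulge`,
#'   `pHairpin`, `pJunction`, `pStrand`, `H`, `groundKind`.
#' @export
ensembleProfiles <- function(structures, positions = NULL,
                             temperature = 310.15, maps = NULL) {
  if (!length(structures)) stop("empty ensemble")
  lens <- vapply(structures, length, 1L)
  if (length(unique(lens)) != 1L)
    stop("ensemble integrity error: structures have different lengths")
  if (is.null(positions)) positions <- seq_len(lens[1])
  if (any(positions < 1L | positions > lens[1]))
    stop("positions outside structure")
  energies <- vapply(structures, freeEnergy, 0)
  if (any(is.na(energies))) {
    if (length(structures) > 1L)
      stop("ensemble structures must carry free energies")
    energies <- 0
  }
  w <- boltzmannWeights(energies, temperature)
  if (is.null(maps)) maps <- lapply(structures, classifySubstructures)
  kindMat <- vapply(maps,
                    function(m) positionIndex(m)$kind[positions],
                    character(length(positions)))
  kindMat <- matrix(kindMat, nrow = length(positions))
  probs <- matrix(0, nrow = length(positions),
                  ncol = length(SUBSTRUCTURE_KINDS),
                  dimnames = list(NULL, SUBSTRUCTURE_KINDS))
  for (s in SUBSTRUCTURE_KINDS)
    probs[, s] <- as.vector((kindMat == s) %*% w)
  H <- apply(probs, 1, structuralEntropy)
  H[H < 1e-12] <- 0   # clear accumulated floating-point noise at H = 0
  g <- which.min(energies)          # first minimum on ties
  data.frame(position = positions,
             pHelix = probs[, "helix"], pInterior = probs[, "interior"],
             pBulge = probs[, "bulge"], pHairpin = probs[, "hairpin"],
             pJunction = probs[, "junction"], pStrand = probs[, "strand"],
             H = H, groundKind = kindMat[, g],
             stringsAsFactors = FALSE)
}

#' Editing frequency versus structural entropy
#'
#' Bins sites by structural entropy within each ground-state stratum
#' (helix and interior loop) and reports the editing frequency with a
#' Wilson 95% interval per bin. Default binning is equal-count per
#' stratum (duplicate quantile edges are collapsed, so a mass of
#' zero-entropy sites forms its own bin); the bin edges used are
#' reported. A stratum yielding fewer than 2 bins is emitted unbinned
#' with a flag.
#'
#' @param sites Annotated site table with columns `label`, `H`,
#'   `groundKind`.
#' @param nBins Target number of equal-count bins per stratum.
#' @param strata Ground-state kinds to profile.
#' @return `data.frame`: `stratum`, `bin`, `hLow`, `hHigh`, `hMean`,
#'   `nSites`, `nE1`, `freq`, `ciLow`, `ciHigh`, `flagged`.
#' @export
entropyProfile <- function(sites, nBins = 10L,
                           strata = c("helix", "interior")) {
  res <- lapply(strata, function(st) {
    s <- sites[sites$groundKind == st, , drop = FALSE]
    if (!nrow(s)) return(NULL)
    edges <- unique(stats::quantile(s$H, probs = seq(0, 1, length.out = nBins + 1L)))
    flagged <- length(edges) < 3L
    if (flagged) {
      bin <- factor(rep(1L, nrow(s)))
    } else {
      bin <- cut(s$H, breaks = edges, include.lowest = TRUE)
    }
    nSites <- as.vector(table(bin))
    nE1 <- as.vector(tapply(s$label == "E1", bin, sum))
    nE1[is.na(nE1)] <- 0L
    hMean <- as.vector(tapply(s$H, bin, mean))
    lows <- if (flagged) min(s$H) else head(edges, -1)
    highs <- if (flagged) max(s$H) else edges[-1]
    keep <- nSites > 0
    ci <- wilsonCI(nE1[keep], nSites[keep])
    data.frame(stratum = st, bin = seq_along(nSites)[keep],
               hLow = lows[keep], hHigh = highs[keep],
               hMean = hMean[keep], nSites = nSites[keep],
               nE1 = nE1[keep], freq = nE1[keep] / nSites[keep],
               ciLow = ci$low, ciHigh = ci$high, flagged = flagged,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
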