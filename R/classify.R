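#' Classify every nucleotide into its secondary-structure element
#'
#' Partitions the positions of a non-crossing secondary structure into
#' maximal helices (stacked base pairs) and loop elements. Unpaired runs
#' are assigned by the loop they lie in: a loop closed by one pair is a
#' hairpin; a loop between two closing pairs with unpaired nucleotides on
#' both strands is an interior loop and with unpaired nucleotides on
#' exactly one side a bulge; loops with three or more closing pairs are
#' multibranch junctions; unpaired nucleotides enclosed by no pair form
#' exterior strands (each maximal run is its own element, dangling ends
#' included). Loop elements contain only their unpaired constituent
#' strands, never the closing pairs.
#'
#' Helix size is counted in stacked base pairs; loop sizes in member
#' nucleotides. The per-position index also records, for every site, the
#' distance to the closest edge of its own strand or helix (`cePos`,
#' 0 = at the very edge; for helices the distance is in base-pair steps
#' from the nearest helix terminus), own- and opposite-strand lengths and
#' bounds, and the interior-loop asymmetry (opposite minus own strand
#' length).
#'
#' @param pt A [PairingTable-class].
#' @return A [SubstructureMap-class].
#' @examples
#' pt <- parseDotBracket("GCAAGGTTTTCCAAGC", "((..((....))..))")
#' classifySubstructures(pt)
#' @export
classifySubstructures <- function(pt) {
  p <- basePairs(pt)
  n <- length(p)
  posKind <- character(n)
  posElem <- integer(n)
  cePos <- integer(n)
  strandLen <- integer(n)
  oppLen <- rep(NA_integer_, n)
  ownS <- integer(n); ownE <- integer(n)
  oppS <- rep(NA_integer_, n); oppE <- rep(NA_integer_, n)

  elemKind <- character(0)
  elemSize <- integer(0)
  elemMembers <- integer(0)
  nextId <- 0L

  markRun <- function(s, e) {
    u <- s:e
    ownS[u] <<- s; ownE[u] <<- e
    strandLen[u] <<- e - s + 1L
    cePos[u] <<- pmin(u - s, e - u)
  }

  ## --- helices: maximal stacks of pairs ---
  opens <- which(p > seq_len(n))
  if (length(opens)) {
    cont <- c(FALSE,
              opens[-1] == opens[-length(opens)] + 1L &
              p[opens[-length(opens)]] == p[opens[-1]] + 1L)
    hid <- cumsum(!cont)
    for (h in seq_len(max(hid))) {
      oi <- opens[hid == h]
      L <- length(oi)
      nextId <- nextId + 1L
      mem <- c(oi, p[oi])
      posKind[mem] <- "helix"
      posElem[mem] <- nextId
      tt <- seq_len(L)
      ce <- pmin(tt - 1L, L - tt)
      cePos[oi] <- ce
      cePos[p[oi]] <- ce
      strandLen[mem] <- L
      ownS[mem] <- oi[1]; ownE[mem] <- p[oi[1]]
      elemKind[nextId] <- "helix"
      elemSize[nextId] <- L
      elemMembers[nextId] <- 2L * L
    }
  }

  ## --- loop decomposition: scan paired positions with a stack,
  ##     recording each pair's parent and each unpaired run's enclosure ---
  rl <- rle(p == 0L)
  re <- cumsum(rl$lengths)
  rs <- re - rl$lengths + 1L
  runS <- rs[rl$values]
  runE <- re[rl$values]
  nr <- length(runS)
  runEncl <- integer(nr)
  parentOf <- integer(n)
  bp <- which(p != 0L)
  stack <- integer(0)
  ri <- 1L
  for (b in bp) {
    while (ri <= nr && runS[ri] < b) {
      runEncl[ri] <- if (length(stack)) stack[length(stack)] else 0L
      ri <- ri + 1L
    }
    if (p[b] > b) {
      parentOf[b] <- if (length(stack)) stack[length(stack)] else 0L
      stack <- c(stack, b)
    } else {
      stack <- stack[-length(stack)]
    }
  }
  while (ri <= nr) { runEncl[ri] <- 0L; ri <- ri + 1L }

  nKids <- integer(n)
  pk <- parentOf[opens]
  if (length(pk)) {
    tb <- table(pk[pk > 0L])
    nKids[as.integer(names(tb))] <- as.integer(tb)
  }
  runsByEncl <- split(seq_len(nr), runEncl)

  addLoop <- function(kind, runIdx) {
    nextId <<- nextId + 1L
    tot <- 0L
    for (r in runIdx) {
      s <- runS[r]; e <- runE[r]
      u <- s:e
      posKind[u] <<- kind
      posElem[u] <<- nextId
      markRun(s, e)
      tot <- tot + (e - s + 1L)
    }
    elemKind[nextId] <<- kind
    elemSize[nextId] <<- tot
    elemMembers[nextId] <<- tot
  }

  ## exterior strands
  for (r in runsByEncl[["0"]]) addLoop("strand", r)

  ## loops closed by a pair
  loopOpens <- unique(c(opens[nKids[opens] != 1L],
                        as.integer(names(runsByEncl)[names(runsByEncl) != "0"])))
  for (i in loopOpens) {
    runIdx <- runsByEncl[[as.character(i)]]
    K <- nKids[i]
    R <- length(runIdx)
    if (R == 0L) next              # stacked pair or bare multiloop: no members
    if (K == 0L) {
      addLoop("hairpin", runIdx)
    } else if (K == 1L) {
      if (R == 1L) {
        addLoop("bulge", runIdx)
        u <- runS[runIdx]:runE[runIdx]
        oppLen[u] <- 0L
      } else {
        addLoop("interior", runIdx)
        a <- runIdx[1]; b <- runIdx[2]
        if (runS[a] > runS[b]) { tmp <- a; a <- b; b <- tmp }
        ua <- runS[a]:runE[a]; ub <- runS[b]:runE[b]
        oppLen[ua] <- length(ub); oppLen[ub] <- length(ua)
        oppS[ua] <- runS[b]; oppE[ua] <- runE[b]
        oppS[ub] <- runS[a]; oppE[ub] <- runE[a]
      }
    } else {
      addLoop("junction", runIdx)
    }
  }

  asym <- rep(NA_integer_, n)
  ii <- posKind == "interior"
  asym[ii] <- oppLen[ii] - strandLen[ii]

  positions <- data.frame(
    position = seq_len(n),
    kind = posKind,
    elementId = posElem,
    cePos = cePos,
    strandLen = strandLen,
    oppLen = oppLen,
    asymmetry = asym,
    ownStart = ownS,
    ownEnd = ownE,
    oppStart = oppS,
    oppEnd = oppE,
    stringsAsFactors = FALSE)
  elements <- data.frame(
    elementId = seq_along(elemKind),
    kind = elemKind,
    size = elemSize,
    nMembers = elemMembers,
    stringsAsFactors = FALSE)
  new("SubstructureMap", positions = positions, elements = elements)
}

#' Nucleotide structurally opposite a site
#'
#' For a site in a helix the opposite nucleotide (opNuc) is its pairing
#' partner. The notion extends to interior-loop sites at the loop edge
#' (`cePos == 0`): the most 5' nucleotide of the site's strand is opposed
#' by the most 3' nucleotide of the loop's other strand, and vice versa.
#' When the site is alone on its strand while the opposite strand is
#' longer than one nucleotide the two rules conflict and the opposite
#' nucleotide is `"undefined"`. Everywhere else (deep loop sites, bulges,
#' hairpins, junctions, exterior strands) it is `"n/a"`.
#'
#' @param pt A [PairingTable-class].
#' @param map Its [SubstructureMap-class] from [classifySubstructures()].
#' @param position 1-based site position.
#' @return One of `"A","C","G","T","undefined","n/a"`.
#' @export
oppositeNucleotide <- function(pt, map, position) {
  pos <- positionIndex(map)
  if (position < 1L || position > nrow(pos))
    stop("position ", position, " outside structure of length ", nrow(pos))
  row <- pos[position, ]
  sq <- structureSequence(pt)
  if (row$kind == "helix")
    return(substr(sq, basePairs(pt)[position], basePairs(pt)[position]))
  if (row$kind != "interior" || row$cePos != 0L)
    return("n/a")
  if (row$strandLen == 1L && row$oppLen > 1L)
    return("undefined")
  j <- if (position == row$ownStart) row$oppEnd else row$oppStart
  substr(sq, j, j)
}

#' Structural and sequence context of one site
#'
#' Collects, for a single position of a classified structure, the
#' substructure kind, strand lengths, interior-loop asymmetry,
#' closest-edge position, opposite nucleotide, flanking-helix direction
#' and the sequence neighbours up to `kMax` positions on each side
#' (taken from the primary sequence regardless of element boundaries;
#' positions outside the record are `NA`).
#'
#' `helixFlank` describes, for loop sites, whether the immediately
#' adjacent positions are paired: `"both"`, `"upstream-only"`,
#' `"downstream-only"` or `"neither"`. It is most meaningful for loop
#' sites at `cePos == 0`; for helix sites it is `NA`.
#'
#' @inheritParams oppositeNucleotide
#' @param kMax Number of sequence neighbours per side.
#' @return A list with elements `position`, `kind`, `strandLen`,
#'   `oppLen`, `asymmetry`, `cePos`, `opNuc`, `helixFlank`, `upNbr`,
#'   `dnNbr`.
#' @export
siteContext <- function(pt, map, position, kMax = 30L) {
  pos <- positionIndex(map)
  n <- nrow(pos)
  if (position < 1L || position > n)
    stop("position ", position, " outside structure of length ", n)
  row <- pos[position, ]
  sq <- strsplit(structureSequence(pt), "")[[1]]
  up <- position - seq_len(kMax)
  dn <- position + seq_len(kMax)
  upNbr <- ifelse(up >= 1L, sq[pmax(up, 1L)], NA_character_)
  dnNbr <- ifelse(dn <= n, sq[pmin(dn, n)], NA_character_)
  names(upNbr) <- paste0("up", seq_len(kMax))
  names(dnNbr) <- paste0("dn", seq_len(kMax))
  p <- basePairs(pt)
  flank <- NA_character_
  if (row$kind != "helix") {
    upHelix <- position > 1L && p[position - 1L] != 0L
    dnHelix <- position < n && p[position + 1L] != 0L
    flank <- if (upHelix && dnHelix) "both"
             else if (upHelix) "upstream-only"
             else if (dnHelix) "downstream-only"
             else "neither"
  }
  list(position = position,
       kind = row$kind,
       strandLen = row$strandLen,
       oppLen = row$oppLen,
       asymmetry = row$asymmetry,
       cePos = row$cePos,
       opNuc = oppositeNucleotide(pt, map, position),
       helixFlank = flank,
       upNbr = upNbr,
       dnNbr = dnNbr)
}

#' Bulk site-context annotation for many positions of one structure
#'
#' Vectorised companion of [siteContext()]: returns a `data.frame` with
#' one row per requested position carrying kind, cePos, strand lengths,
#' asymmetry, opposite nucleotide, immediate neighbours (`up1`, `dn1`)
#' and flanking-helix direction.
#'
#' @inheritParams oppositeNucleotide
#' @param positions Integer vector of 1-based positions.
#' @return A `data.frame`.
#' @export
annotateStructurePositions <- function(pt, map, positions) {
  idx <- positionIndex(map)
  n <- nrow(idx)
  if (any(positions < 1L | positions > n))
    stop("positions outside structure of length ", n)
  row <- idx[positions, , drop = FALSE]
  sq <- strsplit(structureSequence(pt), "")[[1]]
  p <- basePairs(pt)

  opn <- rep("n/a", length(positions))
  isH <- row$kind == "helix"
  opn[isH] <- sq[p[positions[isH]]]
  isEdge <- row$kind == "interior" & row$cePos == 0L
  undef <- isEdge & row$strandLen == 1L & row$oppLen > 1L
  opn[undef] <- "undefined"
  def <- which(isEdge & !undef)
  if (length(def)) {
    j <- ifelse(positions[def] == row$ownStart[def],
                row$oppEnd[def], row$oppStart[def])
    opn[def] <- sq[j]
  }

  up1 <- ifelse(positions > 1L, sq[pmax(positions - 1L, 1L)], NA_character_)
  dn1 <- ifelse(positions < n, sq[pmin(positions + 1L, n)], NA_character_)
  upHelix <- positions > 1L & p[pmax(positions - 1L, 1L)] != 0L
  dnHelix <- positions < n & p[pmin(positions + 1L, n)] != 0L
  flank <- ifelse(isH, NA_character_,
           ifelse(upHelix & dnHelix, "both",
           ifelse(upHelix, "upstream-only",
           ifelse(dnHelix, "downstream-only", "neither"))))

  data.frame(position = positions,
             kind = row$kind,
             elementId = row$elementId,
             cePos = row$cePos,
             strandLen = row$strandLen,
             oppLen = row$oppLen,
             asymmetry = row$asymmetry,
             opNuc = opn,
             up1 = up1,
             dn1 = dn1,
             helixFlank = flank,
             stringsAsFactors = FALSE)
}
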