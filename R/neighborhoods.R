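#' Find the nearest antisense Alu
#'
#' Returns the Alu on the opposite strand (same chromosome) minimising
#' the edge-to-edge gap to `alu`; ties are broken toward the downstream
#' candidate (larger start). Returns `NULL` (with a logged message) when
#' the chromosome carries no antisense Alu.
#'
#' @param alu A length-1 `GRanges` (the edited Alu).
#' @param alus `GRanges` of all Alus (stranded).
#' @return A length-1 `GRanges`, or `NULL`.
#' @export
findPartnerAlu <- function(alu, alus) {
  want <- if (as.character(GenomicRanges::strand(alu)) == "+") "-" else "+"
  cand <- alus[as.character(GenomicRanges::strand(alus)) == want &
               as.character(GenomicRanges::seqnames(alus)) ==
                 as.character(GenomicRanges::seqnames(alu))]
  if (!length(cand)) {
    message("no antisense Alu on ",
            as.character(GenomicRanges::seqnames(alu)),
            "; neighborhood skipped")
    return(NULL)
  }
  d <- GenomicRanges::distance(alu, cand, ignore.strand = TRUE)
  best <- which(d == min(d))
  if (length(best) > 1L)
    best <- best[which.max(GenomicRanges::start(cand)[best])]
  cand[best]
}

#' Build the genomic neighborhood around an Alu pair
#'
#' The neighborhood spans both Alus and everything between them plus
#' `flank` extra nucleotides on each side, clipped to chromosome bounds
#' (clipping is logged). Its strand is the edited Alu's strand; all
#' structure coordinates downstream are in that frame.
#'
#' @param alu,partner Length-1 `GRanges`.
#' @param flank Extra nucleotides per side (default 200).
#' @param seqlen Optional chromosome length for clipping.
#' @return A length-1 `GRanges` with metadata column `aluIds`.
#' @export
buildNeighborhood <- function(alu, partner, flank = 200L, seqlen = NA) {
  if (as.character(GenomicRanges::seqnames(alu)) !=
      as.character(GenomicRanges::seqnames(partner)))
    stop("Alu and partner lie on different chromosomes")
  s <- min(GenomicRanges::start(alu), GenomicRanges::start(partner)) - flank
  e <- max(GenomicRanges::end(alu), GenomicRanges::end(partner)) + flank
  if (s < 1L) {
    message("neighborhood clipped at chromosome start")
    s <- 1L
  }
  if (!is.na(seqlen) && e > seqlen) {
    message("neighborhood clipped at chromosome end")
    e <- seqlen
  }
  gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(alu),
                               IRanges::IRanges(s, e),
                               strand = GenomicRanges::strand(alu))
  gr$aluIds <- S4Vectors::List(c(aluNames(alu), aluNames(partner)))
  gr
}

#' Merge overlapping neighborhoods
#'
#' Neighborhoods sharing strictly more than `minOverlap` bp of overlap on
#' the same strand are merged (transitive closure of the overlap
#' relation), each class being replaced by its spanning interval with the
#' member Alu lists unioned. The result is independent of input order.
#'
#' @param nbhd `GRanges` of neighborhoods (metadata column `aluIds`).
#' @param minOverlap Overlap must exceed this many bp (default 400).
#' @return Merged `GRanges`, sorted.
#' @export
mergeNeighborhoods <- function(nbhd, minOverlap = 400L) {
  if (length(nbhd) < 2L) return(nbhd)
  hits <- GenomicRanges::findOverlaps(nbhd, nbhd,
                                      minoverlap = minOverlap + 1L)
  hits <- hits[S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)]
  ## union-find over the overlap graph
  parent <- seq_along(nbhd)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (k in seq_along(hits)) {
    a <- find(S4Vectors::queryHits(hits)[k])
    b <- find(S4Vectors::subjectHits(hits)[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_along(nbhd), find, 1L)
  out <- lapply(split(seq_along(nbhd), comp), function(idx) {
    g <- range(nbhd[idx])
    g$aluIds <- S4Vectors::List(sort(unique(unlist(nbhd$aluIds[idx]))))
    g
  })
  out <- do.call(c, unname(out))
  sort(out)
}

#' Neighborhood identifier string
#'
#' Canonical name `chrom:start-end(strand)` with BED-style 0-based,
#' half-open coordinates; used to match neighborhoods to their fold
#' ensembles in CT files.
#'
#' @param nbhd `GRanges`.
#' @return Character vector.
#' @export
neighborhoodName <- function(nbhd) {
  sprintf("%s:%d-%d(%s)",
          as.character(GenomicRanges::seqnames(nbhd)),
          GenomicRanges::start(nbhd) - 1L,
          GenomicRanges::end(nbhd),
          as.character(GenomicRanges::strand(nbhd)))
}

#' Extract neighborhood sequences
#'
#' Returns each neighborhood's sequence on the edited Alu's strand
#' (reverse-complemented for minus-strand neighborhoods). Names follow
#' `chrom:start-end(strand)|alu1,alu2` so that structure coordinates can
#' be mapped back to the genome.
#'
#' @param nbhd `GRanges` of neighborhoods.
#' @param genome `DNAStringSet` or FASTA path.
#' @return A `DNAStringSet`.
#' @export
extractSequences <- function(nbhd, genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  chroms <- as.character(GenomicRanges::seqnames(nbhd))
  if (any(GenomicRanges::end(nbhd) >
          Biostrings::width(genome)[match(chroms, names(genome))]))
    stop("neighborhood extends beyond contig end")
  seqs <- Biostrings::DNAStringSet(lapply(seq_along(nbhd), function(i) {
    s <- Biostrings::subseq(genome[[chroms[i]]],
                            GenomicRanges::start(nbhd)[i],
                            GenomicRanges::end(nbhd)[i])
    if (as.character(GenomicRanges::strand(nbhd))[i] == "-")
      s <- Biostrings::reverseComplement(s)
    s
  }))
  ids <- vapply(seq_along(nbhd), function(i) {
    al <- if (!is.null(nbhd$aluIds)) paste(unlist(nbhd$aluIds[i]),
                                           collapse = ",") else ""
    paste0(neighborhoodName(nbhd[i]), "|", al)
  }, "")
  names(seqs) <- ids
  seqs
}

#' Map genomic positions into neighborhood structure coordinates
#'
#' For a plus-strand neighborhood, structure position 1 is the genomic
#' start; for a minus-strand neighborhood, structure position 1 is the
#' genomic end.
#'
#' @param nbhd A length-1 `GRanges`.
#' @param pos 0-based genomic positions.
#' @return 1-based structure positions.
#' @export
genomicToStructure <- function(nbhd, pos) {
  if (as.character(GenomicRanges::strand(nbhd)) == "-")
    GenomicRanges::end(nbhd) - (pos + 1L) + 1L
  else
    (pos + 1L) - GenomicRanges::start(nbhd) + 1L
}

#' @rdname genomicToStructure
#' @param structPos 1-based structure positions.
#' @return `structureToGenomic()`: 0-based genomic positions.
#' @export
structureToGenomic <- function(nbhd, structPos) {
  if (as.character(GenomicRanges::strand(nbhd)) == "-")
    GenomicRanges::end(nbhd) - structPos
  else
    GenomicRanges::start(nbhd) + structPos - 2L
}
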