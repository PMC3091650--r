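#' Read / write mismatch tables
#'
#' A mismatch table records one RNA-to-genome alignment mismatch per row:
#' `rnaId`, `chrom`, `pos` (0-based genomic position of the mismatched
#' base), `strand` (alignment strand of the RNA), `ref` and `alt` bases
#' (given on the plus strand of the reference) and an optional `tissue`
#' tag. Reference and alternative base must differ.
#'
#' @param path TSV path.
#' @param records Mismatch `data.frame`.
#' @return `readMismatchTSV()` returns a `data.frame`.
#' @export
readMismatchTSV <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("rnaId", "chrom", "pos", "strand", "ref", "alt")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("mismatch TSV lacks columns: ", paste(miss, collapse = ", "))
  if (any(d$ref == d$alt))
    stop("mismatch records with identical ref and alt base")
  d
}

#' @rdname readMismatchTSV
#' @export
writeMismatchTSV <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

mismatchGRanges <- function(records) {
  GenomicRanges::GRanges(records$chrom,
                         IRanges::IRanges(records$pos + 1L, records$pos + 1L))
}

checkSortedBed <- function(gr, what) {
  o <- order(as.character(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr))
  if (is.unsorted(o)) {
    warning(what, " intervals are not sorted; sorting internally")
    gr <- gr[o]
  }
  gr
}

#' Remove mismatches overlapping known SNPs
#'
#' Drops every mismatch record whose genomic position overlaps a known
#' SNP interval. Record order is preserved. Unsorted SNP intervals are
#' sorted internally with a warning.
#'
#' @param records Mismatch `data.frame` (see [readMismatchTSV()]).
#' @param snps A `GRanges` of SNP positions, or a BED path.
#' @return The filtered records.
#' @export
filterSNPs <- function(records, snps) {
  if (is.character(snps)) snps <- rtracklayer::import(snps)
  if (!length(snps) || !nrow(records)) return(records)
  snps <- checkSortedBed(snps, "SNP BED")
  ## SNP sets may legitimately cover chromosomes absent from the records
  hit <- suppressWarnings(
    IRanges::overlapsAny(mismatchGRanges(records), snps,
                         ignore.strand = TRUE))
  records[!hit, , drop = FALSE]
}

#' Intersect mismatches with Alu annotations
#'
#' Keeps only mismatches inside an Alu interval and annotates each with
#' the Alu identifier and strand. The mismatch type is re-expressed on
#' the Alu strand (`refAlu`/`altAlu`): an A-to-G change seen as T-to-C on
#' the plus-strand reference inside a minus-strand Alu becomes A-to-G on
#' the Alu strand. A record covered by two overlapping Alus is assigned
#' to the Alu with the smaller start (a message is logged).
#'
#' @param records Mismatch `data.frame`.
#' @param alus `GRanges` with strand and a `name` column (or names), or a
#'   BED path.
#' @return Annotated records (columns `aluId`, `aluStrand`, `refAlu`,
#'   `altAlu` added).
#' @export
intersectAlus <- function(records, alus) {
  if (is.character(alus)) alus <- rtracklayer::import(alus)
  aluIds <- aluNames(alus)
  hits <- GenomicRanges::findOverlaps(mismatchGRanges(records), alus,
                                      ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  if (anyDuplicated(qh)) {
    message("mismatch record(s) inside overlapping Alus; assigning to the ",
            "Alu with the smaller start")
    o <- order(qh, GenomicRanges::start(alus)[sh])
    keep <- !duplicated(qh[o])
    qh <- qh[o][keep]
    sh <- sh[o][keep]
  }
  out <- records[qh, , drop = FALSE]
  out$aluId <- aluIds[sh]
  out$aluStrand <- as.character(GenomicRanges::strand(alus))[sh]
  minus <- out$aluStrand == "-"
  out$refAlu <- ifelse(minus, complementBase(out$ref), out$ref)
  out$altAlu <- ifelse(minus, complementBase(out$alt), out$alt)
  rownames(out) <- NULL
  out
}

complementBase <- function(b) {
  chartr("ACGT", "TGCA", b)
}

aluNames <- function(alus) {
  ids <- names(alus)
  if (is.null(ids) && !is.null(alus$name)) ids <- alus$name
  if (is.null(ids)) ids <- paste0("alu_", seq_along(alus))
  ids
}

#' Call editing sites from mismatch clusters
#'
#' Within each RNA alignment, mismatches are ordered along the transcript
#' (genomic order, reversed for minus-strand alignments) and maximal runs
#' of identical mismatch types with no intervening mismatch of a
#' different type are clusters. All members of clusters of at least
#' `minCluster` mismatches become putative editing-site (E1) positions;
#' positions supported by different RNAs are unioned by genomic
#' coordinate.
#'
#' @param records Mismatch `data.frame` (ideally SNP-filtered and
#'   Alu-intersected).
#' @param minCluster Minimum cluster size (default 3).
#' @return `data.frame` of unique called positions: `chrom`, `pos`,
#'   and, when present in the input, `aluId`, `aluStrand`, `refAlu`,
#'   `altAlu`, `tissue`.
#' @export
callEditingClusters <- function(records, minCluster = 3L) {
  if (!nrow(records))
    return(records[0, intersect(c("chrom", "pos", "aluId", "aluStrand",
                                  "refAlu", "altAlu", "tissue"),
                                names(records)), drop = FALSE])
  picked <- logical(nrow(records))
  for (idx in split(seq_len(nrow(records)), records$rnaId)) {
    o <- order(records$pos[idx])
    if (records$strand[idx[1]] == "-") o <- rev(o)
    idx <- idx[o]
    type <- paste0(records$ref[idx], ">", records$alt[idx])
    r <- rle(type)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$lengths >= minCluster))
      picked[idx[starts[k]:ends[k]]] <- TRUE
  }
  out <- records[picked, , drop = FALSE]
  keep <- intersect(c("chrom", "pos", "aluId", "aluStrand", "refAlu",
                      "altAlu", "tissue"), names(out))
  out <- out[keep]
  out <- out[!duplicated(out[c("chrom", "pos")]), , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the labelled editing-site table
#'
#' Emits every adenosine (read on the Alu's strand) inside the supplied
#' Alu intervals, labelled `E1` if it carries a called editing site and
#' `E0` otherwise. Called positions whose reference base is not an A on
#' the Alu strand are dropped with a warning (likely alignment
#' artifacts). Adenosines outside the supplied Alus do not enter.
#'
#' @param e1 Called positions from [callEditingClusters()].
#' @param alus `GRanges` of the Alus whose adenosines define the site
#'   universe (with strand; names or a `name` column used as ids), or a
#'   BED path.
#' @param genome A `DNAStringSet` (or FASTA path) holding the reference.
#' @return `data.frame` with columns `chrom`, `pos` (0-based), `strand`,
#'   `aluId`, `label` and, when available, `tissue`.
#' @export
assembleSiteSets <- function(e1, alus, genome) {
  if (is.character(alus)) alus <- rtracklayer::import(alus)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  ids <- aluNames(alus)
  chroms <- as.character(GenomicRanges::seqnames(alus))
  strands <- as.character(GenomicRanges::strand(alus))
  starts <- GenomicRanges::start(alus)
  ends <- GenomicRanges::end(alus)
  res <- vector("list", length(alus))
  for (i in seq_along(alus)) {
    sq <- Biostrings::subseq(genome[[chroms[i]]], starts[i], ends[i])
    base <- if (strands[i] == "-") "T" else "A"
    off <- which(strsplit(as.character(sq), "")[[1]] == base)
    if (!length(off)) next
    res[[i]] <- data.frame(chrom = chroms[i],
                           pos = starts[i] - 1L + off - 1L,  # 0-based genomic
                           strand = strands[i],
                           aluId = ids[i],
                           stringsAsFactors = FALSE)
  }
  sites <- do.call(rbind, res)
  if (is.null(sites))
    sites <- data.frame(chrom = character(0), pos = integer(0),
                        strand = character(0), aluId = character(0))
  key <- paste(sites$chrom, sites$pos)
  e1key <- character(0)
  if (!is.null(e1) && nrow(e1)) {
    e1key <- paste(e1$chrom, e1$pos)
    bad <- !(e1key %in% key)
    if (any(bad)) {
      warning(sum(bad), " called site(s) not at an Alu-strand adenosine; ",
              "dropped as likely alignment artifacts")
      e1 <- e1[!bad, , drop = FALSE]
      e1key <- e1key[!bad]
    }
  }
  sites$label <- ifelse(key %in% e1key, "E1", "E0")
  if (!is.null(e1$tissue)) {
    sites$tissue <- e1$tissue[match(key, e1key)]
  }
  rownames(sites) <- NULL
  sites
}
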