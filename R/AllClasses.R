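#' @import methods
#' @importFrom stats rbinom rpois runif
#' @importFrom utils head read.delim write.table
NULL

SUBSTRUCTURE_KINDS <- c("helix", "interior", "bulge", "hairpin",
                        "junction", "strand")

#' One RNA secondary structure as a pairing table
#'
#' A `PairingTable` holds a single secondary structure: the nucleotide
#' sequence, a base-pair map and (optionally) the free energy of the fold.
#' The pair map is a 1-based integer vector with one entry per nucleotide;
#' `0` marks an unpaired position and any other value the index of the
#' pairing partner. Validity enforces symmetry (`pairs[i] == j` implies
#' `pairs[j] == i`), absence of self-pairs, and nesting (no pseudoknots):
#' crossing pairs are rejected, matching the output conventions of
#' dynamic-programming folders such as MFOLD.
#'
#' Sequences are normalised to the DNA alphabet on construction (U is
#' rewritten as T); T and U are treated as identical throughout.
#'
#' @slot sequence Single character string over `A,C,G,T,N`.
#' @slot pairs Integer vector, same length as the sequence; `0` = unpaired.
#' @slot freeEnergy Numeric free energy in kcal/mol (`NA` if unknown).
#' @slot structureId Identifier of the structure within an ensemble.
#'
#' @examples
#' pt <- parseDotBracket("GGAAACC", "((...))", energy = -1.2)
#' basePairs(pt)
#' @export
setClass("PairingTable",
         representation(sequence = "character",
                        pairs = "integer",
                        freeEnergy = "numeric",
                        structureId = "character"))

setValidity("PairingTable", function(object) {
  p <- object@pairs
  n <- nchar(object@sequence)
  if (length(object@sequence) != 1L)
    return("'sequence' must be a single string")
  if (length(p) != n)
    return(sprintf("pair map length (%d) differs from sequence length (%d)",
                   length(p), n))
  if (any(is.na(p)) || any(p < 0L) || any(p > n))
    return("pair indices must lie in [0, length]")
  idx <- which(p > 0L)
  if (any(p[idx] == idx))
    return("a position cannot pair with itself")
  if (any(p[p[idx]] != idx))
    return("pair map is not symmetric")
  ## nesting check by stack scan over paired positions
  stack <- integer(0)
  for (i in idx) {
    if (p[i] > i) {
      stack <- c(stack, i)
    } else {
      if (!length(stack) || stack[length(stack)] != p[i])
        return(sprintf("crossing base pairs (pseudoknot) involving %d-%d",
                       p[i], i))
      stack <- stack[-length(stack)]
    }
  }
  if (!grepl("^[ACGTN]*$", object@sequence))
    return("sequence contains characters outside {A,C,G,T,U,N}")
  TRUE
})

#' Construct a PairingTable
#'
#' @param sequence Nucleotide string (DNA or RNA alphabet; U is normalised
#'   to T).
#' @param pairs Integer vector of partner indices (1-based, `0` = unpaired).
#' @param freeEnergy Free energy in kcal/mol, or `NA`.
#' @param structureId Identifier string.
#' @return A [PairingTable-class] object.
#' @export
PairingTable <- function(sequence, pairs, freeEnergy = NA_real_,
                         structureId = "structure_1") {
  sequence <- normalizeDNA(sequence)
  new("PairingTable", sequence = sequence, pairs = as.integer(pairs),
      freeEnergy = as.numeric(freeEnergy), structureId = as.character(structureId))
}

normalizeDNA <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

#' @describeIn PairingTable-class Number of nucleotides in the structure.
#' @param x A `PairingTable`.
#' @export
setMethod("length", "PairingTable", function(x) length(x@pairs))

#' Accessors for PairingTable
#'
#' `structureSequence()` returns the nucleotide string, `basePairs()` the
#' partner-index vector (`0` = unpaired), `freeEnergy()` the fold free
#' energy in kcal/mol and `structureId()` the structure identifier.
#'
#' @param x A [PairingTable-class].
#' @return See description.
#' @name PairingTable-accessors
NULL

#' @rdname PairingTable-accessors
#' @export
structureSequence <- function(x) x@sequence

#' @rdname PairingTable-accessors
#' @export
basePairs <- function(x) x@pairs

#' @rdname PairingTable-accessors
#' @export
freeEnergy <- function(x) x@freeEnergy

#' @rdname PairingTable-accessors
#' @export
structureId <- function(x) x@structureId

#' @describeIn PairingTable-class Compact display.
#' @param object A `PairingTable`.
#' @export
setMethod("show", "PairingTable", function(object) {
  n <- length(object)
  np <- sum(object@pairs > 0L) %/% 2L
  cat("PairingTable '", object@structureId, "': ", n, " nt, ", np,
      " base pairs", sep = "")
  if (!is.na(object@freeEnergy))
    cat(", dG = ", object@freeEnergy, " kcal/mol", sep = "")
  cat("\n")
})

#' Per-nucleotide substructure classification of one fold
#'
#' Produced by [classifySubstructures()]. Holds the partition of all
#' nucleotides of a [PairingTable-class] into structural elements (helix,
#' interior loop, bulge, hairpin loop, multibranch junction, exterior
#' strand) together with a per-position index carrying everything needed
#' for site-context queries: element membership, closest-edge position
#' (cePos), own/opposite strand bounds and lengths.
#'
#' @slot positions `data.frame` with one row per nucleotide: `position`,
#'   `kind`, `elementId`, `cePos`, `strandLen`, `oppLen`, `asymmetry`,
#'   `ownStart`, `ownEnd`, `oppStart`, `oppEnd`.
#' @slot elements `data.frame` with one row per element: `elementId`,
#'   `kind`, `size`, `nMembers`.
#' @export
setClass("SubstructureMap",
         representation(positions = "data.frame", elements = "data.frame"))

#' @describeIn SubstructureMap-class Compact display.
#' @param object A `SubstructureMap`.
#' @export
setMethod("show", "SubstructureMap", function(object) {
  tab <- table(factor(object@elements$kind, levels = SUBSTRUCTURE_KINDS))
  cat("SubstructureMap:", nrow(object@positions), "nt,",
      nrow(object@elements), "elements\n")
  print(tab)
})

#' @describeIn SubstructureMap-class Per-position annotation table.
#' @param x A `SubstructureMap`.
#' @export
positionIndex <- function(x) x@positions

#' @describeIn SubstructureMap-class Element summary table.
#' @export
structuralElements <- function(x) x@elements
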