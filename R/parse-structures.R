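#' Parse an MFOLD/Zuker connectivity-table (CT) file
#'
#' Reads one or more concatenated CT records. Each record starts with a
#' header line whose first token is the record length and which usually
#' carries the free energy as `dG = <x>` followed by an optional name;
#' the following lines hold the standard six columns
#' `index base prev next pair hist`. Pairing symmetry is enforced and
#' crossing pairs (pseudoknots) are rejected.
#'
#' @param file Path to a CT file, or a character vector of lines.
#' @return A list of [PairingTable-class] objects, one per record.
#' @examples
#' lines <- c("4\tdG = -1.0\ttoy",
#'            "1\tG\t0\t2\t4\t1", "2\tA\t1\t3\t0\t2",
#'            "3\tA\t2\t4\t0\t3", "4\tC\t3\t0\t1\t4")
#' parseCT(lines)
#' @export
parseCT <- function(file) {
  lines <- if (length(file) == 1L && file.exists(file)) readLines(file) else file
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  k <- 0L
  while (i <= length(lines)) {
    header <- trimws(lines[i])
    toks <- strsplit(header, "\\s+")[[1]]
    n <- suppressWarnings(as.integer(toks[1]))
    if (is.na(n) || n < 1L)
      stop("CT parse error at line ", i, ": header must start with the record length")
    if (i + n > length(lines))
      stop("CT parse error at line ", i, ": record of length ", n,
           " runs past end of input")
    energy <- NA_real_
    m <- regmatches(header, regexec("dG\\s*=\\s*(-?[0-9.]+([eE][+-]?[0-9]+)?)", header))[[1]]
    if (length(m) >= 2) energy <- as.numeric(m[2])
    k <- k + 1L
    name <- sub(".*dG\\s*=\\s*-?[0-9.]+([eE][+-]?[0-9]+)?\\s*", "", header)
    if (!nzchar(name) || identical(name, header)) name <- paste0("record_", k)
    body <- lines[(i + 1L):(i + n)]
    fields <- strsplit(trimws(body), "\\s+")
    ncol <- lengths(fields)
    bad <- which(ncol < 6L)
    if (length(bad))
      stop("CT parse error at line ", i + bad[1],
           ": expected 6 columns, found ", ncol[bad[1]])
    idx <- as.integer(vapply(fields, `[`, "", 1L))
    if (any(is.na(idx)) || any(idx != seq_len(n)))
      stop("CT parse error at line ", i + 1L,
           ": position column must run 1..", n)
    base <- vapply(fields, `[`, "", 2L)
    pair <- as.integer(vapply(fields, `[`, "", 5L))
    if (any(is.na(pair)) || any(pair < 0L) || any(pair > n))
      stop("CT parse error at line ", i + 1L, ": invalid pair column")
    pidx <- which(pair > 0L)
    if (any(pair[pair[pidx]] != pidx)) {
      b <- pidx[pair[pair[pidx]] != pidx][1]
      stop("CT integrity error in record ", k, ": line ", b,
           " pairs with ", pair[b], " but line ", pair[b],
           " does not pair back")
    }
    pt <- tryCatch(
      PairingTable(paste(base, collapse = ""), pair, energy, name),
      error = function(e) {
        if (grepl("pseudoknot", conditionMessage(e)))
          stop("CT pseudoknot error in record ", k, ": ",
               conditionMessage(e), call. = FALSE)
        stop(e)
      })
    out[[k]] <- pt
    i <- i + n + 1L
  }
  if (!k) stop("no CT records found")
  out
}

#' Parse a dot-bracket secondary structure
#'
#' Converts a Vienna-style dot-bracket string into a [PairingTable-class].
#' Only round brackets and dots are accepted (no pseudoknot alphabets).
#'
#' @param sequence Nucleotide string, same length as `db`.
#' @param db Dot-bracket string over `(`, `)`, `.`.
#' @param energy Optional free energy (kcal/mol).
#' @param structureId Identifier string.
#' @return A [PairingTable-class].
#' @examples
#' parseDotBracket("GGAAACC", "((...))")
#' @export
parseDotBracket <- function(sequence, db, energy = NA_real_,
                            structureId = "structure_1") {
  if (nchar(sequence) != nchar(db))
    stop("sequence (", nchar(sequence), " nt) and structure (", nchar(db),
         " characters) have different lengths")
  ch <- strsplit(db, "")[[1]]
  if (any(!ch %in% c("(", ")", ".")))
    stop("dot-bracket string contains characters other than '(', ')', '.'")
  n <- length(ch)
  pairs <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack))
        stop("unbalanced dot-bracket string: unmatched ')' at position ", i)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pairs[i] <- j
      pairs[j] <- i
    }
  }
  if (length(stack))
    stop("unbalanced dot-bracket string: unmatched '(' at position ",
         stack[1])
  PairingTable(sequence, pairs, energy, structureId)
}

#' Write structures to CT format
#'
#' Writes one or more [PairingTable-class] objects as concatenated
#' six-column CT records with `dG =` headers, the format consumed by
#' [parseCT()].
#'
#' @param structures A `PairingTable` or list of them.
#' @param file Output path or connection.
#' @return Invisibly, the path.
#' @export
writeCT <- function(structures, file) {
  if (is(structures, "PairingTable")) structures <- list(structures)
  con <- if (is.character(file)) base::file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  for (pt in structures) {
    n <- length(pt)
    e <- if (is.na(freeEnergy(pt))) 0 else freeEnergy(pt)
    writeLines(sprintf("%d\tdG = %.2f\t%s", n, e, structureId(pt)), con)
    base <- strsplit(structureSequence(pt), "")[[1]]
    writeLines(sprintf("%d\t%s\t%d\t%d\t%d\t%d",
                       seq_len(n), base, seq_len(n) - 1L,
                       c(seq_len(n - 1L) + 1L, 0L), basePairs(pt),
                       seq_len(n)), con)
  }
  invisible(file)
}

#' Convert a PairingTable to a dot-bracket string
#'
#' @param pt A [PairingTable-class].
#' @return Dot-bracket character string.
#' @export
toDotBracket <- function(pt) {
  p <- basePairs(pt)
  ch <- rep(".", length(p))
  ch[p > seq_along(p)] <- "("
  ch[p > 0L & p < seq_along(p)] <- ")"
  paste(ch, collapse = "")
}
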