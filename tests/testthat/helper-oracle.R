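# Independent brute-force loop-decomposition oracle.
#
# Classifies every position of a dot-bracket structure by local scanning:
# the enclosing pair of an unpaired position is found by exhaustive search
# over all pairs, and the loop content is walked position by position.
# Deliberately written with none of the machinery of the package's
# single-pass classifier so the two can check each other.

oraclePairs <- function(db) {
  ch <- strsplit(db, "")[[1]]
  n <- length(ch)
  p <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      p[i] <- stack[length(stack)]
      p[stack[length(stack)]] <- i
      stack <- stack[-length(stack)]
    }
  }
  p
}

# walk the loop closed by (i, j): returns child pairs and unpaired runs
oracleLoopContent <- function(p, i, j) {
  kids <- list()
  runs <- list()
  cur <- integer(0)
  t <- i + 1L
  while (t < j) {
    if (p[t] == 0L) {
      cur <- c(cur, t)
      t <- t + 1L
    } else {
      if (length(cur)) { runs[[length(runs) + 1L]] <- cur; cur <- integer(0) }
      kids[[length(kids) + 1L]] <- c(t, p[t])
      t <- p[t] + 1L
    }
  }
  if (length(cur)) runs[[length(runs) + 1L]] <- cur
  list(kids = kids, runs = runs)
}

# kind of every position, by independent per-position search
oracleKinds <- function(db) {
  p <- oraclePairs(db)
  n <- length(p)
  kind <- character(n)
  for (u in seq_len(n)) {
    if (p[u] != 0L) { kind[u] <- "helix"; next }
    # smallest enclosing pair by exhaustive search
    best <- NULL
    for (i in seq_len(n)) {
      if (p[i] > i && i < u && u < p[i]) {
        if (is.null(best) || (p[i] - i) < (best[2] - best[1]))
          best <- c(i, p[i])
      }
    }
    if (is.null(best)) { kind[u] <- "strand"; next }
    cont <- oracleLoopContent(p, best[1], best[2])
    K <- length(cont$kids)
    if (K == 0L) kind[u] <- "hairpin"
    else if (K >= 2L) kind[u] <- "junction"
    else {
      k <- cont$kids[[1]]
      left <- any(vapply(cont$runs, function(r) all(r < k[1]), TRUE))
      right <- any(vapply(cont$runs, function(r) all(r > k[2]), TRUE))
      kind[u] <- if (left && right) "interior" else "bulge"
    }
  }
  kind
}

# all valid dot-bracket strings of length n with hairpin size >= minHairpin
enumDotBrackets <- local({
  memo <- list()
  function(n, minHairpin = 3L) {
    key <- paste(n, minHairpin)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- if (n == 0L) "" else {
      res <- paste0(".", enumDotBrackets(n - 1L, minHairpin))
      k <- minHairpin + 2L
      while (k <= n) {
        for (a in enumDotBrackets(k - 2L, minHairpin))
          res <- c(res, paste0("(", a, ")",
                               enumDotBrackets(n - k, minHairpin)))
        k <- k + 1L
      }
      res
    }
    memo[[key]] <<- out
    out
  }
})

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

# small dot-bracket structures used across tests
FIX_DB <- "((..((....))..))"
FIX_SEQ <- "GCAAGGTTTTCCAAGC"
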