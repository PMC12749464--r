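# Independent oracle for the optimal-matching distance: exhaustive
# enumeration of all monotone alignments (each position matched at most
# once; matched pairs cost the substitution, unmatched positions cost one
# indel each). Independent of the dynamic program in the package.

subsetsCache <- local({
  cache <- list()
  function(n, k) {
    key <- paste(n, k)
    if (is.null(cache[[key]]))
      cache[[key]] <<- if (k == 0) matrix(integer(0), 0, 1)
                       else utils::combn(n, k)
    cache[[key]]
  }
})

omOracle <- function(i1, i2, sub, indel) {
  n1 <- length(i1); n2 <- length(i2)
  best <- (n1 + n2) * indel              # k = 0: delete all, insert all
  for (k in seq_len(min(n1, n2))) {
    S1 <- subsetsCache(n1, k)            # k x a subsets, increasing order
    S2 <- subsetsCache(n2, k)
    costs <- matrix((n1 - k + n2 - k) * indel, ncol(S1), ncol(S2))
    for (r in seq_len(k))
      costs <- costs + sub[i1[S1[r, ]], i2[S2[r, ]], drop = FALSE]
    best <- min(best, min(costs))
  }
  best
}

# random symmetric cost scheme over an alphabet; entries bounded away from
# zero so distances are positive for distinct states
randomScheme <- function(alphabet, lo = 0.5, hi = 2, indel = 1) {
  k <- length(alphabet)
  m <- matrix(0, k, k, dimnames = list(alphabet, alphabet))
  v <- runif(k * (k - 1) / 2, lo, hi)
  m[upper.tri(m)] <- v
  m <- m + t(m)
  new("CostScheme", sub = m, indel = indel, method = "FILE")
}

# all sequences of lengths 1..maxLen over an alphabet, as integer codes
allSequences <- function(nStates, maxLen) {
  out <- list()
  for (L in seq_len(maxLen)) {
    g <- as.matrix(expand.grid(rep(list(seq_len(nStates)), L)))
    out <- c(out, lapply(seq_len(nrow(g)), function(i) unname(g[i, ])))
  }
  out
}
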