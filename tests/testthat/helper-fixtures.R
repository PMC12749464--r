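# Shared fixtures built in code.

# the 4-point two-pair configuration: within-pair distance 0.2, between 1
twoPairD <- function() {
  d <- matrix(1, 4, 4, dimnames = list(paste0("p", 1:4), paste0("p", 1:4)))
  d[1, 2] <- d[2, 1] <- d[3, 4] <- d[4, 3] <- 0.2
  diag(d) <- 0
  d
}

# a tiny two-state cost scheme with sub(N,M) = 4/3 (the hand-derived TRATE
# value from the {"NNMM","NMMM"} toy) and indel 1
toySchemeNM <- function() {
  m <- matrix(c(0, 4 / 3, 4 / 3, 0), 2, 2,
              dimnames = list(c("N", "M"), c("N", "M")))
  new("CostScheme", sub = m, indel = 1, method = "FILE")
}

# a state-sequence set from a character vector of collapsed strings
seqSetFromStrings <- function(x, ids = sprintf("S%03d", seq_along(x))) {
  st <- do.call(rbind, strsplit(x, ""))
  dimnames(st) <- list(ids, paste0("a", SEQ_AGES))
  new("StateSequenceSet", states = st,
      imputed = matrix(FALSE, nrow(st), ncol(st), dimnames = dimnames(st)))
}

# random full-length sequences over the five states (not necessarily legal
# life courses; used for distance-property checks only)
randomSeqSet <- function(n, persist = 0.85) {
  st <- matrix("", n, 36)
  for (i in seq_len(n)) {
    s <- sample(PARTNER_STATES, 1)
    for (j in 1:36) {
      if (j > 1 && runif(1) > persist) s <- sample(PARTNER_STATES, 1)
      st[i, j] <- s
    }
  }
  dimnames(st) <- list(sprintf("R%04d", seq_len(n)), paste0("a", SEQ_AGES))
  new("StateSequenceSet", states = st,
      imputed = matrix(FALSE, n, 36, dimnames = dimnames(st)))
}
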