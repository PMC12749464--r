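# Optimal-matching dissimilarities with transition-rate substitution costs.

#' Estimate pooled year-to-year transition rates
#'
#' Counts all observed transitions (person, age t) -> (person, age t+1),
#' pooled over all ages 15-49 and all persons, and row-normalizes. States
#' never observed as a transition source get an all-zero row and are
#' flagged; [trateCosts()] assigns them the maximum substitution cost.
#'
#' @param seqs a [StateSequenceSet-class] (or bare character matrix)
#' @return list with \code{counts} (5x5 integer), \code{p} (5x5
#'   row-stochastic where defined) and \code{zeroRows} (character vector of
#'   flagged source states)
#' @export
estimateTransitionRates <- function(seqs) {
  st <- if (is(seqs, "StateSequenceSet")) seqStates(seqs) else seqs
  if (nrow(st) == 0) stop("empty sequence set")
  L <- ncol(st)
  from <- factor(st[, -L], levels = PARTNER_STATES)
  to <- factor(st[, -1], levels = PARTNER_STATES)
  counts <- table(from = from, to = to)
  counts <- matrix(as.integer(counts), 5, 5,
                   dimnames = list(from = PARTNER_STATES, to = PARTNER_STATES))
  rs <- rowSums(counts)
  p <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, p = p, zeroRows = PARTNER_STATES[rs == 0])
}

#' Transition-rate (TRATE) substitution costs
#'
#' The standard empirical cost scheme: for distinct states a, b the
#' substitution cost is \code{2 - p(b|a) - p(a|b)}, so frequently observed
#' transitions are cheap to substitute and never-observed ones cost the
#' maximum of 2. States never observed as a transition source fall back to
#' the maximum cost. The indel cost is fixed at 1.
#'
#' @param rates output of [estimateTransitionRates()]
#' @param indel insertion/deletion cost, default 1
#' @return a [CostScheme-class]
#' @export
trateCosts <- function(rates, indel = 1) {
  p <- rates$p
  sub <- 2 - p - t(p)
  diag(sub) <- 0
  if (length(rates$zeroRows)) {
    sub[rates$zeroRows, ] <- 2
    sub[, rates$zeroRows] <- 2
    diag(sub) <- 0
  }
  dimnames(sub) <- list(PARTNER_STATES, PARTNER_STATES)
  new("CostScheme", sub = sub, indel = indel, method = "TRATE")
}

#' Constant substitution costs
#'
#' All off-diagonal substitutions cost the same (default 2), indels 1.
#'
#' @param value off-diagonal substitution cost
#' @param indel insertion/deletion cost
#' @param alphabet state labels
#' @return a [CostScheme-class]
#' @export
constantCosts <- function(value = 2, indel = 1, alphabet = PARTNER_STATES) {
  k <- length(alphabet)
  sub <- matrix(value, k, k, dimnames = list(alphabet, alphabet))
  diag(sub) <- 0
  new("CostScheme", sub = sub, indel = indel, method = "CONSTANT")
}

#' Optimal-matching distance between two sequences
#'
#' Minimum total edit cost (substitutions at the scheme's costs, insertions
#' and deletions at the indel cost) transforming one sequence into the
#' other, by the standard dynamic program. Sequences may have different
#' lengths; states must belong to the scheme's alphabet.
#'
#' @param s1,s2 character vectors of states (or single collapsed strings)
#' @param scheme a [CostScheme-class]
#' @return nonnegative scalar distance
#' @export
#' @examples
#' sc <- constantCosts(value = 2, indel = 1, alphabet = c("N", "M"))
#' omDist(c("N", "M", "M"), c("M", "M", "M"), sc)
omDist <- function(s1, s2, scheme) {
  if (length(s1) == 1 && nchar(s1[1]) > 1) s1 <- strsplit(s1, "")[[1]]
  if (length(s2) == 1 && nchar(s2[1]) > 1) s2 <- strsplit(s2, "")[[1]]
  alpha <- rownames(scheme@sub)
  i1 <- match(s1, alpha); i2 <- match(s2, alpha)
  if (anyNA(i1) || anyNA(i2))
    stop("sequence contains states outside the scheme's alphabet")
  om_dist_pair_cpp(i1 - 1L, i2 - 1L, scheme@sub, scheme@indel)
}

#' Pairwise optimal-matching distance matrix
#'
#' Computes all pairwise [omDist()] values for a set of equal-length
#' sequences. Identical sequences are deduplicated before the dynamic
#' program runs and distances are broadcast back, so the result is
#' independent of input order.
#'
#' @param seqs a [StateSequenceSet-class] or character matrix of states
#' @param scheme a [CostScheme-class]
#' @return a [SeqDissimilarity-class]
#' @export
pairwiseMatrix <- function(seqs, scheme) {
  st <- if (is(seqs, "StateSequenceSet")) seqStates(seqs) else seqs
  if (nrow(st) == 0) stop("empty sequence set")
  alpha <- rownames(scheme@sub)
  code <- matrix(match(st, alpha), nrow(st), ncol(st))
  if (anyNA(code)) stop("sequences contain states outside the scheme's alphabet")
  key <- apply(st, 1, paste, collapse = "")
  uKey <- sort(unique(key))              # canonical order: dedup-order invariant
  uIdx <- match(uKey, key)
  dU <- om_dist_matrix_cpp(code[uIdx, , drop = FALSE] - 1L,
                           scheme@sub, scheme@indel)
  map <- match(key, uKey)
  d <- dU[map, map, drop = FALSE]
  dimnames(d) <- list(rownames(st), rownames(st))
  new("SeqDissimilarity", d = d)
}
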