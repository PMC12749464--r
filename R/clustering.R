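# Ward clustering of the OM dissimilarity matrix and cluster summaries.

#' Ward hierarchical clustering of a dissimilarity matrix
#'
#' Agglomerative clustering under the Ward minimum-variance criterion via
#' Lance-Williams updates. The default \code{"ward.D2"} variant squares the
#' dissimilarities internally and reports merge heights back on the
#' distance scale; \code{"ward.D"} applies the updates to the raw
#' dissimilarities.
#'
#' @param D a [SeqDissimilarity-class], \code{dist} or symmetric matrix
#' @param variant \code{"ward.D2"} (default) or \code{"ward.D"}
#' @return an object of class \code{hclust}
#' @export
wardLinkage <- function(D, variant = c("ward.D2", "ward.D")) {
  variant <- match.arg(variant)
  d <- toDist(D)
  if (attr(d, "Size") < 2) stop("need at least 2 observations")
  hclust(d, method = variant)
}

toDist <- function(D) {
  if (is(D, "SeqDissimilarity")) return(as.dist(D@d))
  if (inherits(D, "dist")) return(D)
  as.dist(D)
}

toDistMatrix <- function(D) {
  if (is(D, "SeqDissimilarity")) return(D@d)
  if (inherits(D, "dist")) return(as.matrix(D))
  as.matrix(D)
}

#' Cut a linkage tree into k clusters
#'
#' Labels come from the k-cluster level of the tree and are renumbered so
#' that cluster 1 is the largest; ties in size are broken by the smallest
#' member index. The relabelling makes solutions stable across runs.
#'
#' @param tree an \code{hclust} object from [wardLinkage()]
#' @param k number of clusters (default 6)
#' @return a [ClusterSolution-class]
#' @export
cutTree <- function(tree, k = 6) {
  n <- length(tree$order)
  if (k < 1 || k > n) stop("k out of range 1..", n)
  raw <- cutree(tree, k = k)
  lab <- renumberLabels(raw, k)
  new("ClusterSolution", labels = lab, k = as.integer(k),
      tree = unclass(tree))
}

renumberLabels <- function(raw, k) {
  sizes <- tabulate(raw, nbins = k)
  firstMember <- vapply(seq_len(k), function(c) min(which(raw == c)), 0L)
  newOrder <- order(-sizes, firstMember)
  remap <- integer(k); remap[newOrder] <- seq_len(k)
  out <- as.integer(remap[raw])
  names(out) <- names(raw)
  out
}

#' Silhouette widths for a partition of a dissimilarity matrix
#'
#' For each observation, \code{s(i) = (b_i - a_i) / max(a_i, b_i)} where
#' \code{a_i} is the mean distance to its own cluster (excluding itself)
#' and \code{b_i} the smallest mean distance to another cluster. Members of
#' singleton clusters get \code{s(i) = 0}. ASW is the unweighted mean.
#'
#' @param D dissimilarities ([SeqDissimilarity-class], \code{dist} or matrix)
#' @param labels integer cluster labels (or a [ClusterSolution-class])
#' @return list with \code{widths} (per-observation) and \code{asw}
#' @export
silhouetteWidths <- function(D, labels) {
  if (is(labels, "ClusterSolution")) labels <- clusterLabels(labels)
  m <- toDistMatrix(D)
  n <- nrow(m)
  stopifnot(length(labels) == n)
  k <- length(unique(labels))
  if (k < 2) stop("silhouette needs at least 2 clusters")
  G <- outer(labels, sort(unique(labels)), "==") * 1  # n x k membership
  sums <- m %*% G                                     # distance sums to clusters
  sizes <- colSums(G)
  own <- match(labels, sort(unique(labels)))
  a <- sums[cbind(seq_len(n), own)] / pmax(sizes[own] - 1, 1)
  meanOther <- sweep(sums, 2, sizes, "/")
  meanOther[cbind(seq_len(n), own)] <- Inf
  b <- apply(meanOther, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[own] == 1] <- 0
  s[!is.finite(s)] <- 0                               # a = b = 0 degenerate
  list(widths = setNames(s, rownames(m)), asw = mean(s))
}

# Discrepancy-based sum of squares for dissimilarity data:
# SS(A) = (1 / (2|A|)) * sum_{i,j in A} d_ij^2.
ssDiscrepancy <- function(m2, idx) sum(m2[idx, idx]) / (2 * length(idx))

#' Cluster-quality indices
#'
#' Computes the standard suite reported for sequence typologies:
#' \describe{
#'   \item{ASW}{average silhouette width ([silhouetteWidths()]).}
#'   \item{R2}{\code{1 - W/T} with T, W the total and pooled within-cluster
#'     discrepancies of the squared dissimilarities.}
#'   \item{CH}{Calinski-Harabasz pseudo-F \code{(B/(k-1)) / (W/(n-k))}.}
#'   \item{HG}{Hubert's Gamma: the Goodman-Kruskal concordance
#'     \code{(C - D)/(C + D)} over all (within-pair, between-pair)
#'     comparisons; C counts within-cluster distances smaller than
#'     between-cluster ones, D the reverse; ties are dropped. Computed
#'     exactly at any n by rank counting.}
#'   \item{HC}{Hubert's C: \code{(S - Smin)/(Smax - Smin)} where S is the
#'     within-cluster distance sum over the m within-cluster pairs and
#'     Smin/Smax are the sums of the m smallest/largest distances overall.}
#' }
#'
#' @param D dissimilarities ([SeqDissimilarity-class], \code{dist} or matrix)
#' @param labels integer cluster labels (or a [ClusterSolution-class])
#' @return a [QualityReport-class]
#' @export
qualityIndices <- function(D, labels) {
  if (is(labels, "ClusterSolution")) labels <- clusterLabels(labels)
  m <- toDistMatrix(D)
  n <- nrow(m)
  stopifnot(length(labels) == n)
  k <- length(unique(labels))
  if (k < 2 || n <= k) stop("need 2 <= k < n")

  m2 <- m^2
  Tot <- ssDiscrepancy(m2, seq_len(n))
  if (Tot <= 0) stop("degenerate dissimilarity matrix: total discrepancy is 0")
  W <- sum(vapply(split(seq_len(n), labels), function(ix)
    ssDiscrepancy(m2, ix), 0))
  B <- Tot - W
  r2 <- 1 - W / Tot
  ch <- (B / (k - 1)) / (W / (n - k))

  ut <- upper.tri(m)
  same <- outer(labels, labels, "==")
  dw <- m[ut & same]
  db <- m[ut & !same]
  hg <- hubertGamma(dw, db)

  allD <- sort(m[ut])
  mw <- length(dw)
  S <- sum(dw)
  Smin <- sum(allD[seq_len(mw)])
  Smax <- sum(allD[seq.int(length(allD) - mw + 1, length(allD))])
  hc <- if (Smax > Smin) (S - Smin) / (Smax - Smin) else 0

  sil <- silhouetteWidths(m, labels)
  new("QualityReport", asw = sil$asw, r2 = r2, ch = ch, hg = hg, hc = hc,
      k = as.integer(k), n = as.integer(n))
}

# Exact concordance between within- and between-cluster distances via
# sorted rank counting: for each within distance, the number of strictly
# larger between distances (concordant) and strictly smaller ones
# (discordant), summed; ties drop out of both counts.
hubertGamma <- function(dw, db) {
  if (!length(dw) || !length(db)) return(NA_real_)
  sb <- sort(db)
  nb <- length(sb)
  lower <- findInterval(dw, sb, left.open = TRUE)  # strictly smaller betweens
  geq <- findInterval(dw, sb)                      # betweens <= dw
  C <- sum(nb - geq)                               # betweens strictly larger
  Dn <- sum(lower)
  if (C + Dn == 0) return(0)
  (C - Dn) / (C + Dn)
}

#' Quality indices across a range of k
#'
#' Cuts the tree at each k and tabulates the five quality indices, the
#' standard table used to motivate the retained number of clusters. No
#' automatic selection is performed.
#'
#' @param D dissimilarities
#' @param tree \code{hclust} tree from [wardLinkage()]
#' @param kRange integer vector of cluster counts to evaluate
#' @return data.frame with columns k, asw, r2, ch, hg, hc
#' @export
qualityScan <- function(D, tree, kRange = 2:10) {
  rows <- lapply(kRange, function(k) {
    q <- qualityIndices(D, cutTree(tree, k))
    data.frame(k = k, asw = q@asw, r2 = q@r2, ch = q@ch, hg = q@hg, hc = q@hc)
  })
  do.call(rbind, rows)
}

#' Per-cluster summaries used for labelling
#'
#' For each cluster: size, share of the sample, the 5 x 36 state
#' distribution, and the mean and median age at first marriage (the first
#' age at state M), computed over members who ever marry; never-married
#' members are counted separately.
#'
#' @param seqs a [StateSequenceSet-class]
#' @param labels integer cluster labels (or a [ClusterSolution-class])
#' @return named list, one element per cluster, each with \code{size},
#'   \code{share}, \code{stateDist}, \code{meanAgeFirstMarriage},
#'   \code{medianAgeFirstMarriage}, \code{nNeverMarried}
#' @export
summarizeClusters <- function(seqs, labels) {
  if (is(labels, "ClusterSolution")) labels <- clusterLabels(labels)
  st <- seqStates(seqs)
  stopifnot(length(labels) == nrow(st))
  afm <- apply(st, 1, function(s) {
    i <- which(s == "M")[1]
    if (is.na(i)) NA_real_ else SEQ_AGES[i]
  })
  n <- nrow(st)
  out <- lapply(split(seq_len(n), labels), function(ix) {
    ages <- afm[ix]
    list(
      size = length(ix),
      share = length(ix) / n,
      stateDist = stateDistribution(
        new("StateSequenceSet", states = st[ix, , drop = FALSE],
            imputed = matrix(FALSE, length(ix), ncol(st),
                             dimnames = dimnames(st[ix, , drop = FALSE])))),
      meanAgeFirstMarriage = if (all(is.na(ages))) NA_real_
                             else mean(ages, na.rm = TRUE),
      medianAgeFirstMarriage = if (all(is.na(ages))) NA_real_
                               else median(ages, na.rm = TRUE),
      nNeverMarried = sum(is.na(ages))
    )
  })
  names(out) <- paste0("cluster", names(out))
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same
#' observations; 1 means identical partitions, 0 the expected agreement of
#' random labelings.
#'
#' @param a,b integer/factor label vectors of equal length
#' @return scalar in (-1, 1]
#' @export
adjustedRand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) sum(x * (x - 1) / 2)
  sumIJ <- comb2(as.numeric(tab))
  sumI <- comb2(rowSums(tab))
  sumJ <- comb2(colSums(tab))
  nPairs <- comb2(length(a))
  expected <- sumI * sumJ / nPairs
  maxIdx <- (sumI + sumJ) / 2
  if (maxIdx == expected) return(1)
  (sumIJ - expected) / (maxIdx - expected)
}
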