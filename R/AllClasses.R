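# Central S4 containers. Sequences are stored as a dense character matrix
# (persons x 36 ages); dissimilarities as a dense symmetric numeric matrix.

#' StateSequenceSet: yearly partnership-state sequences
#'
#' Holds one row per person of yearly partnership states for ages 15-50
#' (36 positions over the alphabet \code{N, M, R, D, W}) together with a
#' logical mask of positions filled by LOCF imputation.
#'
#' @slot states character matrix, persons x 36, rownames are person ids,
#'   colnames \code{a15..a50}.
#' @slot imputed logical matrix of the same shape; \code{TRUE} where the
#'   state was filled by carrying the previous observed state forward.
#' @slot alphabet character vector of valid states.
#'
#' @seealso [buildCohort()], [stateDistribution()], [readSequences()]
#' @export
setClass("StateSequenceSet",
  representation(
    states   = "matrix",
    imputed  = "matrix",
    alphabet = "character"
  ),
  prototype(alphabet = c("N", "M", "R", "D", "W"))
)

setValidity("StateSequenceSet", function(object) {
  msg <- NULL
  st <- object@states
  if (!is.character(st)) msg <- c(msg, "states must be a character matrix")
  if (ncol(st) != length(SEQ_AGES))
    msg <- c(msg, sprintf("states must have %d columns (ages 15-50)", length(SEQ_AGES)))
  bad <- !(st %in% object@alphabet)
  if (any(bad))
    msg <- c(msg, sprintf("%d states outside alphabet {%s}",
                          sum(bad), paste(object@alphabet, collapse = ",")))
  if (!identical(dim(object@imputed), dim(st)))
    msg <- c(msg, "imputed mask must match the shape of states")
  if (is.null(rownames(st)) && nrow(st) > 0)
    msg <- c(msg, "states must carry person ids as rownames")
  if (anyDuplicated(rownames(st)))
    msg <- c(msg, "person ids must be unique")
  if (is.null(msg)) TRUE else msg
})

#' CostScheme: substitution-cost matrix plus indel cost
#'
#' @slot sub symmetric numeric substitution-cost matrix with zero diagonal,
#'   rows/columns labelled by state.
#' @slot indel scalar insertion/deletion cost (default 1).
#' @slot method character tag recording how the costs were derived
#'   (\code{"TRATE"}, \code{"CONSTANT"} or \code{"FILE"}).
#'
#' @seealso [trateCosts()], [constantCosts()], [omDist()]
#' @export
setClass("CostScheme",
  representation(sub = "matrix", indel = "numeric", method = "character"),
  prototype(indel = 1, method = "TRATE")
)

setValidity("CostScheme", function(object) {
  msg <- NULL
  s <- object@sub
  if (nrow(s) != ncol(s)) msg <- c(msg, "sub must be square")
  if (is.null(rownames(s)) || !identical(rownames(s), colnames(s)))
    msg <- c(msg, "sub must have identical state labels on rows and columns")
  if (any(abs(s - t(s)) > 1e-12)) msg <- c(msg, "sub must be symmetric")
  if (any(diag(s) != 0)) msg <- c(msg, "sub must have a zero diagonal")
  if (any(s < 0)) msg <- c(msg, "sub costs must be nonnegative")
  if (length(object@indel) != 1 || object@indel <= 0)
    msg <- c(msg, "indel must be a positive scalar")
  if (is.null(msg)) TRUE else msg
})

#' SeqDissimilarity: pairwise optimal-matching distances
#'
#' @slot d symmetric nonnegative numeric matrix with zero diagonal;
#'   dimnames are person ids.
#'
#' @seealso [pairwiseMatrix()], [wardLinkage()]
#' @export
setClass("SeqDissimilarity", representation(d = "matrix"))

setValidity("SeqDissimilarity", function(object) {
  msg <- NULL
  d <- object@d
  if (nrow(d) != ncol(d)) msg <- c(msg, "d must be square")
  if (any(abs(d - t(d)) > 1e-9)) msg <- c(msg, "d must be symmetric")
  if (any(diag(d) != 0)) msg <- c(msg, "d must have zero diagonal")
  if (any(d < 0)) msg <- c(msg, "d must be nonnegative")
  if (is.null(rownames(d)) && nrow(d) > 0) msg <- c(msg, "d must carry ids")
  if (is.null(msg)) TRUE else msg
})

#' ClusterSolution: a k-cluster partition of sequences
#'
#' Labels are integers 1..k aligned to person ids, renumbered so cluster 1
#' is the largest (ties broken by smallest member id).
#'
#' @slot labels named integer vector of cluster ids.
#' @slot k number of clusters.
#' @slot tree the \code{hclust} object the partition was cut from (may be
#'   a zero-length list when labels were loaded from file).
#'
#' @seealso [cutTree()], [qualityIndices()], [summarizeClusters()]
#' @export
setClass("ClusterSolution",
  representation(labels = "integer", k = "integer", tree = "list")
)

setValidity("ClusterSolution", function(object) {
  msg <- NULL
  lab <- object@labels
  if (is.null(names(lab))) msg <- c(msg, "labels must be named by person id")
  if (length(lab) && (min(lab) < 1L || max(lab) > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (length(lab) && length(unique(lab)) != object@k)
    msg <- c(msg, "every cluster must be nonempty")
  if (is.null(msg)) TRUE else msg
})

#' QualityReport: cluster-quality indices
#'
#' @slot asw average silhouette width, in [-1, 1].
#' @slot r2 share of discrepancy explained, in [0, 1].
#' @slot ch Calinski-Harabasz pseudo-F, nonnegative.
#' @slot hg Hubert's Gamma (concordance of distances with the partition),
#'   in [-1, 1].
#' @slot hc Hubert's C index (normalized within-cluster distance sum),
#'   in [0, 1]; lower is better.
#' @slot k,n number of clusters and observations.
#'
#' @seealso [qualityIndices()]
#' @export
setClass("QualityReport",
  representation(asw = "numeric", r2 = "numeric", ch = "numeric",
                 hg = "numeric", hc = "numeric", k = "integer", n = "integer")
)

#' TrajModelFit: one fitted model specification
#'
#' A light wrapper around a fitted multinomial-logit, ordered-logit,
#' negative-binomial or logistic model carrying a tidy coefficient table
#' and fit statistics.
#'
#' @slot family one of \code{"multinomial_logit"}, \code{"ordered_logit"},
#'   \code{"negative_binomial"}, \code{"logistic"}.
#' @slot tidy data.frame with columns term, (outcome level for multinomial),
#'   estimate, se, z, p, stars.
#' @slot cutpoints named numeric vector of ordered-logit cutpoints
#'   (length 0 otherwise).
#' @slot lnalpha NB2 log-dispersion and its standard error (length 0
#'   otherwise).
#' @slot logLik,logLikNull,pseudoR2McFadden,pseudoR2CoxSnell,n fit statistics.
#' @slot converged logical convergence flag.
#' @slot fit the underlying fitted object (\code{multinom}, \code{polr},
#'   \code{negbin} or \code{glm}).
#'
#' @seealso [fitMultinomial()], [fitOrderedLogit()], [fitNegbin()]
#' @export
setClass("TrajModelFit",
  representation(
    family = "character", tidy = "data.frame",
    cutpoints = "numeric", lnalpha = "numeric",
    logLik = "numeric", logLikNull = "numeric",
    pseudoR2McFadden = "numeric", pseudoR2CoxSnell = "numeric",
    n = "integer", converged = "logical", fit = "ANY"
  )
)
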