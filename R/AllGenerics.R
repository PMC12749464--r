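# Accessors and show methods.

#' Extract person ids
#' @param x a StateSequenceSet, SeqDissimilarity or ClusterSolution
#' @return character vector of person ids, in row order
#' @export
setGeneric("personIds", function(x) standardGeneric("personIds"))

#' @rdname personIds
#' @export
setMethod("personIds", "StateSequenceSet", function(x) rownames(x@states))

#' @rdname personIds
#' @export
setMethod("personIds", "SeqDissimilarity", function(x) rownames(x@d))

#' @rdname personIds
#' @export
setMethod("personIds", "ClusterSolution", function(x) names(x@labels))

#' Extract the state matrix
#' @param x a StateSequenceSet
#' @return character matrix persons x 36 ages
#' @export
setGeneric("seqStates", function(x) standardGeneric("seqStates"))

#' @rdname seqStates
#' @export
setMethod("seqStates", "StateSequenceSet", function(x) x@states)

#' Extract the imputation mask
#' @param x a StateSequenceSet
#' @return logical matrix marking LOCF-filled positions
#' @export
setGeneric("imputedMask", function(x) standardGeneric("imputedMask"))

#' @rdname imputedMask
#' @export
setMethod("imputedMask", "StateSequenceSet", function(x) x@imputed)

#' Extract cluster labels
#' @param x a ClusterSolution
#' @return named integer vector of cluster ids 1..k
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname clusterLabels
#' @export
setMethod("clusterLabels", "ClusterSolution", function(x) x@labels)

#' Substitution costs and indel cost
#' @param x a CostScheme
#' @return for `subCosts`, the symmetric substitution-cost matrix; for
#'   `indelCost`, the scalar insertion/deletion cost
#' @export
setGeneric("subCosts", function(x) standardGeneric("subCosts"))

#' @rdname subCosts
#' @export
setMethod("subCosts", "CostScheme", function(x) x@sub)

#' @rdname subCosts
#' @export
setGeneric("indelCost", function(x) standardGeneric("indelCost"))

#' @rdname subCosts
#' @export
setMethod("indelCost", "CostScheme", function(x) x@indel)

#' @export
#' @describeIn qualityIndices coerce a QualityReport to a named numeric vector
setMethod("as.numeric", "QualityReport", function(x, ...) {
  c(asw = x@asw, r2 = x@r2, ch = x@ch, hg = x@hg, hc = x@hc)
})

#' Coerce a SeqDissimilarity to a base matrix
#' @param x a SeqDissimilarity
#' @param ... unused
#' @export
setMethod("as.matrix", "SeqDissimilarity", function(x, ...) x@d)

setMethod("show", "StateSequenceSet", function(object) {
  n <- nrow(object@states)
  cat("StateSequenceSet:", n, "sequences x", ncol(object@states),
      "ages (15-50), alphabet {", paste(object@alphabet, collapse = ","),
      "}\n")
  cat(sprintf("  imputed positions: %d (%.2f%%)\n",
              sum(object@imputed), 100 * mean(object@imputed)))
  if (n > 0) {
    k <- min(n, 3L)
    for (i in seq_len(k))
      cat("  ", rownames(object@states)[i], ": ",
          paste(object@states[i, ], collapse = ""), "\n", sep = "")
    if (n > k) cat("  ...\n")
  }
})

setMethod("show", "CostScheme", function(object) {
  cat("CostScheme (", object@method, "), indel = ", object@indel, "\n", sep = "")
  print(round(object@sub, 4))
})

setMethod("show", "SeqDissimilarity", function(object) {
  cat("SeqDissimilarity:", nrow(object@d), "x", ncol(object@d),
      "optimal-matching distances\n")
  if (nrow(object@d) > 1) {
    up <- object@d[upper.tri(object@d)]
    cat(sprintf("  range %.4f-%.4f, mean %.4f\n", min(up), max(up), mean(up)))
  }
})

setMethod("show", "ClusterSolution", function(object) {
  cat("ClusterSolution: k =", object@k, "over", length(object@labels),
      "sequences\n")
  print(table(cluster = object@labels))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf(
    "QualityReport (k = %d, n = %d)\n  ASW %.4f | R2 %.4f | CH %.1f | HG %.4f | HC %.4f\n",
    object@k, object@n, object@asw, object@r2, object@ch, object@hg, object@hc))
})

setMethod("show", "TrajModelFit", function(object) {
  cat("TrajModelFit:", object@family, "| n =", object@n,
      "| logLik =", format(object@logLik, digits = 6),
      "| McFadden R2 =", format(object@pseudoR2McFadden, digits = 4), "\n")
  if (!object@converged) cat("  ** did not converge **\n")
  print(head(object@tidy, 12), digits = 4)
  if (nrow(object@tidy) > 12) cat("  ... (", nrow(object@tidy), "rows )\n")
})
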