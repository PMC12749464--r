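# Polygenic score computation: PGS_i = sum_j W_j * G_ij over effect-allele
# dosages, with negative GWAS weights resolved by allele flipping.

#' Flip SNPs with negative weights
#'
#' For every SNP with a negative weight, the effect and other alleles are
#' swapped, the weight is negated, and dosages are recoded as \code{2 - G}
#' so that all effect sizes are positive. Standardized scores are invariant
#' to this recoding.
#'
#' @param weights data.frame with columns \code{snp_id},
#'   \code{effect_allele}, \code{other_allele}, \code{weight}
#' @param G numeric matrix of dosages in \{0, 1, 2\} (persons x SNPs),
#'   columns aligned to \code{weights$snp_id}
#' @return list with flipped \code{weights} and \code{G}
#' @export
flipNegativeWeights <- function(weights, G) {
  checkAligned(weights, G)
  neg <- weights$weight < 0
  if (any(neg)) {
    ea <- weights$effect_allele[neg]
    weights$effect_allele[neg] <- weights$other_allele[neg]
    weights$other_allele[neg] <- ea
    weights$weight[neg] <- -weights$weight[neg]
    G[, neg] <- 2 - G[, neg]
  }
  list(weights = weights, G = G)
}

checkAligned <- function(weights, G) {
  if (anyDuplicated(weights$snp_id)) stop("duplicate snp ids in weight table")
  if (is.null(colnames(G)) || !identical(colnames(G), weights$snp_id)) {
    missing <- setdiff(weights$snp_id, colnames(G))
    extra <- setdiff(colnames(G), weights$snp_id)
    stop("genotype columns misaligned with weight table",
         if (length(missing)) paste0("; missing: ",
                                     paste(head(missing, 5), collapse = ",")),
         if (length(extra)) paste0("; extra: ",
                                   paste(head(extra, 5), collapse = ",")))
  }
  bad <- !(G %in% 0:2)
  if (any(bad)) {
    if (any(G < 0 | G > 2)) stop("dosages must lie in [0, 2]")
    warning("fractional imputed dosages detected; accepted as-is")
  }
  invisible(TRUE)
}

#' Compute raw and standardized polygenic scores
#'
#' \code{raw_i = sum_j W_j G_ij}; \code{z} standardizes raw scores to mean
#' 0 and SD 1 within the scored sample. Call [flipNegativeWeights()] first
#' when the weight table contains negative effect sizes.
#'
#' @inheritParams flipNegativeWeights
#' @return data.frame with columns \code{person_id}, \code{raw}, \code{z}
#' @export
#' @examples
#' w <- data.frame(snp_id = c("s1", "s2"), effect_allele = c("A", "C"),
#'                 other_allele = c("G", "T"), weight = c(0.2, 0.3))
#' G <- matrix(c(2, 1), 1, 2, dimnames = list("p1", c("s1", "s2")))
#' computePGS(w, G)$raw  # 0.7
computePGS <- function(weights, G) {
  checkAligned(weights, G)
  raw <- as.numeric(G %*% weights$weight)
  s <- sd(raw)
  z <- if (is.na(s) || s == 0) rep(0, length(raw)) else (raw - mean(raw)) / s
  data.frame(person_id = rownames(G), raw = raw, z = z,
             stringsAsFactors = FALSE)
}
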