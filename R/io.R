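# Plain-text interchange formats. All round-trip losslessly.

#' Read and write the persons and marriages tables
#'
#' Persons: CSV \code{person_id,birth_year,gender}. Marriages: CSV
#' \code{person_id,order,start_year,end_year,end_reason} with a blank
#' \code{end_year} meaning ongoing and \code{end_reason} in
#' \{divorce, widowhood, ongoing\}.
#'
#' @param path file path
#' @return data.frame
#' @export
readPersons <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "birth_year", "gender")
  if (!all(need %in% names(df)))
    stop("persons file must have columns: ", paste(need, collapse = ","))
  df$person_id <- as.character(df$person_id)
  df
}

#' @rdname readPersons
#' @export
readMarriages <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("person_id", "order", "start_year", "end_year", "end_reason")
  if (!all(need %in% names(df)))
    stop("marriages file must have columns: ", paste(need, collapse = ","))
  df$person_id <- as.character(df$person_id)
  df$end_year <- suppressWarnings(as.integer(df$end_year))
  bad <- !(is.na(df$end_reason) | df$end_reason %in%
             c("divorce", "widowhood", "ongoing", ""))
  if (any(bad))
    stop("invalid end_reason at rows: ",
         paste(head(which(bad), 5), collapse = ","))
  df$end_reason[df$end_reason == ""] <- NA_character_
  df
}

#' Read/write sequences as wide STS-style CSV
#'
#' One row per person: \code{person_id,a15,...,a50} with single-character
#' states.
#'
#' @param seqs a [StateSequenceSet-class]
#' @param path file path
#' @return \code{readSequences} returns a [StateSequenceSet-class];
#'   \code{writeSequences} returns the path invisibly
#' @export
writeSequences <- function(seqs, path) {
  st <- seqStates(seqs)
  df <- data.frame(person_id = rownames(st), st, stringsAsFactors = FALSE,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeSequences
#' @export
readSequences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character")
  stopifnot(names(df)[1] == "person_id",
            identical(names(df)[-1], paste0("a", SEQ_AGES)))
  st <- as.matrix(df[, -1])
  rownames(st) <- df$person_id
  new("StateSequenceSet", states = st,
      imputed = matrix(FALSE, nrow(st), ncol(st), dimnames = dimnames(st)))
}

#' Read/write a cost scheme
#'
#' The substitution matrix goes to a state-labelled 5x5 CSV; the indel
#' cost and derivation method to a YAML sidecar \code{<path>.yaml}.
#'
#' @param scheme a [CostScheme-class]
#' @param path CSV path
#' @return \code{readCostScheme} returns a [CostScheme-class]
#' @export
writeCostScheme <- function(scheme, path) {
  write.csv(data.frame(state = rownames(scheme@sub), scheme@sub,
                       check.names = FALSE),
            path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(indel = scheme@indel, method = scheme@method),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname writeCostScheme
#' @export
readCostScheme <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sub <- as.matrix(df[, -1])
  rownames(sub) <- df$state
  side <- yaml::read_yaml(paste0(path, ".yaml"))
  new("CostScheme", sub = sub, indel = side$indel,
      method = if (is.null(side$method)) "FILE" else side$method)
}

#' Read/write a distance matrix as square CSV
#'
#' Ids in the header row and first column.
#'
#' @param D a [SeqDissimilarity-class]
#' @param path file path
#' @return \code{readDistances} returns a [SeqDissimilarity-class]
#' @export
writeDistances <- function(D, path) {
  d <- as.matrix(D)
  write.csv(data.frame(person_id = rownames(d), d, check.names = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeDistances
#' @export
readDistances <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  d <- as.matrix(df[, -1])
  rownames(d) <- as.character(df$person_id)
  colnames(d) <- rownames(d)
  new("SeqDissimilarity", d = d)
}

#' Write cluster labels and quality report
#'
#' Labels: CSV \code{person_id,cluster}. Quality: JSON with the five
#' indices plus k and n.
#'
#' @param solution a [ClusterSolution-class]
#' @param quality a [QualityReport-class]
#' @param path file path
#' @return the path, invisibly
#' @export
writeLabels <- function(solution, path) {
  lab <- clusterLabels(solution)
  write.csv(data.frame(person_id = names(lab), cluster = unname(lab)),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeLabels
#' @export
readLabels <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  lab <- setNames(as.integer(df$cluster), as.character(df$person_id))
  new("ClusterSolution", labels = lab, k = length(unique(lab)),
      tree = list())
}

#' @rdname writeLabels
#' @export
writeQuality <- function(quality, path) {
  jsonlite::write_json(
    list(asw = quality@asw, r2 = quality@r2, ch = quality@ch,
         hg = quality@hg, hc = quality@hc, k = quality@k, n = quality@n),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
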