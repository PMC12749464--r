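# Sequence construction: event records -> yearly state sequences.
#
# Event-year convention: the year of an event takes the NEW state (a marriage
# year is coded M/R, a dissolution year D/W). When two events fall in the
# same calendar year the later-ordered event wins.

#' Legal partnership-state transition rules
#'
#' Returns the 5x5 logical matrix of legal year-to-year transitions.
#' A married (M) or remarried (R) person can only stay put or move to
#' divorced (D) or widowed (W); never back to not-married (N). D and W can
#' only persist or move to remarried. N can persist or marry; N -> D and
#' N -> W are legal only when a prior marriage occurred earlier in the
#' sequence (that relaxation is applied by [validateSequence()], not encoded
#' here).
#'
#' @return logical matrix with from-states on rows, to-states on columns
#' @export
transitionRules <- function() {
  s <- PARTNER_STATES
  legal <- matrix(FALSE, 5, 5, dimnames = list(from = s, to = s))
  diag(legal) <- TRUE
  legal["N", "M"] <- TRUE
  legal["M", c("D", "W")] <- TRUE
  legal["R", c("D", "W")] <- TRUE
  legal["D", "R"] <- TRUE
  legal["W", "R"] <- TRUE
  legal
}

# Normalize one person's marriage records: sorted by start year, order
# re-checked. Returns the data.frame or a character exclusion reason.
cleanRecords <- function(rec) {
  if (nrow(rec) == 0) return(rec)
  rec <- rec[order(rec$start_year, rec$order), , drop = FALSE]
  if (any(!is.na(rec$end_year) & rec$end_year < rec$start_year))
    return("end_before_start")
  if (nrow(rec) > 1) {
    for (j in seq_len(nrow(rec) - 1)) {
      ej <- rec$end_year[j]
      if (is.na(ej)) return("overlapping_records")   # open marriage not last
      if (rec$start_year[j + 1] < ej) return("overlapping_records")
    }
  }
  rec$order <- seq_len(nrow(rec))
  rec
}

#' Assign yearly partnership states from marriage records
#'
#' Maps one person's cleaned marriage/dissolution records onto calendar
#' years \code{birth_year + 15 .. birth_year + 50}. Before the first
#' marriage the state is N; a marriage of order 1 contributes M from its
#' start year, any later marriage contributes R; a dissolution year takes
#' D (divorce) or W (widowhood) which then persists until the next
#' marriage. A closed marriage with no recorded end reason leaves the
#' positions from its end year onward undetermined (\code{NA}), to be
#' imputed or excluded downstream.
#'
#' @param birthYear calendar birth year
#' @param records data.frame with columns \code{order}, \code{start_year},
#'   \code{end_year} (NA = ongoing) and \code{end_reason}
#'   (\code{divorce}, \code{widowhood}, \code{ongoing} or NA)
#' @return character vector of length 36 (ages 15-50), possibly with NAs
#' @export
#' @examples
#' recs <- data.frame(order = 1:2, start_year = c(1970, 1985),
#'                    end_year = c(1980, NA),
#'                    end_reason = c("divorce", NA))
#' assignStates(1950, recs)
assignStates <- function(birthYear, records) {
  if (is.na(birthYear)) stop("missing birth year")
  years <- birthYear + SEQ_AGES
  if (nrow(records) == 0)
    return(setNames(rep("N", length(years)), paste0("a", SEQ_AGES)))

  # Build the chronological event list: (year, new state). NA state marks
  # an undetermined stretch (closed marriage, end reason missing).
  evYear <- integer(0); evState <- character(0)
  for (j in seq_len(nrow(records))) {
    st <- if (records$order[j] == 1L) "M" else "R"
    evYear <- c(evYear, records$start_year[j]); evState <- c(evState, st)
    ey <- records$end_year[j]
    if (!is.na(ey)) {
      er <- records$end_reason[j]
      ds <- if (!is.na(er) && er == "divorce") "D"
            else if (!is.na(er) && er == "widowhood") "W"
            else if (!is.na(er) && er == "ongoing") NA_character_  # treated as open
            else NA_character_
      if (is.na(er) || er %in% c("divorce", "widowhood")) {
        evYear <- c(evYear, ey); evState <- c(evState, ds)
      }
    }
  }
  ord <- order(evYear)                 # stable: later-generated event wins ties
  evYear <- evYear[ord]; evState <- evState[ord]

  idx <- findInterval(years, evYear)   # last event at or before each year
  out <- ifelse(idx == 0L, "N", evState[pmax(idx, 1L)])
  setNames(out, paste0("a", SEQ_AGES))
}

#' Impute interior gaps by carrying the last observed state forward
#'
#' Fills each undetermined position with the nearest preceding observed
#' state (LOCF). Leading missing positions cannot be invented: the person
#' is flagged invalid. Observed positions are never altered.
#'
#' @param states character vector of length 36, NAs marking gaps
#' @return list with \code{states} (gap-free vector), \code{imputed}
#'   (logical mask), and \code{valid} (FALSE with a \code{reason} of
#'   \code{"all_missing"} or \code{"leading_missing"} when LOCF cannot
#'   repair the sequence)
#' @export
imputeLOCF <- function(states) {
  miss <- is.na(states)
  if (all(miss))
    return(list(states = states, imputed = miss, valid = FALSE,
                reason = "all_missing"))
  if (miss[1])
    return(list(states = states, imputed = miss, valid = FALSE,
                reason = "leading_missing"))
  if (any(miss)) {
    nm <- names(states)
    obs <- which(!miss)
    states <- states[obs][cumsum(!miss)]
    names(states) <- nm
  }
  list(states = states, imputed = miss, valid = TRUE, reason = NA_character_)
}

#' Check a sequence against the legal transition rules
#'
#' Reports every adjacent pair of states that is not a legal life-course
#' transition. N -> D and N -> W are accepted only when an M or R state
#' occurs earlier in the sequence (a prior marriage).
#'
#' @param states character vector of length 36 over the alphabet
#' @param rules logical from x to matrix, default [transitionRules()]
#' @return data.frame with columns \code{position} (age of the origin
#'   state), \code{from}, \code{to}; zero rows when the sequence is legal
#' @export
validateSequence <- function(states, rules = transitionRules()) {
  if (any(!states %in% PARTNER_STATES))
    stop("unknown state symbol: ",
         paste(unique(states[!states %in% PARTNER_STATES]), collapse = ","))
  n <- length(states)
  from <- states[-n]; to <- states[-1]
  ok <- rules[cbind(from, to)]
  everMarried <- cumsum(states %in% c("M", "R")) > 0
  relax <- from == "N" & to %in% c("D", "W") & everMarried[-n]
  bad <- which(!ok & !relax)
  data.frame(position = SEQ_AGES[bad], from = unname(from[bad]),
             to = unname(to[bad]), stringsAsFactors = FALSE)
}

#' Build a cohort of validated partnership sequences
#'
#' Runs [assignStates()], [imputeLOCF()] and [validateSequence()] for every
#' person, excluding (and logging) persons whose sequences cannot be made
#' valid: missing birth year, overlapping marriage records, leading or
#' total missingness, or illegal transitions.
#'
#' @param persons data.frame with columns \code{person_id},
#'   \code{birth_year}, \code{gender}
#' @param marriages data.frame with columns \code{person_id}, \code{order},
#'   \code{start_year}, \code{end_year} (NA = ongoing), \code{end_reason}
#' @param rawStates optional character matrix (persons x 36, NAs = gaps)
#'   overriding the record-derived raw sequences, e.g. the gap-injected
#'   output of [simulateCohort()]; rownames must be person ids
#' @return list with \code{sequences} (a [StateSequenceSet-class]) and
#'   \code{exclusions} (data.frame \code{person_id}, \code{reason})
#' @export
buildCohort <- function(persons, marriages, rawStates = NULL) {
  nP <- nrow(persons)
  keepStates <- keepMask <- vector("list", nP)
  keepIds <- character(0)
  exId <- exReason <- character(0)
  exclude <- function(id, why) {
    exId <<- c(exId, id); exReason <<- c(exReason, why)
  }
  recsByPerson <- split(marriages, factor(marriages$person_id,
                                          levels = persons$person_id))
  for (i in seq_len(nP)) {
    id <- persons$person_id[i]
    if (is.na(persons$birth_year[i])) { exclude(id, "missing_birth_year"); next }
    if (!is.null(rawStates) && id %in% rownames(rawStates)) {
      raw <- rawStates[id, ]
    } else {
      rec <- cleanRecords(recsByPerson[[id]])
      if (is.character(rec)) { exclude(id, rec); next }
      raw <- assignStates(persons$birth_year[i], rec)
    }
    imp <- imputeLOCF(raw)
    if (!imp$valid) { exclude(id, imp$reason); next }
    if (nrow(validateSequence(imp$states)) > 0) {
      exclude(id, "illegal_transition"); next
    }
    keepIds <- c(keepIds, id)
    keepStates[[i]] <- imp$states
    keepMask[[i]] <- imp$imputed
  }
  keepStates <- keepStates[!vapply(keepStates, is.null, TRUE)]
  keepMask <- keepMask[!vapply(keepMask, is.null, TRUE)]
  if (length(keepIds) == 0) {
    st <- matrix(character(0), 0, 36,
                 dimnames = list(NULL, paste0("a", SEQ_AGES)))
    msk <- matrix(logical(0), 0, 36,
                  dimnames = list(NULL, paste0("a", SEQ_AGES)))
  } else {
    st <- matrix(unlist(keepStates), nrow = length(keepIds), byrow = TRUE,
                 dimnames = list(keepIds, paste0("a", SEQ_AGES)))
    msk <- matrix(unlist(keepMask), nrow = length(keepIds), byrow = TRUE,
                  dimnames = list(keepIds, paste0("a", SEQ_AGES)))
  }
  list(
    sequences = new("StateSequenceSet", states = st, imputed = msk),
    exclusions = data.frame(person_id = exId, reason = exReason,
                            stringsAsFactors = FALSE)
  )
}

#' Cross-sectional state distribution by age
#'
#' Proportion of persons in each partnership state at each age; each age
#' column sums to one. Optionally stratified.
#'
#' @param seqs a [StateSequenceSet-class]
#' @param by optional factor/vector aligned to sequences (e.g. gender);
#'   when given, a list of per-stratum tables is returned
#' @return 5 x 36 numeric matrix (states x ages), or a named list of them
#' @export
stateDistribution <- function(seqs, by = NULL) {
  st <- seqStates(seqs)
  if (nrow(st) == 0) stop("empty sequence set")
  one <- function(m) {
    out <- vapply(seq_len(ncol(m)), function(j) {
      tab <- table(factor(m[, j], levels = PARTNER_STATES))
      as.numeric(tab) / nrow(m)
    }, numeric(5))
    dimnames(out) <- list(state = PARTNER_STATES, age = colnames(m))
    out
  }
  if (is.null(by)) return(one(st))
  stopifnot(length(by) == nrow(st))
  lapply(split(seq_len(nrow(st)), by), function(ix) one(st[ix, , drop = FALSE]))
}
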