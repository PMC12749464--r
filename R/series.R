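# The staged specification series relating trajectory clusters, polygenic
# scores and socioeconomic background to later-life health, with gender
# stratification and interaction variants.
#
# Analytic-table column dictionary (see also simulateCohort()):
#   person_id; cluster (factor, 6 trajectory labels); srh (integer 1..5,
#   5 = excellent); cesd (integer count, 0..8 in the motivating data);
#   pgs_edu, pgs_wellbeing, pgs_dep, pgs_bmi (standardized scores);
#   educ_years, mother_educ, father_educ; childhood_ses (factor: poor /
#   average / well_off / varied_missing, ref poor); gender (male/female);
#   birth_year; cohort (factor: "<1948", "1948-1959", ">=1960");
#   age_diff_srh, age_diff_cesd (years between age 50 and measurement);
#   pc1..pc10 (ancestry principal components).

#' The six partnership trajectory cluster labels
#'
#' Factor levels for the trajectory typology, in the order used by the
#' synthetic generator. The modelling reference category is
#' \code{"Married in 20s and Continuously Married"}.
#'
#' @export
CLUSTER_LABELS <- c(
  "Never Married",
  "Married in 30s and Widowed",
  "Married and Divorced",
  "Married in 20s and Continuously Married",
  "Married by 20 and Continuously Married",
  "Married and Remarried"
)

#' @rdname CLUSTER_LABELS
#' @export
REFERENCE_CLUSTER <- "Married in 20s and Continuously Married"

pgsVars <- c("pgs_edu", "pgs_wellbeing", "pgs_dep", "pgs_bmi")
sesVars <- c("educ_years", "mother_educ", "father_educ", "childhood_ses")
pcVars <- paste0("pc", 1:10)

# Assemble the RHS for one specification stage.
#   blocks: subset of {"clusters","pgs","ses","controls"}
#   PCs enter stages containing PGSs unless includePCsAllStages.
stageTerms <- function(blocks, stratum, ageDiffVar, includePCsAllStages) {
  terms <- character(0)
  if ("clusters" %in% blocks) terms <- c(terms, "cluster")
  if ("pgs" %in% blocks) terms <- c(terms, pgsVars)
  if ("ses" %in% blocks) terms <- c(terms, sesVars)
  if ("controls" %in% blocks) {
    if (stratum == "all") terms <- c(terms, "gender")
    terms <- c(terms, "birth_year", "cohort", ageDiffVar)
  }
  if (("pgs" %in% blocks) || includePCsAllStages) terms <- c(terms, pcVars)
  terms
}

seriesStages <- list(
  stage1 = c("clusters"),
  stage2 = c("pgs"),
  stage3 = c("clusters", "pgs"),
  stage4 = c("clusters", "ses", "controls"),
  stage5 = c("clusters", "pgs", "ses", "controls")
)

prepareAnalytic <- function(data) {
  # center birth year for numerical conditioning of the ML Hessians; the
  # slope is invariant, cutpoints/intercepts are reported on this scale
  if ("birth_year" %in% names(data) && mean(data$birth_year, na.rm = TRUE) > 100)
    data$birth_year <- data$birth_year - 1944
  if (!is.factor(data$cluster))
    data$cluster <- factor(data$cluster, levels = CLUSTER_LABELS)
  data$cluster <- stats::relevel(factor(data$cluster), ref = REFERENCE_CLUSTER)
  if (!is.factor(data$gender)) data$gender <- factor(data$gender)
  if (!is.factor(data$cohort)) data$cohort <- factor(data$cohort)
  if ("childhood_ses" %in% names(data) && !is.factor(data$childhood_ses))
    data$childhood_ses <- factor(
      data$childhood_ses,
      levels = c("poor", "average", "well_off", "varied_missing"))
  data
}

#' Run the staged model series
#'
#' Fits, for each outcome and stratum, the five specification stages:
#' clusters only; PGSs only; clusters + PGSs; clusters + SES + controls;
#' clusters + PGSs + SES + controls. Self-rated health uses ordered logit,
#' the CESD count uses NB2; the outcome-specific measurement-age offset
#' enters with the controls, and the ten ancestry PCs enter every stage
#' containing PGSs (or all stages when \code{includePCsAllStages}).
#'
#' @param data analytic data.frame (column dictionary in the package
#'   sources; [simulateCohort()] emits it)
#' @param outcomes named character vector mapping outcome columns to
#'   families (\code{"ordered_logit"} or \code{"negative_binomial"})
#' @param strata subset of \code{c("all", "male", "female")}
#' @param stages subset of 1:5
#' @param weightsCol optional name of an analytic-weights column (e.g.
#'   IPW weights merged onto \code{data})
#' @param includePCsAllStages include PCs in every stage, not only
#'   PGS-containing ones
#' @return list with \code{fits} (named list of [TrajModelFit-class],
#'   keys \code{outcome.stratum.stageK}) and \code{table} (tidy rows with
#'   model identifiers, the Tables-2/3-style export)
#' @export
runModelSeries <- function(data,
                           outcomes = c(srh = "ordered_logit",
                                        cesd = "negative_binomial"),
                           strata = c("all", "male", "female"),
                           stages = 1:5,
                           weightsCol = NULL,
                           includePCsAllStages = FALSE) {
  data <- prepareAnalytic(data)
  fits <- list()
  rows <- list()
  for (oc in names(outcomes)) {
    ageDiffVar <- paste0("age_diff_", oc)
    if (!ageDiffVar %in% names(data)) ageDiffVar <- NULL
    for (st in strata) {
      sub <- if (st == "all") data else data[data$gender == st, , drop = FALSE]
      w <- if (is.null(weightsCol)) NULL else sub[[weightsCol]]
      for (sg in stages) {
        key <- paste(oc, st, paste0("stage", sg), sep = ".")
        terms <- stageTerms(seriesStages[[sg]], st, ageDiffVar,
                            includePCsAllStages)
        fm <- stats::reformulate(terms, response = oc)
        fit <- switch(outcomes[[oc]],
          ordered_logit = fitOrderedLogit(fm, sub, weights = w),
          negative_binomial = fitNegbin(fm, sub, weights = w),
          stop("unknown family: ", outcomes[[oc]]))
        fits[[key]] <- fit
        td <- fit@tidy
        # harmonize the effect-ratio column (OR vs IRR) across families
        td$ratio <- if ("or" %in% names(td)) td$or
                    else if ("irr" %in% names(td)) td$irr else NA_real_
        td$or <- td$irr <- NULL
        rows[[key]] <- cbind(outcome = oc, stratum = st,
                             stage = sg, model = key, td,
                             row.names = NULL)
      }
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}

#' Fit interaction models (gender x cluster, gender x cluster x PGS)
#'
#' Augments the fully adjusted specification with interaction terms, with
#' all lower-order terms included. For three-way models the fit is
#' accompanied by predicted probabilities of the top outcome category over
#' a PGS grid by gender and cluster (the interaction surface).
#'
#' @param data analytic data.frame
#' @param outcome outcome column (default \code{"srh"})
#' @param family \code{"ordered_logit"} or \code{"negative_binomial"}
#' @param pgs optional PGS column name; when given, the three-way
#'   gender x cluster x PGS interaction is fit, otherwise gender x cluster
#' @param pgsGrid grid of PGS values for predicted probabilities
#' @param clusters clusters to show on the predicted surface (default: all)
#' @return list with \code{fit} (a [TrajModelFit-class]) and, for
#'   three-way models with an ordered-logit family, \code{predicted}
#'   (data.frame gender, cluster, pgs value, and the probability of each
#'   outcome category, columns \code{prob_<level>}, plus \code{probTop})
#' @export
fitInteractions <- function(data, outcome = "srh", family = "ordered_logit",
                            pgs = NULL, pgsGrid = seq(-2, 2, by = 0.5),
                            clusters = NULL) {
  data <- prepareAnalytic(data)
  ageDiffVar <- paste0("age_diff_", outcome)
  if (!ageDiffVar %in% names(data)) ageDiffVar <- NULL
  base <- stageTerms(seriesStages$stage5, "all", ageDiffVar, FALSE)
  inter <- if (is.null(pgs)) "gender * cluster"
           else paste0("gender * cluster * ", pgs)
  fm <- stats::reformulate(c(setdiff(base, "cluster"), inter),
                           response = outcome)

  X <- stats::model.matrix(fm, data = stats::model.frame(fm, data))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient interaction design; aliased columns: ",
         paste(aliased, collapse = ", "))
  }

  fit <- switch(family,
    ordered_logit = fitOrderedLogit(fm, data),
    negative_binomial = fitNegbin(fm, data),
    stop("unknown family: ", family))

  out <- list(fit = fit)
  if (!is.null(pgs) && family == "ordered_logit") {
    if (is.null(clusters)) clusters <- levels(data$cluster)
    nd <- expand.grid(gender = levels(data$gender),
                      cluster = clusters, g = pgsGrid,
                      stringsAsFactors = FALSE)
    names(nd)[3] <- pgs
    nd$cluster <- factor(nd$cluster, levels = levels(data$cluster))
    nd$gender <- factor(nd$gender, levels = levels(data$gender))
    # remaining covariates held at sample means / reference levels
    for (v in setdiff(all.vars(fm)[-1], c("gender", "cluster", pgs))) {
      nd[[v]] <- if (is.numeric(data[[v]])) mean(data[[v]], na.rm = TRUE)
                 else factor(levels(factor(data[[v]]))[1],
                             levels = levels(factor(data[[v]])))
    }
    pr <- predict(fit@fit, newdata = nd, type = "probs")
    colnames(pr) <- paste0("prob_", colnames(pr))
    out$predicted <- cbind(nd[, c("gender", "cluster", pgs)], pr,
                           probTop = pr[, ncol(pr)])
  }
  out
}
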