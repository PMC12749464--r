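# Synthetic cohort generator with full ground truth. Emulates the study's
# statistical structure: six archetypal partnership trajectories with noisy
# timing, polygenic scores and SES correlated with trajectory class through
# a multinomial-logit membership model, and health outcomes drawn from
# ordered-logit (5-category) and NB2 count models with known coefficients.
# It does not emulate real survey microdata distributions or LD-structured
# genotypes.

rtnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd)), mean, sd)
}

#' Default generator configuration
#'
#' Study-condition defaults: six archetype shares matching the motivating
#' cohort's cluster shares, truncated-normal timing laws keeping all events
#' within ages 15-50, membership-model coefficients with the sign pattern
#' of the cluster-membership estimates, and outcome coefficients at
#' magnitudes detectable at n = 5000. All values are configuration, not
#' constants; they are serialized with every simulated cohort.
#'
#' @param n number of persons
#' @param classShares 6-vector of archetype shares (summing to 1), in the
#'   order of [CLUSTER_LABELS]
#' @param missingRate probability of masking each eligible interior
#'   position (strictly inside a state spell, so LOCF provably repairs it)
#' @param snpsPerTrait SNPs per trait panel (4 panels: edu, wellbeing,
#'   dep, bmi)
#' @param gamma membership-model coefficient matrix (5 non-reference
#'   classes x covariates); \code{NULL} for the defaults, \code{0} for a
#'   pure-shares membership model
#' @param srhBeta,kappa,cesdBeta,alpha outcome-model parameters
#' @return a named config list, accepted by [simulateCohort()]
#' @export
generatorConfig <- function(n = 1000,
                            classShares = c(0.057, 0.055, 0.037,
                                            0.360, 0.442, 0.048),
                            missingRate = 0,
                            snpsPerTrait = 60,
                            gamma = NULL,
                            srhBeta = NULL, kappa = NULL,
                            cesdBeta = NULL, alpha = 1.5) {
  stopifnot(length(classShares) == 6, all(classShares > 0),
            abs(sum(classShares) - 1) < 0.01)   # printed shares sum to 0.999
  classShares <- classShares / sum(classShares)
  # membership covariates: educC, female, z_edu, z_wellbeing, z_dep, z_bmi,
  # cohort2, cohort3 (reference class: Married in 20s and Continuously Married)
  covs <- c("educC", "female", "pgs_edu", "pgs_wellbeing", "pgs_dep",
            "pgs_bmi", "cohort2", "cohort3")
  if (is.null(gamma)) {
    gamma <- rbind(
      `Never Married`              = c(-0.04, 0.11, 0.05, -0.15, -0.05, -0.03, -0.30, -0.38),
      `Married in 30s and Widowed` = c(-0.05, -0.25, 0.13, -0.04, 0.00, -0.11, -0.40, -0.40),
      `Married and Divorced`       = c(-0.10, 0.00, -0.10, 0.09, 0.12, -0.03, 0.38, -0.52),
      `Married by 20 and Continuously Married` =
                                     c(-0.22, 0.91, -0.09, 0.04, 0.07, 0.00, -0.05, -0.68),
      `Married and Remarried`      = c(-0.16, 0.48, -0.25, 0.03, -0.08, 0.02, 0.22, -0.22))
    colnames(gamma) <- covs
  } else if (identical(gamma, 0)) {
    gamma <- matrix(0, 5, length(covs),
                    dimnames = list(CLUSTER_LABELS[-4], covs))
  }
  # outcome coefficients over: five non-reference cluster dummies, the four
  # PGSs, centered education, female, measurement-age offset
  ocovs <- c(paste0("cl_", c(1, 2, 3, 5, 6)), "pgs_edu", "pgs_wellbeing",
             "pgs_dep", "pgs_bmi", "educC", "female", "age_diff")
  if (is.null(srhBeta))
    srhBeta <- setNames(c(-0.26, 0.15, -0.33, 0.00, 0.10,
                          0.01, 0.10, -0.07, -0.21, 0.15, 0.09, -0.05), ocovs)
  if (is.null(kappa))
    kappa <- c(-3.2, -1.8, -0.4, 1.2)   # marginals peaking at good health
  if (is.null(cesdBeta))
    cesdBeta <- setNames(c(0.24, 0.07, 0.14, -0.03, 0.04,
                           0.02, -0.07, 0.10, 0.03, -0.08, 0.33, 0.01), ocovs)
  list(n = n, classShares = classShares, missingRate = missingRate,
       snpsPerTrait = snpsPerTrait, gamma = gamma,
       srhBeta = srhBeta, kappa = kappa, cesdBeta = cesdBeta, alpha = alpha,
       educCenter = 13.8,
       timing = list(
         m30w = list(m1 = c(33, 2, 30, 38), gap = c(10, 3, 3, 16)),
         mdiv = list(m1 = c(24, 2, 20, 29), gap = c(8, 3, 3, 15)),
         m20s = list(m1 = c(25, 2, 21, 29)),
         mby20 = list(m1 = c(18, 1.3, 15, 20)),
         remar = list(m1 = c(22, 2, 18, 27), gap = c(5, 2, 2, 9),
                      regap = c(4, 1.5, 1, 7))))
}

drawAge <- function(n, par) as.integer(round(rtnorm(n, par[1], par[2],
                                                    par[3], par[4])))

# Direct construction of the latent yearly state matrix from event ages.
# Deliberately independent of assignStates(): the round-trip equality of
# the two constructions is a tested invariant.
latentRow <- function(class, m1, d, m2) {
  s <- rep("N", 36)
  a <- function(age) age - 14L
  if (class == 1) return(s)
  if (class %in% c(4, 5)) { s[a(m1):36] <- "M"; return(s) }
  if (class == 2) {          # married in 30s, widowed
    s[a(m1):36] <- "M"; s[a(d):36] <- "W"; return(s)
  }
  if (class == 3) {          # married, divorced, no remarriage
    s[a(m1):36] <- "M"; s[a(d):36] <- "D"; return(s)
  }
  s[a(m1):36] <- "M"; s[a(d):36] <- "D"; s[a(m2):36] <- "R"  # remarried
  s
}

#' Simulate a cohort with known ground truth
#'
#' Seeded, reproducible pipeline: draw covariates and genotypes; compute
#' polygenic scores; draw the latent trajectory class from a
#' multinomial-logit membership model; draw the event history from the
#' class timing law; emit marriage records (optionally with repairable
#' interior gaps in the raw yearly states); draw self-rated health from an
#' ordered logit and the CESD count from NB2 with the configured
#' coefficients.
#'
#' @param config a list from [generatorConfig()]
#' @param seed integer RNG seed
#' @return list with \code{persons}, \code{marriages} (event records),
#'   \code{rawStates} (36-column character matrix, NA at injected gaps),
#'   \code{genotypes} (dosage matrix), \code{weights} (list of 4 SNP
#'   weight tables), \code{analytic} (model-ready table using the latent
#'   class as \code{cluster}), and \code{truth} (latent classes, latent
#'   state matrix, linear predictors, all parameters, the serialized
#'   config and seed)
#' @export
simulateCohort <- function(config = generatorConfig(), seed = 1) {
  set.seed(seed)
  n <- config$n
  ids <- sprintf("P%05d", seq_len(n))

  gender <- factor(sample(c("male", "female"), n, TRUE, prob = c(0.4, 0.6)),
                   levels = c("male", "female"))
  birthYear <- as.integer(round(rtnorm(n, 1944, 10, 1914, 1968)))
  cohort <- cut(birthYear, c(-Inf, 1947, 1959, Inf),
                labels = c("<1948", "1948-1959", ">=1960"))
  persons <- data.frame(person_id = ids, birth_year = birthYear,
                        gender = gender, stringsAsFactors = FALSE)

  # genotypes: 4 disjoint SNP panels, independent binomial(2, f) dosages
  J <- config$snpsPerTrait
  traits <- c("edu", "wellbeing", "dep", "bmi")
  weights <- list(); zs <- list()
  Gall <- NULL
  for (tr in traits) {
    f <- runif(J, 0.1, 0.9)
    w <- data.frame(snp_id = paste0(tr, "_snp", seq_len(J)),
                    effect_allele = sample(c("A", "C", "G", "T"), J, TRUE),
                    other_allele = sample(c("A", "C", "G", "T"), J, TRUE),
                    weight = rnorm(J, 0, 0.15), stringsAsFactors = FALSE)
    G <- matrix(rbinom(n * J, 2, rep(f, each = n)), n, J,
                dimnames = list(ids, w$snp_id))
    fl <- flipNegativeWeights(w, G)
    zs[[tr]] <- computePGS(fl$weights, fl$G)
    weights[[tr]] <- w
    Gall <- cbind(Gall, G)
  }
  pgs <- data.frame(pgs_edu = zs$edu$z, pgs_wellbeing = zs$wellbeing$z,
                    pgs_dep = zs$dep$z, pgs_bmi = zs$bmi$z)

  educ <- pmin(pmax(round(config$educCenter + 0.8 * pgs$pgs_edu +
                            rnorm(n, 0, 2)), 8), 17)
  educC <- educ - config$educCenter
  motherEduc <- pmin(pmax(round(rnorm(n, 11.2, 2.9)), 0), 17)
  fatherEduc <- pmin(pmax(round(rnorm(n, 10.9, 3.5)), 0), 17)
  childSES <- factor(sample(c("poor", "average", "well_off", "varied_missing"),
                            n, TRUE, prob = c(0.212, 0.689, 0.086, 0.013)),
                     levels = c("poor", "average", "well_off", "varied_missing"))
  pcs <- matrix(rnorm(n * 10), n, 10, dimnames = list(ids, paste0("pc", 1:10)))

  # latent class via multinomial logit around the configured shares
  X <- cbind(educC = educC, female = as.numeric(gender == "female"),
             pgs_edu = pgs$pgs_edu, pgs_wellbeing = pgs$pgs_wellbeing,
             pgs_dep = pgs$pgs_dep, pgs_bmi = pgs$pgs_bmi,
             cohort2 = as.numeric(cohort == "1948-1959"),
             cohort3 = as.numeric(cohort == ">=1960"))
  etaX <- matrix(0, n, 6)
  for (c in seq_len(6)) {
    if (c != 4) {
      gname <- CLUSTER_LABELS[c]
      etaX[, c] <- X %*% config$gamma[gname, colnames(X)]
    }
  }
  # calibrate intercepts so the *marginal* class shares equal the
  # configured shares under the covariate effects (fixed-point iteration
  # on the softmax; exact in one step when gamma = 0)
  a <- log(config$classShares / config$classShares[4])
  for (it in 1:200) {
    eta <- sweep(etaX, 2, a, "+")
    pr <- exp(eta - apply(eta, 1, max))
    pr <- pr / rowSums(pr)
    adj <- log(config$classShares / colMeans(pr))
    a <- a + adj - (a[4] + adj[4])
    if (max(abs(adj)) < 1e-10) break
  }
  class <- vapply(seq_len(n), function(i)
    sample.int(6, 1, prob = pr[i, ]), 0L)

  # event histories from the class timing laws
  tl <- config$timing
  m1 <- d <- m2 <- rep(NA_integer_, n)
  i2 <- class == 2; i3 <- class == 3; i4 <- class == 4
  i5 <- class == 5; i6 <- class == 6
  m1[i2] <- drawAge(sum(i2), tl$m30w$m1)
  d[i2] <- pmin(m1[i2] + drawAge(sum(i2), tl$m30w$gap), 50L)
  m1[i3] <- drawAge(sum(i3), tl$mdiv$m1)
  d[i3] <- pmin(m1[i3] + drawAge(sum(i3), tl$mdiv$gap), 49L)
  m1[i4] <- drawAge(sum(i4), tl$m20s$m1)
  m1[i5] <- drawAge(sum(i5), tl$mby20$m1)
  m1[i6] <- drawAge(sum(i6), tl$remar$m1)
  d[i6] <- m1[i6] + drawAge(sum(i6), tl$remar$gap)
  m2[i6] <- pmin(d[i6] + drawAge(sum(i6), tl$remar$regap), 48L)
  if (any(!is.na(d) & !is.na(m1) & d <= m1))
    stop("infeasible timing law: dissolution at or before marriage")

  latent <- t(vapply(seq_len(n), function(i)
    latentRow(class[i], m1[i], d[i], m2[i]), character(36)))
  dimnames(latent) <- list(ids, paste0("a", SEQ_AGES))

  mar <- do.call(rbind, lapply(which(class != 1), function(i) {
    by <- birthYear[i]
    reason1 <- if (class[i] == 2) "widowhood"
               else if (class[i] %in% c(3, 6)) "divorce" else "ongoing"
    r <- data.frame(person_id = ids[i], order = 1L,
                    start_year = by + m1[i],
                    end_year = if (reason1 == "ongoing") NA_integer_
                               else by + d[i],
                    end_reason = reason1, stringsAsFactors = FALSE)
    if (class[i] == 6)
      r <- rbind(r, data.frame(person_id = ids[i], order = 2L,
                               start_year = by + m2[i],
                               end_year = NA_integer_,
                               end_reason = "ongoing",
                               stringsAsFactors = FALSE))
    r
  }))
  if (is.null(mar))
    mar <- data.frame(person_id = character(0), order = integer(0),
                      start_year = integer(0), end_year = integer(0),
                      end_reason = character(0))

  # optional repairable interior gaps: mask only positions whose left
  # neighbour is in the same spell, so LOCF reconstructs truth exactly
  rawStates <- latent
  if (config$missingRate > 0) {
    eligible <- latent[, -1] == latent[, -36]
    mask <- eligible & matrix(runif(n * 35) < config$missingRate, n, 35)
    rawStates[, -1][mask] <- NA_character_
  }

  # outcomes
  ageDiffSrh <- pmin(stats::rpois(n, 5), 15)
  ageDiffCesd <- pmin(stats::rpois(n, 5.7), 15)
  clDum <- cbind(cl_1 = class == 1, cl_2 = class == 2, cl_3 = class == 3,
                 cl_5 = class == 5, cl_6 = class == 6) * 1
  baseX <- cbind(clDum, pgs_edu = pgs$pgs_edu,
                 pgs_wellbeing = pgs$pgs_wellbeing, pgs_dep = pgs$pgs_dep,
                 pgs_bmi = pgs$pgs_bmi, educC = educC,
                 female = as.numeric(gender == "female"))
  etaSrh <- as.numeric(cbind(baseX, age_diff = ageDiffSrh) %*%
                         config$srhBeta[c(colnames(baseX), "age_diff")])
  srh <- 1L + rowSums(outer(etaSrh + rlogis(n), config$kappa, ">"))
  etaCesd <- as.numeric(cbind(baseX, age_diff = ageDiffCesd) %*%
                          config$cesdBeta[c(colnames(baseX), "age_diff")])
  cesd <- rnbinom(n, size = 1 / config$alpha, mu = exp(etaCesd))

  analytic <- data.frame(
    person_id = ids,
    cluster = factor(CLUSTER_LABELS[class], levels = CLUSTER_LABELS),
    srh = as.integer(srh), cesd = as.integer(cesd),
    pgs, educ_years = educ, mother_educ = motherEduc,
    father_educ = fatherEduc, childhood_ses = childSES,
    gender = gender, birth_year = birthYear, cohort = cohort,
    age_diff_srh = ageDiffSrh, age_diff_cesd = ageDiffCesd,
    pcs, stringsAsFactors = FALSE)

  truth <- list(class = setNames(class, ids), latentStates = latent,
                firstMarriageAge = setNames(m1, ids),
                gamma = config$gamma, srhBeta = config$srhBeta,
                kappa = config$kappa, cesdBeta = config$cesdBeta,
                alpha = config$alpha, etaSrh = etaSrh, etaCesd = etaCesd,
                pgsZ = pgs, config = config, seed = seed)

  list(persons = persons, marriages = mar, rawStates = rawStates,
       genotypes = Gall, weights = weights, analytic = analytic,
       truth = truth)
}

#' Parameter-recovery table
#'
#' Compares fitted coefficients with the generator's truth: per parameter
#' the truth, estimate, standard error and the z-score
#' \code{(estimate - truth) / se}; optionally the adjusted Rand index of a
#' clustering run against the latent classes.
#'
#' @param fit a [TrajModelFit-class]
#' @param truth named numeric vector of true values; names must match the
#'   tidy table's \code{term} (prefixed \code{outcome|term} for
#'   multinomial fits)
#' @param clustering optional [ClusterSolution-class]
#' @param latentClass optional named latent-class vector aligned to the
#'   clustering's ids
#' @return list with \code{params} (data.frame) and \code{ari} (or NA)
#' @export
truthReport <- function(fit, truth, clustering = NULL, latentClass = NULL) {
  td <- fit@tidy
  key <- if ("outcome" %in% names(td)) paste(td$outcome, td$term, sep = "|")
         else td$term
  m <- match(names(truth), key)
  if (anyNA(m))
    stop("truth parameters not found in fit: ",
         paste(names(truth)[is.na(m)], collapse = ", "))
  params <- data.frame(
    param = names(truth), truth = unname(truth),
    estimate = td$estimate[m], se = td$se[m],
    z = (td$estimate[m] - unname(truth)) / td$se[m],
    stringsAsFactors = FALSE)
  ari <- NA_real_
  if (!is.null(clustering) && !is.null(latentClass)) {
    lab <- clusterLabels(clustering)
    ari <- adjustedRand(lab, latentClass[names(lab)])
  }
  list(params = params, ari = ari)
}
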