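# Model fitting wrappers: multinomial logit (cluster membership), ordered
# logit (self-rated health), NB2 (CESD counts), logistic (IPW inclusion).
# All support analytic weights and return a TrajModelFit with a tidy
# coefficient table and the fit statistics reported alongside the staged
# model series.

signifStars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

tidyFromEst <- function(est, se, outcome = NULL) {
  z <- est / se
  p <- 2 * pnorm(-abs(z))
  out <- data.frame(term = names(est), estimate = unname(est),
                    se = unname(se), z = unname(z), p = unname(p),
                    stars = signifStars(unname(p)), stringsAsFactors = FALSE)
  if (!is.null(outcome)) out <- cbind(outcome = outcome, out)
  rownames(out) <- NULL
  out
}

pseudoR2 <- function(ll, ll0, n) {
  list(mcfadden = 1 - ll / ll0,
       coxsnell = 1 - exp((2 / n) * (ll0 - ll)))
}

# Inject a weights vector as a column so model.frame can find it and apply
# listwise deletion consistently.
withWeights <- function(data, weights) {
  if (is.null(weights)) return(data)
  stopifnot(length(weights) == nrow(data))
  data$.wts <- weights
  data
}

# Listwise deletion on the model variables, so full and null fits use the
# same analytic rows.
dropIncomplete <- function(formula, data) {
  v <- intersect(all.vars(formula), names(data))
  if (".wts" %in% names(data)) v <- union(v, ".wts")
  data[complete.cases(data[, v, drop = FALSE]), , drop = FALSE]
}

#' Fit a multinomial logit model
#'
#' Maximum likelihood fit of \code{P(c | x) = exp(x'b_c) / sum_k exp(x'b_k)}
#' with coefficients fixed at zero for the reference category. Standard
#' errors come from the inverse observed information.
#'
#' @param formula model formula; the response is coerced to a factor
#' @param data data.frame (complete cases are used)
#' @param ref reference outcome category (default: first factor level)
#' @param weights optional analytic weights aligned to \code{data} rows
#' @param maxit,reltol optimizer controls
#' @return a [TrajModelFit-class]
#' @export
fitMultinomial <- function(formula, data, ref = NULL, weights = NULL,
                           maxit = 1000, reltol = 1e-14, abstol = 1e-14) {
  data <- dropIncomplete(formula, withWeights(data, weights))
  if (!is.null(weights)) weights <- data$.wts
  yname <- all.vars(formula)[1]
  y <- data[[yname]]
  if (!is.factor(y)) y <- factor(y)
  if (!is.null(ref)) y <- stats::relevel(y, ref = ref)
  data[[yname]] <- y

  fit <- if (is.null(weights))
    nnet::multinom(formula, data = data, trace = FALSE, maxit = maxit,
                   reltol = reltol, abstol = abstol, Hess = TRUE,
                   model = TRUE)
  else
    nnet::multinom(formula, data = data, weights = .wts, trace = FALSE,
                   maxit = maxit, reltol = reltol, abstol = abstol,
                   Hess = TRUE, model = TRUE)
  conv <- fit$convergence == 0
  if (!conv) warning("multinomial fit did not converge; diagnostics flagged")

  cf <- coef(fit)
  V <- vcov(fit)
  se <- sqrt(diag(V))
  if (is.matrix(cf)) {
    levs <- rownames(cf)
    tidy <- do.call(rbind, lapply(levs, function(l) {
      est <- cf[l, ]
      s <- se[paste0(l, ":", names(est))]
      tidyFromEst(setNames(est, colnames(cf)), setNames(s, colnames(cf)),
                  outcome = l)
    }))
  } else {
    tidy <- tidyFromEst(cf, se[names(cf)], outcome = levels(y)[2])
  }

  ll <- as.numeric(logLik(fit))
  nullFm <- stats::reformulate("1", response = yname)
  fit0 <- if (is.null(weights))
    nnet::multinom(nullFm, data = fit$model, trace = FALSE, maxit = maxit,
                   reltol = reltol, abstol = abstol)
  else
    nnet::multinom(nullFm, data = data, weights = .wts, trace = FALSE,
                   maxit = maxit, reltol = reltol, abstol = abstol)
  ll0 <- as.numeric(logLik(fit0))
  n <- nrow(fit$model)
  pr <- pseudoR2(ll, ll0, n)
  new("TrajModelFit", family = "multinomial_logit", tidy = tidy,
      cutpoints = numeric(0), lnalpha = numeric(0),
      logLik = ll, logLikNull = ll0,
      pseudoR2McFadden = pr$mcfadden, pseudoR2CoxSnell = pr$coxsnell,
      n = as.integer(n), converged = conv, fit = fit)
}

#' Fit a proportional-odds ordered logit model
#'
#' Maximum likelihood fit of \code{P(Y <= m | x) = logistic(kappa_m - x'b)}.
#' The response is coerced to an ordered factor; empty categories are
#' dropped with a warning. Odds ratios are \code{exp(b)}.
#'
#' @inheritParams fitMultinomial
#' @return a [TrajModelFit-class]; cutpoints in \code{@cutpoints}
#' @export
fitOrderedLogit <- function(formula, data, weights = NULL,
                            maxit = 500, reltol = 1e-12) {
  data <- dropIncomplete(formula, withWeights(data, weights))
  if (!is.null(weights)) weights <- data$.wts
  yname <- all.vars(formula)[1]
  y <- data[[yname]]
  if (!is.ordered(y)) y <- factor(y, ordered = TRUE)
  if (any(table(y) == 0)) {
    warning("empty outcome categories collapsed: ",
            paste(levels(y)[table(y) == 0], collapse = ","))
    y <- droplevels(y)
  }
  data[[yname]] <- y

  if (nlevels(y) == 2) return(orderedLogitBinary(formula, data, weights,
                                                 yname, y))

  fit <- if (is.null(weights))
    MASS::polr(formula, data = data, Hess = TRUE, method = "logistic",
               model = TRUE, control = list(reltol = reltol, maxit = maxit))
  else
    MASS::polr(formula, data = data, weights = .wts, Hess = TRUE,
               method = "logistic", model = TRUE,
               control = list(reltol = reltol, maxit = maxit))
  conv <- is.null(fit$convergence) || fit$convergence == 0
  se <- sqrt(diag(vcov(fit)))
  beta <- coef(fit)
  kappa <- fit$zeta
  tidy <- tidyFromEst(beta, se[names(beta)])
  tidy$or <- exp(tidy$estimate)
  cuts <- tidyFromEst(kappa, se[names(kappa)])

  ll <- as.numeric(logLik(fit))
  nullFm <- stats::reformulate("1", response = yname)
  fit0 <- if (is.null(weights))
    MASS::polr(nullFm, data = data, method = "logistic")
  else
    MASS::polr(nullFm, data = data, weights = .wts, method = "logistic")
  ll0 <- as.numeric(logLik(fit0))
  n <- nrow(fit$model)
  pr <- pseudoR2(ll, ll0, n)
  kp <- setNames(kappa, names(kappa))
  attr(kp, "se") <- unname(se[names(kappa)])
  out <- new("TrajModelFit", family = "ordered_logit",
             tidy = rbind(tidy, cbind(cuts, or = NA_real_)),
             cutpoints = kp, lnalpha = numeric(0),
             logLik = ll, logLikNull = ll0,
             pseudoR2McFadden = pr$mcfadden, pseudoR2CoxSnell = pr$coxsnell,
             n = as.integer(n), converged = conv, fit = fit)
  out
}

# Two-category ordered logit is structurally a binary logistic model:
# P(Y = 2 | x) = logistic(x'b - kappa_1), so b equals the glm slopes and
# kappa_1 = -intercept. polr requires >= 3 levels, hence this path.
orderedLogitBinary <- function(formula, data, weights, yname, y) {
  data[[yname]] <- as.integer(y == levels(y)[2])
  fl <- fitLogistic(formula, data, weights = weights)
  td <- fl@tidy
  iInt <- td$term == "(Intercept)"
  kap <- setNames(-td$estimate[iInt], paste(levels(y), collapse = "|"))
  attr(kap, "se") <- td$se[iInt]
  cuts <- tidyFromEst(kap, setNames(td$se[iInt], names(kap)))
  tidy <- td[!iInt, , drop = FALSE]
  tidy$or <- exp(tidy$estimate)
  new("TrajModelFit", family = "ordered_logit",
      tidy = rbind(tidy, cbind(cuts, or = NA_real_)),
      cutpoints = kap, lnalpha = numeric(0),
      logLik = fl@logLik, logLikNull = fl@logLikNull,
      pseudoR2McFadden = fl@pseudoR2McFadden,
      pseudoR2CoxSnell = fl@pseudoR2CoxSnell,
      n = fl@n, converged = fl@converged, fit = fl@fit)
}

#' Fit an NB2 negative binomial count model
#'
#' Maximum likelihood fit of \code{mu = exp(x'b)} with variance
#' \code{mu + alpha * mu^2}; the dispersion is reported as
#' \code{lnalpha = log(alpha)}. Incidence-rate ratios are \code{exp(b)}.
#' When the estimated dispersion is at the Poisson boundary
#' (\code{alpha < 1e-6}) the fit is flagged. \code{alphaFixed} fixes the
#' dispersion (e.g. \code{1e-8} for a Poisson-limit fit).
#'
#' @inheritParams fitMultinomial
#' @param alphaFixed optional fixed dispersion alpha
#' @return a [TrajModelFit-class]; \code{@lnalpha} holds the estimate and
#'   its standard error
#' @export
fitNegbin <- function(formula, data, weights = NULL, alphaFixed = NULL) {
  data <- dropIncomplete(formula, withWeights(data, weights))
  if (!is.null(weights)) weights <- data$.wts
  yname <- all.vars(formula)[1]

  if (!is.null(alphaFixed)) {
    fam <- MASS::negative.binomial(theta = 1 / alphaFixed, link = "log")
    fit <- if (is.null(weights))
      glm(formula, family = fam, data = data, model = TRUE,
          control = list(epsilon = 1e-12, maxit = 100))
    else
      glm(formula, family = fam, data = data, weights = .wts, model = TRUE,
          control = list(epsilon = 1e-12, maxit = 100))
    theta <- 1 / alphaFixed
    seLnalpha <- NA_real_
    conv <- fit$converged
    # glm uses a dispersion-scaled vcov for this family; the NB2 likelihood
    # treats the dispersion as known, so rescale to dispersion 1.
    V <- vcov(fit) / summary(fit)$dispersion
    se <- sqrt(diag(V))
    llFun <- function() {
      mu <- fitted(fit); yv <- fit$model[[1]]
      sum(dnbinom(yv, size = theta, mu = mu, log = TRUE))
    }
    ll <- llFun()
    fit0 <- glm(stats::reformulate("1", response = yname), family = fam,
                data = data)
    mu0 <- fitted(fit0)
    ll0 <- sum(dnbinom(fit$model[[1]], size = theta, mu = mu0, log = TRUE))
  } else {
    fit <- if (is.null(weights))
      MASS::glm.nb(formula, data = data, model = TRUE,
                   control = glm.control(epsilon = 1e-10, maxit = 100))
    else
      MASS::glm.nb(formula, data = data, weights = .wts, model = TRUE,
                   control = glm.control(epsilon = 1e-10, maxit = 100))
    theta <- fit$theta
    seLnalpha <- fit$SE.theta / theta   # delta method: lnalpha = -log(theta)
    conv <- fit$converged
    se <- sqrt(diag(vcov(fit)))
    ll <- as.numeric(logLik(fit))
    fit0 <- MASS::glm.nb(stats::reformulate("1", response = yname),
                         data = data)
    ll0 <- as.numeric(logLik(fit0))
  }
  alpha <- 1 / theta
  if (alpha < 1e-6 && is.null(alphaFixed))
    warning("dispersion at the Poisson boundary (alpha ~ 0); flagged")

  est <- coef(fit)
  tidy <- tidyFromEst(est, se[names(est)])
  tidy$irr <- exp(tidy$estimate)
  n <- nrow(fit$model)
  pr <- pseudoR2(ll, ll0, n)
  new("TrajModelFit", family = "negative_binomial", tidy = tidy,
      cutpoints = numeric(0),
      lnalpha = c(estimate = log(alpha), se = seLnalpha),
      logLik = ll, logLikNull = ll0,
      pseudoR2McFadden = pr$mcfadden, pseudoR2CoxSnell = pr$coxsnell,
      n = as.integer(n), converged = conv, fit = fit)
}

#' Fit a binary logistic regression
#'
#' Thin wrapper used for the IPW inclusion model and as the k = 2
#' reference implementation for the multinomial fitter.
#'
#' @inheritParams fitMultinomial
#' @return a [TrajModelFit-class]
#' @export
fitLogistic <- function(formula, data, weights = NULL) {
  data <- dropIncomplete(formula, withWeights(data, weights))
  if (!is.null(weights)) weights <- data$.wts
  fit <- if (is.null(weights))
    glm(formula, family = binomial(), data = data, model = TRUE,
        control = list(epsilon = 1e-12, maxit = 100))
  else
    glm(formula, family = binomial(), data = data, weights = .wts,
        model = TRUE, control = list(epsilon = 1e-12, maxit = 100))
  se <- sqrt(diag(vcov(fit)))
  tidy <- tidyFromEst(coef(fit), se[names(coef(fit))])
  ll <- as.numeric(logLik(fit))
  yname <- all.vars(formula)[1]
  fit0 <- glm(stats::reformulate("1", response = yname),
              family = binomial(), data = data)
  ll0 <- as.numeric(logLik(fit0))
  n <- nrow(fit$model)
  pr <- pseudoR2(ll, ll0, n)
  new("TrajModelFit", family = "logistic", tidy = tidy,
      cutpoints = numeric(0), lnalpha = numeric(0),
      logLik = ll, logLikNull = ll0,
      pseudoR2McFadden = pr$mcfadden, pseudoR2CoxSnell = pr$coxsnell,
      n = as.integer(n), converged = fit$converged, fit = fit)
}

#' Inverse-probability weights for analytic-sample inclusion
#'
#' Fits a logistic regression of inclusion in the analytic sample on the
#' roster covariates (by default birth year, birth cohort and gender),
#' takes \code{w = 1 / p-hat} for included persons, and rescales the
#' weights to mean one. Predicted probabilities below \code{pFloor} are
#' winsorized with a warning.
#'
#' @param roster data.frame covering the full sample, complete on the
#'   weight-model covariates, with a \code{person_id} column
#' @param included logical vector (aligned to roster) or character vector
#'   of included person ids
#' @param formula inclusion model, default
#'   \code{included ~ birth_year + cohort + gender}
#' @param pFloor winsorization floor for predicted probabilities
#' @return data.frame \code{person_id}, \code{p} (predicted inclusion
#'   probability), \code{w} (normalized weight, included persons only)
#' @export
computeIPW <- function(roster, included,
                       formula = included ~ birth_year + cohort + gender,
                       pFloor = 0.01) {
  if (is.character(included)) included <- roster$person_id %in% included
  stopifnot(length(included) == nrow(roster))
  roster$included <- as.integer(included)
  fit <- glm(formula, family = binomial(), data = roster,
             control = list(epsilon = 1e-12, maxit = 100))
  p <- predict(fit, type = "response")
  if (any(p[included] < pFloor)) {
    warning("winsorizing ", sum(p[included] < pFloor),
            " inclusion probabilities below ", pFloor)
    p[p < pFloor] <- pFloor
  }
  w <- 1 / p[included]
  w <- w / mean(w)
  data.frame(person_id = roster$person_id[included],
             p = unname(p[included]), w = unname(w),
             stringsAsFactors = FALSE)
}

#' Descriptive statistics table
#'
#' Means and SDs for numeric variables and category shares for factors,
#' pooled and stratified.
#'
#' @param data analytic data.frame
#' @param vars variables to summarize (default: all except ids)
#' @param by optional stratifying column name (e.g. \code{"gender"})
#' @return data.frame with columns variable, level, group, n, mean, sd
#' @export
descriptives <- function(data, vars = NULL, by = NULL) {
  if (is.null(vars))
    vars <- setdiff(names(data), c("person_id", by))
  groups <- list(All = rep(TRUE, nrow(data)))
  if (!is.null(by))
    for (lev in levels(factor(data[[by]])))
      groups[[lev]] <- data[[by]] == lev
  rows <- list()
  for (v in vars) {
    x <- data[[v]]
    for (g in names(groups)) {
      xi <- x[groups[[g]]]
      if (is.numeric(xi)) {
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = NA_character_, group = g,
          n = sum(!is.na(xi)), mean = mean(xi, na.rm = TRUE),
          sd = sd(xi, na.rm = TRUE), stringsAsFactors = FALSE)
      } else {
        tab <- table(factor(xi))
        shares <- as.numeric(tab) / sum(tab)
        rows[[length(rows) + 1]] <- data.frame(
          variable = v, level = names(tab), group = g,
          n = as.integer(tab), mean = shares, sd = NA_real_,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
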