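.as01 <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.numeric(y)) {
    if (!all(y %in% c(0, 1))) stop("binary outcome must be 0/1")
    return(as.integer(y))
  }
  y <- tolower(as.character(y))
  if (!all(y %in% c("yes", "no"))) stop("cannot coerce outcome to binary")
  as.integer(y == "yes")
}

#' Fit a generalized estimating equation model
#'
#' Solves the GEE for a marginal Poisson (log link) or binomial (logit
#' link) regression with observations clustered (e.g. siblings within
#' families), using Fisher scoring with an independence or exchangeable
#' working correlation. The scale parameter and exchangeable correlation
#' are moment-estimated from Pearson residuals at each step. Inference
#' uses the cluster-robust sandwich covariance; with one observation per
#' cluster and independence correlation the estimates coincide with the
#' ordinary GLM fit.
#'
#' @param formula Model formula (counts for Poisson, binary/`yes`/`no`
#'   outcome for binomial).
#' @param data data.frame.
#' @param family `"poisson"` or `"binomial"`.
#' @param cluster Name of the clustering column in `data`.
#' @param corstr Working correlation structure.
#' @param maxit,tol Scoring iterations and convergence tolerance on the
#'   coefficient update.
#' @return A [GEEFit].
#' @export
fitGee <- function(formula, data, family = c("poisson", "binomial"),
                   cluster, corstr = c("exchangeable", "independence"),
                   maxit = 100, tol = 1e-10) {
  family <- match.arg(family)
  corstr <- match.arg(corstr)
  vars <- all.vars(formula)
  use <- stats::complete.cases(data[, c(vars, cluster), drop = FALSE])
  df <- data[use, , drop = FALSE]
  if (family == "binomial") df[[vars[1]]] <- .as01(df[[vars[1]]])
  mf <- stats::model.frame(formula, df)
  X <- stats::model.matrix(formula, mf)
  y <- as.numeric(stats::model.response(mf))
  id <- as.character(df[[cluster]])
  N <- length(y); k <- ncol(X)
  idx <- split(seq_len(N), id)
  nclust <- length(idx)
  if (nclust < 2) stop("need at least 2 clusters for robust inference")

  glm_fam <- if (family == "poisson") stats::poisson() else
    stats::binomial()
  start <- suppressWarnings(
    stats::glm.fit(X, y, family = glm_fam,
                   control = stats::glm.control(epsilon = 1e-12,
                                                maxit = 100)))
  beta <- start$coefficients
  if (anyNA(beta)) stop("design matrix is rank deficient")

  linkinv <- glm_fam$linkinv
  varfun <- glm_fam$variance
  converged <- FALSE
  alpha <- 0
  phi <- 1
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- linkinv(eta)
    v <- varfun(mu)
    pr <- (y - mu) / sqrt(v)
    phi <- sum(pr^2) / (N - k)
    if (corstr == "exchangeable") {
      num <- 0; npairs <- 0
      for (ii in idx) {
        ni <- length(ii)
        if (ni > 1) {
          s <- sum(pr[ii])
          num <- num + (s^2 - sum(pr[ii]^2)) / 2
          npairs <- npairs + ni * (ni - 1) / 2
        }
      }
      alpha <- if (npairs > k && phi > 0)
        max(min(num / ((npairs - k) * phi), 0.99), -0.49) else 0
    }
    H <- matrix(0, k, k)
    U <- numeric(k)
    for (ii in idx) {
      ni <- length(ii)
      Xi <- X[ii, , drop = FALSE]
      wi <- v[ii]                       # canonical links: dmu/deta = var
      sv <- sqrt(v[ii])
      Ri <- diag(1 - alpha, ni) + matrix(alpha, ni, ni)
      Vi <- phi * (sv %o% sv) * Ri
      Di <- Xi * wi
      tDVinv <- t(Di) %*% solve(Vi)
      H <- H + tDVinv %*% Di
      U <- U + drop(tDVinv %*% (y[ii] - mu[ii]))
    }
    delta <- solve(H, U)
    beta <- beta + delta
    if (max(abs(delta)) < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("GEE did not converge in ", maxit, " iterations")
  if (family == "binomial" && any(abs(beta) > 20)) {
    worst <- colnames(X)[which.max(abs(beta))]
    stop("apparent separation on covariate ", worst)
  }

  eta <- drop(X %*% beta)
  mu <- linkinv(eta)
  v <- varfun(mu)
  H <- matrix(0, k, k)
  M <- matrix(0, k, k)
  for (ii in idx) {
    ni <- length(ii)
    Xi <- X[ii, , drop = FALSE]
    sv <- sqrt(v[ii])
    Ri <- diag(1 - alpha, ni) + matrix(alpha, ni, ni)
    Vi <- phi * (sv %o% sv) * Ri
    Di <- Xi * v[ii]
    tDVinv <- t(Di) %*% solve(Vi)
    H <- H + tDVinv %*% Di
    g <- drop(tDVinv %*% (y[ii] - mu[ii]))
    M <- M + g %o% g
  }
  Hinv <- solve(H)
  vrob <- Hinv %*% M %*% Hinv
  rse <- sqrt(diag(vrob))
  nse <- sqrt(diag(Hinv))
  names(beta) <- colnames(X)
  z <- beta / rse
  new("GEEFit",
      formula = deparse(formula), family = family, corstr = corstr,
      clusterVar = cluster, coefficients = beta,
      robustSE = stats::setNames(rse, colnames(X)),
      naiveSE = stats::setNames(nse, colnames(X)),
      pValues = stats::setNames(2 * stats::pnorm(-abs(z)), colnames(X)),
      vcovRobust = vrob, alpha = alpha, dispersion = phi,
      nClusters = nclust, nObs = as.integer(N), converged = converged)
}

#' Variant burden test between groups
#'
#' GEE Poisson comparison of per-child variant counts between two ASD x
#' preterm groups, adjusted for sex and clustered on family. The group
#' coefficient is the log rate ratio of the first group versus the
#' second.
#'
#' @param counts data.frame with `child_id` and `n` (per-child counts,
#'   e.g. from [perChildCounts()]).
#' @param individuals Individuals data.frame.
#' @param groups Length-2 character vector of [asdPretermGroup()] labels;
#'   the second is the reference.
#' @param corstr Working correlation.
#' @return List with `fit` ([GEEFit]), `rate_ratio`, `ci`, `p`.
#' @export
burdenTest <- function(counts, individuals, groups, corstr = "exchangeable") {
  ind <- individuals
  dat <- merge(counts, ind[, c("person_id", "family_id", "sex", "asd",
                               "preterm")],
               by.x = "child_id", by.y = "person_id")
  dat$group <- as.character(asdPretermGroup(dat))
  dat <- dat[dat$group %in% groups, , drop = FALSE]
  found <- unique(dat$group)
  if (length(found) < 2)
    stop("group with zero children: ",
         paste(setdiff(groups, found), collapse = ", "))
  dat$group <- factor(dat$group, levels = rev(groups))
  dat$male <- as.integer(dat$sex == "male")
  fit <- fitGee(n ~ group + male, dat, family = "poisson",
                cluster = "family_id", corstr = corstr)
  gterm <- grep("^group", names(coef(fit)), value = TRUE)
  est <- coef(fit)[gterm]
  se <- fit@robustSE[gterm]
  list(fit = fit, rate_ratio = unname(exp(est)),
       ci = unname(exp(est + c(-1.96, 1.96) * se)),
       p = unname(fit@pValues[gterm]))
}

#' Multimorbidity--burden association
#'
#' GEE Poisson model of per-child variant counts on the multimorbidity
#' count (number of diagnostic categories present), adjusted for sex and
#' clustered on family. Optionally also fits a GEE logistic model of a
#' binary outcome (e.g. ASD) on multimorbidity, burden and their
#' interaction.
#'
#' @param data data.frame with columns `n` (counts), `multimorbidity`,
#'   `sex`, `family_id`, and `outcome` when `interaction_outcome` is set.
#' @param interaction_outcome Optional name of a binary outcome column
#'   for the interaction model.
#' @return List with `burden_fit` and optionally `interaction_fit`.
#' @export
multimorbidityBurdenModel <- function(data, interaction_outcome = NULL) {
  data$male <- as.integer(data$sex == "male")
  out <- list(
    burden_fit = fitGee(n ~ multimorbidity + male, data,
                        family = "poisson", cluster = "family_id")
  )
  if (!is.null(interaction_outcome)) {
    data$.y <- .as01(data[[interaction_outcome]])
    out$interaction_fit <- fitGee(.y ~ multimorbidity * n + male, data,
                                  family = "binomial",
                                  cluster = "family_id")
  }
  out
}

#' Covariate-adjusted odds ratio
#'
#' GEE logistic regression of a binary outcome on an exposure with
#' covariates (default sex and age), clustered on family; reports the
#' exposure OR with a robust 95% CI.
#'
#' @param data data.frame.
#' @param outcome,exposure Column names (outcome binary, exposure binary
#'   or numeric).
#' @param covariates Character vector of adjustment columns.
#' @param cluster Clustering column.
#' @return List with `or`, `ci_low`, `ci_high`, `p`, `fit`.
#' @export
adjustedOr <- function(data, outcome, exposure,
                       covariates = c("sex", "age_years"),
                       cluster = "family_id") {
  rhs <- paste(c(exposure, covariates), collapse = " + ")
  f <- stats::as.formula(paste(outcome, "~", rhs))
  fit <- fitGee(f, data, family = "binomial", cluster = cluster)
  term <- grep(paste0("^", exposure), names(coef(fit)), value = TRUE)[1]
  est <- coef(fit)[term]; se <- fit@robustSE[term]
  list(or = unname(exp(est)),
       ci_low = unname(exp(est - 1.96 * se)),
       ci_high = unname(exp(est + 1.96 * se)),
       p = unname(fit@pValues[term]), fit = fit)
}
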