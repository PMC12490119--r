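#' Polygenic scores from allele dosages
#'
#' Computes per-person polygenic scores as the weighted sum of effect
#' allele dosages. Effect alleles are oriented against the genotype
#' panel: when the effect allele is the ALT allele the dosage is used as
#' is, when it is the REF allele the dosage is flipped (`2 - dosage`), and
#' variants matching neither allele are skipped and counted. The default
#' (`mode = "avg"`) divides by the number of non-missing alleles (2 x
#' variants used), the per-allele average convention of PLINK-style score
#' functions; `mode = "sum"` reports the plain weighted sum. Scores are
#' z-standardized over the scored cohort.
#'
#' @param geno Dosage matrix (persons x variants, values 0/1/2 or `NA`),
#'   with person row names and variant-id column names.
#' @param variantInfo data.frame with `variant_id`, `ref`, `alt`.
#' @param weights data.frame with `variant_id`, `effect_allele`, `weight`.
#' @param mode `"avg"` (per-allele average) or `"sum"`.
#' @return data.frame person_id, raw_score, z_score, n_variants_used;
#'   skipped variants in the `"skipped_variants"` attribute.
#' @export
scorePrs <- function(geno, variantInfo, weights, mode = c("avg", "sum")) {
  mode <- match.arg(mode)
  common <- intersect(colnames(geno), weights$variant_id)
  w <- weights[match(common, weights$variant_id), , drop = FALSE]
  vi <- variantInfo[match(common, variantInfo$variant_id), , drop = FALSE]
  is_alt <- w$effect_allele == vi$alt
  is_ref <- w$effect_allele == vi$ref
  skipped <- common[!is_alt & !is_ref]
  if (length(skipped))
    warning(length(skipped),
            " variant(s) skipped: effect allele matches neither REF nor ALT")
  use <- common[is_alt | is_ref]
  g <- geno[, use, drop = FALSE]
  flip <- is_ref[is_alt | is_ref]
  g[, flip] <- 2 - g[, flip]
  wt <- w$weight[is_alt | is_ref]
  nonmiss <- !is.na(g)
  g0 <- g; g0[!nonmiss] <- 0
  raw <- drop(g0 %*% wt)
  nused <- rowSums(nonmiss)
  if (any(nused == 0)) {
    warning(sum(nused == 0), " person(s) with no scorable variants")
    raw[nused == 0] <- NA_real_
  }
  if (mode == "avg") raw <- raw / (2 * nused)
  sdr <- stats::sd(raw, na.rm = TRUE)
  if (is.na(sdr) || sdr == 0)
    stop("zero variance in raw scores: cannot standardize")
  z <- (raw - mean(raw, na.rm = TRUE)) / sdr
  out <- data.frame(person_id = rownames(geno), raw_score = raw,
                    z_score = z, n_variants_used = nused,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "skipped_variants") <- skipped
  out
}

#' Genotype-based ancestry principal components
#'
#' Plain PCA on the standardized dosage matrix; constant variants are
#' dropped. Used as ancestry covariates in PRS association models.
#'
#' @param geno Dosage matrix (persons x variants).
#' @param n Number of components.
#' @return data.frame person_id, pc1..pcn.
#' @export
ancestryPCs <- function(geno, n = 10) {
  keep <- apply(geno, 2, function(x) stats::sd(x, na.rm = TRUE) > 0)
  g <- geno[, keep, drop = FALSE]
  g[is.na(g)] <- 0
  pc <- stats::prcomp(g, center = TRUE, scale. = TRUE)
  n <- min(n, ncol(pc$x))
  out <- data.frame(person_id = rownames(geno), pc$x[, seq_len(n)],
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c("person_id", paste0("pc", seq_len(n)))
  out
}

#' PRS distribution and association tests per contrast
#'
#' For each contrast (a pair of group labels from [asdPretermGroup()], or
#' `"asd"`/`"non_asd"` for the collapsed diagnosis groups), runs a
#' two-sided Wilcoxon rank-sum test on the standardized scores and a GEE
#' logistic model of membership in the first group on PRS with sex (and
#' ancestry PCs when supplied) as covariates, clustered on family.
#'
#' @param scores Output of [scorePrs()].
#' @param individuals Individuals data.frame.
#' @param contrasts List of length-2 character vectors.
#' @param pcs Optional data.frame from [ancestryPCs()]; when missing the
#'   models run without PCs and are flagged.
#' @return data.frame, one row per contrast, with Wilcoxon and GEE
#'   results.
#' @export
prsGroupTests <- function(scores, individuals,
                          contrasts = list(c("asd_preterm", "asd_term"),
                                           c("asd_preterm",
                                             "non_asd_preterm"),
                                           c("asd", "non_asd")),
                          pcs = NULL) {
  ind <- individuals
  dat <- merge(ind, scores, by = "person_id")
  dat$group4 <- as.character(asdPretermGroup(dat))
  dat$male <- as.integer(dat$sex == "male")
  pcs_used <- !is.null(pcs)
  if (pcs_used) dat <- merge(dat, pcs, by = "person_id")
  pc_terms <- if (pcs_used) paste0(" + ", paste0("pc", 1:10,
                                                 collapse = " + ")) else ""
  res <- lapply(contrasts, function(ct) {
    lab <- function(l) {
      if (l %in% c("asd", "non_asd"))
        dat$person_id[dat$asd == ifelse(l == "asd", "yes", "no")]
      else dat$person_id[!is.na(dat$group4) & dat$group4 == l]
    }
    ids1 <- lab(ct[1]); ids2 <- lab(ct[2])
    z1 <- dat$z_score[dat$person_id %in% ids1]
    z2 <- dat$z_score[dat$person_id %in% ids2]
    wt <- suppressWarnings(stats::wilcox.test(z1, z2, exact = FALSE))
    sub <- dat[dat$person_id %in% c(ids1, ids2), , drop = FALSE]
    sub$.y <- as.integer(sub$person_id %in% ids1)
    f <- stats::as.formula(paste0(".y ~ z_score + male", pc_terms))
    gee <- fitGee(f, sub, family = "binomial", cluster = "family_id")
    data.frame(contrast = paste(ct, collapse = "_vs_"),
               n1 = length(z1), n2 = length(z2),
               wilcox_p = wt$p.value,
               gee_beta_prs = unname(coef(gee)["z_score"]),
               gee_p_prs = unname(gee@pValues["z_score"]),
               pcs_used = pcs_used,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' ASD probability model on sex, preterm status and PRS
#'
#' Fits the GEE logistic model `asd ~ sex + preterm + PRS` (optionally
#' with a preterm x PRS interaction), clustered on family, and computes
#' average predicted probabilities over a grid of PRS values for each
#' sex x preterm cell: for each grid point the focal variables are fixed
#' and predictions are averaged over the observed rows (effect-display
#' style marginal probabilities).
#'
#' @param data data.frame of children with columns `asd`, `sex`,
#'   `preterm`, `z_score`, `family_id`.
#' @param with_interaction Include `preterm:z_score`.
#' @param prs_grid Grid of standardized PRS values.
#' @return List with `fit` ([GEEFit]) and `grid` (sex, preterm, prs,
#'   probability).
#' @export
fitProbabilityModel <- function(data, with_interaction = FALSE,
                                prs_grid = seq(-3, 3, by = 0.5)) {
  dat <- data
  dat$male <- as.integer(dat$sex == "male")
  dat$pre <- as.integer(dat$preterm == "yes")
  f <- if (with_interaction)
    .y ~ male + pre + z_score + pre:z_score else .y ~ male + pre + z_score
  dat$.y <- .as01(dat$asd)
  fit <- fitGee(f, dat, family = "binomial", cluster = "family_id")
  b <- coef(fit)
  cells <- expand.grid(male = c(1, 0), pre = c(1, 0), z = prs_grid)
  prob <- vapply(seq_len(nrow(cells)), function(i) {
    eta <- b["(Intercept)"] + b["male"] * cells$male[i] +
      b["pre"] * cells$pre[i] + b["z_score"] * cells$z[i]
    if (with_interaction)
      eta <- eta + b["pre:z_score"] * cells$pre[i] * cells$z[i]
    mean(stats::plogis(eta))
  }, numeric(1))
  grid <- data.frame(
    sex = ifelse(cells$male == 1, "male", "female"),
    preterm = ifelse(cells$pre == 1, "yes", "no"),
    prs = cells$z, probability = prob, stringsAsFactors = FALSE)
  list(fit = fit, grid = grid)
}

#' McFadden pseudo-r-squared of PRS for ASD
#'
#' Ordinary logistic regressions: full model (sex + ancestry PCs + PRS)
#' against the intercept-only model gives `r2_full`; the gain over the
#' covariate-only model (sex + PCs) gives `r2_increment`.
#'
#' @param data data.frame of children with `asd`, `sex`, `z_score` and
#'   optionally `pc1`..`pc10` columns.
#' @return List with `r2_full` and `r2_increment`.
#' @export
mcfaddenR2 <- function(data) {
  dat <- data
  dat$.y <- .as01(dat$asd)
  dat$male <- as.integer(dat$sex == "male")
  pc_cols <- grep("^pc[0-9]+$", names(dat), value = TRUE)
  covs <- c("male", pc_cols)
  f_full <- stats::as.formula(paste(".y ~",
                                    paste(c(covs, "z_score"),
                                          collapse = " + ")))
  f_red <- stats::as.formula(paste(".y ~", paste(covs, collapse = " + ")))
  full <- stats::glm(f_full, dat, family = stats::binomial())
  if (!full$converged || any(abs(stats::coef(full)) > 20))
    stop("perfect separation in the logistic fit")
  red <- stats::glm(f_red, dat, family = stats::binomial())
  null <- stats::glm(.y ~ 1, dat, family = stats::binomial())
  ll <- function(m) as.numeric(stats::logLik(m))
  r2_full <- 1 - ll(full) / ll(null)
  r2_red <- 1 - ll(red) / ll(null)
  list(r2_full = r2_full, r2_increment = r2_full - r2_red)
}
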