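#' @import methods
#' @import data.table
NULL

#' Diagnostic category names
#'
#' The nine diagnostic categories used to profile co-occurring conditions:
#' behavior, development, mood, growth, birth, eating habits, neurological
#' conditions, visual/auditory impairments, and sleep. An individual is
#' positive for a category when at least one specific diagnosis within it is
#' present; multimorbidity is the number of positive categories (0--9).
#'
#' @return Character vector of the nine category names.
#' @export
diagCategories <- function() {
  c("behavior", "development", "mood", "growth", "birth",
    "eat", "neuro", "visaud", "sleep")
}

#' Loss-of-function consequence terms
#'
#' Sequence Ontology consequence classes counted as loss-of-function (LOF):
#' frameshift, splice acceptor, splice donor, start lost, stop gained and
#' stop lost. Terms are matched after stripping a trailing `_variant`
#' suffix, so both `"frameshift"` and `"frameshift_variant"` qualify.
#'
#' @return Character vector of the six LOF term stems.
#' @export
lofTerms <- function() {
  c("frameshift", "splice_acceptor", "splice_donor",
    "start_lost", "stop_gained", "stop_lost")
}

.GT_LEVELS <- c("hom_ref", "het", "hom_alt", "missing")

.STRATUM_LEVELS <- c("extremely", "very", "moderate", "late",
                     "unknown_ga", "term")

.IND_COLS <- c("person_id", "family_id", "sex", "role", "asd",
               "gestational_age_weeks", "preterm", "preterm_stratum")

.VARIANT_COLS <- c("record_id", "variant_id", "chrom", "pos", "ref", "alt",
                   "n_alt_alleles_at_site", "family_id", "child_id",
                   "child_gt", "mother_gt", "father_gt",
                   "ref_reads", "alt_reads",
                   "gq_child", "gq_mother", "gq_father",
                   "dp_child", "dp_mother", "dp_father",
                   "popmax_af", "consequence", "gene", "is_exonic",
                   "cadd", "phylop", "revel", "sift", "polyphen", "origin")

setClassUnion("listOrNULL", c("list", "NULL"))

#' Cohort container
#'
#' Holds a family-based cohort: one `individuals` row per person (children
#' and parents), per-person diagnostic `profiles` (specific-diagnosis counts
#' for the nine categories), quantitative measures, trio variant records
#' (one row per child x site), polygenic-score genotypes and weights, a
#' neurodevelopmental-disorder (NDD) gene panel with inheritance modes, and
#' an excluded-region set. Simulated cohorts additionally carry the
#' generating truth in `truth` and their configuration in `metadata`.
#'
#' @slot individuals data.frame of persons (id, family, sex, role, ASD
#'   status, gestational age, preterm stratum, clinical flags).
#' @slot profiles data.frame of per-person specific-diagnosis counts, one
#'   column per category of [diagCategories()].
#' @slot quant data.frame of quantitative measures (CBCL 1.5-5 and 6-18,
#'   DCDQ, RBS-R, SCQ, FSIQ), `NA` where not assessed.
#' @slot variants data.frame of trio variant records.
#' @slot prsGeno numeric matrix of allele dosages (persons x variants).
#' @slot prsVariants data.frame describing scored variants (id, ref, alt,
#'   minor-allele frequency).
#' @slot prsWeights data.frame of per-SNP effect weights
#'   (variant_id, effect_allele, weight).
#' @slot panel data.frame gene panel (gene, inheritance, source_flag).
#' @slot regions GRanges of excluded regions (centromeres, low-complexity).
#' @slot truth list with the simulation ground truth, empty otherwise.
#' @slot metadata list of free-form metadata (e.g. the simulation config).
#'
#' @export
setClass("Cohort",
  representation(
    individuals = "data.frame",
    profiles    = "data.frame",
    quant       = "data.frame",
    variants    = "data.frame",
    prsGeno     = "matrix",
    prsVariants = "data.frame",
    prsWeights  = "data.frame",
    panel       = "data.frame",
    regions     = "ANY",
    truth       = "list",
    metadata    = "list"
  ),
  prototype(
    individuals = data.frame(), profiles = data.frame(),
    quant = data.frame(), variants = data.frame(),
    prsGeno = matrix(numeric(0), 0, 0), prsVariants = data.frame(),
    prsWeights = data.frame(), panel = data.frame(),
    regions = NULL, truth = list(), metadata = list()
  )
)

setValidity("Cohort", function(object) {
  msg <- character(0)
  ind <- object@individuals
  if (nrow(ind)) {
    miss <- setdiff(.IND_COLS, names(ind))
    if (length(miss))
      msg <- c(msg, paste("individuals lacks columns:",
                          paste(miss, collapse = ", ")))
    if (!length(miss)) {
      known <- !is.na(ind$gestational_age_weeks)
      bad <- known & ((ind$gestational_age_weeks < 37) != (ind$preterm == "yes"))
      if (any(bad, na.rm = TRUE))
        msg <- c(msg, "preterm flag inconsistent with gestational age < 37")
      un <- !is.na(ind$preterm_stratum) & ind$preterm_stratum == "unknown_ga"
      if (any(un & (known | is.na(ind$preterm) | ind$preterm != "yes")))
        msg <- c(msg, "unknown_ga stratum requires preterm == yes and missing GA")
    }
  }
  prof <- object@profiles
  if (nrow(prof)) {
    miss <- setdiff(c("person_id", diagCategories()), names(prof))
    if (length(miss))
      msg <- c(msg, paste("profiles lacks columns:",
                          paste(miss, collapse = ", ")))
    else if (any(as.matrix(prof[, diagCategories()]) < 0, na.rm = TRUE))
      msg <- c(msg, "negative specific-diagnosis count")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn Cohort persons table
#' @param x,object A `Cohort`.
#' @export
setGeneric("individuals", function(x) standardGeneric("individuals"))

#' @export
setMethod("individuals", "Cohort", function(x) x@individuals)

#' @describeIn Cohort diagnostic-profile table (specific-diagnosis counts)
#' @export
setGeneric("profiles", function(x) standardGeneric("profiles"))

#' @export
setMethod("profiles", "Cohort", function(x) x@profiles)

#' @describeIn Cohort quantitative-measure table
#' @export
setGeneric("quantMeasures", function(x) standardGeneric("quantMeasures"))

#' @export
setMethod("quantMeasures", "Cohort", function(x) x@quant)

#' @describeIn Cohort trio variant record table
#' @export
setGeneric("variantRecords", function(x) standardGeneric("variantRecords"))

#' @export
setMethod("variantRecords", "Cohort", function(x) x@variants)

#' @describeIn Cohort NDD gene panel
#' @export
setGeneric("genePanel", function(x) standardGeneric("genePanel"))

#' @export
setMethod("genePanel", "Cohort", function(x) x@panel)

#' @describeIn Cohort excluded-region set (GRanges or NULL)
#' @export
setGeneric("excludedRegions", function(x) standardGeneric("excludedRegions"))

#' @export
setMethod("excludedRegions", "Cohort", function(x) x@regions)

#' @describeIn Cohort PRS weight table
#' @export
setGeneric("prsWeights", function(x) standardGeneric("prsWeights"))

#' @export
setMethod("prsWeights", "Cohort", function(x) x@prsWeights)

#' @describeIn Cohort PRS genotype dosage matrix
#' @export
setGeneric("prsGenotypes", function(x) standardGeneric("prsGenotypes"))

#' @export
setMethod("prsGenotypes", "Cohort", function(x) x@prsGeno)

#' @describeIn Cohort simulation ground truth (empty list for real data)
#' @export
setGeneric("simTruth", function(x) standardGeneric("simTruth"))

#' @export
setMethod("simTruth", "Cohort", function(x) x@truth)

#' @export
setMethod("show", "Cohort", function(object) {
  ind <- object@individuals
  nchild <- sum(ind$role %in% c("proband", "sibling"))
  cat("Cohort:", nrow(ind), "persons in",
      length(unique(ind$family_id)), "families\n")
  cat("  children:", nchild,
      "| ASD:", sum(ind$asd == "yes", na.rm = TRUE),
      "| preterm:", sum(ind$preterm == "yes", na.rm = TRUE), "\n")
  cat("  variant records:", nrow(object@variants),
      "| PRS variants:", ncol(object@prsGeno),
      "| panel genes:", nrow(object@panel), "\n")
  if (length(object@truth)) cat("  simulated (truth attached)\n")
  invisible(object)
})

#' Fitted generalized estimating equation model
#'
#' Result of [fitGee()]: marginal regression coefficients solving the
#' estimating equations under a working correlation, with both the
#' model-based (naive) and sandwich (robust) standard errors. Wald p-values
#' use the robust errors. Clustering is on families, so standard errors are
#' valid under within-family outcome correlation.
#'
#' @slot formula character representation of the fitted formula.
#' @slot family `"poisson"` (log link) or `"binomial"` (logit link).
#' @slot corstr working correlation: `"independence"` or `"exchangeable"`.
#' @slot clusterVar name of the clustering column.
#' @slot coefficients named numeric coefficient vector.
#' @slot robustSE sandwich standard errors.
#' @slot naiveSE model-based standard errors.
#' @slot pValues two-sided Wald p-values (robust).
#' @slot vcovRobust robust covariance matrix.
#' @slot alpha estimated exchangeable correlation (0 under independence).
#' @slot dispersion estimated scale parameter.
#' @slot nClusters,nObs cluster and observation counts.
#' @slot converged logical convergence flag.
#'
#' @export
setClass("GEEFit",
  representation(
    formula = "character", family = "character", corstr = "character",
    clusterVar = "character", coefficients = "numeric",
    robustSE = "numeric", naiveSE = "numeric", pValues = "numeric",
    vcovRobust = "matrix", alpha = "numeric", dispersion = "numeric",
    nClusters = "integer", nObs = "integer", converged = "logical"
  )
)

setValidity("GEEFit", function(object) {
  k <- length(object@coefficients)
  if (length(object@robustSE) != k || length(object@pValues) != k)
    return("coefficient, SE and p-value lengths differ")
  TRUE
})

#' @export
setMethod("coef", "GEEFit", function(object) object@coefficients)

#' @describeIn GEEFit coefficient table with robust inference
#' @param fit A `GEEFit`.
#' @export
geeCoefTable <- function(fit) {
  stopifnot(is(fit, "GEEFit"))
  est <- fit@coefficients
  se <- fit@robustSE
  data.frame(
    term = names(est), estimate = unname(est), robust_se = unname(se),
    z = unname(est / se), p = unname(fit@pValues),
    exp_estimate = exp(unname(est)),
    exp_ci_low = exp(unname(est - 1.96 * se)),
    exp_ci_high = exp(unname(est + 1.96 * se)),
    row.names = NULL
  )
}

#' @export
setMethod("show", "GEEFit", function(object) {
  cat(sprintf("GEE %s fit (%s working correlation), clustered on %s\n",
              object@family, object@corstr, object@clusterVar))
  cat(sprintf("  %d observations in %d clusters; converged: %s\n",
              object@nObs, object@nClusters, object@converged))
  print(geeCoefTable(object), digits = 4)
  invisible(object)
})
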