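#' Simulation configuration
#'
#' Builds the parameter set for [simulateCohort()]. Defaults emulate the
#' composition and effect structure of a large family-based ASD cohort:
#' multi-child families (mean ~1.7 children), ~10% preterm births with the
#' published gestational-age stratum mix, a mean of 75.9 true de novo
#' variants (DNVs) per child of which ~3.7% are exonic and ~0.23%
#' loss-of-function, dominant/recessive inherited-variant rates of ~43 and
#' ~0.76 per child in panel genes, and an ASD liability that rises with
#' male sex, preterm birth and polygenic score. Effect sizes are marginal
#' log-odds ratios: a family-shared random intercept induces within-family
#' correlation, and the conditional coefficients are inflated by
#' `sqrt(1 + 0.346 * family_sd^2)` so that the configured values are what a
#' marginal (GEE) model estimates.
#'
#' @param n_families Number of families.
#' @param children_per_family Probability vector over 1, 2, ... children.
#' @param preterm_rate Probability a child is born preterm (< 37 weeks).
#' @param stratum_probs Probabilities of the four preterm strata
#'   (extremely, very, moderate, late) given preterm with known GA.
#' @param unknown_ga_rate Probability a preterm birth has no recorded GA.
#' @param term_ga_missing_rate Probability a term birth has no recorded GA.
#' @param sex_ratio Male fraction at birth.
#' @param asd_base_logodds Intercept of the ASD liability (marginal scale).
#' @param male_effect_logOR,preterm_effect_logOR,prs_effect_logOR Marginal
#'   log-odds ratios for male sex, preterm birth and +1 SD of PRS.
#' @param interaction_logOR Marginal log-OR of the preterm x PRS
#'   interaction (0 = additive model).
#' @param bc_effect_logOR,oxy_effect_logOR Log-ORs of birth complications
#'   and insufficient oxygen at birth on ASD.
#' @param family_sd SD of the family-shared random intercept (liability).
#' @param baseline_dnv_rate Mean true DNVs per child.
#' @param burden_rate_ratio_asd_preterm Poisson rate ratio of DNV counts in
#'   ASD-preterm children versus all others.
#' @param count_family_sd SD (log scale) of the family-shared lognormal
#'   frailty on DNV counts (mean-one; induces within-family correlation).
#' @param exonic_fraction,lof_fraction Fractions of all DNVs that are
#'   exonic / loss-of-function (LOF is a subset of exonic).
#' @param ndd_fraction Fraction of exonic variants assigned to panel genes.
#' @param inherited_dom_rate,inherited_rec_rate Mean inherited variants per
#'   child in dominant / recessive panel genes.
#' @param compound_het_rate Mean compound-heterozygote pairs per child.
#' @param dom_lof_frac,dom_dmis_frac Fractions of dominant-gene inherited
#'   variants that are LOF / damaging missense.
#' @param category_base_prevs Baseline prevalences of the nine diagnostic
#'   categories (order of [diagCategories()]).
#' @param category_asd_logOR,category_preterm_logOR Per-category log-ORs of
#'   ASD and preterm status on category presence.
#' @param birth_complication_rate,insufficient_oxygen_rate Baseline rates
#'   of the two perinatal flags; `bc_preterm_logOR`/`oxy_preterm_logOR`
#'   raise them in preterm births.
#' @param bc_preterm_logOR,oxy_preterm_logOR See above.
#' @param n_prs_snps Number of PRS panel SNPs (independent, dosage
#'   Binomial(2, maf)).
#' @param n_panel_dominant,n_panel_recessive,n_panel_unannotated Gene
#'   panel composition.
#' @param artifact_rates Named per-child rates for [plantArtifacts()]
#'   (types: low_gq, low_dp, common_af, homopolymer, region, cross_family,
#'   recurrent_child, multiallelic_excess).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `sim_config` list.
#' @export
simConfig <- function(n_families = 300,
                      children_per_family = c(0.45, 0.40, 0.15),
                      preterm_rate = 0.102,
                      stratum_probs = c(extremely = 0.081, very = 0.115,
                                        moderate = 0.148, late = 0.656),
                      unknown_ga_rate = 0.063,
                      term_ga_missing_rate = 0.2,
                      sex_ratio = 0.5,
                      asd_base_logodds = -0.5,
                      male_effect_logOR = 1.1,
                      preterm_effect_logOR = 0.9,
                      prs_effect_logOR = 0.5,
                      interaction_logOR = 0,
                      bc_effect_logOR = 0.3,
                      oxy_effect_logOR = 0.3,
                      family_sd = 0.5,
                      baseline_dnv_rate = 75.9,
                      burden_rate_ratio_asd_preterm = 1.5,
                      count_family_sd = 0.15,
                      exonic_fraction = 16155 / 432903,
                      lof_fraction = 986 / 432903,
                      ndd_fraction = 0.10,
                      inherited_dom_rate = 43.0,
                      inherited_rec_rate = 0.76,
                      compound_het_rate = 0,
                      dom_lof_frac = 2717 / 245671,
                      dom_dmis_frac = 39136 / 245671,
                      category_base_prevs = c(behavior = 0.35,
                        development = 0.45, mood = 0.20, growth = 0.15,
                        birth = 0.12, eat = 0.18, neuro = 0.10,
                        visaud = 0.12, sleep = 0.20),
                      category_asd_logOR = rep(1.1, 9),
                      category_preterm_logOR = c(0.18, 0.40, 0.30, 0.78,
                                                 0.78, 0.50, 0.50, 0.50,
                                                 0.30),
                      birth_complication_rate = 0.10,
                      insufficient_oxygen_rate = 0.05,
                      bc_preterm_logOR = 1.2,
                      oxy_preterm_logOR = 1.2,
                      n_prs_snps = 200,
                      n_panel_dominant = 738,
                      n_panel_recessive = 944,
                      n_panel_unannotated = 405,
                      artifact_rates = c(low_gq = 0.05, low_dp = 0.05,
                                         common_af = 0.05,
                                         homopolymer = 0.05, region = 0.05,
                                         cross_family = 0.05,
                                         recurrent_child = 0.05,
                                         multiallelic_excess = 0.05),
                      seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_families >= 1,
            abs(sum(children_per_family) - 1) < 1e-8,
            all(children_per_family >= 0),
            preterm_rate >= 0, preterm_rate <= 1,
            abs(sum(stratum_probs) - 1) < 1e-8,
            all(stratum_probs >= 0),
            sex_ratio >= 0, sex_ratio <= 1,
            baseline_dnv_rate >= 0,
            burden_rate_ratio_asd_preterm > 0,
            all(category_base_prevs > 0 & category_base_prevs < 1),
            length(category_base_prevs) == 9,
            length(category_asd_logOR) == 9,
            length(category_preterm_logOR) == 9,
            all(artifact_rates >= 0))
  if (any(artifact_rates > 1))
    stop("artifact rates must be <= 1")
  class(cfg) <- "sim_config"
  cfg
}

.rcat <- function(n, probs) {
  sample.int(length(probs), n, replace = TRUE, prob = probs)
}

# liability attenuation factor: conditional = marginal * .att(family_sd)
.att <- function(sd) sqrt(1 + 0.346 * sd^2)

.sim_panel <- function(cfg) {
  data.frame(
    gene = c(sprintf("DOMG%04d", seq_len(cfg$n_panel_dominant)),
             sprintf("RECG%04d", seq_len(cfg$n_panel_recessive)),
             sprintf("UNAG%04d", seq_len(cfg$n_panel_unannotated))),
    inheritance = c(rep("dominant", cfg$n_panel_dominant),
                    rep("recessive", cfg$n_panel_recessive),
                    rep("unannotated", cfg$n_panel_unannotated)),
    source_flag = "synthetic",
    stringsAsFactors = FALSE
  )
}

# position layout: each record kind draws from its own band so ids never
# collide across kinds; the excluded-region band lives at [1.2e8, 1.25e8)
# on every chromosome so only planted region artifacts fall inside it
.REGION_START <- 1.2e8
.REGION_END <- 1.25e8
.POS_BAND <- list(dnv = c(1, 5e7), inherited = c(5e7 + 1, 1e8),
                  artifact = c(1e8 + 1, 1.1e8))

.sim_regions <- function() {
  GenomicRanges::GRanges(
    seqnames = as.character(1:22),
    ranges = IRanges::IRanges(start = .REGION_START + 1, end = .REGION_END)
  )
}

.base_records <- function(n, child, fam, kind = "dnv") {
  band <- if (startsWith(kind, "inherited")) .POS_BAND$inherited
          else if (startsWith(kind, "artifact")) .POS_BAND$artifact
          else .POS_BAND$dnv
  bases <- c("A", "C", "G", "T")
  chrom <- as.character(sample.int(22, n, replace = TRUE))
  # without replacement: positions unique within a call, so clean variants
  # never recur across families by accident
  pos <- band[1] - 1 + sample.int(band[2] - band[1] + 1, n,
                                  replace = FALSE)
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))
  dp_c <- sample(15:60, n, replace = TRUE)
  ab <- stats::runif(n, 0.30, 0.70)
  alt_reads <- round(dp_c * ab)
  data.frame(
    record_id = NA_character_,
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    n_alt_alleles_at_site = 1L,
    family_id = fam, child_id = child,
    child_gt = "het", mother_gt = "hom_ref", father_gt = "hom_ref",
    ref_reads = dp_c - alt_reads, alt_reads = alt_reads,
    gq_child = sample(30:99, n, TRUE), gq_mother = sample(30:99, n, TRUE),
    gq_father = sample(30:99, n, TRUE),
    dp_child = dp_c, dp_mother = sample(15:60, n, TRUE),
    dp_father = sample(15:60, n, TRUE),
    popmax_af = ifelse(stats::runif(n) < 0.7, NA_real_,
                       stats::runif(n, 0, 0.001)),
    consequence = "intron_variant", gene = NA_character_,
    is_exonic = FALSE,
    cadd = NA_real_, phylop = NA_real_, revel = NA_real_,
    sift = NA_character_, polyphen = NA_character_,
    origin = kind,
    stringsAsFactors = FALSE
  )
}

.annotate_dnvs <- function(rec, cfg, panel, exonic) {
  n <- nrow(rec)
  if (!n) return(rec)
  p_lof <- if (cfg$exonic_fraction > 0)
    cfg$lof_fraction / cfg$exonic_fraction else 0
  lof <- exonic & stats::runif(n) < p_lof
  rec$is_exonic <- exonic
  rec$consequence[!exonic] <- sample(c("intron_variant",
                                       "intergenic_variant"),
                                     sum(!exonic), TRUE)
  nonlof_ex <- exonic & !lof
  rec$consequence[nonlof_ex] <- sample(c("missense_variant",
                                         "synonymous_variant"),
                                       sum(nonlof_ex), TRUE, c(0.7, 0.3))
  lof_terms <- paste0(lofTerms(),
                      c("_variant", "_variant", "_variant", "", "", ""))
  rec$consequence[lof] <- sample(lof_terms, sum(lof), TRUE)
  panel_genes <- panel$gene[panel$inheritance != "unannotated"]
  on_panel <- exonic & stats::runif(n) < cfg$ndd_fraction
  rec$gene[exonic] <- sprintf("GENE%05d", sample.int(18000,
                                                     sum(exonic), TRUE))
  if (any(on_panel))
    rec$gene[on_panel] <- sample(panel_genes, sum(on_panel), TRUE)
  rec$cadd[exonic] <- round(ifelse(lof[exonic], stats::runif(sum(exonic),
                                                             25, 45),
                                   stats::runif(sum(exonic), 0, 30)), 2)
  rec
}

.sim_inherited <- function(cfg, children, panel) {
  dom_genes <- panel$gene[panel$inheritance == "dominant"]
  rec_genes <- panel$gene[panel$inheritance == "recessive"]
  out <- list()
  nd <- stats::rpois(nrow(children), cfg$inherited_dom_rate)
  nr <- stats::rpois(nrow(children), cfg$inherited_rec_rate)
  nc <- stats::rpois(nrow(children), cfg$compound_het_rate)
  for (i in seq_len(nrow(children))) {
    ch <- children$person_id[i]; fam <- children$family_id[i]
    recs <- list()
    if (nd[i] > 0) {
      r <- .base_records(nd[i], ch, fam, "inherited_dom")
      r$gene <- sample(dom_genes, nd[i], TRUE)
      r$is_exonic <- TRUE
      r$popmax_af <- stats::runif(nd[i], 0, 0.001)
      u <- stats::runif(nd[i])
      cls <- ifelse(u < cfg$dom_lof_frac, "lof",
                    ifelse(u < cfg$dom_lof_frac + cfg$dom_dmis_frac,
                           "dmis", "benign"))
      r$consequence[cls == "lof"] <- sample(c("stop_gained",
                                              "frameshift_variant"),
                                            sum(cls == "lof"), TRUE)
      r$consequence[cls != "lof"] <- "missense_variant"
      ndm <- sum(cls == "dmis")
      if (ndm) {
        which_crit <- .rcat(ndm, rep(1, 5))
        idx <- which(cls == "dmis")
        r$cadd[idx] <- ifelse(which_crit == 1, stats::runif(ndm, 20, 40),
                              stats::runif(ndm, 0, 19))
        r$sift[idx] <- ifelse(which_crit == 2, "D", "T")
        r$polyphen[idx] <- ifelse(which_crit == 3,
                                  sample(c("P", "D"), ndm, TRUE), "B")
        r$phylop[idx] <- ifelse(which_crit == 4, stats::runif(ndm, 2, 8),
                                stats::runif(ndm, -2, 1.9))
        r$revel[idx] <- ifelse(which_crit == 5, stats::runif(ndm, 0.5, 1),
                               stats::runif(ndm, 0, 0.49))
      }
      ben <- cls == "benign"
      if (any(ben)) {
        r$cadd[ben] <- stats::runif(sum(ben), 0, 19)
        r$sift[ben] <- "T"; r$polyphen[ben] <- "B"
        r$phylop[ben] <- stats::runif(sum(ben), -2, 1.9)
        r$revel[ben] <- stats::runif(sum(ben), 0, 0.49)
      }
      from_mother <- stats::runif(nd[i]) < 0.5
      r$mother_gt <- ifelse(from_mother, "het", "hom_ref")
      r$father_gt <- ifelse(from_mother, "hom_ref", "het")
      recs <- c(recs, list(r))
    }
    if (nr[i] > 0) {
      r <- .base_records(nr[i], ch, fam, "inherited_rec")
      r$gene <- sample(rec_genes, nr[i], TRUE)
      r$is_exonic <- TRUE
      r$consequence <- "missense_variant"
      r$popmax_af <- stats::runif(nr[i], 0, 0.01)
      r$child_gt <- "hom_alt"
      r$mother_gt <- "het"; r$father_gt <- "het"
      r$ref_reads <- 0L; r$alt_reads <- r$dp_child
      recs <- c(recs, list(r))
    }
    if (nc[i] > 0) {
      for (k in seq_len(nc[i])) {
        g <- sample(rec_genes, 1)
        pair <- .base_records(2, ch, fam, "inherited_cht")
        pair$gene <- g
        pair$is_exonic <- TRUE
        pair$consequence <- "missense_variant"
        pair$popmax_af <- stats::runif(2, 0, 0.01)
        pair$mother_gt <- c("het", "hom_ref")
        pair$father_gt <- c("hom_ref", "het")
        recs <- c(recs, list(pair))
      }
    }
    if (length(recs)) out[[length(out) + 1]] <- do.call(rbind, recs)
  }
  if (!length(out)) return(emptyVariantTable())
  do.call(rbind, out)
}

#' Simulate a family-based cohort
#'
#' Generates a cohort with the statistical structure the downstream
#' analyses assume: multi-child families; gestational age with the four
#' preterm strata (plus unknown-GA preterm births); ASD assigned by a
#' logistic liability on sex, preterm status, standardized polygenic
#' score and perinatal flags, with a family-shared random intercept;
#' per-child true DNV counts Poisson with a configurable ASD-preterm rate
#' ratio and a family-shared frailty; nine diagnostic categories whose
#' prevalence rises with ASD and preterm status; quantitative measures
#' with group mean shifts; and per-SNP PRS genotypes/weights. Variant
#' records are emitted as one clean record per true DNV or inherited
#' variant; use [plantArtifacts()] to add records that the de novo QC
#' cascade must reject.
#'
#' @param config A [simConfig()] list.
#' @param variants Generate variant-level records (set `FALSE` for
#'   phenotype/count-level studies; per-child true counts are kept either
#'   way).
#' @return A [Cohort] with `simTruth()` attached.
#' @export
simulateCohort <- function(config = simConfig(), variants = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  nF <- cfg$n_families
  if (nF < 1) stop("need at least one family")

  nch <- .rcat(nF, cfg$children_per_family)
  fam_ids <- sprintf("F%04d", seq_len(nF))
  fam_of_child <- rep(fam_ids, nch)
  child_ids <- unlist(lapply(seq_len(nF), function(i)
    sprintf("%s_C%d", fam_ids[i], seq_len(nch[i]))))
  nC <- length(child_ids)

  male <- stats::runif(nC) < cfg$sex_ratio
  preterm <- stats::runif(nC) < cfg$preterm_rate
  ga <- rep(NA_integer_, nC)
  npre <- sum(preterm)
  if (npre) {
    unk <- stats::runif(npre) < cfg$unknown_ga_rate
    strat <- .rcat(npre, cfg$stratum_probs)
    ga_pre <- c(sample(23:27, npre, TRUE), sample(28:31, npre, TRUE),
                sample(32:33, npre, TRUE), sample(34:36, npre, TRUE))
    ga_pre <- ga_pre[(strat - 1) * npre + seq_len(npre)]
    ga_pre[unk] <- NA_integer_
    ga[preterm] <- ga_pre
  }
  nterm <- sum(!preterm)
  ga_term <- sample(37:41, nterm, TRUE)
  ga_term[stats::runif(nterm) < cfg$term_ga_missing_rate] <- NA_integer_
  ga[!preterm] <- ga_term

  bc <- stats::runif(nC) < stats::plogis(stats::qlogis(
    cfg$birth_complication_rate) + cfg$bc_preterm_logOR * preterm)
  oxy <- stats::runif(nC) < stats::plogis(stats::qlogis(
    cfg$insufficient_oxygen_rate) + cfg$oxy_preterm_logOR * preterm)

  ## PRS panel, genotypes for everyone, child standardized scores
  maf <- stats::runif(cfg$n_prs_snps, 0.05, 0.5)
  snp_ids <- sprintf("rs%06d", seq_len(cfg$n_prs_snps))
  bases <- c("A", "C", "G", "T")
  snp_ref <- sample(bases, cfg$n_prs_snps, TRUE)
  snp_alt <- vapply(snp_ref, function(b) sample(setdiff(bases, b), 1),
                    character(1))
  weights <- data.frame(variant_id = snp_ids, effect_allele = snp_alt,
                        weight = stats::rnorm(cfg$n_prs_snps, 0, 0.05),
                        stringsAsFactors = FALSE)
  mothers <- sprintf("%s_M", fam_ids)
  fathers <- sprintf("%s_F", fam_ids)
  persons <- c(child_ids, mothers, fathers)
  geno <- matrix(stats::rbinom(length(persons) * cfg$n_prs_snps, 2,
                               rep(maf, each = length(persons))),
                 nrow = length(persons),
                 dimnames = list(persons, snp_ids))
  raw_child <- as.numeric(geno[child_ids, , drop = FALSE] %*%
                            weights$weight) / (2 * cfg$n_prs_snps)
  prs_z <- as.numeric(scale(raw_child))

  ## ASD liability (marginal coefficients scaled to conditional)
  a <- .att(cfg$family_sd)
  bf <- stats::rnorm(nF, 0, cfg$family_sd)
  b_fam <- bf[match(fam_of_child, fam_ids)]
  eta <- a * (cfg$asd_base_logodds +
                cfg$male_effect_logOR * male +
                cfg$preterm_effect_logOR * preterm +
                cfg$prs_effect_logOR * prs_z +
                cfg$interaction_logOR * preterm * prs_z +
                cfg$bc_effect_logOR * bc +
                cfg$oxy_effect_logOR * oxy) + b_fam
  asd <- stats::runif(nC) < stats::plogis(eta)

  ## true DNV counts: Poisson with a family frailty; the ASD-preterm rate
  ## ratio acts on the exonic component (where the burden excess lives),
  ## leaving the genome-wide background rate shared by all groups
  frailty <- exp(stats::rnorm(nF, -cfg$count_family_sd^2 / 2,
                              cfg$count_family_sd))[match(fam_of_child,
                                                          fam_ids)]
  rr <- ifelse(asd & preterm, cfg$burden_rate_ratio_asd_preterm, 1)
  mu_ex <- cfg$baseline_dnv_rate * cfg$exonic_fraction * rr * frailty
  mu_nx <- cfg$baseline_dnv_rate * (1 - cfg$exonic_fraction) * frailty
  dnv_exonic <- stats::rpois(nC, mu_ex)
  dnv_nonexonic <- stats::rpois(nC, mu_nx)
  dnv_count <- dnv_exonic + dnv_nonexonic

  ## diagnostic categories
  cats <- diagCategories()
  prof_counts <- matrix(0L, nC, 9, dimnames = list(NULL, cats))
  for (j in seq_len(9)) {
    p <- stats::plogis(stats::qlogis(cfg$category_base_prevs[j]) +
                         cfg$category_asd_logOR[j] * asd +
                         cfg$category_preterm_logOR[j] * preterm)
    present <- stats::runif(nC) < p
    prof_counts[, j] <- ifelse(present, 1L + stats::rpois(nC, 0.7), 0L)
  }

  ## quantitative measures (children only, more severe in ASD-preterm)
  shift <- function(base, sd, d_asd, d_pre)
    stats::rnorm(nC, base + d_asd * asd + d_pre * preterm, sd)
  quant <- data.frame(
    person_id = child_ids,
    cbcl_1_5 = shift(55, 10, 5, 2), cbcl_6_18 = shift(55, 10, 5, 2),
    dcdq = shift(40, 10, -5, -3), rbsr = shift(15, 12, 6, 3),
    scq = shift(12, 7, 6, 2), fsiq = shift(100, 18, -5, -4),
    stringsAsFactors = FALSE
  )

  children <- data.frame(
    person_id = child_ids, family_id = fam_of_child,
    sex = ifelse(male, "male", "female"),
    role = ifelse(stats::ave(seq_len(nC), fam_of_child,
                             FUN = seq_along) == 1, "proband", "sibling"),
    asd = ifelse(asd, "yes", "no"),
    gestational_age_weeks = ga,
    preterm = ifelse(preterm, "yes", "no"),
    preterm_stratum = pretermStratum(ga, preterm),
    mother_id = paste0(fam_of_child, "_M"),
    father_id = paste0(fam_of_child, "_F"),
    age_years = sample(3:17, nC, TRUE),
    birth_complications = as.integer(bc),
    insufficient_oxygen = as.integer(oxy),
    dnv_count_true = dnv_count,
    dnv_exonic_true = dnv_exonic,
    stringsAsFactors = FALSE
  )
  parents <- data.frame(
    person_id = c(mothers, fathers),
    family_id = rep(fam_ids, 2),
    sex = rep(c("female", "male"), each = nF),
    role = rep(c("mother", "father"), each = nF),
    asd = "no", gestational_age_weeks = NA_integer_,
    preterm = NA_character_,
    preterm_stratum = factor(NA, levels = .STRATUM_LEVELS),
    mother_id = NA_character_, father_id = NA_character_,
    age_years = sample(25:55, 2 * nF, TRUE),
    birth_complications = NA_integer_, insufficient_oxygen = NA_integer_,
    dnv_count_true = NA_integer_, dnv_exonic_true = NA_integer_,
    stringsAsFactors = FALSE
  )
  ind <- rbind(children, parents)

  panel <- .sim_panel(cfg)
  regions <- .sim_regions()

  truth <- list(
    config_seed = cfg$seed,
    prs_z = stats::setNames(prs_z, child_ids),
    liability = stats::setNames(eta, child_ids),
    family_intercept = stats::setNames(bf, fam_ids),
    dnv_count = stats::setNames(dnv_count, child_ids),
    dnv_exonic = stats::setNames(dnv_exonic, child_ids),
    dnv_ids = list(), inherited_ids = list(),
    artifacts = data.frame(record_id = character(0),
                           expected_filter = character(0),
                           stringsAsFactors = FALSE)
  )

  vtab <- emptyVariantTable()
  if (variants) {
    recs <- list()
    tot <- sum(dnv_count)
    if (tot > 0) {
      r <- .base_records(tot, rep(child_ids, dnv_count),
                         rep(fam_of_child, dnv_count), "dnv")
      exonic_flag <- unlist(mapply(function(e, x) c(rep(TRUE, e),
                                                    rep(FALSE, x)),
                                   dnv_exonic, dnv_nonexonic,
                                   SIMPLIFY = FALSE))
      r <- .annotate_dnvs(r, cfg, panel, exonic_flag)
      recs <- c(recs, list(r))
    }
    inh <- .sim_inherited(cfg, children, panel)
    if (nrow(inh)) recs <- c(recs, list(inh))
    if (length(recs)) {
      vtab <- do.call(rbind, recs)
      vtab$record_id <- sprintf("R%06d", seq_len(nrow(vtab)))
      rownames(vtab) <- NULL
      truth$dnv_ids <- split(vtab$record_id[vtab$origin == "dnv"],
                             vtab$child_id[vtab$origin == "dnv"])
      truth$inherited_ids <- split(
        vtab$record_id[startsWith(vtab$origin, "inherited")],
        vtab$origin[startsWith(vtab$origin, "inherited")])
    }
  }

  prof <- data.frame(person_id = child_ids, prof_counts,
                     stringsAsFactors = FALSE)
  prs_variants <- data.frame(variant_id = snp_ids, ref = snp_ref,
                             alt = snp_alt, maf = maf,
                             stringsAsFactors = FALSE)
  assembleCohort(ind, prof, quant, vtab, geno, prs_variants, weights,
                 panel, regions, truth,
                 metadata = list(config = unclass(cfg)))
}

#' Plant rejectable artifact records
#'
#' Injects candidate de novo records that the QC cascade must reject, each
#' violating exactly one filter: low genotype quality (GQ < 20 in one trio
#' member), low depth (DP < 10), common allele (population AF > 0.001), a
#' homopolymer allele (run of >= 10 A or T), a position inside the
#' excluded-region set, presence in another family's parent, recurrence as
#' a candidate in children of more than three families, or a site with
#' more than three ALT alleles. Rates come from the cohort's simulation
#' config (`artifact_rates`, expected records per child; recurrence units
#' span four families). The truth table gains one row per artifact with
#' the filter expected to reject it.
#'
#' @param cohort A simulated [Cohort] (with variant records).
#' @param rates Optional named rate vector overriding the config.
#' @return The cohort with artifact records appended and
#'   `simTruth(cohort)$artifacts` filled.
#' @export
plantArtifacts <- function(cohort, rates = NULL) {
  stopifnot(is(cohort, "Cohort"))
  cfg <- cohort@metadata$config
  if (is.null(rates)) rates <- cfg$artifact_rates
  if (any(rates > 1)) stop("artifact rates must be <= 1")
  if (any(rates < 0)) stop("artifact rates must be >= 0")
  set.seed(cfg$seed + 7777L)
  ind <- cohort@individuals
  children <- ind[ind$role %in% c("proband", "sibling"), , drop = FALSE]
  nC <- nrow(children)
  fam_ids <- unique(children$family_id)
  recs <- list()
  truth_rows <- list()
  add <- function(r, filt) {
    recs[[length(recs) + 1]] <<- r
    truth_rows[[length(truth_rows) + 1]] <<-
      data.frame(record_id = NA_character_, expected_filter = filt,
                 n = nrow(r), stringsAsFactors = FALSE)
  }
  draw_children <- function(rate) {
    n <- stats::rpois(nC, rate)
    which(n > 0)[rep(seq_along(which(n > 0)), n[n > 0])]
  }
  simple <- function(type, tweak) {
    idx <- draw_children(rates[[type]])
    if (!length(idx)) return()
    r <- .base_records(length(idx), children$person_id[idx],
                       children$family_id[idx], paste0("artifact_", type))
    add(tweak(r), .ARTIFACT_FILTER[[type]])
  }
  simple("low_gq", function(r) {
    member <- sample(c("gq_child", "gq_mother", "gq_father"), nrow(r), TRUE)
    for (m in unique(member))
      r[[m]][member == m] <- sample(0:19, sum(member == m), TRUE)
    r
  })
  simple("low_dp", function(r) {
    member <- sample(c("dp_child", "dp_mother", "dp_father"), nrow(r), TRUE)
    for (m in unique(member)) {
      sel <- member == m
      r[[m]][sel] <- sample(4:9, sum(sel), TRUE)
      if (m == "dp_child") {   # keep AD consistent with the lowered depth
        alt <- pmax(2L, round(r$dp_child[sel] * 0.5))
        r$alt_reads[sel] <- alt
        r$ref_reads[sel] <- r$dp_child[sel] - alt
      }
    }
    r
  })
  simple("common_af", function(r) {
    r$popmax_af <- stats::runif(nrow(r), 0.0011, 0.1)
    r
  })
  simple("homopolymer", function(r) {
    run <- sample(c(strrep("A", 10), strrep("T", 10)), nrow(r), TRUE)
    r$alt <- paste0(r$ref, run)
    r$variant_id <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
    r
  })
  simple("region", function(r) {
    r$pos <- .REGION_START + sample.int(.REGION_END - .REGION_START,
                                        nrow(r), TRUE)
    r$variant_id <- paste(r$chrom, r$pos, r$ref, r$alt, sep = ":")
    r
  })
  simple("multiallelic_excess", function(r) {
    r$n_alt_alleles_at_site <- sample(4:6, nrow(r), TRUE)
    r
  })
  ## cross_family: candidate here + the same variant het in another family's
  ## parent (support record is inherited-like, not itself a candidate)
  idx <- draw_children(rates[["cross_family"]])
  if (length(idx)) {
    r <- .base_records(length(idx), children$person_id[idx],
                       children$family_id[idx], "artifact_cross_family")
    other_fam <- vapply(r$family_id, function(f)
      sample(setdiff(fam_ids, f), 1), character(1))
    other_child <- vapply(other_fam, function(f)
      children$person_id[children$family_id == f][1], character(1))
    sup <- r
    sup$family_id <- other_fam
    sup$child_id <- other_child
    sup$father_gt <- "het"   # carrier parent in the unrelated family
    sup$origin <- "artifact_support_cross_family"
    add(r, .ARTIFACT_FILTER[["cross_family"]])
    recs[[length(recs) + 1]] <- sup
    truth_rows[[length(truth_rows) + 1]] <-
      data.frame(record_id = NA_character_, expected_filter = NA_character_,
                 n = nrow(sup), stringsAsFactors = FALSE)
  }
  ## recurrent_child: same variant as a candidate in children of 4 families
  n_units <- stats::rpois(1, rates[["recurrent_child"]] * nC / 4)
  if (n_units > 0 && length(fam_ids) >= 4) {
    for (u in seq_len(n_units)) {
      fams <- sample(fam_ids, 4)
      kids <- vapply(fams, function(f)
        children$person_id[children$family_id == f][1], character(1))
      r <- .base_records(1, kids[1], fams[1], "artifact_recurrent_child")
      r4 <- r[rep(1, 4), ]
      r4$child_id <- kids; r4$family_id <- fams
      rownames(r4) <- NULL
      add(r4, .ARTIFACT_FILTER[["recurrent_child"]])
    }
  }
  if (!length(recs)) return(cohort)
  newrec <- do.call(rbind, recs)
  n0 <- nrow(cohort@variants)
  newrec$record_id <- sprintf("R%06d", n0 + seq_len(nrow(newrec)))
  rownames(newrec) <- NULL
  truth <- cohort@truth
  tr <- do.call(rbind, truth_rows)
  tr_expanded <- data.frame(record_id = newrec$record_id,
                            expected_filter = rep(tr$expected_filter, tr$n),
                            origin = newrec$origin,
                            stringsAsFactors = FALSE)
  truth$artifacts <- tr_expanded[!is.na(tr_expanded$expected_filter), ,
                                 drop = FALSE]
  cohort@variants <- rbind(cohort@variants, newrec)
  cohort@truth <- truth
  cohort
}

.ARTIFACT_FILTER <- c(
  low_gq = "gq", low_dp = "dp", common_af = "af",
  homopolymer = "homopolymer", region = "region",
  cross_family = "parent_other_family",
  recurrent_child = "multi_family_children",
  multiallelic_excess = "multiallelic"
)
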