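#' ASD x preterm group labels
#'
#' Combines ASD diagnosis and preterm status into the four analysis groups
#' (`asd_preterm`, `asd_term`, `non_asd_preterm`, `non_asd_term`). Persons
#' with unknown status get `NA`.
#'
#' @param individuals Individuals data.frame.
#' @return Factor of group labels aligned with the rows.
#' @export
asdPretermGroup <- function(individuals) {
  asd <- individuals$asd
  pre <- individuals$preterm
  g <- ifelse(is.na(asd) | is.na(pre), NA_character_,
              paste0(ifelse(asd == "yes", "asd", "non_asd"), "_",
                     ifelse(pre == "yes", "preterm", "term")))
  factor(g, levels = c("asd_preterm", "asd_term", "non_asd_preterm",
                       "non_asd_term"))
}

.split_terms <- function(consequence) {
  lapply(strsplit(ifelse(is.na(consequence), "", consequence), "&",
                  fixed = TRUE),
         function(x) sub("_variant$", "", x))
}

.is_lof <- function(consequence) {
  vapply(.split_terms(consequence),
         function(t) any(t %in% lofTerms()), logical(1))
}

.is_missense <- function(consequence) {
  vapply(.split_terms(consequence),
         function(t) "missense" %in% t, logical(1))
}

#' Detect candidate de novo variants
#'
#' Scans trio variant records for the de novo genotype configuration:
#' child heterozygous with both parents homozygous reference and child
#' allele balance (AB, alternate reads over total reads) strictly above
#' 0.25. On chromosome X a hemizygous male child may be het or hom-alt and
#' only the mother is required to be homozygous reference. Records with
#' undefined AB (zero informative depth) or any missing/carrier parent
#' genotype are not candidates. Chromosome Y is excluded by default.
#'
#' @param variants Trio variant record data.frame.
#' @param individuals Individuals table (for child sex on chrX).
#' @param ab_min Allele-balance threshold (strict inequality).
#' @param exclude_chrY Drop chrY records before detection.
#' @return Candidate calls: the matching records plus `ab`, `passed`,
#'   `rejected_by` and `child_excluded` columns.
#' @export
detectDenovoCandidates <- function(variants, individuals = NULL,
                                   ab_min = 0.25, exclude_chrY = TRUE) {
  v <- variants
  if (!nrow(v)) {
    out <- emptyVariantTable()
    out$ab <- numeric(0); out$passed <- logical(0)
    out$rejected_by <- character(0); out$child_excluded <- logical(0)
    return(out)
  }
  if (exclude_chrY) v <- v[!v$chrom %in% c("Y", "chrY"), , drop = FALSE]
  tot <- v$ref_reads + v$alt_reads
  ab <- ifelse(!is.na(tot) & tot > 0, v$alt_reads / tot, NA_real_)
  is_x <- v$chrom %in% c("X", "chrX")
  male_child <- rep(FALSE, nrow(v))
  if (!is.null(individuals)) {
    sex <- individuals$sex[match(v$child_id, individuals$person_id)]
    male_child <- !is.na(sex) & sex == "male"
  }
  hemi <- is_x & male_child
  auto_cand <- v$child_gt == "het" & v$mother_gt == "hom_ref" &
    v$father_gt == "hom_ref"
  hemi_cand <- v$child_gt %in% c("het", "hom_alt") &
    v$mother_gt == "hom_ref"
  cand <- ifelse(hemi, hemi_cand, auto_cand) & !is.na(ab) & ab > ab_min
  out <- v[cand, , drop = FALSE]
  out$ab <- ab[cand]
  out$passed <- rep(TRUE, nrow(out))
  out$rejected_by <- rep("", nrow(out))
  out$child_excluded <- rep(FALSE, nrow(out))
  rownames(out) <- NULL
  out
}

.DNV_FILTERS <- c("gq", "dp", "af", "homopolymer", "region",
                  "parent_other_family", "multi_family_children",
                  "multiallelic")

#' Apply the de novo QC cascade
#'
#' Runs the record-level quality filters over candidate calls, in a fixed
#' order so per-filter audit counts are reproducible: (1) minimum genotype
#' quality over the trio >= `gq_min`; (2) minimum depth over the trio >=
#' `dp_min`; (3) population allele frequency <= `af_max` (missing treated
#' as 0, i.e. novel); (4) REF or ALT containing a run of >=
#' `homopolymer_len` consecutive A or T; (5) position inside the
#' excluded-region set; (6) the variant genotyped as carrier in a parent
#' of another family; (7) the variant appearing as a candidate in children
#' of more than `max_families` distinct families; (8) more than `max_alt`
#' ALT alleles at the originating site. All failing filters are recorded
#' per call; audit counts attribute each rejection to the first failing
#' filter. Finally, children whose passing-call count lies beyond
#' `sd_k` standard deviations from the cohort mean (two-sided) are flagged
#' excluded.
#'
#' @param calls Candidate calls from [detectDenovoCandidates()].
#' @param variants Full cohort record table (parent-carrier index source).
#' @param regions `GRanges` of excluded regions, or `NULL` to skip.
#' @param children Character vector of all children in the trio universe
#'   (zero-candidate children count as zeros in the outlier step);
#'   defaults to the children seen in `variants`.
#' @param qc_scope `"trio"` applies GQ/DP thresholds to all three members,
#'   `"child"` to the child only.
#' @param gq_min,dp_min,af_max,homopolymer_len,max_families,max_alt,sd_k
#'   Filter thresholds.
#' @return List with `calls` (annotated with `passed`, `rejected_by`,
#'   `child_excluded`) and `audit` (candidate/pass counts, first-failure
#'   rejection counts per filter, per-child passing counts, excluded
#'   children).
#' @export
applyQcCascade <- function(calls, variants, regions = NULL,
                           children = NULL,
                           qc_scope = c("trio", "child"),
                           gq_min = 20, dp_min = 10, af_max = 0.001,
                           homopolymer_len = 10, max_families = 3,
                           max_alt = 3, sd_k = 3) {
  qc_scope <- match.arg(qc_scope)
  n <- nrow(calls)
  if (is.null(children))
    children <- unique(variants$child_id)
  fail <- matrix(FALSE, n, length(.DNV_FILTERS),
                 dimnames = list(NULL, .DNV_FILTERS))
  if (n) {
    if (qc_scope == "trio") {
      gq <- pmin(calls$gq_child, calls$gq_mother, calls$gq_father)
      dp <- pmin(calls$dp_child, calls$dp_mother, calls$dp_father)
    } else {
      gq <- calls$gq_child
      dp <- calls$dp_child
    }
    fail[, "gq"] <- is.na(gq) | gq < gq_min
    fail[, "dp"] <- is.na(dp) | dp < dp_min
    af <- ifelse(is.na(calls$popmax_af), 0, calls$popmax_af)
    fail[, "af"] <- af > af_max
    pat <- sprintf("A{%d}|T{%d}", homopolymer_len, homopolymer_len)
    fail[, "homopolymer"] <- grepl(pat, calls$ref) | grepl(pat, calls$alt)
    if (!is.null(regions) && length(regions)) {
      pos_gr <- GenomicRanges::GRanges(
        seqnames = calls$chrom,
        ranges = IRanges::IRanges(start = calls$pos, width = 1L))
      hits <- GenomicRanges::findOverlaps(pos_gr, regions)
      fail[unique(S4Vectors::queryHits(hits)), "region"] <- TRUE
    }
    ## parent-carrier index across the whole cohort
    carrier <- variants$mother_gt %in% c("het", "hom_alt") |
      variants$father_gt %in% c("het", "hom_alt")
    pidx <- unique(data.frame(variant_id = variants$variant_id[carrier],
                              family_id = variants$family_id[carrier],
                              stringsAsFactors = FALSE))
    if (nrow(pidx)) {
      key_fam <- paste(calls$variant_id, calls$family_id)
      in_any <- calls$variant_id %in% pidx$variant_id
      only_own <- paste(pidx$variant_id, pidx$family_id)
      # carrier in some family that is not the call's own family
      n_fam_carrier <- table(pidx$variant_id)
      own_carrier <- key_fam %in% only_own
      cnt <- as.integer(n_fam_carrier[calls$variant_id])
      cnt[is.na(cnt)] <- 0L
      fail[, "parent_other_family"] <- (cnt - as.integer(own_carrier)) > 0
    }
    ## candidate recurrence across families
    fam_per_var <- tapply(calls$family_id, calls$variant_id,
                          function(x) length(unique(x)))
    fail[, "multi_family_children"] <-
      as.integer(fam_per_var[calls$variant_id]) > max_families
    fail[, "multiallelic"] <- calls$n_alt_alleles_at_site > max_alt
  }
  passed <- !apply(fail, 1, any)
  rejected_by <- apply(fail, 1, function(f)
    paste(.DNV_FILTERS[f], collapse = ","))
  first <- apply(fail, 1, function(f)
    if (any(f)) .DNV_FILTERS[which(f)[1]] else NA_character_)
  calls$passed <- passed
  calls$rejected_by <- rejected_by

  counts <- table(factor(calls$child_id[passed], levels = children))
  per_child <- data.frame(child_id = names(counts),
                          n_dnv = as.integer(counts),
                          stringsAsFactors = FALSE)
  m <- mean(per_child$n_dnv)
  s <- stats::sd(per_child$n_dnv)
  out_lo <- m - sd_k * s
  out_hi <- m + sd_k * s
  excl <- if (is.na(s) || s == 0) character(0) else
    per_child$child_id[per_child$n_dnv > out_hi | per_child$n_dnv < out_lo]
  calls$child_excluded <- calls$child_id %in% excl

  rej_counts <- table(factor(first[!passed], levels = .DNV_FILTERS))
  audit <- list(
    n_candidates = n,
    n_passed = sum(passed),
    rejections = stats::setNames(as.integer(rej_counts), .DNV_FILTERS),
    per_child_counts = per_child,
    excluded_children = excl,
    count_mean = m, count_sd = s,
    thresholds = list(gq_min = gq_min, dp_min = dp_min, af_max = af_max,
                      homopolymer_len = homopolymer_len,
                      max_families = max_families, max_alt = max_alt,
                      sd_k = sd_k, qc_scope = qc_scope)
  )
  list(calls = calls, audit = audit)
}

#' Classify de novo calls
#'
#' Adds classification flags: `class_exonic` from the record annotation,
#' `class_lof` when any consequence term is one of the six
#' loss-of-function classes ([lofTerms()]), `class_ndd` when the gene is
#' in the panel, and `class_lof_ndd` for LOF calls on panel genes.
#'
#' @param calls Call data.frame.
#' @param panel Gene panel data.frame (any inheritance mode counts).
#' @return `calls` with the four logical class columns.
#' @export
classifyCalls <- function(calls, panel) {
  calls$class_exonic <- !is.na(calls$is_exonic) & calls$is_exonic
  calls$class_lof <- .is_lof(calls$consequence)
  calls$class_ndd <- !is.na(calls$gene) & calls$gene %in% panel$gene
  calls$class_lof_ndd <- calls$class_lof & calls$class_ndd
  calls
}

.class_mask <- function(calls, classFilter) {
  switch(classFilter,
         all = rep(TRUE, nrow(calls)),
         exonic = calls$class_exonic,
         lof = calls$class_lof,
         ndd = calls$class_ndd,
         lof_ndd = calls$class_lof_ndd,
         stop("unknown class filter: ", classFilter))
}

#' Per-child variant counts
#'
#' Counts passing, non-excluded calls per child for a variant class, with
#' zero rows for children that have none.
#'
#' @param calls Classified calls (post-cascade).
#' @param children Character vector of child ids forming the universe.
#' @param classFilter One of `"all"`, `"exonic"`, `"lof"`, `"ndd"`,
#'   `"lof_ndd"`.
#' @param drop_excluded Drop children flagged as count outliers.
#' @return data.frame child_id, n.
#' @export
perChildCounts <- function(calls, children, classFilter = "all",
                           drop_excluded = TRUE) {
  keep <- calls$passed & .class_mask(calls, classFilter)
  if (drop_excluded) keep <- keep & !calls$child_excluded
  counts <- table(factor(calls$child_id[keep], levels = children))
  out <- data.frame(child_id = names(counts), n = as.integer(counts),
                    stringsAsFactors = FALSE)
  if (drop_excluded) {
    excl <- unique(calls$child_id[calls$child_excluded])
    out <- out[!out$child_id %in% excl, , drop = FALSE]
  }
  out
}

#' Group-wise event rates
#'
#' Mean variant count per child and standard error (sd/sqrt(n)) within
#' each ASD x preterm group, for a variant class.
#'
#' @param calls Classified calls (post-cascade).
#' @param individuals Individuals data.frame (children define the
#'   universe; grouping from [asdPretermGroup()]).
#' @param classFilter Variant class, see [perChildCounts()].
#' @return data.frame group, n_children, mean_rate, se.
#' @export
eventRates <- function(calls, individuals, classFilter = "all") {
  ch <- individuals[individuals$role %in% c("proband", "sibling"), ,
                    drop = FALSE]
  counts <- perChildCounts(calls, ch$person_id, classFilter)
  grp <- asdPretermGroup(ch)[match(counts$child_id, ch$person_id)]
  keep <- !is.na(grp)
  counts <- counts[keep, , drop = FALSE]
  grp <- droplevels(grp[keep])
  agg <- lapply(split(counts$n, grp), function(x) {
    c(n = length(x), mean = mean(x),
      se = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_)
  })
  empty <- names(agg)[vapply(agg, function(a) a[["n"]] == 0, logical(1))]
  if (length(empty))
    warning("empty group(s): ", paste(empty, collapse = ", "))
  data.frame(
    group = names(agg),
    n_children = vapply(agg, `[[`, numeric(1), "n"),
    mean_rate = vapply(agg, `[[`, numeric(1), "mean"),
    se = vapply(agg, `[[`, numeric(1), "se"),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run the full de novo pipeline on a cohort
#'
#' Convenience wrapper: detection, QC cascade, classification.
#'
#' @param cohort A [Cohort].
#' @param ... Threshold arguments passed to [applyQcCascade()].
#' @return List with `calls`, `audit`.
#' @export
dnvPipeline <- function(cohort, ...) {
  stopifnot(is(cohort, "Cohort"))
  v <- variantRecords(cohort)
  ind <- individuals(cohort)
  ch <- ind$person_id[ind$role %in% c("proband", "sibling")]
  cand <- detectDenovoCandidates(v, ind)
  qc <- applyQcCascade(cand, v, regions = excludedRegions(cohort),
                       children = ch, ...)
  qc$calls <- classifyCalls(qc$calls, genePanel(cohort))
  qc
}
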