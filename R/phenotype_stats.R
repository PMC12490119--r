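#' Category prevalence
#'
#' Fraction of a group of persons positive for a diagnostic category (at
#' least one specific diagnosis within it, regardless of how many).
#'
#' @param profiles Profiles data.frame (specific-diagnosis counts).
#' @param category One of [diagCategories()].
#' @param persons Optional person ids restricting the group (default all).
#' @return Numeric prevalence in [0, 1].
#' @export
prevalence <- function(profiles, category, persons = NULL) {
  stopifnot(category %in% names(profiles))
  p <- profiles
  if (!is.null(persons))
    p <- p[p$person_id %in% persons, , drop = FALSE]
  if (!nrow(p)) stop("empty group for prevalence of ", category)
  mean(p[[category]] >= 1)
}

#' Odds ratio with confidence interval
#'
#' OR for a 2x2 table (exposed-case `a`, exposed-noncase `b`,
#' unexposed-case `c`, unexposed-noncase `d`). When any cell is zero the
#' Haldane-Anscombe 0.5 correction is applied to the OR and interval. The
#' 95% CI uses the Woolf log method. The p-value comes from the chi-square
#' test on the uncorrected table, or Fisher's exact test when any
#' expected cell count is below 5.
#'
#' @param a,b,c,d Non-negative integer cells; `a` may also be a 2x2
#'   matrix/table (rows = exposure, columns = outcome, case column first).
#' @return List with `or`, `ci_low`, `ci_high`, `p`, `method`.
#' @export
oddsRatio <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.matrix(a) || is.table(a)) {
    m <- as.matrix(a)
    stopifnot(all(dim(m) == 2))
    b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]; a <- m[1, 1]
  }
  cells <- c(a, b, c, d)
  stopifnot(all(cells >= 0))
  if ((a + b) == 0 || (c + d) == 0)
    stop("a margin of the 2x2 table is empty")
  tab <- matrix(c(a, b, c, d), 2, 2, byrow = TRUE)
  corr <- if (any(cells == 0)) 0.5 else 0
  aa <- a + corr; bb <- b + corr; cc <- c + corr; dd <- d + corr
  or <- (aa * dd) / (bb * cc)
  se <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  ci <- exp(log(or) + c(-1, 1) * 1.96 * se)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    p <- stats::fisher.test(tab)$p.value
    method <- "fisher"
  } else {
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    method <- "chisq"
  }
  list(or = or, ci_low = ci[1], ci_high = ci[2], p = p, method = method,
       haldane = corr > 0)
}

#' Prevalence odds ratios between two groups
#'
#' Per-category prevalence and OR (group1 as exposed, category presence as
#' outcome) with FDR-adjusted p-values over the nine-category family.
#'
#' @param profiles Profiles data.frame.
#' @param group1,group2 Person-id vectors (e.g. ASD-preterm vs ASD-term).
#' @return data.frame with prevalences, OR, CI, raw and FDR p per category.
#' @export
categoryOddsRatios <- function(profiles, group1, group2) {
  res <- lapply(diagCategories(), function(cat) {
    x1 <- profiles[[cat]][profiles$person_id %in% group1] >= 1
    x2 <- profiles[[cat]][profiles$person_id %in% group2] >= 1
    orr <- oddsRatio(sum(x1), sum(!x1), sum(x2), sum(!x2))
    data.frame(category = cat, prev1 = mean(x1), prev2 = mean(x2),
               or = orr$or, ci_low = orr$ci_low, ci_high = orr$ci_high,
               p_raw = orr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- fdrAdjust(out$p_raw)
  out
}

#' Multimorbidity per person
#'
#' Number of distinct diagnostic categories present (0--9).
#'
#' @param profiles Profiles data.frame.
#' @return Named integer vector keyed by person id.
#' @export
multimorbidity <- function(profiles) {
  m <- rowSums(as.matrix(profiles[, diagCategories()]) >= 1)
  stats::setNames(as.integer(m), profiles$person_id)
}

.MM_BUCKETS <- c("0", "1", "2", "3", "4", "5+")

.bucketize <- function(m) {
  factor(ifelse(m >= 5, "5+", as.character(m)), levels = .MM_BUCKETS)
}

#' Multimorbidity distribution across groups
#'
#' Buckets multimorbidity as 0, 1, 2, 3, 4 or >= 5 categories, tabulates
#' the buckets per group, tests for distributional differences with a
#' chi-square test on the group x bucket table, and (for the first two
#' groups) reports a per-bucket odds ratio of bucket membership with
#' FDR-adjusted p-values.
#'
#' @param profiles Profiles data.frame.
#' @param groups Named list of person-id vectors (>= 2 groups).
#' @return List with `counts` (group x bucket), `chisq_p`, and
#'   `bucket_or` data.frame for the first two groups.
#' @export
multimorbidityDistribution <- function(profiles, groups) {
  stopifnot(length(groups) >= 2, !is.null(names(groups)))
  mm <- multimorbidity(profiles)
  counts <- t(vapply(groups, function(ids)
    table(.bucketize(mm[names(mm) %in% ids])), integer(length(.MM_BUCKETS))))
  colnames(counts) <- .MM_BUCKETS
  nonzero <- colSums(counts) > 0
  chisq_p <- suppressWarnings(
    stats::chisq.test(counts[, nonzero, drop = FALSE])$p.value)
  g1 <- counts[1, ]; g2 <- counts[2, ]
  ors <- lapply(.MM_BUCKETS, function(b) {
    a <- g1[[b]]; bb <- sum(g1) - a; cc <- g2[[b]]; dd <- sum(g2) - cc
    if ((a + cc) == 0)
      return(data.frame(bucket = b, or = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, p_raw = NA_real_))
    orr <- oddsRatio(a, bb, cc, dd)
    data.frame(bucket = b, or = orr$or, ci_low = orr$ci_low,
               ci_high = orr$ci_high, p_raw = orr$p,
               stringsAsFactors = FALSE)
  })
  bucket_or <- do.call(rbind, ors)
  ok <- !is.na(bucket_or$p_raw)
  bucket_or$p_fdr <- NA_real_
  bucket_or$p_fdr[ok] <- fdrAdjust(bucket_or$p_raw[ok])
  list(counts = counts, chisq_p = chisq_p, bucket_or = bucket_or)
}

#' Rank trend of prevalence over preterm strata
#'
#' Kendall rank correlation between ordered gestational-age strata and
#' per-stratum prevalences. The stratum rank runs from most premature
#' (extremely = 1) upward, so a negative tau means prevalence falls as
#' gestational age increases toward term.
#'
#' @param prev Numeric prevalences ordered by stratum severity
#'   (most premature first).
#' @return List with `tau`, `p` (two-sided); both `NA` when prevalences
#'   are constant.
#' @export
pretermTrend <- function(prev) {
  stopifnot(length(prev) >= 3)
  if (stats::sd(prev) == 0) {
    warning("constant prevalences: tau undefined")
    return(list(tau = NA_real_, p = NA_real_))
  }
  ct <- suppressWarnings(
    stats::cor.test(seq_along(prev), prev, method = "kendall"))
  list(tau = unname(ct$estimate), p = ct$p.value)
}

#' Pairwise post hoc chi-square comparisons of strata
#'
#' For a category, 2x2 chi-square comparisons of category presence for
#' every pair of strata (including term), FDR-adjusted over the pair set.
#'
#' @param profiles Profiles data.frame.
#' @param strata Named list of person-id vectors, one per stratum.
#' @param category Diagnostic category.
#' @return data.frame with pair labels, OR and raw/FDR p.
#' @export
strataPosthoc <- function(profiles, strata, category) {
  pairs <- utils::combn(names(strata), 2, simplify = FALSE)
  res <- lapply(pairs, function(pr) {
    x1 <- profiles[[category]][profiles$person_id %in% strata[[pr[1]]]] >= 1
    x2 <- profiles[[category]][profiles$person_id %in% strata[[pr[2]]]] >= 1
    orr <- oddsRatio(sum(x1), sum(!x1), sum(x2), sum(!x2))
    data.frame(stratum1 = pr[1], stratum2 = pr[2], or = orr$or,
               p_raw = orr$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_fdr <- fdrAdjust(out$p_raw)
  out
}

#' Compare a quantitative measure across groups
#'
#' Two groups: two-sided Wilcoxon rank-sum test (normal approximation
#' with tie correction). More than two: Kruskal-Wallis rank-sum test.
#' Missing values are dropped per group; groups left with fewer than two
#' observations give a missing result with a warning.
#'
#' @param values Numeric vector of the measure.
#' @param groups Factor/character group labels aligned with `values`.
#' @return List with `method`, `statistic`, `p`.
#' @export
compareScores <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- droplevels(factor(groups[keep]))
  sizes <- table(groups)
  if (any(sizes < 2) || length(sizes) < 2) {
    warning("group with fewer than 2 observations; result missing")
    return(list(method = NA_character_, statistic = NA_real_,
                p = NA_real_))
  }
  if (length(sizes) == 2) {
    spl <- split(values, groups)
    ht <- suppressWarnings(stats::wilcox.test(spl[[1]], spl[[2]],
                                              exact = FALSE))
    list(method = "wilcoxon", statistic = unname(ht$statistic),
         p = ht$p.value)
  } else {
    ht <- stats::kruskal.test(values, groups)
    list(method = "kruskal-wallis", statistic = unname(ht$statistic),
         p = ht$p.value)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate correction with monotonicity enforcement.
#'
#' @param pvalues Numeric p-values in [0, 1].
#' @return Adjusted p-values in the input order.
#' @export
fdrAdjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}
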