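test_that("de novo detection follows the trio genotype and allele-balance rules", {
  v <- bindRecords(
    makeRecord(record_id = "ok", ref_reads = 5L, alt_reads = 5L),
    makeRecord(record_id = "father_het", father_gt = "het"),
    makeRecord(record_id = "mother_missing", mother_gt = "missing"),
    makeRecord(record_id = "child_homref", child_gt = "hom_ref"),
    makeRecord(record_id = "child_homalt", child_gt = "hom_alt"),
    makeRecord(record_id = "ab_boundary", ref_reads = 9L, alt_reads = 3L),
    makeRecord(record_id = "ab_just_above", ref_reads = 8L,
               alt_reads = 3L),
    makeRecord(record_id = "ab_undefined", ref_reads = 0L, alt_reads = 0L)
  )
  ind <- makeChildren(v)
  cand <- detectDenovoCandidates(v, ind)
  expect_setequal(cand$record_id, c("ok", "ab_just_above"))
  expect_equal(cand$ab[cand$record_id == "ok"], 0.5)
  # AB = 3/12 = 0.25 exactly is rejected (strictly greater than 0.25)
  expect_false("ab_boundary" %in% cand$record_id)
})

test_that("hemizygous male X detection needs only a hom-ref mother", {
  v <- bindRecords(
    makeRecord(record_id = "x_homalt_male", chrom = "X",
               child_gt = "hom_alt", father_gt = "het"),
    makeRecord(record_id = "x_mother_het", chrom = "X",
               child_gt = "hom_alt", mother_gt = "het"),
    makeRecord(record_id = "y_site", chrom = "Y")
  )
  ind <- makeChildren(v, sex = "male")
  cand <- detectDenovoCandidates(v, ind)
  expect_equal(cand$record_id, "x_homalt_male")
  # same records for a female child: hom_alt is not a de novo pattern
  cand_f <- detectDenovoCandidates(v, makeChildren(v, sex = "female"))
  expect_equal(nrow(cand_f), 0)
})

test_that("the QC cascade matches brute-force rule evaluation on boundary trios", {
  v <- .boundary_trios()
  ind <- makeChildren(v)
  regions <- makeRegions()
  cand <- detectDenovoCandidates(v, ind)
  res <- applyQcCascade(cand, v, regions = regions,
                        children = unique(ind$person_id))
  oracle <- oracleDnv(v, ind, regions)
  # same candidate set
  expect_setequal(cand$record_id,
                  oracle$record_id[oracle$candidate])
  m <- match(res$calls$record_id, oracle$record_id)
  expect_equal(res$calls$passed, oracle$passed[m])
  # identical failing-filter sets, order-insensitive
  sort_f <- function(s) vapply(strsplit(s, ","), function(x)
    paste(sort(x), collapse = ","), character(1))
  expect_equal(sort_f(res$calls$rejected_by), sort_f(oracle$rejected_by[m]))
  # spot-check the named boundaries
  rb <- setNames(res$calls$rejected_by, res$calls$record_id)
  passed <- setNames(res$calls$passed, res$calls$record_id)
  expect_true(passed[["H0001"]])
  expect_match(rb[["H0002"]], "gq")
  expect_match(rb[["H0005"]], "dp")
  expect_true(passed[["H0008"]])      # AF == 0.001 kept
  expect_match(rb[["H0009"]], "af")
  expect_match(rb[["H0011"]], "homopolymer")
  expect_true(passed[["H0012"]])      # 9-run kept
  expect_match(rb[["H0015"]], "region")
  expect_true(passed[["H0017"]])      # outside region
  expect_match(rb[["H0019"]], "multiallelic")
  expect_true(passed[["H0020"]])      # 3 ALT alleles kept
  # candidate in 4 families rejected everywhere, 3 families kept
  four <- res$calls[res$calls$variant_id == "1:999999:C:T", ]
  expect_true(all(grepl("multi_family_children", four$rejected_by)))
  three <- res$calls[res$calls$variant_id == "1:999988:G:A", ]
  expect_true(all(three$passed))
  cross <- res$calls[res$calls$variant_id == "1:999977:A:G" &
                       res$calls$family_id == "B10", ]
  expect_match(cross$rejected_by, "parent_other_family")
})

test_that("oracle equivalence holds on random simulated cohorts", {
  for (seed in c(101, 202)) {
    co <- plantArtifacts(simulateCohort(simConfig(
      n_families = 8, baseline_dnv_rate = 4, inherited_dom_rate = 2,
      seed = seed)))
    v <- variantRecords(co)
    ind <- individuals(co)
    cand <- detectDenovoCandidates(v, ind)
    res <- applyQcCascade(cand, v, regions = excludedRegions(co),
                          children = cohortPedigree(ind)$child_id)
    oracle <- oracleDnv(v, ind, excludedRegions(co))
    expect_setequal(cand$record_id, oracle$record_id[oracle$candidate])
    m <- match(res$calls$record_id, oracle$record_id)
    expect_equal(res$calls$passed, oracle$passed[m])
  }
})

test_that("audit counts attribute each rejection to the first failing filter", {
  v <- .boundary_trios()
  ind <- makeChildren(v)
  cand <- detectDenovoCandidates(v, ind)
  res <- applyQcCascade(cand, v, regions = makeRegions(),
                        children = unique(ind$person_id))
  aud <- res$audit
  expect_equal(aud$n_candidates, nrow(cand))
  expect_equal(aud$n_candidates, aud$n_passed + sum(aud$rejections))
  # the double-violation record (gq + af) is charged to gq, listed first
  both <- res$calls[res$calls$record_id == "H0030", ]
  expect_equal(both$rejected_by, "gq,af")
})

test_that("relaxing a threshold never shrinks the passing set", {
  co <- plantArtifacts(simulateCohort(simConfig(n_families = 25,
                                                seed = 77)))
  v <- variantRecords(co)
  ind <- individuals(co)
  cand <- detectDenovoCandidates(v, ind)
  kids <- cohortPedigree(ind)$child_id
  base <- applyQcCascade(cand, v, regions = excludedRegions(co),
                         children = kids)
  passed0 <- base$calls$record_id[base$calls$passed]
  relaxed <- list(
    applyQcCascade(cand, v, excludedRegions(co), kids, gq_min = 10),
    applyQcCascade(cand, v, excludedRegions(co), kids, dp_min = 5),
    applyQcCascade(cand, v, excludedRegions(co), kids, af_max = 0.01),
    applyQcCascade(cand, v, excludedRegions(co), kids, max_families = 10),
    applyQcCascade(cand, v, excludedRegions(co), kids, max_alt = 10)
  )
  for (r in relaxed)
    expect_true(all(passed0 %in% r$calls$record_id[r$calls$passed]))
})

test_that("calls are classified by consequence, exonic flag and panel membership", {
  panel <- data.frame(gene = "NDD1", inheritance = "dominant",
                      source_flag = "")
  v <- bindRecords(
    makeRecord(record_id = "lof", consequence = "stop_gained"),
    makeRecord(record_id = "lof_suffix",
               consequence = "frameshift_variant"),
    makeRecord(record_id = "mis", consequence = "missense_variant"),
    makeRecord(record_id = "lofndd", consequence = "frameshift_variant",
               gene = "NDD1"),
    makeRecord(record_id = "intron", consequence = "intron_variant",
               is_exonic = FALSE)
  )
  v$passed <- TRUE; v$child_excluded <- FALSE
  cls <- classifyCalls(v, panel)
  got <- setNames(cls$class_lof, cls$record_id)
  expect_true(got[["lof"]] && got[["lof_suffix"]])
  expect_false(got[["mis"]])
  expect_true(cls$class_lof_ndd[cls$record_id == "lofndd"])
  expect_true(cls$class_ndd[cls$record_id == "lofndd"])
  expect_false(cls$class_exonic[cls$record_id == "intron"])
})

test_that("event rates are group means with sd/sqrt(n) errors", {
  v <- bindRecords(
    makeRecord(child_id = "a", family_id = "fa"),
    makeRecord(child_id = "a", family_id = "fa"),
    makeRecord(child_id = "b", family_id = "fb"),
    makeRecord(child_id = "b", family_id = "fb"),
    makeRecord(child_id = "b", family_id = "fb"),
    makeRecord(child_id = "b", family_id = "fb"),
    makeRecord(child_id = "c", family_id = "fc"),
    makeRecord(child_id = "c", family_id = "fc"),
    makeRecord(child_id = "c", family_id = "fc"),
    makeRecord(child_id = "c", family_id = "fc"),
    makeRecord(child_id = "c", family_id = "fc"),
    makeRecord(child_id = "c", family_id = "fc")
  )
  v$passed <- TRUE; v$child_excluded <- FALSE
  v$class_exonic <- v$class_lof <- v$class_ndd <- v$class_lof_ndd <- FALSE
  ind <- makeChildren(v)   # all asd-term -> one group with counts 2,4,6
  er <- eventRates(v, ind)
  expect_equal(er$mean_rate, 4)
  expect_equal(er$se, sd(c(2, 4, 6)) / sqrt(3), tolerance = 1e-12)
  expect_equal(er$se, 1.1547, tolerance = 1e-4)
})

test_that("children with outlying counts are excluded two-sidedly", {
  kids <- sprintf("k%02d", 1:40)
  counts <- c(rep(50, 38), 90, 10)   # one high and one low outlier
  total <- sum(counts)
  tmpl <- makeRecord()
  v <- tmpl[rep(1, total), ]
  v$child_id <- rep(kids, counts)
  v$family_id <- paste0("f", v$child_id)
  v$pos <- 500000L + seq_len(total)
  v$record_id <- sprintf("O%05d", seq_len(total))
  v$variant_id <- paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  rownames(v) <- NULL
  ind <- makeChildren(v)
  cand <- detectDenovoCandidates(v, ind)
  res <- applyQcCascade(cand, v, children = kids)
  expect_true("k39" %in% res$audit$excluded_children)   # high outlier
  expect_true("k40" %in% res$audit$excluded_children)   # low outlier
  expect_equal(length(res$audit$excluded_children), 2)
  pc <- perChildCounts(res$calls, kids)
  expect_false(any(c("k39", "k40") %in% pc$child_id))
})
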