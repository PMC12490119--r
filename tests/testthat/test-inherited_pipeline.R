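.test_panel <- data.frame(
  gene = c("DOM1", "DOM2", "REC1", "REC2", "UNA1"),
  inheritance = c("dominant", "dominant", "recessive", "recessive",
                  "unannotated"),
  source_flag = "", stringsAsFactors = FALSE)

test_that("panel extraction keeps annotated panel genes only", {
  v <- bindRecords(
    makeRecord(record_id = "in_dom", gene = "DOM1"),
    makeRecord(record_id = "in_rec", gene = "REC1"),
    makeRecord(record_id = "unann", gene = "UNA1"),
    makeRecord(record_id = "off_panel", gene = "OTHER"),
    makeRecord(record_id = "no_gene", gene = NA_character_)
  )
  expect_message(out <- extractPanelVariants(v, .test_panel),
                 "unannotated")
  expect_setequal(out$record_id, c("in_dom", "in_rec"))
  expect_equal(attr(out, "n_unannotated_dropped"), 1L)
  expect_equal(out$mode[out$record_id == "in_dom"], "dominant")
})

test_that("allele-frequency ceilings depend on the inheritance mode", {
  v <- bindRecords(
    makeRecord(record_id = "dom_rare", gene = "DOM1", popmax_af = 0.0005,
               mother_gt = "het"),
    makeRecord(record_id = "dom_common", gene = "DOM1", popmax_af = 0.005,
               mother_gt = "het"),
    makeRecord(record_id = "rec_mid", gene = "REC1", popmax_af = 0.005,
               child_gt = "hom_alt", mother_gt = "het",
               father_gt = "het"),
    makeRecord(record_id = "rec_common", gene = "REC1", popmax_af = 0.02,
               child_gt = "hom_alt", mother_gt = "het",
               father_gt = "het"),
    makeRecord(record_id = "dom_na_af", gene = "DOM2",
               popmax_af = NA_real_, father_gt = "het")
  )
  calls <- filterInherited(extractPanelVariants(v, .test_panel))
  expect_setequal(calls$record_id, c("dom_rare", "rec_mid", "dom_na_af"))
})

test_that("genotype configurations must match the mode; de novo patterns are excluded", {
  v <- bindRecords(
    makeRecord(record_id = "denovo_like", gene = "DOM1"),  # both parents ref
    makeRecord(record_id = "dom_mother", gene = "DOM1", mother_gt = "het"),
    makeRecord(record_id = "dom_father", gene = "DOM1", father_gt = "het"),
    makeRecord(record_id = "dom_both", gene = "DOM1", mother_gt = "het",
               father_gt = "het"),
    makeRecord(record_id = "dom_homalt_child", gene = "DOM1",
               child_gt = "hom_alt", mother_gt = "het"),
    makeRecord(record_id = "rec_homalt", gene = "REC1",
               child_gt = "hom_alt", mother_gt = "het",
               father_gt = "het"),
    makeRecord(record_id = "rec_one_parent", gene = "REC1",
               child_gt = "hom_alt", mother_gt = "het"),
    makeRecord(record_id = "low_gq_parent", gene = "DOM1",
               mother_gt = "het", gq_mother = 19L),
    makeRecord(record_id = "low_dp_parent", gene = "DOM1",
               mother_gt = "het", dp_mother = 9L),
    makeRecord(record_id = "untransmitting_ok", gene = "DOM1",
               mother_gt = "het", gq_father = 5L, dp_father = 2L)
  )
  calls <- filterInherited(extractPanelVariants(v, .test_panel))
  expect_setequal(calls$record_id,
                  c("dom_mother", "dom_father", "dom_both", "rec_homalt",
                    "untransmitting_ok"))
  tf <- setNames(calls$transmitted_from, calls$record_id)
  expect_equal(tf[["dom_mother"]], "mother")
  expect_equal(tf[["dom_father"]], "father")
  expect_equal(tf[["dom_both"]], "both")
  expect_equal(tf[["rec_homalt"]], "both")
})

test_that("filtering matches the brute-force rule oracle on simulated data", {
  co <- simulateCohort(simConfig(n_families = 15, seed = 66))
  v <- variantRecords(co)
  panel <- genePanel(co)
  got <- filterInherited(extractPanelVariants(v, panel))
  expect_setequal(got$record_id, oracleInherited(v, panel))
})

test_that("compound heterozygotes pair only across parental origins", {
  v <- bindRecords(
    makeRecord(record_id = "m1", child_id = "k1", family_id = "f1",
               gene = "REC1", mother_gt = "het"),
    makeRecord(record_id = "p1", child_id = "k1", family_id = "f1",
               gene = "REC1", father_gt = "het"),
    makeRecord(record_id = "m2", child_id = "k2", family_id = "f2",
               gene = "REC1", mother_gt = "het"),
    makeRecord(record_id = "m3", child_id = "k2", family_id = "f2",
               gene = "REC1", mother_gt = "het"),   # cis: both maternal
    makeRecord(record_id = "solo", child_id = "k3", family_id = "f3",
               gene = "REC2", mother_gt = "het"),
    makeRecord(record_id = "amb", child_id = "k4", family_id = "f4",
               gene = "REC1", mother_gt = "het", father_gt = "het"),
    makeRecord(record_id = "dom_keep", child_id = "k1", family_id = "f1",
               gene = "DOM1", mother_gt = "het")
  )
  calls <- scanCompoundHet(filterInherited(
    extractPanelVariants(v, .test_panel)))
  # trans pair kept and cross-linked
  expect_true(all(c("m1", "p1") %in% calls$record_id))
  expect_equal(calls$compound_het_partner[calls$record_id == "m1"], "p1")
  expect_equal(calls$compound_het_partner[calls$record_id == "p1"], "m1")
  # cis pair, singleton and unphaseable candidates are dropped
  expect_false(any(c("m2", "m3", "solo", "amb") %in% calls$record_id))
  # dominant calls untouched
  expect_true("dom_keep" %in% calls$record_id)
  expect_true(is.na(calls$compound_het_partner[
    calls$record_id == "dom_keep"]))
})

test_that("damaging-missense needs one criterion; LOF follows the term list", {
  mk <- function(id, gene = "DOM1", ...)
    makeRecord(record_id = id, gene = gene, mother_gt = "het", ...)
  v <- bindRecords(
    mk("cadd_hit", cadd = 25),
    mk("cadd_boundary", cadd = 20),
    mk("sift_hit", sift = "D"),
    mk("polyphen_P", polyphen = "P"),
    mk("polyphen_B", polyphen = "B"),
    mk("phylop_hit", phylop = 2.0),
    mk("revel_boundary", revel = 0.5),
    mk("all_benign", cadd = 10, sift = "T", polyphen = "B", phylop = 0,
       revel = 0.1),
    mk("all_missing"),
    mk("lof_call", consequence = "splice_acceptor_variant", cadd = 5),
    mk("rec_lof", gene = "REC1", child_gt = "hom_alt", father_gt = "het",
       consequence = "stop_gained")
  )
  calls <- classifyDominant(scanCompoundHet(filterInherited(
    extractPanelVariants(v, .test_panel))))
  dm <- setNames(calls$class_damaging_missense, calls$record_id)
  expect_true(all(dm[c("cadd_hit", "cadd_boundary", "sift_hit",
                       "polyphen_P", "phylop_hit", "revel_boundary")]))
  expect_false(any(dm[c("polyphen_B", "all_benign", "all_missing",
                        "lof_call")]))
  expect_true(calls$class_lof[calls$record_id == "lof_call"])
  # recessive-gene calls are never classified by the dominant criteria
  expect_false(calls$class_lof[calls$record_id == "rec_lof"])
})

test_that("no variant call lands in both the de novo and inherited outputs", {
  co <- plantArtifacts(simulateCohort(simConfig(n_families = 30,
                                                seed = 13)))
  dnv <- dnvPipeline(co)
  inh <- inheritedPipeline(co)
  dnv_keys <- with(dnv$calls[dnv$calls$passed, ],
                   paste(child_id, variant_id))
  inh_keys <- with(inh, paste(child_id, variant_id))
  expect_length(intersect(dnv_keys, inh_keys), 0)
})

test_that("recessive call counts are invariant to swapping parental labels", {
  co <- simulateCohort(simConfig(n_families = 25, compound_het_rate = 0.3,
                                 seed = 17))
  v <- variantRecords(co)
  sw <- v
  sw[, c("mother_gt", "father_gt")] <- v[, c("father_gt", "mother_gt")]
  sw[, c("gq_mother", "gq_father")] <- v[, c("gq_father", "gq_mother")]
  sw[, c("dp_mother", "dp_father")] <- v[, c("dp_father", "dp_mother")]
  a <- scanCompoundHet(filterInherited(
    extractPanelVariants(v, genePanel(co))))
  b <- scanCompoundHet(filterInherited(
    extractPanelVariants(sw, genePanel(co))))
  expect_setequal(a$record_id, b$record_id)
  expect_equal(sum(a$mode == "recessive"), sum(b$mode == "recessive"))
  # origins flip, partnerships survive
  flip <- c(mother = "father", father = "mother", both = "both")
  expect_equal(unname(flip[a$transmitted_from]),
               b$transmitted_from[match(a$record_id, b$record_id)])
})
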