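# hand-built trio variant records with sensible defaults; every field can
# be overridden to probe one rule at a time
.rec_counter <- local({
  i <- 0L
  function(reset = FALSE) {
    if (reset) {
      i <<- 0L
      return(invisible(0L))
    }
    i <<- i + 1L
    i
  }
})

resetRecordIds <- function() .rec_counter(reset = TRUE)

makeRecord <- function(child_id = "F01_C1", family_id = "F01",
                       chrom = "1", pos = NULL, ref = "C", alt = "T",
                       n_alt = 1L,
                       child_gt = "het", mother_gt = "hom_ref",
                       father_gt = "hom_ref",
                       ref_reads = 10L, alt_reads = 10L,
                       gq_child = 50L, gq_mother = 50L, gq_father = 50L,
                       dp_child = 30L, dp_mother = 30L, dp_father = 30L,
                       popmax_af = NA_real_,
                       consequence = "missense_variant",
                       gene = NA_character_, is_exonic = TRUE,
                       cadd = NA_real_, phylop = NA_real_,
                       revel = NA_real_, sift = NA_character_,
                       polyphen = NA_character_, origin = "manual",
                       record_id = NULL) {
  k <- .rec_counter()
  if (is.null(pos)) pos <- 10000L + 10L * k
  if (is.null(record_id)) record_id <- sprintf("H%04d", k)
  data.frame(
    record_id = record_id,
    variant_id = paste(chrom, pos, ref, alt, sep = ":"),
    chrom = chrom, pos = pos, ref = ref, alt = alt,
    n_alt_alleles_at_site = n_alt,
    family_id = family_id, child_id = child_id,
    child_gt = child_gt, mother_gt = mother_gt, father_gt = father_gt,
    ref_reads = ref_reads, alt_reads = alt_reads,
    gq_child = gq_child, gq_mother = gq_mother, gq_father = gq_father,
    dp_child = dp_child, dp_mother = dp_mother, dp_father = dp_father,
    popmax_af = popmax_af, consequence = consequence, gene = gene,
    is_exonic = is_exonic, cadd = cadd, phylop = phylop, revel = revel,
    sift = sift, polyphen = polyphen, origin = origin,
    stringsAsFactors = FALSE
  )
}

bindRecords <- function(...) {
  do.call(rbind, list(...))
}

makeChildren <- function(variants, sex = "female") {
  ch <- unique(variants[, c("child_id", "family_id")])
  data.frame(person_id = ch$child_id, family_id = ch$family_id,
             sex = if (length(sex) == 1) rep(sex, nrow(ch)) else sex,
             role = "proband", asd = "yes",
             gestational_age_weeks = 40L, preterm = "no",
             preterm_stratum = factor("term",
               levels = c("extremely", "very", "moderate", "late",
                          "unknown_ga", "term")),
             stringsAsFactors = FALSE)
}

# regions fixture: one excluded block, chr1 positions 1001..2000 (1-based)
makeRegions <- function() {
  GenomicRanges::GRanges("1", IRanges::IRanges(start = 1001, end = 2000))
}

# thirty hand-built trios covering every filter boundary of the de novo
# cascade; used both by the unit tests and the oracle-equivalence
# acceptance check (ids H0001..H0030 in construction order)
.boundary_trios <- function() {
  resetRecordIds()
  fams <- sprintf("B%02d", 1:10)
  kid <- function(i) sprintf("%s_C1", fams[i])
  mk <- function(i, ...) makeRecord(child_id = kid(i),
                                    family_id = fams[i], ...)
  bindRecords(
    mk(1),                                           # clean pass
    mk(1, gq_child = 19L), mk(1, gq_mother = 19L),   # GQ boundary fails
    mk(1, gq_father = 20L),                          # GQ boundary passes
    mk(2, dp_child = 9L), mk(2, dp_father = 9L),     # DP fails
    mk(2, dp_mother = 10L),                          # DP passes
    mk(2, popmax_af = 0.001),                        # AF boundary kept
    mk(3, popmax_af = 0.0011),                       # AF above: rejected
    mk(3, popmax_af = NA_real_),                     # missing AF = novel
    mk(3, alt = paste0("C", strrep("A", 10))),       # 10-A run: rejected
    mk(3, alt = paste0("C", strrep("A", 9))),        # 9-A run: kept
    mk(4, ref = strrep("T", 10), alt = "G"),         # run in REF
    mk(4, alt = paste0("G", strrep("T", 9), "C",
                       strrep("T", 9))),             # interrupted run kept
    mk(4, pos = 1500L),                              # inside region
    mk(5, pos = 2000L),                              # region end, inside
    mk(5, pos = 2001L),                              # just outside
    mk(5, pos = 1000L),                              # before region
    mk(5, n_alt = 4L),                               # >3 ALT alleles
    mk(6, n_alt = 3L),                               # 3 ALT alleles kept
    mk(6, chrom = "1", pos = 999999L, ref = "C", alt = "T"),
    mk(7, chrom = "1", pos = 999999L, ref = "C", alt = "T"),
    mk(8, chrom = "1", pos = 999999L, ref = "C", alt = "T"),
    mk(9, chrom = "1", pos = 999999L, ref = "C", alt = "T"),
    mk(6, chrom = "1", pos = 999988L, ref = "G", alt = "A"),
    mk(7, chrom = "1", pos = 999988L, ref = "G", alt = "A"),
    mk(8, chrom = "1", pos = 999988L, ref = "G", alt = "A"),
    mk(10, chrom = "1", pos = 999977L, ref = "A", alt = "G"),
    mk(9, chrom = "1", pos = 999977L, ref = "A", alt = "G",
       child_gt = "het", mother_gt = "het"),         # carrier parent
    mk(10, gq_child = 19L, popmax_af = 0.5)          # two failing rules
  )
}

writeLinesTmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
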