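# brute-force re-implementation of the de novo rules, written as plain
# per-record loops, independent of the vectorized cascade: every rule is
# re-derived from first principles against every record
oracleDnv <- function(variants, individuals, regions = NULL,
                      gq_min = 20, dp_min = 10, af_max = 0.001,
                      homopolymer_len = 10, max_families = 3,
                      max_alt = 3) {
  n <- nrow(variants)
  candidate <- logical(n)
  ab <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    r <- variants[i, ]
    if (r$chrom %in% c("Y", "chrY")) next
    tot <- r$ref_reads + r$alt_reads
    if (is.na(tot) || tot == 0) next
    ab[i] <- r$alt_reads / tot
    if (ab[i] <= 0.25) next
    sex <- individuals$sex[individuals$person_id == r$child_id]
    hemi <- r$chrom %in% c("X", "chrX") && length(sex) && sex == "male"
    if (hemi) {
      if (r$child_gt %in% c("het", "hom_alt") && r$mother_gt == "hom_ref")
        candidate[i] <- TRUE
    } else {
      if (r$child_gt == "het" && r$mother_gt == "hom_ref" &&
            r$father_gt == "hom_ref")
        candidate[i] <- TRUE
    }
  }
  fails <- vector("list", n)
  has_run <- function(s, len) {
    chars <- strsplit(s, "")[[1]]
    run <- 0; best <- 0; prev <- ""
    for (ch in chars) {
      if (ch %in% c("A", "T") && ch == prev) run <- run + 1
      else if (ch %in% c("A", "T")) run <- 1
      else run <- 0
      prev <- ch
      best <- max(best, run)
    }
    best >= len
  }
  for (i in which(candidate)) {
    r <- variants[i, ]
    f <- character(0)
    if (min(r$gq_child, r$gq_mother, r$gq_father) < gq_min)
      f <- c(f, "gq")
    if (min(r$dp_child, r$dp_mother, r$dp_father) < dp_min)
      f <- c(f, "dp")
    afv <- if (is.na(r$popmax_af)) 0 else r$popmax_af
    if (afv > af_max) f <- c(f, "af")
    if (has_run(r$ref, homopolymer_len) || has_run(r$alt, homopolymer_len))
      f <- c(f, "homopolymer")
    in_region <- FALSE
    if (!is.null(regions) && length(regions)) {
      for (j in seq_along(regions)) {
        if (as.character(GenomicRanges::seqnames(regions)[j]) == r$chrom &&
              r$pos >= GenomicRanges::start(regions)[j] &&
              r$pos <= GenomicRanges::end(regions)[j])
          in_region <- TRUE
      }
    }
    if (in_region) f <- c(f, "region")
    other_parent <- FALSE
    for (j in seq_len(nrow(variants))) {
      rj <- variants[j, ]
      if (rj$variant_id == r$variant_id &&
            rj$family_id != r$family_id &&
            (rj$mother_gt %in% c("het", "hom_alt") ||
               rj$father_gt %in% c("het", "hom_alt")))
        other_parent <- TRUE
    }
    if (other_parent) f <- c(f, "parent_other_family")
    fams <- unique(variants$family_id[candidate &
                                        variants$variant_id == r$variant_id])
    if (length(fams) > max_families) f <- c(f, "multi_family_children")
    if (r$n_alt_alleles_at_site > max_alt) f <- c(f, "multiallelic")
    fails[[i]] <- f
  }
  data.frame(
    record_id = variants$record_id,
    candidate = candidate,
    passed = candidate & vapply(fails, length, integer(1)) == 0,
    rejected_by = vapply(fails, paste, character(1), collapse = ","),
    stringsAsFactors = FALSE
  )
}

# inherited-variant rules, brute force per record
oracleInherited <- function(variants, panel, af_dom = 0.001,
                            af_rec = 0.01, gq_min = 20, dp_min = 10) {
  keep <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    r <- variants[i, ]
    mode <- panel$inheritance[panel$gene %in% r$gene]
    if (!length(mode) || !mode %in% c("dominant", "recessive")) next
    afv <- if (is.na(r$popmax_af)) 0 else r$popmax_af
    if (mode == "dominant" && afv > af_dom) next
    if (mode == "recessive" && afv > af_rec) next
    mo <- r$mother_gt %in% c("het", "hom_alt")
    fa <- r$father_gt %in% c("het", "hom_alt")
    gq <- r$gq_child; dp <- r$dp_child
    if (mo) { gq <- min(gq, r$gq_mother); dp <- min(dp, r$dp_mother) }
    if (fa) { gq <- min(gq, r$gq_father); dp <- min(dp, r$dp_father) }
    if (gq < gq_min || dp < dp_min) next
    ok <- FALSE
    if (mode == "dominant" && r$child_gt == "het" && (mo || fa)) ok <- TRUE
    if (mode == "recessive" && r$child_gt == "hom_alt" && mo && fa)
      ok <- TRUE
    if (mode == "recessive" && r$child_gt == "het" && (mo || fa))
      ok <- TRUE   # compound-het candidate stage
    keep[i] <- ok
  }
  variants$record_id[keep]
}
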