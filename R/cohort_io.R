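#' Assign gestational-age strata
#'
#' Maps gestational age at birth (completed weeks) to the preterm strata
#' used throughout: extremely preterm (< 28 weeks), very preterm (28--31),
#' moderate preterm (32--33), late preterm (34--36) and term (>= 37).
#' Individuals flagged preterm without a recorded gestational age fall into
#' the `unknown_ga` stratum.
#'
#' @param ga Integer vector of gestational ages in weeks (`NA` allowed).
#' @param preterm Optional character (`"yes"`/`"no"`) or logical vector used
#'   only where `ga` is missing. When `NULL`, missing `ga` yields `NA`.
#' @return Factor with levels extremely, very, moderate, late, unknown_ga,
#'   term.
#' @export
pretermStratum <- function(ga, preterm = NULL) {
  n <- length(ga)
  out <- rep(NA_character_, n)
  known <- !is.na(ga)
  out[known & ga < 28] <- "extremely"
  out[known & ga >= 28 & ga <= 31] <- "very"
  out[known & ga >= 32 & ga <= 33] <- "moderate"
  out[known & ga >= 34 & ga <= 36] <- "late"
  out[known & ga >= 37] <- "term"
  if (!is.null(preterm)) {
    if (is.logical(preterm)) preterm <- ifelse(preterm, "yes", "no")
    out[!known & !is.na(preterm) & preterm == "yes"] <- "unknown_ga"
    out[!known & !is.na(preterm) & preterm == "no"] <- "term"
  }
  factor(out, levels = .STRATUM_LEVELS)
}

.norm_yesno <- function(x) {
  if (is.logical(x)) return(ifelse(x, "yes", "no"))
  if (is.numeric(x)) return(ifelse(x > 0, "yes", "no"))
  tolower(as.character(x))
}

#' Read a phenotype table
#'
#' Reads a one-row-per-person CSV holding demographics, gestational age,
#' ASD status, specific-diagnosis counts for the nine diagnostic categories
#' (counts or booleans), and quantitative measures. Rows with implausible
#' or post-term gestational ages are rejected (defaults: keep 20--40
#' weeks, configurable). The preterm flag and stratum are derived from
#' gestational age where known; a preterm flag in the file covers the
#' missing-GA ("unknown GA") cases.
#'
#' @param path CSV file path.
#' @param ga_min,ga_max Gestational-age acceptance bounds in weeks; rows
#'   outside are dropped with a message.
#' @return List with `individuals`, `profiles` and `quant` data.frames.
#' @export
readPhenotypeTable <- function(path, ga_min = 20, ga_max = 40) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("person_id", "family_id", "sex", "role", "asd")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  if (!"gestational_age_weeks" %in% names(df))
    df$gestational_age_weeks <- NA_integer_
  ga <- df$gestational_age_weeks
  bad <- !is.na(ga) & (ga < ga_min | ga > ga_max)
  if (any(bad)) {
    message(sum(bad), " row(s) rejected: gestational age outside [",
            ga_min, ", ", ga_max, "] weeks")
    df <- df[!bad, , drop = FALSE]
  }
  ga <- df$gestational_age_weeks
  flag <- if ("preterm" %in% names(df)) .norm_yesno(df$preterm) else
    rep(NA_character_, nrow(df))
  preterm <- ifelse(!is.na(ga), ifelse(ga < 37, "yes", "no"), flag)
  ind <- data.frame(
    person_id = as.character(df$person_id),
    family_id = as.character(df$family_id),
    sex = tolower(df$sex),
    role = tolower(df$role),
    asd = .norm_yesno(df$asd),
    gestational_age_weeks = as.integer(ga),
    preterm = preterm,
    preterm_stratum = pretermStratum(ga, preterm),
    stringsAsFactors = FALSE
  )
  for (col in c("mother_id", "father_id"))
    ind[[col]] <- if (col %in% names(df)) as.character(df[[col]]) else NA_character_
  for (col in c("age_years"))
    ind[[col]] <- if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  for (col in c("birth_complications", "insufficient_oxygen"))
    ind[[col]] <- if (col %in% names(df)) as.integer(df[[col]] > 0) else NA_integer_

  prof <- data.frame(person_id = ind$person_id, stringsAsFactors = FALSE)
  for (cat in diagCategories()) {
    v <- if (cat %in% names(df)) df[[cat]] else 0
    if (is.logical(v) || is.character(v))
      v <- as.integer(.norm_yesno(v) == "yes")
    prof[[cat]] <- as.integer(v)
  }
  qcols <- c("cbcl_1_5", "cbcl_6_18", "dcdq", "rbsr", "scq", "fsiq")
  quant <- data.frame(person_id = ind$person_id, stringsAsFactors = FALSE)
  for (col in qcols)
    quant[[col]] <- if (col %in% names(df)) as.numeric(df[[col]]) else NA_real_
  list(individuals = ind, profiles = prof, quant = quant)
}

#' Read an NDD gene panel
#'
#' Reads a tab-separated gene panel with columns `gene` and `inheritance`
#' (plus optional `source_flag`). Inheritance labels are normalized:
#' monoallelic/dominant -> dominant, biallelic/recessive -> recessive,
#' anything else -> unannotated. Duplicate rows for a gene are collapsed;
#' duplicates with conflicting modes are an error.
#'
#' @param path TSV file path.
#' @return data.frame with columns gene, inheritance, source_flag.
#' @export
readGenePanel <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "inheritance") %in% names(df)))
    stop("gene panel needs columns gene, inheritance")
  if (!"source_flag" %in% names(df)) df$source_flag <- ""
  normalizeInheritance(df)
}

#' @rdname readGenePanel
#' @param df data.frame with gene/inheritance columns (in-memory variant).
#' @export
normalizeInheritance <- function(df) {
  mode <- tolower(trimws(df$inheritance))
  mode[mode %in% c("monoallelic", "dominant")] <- "dominant"
  mode[mode %in% c("biallelic", "recessive")] <- "recessive"
  mode[!mode %in% c("dominant", "recessive")] <- "unannotated"
  out <- data.frame(gene = as.character(df$gene), inheritance = mode,
                    source_flag = as.character(df$source_flag),
                    stringsAsFactors = FALSE)
  dup <- unique(out$gene[duplicated(out$gene)])
  for (g in dup) {
    modes <- unique(out$inheritance[out$gene == g])
    if (length(modes) > 1)
      stop("conflicting inheritance modes for gene ", g, ": ",
           paste(modes, collapse = " vs "))
  }
  out[!duplicated(out$gene), , drop = FALSE]
}

#' Read an excluded-region BED file
#'
#' Imports a BED file (0-based half-open intervals) of regions excluded
#' from de novo calling (genomic centromeres, low-complexity regions) and
#' normalizes it by sorting and merging overlaps.
#'
#' @param path BED file path.
#' @return A reduced, sorted `GRanges`.
#' @export
readRegionsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

#' Read a PRS weight table
#'
#' Tab-separated columns: `variant_id`, `effect_allele`, `weight`.
#' Variant ids must be unique.
#'
#' @param path TSV file path.
#' @return data.frame of weights.
#' @export
readPrsWeights <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("variant_id", "effect_allele", "weight") %in% names(df)))
    stop("weights need columns variant_id, effect_allele, weight")
  if (anyDuplicated(df$variant_id))
    stop("duplicate variant_id in PRS weights")
  df$weight <- as.numeric(df$weight)
  df
}

.parse_gt <- function(gt, k) {
  # gt: character genotype strings; k: 1-based ALT allele index
  out <- rep("missing", length(gt))
  parts <- strsplit(gt, "[/|]")
  for (i in seq_along(parts)) {
    al <- parts[[i]]
    if (any(al == "." | is.na(al)) || !length(al)) next
    al <- suppressWarnings(as.integer(al))
    if (anyNA(al)) next
    nk <- sum(al == k)
    if (length(al) == 1) {            # hemizygous call
      out[i] <- if (nk == 1) "hom_alt" else "hom_ref"
    } else {
      out[i] <- c("hom_ref", "het", "hom_alt")[nk + 1]
    }
  }
  out
}

.info_field <- function(info_df, field, idx, k, default = NA) {
  if (!field %in% names(info_df)) return(rep(default, length(idx)))
  v <- info_df[[field]]
  if (is(v, "List") || is.list(v)) {
    mapply(function(i, kk) {
      x <- v[[i]]
      if (length(x) >= kk) x[[kk]] else default
    }, idx, k)
  } else {
    unlist(v)[idx]
  }
}

#' Read trio variant records from a VCF
#'
#' Parses a multi-sample VCF (GT/AD/GQ/DP per sample) into one record per
#' (child, site), using a pedigree to pair each child with its mother and
#' father; multi-child families yield one trio per child. Multiallelic
#' sites are decomposed into biallelic records that retain the original
#' ALT-allele count of the site (INFO field `NALT` overrides the observed
#' count, so pre-decomposed VCFs keep their site-level count). Variant
#' annotations are taken from INFO fields `AFPOP`, `GENE`, `CSQ`
#' (`&`-separated consequence terms), `EXONIC`, `CADD`, `PHYLOP`, `REVEL`,
#' `SIFT`, `POLYPHEN` when present.
#'
#' @param path VCF file path.
#' @param pedigree data.frame with columns `child_id`, `mother_id`,
#'   `father_id`, `family_id`.
#' @return data.frame of trio variant records (one row per child x site).
#' @export
readTrioVcf <- function(path, pedigree) {
  req <- c("child_id", "mother_id", "father_id", "family_id")
  if (!all(req %in% names(pedigree)))
    stop("pedigree needs columns ", paste(req, collapse = ", "))
  vcf <- VariantAnnotation::readVcf(path)
  samples <- colnames(vcf)
  gt <- VariantAnnotation::geno(vcf)$GT
  ad <- if ("AD" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$AD else NULL
  gq <- if ("GQ" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$GQ else NULL
  dp <- if ("DP" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$DP else NULL
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  refs <- as.character(VariantAnnotation::ref(vcf))
  alt_list <- VariantAnnotation::alt(vcf)
  nalt <- S4Vectors::elementNROWS(alt_list)
  info_df <- VariantAnnotation::info(vcf)

  # expand (site, alt index) pairs
  site_idx <- rep(seq_along(pos), nalt)
  alt_idx <- unlist(lapply(nalt, seq_len))
  alts <- as.character(unlist(alt_list))
  nalt_site <- nalt[site_idx]
  if ("NALT" %in% names(info_df)) {
    declared <- suppressWarnings(as.integer(unlist(info_df$NALT)))[site_idx]
    nalt_site <- ifelse(is.na(declared), nalt_site, declared)
  }

  out <- vector("list", nrow(pedigree))
  for (ci in seq_len(nrow(pedigree))) {
    ch <- pedigree$child_id[ci]
    mo <- pedigree$mother_id[ci]
    fa <- pedigree$father_id[ci]
    if (!all(c(mo, fa) %in% samples)) {
      warning("child ", ch, " skipped: parent sample(s) missing from VCF")
      next
    }
    if (!ch %in% samples) {
      warning("child ", ch, " skipped: sample missing from VCF")
      next
    }
    cgt <- mgt <- fgt <- character(length(site_idx))
    for (kk in unique(alt_idx)) {
      sel <- alt_idx == kk
      cgt[sel] <- .parse_gt(gt[site_idx[sel], ch], kk)
      mgt[sel] <- .parse_gt(gt[site_idx[sel], mo], kk)
      fgt[sel] <- .parse_gt(gt[site_idx[sel], fa], kk)
    }
    get_ad <- function(i, k) {
      if (is.null(ad)) return(c(NA_integer_, NA_integer_))
      x <- ad[i, ch][[1]]
      if (length(x) < k + 1) return(c(NA_integer_, NA_integer_))
      c(x[1], x[k + 1])
    }
    adm <- t(mapply(get_ad, site_idx, alt_idx))
    num_geno <- function(m, s) {
      if (is.null(m)) return(rep(NA_integer_, length(site_idx)))
      as.integer(m[site_idx, s])
    }
    rec <- data.frame(
      record_id = NA_character_,
      variant_id = paste(chrom[site_idx], pos[site_idx], refs[site_idx],
                         alts, sep = ":"),
      chrom = chrom[site_idx], pos = pos[site_idx],
      ref = refs[site_idx], alt = alts,
      n_alt_alleles_at_site = as.integer(nalt_site),
      family_id = pedigree$family_id[ci], child_id = ch,
      child_gt = cgt, mother_gt = mgt, father_gt = fgt,
      ref_reads = adm[, 1], alt_reads = adm[, 2],
      gq_child = num_geno(gq, ch), gq_mother = num_geno(gq, mo),
      gq_father = num_geno(gq, fa),
      dp_child = num_geno(dp, ch), dp_mother = num_geno(dp, mo),
      dp_father = num_geno(dp, fa),
      popmax_af = as.numeric(.info_field(info_df, "AFPOP", site_idx, alt_idx,
                                         NA_real_)),
      consequence = as.character(.info_field(info_df, "CSQ", site_idx,
                                             alt_idx, NA_character_)),
      gene = as.character(.info_field(info_df, "GENE", site_idx, alt_idx,
                                      NA_character_)),
      is_exonic = as.logical(as.integer(.info_field(info_df, "EXONIC",
                                                    site_idx, alt_idx, NA))),
      cadd = as.numeric(.info_field(info_df, "CADD", site_idx, alt_idx,
                                    NA_real_)),
      phylop = as.numeric(.info_field(info_df, "PHYLOP", site_idx, alt_idx,
                                      NA_real_)),
      revel = as.numeric(.info_field(info_df, "REVEL", site_idx, alt_idx,
                                     NA_real_)),
      sift = as.character(.info_field(info_df, "SIFT", site_idx, alt_idx,
                                      NA_character_)),
      polyphen = as.character(.info_field(info_df, "POLYPHEN", site_idx,
                                          alt_idx, NA_character_)),
      origin = NA_character_,
      stringsAsFactors = FALSE
    )
    rec$gene[rec$gene %in% c(".", "")] <- NA_character_
    rec$sift[!rec$sift %in% c("D", "T")] <- NA_character_
    rec$polyphen[!rec$polyphen %in% c("D", "P", "B")] <- NA_character_
    out[[ci]] <- rec
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res)) return(emptyVariantTable())
  res$record_id <- sprintf("R%06d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

#' @rdname readTrioVcf
#' @export
emptyVariantTable <- function() {
  cols <- .VARIANT_COLS
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                      stringsAsFactors = FALSE)
  df
}

.gt_string <- function(gt) {
  c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")[gt]
}

#' Write a cohort to disk
#'
#' Writes the standard file layout for a cohort directory: a multi-sample
#' VCF of the trio variant records (`cohort.vcf`), `phenotype.csv`,
#' `panel.tsv`, `prs_weights.tsv`, `prs_genotypes.tsv`, `regions.bed`, and,
#' when simulation truth is attached, `truth.json`. Intended for small to
#' moderate cohorts; the VCF carries one column per cohort member.
#'
#' @param cohort A [Cohort].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  stopifnot(is(cohort, "Cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ind <- cohort@individuals
  v <- cohort@variants

  ## phenotype table
  ph <- merge(ind, cohort@profiles, by = "person_id", all.x = TRUE)
  ph <- merge(ph, cohort@quant, by = "person_id", all.x = TRUE)
  ph$preterm_stratum <- NULL
  utils::write.csv(ph, file.path(dir, "phenotype.csv"), row.names = FALSE)

  if (nrow(cohort@panel))
    utils::write.table(cohort@panel, file.path(dir, "panel.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (nrow(cohort@prsWeights))
    utils::write.table(cohort@prsWeights, file.path(dir, "prs_weights.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (ncol(cohort@prsGeno)) {
    g <- data.frame(person_id = rownames(cohort@prsGeno), cohort@prsGeno,
                    check.names = FALSE)
    utils::write.table(g, file.path(dir, "prs_genotypes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(cohort@prsVariants, file.path(dir, "prs_variants.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(cohort@regions) && length(cohort@regions))
    rtracklayer::export(cohort@regions, file.path(dir, "regions.bed"),
                        format = "BED")
  if (length(cohort@truth))
    jsonlite::write_json(cohort@truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  if (nrow(v)) .write_cohort_vcf(cohort, file.path(dir, "cohort.vcf"))
  invisible(dir)
}

.write_cohort_vcf <- function(cohort, path) {
  v <- cohort@variants
  ind <- cohort@individuals
  samples <- ind$person_id
  vt <- data.table::as.data.table(v)
  vt <- vt[order(chrom, pos, alt)]
  keys <- unique(vt$variant_id)
  nS <- length(samples)
  sidx <- stats::setNames(seq_len(nS), samples)

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AFPOP,Number=A,Type=Float,Description=\"Population popmax allele frequency\">",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQ,Number=A,Type=String,Description=\"Consequence terms, &-separated\">",
    "##INFO=<ID=EXONIC,Number=A,Type=Integer,Description=\"Exonic flag\">",
    "##INFO=<ID=CADD,Number=A,Type=Float,Description=\"CADD phred score\">",
    "##INFO=<ID=PHYLOP,Number=A,Type=Float,Description=\"PhyloP conservation\">",
    "##INFO=<ID=REVEL,Number=A,Type=Float,Description=\"REVEL score\">",
    "##INFO=<ID=SIFT,Number=A,Type=String,Description=\"SIFT class\">",
    "##INFO=<ID=POLYPHEN,Number=A,Type=String,Description=\"PolyPhen class\">",
    "##INFO=<ID=NALT,Number=1,Type=Integer,Description=\"ALT allele count at original site\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  vsplit <- split(seq_len(nrow(vt)), vt$variant_id)
  for (key in keys) {
    rows <- vt[vsplit[[key]]]
    r1 <- rows[1]
    gts <- rep("0/0", nS); ads <- rep("30,0", nS)
    dps <- rep("30", nS); gqs <- rep("60", nS)
    for (j in seq_len(nrow(rows))) {
      rj <- rows[j]
      fam <- ind[ind$person_id == rj$child_id, ]
      mo <- fam$mother_id; fa <- fam$father_id
      ci <- sidx[[rj$child_id]]
      gts[ci] <- .gt_string(rj$child_gt)
      ads[ci] <- paste0(rj$ref_reads, ",", rj$alt_reads)
      dps[ci] <- fmt_num(rj$dp_child); gqs[ci] <- fmt_num(rj$gq_child)
      if (!is.na(mo) && mo %in% samples) {
        mi <- sidx[[mo]]
        gts[mi] <- .gt_string(rj$mother_gt)
        dpm <- rj$dp_mother
        ads[mi] <- switch(rj$mother_gt,
          hom_ref = paste0(dpm, ",0"), het = paste0(dpm %/% 2, ",", dpm %/% 2),
          hom_alt = paste0("0,", dpm), "./.")
        dps[mi] <- fmt_num(dpm); gqs[mi] <- fmt_num(rj$gq_mother)
      }
      if (!is.na(fa) && fa %in% samples) {
        fi <- sidx[[fa]]
        gts[fi] <- .gt_string(rj$father_gt)
        dpf <- rj$dp_father
        ads[fi] <- switch(rj$father_gt,
          hom_ref = paste0(dpf, ",0"), het = paste0(dpf %/% 2, ",", dpf %/% 2),
          hom_alt = paste0("0,", dpf), "./.")
        dps[fi] <- fmt_num(dpf); gqs[fi] <- fmt_num(rj$gq_father)
      }
    }
    info <- paste0(
      "AFPOP=", fmt_num(r1$popmax_af),
      ";GENE=", ifelse(is.na(r1$gene), ".", r1$gene),
      ";CSQ=", ifelse(is.na(r1$consequence), ".", r1$consequence),
      ";EXONIC=", ifelse(is.na(r1$is_exonic), ".", as.integer(r1$is_exonic)),
      ";CADD=", fmt_num(r1$cadd), ";PHYLOP=", fmt_num(r1$phylop),
      ";REVEL=", fmt_num(r1$revel),
      ";SIFT=", ifelse(is.na(r1$sift), ".", r1$sift),
      ";POLYPHEN=", ifelse(is.na(r1$polyphen), ".", r1$polyphen),
      ";NALT=", r1$n_alt_alleles_at_site
    )
    line <- paste(c(r1$chrom, r1$pos, ".", r1$ref, r1$alt, ".", "PASS", info,
                    "GT:AD:DP:GQ",
                    paste(gts, ads, dps, gqs, sep = ":")), collapse = "\t")
    writeLines(line, con)
  }
  invisible(path)
}

#' Pedigree of a cohort
#'
#' One row per child with its parent sample ids, derived from the
#' individuals table.
#'
#' @param individuals Individuals data.frame (as in [Cohort]).
#' @return data.frame with child_id, mother_id, father_id, family_id.
#' @export
cohortPedigree <- function(individuals) {
  ch <- individuals[individuals$role %in% c("proband", "sibling") &
                      !is.na(individuals$mother_id), , drop = FALSE]
  data.frame(child_id = ch$person_id, mother_id = ch$mother_id,
             father_id = ch$father_id, family_id = ch$family_id,
             stringsAsFactors = FALSE)
}

#' Cohort composition and preterm fractions
#'
#' Tabulates individuals by ASD and preterm status and reports the preterm
#' fraction within each ASD group (the "preterm in ASD" percentage of
#' cohort-characteristics tables). Rows with unknown preterm status are
#' excluded from the fractions.
#'
#' @param individuals Individuals data.frame, or a count data.frame with
#'   columns `asd` (`"yes"`/`"no"`), `preterm` (`"yes"`/`"no"`) and `n`.
#' @return List with `counts` (asd x preterm table) and
#'   `preterm_fraction` named by ASD group.
#' @export
cohortComposition <- function(individuals) {
  if ("n" %in% names(individuals)) {
    df <- individuals
  } else {
    keep <- !is.na(individuals$preterm) & !is.na(individuals$asd)
    df <- as.data.frame(table(asd = individuals$asd[keep],
                              preterm = individuals$preterm[keep]),
                        responseName = "n", stringsAsFactors = FALSE)
  }
  agg <- stats::aggregate(n ~ asd + preterm, df, sum)
  counts <- stats::xtabs(n ~ asd + preterm, agg)
  frac <- vapply(rownames(counts), function(g) {
    tot <- sum(counts[g, ])
    if (tot == 0) NA_real_ else counts[g, "yes"] / tot
  }, numeric(1))
  list(counts = counts, preterm_fraction = frac)
}

#' Assemble a cohort object
#'
#' Builds a validated [Cohort] from its component tables.
#'
#' @param individuals,profiles,quant,variants Component data.frames (see
#'   [Cohort]); missing pieces default to empty.
#' @param prsGeno,prsVariants,prsWeights PRS genotype matrix and tables.
#' @param panel Gene panel data.frame.
#' @param regions GRanges of excluded regions or `NULL`.
#' @param truth,metadata Lists.
#' @return A [Cohort].
#' @export
assembleCohort <- function(individuals, profiles = NULL, quant = NULL,
                           variants = NULL, prsGeno = NULL,
                           prsVariants = NULL, prsWeights = NULL,
                           panel = NULL, regions = NULL, truth = list(),
                           metadata = list()) {
  new("Cohort",
      individuals = individuals,
      profiles = if (is.null(profiles))
        data.frame(person_id = character(0)) else profiles,
      quant = if (is.null(quant))
        data.frame(person_id = character(0)) else quant,
      variants = if (is.null(variants)) emptyVariantTable() else variants,
      prsGeno = if (is.null(prsGeno)) matrix(numeric(0), 0, 0) else prsGeno,
      prsVariants = if (is.null(prsVariants)) data.frame() else prsVariants,
      prsWeights = if (is.null(prsWeights)) data.frame() else prsWeights,
      panel = if (is.null(panel)) data.frame() else panel,
      regions = regions, truth = truth, metadata = metadata)
}
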