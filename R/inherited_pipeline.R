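#' Extract records in annotated panel genes
#'
#' Restricts trio variant records to genes present in the NDD panel with a
#' dominant or recessive inheritance annotation. Records in panel genes
#' whose mode is unannotated are dropped and counted (reported via a
#' message and the `"n_unannotated_dropped"` attribute).
#'
#' @param variants Trio variant record data.frame.
#' @param panel Gene panel data.frame from [readGenePanel()].
#' @return Records in annotated panel genes, with a `mode` column.
#' @export
extractPanelVariants <- function(variants, panel) {
  mode <- panel$inheritance[match(variants$gene, panel$gene)]
  in_panel <- !is.na(mode)
  unann <- in_panel & mode == "unannotated"
  if (any(unann))
    message(sum(unann), " record(s) in unannotated panel genes dropped")
  keep <- in_panel & mode %in% c("dominant", "recessive")
  out <- variants[keep, , drop = FALSE]
  out$mode <- mode[keep]
  rownames(out) <- NULL
  attr(out, "n_unannotated_dropped") <- sum(unann)
  out
}

#' Filter rare inherited variants
#'
#' Applies the inherited-variant rules to panel-gene records: allele
#' frequency at most `af_dom` (dominant genes) or `af_rec` (recessive
#' genes; missing frequency counts as 0), genotype configurations
#' consistent with the gene's inheritance mode, and GQ/DP thresholds in
#' the child and the transmitting parent(s). Consistent configurations
#' are: dominant -- child het with at least one carrier parent; recessive
#' -- child hom-alt with both parents carriers, or child het with a
#' carrier parent, which is only a compound-heterozygote candidate (see
#' [scanCompoundHet()]). The de novo pattern (child het, both parents
#' hom-ref) is excluded here by definition. Recessive het calls with both
#' parents carriers cannot be phased by transmission and are marked
#' unphaseable.
#'
#' @param records Output of [extractPanelVariants()].
#' @param af_dom,af_rec Allele-frequency ceilings by mode.
#' @param gq_min,dp_min Quality/depth thresholds.
#' @return Inherited calls with `mode`, `transmitted_from`,
#'   `cht_candidate`, `unphaseable` and `compound_het_partner` columns.
#' @export
filterInherited <- function(records, af_dom = 0.001, af_rec = 0.01,
                            gq_min = 20, dp_min = 10) {
  r <- records
  n <- nrow(r)
  if (!n) {
    r$transmitted_from <- character(0); r$cht_candidate <- logical(0)
    r$unphaseable <- logical(0); r$compound_het_partner <- character(0)
    return(r)
  }
  af <- ifelse(is.na(r$popmax_af), 0, r$popmax_af)
  af_ok <- ifelse(r$mode == "dominant", af <= af_dom, af <= af_rec)
  mo_car <- r$mother_gt %in% c("het", "hom_alt")
  fa_car <- r$father_gt %in% c("het", "hom_alt")
  denovo <- r$child_gt == "het" & r$mother_gt == "hom_ref" &
    r$father_gt == "hom_ref"

  transmitted <- ifelse(mo_car & fa_car, "both",
                        ifelse(mo_car, "mother",
                               ifelse(fa_car, "father", NA_character_)))
  qc_ok <- function(need_mo, need_fa) {
    gq <- r$gq_child; dp <- r$dp_child
    gq <- ifelse(need_mo, pmin(gq, r$gq_mother), gq)
    dp <- ifelse(need_mo, pmin(dp, r$dp_mother), dp)
    gq <- ifelse(need_fa, pmin(gq, r$gq_father), gq)
    dp <- ifelse(need_fa, pmin(dp, r$dp_father), dp)
    !is.na(gq) & gq >= gq_min & !is.na(dp) & dp >= dp_min
  }
  qc <- qc_ok(mo_car, fa_car)

  dom_ok <- r$mode == "dominant" & r$child_gt == "het" & !denovo &
    (mo_car | fa_car)
  rec_hom <- r$mode == "recessive" & r$child_gt == "hom_alt" &
    mo_car & fa_car
  rec_het <- r$mode == "recessive" & r$child_gt == "het" & !denovo &
    (mo_car | fa_car)
  keep <- af_ok & qc & (dom_ok | rec_hom | rec_het)

  out <- r[keep, , drop = FALSE]
  out$transmitted_from <- transmitted[keep]
  out$cht_candidate <- rec_het[keep]
  out$unphaseable <- rec_het[keep] & transmitted[keep] == "both"
  out$compound_het_partner <- NA_character_
  rownames(out) <- NULL
  out
}

#' Pair compound-heterozygote candidates
#'
#' Among recessive-gene heterozygous calls, pairs calls in the same gene
#' and child with opposite parental origin (phased by transmission): every
#' maternal call is partnered with a paternal call in the same gene and
#' vice versa. Candidates that cannot be paired -- including unphaseable
#' calls (both parents carriers) -- are dropped from the recessive call
#' set. Dominant calls and recessive hom-alt calls pass through.
#'
#' @param calls Output of [filterInherited()].
#' @return Calls with `compound_het_partner` filled for paired hets and
#'   unpaired recessive hets removed.
#' @export
scanCompoundHet <- function(calls) {
  if (!nrow(calls)) return(calls)
  is_cand <- calls$cht_candidate
  keep <- !is_cand
  cand <- calls[is_cand & !calls$unphaseable, , drop = FALSE]
  paired_ids <- character(0)
  partners <- character(0)
  if (nrow(cand)) {
    grp <- split(seq_len(nrow(cand)),
                 paste(cand$child_id, cand$gene, sep = "\r"))
    for (idx in grp) {
      mat <- idx[cand$transmitted_from[idx] == "mother"]
      pat <- idx[cand$transmitted_from[idx] == "father"]
      if (length(mat) && length(pat)) {
        paired_ids <- c(paired_ids, cand$record_id[c(mat, pat)])
        partners <- c(partners,
                      rep(cand$record_id[pat[1]], length(mat)),
                      rep(cand$record_id[mat[1]], length(pat)))
      }
    }
  }
  out <- calls[keep | calls$record_id %in% paired_ids, , drop = FALSE]
  hit <- match(out$record_id, paired_ids)
  out$compound_het_partner <- ifelse(is.na(hit), NA_character_,
                                     partners[hit])
  rownames(out) <- NULL
  out
}

#' Classify dominant-gene inherited calls
#'
#' Flags loss-of-function calls (the six consequence classes of
#' [lofTerms()]) and damaging missense calls. A missense call is damaging
#' when at least one criterion holds: CADD >= 20, SIFT = D, PolyPhen in
#' {P, D}, PhyloP >= 2.0, or REVEL >= 0.5; missing scores contribute
#' nothing. Classification applies to dominant-gene calls only; recessive
#' calls are classified by genotype configuration alone.
#'
#' @param calls Inherited calls.
#' @return Calls with `class_lof` and `class_damaging_missense` columns.
#' @export
classifyDominant <- function(calls) {
  n <- nrow(calls)
  lof <- .is_lof(calls$consequence)
  mis <- .is_missense(calls$consequence)
  crit <- (!is.na(calls$cadd) & calls$cadd >= 20) |
    (!is.na(calls$sift) & calls$sift == "D") |
    (!is.na(calls$polyphen) & calls$polyphen %in% c("P", "D")) |
    (!is.na(calls$phylop) & calls$phylop >= 2.0) |
    (!is.na(calls$revel) & calls$revel >= 0.5)
  dom <- calls$mode == "dominant"
  calls$class_lof <- dom & lof
  calls$class_damaging_missense <- dom & mis & crit
  calls
}

#' Run the full inherited-variant pipeline on a cohort
#'
#' Panel extraction, rare-variant filtering, compound-heterozygote scan
#' and dominant-gene classification.
#'
#' @param cohort A [Cohort].
#' @param ... Passed to [filterInherited()].
#' @return Inherited call data.frame.
#' @export
inheritedPipeline <- function(cohort, ...) {
  stopifnot(is(cohort, "Cohort"))
  pv <- extractPanelVariants(variantRecords(cohort), genePanel(cohort))
  calls <- filterInherited(pv, ...)
  calls <- scanCompoundHet(calls)
  classifyDominant(calls)
}
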