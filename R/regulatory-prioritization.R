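#' @title High-risk regulatory variant prioritization
#' @description
#' The regulatory cascade works on a candidate table: one row per
#' (variant, sample) mapped to a regulatory region, with columns
#' `sample_id`, `chrom`, `pos`, `ref`, `alt`, `gene`, `lv_active`,
#' `in_regulatory_build`, `gnomad_af`, `popmax_af`, the four TFBS verdict
#' columns (`tfbs_regulomedb`, `tfbs_motifbreakr`, `tfbs_deepsea`,
#' `tfbs_fathmm_mkl`), and optionally `variant_type` ("snv" or
#' "cnv_or_indel" — the latter bypasses the TFBS consensus, which is
#' SNV-oriented, but must pass every other gate).
#' @name regulatory_prioritization
NULL

#' Default thresholds for the regulatory cascade
#'
#' @param tfbs_min_tools Minimum TFBS tools calling an alteration, of 4.
#'   Default 3.
#' @param gnomad_af_max Strict gnomAD AF bound for high-risk status.
#'   Default 1e-4 (0.01%).
#' @param popmax_af_max Strict Popmax AF bound for prioritization. Default
#'   1e-3 (0.1%).
#' @param cohort_fraction_max Inclusive cohort carrier-fraction exclusion
#'   bound. Default 0.015 (1.5%).
#' @param or_min Inclusive per-gene odds-ratio gate. Default 1.3.
#' @return Named list of thresholds.
#' @export
reg_thresholds <- function(tfbs_min_tools = 3, gnomad_af_max = 1e-4,
                           popmax_af_max = 1e-3, cohort_fraction_max = 0.015,
                           or_min = 1.3) {
  stopifnot(tfbs_min_tools >= 1, tfbs_min_tools <= 4, gnomad_af_max > 0,
            popmax_af_max > 0, cohort_fraction_max > 0, or_min > 0)
  list(tfbs_min_tools = tfbs_min_tools, gnomad_af_max = gnomad_af_max,
       popmax_af_max = popmax_af_max,
       cohort_fraction_max = cohort_fraction_max, or_min = or_min)
}

#' TFBS alteration consensus over the four predictors
#'
#' True when at least `min_tools` of exactly 4 tool verdicts call the
#' binding site altered (motif gain or loss).
#'
#' @param altered Logical vector of length 4 (one variant) or an n x 4
#'   logical matrix / data frame.
#' @param min_tools Minimum agreeing tools, default 3.
#' @return Logical scalar or vector.
#' @export
#' @examples
#' tfbs_consensus(c(TRUE, TRUE, TRUE, FALSE))  # TRUE
tfbs_consensus <- function(altered, min_tools = 3) {
  if (is.data.frame(altered)) altered <- as.matrix(altered)
  if (is.matrix(altered)) {
    if (ncol(altered) != 4) .stopf("expected exactly 4 TFBS tool verdicts")
    return(rowSums(altered, na.rm = TRUE) >= min_tools)
  }
  if (length(altered) != 4) .stopf("expected exactly 4 TFBS tool verdicts")
  sum(altered, na.rm = TRUE) >= min_tools
}

#' High-risk regulatory variant filter
#'
#' A candidate is high-risk when its region overlaps the Ensembl Regulatory
#' Build, it is rare in gnomAD (AF < 0.01%, strict; absent passes), and the
#' TFBS consensus holds (3 of 4 tools; bypassed for `variant_type ==
#' "cnv_or_indel"`).
#'
#' @param candidates Candidate table (see [regulatory_prioritization]).
#' @param thresholds See [reg_thresholds].
#' @return Logical vector.
#' @export
high_risk_filter <- function(candidates, thresholds = reg_thresholds()) {
  tf <- tfbs_consensus(candidates[, .tfbs_cols], thresholds$tfbs_min_tools)
  if (!is.null(candidates$variant_type))
    tf <- tf | candidates$variant_type == "cnv_or_indel"
  candidates$in_regulatory_build &
    is_rare(candidates$gnomad_af, thresholds$gnomad_af_max) &
    tf
}

#' Cohort carrier-frequency exclusion
#'
#' A variant carried by at least 1.5% of study-cohort samples (inclusive) is
#' excluded from burden testing as a likely recurrent artifact: 4 carriers
#' of 209 (1.91%) are excluded, 3 of 209 (1.44%) are kept.
#'
#' @param carriers Carrier count(s) for the variant in the study cohort.
#' @param n_samples Study cohort size.
#' @param max_frac Inclusive exclusion bound, default 0.015.
#' @return Logical: TRUE when the variant is excluded.
#' @export
cohort_frequency_exclusion <- function(carriers, n_samples,
                                       max_frac = 0.015) {
  carriers / n_samples >= max_frac
}

#' Build the regulatory candidate table from variants and regions
#'
#' Maps variants to merged regulatory regions (a variant at 1-based
#' position p overlaps \[s, e) iff s <= p - 1 < e) and expands one
#' candidate row per (variant, linked gene). The region's `lv_active` and
#' `in_regulatory_build` flags are carried onto each candidate. SNVs get
#' `variant_type "snv"`; indels (multi-base ref or alt) get
#' `"cnv_or_indel"`, which bypasses the SNV-oriented TFBS consensus
#' downstream.
#'
#' @param variants QC-passed variant table.
#' @param regions Merged region table (see [merge_regions]).
#' @return Candidate table (see [regulatory_prioritization]).
#' @export
build_regulatory_candidates <- function(variants, regions) {
  check_variants(variants)
  .check_regions(regions)
  out <- list()
  for (ch in intersect(unique(variants$chrom), unique(regions$chrom))) {
    v <- variants[variants$chrom == ch, , drop = FALSE]
    r <- regions[regions$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(v$pos, width = 1L),          # 1-based point
      IRanges::IRanges(r$start + 1L, r$end))
    if (length(hits) == 0) next
    vi <- S4Vectors::queryHits(hits); ri <- S4Vectors::subjectHits(hits)
    genes <- strsplit(r$genes[ri], ";", fixed = TRUE)
    rep_v <- rep(vi, lengths(genes))
    rep_r <- rep(ri, lengths(genes))
    cand <- v[rep_v, c("sample_id", "chrom", "pos", "ref", "alt",
                       "gnomad_af", "popmax_af", .tfbs_cols), drop = FALSE]
    cand$gene <- unlist(genes)
    cand$region_kind <- r$kind[rep_r]
    cand$lv_active <- r$lv_active[rep_r]
    cand$in_regulatory_build <- r$in_regulatory_build[rep_r]
    cand$variant_type <- ifelse(nchar(v$ref[rep_v]) > 1 |
                                  nchar(v$alt[rep_v]) > 1,
                                "cnv_or_indel", "snv")
    out[[length(out) + 1]] <- cand
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gnomad_af = numeric(0),
                      popmax_af = numeric(0),
                      tfbs_regulomedb = logical(0),
                      tfbs_motifbreakr = logical(0),
                      tfbs_deepsea = logical(0),
                      tfbs_fathmm_mkl = logical(0), gene = character(0),
                      region_kind = character(0), lv_active = logical(0),
                      in_regulatory_build = logical(0),
                      variant_type = character(0)))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-pass prioritization of high-risk regulatory variants
#'
#' Pass 1 keeps high-risk candidates (see [high_risk_filter]) whose region
#' is active in the human left ventricle, whose Popmax AF is below 0.1%
#' (strict, absent passes), and which survive the cohort-frequency
#' exclusion (computed over case-cohort carriers of the variant). Pass 2
#' computes, per gene, the Haldane-Anscombe odds ratio of distinct pass-1
#' carrier samples in cases versus controls and retains only candidates
#' whose gene reaches `or_min` (inclusive); the final prioritized set is
#' further restricted to carriers that are gene-elusive cases. The odds
#' ratio gate is computed on the post-filter, pre-prioritization candidate
#' set.
#'
#' @param candidates Candidate table covering case and control samples.
#' @param case_status Data frame with columns `sample_id`, `cohort`
#'   ("case"/"control"), and `gene_elusive` (logical; only meaningful for
#'   cases).
#' @param thresholds See [reg_thresholds].
#' @return The candidate table with added logical columns `high_risk`,
#'   `pass1`, `prioritized`, plus `gene_or` (the gene's pass-1 odds ratio).
#'   The per-gene odds-ratio table is attached as attribute `"gene_or"`.
#' @export
prioritize_regulatory <- function(candidates, case_status,
                                  thresholds = reg_thresholds()) {
  cs <- case_status
  n_cases <- sum(cs$cohort == "case")
  n_controls <- sum(cs$cohort == "control")
  if (n_controls == 0)
    .stopf("no control samples supplied: odds ratio undefined")
  x <- candidates
  cohort <- cs$cohort[match(x$sample_id, cs$sample_id)]
  elusive <- cs$gene_elusive[match(x$sample_id, cs$sample_id)]
  if (any(is.na(cohort))) .stopf("candidate sample missing from case_status")

  x$high_risk <- high_risk_filter(x, thresholds)

  # cohort-frequency exclusion over distinct case carriers of each variant
  key <- paste(x$chrom, x$pos, x$ref, x$alt)
  case_carriers_of <- vapply(unique(key), function(k)
    length(unique(x$sample_id[key == k & cohort == "case"])), integer(1))
  excluded <- cohort_frequency_exclusion(case_carriers_of[key], n_cases,
                                         thresholds$cohort_fraction_max)

  x$pass1 <- x$high_risk & x$lv_active &
    is_rare(x$popmax_af, thresholds$popmax_af_max) & !excluded

  # pass 2: per-gene carrier odds ratio on pass-1 candidates
  p1 <- x[x$pass1, , drop = FALSE]
  p1_cohort <- cohort[x$pass1]
  genes <- sort(unique(x$gene))
  a <- vapply(genes, function(g)
    length(unique(p1$sample_id[p1$gene == g & p1_cohort == "case"])),
    integer(1))
  cc <- vapply(genes, function(g)
    length(unique(p1$sample_id[p1$gene == g & p1_cohort == "control"])),
    integer(1))
  or <- ha_odds_ratio(a, n_cases - a, cc, n_controls - cc)
  gene_or <- data.frame(gene = genes, case_carriers = a,
                        control_carriers = cc, or_value = or,
                        stringsAsFactors = FALSE, row.names = NULL)

  x$gene_or <- gene_or$or_value[match(x$gene, gene_or$gene)]
  x$prioritized <- x$pass1 & x$gene_or >= thresholds$or_min &
    cohort == "case" & !is.na(elusive) & elusive
  attr(x, "gene_or") <- gene_or
  x
}
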