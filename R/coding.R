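#' @title Coding variant prioritization cascade
#' @description
#' Rarity, loss-of-function, cryptic-splice, missense-consensus and
#' zygosity-concordance rules applied to protein-coding variants in known
#' panel genes, plus the candidate-gene LoF scan for gene-elusive cases.
#' Boundary conventions, read literally from the filter definitions:
#' allele-frequency cutoffs are strict (`af < threshold`), the splice delta
#' threshold is inclusive (`delta >= 0.5`), and absence from gnomAD counts
#' as rare.
#' @name coding_prioritization
NULL

.lof_consequences <- c("frameshift", "stopgain", "stoploss",
                       "splice_dinucleotide")

#' Default thresholds for the coding cascade
#'
#' @param rare_af gnomAD minor allele frequency cutoff, strict. Default
#'   1e-4 (0.01%).
#' @param splice_delta_min Minimum cryptic-splice delta score, inclusive.
#'   Default 0.5.
#' @param pli_min pLI cutoff (strict) flagging constrained candidate genes.
#'   Default 0.9.
#' @param family_frac_max Maximum fraction of unrelated cohort families
#'   carrying a candidate LoF variant, strict. Default 0.01.
#' @param missense_tools_min Minimum number of reporting missense predictors.
#'   Default 5.
#' @return Named list of thresholds.
#' @export
coding_thresholds <- function(rare_af = 1e-4, splice_delta_min = 0.5,
                              pli_min = 0.9, family_frac_max = 0.01,
                              missense_tools_min = 5) {
  stopifnot(rare_af > 0, rare_af <= 1, splice_delta_min > 0,
            splice_delta_min <= 1, pli_min > 0, pli_min <= 1,
            family_frac_max > 0, family_frac_max <= 1,
            missense_tools_min >= 1)
  list(rare_af = rare_af, splice_delta_min = splice_delta_min,
       pli_min = pli_min, family_frac_max = family_frac_max,
       missense_tools_min = missense_tools_min)
}

#' Rarity test against a reference allele frequency
#'
#' True when the allele frequency is strictly below the threshold, or absent
#' (NA): a variant unobserved in the reference population is rarer than any
#' observed frequency.
#'
#' @param af Allele frequency vector in \[0, 1\]; NA = absent.
#' @param threshold Strict upper cutoff, default 1e-4.
#' @return Logical vector.
#' @export
#' @examples
#' is_rare(c(9e-5, 1e-4, NA))  # TRUE FALSE TRUE
is_rare <- function(af, threshold = 1e-4) {
  if (threshold <= 0 || threshold >= 1) .stopf("threshold must be in (0, 1)")
  if (any(!is.na(af) & (af < 0 | af > 1))) .stopf("allele frequency outside [0, 1]")
  is.na(af) | af < threshold
}

#' High-confidence loss-of-function call
#'
#' True for frameshift, stopgain, stoploss and canonical splice-dinucleotide
#' variants annotated high-confidence by a LOFTEE-style annotator;
#' low-confidence flags demote the call.
#'
#' @param consequence Consequence vector.
#' @param lof_confidence Confidence vector ("high", "low", "none").
#' @return Logical vector.
#' @export
classify_lof <- function(consequence, lof_confidence) {
  consequence %in% .lof_consequences &
    !is.na(lof_confidence) & lof_confidence == "high"
}

#' Cryptic-splice filter on the splice delta score
#'
#' True when the delta score is present, at least `min_delta` (inclusive),
#' and the variant lies in the transcribed region of a gene.
#'
#' @param delta Splice delta score vector in \[0, 1\]; NA = not scored.
#' @param in_transcribed_region Logical vector.
#' @param min_delta Inclusive threshold, default 0.5.
#' @return Logical vector.
#' @export
cryptic_splice_filter <- function(delta, in_transcribed_region,
                                  min_delta = 0.5) {
  if (any(!is.na(delta) & (delta < 0 | delta > 1)))
    .stopf("splice delta outside [0, 1]")
  !is.na(delta) & delta >= min_delta & in_transcribed_region
}

#' Missense pathogenicity consensus over prediction tools
#'
#' A missense variant is called deleterious when at least `min_tools`
#' predictors report a score and a strict majority of the reporting tools
#' call it deleterious. The combination rule over the individual predictors
#' is a package convention (reproducible and monotone), recorded per
#' variant; the source predictors themselves are consumed as annotations.
#'
#' @param n_tools Number of reporting tools per variant.
#' @param n_deleterious Number of tools calling deleterious.
#' @param min_tools Minimum reporting tools, default 5.
#' @return Logical vector.
#' @export
#' @examples
#' missense_consensus(c(7, 4, 6), c(5, 4, 3))  # TRUE FALSE FALSE
missense_consensus <- function(n_tools, n_deleterious, min_tools = 5) {
  if (any(n_deleterious > n_tools, na.rm = TRUE))
    .stopf("n_deleterious exceeds n_tools")
  !is.na(n_tools) & n_tools >= min_tools &
    !is.na(n_deleterious) & n_deleterious > n_tools / 2
}

#' Zygosity concordance with a gene's mode of inheritance
#'
#' AD genes accept het or hom_alt; AR genes accept hom_alt, or compound
#' heterozygosity (two distinct qualifying het alleles in the same gene and
#' sample — phase is unknown, so this over-calls cis pairs); XL genes accept
#' hemi or hom_alt. An unknown inheritance mode is treated as AD with a
#' warning.
#'
#' @param genotype Genotype vector (het / hom_alt / hemi).
#' @param inheritance Inheritance mode vector (AD / AR / XL), recycled.
#' @param compound_het Logical vector: the sample carries a second distinct
#'   qualifying het allele in the same gene. Default FALSE.
#' @return Logical vector.
#' @export
zygosity_concordance <- function(genotype, inheritance,
                                 compound_het = FALSE) {
  if (any(genotype == "missing")) .stopf("genotype must not be missing")
  unknown <- !inheritance %in% c("AD", "AR", "XL")
  if (any(unknown)) {
    .warnf("unknown inheritance mode treated as AD (%d records)", sum(unknown))
    inheritance[unknown] <- "AD"
  }
  n <- max(length(genotype), length(inheritance))
  genotype <- rep_len(genotype, n)
  inheritance <- rep_len(inheritance, n)
  compound_het <- rep_len(compound_het, n)
  ifelse(inheritance == "AD", genotype %in% c("het", "hom_alt"),
  ifelse(inheritance == "AR", genotype == "hom_alt" |
           (genotype == "het" & compound_het),
         genotype %in% c("hemi", "hom_alt")))
}

# per-variant verdicts for known panel genes; the cascade engine behind
# classify_case_coding
classify_variants_coding <- function(variants, registry,
                                     thresholds = coding_thresholds()) {
  check_variants(variants)
  v <- variants
  n <- nrow(v)
  if (is.null(v$in_transcribed_region)) v$in_transcribed_region <- TRUE
  known <- registry[registry$tier != "candidate", , drop = FALSE]
  idx <- match(v$gene, known$symbol)
  in_panel <- !is.na(idx)

  rare <- is_rare(v$gnomad_af, thresholds$rare_af)
  lof <- classify_lof(v$consequence, v$lof_confidence)
  splice <- cryptic_splice_filter(v$splice_delta, v$in_transcribed_region,
                                  thresholds$splice_delta_min) &
    !v$consequence %in% c("regulatory")
  mis <- v$consequence == "missense" &
    missense_consensus(v$missense_n_tools, v$missense_n_deleterious,
                       thresholds$missense_tools_min)

  class <- rep("not_prioritized", n)
  class[in_panel & mis] <- "pathogenic_missense"
  class[in_panel & splice] <- "cryptic_splice"
  class[in_panel & lof] <- "pathogenic_lof"

  # compound-het detection: two distinct qualifying het alleles, same
  # sample and gene, both rare and classed
  qualifying <- class != "not_prioritized" & rare & v$genotype == "het"
  grp <- paste(v$sample_id, v$gene)
  allele <- paste(v$chrom, v$pos, v$ref, v$alt)
  n_alleles <- stats::ave(ifelse(qualifying, allele, NA), grp,
                          FUN = function(x) length(unique(x[!is.na(x)])))
  compound <- qualifying & as.numeric(n_alleles) >= 2

  inheritance <- known$inheritance[idx]
  zyg <- rep(FALSE, n)
  ok_gt <- v$genotype != "missing" & in_panel
  if (any(ok_gt))
    zyg[ok_gt] <- zygosity_concordance(v$genotype[ok_gt], inheritance[ok_gt],
                                       compound[ok_gt])

  # clinically-reportable gate: Tier 2 and secondary genes need a reported
  # pathogenic / likely pathogenic ClinVar status
  gated <- in_panel & (known$tier[idx] == "2" | known$cmp_class[idx] == "secondary")
  clinvar_ok <- !gated |
    (!is.na(v$clinvar_status) &
       v$clinvar_status %in% c("pathogenic", "likely_pathogenic"))

  retained <- in_panel & class != "not_prioritized" & rare & zyg & clinvar_ok
  reasons <- vapply(seq_len(n), function(i) {
    if (class[i] == "not_prioritized") return("")
    tags <- c(class[i],
              if (rare[i]) "rare" else "common",
              if (zyg[i]) "zygosity_concordant" else "zygosity_discordant",
              if (compound[i]) "compound_het",
              if (!clinvar_ok[i]) "fails_clinvar_gate")
    paste(tags, collapse = ";")
  }, character(1))

  data.frame(sample_id = v$sample_id, chrom = v$chrom, pos = v$pos,
             ref = v$ref, alt = v$alt, gene = v$gene, class = class,
             rare = rare, zygosity_concordant = zyg, clinvar_ok = clinvar_ok,
             retained = retained, reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Per-case coding verdict
#'
#' A case is coding-positive when it carries at least one variant in a known
#' panel gene that is rare, classed pathogenic (LoF, missense-consensus, or
#' cryptic splice), zygosity-concordant with the gene's inheritance mode
#' (compound-het counted for AR genes), and — for Tier 2 or secondary genes —
#' reported pathogenic or likely pathogenic in ClinVar.
#'
#' @param variants QC-passed variant table.
#' @param registry Gene registry (see [load_gene_registry]).
#' @param samples Sample sheet; verdicts are returned for every sample in it.
#' @param thresholds See [coding_thresholds].
#' @return Data frame: `sample_id`, `coding_positive`, `n_coding` (retained
#'   variant count), `genes` (semicolon-joined). The per-variant verdict
#'   table is attached as attribute `"verdicts"`.
#' @export
classify_case_coding <- function(variants, registry, samples,
                                 thresholds = coding_thresholds()) {
  verdicts <- classify_variants_coding(variants, registry, thresholds)
  kept <- verdicts[verdicts$retained, , drop = FALSE]
  n_coding <- table(factor(kept$sample_id, levels = samples$sample_id))
  genes <- vapply(samples$sample_id, function(s) {
    g <- sort(unique(kept$gene[kept$sample_id == s]))
    paste(g, collapse = ";")
  }, character(1))
  out <- data.frame(sample_id = samples$sample_id,
                    coding_positive = as.integer(n_coding) > 0,
                    n_coding = as.integer(n_coding),
                    genes = genes, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "verdicts") <- verdicts
  out
}

#' Candidate-gene LoF scan in gene-elusive cases
#'
#' Retains high-confidence LoF variants in candidate genes carried by
#' gene-elusive cases when the variant is rare in gnomAD (< 0.01%, absent
#' passes), carried by fewer than 1% of distinct unrelated case families
#' (strict; 209 families allow at most 2 carrier families), and the gene is
#' expressed in the human heart (moderate or high). Variants in constrained
#' genes (pLI > 0.9) are additionally flagged `prioritized`.
#'
#' @param variants QC-passed variant table.
#' @param candidate_genes Candidate gene table (see [load_candidate_genes]).
#' @param samples Sample sheet (family ids come from here; the family total
#'   is the number of distinct case families).
#' @param gene_elusive Character vector of gene-elusive case sample ids.
#' @param thresholds See [coding_thresholds].
#' @return Data frame of retained verdicts with `class = "candidate_lof"`,
#'   `carrier_families`, and `prioritized`.
#' @export
candidate_lof_scan <- function(variants, candidate_genes, samples,
                               gene_elusive,
                               thresholds = coding_thresholds()) {
  check_variants(variants)
  fam <- samples$family_id[match(variants$sample_id, samples$sample_id)]
  n_families <- length(unique(samples$family_id[samples$cohort == "case"]))
  v <- variants
  keep <- v$sample_id %in% gene_elusive &
    v$gene %in% candidate_genes$symbol &
    classify_lof(v$consequence, v$lof_confidence) &
    is_rare(v$gnomad_af, thresholds$rare_af)
  v <- v[keep, , drop = FALSE]
  fam <- fam[keep]
  if (nrow(v) == 0)
    return(data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), gene = character(0),
                      class = character(0), carrier_families = integer(0),
                      prioritized = logical(0)))
  allele <- paste(v$chrom, v$pos, v$ref, v$alt)
  carrier_families <- vapply(allele, function(k)
    length(unique(fam[allele == k])), integer(1))
  gidx <- match(v$gene, candidate_genes$symbol)
  heart_ok <- candidate_genes$heart_expression[gidx] %in% c("moderate", "high")
  fam_ok <- carrier_families / n_families < thresholds$family_frac_max
  out <- v[fam_ok & heart_ok,
           c("sample_id", "chrom", "pos", "ref", "alt", "gene"), drop = FALSE]
  out$class <- rep("candidate_lof", nrow(out))
  out$carrier_families <- as.integer(carrier_families[fam_ok & heart_ok])
  pli <- candidate_genes$pli[match(out$gene, candidate_genes$symbol)]
  out$prioritized <- !is.na(pli) & pli > thresholds$pli_min
  rownames(out) <- NULL
  out
}
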