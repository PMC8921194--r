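#' @title Cohort model: variant records, QC filters, and the gene registry
#' @description
#' Variants are held as plain data frames in "long" form, one row per called
#' allele per sample, with 1-based positions and an annotation bundle spread
#' over columns. Multi-allelic sites must be pre-split into bi-allelic rows;
#' the variant identity key is (chrom, pos, ref, alt).
#'
#' Required columns: `sample_id`, `chrom`, `pos`, `ref`, `alt`, `filter`,
#' `depth`, `genotype` (one of het / hom_alt / hemi / missing), `gq`.
#' Annotation columns (any may be NA): `gene`, `gnomad_af`, `popmax_af`,
#' `consequence`, `lof_confidence`, `splice_delta`, `in_transcribed_region`,
#' `missense_n_tools`, `missense_n_deleterious`, `clinvar_status`, and four
#' TFBS verdict columns `tfbs_regulomedb`, `tfbs_motifbreakr`, `tfbs_deepsea`,
#' `tfbs_fathmm_mkl`.
#' @name cohort_model
NULL

.variant_required_cols <- c("sample_id", "chrom", "pos", "ref", "alt",
                            "filter", "depth", "genotype", "gq")
.genotype_levels <- c("het", "hom_alt", "hemi", "missing")
.tfbs_cols <- c("tfbs_regulomedb", "tfbs_motifbreakr", "tfbs_deepsea",
                "tfbs_fathmm_mkl")

#' Validate a variant table
#'
#' Checks the structural invariants of the long variant table: required
#' columns present, positions >= 1, `ref != alt`, non-negative depth, allele
#' frequencies inside \[0, 1\], and recognised genotype codes.
#'
#' @param variants Data frame of variant records.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
check_variants <- function(variants) {
  missing_cols <- setdiff(.variant_required_cols, names(variants))
  if (length(missing_cols))
    .stopf("variant table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (nrow(variants) == 0) return(invisible(variants))
  if (any(variants$pos < 1)) .stopf("variant positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) .stopf("ref and alt alleles must differ")
  if (any(variants$depth < 0)) .stopf("negative read depth")
  if (!all(variants$genotype %in% .genotype_levels))
    .stopf("genotype must be one of: %s", paste(.genotype_levels, collapse = ", "))
  for (col in intersect(c("gnomad_af", "popmax_af"), names(variants))) {
    af <- variants[[col]]
    if (any(!is.na(af) & (af < 0 | af > 1)))
      .stopf("%s outside [0, 1]", col)
  }
  invisible(variants)
}

#' Site-level QC filter
#'
#' Retains records with a PASS value in the FILTER field and a total filtered
#' read depth of at least `min_depth` (10x by default, inclusive). Depth is a
#' single field regardless of variant type: producers supply DP for SNVs and
#' DPI (depth at the position preceding the indel) for indels. Row order is
#' preserved; the number of records dropped by each rule is attached as the
#' `"dropped"` attribute.
#'
#' @param variants Variant table (see [cohort_model]).
#' @param min_depth Minimum read depth, inclusive. Default 10.
#' @return The retained subset of `variants`, with attribute `dropped`, a
#'   named integer vector of per-rule drop counts.
#' @export
#' @examples
#' v <- data.frame(sample_id = "S1", chrom = "chr1", pos = 100, ref = "A",
#'                 alt = "T", filter = c("PASS", "PASS", "LowQual"),
#'                 depth = c(10, 9, 30), genotype = "het", gq = 50)
#' qc_filter(v)  # keeps only the first row
qc_filter <- function(variants, min_depth = 10) {
  check_variants(variants)
  pass <- variants$filter == "PASS"
  deep <- variants$depth >= min_depth
  keep <- pass & deep
  out <- variants[keep, , drop = FALSE]
  attr(out, "dropped") <- c(non_pass = sum(!pass),
                            low_depth = sum(pass & !deep))
  out
}

#' De novo trio genotype filter
#'
#' A site is accepted as a high-confidence de novo call when all three trio
#' members have genotype quality GQ >= 20 and read depth >= 10 (both
#' inclusive) and the proband carries an allele absent from both parents.
#' A missing genotype in any member fails the site, with the reason recorded.
#'
#' @param trio Data frame with three rows (proband, mother, father) and
#'   columns `member`, `genotype`, `gq`, `depth`. `member` must contain
#'   exactly "proband", "mother", "father".
#' @param min_gq Minimum genotype quality, inclusive. Default 20.
#' @param min_depth Minimum depth, inclusive. Default 10.
#' @return Logical scalar; on rejection the attribute `"reason"` names the
#'   first failed rule.
#' @export
denovo_trio_filter <- function(trio, min_gq = 20, min_depth = 10) {
  if (!is.data.frame(trio) || nrow(trio) != 3)
    .stopf("trio must be a 3-row data frame (proband, mother, father)")
  need <- c("proband", "mother", "father")
  if (!setequal(trio$member, need))
    .stopf("trio$member must be exactly: %s", paste(need, collapse = ", "))
  rownames(trio) <- trio$member
  fail <- function(reason) structure(FALSE, reason = reason)
  if (any(trio$genotype == "missing") || any(is.na(trio$genotype)))
    return(fail("missing genotype"))
  if (any(is.na(trio$gq)) || any(trio$gq < min_gq))
    return(fail(sprintf("GQ below %d", min_gq)))
  if (any(is.na(trio$depth)) || any(trio$depth < min_depth))
    return(fail(sprintf("depth below %d", min_depth)))
  carries <- function(g) g %in% c("het", "hom_alt", "hemi")
  if (!carries(trio["proband", "genotype"]))
    return(fail("proband carries no alternate allele"))
  if (carries(trio["mother", "genotype"]) || carries(trio["father", "genotype"]))
    return(fail("allele inherited from a parent"))
  TRUE
}

.registry_enums <- list(
  tier = c("1", "2", "candidate"),
  cmp_class = c("primary", "secondary", "candidate"),
  category = c("sarcomere", "desmosomal", "cytoskeletal", "dystroglycan",
               "ion_channel", "other"),
  inheritance = c("AD", "AR", "XL"),
  heart_expression = c("high", "moderate", "low", "not_expressed"))

#' Load a cardiomyopathy gene registry
#'
#' Reads a gene panel TSV with columns `symbol`, `tier`, `cmp_class`,
#' `category`, `inheritance`, `pli`, `heart_expression`. With no `path` the
#' bundled panel is loaded: a *synthetic* reconstruction of an 84-gene
#' clinical cardiomyopathy panel (real gene symbols, synthetic tier/category
#' assignments) with exactly 9 sarcomere genes, matching the structure the
#' burden prior 9/84 assumes.
#'
#' For the bundled panel the 84-gene / 9-sarcomere invariants are asserted
#' as errors; for a user-supplied panel they are downgraded to warnings so
#' that other panels can be analysed.
#'
#' @param path Optional path to a registry TSV; default bundled panel.
#' @param strict Logical; assert the 84/9 invariants as errors. Defaults to
#'   TRUE for the bundled panel, FALSE for user files.
#' @return Data frame of gene entries, one row per gene.
#' @export
#' @examples
#' reg <- load_gene_registry()
#' nrow(reg)                               # 84
#' sum(reg$category == "sarcomere")        # 9
load_gene_registry <- function(path = NULL, strict = is.null(path)) {
  if (is.null(path))
    path <- system.file("extdata", "cmp_gene_registry_synthetic.tsv",
                        package = "cmpburden", mustWork = TRUE)
  reg <- .read_tsv(path, colClasses = c(tier = "character"))
  need <- c("symbol", "tier", "cmp_class", "category", "inheritance",
            "pli", "heart_expression")
  missing_cols <- setdiff(need, names(reg))
  if (length(missing_cols))
    .stopf("registry lacks columns: %s", paste(missing_cols, collapse = ", "))
  dup <- reg$symbol[duplicated(reg$symbol)]
  if (length(dup))
    .stopf("duplicated gene symbol(s) in registry: %s",
           paste(unique(dup), collapse = ", "))
  for (col in names(.registry_enums)) {
    bad <- which(!reg[[col]] %in% .registry_enums[[col]] & !is.na(reg[[col]]))
    if (length(bad))
      .stopf("registry row %d: invalid %s value '%s'", bad[1], col, reg[[col]][bad[1]])
  }
  if (any(!is.na(reg$pli) & (reg$pli < 0 | reg$pli > 1)))
    .stopf("registry pLI outside [0, 1]")
  known <- reg[reg$tier != "candidate", , drop = FALSE]
  complain <- if (strict) .stopf else .warnf
  if (nrow(known) != 84)
    complain("known-gene registry has %d entries, expected 84", nrow(known))
  if (sum(known$category == "sarcomere") != 9)
    complain("registry has %d sarcomere genes, expected 9",
             sum(known$category == "sarcomere"))
  reg
}

#' Load the bundled synthetic candidate-gene list
#'
#' Ten candidate cardiomyopathy genes (not on the 84-gene panel) used by the
#' candidate LoF scan, with pLI and heart-expression annotations. Synthetic
#' stand-in for the study's curated candidate set.
#'
#' @param path Optional path to a candidate gene TSV.
#' @return Data frame with the registry columns.
#' @export
load_candidate_genes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cmp_candidate_genes_synthetic.tsv",
                        package = "cmpburden", mustWork = TRUE)
  .read_tsv(path, colClasses = c(tier = "character"))
}

#' Load a transcription start site table
#'
#' TSS sidecar for the fallback promoter rule: columns `gene`, `chrom`,
#' `position` (0-based), `strand`. The bundled table carries one synthetic
#' canonical-transcript TSS per registry gene.
#'
#' @param path Optional path; default bundled synthetic table.
#' @return Data frame of TSS entries.
#' @export
load_tss_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "cmp_gene_tss_synthetic.tsv",
                        package = "cmpburden", mustWork = TRUE)
  tss <- .read_tsv(path)
  if (any(tss$position < 0)) .stopf("TSS positions must be >= 0")
  if (!all(tss$strand %in% c("+", "-"))) .stopf("TSS strand must be + or -")
  tss
}

#' Load a sample sheet
#'
#' Columns: `sample_id`, `cohort` (case/control), `family_id`, `phenotype`
#' (HCM, DCM, LVNC, RCM, ACM or none), `trio_complete`.
#'
#' @param path Path to a TSV sample sheet.
#' @return Data frame of sample entries.
#' @export
load_sample_sheet <- function(path) {
  s <- .read_tsv(path)
  need <- c("sample_id", "cohort", "family_id", "phenotype", "trio_complete")
  missing_cols <- setdiff(need, names(s))
  if (length(missing_cols))
    .stopf("sample sheet lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(s$sample_id)) .stopf("duplicated sample_id in sample sheet")
  if (any(!nzchar(s$family_id)))  .stopf("empty family_id")
  if (!all(s$cohort %in% c("case", "control")))
    .stopf("cohort must be 'case' or 'control'")
  s
}

#' Read / write the flattened variant TSV dialect
#'
#' The flattened dialect carries one row per (variant, sample) with all
#' annotation columns inline; it is the exchange format the synthetic-data
#' generator emits and the pipeline consumes.
#'
#' @param path File path.
#' @return `read_variant_table` returns a validated variant data frame.
#' @export
read_variant_table <- function(path) {
  v <- .read_tsv(path)
  for (col in intersect(c("pos", "depth", "gq", "missense_n_tools",
                          "missense_n_deleterious"), names(v)))
    v[[col]] <- as.integer(v[[col]])
  for (col in intersect(c("gnomad_af", "popmax_af", "splice_delta"),
                        names(v)))
    v[[col]] <- as.numeric(v[[col]])
  for (col in intersect(c("in_transcribed_region", .tfbs_cols), names(v)))
    v[[col]] <- as.logical(v[[col]])
  for (col in intersect(c("gene", "consequence", "lof_confidence",
                          "clinvar_status"), names(v)))
    v[[col]] <- as.character(v[[col]])
  check_variants(v)
  v
}

#' @rdname read_variant_table
#' @param variants Variant table to write.
#' @export
write_variant_table <- function(variants, path) {
  check_variants(variants)
  .write_tsv(variants, path)
  invisible(path)
}
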