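#' Write a cohort variant table as VCF plus annotation sidecar
#'
#' Emits a minimal multi-sample VCF 4.2 (FORMAT `GT:DP:GQ`) holding the
#' genotype, depth and genotype-quality fields, and a sidecar TSV keyed by
#' (chrom, pos, ref, alt) holding the annotation bundle. FILTER is a
#' site-level field in VCF, so the per-record filter flag must be uniform
#' within a site; mixed flags at one site are an error.
#'
#' Genotype coding: het `0/1`, hom_alt `1/1`, hemi `1`, missing `./.`;
#' samples without a record at a site are written `0/0`. Sites are written
#' bi-allelic (pre-split), sorted by chromosome then position.
#'
#' @param variants Long variant table (see [cohort_model]).
#' @param samples Sample sheet giving the column order of the VCF.
#' @param vcf_path Output VCF path.
#' @param annotation_path Optional output path for the annotation sidecar.
#' @return `vcf_path`, invisibly.
#' @export
write_vcf_cohort <- function(variants, samples, vcf_path,
                             annotation_path = NULL) {
  check_variants(variants)
  key <- paste(variants$chrom, variants$pos, variants$ref, variants$alt)
  site <- !duplicated(key)
  flt <- tapply(variants$filter, key, function(x) length(unique(x)))
  if (any(flt > 1))
    .stopf("FILTER is site-level in VCF; %d site(s) carry mixed flags",
           sum(flt > 1))
  sites <- variants[site, c("chrom", "pos", "ref", "alt", "filter")]
  ord <- order(sites$chrom, sites$pos, sites$ref, sites$alt)
  sites <- sites[ord, ]
  skey <- paste(sites$chrom, sites$pos, sites$ref, sites$alt)

  gt_code <- c(het = "0/1", hom_alt = "1/1", hemi = "1", missing = "./.")
  cells <- matrix("0/0:.:.", nrow = nrow(sites), ncol = nrow(samples),
                  dimnames = list(skey, samples$sample_id))
  val <- sprintf("%s:%d:%s", gt_code[variants$genotype], variants$depth,
                 ifelse(is.na(variants$gq), ".", variants$gq))
  cells[cbind(match(key, skey), match(variants$sample_id, samples$sample_id))] <- val

  header <- c("##fileformat=VCFv4.2",
              "##source=cmpburden",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Filtered read depth (DP for SNVs, DPI for indels)">',
              '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples$sample_id), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                sites$filter, ".", "GT:DP:GQ",
                apply(cells, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)

  if (!is.null(annotation_path)) {
    ann_cols <- setdiff(names(variants),
                        c("sample_id", "filter", "depth", "genotype", "gq"))
    ann <- variants[!duplicated(key), ann_cols, drop = FALSE]
    .write_tsv(ann[order(ann$chrom, ann$pos, ann$ref, ann$alt), ], annotation_path)
  }
  invisible(vcf_path)
}

#' Read a cohort VCF (plus optional annotation sidecar) into the long table
#'
#' Parses a VCF through \pkg{vcfR}, melts the genotype matrix into one row
#' per carried allele per sample (genotypes `0/0` and `./.` are not carrier
#' records and are skipped), and joins the annotation sidecar by the
#' (chrom, pos, ref, alt) key when supplied.
#'
#' @param vcf_path Path to a VCF (plain text or bgzipped).
#' @param annotation_path Optional annotation sidecar TSV.
#' @return Long variant table (see [cohort_model]).
#' @export
read_vcf_cohort <- function(vcf_path, annotation_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  gq <- suppressWarnings(vcfR::extract.gt(v, element = "GQ", as.numeric = TRUE))

  code <- c("0/1" = "het", "1/0" = "het", "0|1" = "het", "1|0" = "het",
            "1/1" = "hom_alt", "1|1" = "hom_alt", "1" = "hemi")
  carrier <- which(!is.na(gt) & gt %in% names(code), arr.ind = TRUE)
  out <- data.frame(
    sample_id = colnames(gt)[carrier[, "col"]],
    chrom = fix$CHROM[carrier[, "row"]],
    pos = as.integer(fix$POS[carrier[, "row"]]),
    ref = fix$REF[carrier[, "row"]],
    alt = fix$ALT[carrier[, "row"]],
    filter = fix$FILTER[carrier[, "row"]],
    depth = as.integer(dp[carrier]),
    genotype = unname(code[gt[carrier]]),
    gq = as.integer(gq[carrier]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chrom, out$pos, out$ref, out$alt, out$sample_id), ]
  rownames(out) <- NULL

  if (!is.null(annotation_path)) {
    ann <- .read_tsv(annotation_path)
    key_out <- paste(out$chrom, out$pos, out$ref, out$alt)
    key_ann <- paste(ann$chrom, ann$pos, ann$ref, ann$alt)
    add <- setdiff(names(ann), c("chrom", "pos", "ref", "alt"))
    out[add] <- ann[match(key_out, key_ann), add]
  }
  check_variants(out)
  out
}
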