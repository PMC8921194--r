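#' @title End-to-end pipeline orchestration
#' @description
#' Runs the stages in cascade order — QC, coding classification, CNV
#' consensus, gene-elusive determination (computed once and frozen),
#' candidate LoF scan, regulatory prioritization, gene-level burden,
#' cohort tally — over a supplied or simulated cohort, collecting per-stage
#' tables and per-filter drop counts. Any stage failure is re-raised with
#' the stage name; previously completed stage outputs are preserved on the
#' returned error condition.
#' @name cli
NULL

.stage <- function(name, results, expr) {
  tryCatch(expr, error = function(e)
    stop(structure(class = c("cmp_pipeline_error", "error", "condition"),
                   list(message = sprintf("stage '%s' failed: %s", name,
                                          conditionMessage(e)),
                        call = sys.call(-1), stage = name,
                        partial = results))))
}

#' Run the full prioritization and burden pipeline
#'
#' @param cohort A cohort list as returned by [simulate_cohort()] (or
#'   assembled from the readers: components `samples`, `variants`,
#'   `regions`, `exons`, `cnv_calls_a`, `cnv_calls_b`, `masks`,
#'   `panel_freqs`, `candidate_genes`). When NULL, a cohort is simulated
#'   from `config`.
#' @param config A [sim_config()] used when `cohort` is NULL.
#' @param coding Thresholds for the coding cascade, see
#'   [coding_thresholds()].
#' @param regulatory Thresholds for the regulatory cascade, see
#'   [reg_thresholds()].
#' @param out_dir Optional directory; when given, every stage table is
#'   written there as TSV.
#' @return An object of class `"cmp_pipeline"`: list with `case_coding`,
#'   `coding_verdicts`, `cnv_retained`, `classifications` (per-case
#'   verdicts), `candidate_lof`, `regulatory` (candidate table with
#'   prioritization flags), `burden` (a [cmp_burden()] fit over genes with
#'   any pass-1 regulatory carrier), `tally`, `drop_log`.
#' @export
run_pipeline <- function(cohort = NULL, config = sim_config(),
                         coding = coding_thresholds(),
                         regulatory = reg_thresholds(), out_dir = NULL) {
  results <- list()
  if (is.null(cohort))
    cohort <- .stage("simulate", results, simulate_cohort(config))
  samples <- cohort$samples
  registry <- if (!is.null(cohort$config)) cohort$config$registry
              else load_gene_registry()
  case_ids <- samples$sample_id[samples$cohort == "case"]
  n_cases <- length(case_ids)
  n_controls <- sum(samples$cohort == "control")
  drop_log <- list()

  ## QC ---------------------------------------------------------------
  variants <- .stage("qc", results, qc_filter(cohort$variants))
  drop_log$qc <- attr(variants, "dropped")
  results$variants <- variants

  ## coding cascade ----------------------------------------------------
  case_coding <- .stage("coding", results,
    classify_case_coding(variants, registry, samples, coding))
  results$case_coding <- case_coding
  results$coding_verdicts <- attr(case_coding, "verdicts")

  ## CNV consensus + overlap annotation --------------------------------
  cnv <- .stage("cnv", results,
    cnv_consensus_filter(cohort$cnv_calls_a, cohort$cnv_calls_b,
                         cohort$masks, cohort$panel_freqs))
  drop_log$cnv <- attr(cnv, "dropped")
  cnv <- .stage("cnv", results,
    cnv_gene_overlap(cnv, cohort$exons, cohort$regions))
  results$cnv_retained <- cnv

  ## gene-elusive status: frozen here, never revisited ------------------
  known <- registry$symbol[registry$tier != "candidate"]
  cnv_hit <- vapply(case_ids, function(s) {
    g <- cnv$coding_genes[cnv$sample_id == s]
    any(unlist(strsplit(g, ";", fixed = TRUE)) %in% known)
  }, logical(1))
  coding_pos <- case_coding$coding_positive[match(case_ids,
                                                  case_coding$sample_id)]
  gene_elusive <- !(coding_pos | cnv_hit)
  elusive_ids <- case_ids[gene_elusive]

  ## candidate LoF scan on gene-elusive cases --------------------------
  cand <- .stage("candidate_lof", results,
    candidate_lof_scan(variants, cohort$candidate_genes, samples,
                       elusive_ids, coding))
  results$candidate_lof <- cand

  ## regulatory prioritization -----------------------------------------
  case_status <- data.frame(
    sample_id = samples$sample_id, cohort = samples$cohort,
    gene_elusive = ifelse(samples$cohort == "case",
                          gene_elusive[match(samples$sample_id, case_ids)],
                          FALSE))
  candidates <- .stage("regulatory", results,
    build_regulatory_candidates(variants, cohort$regions))
  # intergenic/intronic CNVs overlapping regulatory elements join the
  # candidate set (TFBS consensus bypassed, every other gate applies)
  reg_cnv <- cnv[cnv$regulatory_genes != "" & cnv$coding_genes == "", ,
                 drop = FALSE]
  if (nrow(reg_cnv)) {
    genes <- strsplit(reg_cnv$regulatory_genes, ";", fixed = TRUE)
    idx <- rep(seq_len(nrow(reg_cnv)), lengths(genes))
    cnv_cand <- data.frame(
      sample_id = reg_cnv$sample_id[idx], chrom = reg_cnv$chrom[idx],
      pos = reg_cnv$start[idx] + 1L,
      ref = "N", alt = sprintf("<%s>", toupper(substr(reg_cnv$cn_type[idx],
                                                      1, 3))),
      gnomad_af = NA_real_, popmax_af = NA_real_,
      tfbs_regulomedb = NA, tfbs_motifbreakr = NA, tfbs_deepsea = NA,
      tfbs_fathmm_mkl = NA, gene = unlist(genes),
      region_kind = "enhancer", lv_active = TRUE,
      in_regulatory_build = TRUE, variant_type = "cnv_or_indel",
      stringsAsFactors = FALSE)
    candidates <- rbind(candidates, cnv_cand)
  }
  reg_out <- .stage("regulatory", results,
    prioritize_regulatory(candidates, case_status, regulatory))
  results$regulatory <- reg_out

  ## gene-level burden over pass-1 regulatory carriers ------------------
  gene_or <- attr(reg_out, "gene_or")
  burden <- .stage("burden", results, {
    if (n_controls == 0) .stopf("no control samples: burden undefined")
    cmp_burden(stats::setNames(gene_or$case_carriers, gene_or$gene),
               stats::setNames(gene_or$control_carriers, gene_or$gene),
               n_cases = n_cases, n_controls = n_controls)
  })
  results$burden <- burden

  ## per-case classification and tally ----------------------------------
  prio <- reg_out[reg_out$prioritized, , drop = FALSE]
  # for the multiple/both tallies, count variants passing every gate except
  # the gene-elusive restriction (coding-positive cases can carry them too)
  hr <- reg_out[reg_out$pass1 & !is.na(reg_out$gene_or) &
                  reg_out$gene_or >= regulatory$or_min, , drop = FALSE]
  n_reg <- vapply(case_ids, function(s)
    length(unique(paste(hr$chrom, hr$pos, hr$ref,
                        hr$alt)[hr$sample_id == s])), integer(1))
  reg_pos <- vapply(case_ids, function(s)
    any(prio$sample_id == s), logical(1))
  classifications <- data.frame(
    sample_id = case_ids,
    coding_positive = coding_pos,
    cnv_positive = cnv_hit,
    candidate_lof = case_ids %in% cand$sample_id,
    regulatory_positive = reg_pos,
    gene_elusive = gene_elusive,
    n_coding = case_coding$n_coding[match(case_ids,
                                          case_coding$sample_id)] +
      as.integer(cnv_hit),
    n_regulatory = n_reg,
    stringsAsFactors = FALSE, row.names = NULL)
  results$classifications <- classifications
  results$tally <- .stage("tally", results,
                          case_tally(classifications, n_cases))
  results$drop_log <- do.call(rbind, lapply(names(drop_log), function(st)
    data.frame(stage = st, rule = names(drop_log[[st]]),
               dropped = as.integer(drop_log[[st]]),
               stringsAsFactors = FALSE)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) .write_tsv(x, file.path(out_dir, f))
    w(results$coding_verdicts, "coding_verdicts.tsv")
    w(results$case_coding, "case_coding.tsv")
    w(results$cnv_retained, "cnv_retained.tsv")
    w(results$candidate_lof, "candidate_lof.tsv")
    w(results$regulatory, "regulatory_candidates.tsv")
    w(results$burden$table, "burden.tsv")
    w(results$classifications, "classifications.tsv")
    w(results$tally, "tally.tsv")
    w(results$drop_log, "drop_log.tsv")
  }
  structure(results, class = "cmp_pipeline")
}

#' @export
print.cmp_pipeline <- function(x, ...) {
  t <- x$tally
  cat("Cardiomyopathy WGS prioritization pipeline\n")
  cat(sprintf("  cases: %d, controls: %d\n", x$burden$n_cases,
              x$burden$n_controls))
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-20s %4d (%.1f%%)\n", t$category[i], t$count[i],
                t$percent[i]))
  cat(sprintf("  prioritized regulatory candidates: %d\n",
              sum(x$regulatory$prioritized)))
  invisible(x)
}
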