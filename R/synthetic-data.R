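#' @title Seeded synthetic cohorts with planted gene-level enrichment
#' @description
#' Generates case-control cohorts with the statistical structure every
#' pipeline stage assumes: per-gene carrier frequencies planted on the odds
#' scale, correlated four-tool TFBS verdicts, an allele-frequency spectrum
#' with a point mass at "absent from gnomAD" plus a log-uniform rare tail,
#' consensus-consistent two-caller CNV tracks, and expression down-shifted
#' in loss-of-function carriers. All randomness flows from a single seed.
#' @name synthetic_data
NULL

#' Simulation configuration
#'
#' Defaults emulate the study conditions: 209 unrelated case probands
#' against 1326 cancer-cohort controls; subtype mix 52/31/7/5/2 percent
#' DCM/HCM/LVNC/RCM/ACM; 32/209 complete trios; coding-positive rate 0.37;
#' CNV-positive rate 5/209; candidate-LoF rate 0.05; per-gene regulatory
#' enrichment planted in the four top genes (FKTN, DTNA, DSC2, DSG2) over a
#' baseline control carrier rate of 0.005 — the order of the observed
#' per-gene control carrier fractions (e.g. 12/1326).
#'
#' @param n_cases,n_controls Cohort sizes.
#' @param registry Gene registry (see [load_gene_registry]).
#' @param tss TSS table (see [load_tss_table]).
#' @param candidate_genes Candidate gene table.
#' @param per_gene_true_or Named vector of planted per-gene carrier odds
#'   ratios; genes not named get 1 (null).
#' @param baseline_control_carrier_rate Per-gene control carrier
#'   probability for qualifying regulatory variants.
#' @param af_spectrum List: `p_absent` (point mass at NA = unobserved in
#'   gnomAD) and `log10_min` / `log10_max` (log-uniform AF tail).
#' @param tfbs_tool_agreement Probability that each of the 4 TFBS tools
#'   reports the latent truth of a variant.
#' @param background_reg_rate Per-gene, per-sample rate of non-functional
#'   regulatory background variants (latent truth: not altered).
#' @param coding_positive_rate,cnv_positive_rate,candidate_lof_rate
#'   Per-case probabilities of carrying a planted pathogenic coding
#'   variant, a pathogenic CNV, and a candidate-gene LoF variant.
#' @param expression_noise_sd SD of log expression noise.
#' @param expression_lof_shift Down-shift (in SD units of log expression)
#'   applied to loss-of-function carriers.
#' @param n_expression_samples Myocardial RNA subset size (default 35).
#' @param seed Integer seed; every random draw derives from it.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_cases = 209, n_controls = 1326,
                       registry = load_gene_registry(),
                       tss = load_tss_table(),
                       candidate_genes = load_candidate_genes(),
                       per_gene_true_or = c(FKTN = 30, DTNA = 7,
                                            DSC2 = 20, DSG2 = 10),
                       baseline_control_carrier_rate = 0.005,
                       af_spectrum = list(p_absent = 0.5, log10_min = -6,
                                          log10_max = -3),
                       tfbs_tool_agreement = 0.9,
                       background_reg_rate = 0.001,
                       coding_positive_rate = 0.37,
                       cnv_positive_rate = 5 / 209,
                       candidate_lof_rate = 0.05,
                       expression_noise_sd = 1,
                       expression_lof_shift = 1.5,
                       n_expression_samples = 35,
                       seed = 1) {
  stopifnot(n_cases >= 1, n_controls >= 0,
            baseline_control_carrier_rate > 0,
            baseline_control_carrier_rate < 1,
            tfbs_tool_agreement >= 0, tfbs_tool_agreement <= 1,
            all(per_gene_true_or > 0),
            coding_positive_rate >= 0, coding_positive_rate <= 1)
  or <- stats::setNames(rep(1, nrow(registry)), registry$symbol)
  or[names(per_gene_true_or)] <- per_gene_true_or
  r <- baseline_control_carrier_rate
  p_case <- or * r / (1 - r + or * r)   # odds-scale planting
  if (any(p_case >= 1))
    .stopf("infeasible odds ratio / baseline rate: implied case carrier probability >= 1")
  structure(list(n_cases = n_cases, n_controls = n_controls,
                 registry = registry, tss = tss,
                 candidate_genes = candidate_genes,
                 per_gene_true_or = or, case_carrier_rate = p_case,
                 baseline_control_carrier_rate = r,
                 af_spectrum = af_spectrum,
                 tfbs_tool_agreement = tfbs_tool_agreement,
                 background_reg_rate = background_reg_rate,
                 coding_positive_rate = coding_positive_rate,
                 cnv_positive_rate = cnv_positive_rate,
                 candidate_lof_rate = candidate_lof_rate,
                 expression_noise_sd = expression_noise_sd,
                 expression_lof_shift = expression_lof_shift,
                 n_expression_samples = n_expression_samples,
                 seed = seed),
            class = "sim_config")
}

.draw_af <- function(n, spec) {
  absent <- stats::runif(n) < spec$p_absent
  af <- 10^stats::runif(n, spec$log10_min, spec$log10_max)
  af[absent] <- NA_real_
  af
}

.draw_tfbs <- function(latent, agreement) {
  n <- length(latent)
  m <- matrix(stats::runif(n * 4) < agreement, n, 4)
  out <- m == matrix(latent, n, 4)  # tool reports truth where m is TRUE
  out <- ifelse(m, latent, !latent)
  colnames(out) <- .tfbs_cols
  out
}

.rand_base <- function(n, not = NULL) {
  bases <- c("A", "C", "G", "T")
  out <- sample(bases, n, replace = TRUE)
  if (!is.null(not)) {
    clash <- out == not
    while (any(clash)) {
      out[clash] <- sample(bases, sum(clash), replace = TRUE)
      clash <- out == not
    }
  }
  out
}

# empty long variant table with all annotation columns
.empty_variants <- function() {
  data.frame(sample_id = character(0), chrom = character(0), pos = integer(0),
             ref = character(0), alt = character(0), filter = character(0),
             depth = integer(0), genotype = character(0), gq = integer(0),
             gene = character(0), gnomad_af = numeric(0),
             popmax_af = numeric(0), consequence = character(0),
             lof_confidence = character(0), splice_delta = numeric(0),
             in_transcribed_region = logical(0),
             missense_n_tools = integer(0),
             missense_n_deleterious = integer(0),
             clinvar_status = character(0),
             tfbs_regulomedb = logical(0), tfbs_motifbreakr = logical(0),
             tfbs_deepsea = logical(0), tfbs_fathmm_mkl = logical(0),
             stringsAsFactors = FALSE)
}

.variant_row <- function(sample_id, chrom, pos, ref, alt, gene, consequence,
                         genotype, gnomad_af = NA_real_,
                         popmax_af = NA_real_, lof_confidence = "none",
                         splice_delta = NA_real_,
                         in_transcribed_region = TRUE,
                         missense_n_tools = NA_integer_,
                         missense_n_deleterious = NA_integer_,
                         clinvar_status = "unreported",
                         tfbs = rep(NA, 4), filter = "PASS",
                         depth = NA_integer_, gq = NA_integer_) {
  data.frame(sample_id = sample_id, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, filter = filter, depth = depth,
             genotype = genotype, gq = gq, gene = gene,
             gnomad_af = gnomad_af, popmax_af = popmax_af,
             consequence = consequence, lof_confidence = lof_confidence,
             splice_delta = splice_delta,
             in_transcribed_region = in_transcribed_region,
             missense_n_tools = missense_n_tools,
             missense_n_deleterious = missense_n_deleterious,
             clinvar_status = clinvar_status,
             tfbs_regulomedb = tfbs[1], tfbs_motifbreakr = tfbs[2],
             tfbs_deepsea = tfbs[3], tfbs_fathmm_mkl = tfbs[4],
             stringsAsFactors = FALSE)
}

#' Simulate a full cohort
#'
#' Deterministic given `config$seed`. Per gene, control samples carry a
#' qualifying regulatory variant with the baseline probability and cases
#' with the probability implied by the planted odds ratio on the odds
#' scale, so the planted parameter matches the estimand of the burden test.
#' Planted regulatory variants have latent TFBS truth "altered"; each of
#' the four tools reports the truth independently with probability
#' `tfbs_tool_agreement`. Planted CNVs are emitted into both caller tracks
#' with breakpoint jitter under 20% of their length, so two-caller
#' consensus holds by construction.
#'
#' @param config A [sim_config()].
#' @return List with components `samples`, `variants`, `regions`, `tss`,
#'   `exons`, `cnv_calls_a`, `cnv_calls_b`, `masks`, `panel_freqs`,
#'   `expression`, `candidate_genes`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(config$seed, .simulate_cohort_impl(config))
}

.simulate_cohort_impl <- function(cfg) {
  reg <- cfg$registry
  tss <- cfg$tss

  ## samples -----------------------------------------------------------
  n_ca <- cfg$n_cases; n_co <- cfg$n_controls
  pheno <- sample(c("DCM", "HCM", "LVNC", "RCM", "ACM"), n_ca, TRUE,
                  prob = c(52, 31, 7, 5, 2))
  samples <- data.frame(
    sample_id = c(sprintf("CASE%04d", seq_len(n_ca)),
                  sprintf("CTRL%04d", seq_len(n_co))),
    cohort = rep(c("case", "control"), c(n_ca, n_co)),
    family_id = c(sprintf("FAM%04d", seq_len(n_ca)),
                  sprintf("CFAM%04d", seq_len(n_co))),
    phenotype = c(pheno, rep("none", n_co)),
    trio_complete = c(stats::runif(n_ca) < 32 / 209, rep(FALSE, n_co)),
    stringsAsFactors = FALSE)
  case_ids <- samples$sample_id[samples$cohort == "case"]
  all_ids <- samples$sample_id

  ## regulatory regions: fallback promoter + 1-3 enhancers per gene -----
  promoters <- fallback_promoter(tss)
  promoters$lv_active <- TRUE
  promoters$in_regulatory_build <- TRUE
  enh <- do.call(rbind, lapply(seq_len(nrow(tss)), function(i) {
    k <- sample(1:3, 1)
    off <- sample(5000:50000, k) * sample(c(-1, 1), k, replace = TRUE)
    start <- pmax(0, tss$position[i] + off)
    data.frame(chrom = tss$chrom[i], start = start,
               end = start + sample(300:1500, k, replace = TRUE),
               kind = "enhancer", genes = tss$gene[i],
               lv_active = stats::runif(k) < 0.8,
               in_regulatory_build = stats::runif(k) < 0.85,
               stringsAsFactors = FALSE)
  }))
  regions <- merge_regions(rbind(promoters, enh))

  ## coding exons: five 200 bp exons downstream of each TSS -------------
  exons <- do.call(rbind, lapply(seq_len(nrow(tss)), function(i) {
    start <- tss$position[i] + (0:4) * 1000
    data.frame(chrom = tss$chrom[i], start = start, end = start + 200,
               gene = tss$gene[i], stringsAsFactors = FALSE)
  }))

  qc_fields <- function(n) list(
    filter = ifelse(stats::runif(n) < 0.98, "PASS", "LowQual"),
    depth = stats::rpois(n, 31),
    gq = sample(30:99, n, replace = TRUE))

  variants <- list(.empty_variants())

  ## planted regulatory variants (carrier model, odds-scale) ------------
  prom_by_gene <- split(regions[regions$kind == "promoter", ],
                        vapply(strsplit(regions$genes[regions$kind == "promoter"],
                                        ";", fixed = TRUE),
                               `[`, character(1), 1))
  for (i in seq_len(nrow(reg))) {
    g <- reg$symbol[i]
    p_case <- cfg$case_carrier_rate[g]
    p_ctrl <- cfg$baseline_control_carrier_rate
    carrier <- c(stats::runif(n_ca) < p_case, stats::runif(n_co) < p_ctrl)
    ids <- all_ids[carrier]
    n <- length(ids)
    if (n == 0) next
    pr <- prom_by_gene[[g]]
    pos <- sample(seq.int(pr$start[1] + 1L, pr$end[1]), n, replace = TRUE)
    qc <- qc_fields(n)
    af <- .draw_af(n, cfg$af_spectrum)
    tf <- .draw_tfbs(rep(TRUE, n), cfg$tfbs_tool_agreement)
    ref <- .rand_base(n)
    v <- .variant_row(ids, pr$chrom[1], pos, ref, .rand_base(n, ref), g,
                      "regulatory", "het", gnomad_af = af,
                      popmax_af = ifelse(is.na(af), NA,
                                         pmin(1, af * stats::runif(n, 1, 5))),
                      in_transcribed_region = FALSE,
                      filter = qc$filter, depth = qc$depth, gq = qc$gq)
    v[, .tfbs_cols] <- tf
    variants[[length(variants) + 1]] <- v
  }

  ## background regulatory variants (latent: not altered) ---------------
  n_bg <- stats::rbinom(1, length(all_ids) * nrow(reg),
                        cfg$background_reg_rate)
  if (n_bg > 0) {
    gi <- sample(nrow(reg), n_bg, replace = TRUE)
    g <- reg$symbol[gi]
    ids <- sample(all_ids, n_bg, replace = TRUE)
    pr <- do.call(rbind, lapply(g, function(x) prom_by_gene[[x]][1, ]))
    pos <- pr$start + 1L + floor(stats::runif(n_bg) * (pr$end - pr$start))
    qc <- qc_fields(n_bg)
    af <- .draw_af(n_bg, cfg$af_spectrum)
    # background sites are often common: half get a non-rare AF
    common <- stats::runif(n_bg) < 0.5
    af[common] <- stats::runif(sum(common), 1e-3, 0.05)
    tf <- .draw_tfbs(rep(FALSE, n_bg), cfg$tfbs_tool_agreement)
    ref <- .rand_base(n_bg)
    v <- .variant_row(ids, pr$chrom, pos, ref, .rand_base(n_bg, ref), g,
                      "regulatory", "het", gnomad_af = af,
                      popmax_af = ifelse(is.na(af), NA,
                                         pmin(1, af * stats::runif(n_bg, 1, 5))),
                      in_transcribed_region = FALSE,
                      filter = qc$filter, depth = qc$depth, gq = qc$gq)
    v[, .tfbs_cols] <- tf
    variants[[length(variants) + 1]] <- v
  }

  ## planted pathogenic coding variants in cases ------------------------
  coding_case <- case_ids[stats::runif(n_ca) < cfg$coding_positive_rate]
  if (length(coding_case)) {
    n <- length(coding_case)
    sarc <- reg$symbol[reg$category == "sarcomere"]
    pick_sarc <- stats::runif(n) < 0.66
    g <- ifelse(pick_sarc, sample(sarc, n, replace = TRUE),
                sample(setdiff(reg$symbol, sarc), n, replace = TRUE))
    gi <- match(g, reg$symbol)
    kind <- sample(c("lof", "missense", "splice"), n, TRUE,
                   prob = c(0.55, 0.3, 0.15))
    ex1 <- exons[match(g, exons$gene), ]
    pos <- ex1$start + 1L + floor(stats::runif(n) * 200)
    genotype <- ifelse(reg$inheritance[gi] == "AR", "hom_alt",
                ifelse(reg$inheritance[gi] == "XL", "hemi", "het"))
    gated <- reg$tier[gi] == "2" | reg$cmp_class[gi] == "secondary"
    qc <- qc_fields(n)
    ref <- .rand_base(n)
    v <- .variant_row(coding_case, ex1$chrom, pos, ref, .rand_base(n, ref),
                      g,
                      consequence = ifelse(kind == "lof",
                        sample(c("frameshift", "stopgain"), n, TRUE),
                        ifelse(kind == "missense", "missense", "intronic")),
                      genotype = genotype,
                      # planted pathogenic alleles are rare by construction;
                      # the spectrum here stays below the rarity cutoff
                      gnomad_af = .draw_af(n, list(p_absent = 0.6,
                                                   log10_min = -6,
                                                   log10_max = -4.5)),
                      lof_confidence = ifelse(kind == "lof", "high", "none"),
                      splice_delta = ifelse(kind == "splice",
                                            stats::runif(n, 0.5, 1), NA),
                      missense_n_tools = ifelse(kind == "missense",
                                                sample(7:9, n, TRUE), NA),
                      clinvar_status = ifelse(gated, "pathogenic",
                        sample(c("pathogenic", "likely_pathogenic", "vus",
                                 "unreported"), n, TRUE)),
                      filter = qc$filter, depth = qc$depth, gq = qc$gq)
    v$missense_n_deleterious <-
      ifelse(is.na(v$missense_n_tools), NA,
             pmin(v$missense_n_tools,
                  floor(v$missense_n_tools / 2) + sample(1:3, n, TRUE)))
    variants[[length(variants) + 1]] <- v
  }

  ## non-qualifying coding noise (common alleles, benign misssense) -----
  n_noise <- stats::rpois(1, n_ca)
  if (n_noise > 0) {
    ids <- sample(case_ids, n_noise, replace = TRUE)
    g <- sample(reg$symbol, n_noise, replace = TRUE)
    ex1 <- exons[match(g, exons$gene), ]
    qc <- qc_fields(n_noise)
    ref <- .rand_base(n_noise)
    v <- .variant_row(ids, ex1$chrom,
                      ex1$start + 1L + floor(stats::runif(n_noise) * 200),
                      ref, .rand_base(n_noise, ref), g,
                      consequence = sample(c("missense", "synonymous"),
                                           n_noise, TRUE),
                      genotype = "het",
                      gnomad_af = stats::runif(n_noise, 2e-4, 0.1),
                      missense_n_tools = sample(5:9, n_noise, TRUE),
                      filter = qc$filter, depth = qc$depth, gq = qc$gq)
    v$missense_n_deleterious <- pmin(v$missense_n_tools,
                                     sample(0:2, n_noise, TRUE))
    variants[[length(variants) + 1]] <- v
  }

  ## candidate-gene LoF variants in cases -------------------------------
  cand_case <- case_ids[stats::runif(n_ca) < cfg$candidate_lof_rate]
  if (length(cand_case)) {
    n <- length(cand_case)
    g <- sample(cfg$candidate_genes$symbol, n, replace = TRUE)
    chrom <- "chr2"  # candidate genes live off the panel's TSS map
    pos <- 5e6 + match(g, cfg$candidate_genes$symbol) * 1e5 +
      sample(0:50, n, replace = TRUE)
    qc <- qc_fields(n)
    ref <- .rand_base(n)
    v <- .variant_row(cand_case, chrom, pos, ref, .rand_base(n, ref), g,
                      consequence = sample(c("frameshift", "stopgain"), n, TRUE),
                      genotype = "het",
                      gnomad_af = .draw_af(n, list(p_absent = 0.7,
                                                   log10_min = -6,
                                                   log10_max = -4.5)),
                      lof_confidence = "high",
                      filter = qc$filter, depth = qc$depth, gq = qc$gq)
    variants[[length(variants) + 1]] <- v
  }

  variants <- do.call(rbind, variants)
  rownames(variants) <- NULL

  ## CNVs: planted deletions over promoter + first exon -----------------
  cnv_case <- case_ids[stats::runif(n_ca) < cfg$cnv_positive_rate]
  jitter_call <- function(start, end) {
    len <- end - start
    j <- function() floor(stats::runif(1, -0.09, 0.09) * len)
    c(max(0, start + j()), end + j())
  }
  calls_a <- calls_b <- list()
  for (s in cnv_case) {
    g <- sample(reg$symbol, 1)
    t0 <- tss$position[tss$gene == g]
    true_int <- c(t0 - 2000, t0 + 3000)
    ja <- jitter_call(true_int[1], true_int[2])
    jb <- jitter_call(true_int[1], true_int[2])
    ch <- tss$chrom[tss$gene == g]
    calls_a[[length(calls_a) + 1]] <- data.frame(
      sample_id = s, chrom = ch, start = ja[1], end = ja[2],
      cn_type = "deletion", stringsAsFactors = FALSE)
    calls_b[[length(calls_b) + 1]] <- data.frame(
      sample_id = s, chrom = ch, start = jb[1], end = jb[2],
      cn_type = "deletion", stringsAsFactors = FALSE)
  }
  # single-caller noise calls: never reach consensus
  for (s in sample(case_ids, min(30, n_ca))) {
    ch <- sample(unique(tss$chrom), 1)
    st <- sample(6e7:9e7, 1)
    calls_a[[length(calls_a) + 1]] <- data.frame(
      sample_id = s, chrom = ch, start = st, end = st + sample(2000:8000, 1),
      cn_type = sample(c("deletion", "duplication"), 1),
      stringsAsFactors = FALSE)
  }
  empty_cnv <- data.frame(sample_id = character(0), chrom = character(0),
                          start = integer(0), end = integer(0),
                          cn_type = character(0))
  cnv_calls_a <- if (length(calls_a)) do.call(rbind, calls_a) else empty_cnv
  cnv_calls_b <- if (length(calls_b)) do.call(rbind, calls_b) else empty_cnv

  ## masks and reference-panel CNV frequencies --------------------------
  chroms <- unique(tss$chrom)
  masks <- do.call(rbind, lapply(chroms, function(ch) rbind(
    data.frame(name = "telomere", chrom = ch, start = 0L, end = 10000L),
    data.frame(name = "telomere", chrom = ch, start = 199990000L,
               end = 200000000L),
    data.frame(name = "centromere", chrom = ch, start = 100000000L,
               end = 100300000L),
    data.frame(name = "segdup", chrom = ch,
               start = (s <- sample(15e7:18e7, 1)), end = s + 20000L),
    data.frame(name = "cn_prone", chrom = ch,
               start = (p <- sample(11e7:14e7, 1)), end = p + 50000L))))
  panel_freqs <- data.frame(chrom = sample(chroms, 20, replace = TRUE),
                            start = (st <- sample(6e7:9e7, 20)),
                            end = st + sample(2000:8000, 20, replace = TRUE),
                            freq = stats::runif(20, 0.011, 0.05))

  ## myocardial expression with LoF carriers shifted down ---------------
  n_expr <- min(cfg$n_expression_samples, n_ca)
  expr_samples <- case_ids[seq_len(n_expr)]
  mu <- stats::rnorm(nrow(reg), 3, 1)
  sd <- cfg$expression_noise_sd
  expression <- matrix(exp(stats::rnorm(nrow(reg) * n_expr, mu, sd)),
                       nrow = nrow(reg),
                       dimnames = list(reg$symbol, expr_samples))
  lof_rows <- variants[variants$lof_confidence == "high" &
                         variants$gene %in% reg$symbol &
                         variants$sample_id %in% expr_samples, ]
  if (nrow(lof_rows)) {
    for (i in seq_len(nrow(lof_rows))) {
      g <- lof_rows$gene[i]; s <- lof_rows$sample_id[i]
      expression[g, s] <-
        exp(stats::rnorm(1, mu[match(g, reg$symbol)] -
                           cfg$expression_lof_shift * sd, sd / 2))
    }
  }

  list(samples = samples, variants = variants, regions = regions,
       tss = tss, exons = exons, cnv_calls_a = cnv_calls_a,
       cnv_calls_b = cnv_calls_b, masks = masks,
       panel_freqs = panel_freqs, expression = expression,
       candidate_genes = cfg$candidate_genes, config = cfg)
}

#' Draw per-gene carrier counts under odds-scale planting
#'
#' Fast carrier-count simulator used by the calibration and recovery
#' studies: for each gene, case carriers are Binomial(n_cases, p) with p
#' derived from the control rate and the planted odds ratio on the odds
#' scale, control carriers Binomial(n_controls, rate).
#'
#' @param n_genes Number of genes to draw.
#' @param or Planted odds ratio (scalar or length `n_genes`).
#' @param rate Control carrier rate.
#' @param n_cases,n_controls Cohort sizes.
#' @return Data frame with columns `a` (case carriers), `c` (control
#'   carriers).
#' @export
simulate_gene_carriers <- function(n_genes, or, rate, n_cases, n_controls) {
  odds <- or * rate / (1 - rate)
  p_case <- odds / (1 + odds)
  data.frame(a = stats::rbinom(n_genes, n_cases, p_case),
             c = stats::rbinom(n_genes, n_controls, rate))
}

#' Reconstruct carrier tables from printed odds ratios and intervals
#'
#' Brute-force oracle: scans all case-carrier counts `a <= a_max` and
#' control-carrier counts `c <= c_max` and keeps the tables whose
#' Haldane-Anscombe odds ratio and both Woolf 95% interval bounds, rounded
#' half-up to the precision each printed value carries, match the printed
#' values simultaneously. Exactly one match per row is required: zero or
#' multiple matches stop with a report, so no unverified reconstruction can
#' enter the package.
#'
#' @param printed Data frame with columns `gene`, `or_value`, `ci_low`,
#'   `ci_high`, `digits_or`, `digits_low`, `digits_high` (decimals each
#'   value is printed with).
#' @param n_cases,n_controls Cohort sizes behind the printed table.
#' @param a_max,c_max Scan bounds.
#' @return Data frame `gene, a, b, c, d` with one row per input row.
#' @export
reconstruct_burden_tables <- function(printed, n_cases = 209,
                                      n_controls = 1326,
                                      a_max = 30, c_max = 30) {
  grid <- expand.grid(a = 0:a_max, c = 0:c_max)
  b <- n_cases - grid$a
  d <- n_controls - grid$c
  or <- ha_odds_ratio(grid$a, b, grid$c, d)
  ci <- woolf_ci(grid$a, b, grid$c, d)
  out <- lapply(seq_len(nrow(printed)), function(i) {
    p <- printed[i, ]
    hit <- round_half_up(or, p$digits_or) == p$or_value &
      round_half_up(ci[, "low"], p$digits_low) == p$ci_low &
      round_half_up(ci[, "high"], p$digits_high) == p$ci_high
    n_hit <- sum(hit)
    if (n_hit != 1)
      .stopf("oracle found %d tables matching %s (OR %s, CI %s-%s); expected exactly 1",
             n_hit, p$gene, p$or_value, p$ci_low, p$ci_high)
    data.frame(gene = p$gene, a = grid$a[hit], b = b[hit], c = grid$c[hit],
               d = d[hit], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Reconstructed worked-example carrier tables
#'
#' The four gene-level burden examples printed as odds ratio with 95%
#' interval — FKTN 58.1 (3.1-1083), DTNA 6.7 (3.0-14.8), DSC2 32.0
#' (1.5-668), DSG2 10.6 (1.4-81), each over 209 cases and 1326 controls —
#' reconstructed into 2x2 carrier tables by [reconstruct_burden_tables()].
#' The oracle runs on every call, so the fixtures can never drift from the
#' printed values.
#'
#' @return Named list of `c(a, b, c, d)` integer tables.
#' @export
#' @examples
#' worked_example_tables()$FKTN  # 4 205 0 1326
worked_example_tables <- function() {
  printed <- data.frame(
    gene = c("FKTN", "DTNA", "DSC2", "DSG2"),
    or_value = c(58.1, 6.7, 32.0, 10.6),
    ci_low = c(3.1, 3.0, 1.5, 1.4),
    ci_high = c(1083, 14.8, 668, 81),
    digits_or = 1, digits_low = 1,
    digits_high = c(0, 1, 0, 0),
    stringsAsFactors = FALSE)
  rec <- reconstruct_burden_tables(printed)
  out <- lapply(seq_len(nrow(rec)), function(i)
    c(a = as.integer(rec$a[i]), b = as.integer(rec$b[i]),
      c = as.integer(rec$c[i]), d = as.integer(rec$d[i])))
  stats::setNames(out, rec$gene)
}
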