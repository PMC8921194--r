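test_that("TFBS consensus needs at least 3 of exactly 4 tools", {
  expect_true(tfbs_consensus(c(TRUE, TRUE, TRUE, FALSE)))
  expect_false(tfbs_consensus(c(TRUE, TRUE, FALSE, FALSE)))
  expect_true(tfbs_consensus(rep(TRUE, 4)))
  expect_error(tfbs_consensus(rep(TRUE, 3)), "exactly 4")
  m <- matrix(c(TRUE, TRUE, TRUE, FALSE,
                TRUE, FALSE, FALSE, FALSE), 2, 4, byrow = TRUE)
  expect_equal(tfbs_consensus(m), c(TRUE, FALSE))
})

mk_cand <- function(n = 1, ...) {
  base <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                     chrom = "chr1", pos = 100 + seq_len(n), ref = "A",
                     alt = "T", gnomad_af = 1e-6, popmax_af = 1e-5,
                     tfbs_regulomedb = TRUE, tfbs_motifbreakr = TRUE,
                     tfbs_deepsea = TRUE, tfbs_fathmm_mkl = FALSE,
                     gene = "FKTN", region_kind = "promoter",
                     lv_active = TRUE, in_regulatory_build = TRUE,
                     variant_type = "snv", stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("high-risk filter needs build overlap, rarity, and TFBS consensus", {
  expect_true(high_risk_filter(mk_cand()))
  expect_false(high_risk_filter(mk_cand(in_regulatory_build = FALSE,
                                        tfbs_fathmm_mkl = TRUE)))
  expect_false(high_risk_filter(mk_cand(gnomad_af = 5e-4,
                                        tfbs_fathmm_mkl = TRUE)))
  expect_true(high_risk_filter(mk_cand(gnomad_af = NA)))  # absent passes
  expect_false(high_risk_filter(mk_cand(tfbs_motifbreakr = FALSE,
                                        tfbs_deepsea = FALSE)))
  # indels and small CNVs bypass the SNV-oriented TFBS consensus
  expect_true(high_risk_filter(mk_cand(variant_type = "cnv_or_indel",
                                       tfbs_regulomedb = NA,
                                       tfbs_motifbreakr = NA,
                                       tfbs_deepsea = NA,
                                       tfbs_fathmm_mkl = NA)))
})

test_that("cohort frequency exclusion is inclusive at 1.5%", {
  expect_true(cohort_frequency_exclusion(4, 209))    # 1.91%
  expect_false(cohort_frequency_exclusion(3, 209))   # 1.44%
  expect_false(cohort_frequency_exclusion(0, 209))
  n <- 200
  expect_true(cohort_frequency_exclusion(3, n))      # exactly 1.5%
})

status_for <- function(n_cases, n_controls, elusive_cases) {
  data.frame(
    sample_id = c(sprintf("CASE%04d", seq_len(n_cases)),
                  sprintf("CTRL%04d", seq_len(n_controls))),
    cohort = rep(c("case", "control"), c(n_cases, n_controls)),
    gene_elusive = c(seq_len(n_cases) %in% elusive_cases,
                     rep(FALSE, n_controls)),
    stringsAsFactors = FALSE)
}

test_that("two-pass prioritization applies the gene OR gate and elusive gate", {
  cs <- status_for(209, 1326, elusive_cases = 1:150)
  # enriched gene: 12 elusive case carriers vs 12 control carriers -> OR 6.66
  enr <- mk_cand(24,
                 sample_id = c(sprintf("CASE%04d", 1:12),
                               sprintf("CTRL%04d", 1:12)),
                 pos = 100 + 1:24)
  # null gene: identical carrier proportions -> OR ~ 1, dropped
  null <- mk_cand(27, gene = "MYH7", pos = 1000 + 1:27,
                  sample_id = c(sprintf("CASE%04d", 21:24),
                                sprintf("CTRL%04d", 100:122)))
  out <- prioritize_regulatory(rbind(enr, null), cs)
  gor <- attr(out, "gene_or")
  expect_equal(gor$case_carriers[gor$gene == "FKTN"], 12L)
  expect_equal(round(gor$or_value[gor$gene == "FKTN"], 2), 6.66)
  expect_true(all(out$prioritized[out$gene == "FKTN" &
                                    grepl("CASE", out$sample_id)]))
  expect_false(any(out$prioritized[out$gene == "MYH7"]))
  # control carriers are never prioritized
  expect_false(any(out$prioritized[grepl("CTRL", out$sample_id)]))
})

test_that("a high-risk variant in a coding-positive case is not prioritized", {
  cs <- status_for(209, 1326, elusive_cases = 2)
  v <- mk_cand(2, sample_id = c("CASE0001", "CASE0002"), pos = c(101, 101),
               ref = "A", alt = "T")
  out <- prioritize_regulatory(v, cs)
  expect_false(out$prioritized[out$sample_id == "CASE0001"])
  expect_true(out$prioritized[out$sample_id == "CASE0002"])
  expect_true(all(out$pass1))
})

test_that("variants at >= 1.5% cohort carriage are excluded from burden", {
  cs <- status_for(209, 1326, elusive_cases = 1:209)
  # one variant shared by 4 cases (1.91% of 209) at the same locus
  shared <- mk_cand(4, sample_id = sprintf("CASE%04d", 1:4),
                    pos = rep(500L, 4))
  out <- prioritize_regulatory(shared, cs)
  expect_false(any(out$pass1))
  shared3 <- mk_cand(3, sample_id = sprintf("CASE%04d", 1:3),
                     pos = rep(500L, 3))
  expect_true(all(prioritize_regulatory(shared3, cs)$pass1))
})

test_that("prioritization errors without controls and needs known samples", {
  cs <- status_for(10, 0, elusive_cases = 1:10)
  expect_error(prioritize_regulatory(mk_cand(), cs), "control")
  cs2 <- status_for(10, 10, elusive_cases = 1:10)
  expect_error(prioritize_regulatory(mk_cand(sample_id = "NOBODY"), cs2),
               "missing")
})

test_that("prioritized set is a subset of high-risk, in gene-elusive cases only", {
  set.seed(5)
  cs <- status_for(50, 200, elusive_cases = sample(50, 30))
  n <- 120
  cand <- mk_cand(n,
                  sample_id = sample(cs$sample_id, n, TRUE),
                  pos = sample(1:5000, n, TRUE),
                  gene = sample(c("FKTN", "DTNA", "MYH7"), n, TRUE),
                  gnomad_af = ifelse(runif(n) < 0.3, NA,
                                     10^runif(n, -7, -3)),
                  popmax_af = 10^runif(n, -7, -2),
                  lv_active = runif(n) < 0.8,
                  in_regulatory_build = runif(n) < 0.8,
                  tfbs_regulomedb = runif(n) < 0.7,
                  tfbs_motifbreakr = runif(n) < 0.7,
                  tfbs_deepsea = runif(n) < 0.7,
                  tfbs_fathmm_mkl = runif(n) < 0.7)
  out <- prioritize_regulatory(cand, cs)
  expect_true(all(out$high_risk[out$prioritized]))
  expect_true(all(out$pass1[out$prioritized]))
  elusive_ids <- cs$sample_id[cs$gene_elusive]
  expect_true(all(out$sample_id[out$prioritized] %in% elusive_ids))
  expect_true(all(out$gene_or[out$prioritized] >= 1.3))
})

test_that("removing control carriers only increases the corrected gene OR", {
  for (d_extra in c(0, 3, 7)) {
    a <- 8; cc <- 10 - d_extra
    or1 <- ha_odds_ratio(a, 201, cc, 1326 - cc)
    or2 <- ha_odds_ratio(a, 201, max(0, cc - 1), 1326 - max(0, cc - 1))
    expect_gt(or2, or1)
  }
})

test_that("a planted OR-5 gene outranks nulls across seeded replicates", {
  set.seed(2024)
  n_rep <- 60
  planted_kept <- 0
  null_kept <- 0
  for (r in seq_len(n_rep)) {
    genes <- c("PLANT", paste0("NULL", 1:10))
    ors <- c(5, rep(1, 10))
    cars <- simulate_gene_carriers(11, ors, rate = 0.01,
                                   n_cases = 209, n_controls = 1326)
    or <- ha_odds_ratio(cars$a, 209 - cars$a, cars$c, 1326 - cars$c)
    planted_kept <- planted_kept + (or[1] >= 1.3 && cars$a[1] > 0)
    null_kept <- null_kept + mean(or[-1] >= 1.3 & cars$a[-1] > 0)
  }
  expect_gt(planted_kept / n_rep, 0.9)
  expect_lt(null_kept / n_rep, 0.5)   # nulls retained only in a minority
})
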