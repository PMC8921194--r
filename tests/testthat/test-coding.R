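test_that("rarity is strict at the threshold and absent counts as rare", {
  expect_true(is_rare(9e-5))
  expect_false(is_rare(1e-4))          # boundary: "< 0.01%" is strict
  expect_true(is_rare(NA))
  expect_equal(is_rare(c(0, 5e-5, 2e-4, NA)), c(TRUE, TRUE, FALSE, TRUE))
  expect_error(is_rare(1.2), "\\[0, 1\\]")
  expect_error(is_rare(0.5, threshold = 0), "threshold")
})

test_that("LoF classification requires a qualifying consequence at high confidence", {
  expect_true(classify_lof("frameshift", "high"))
  expect_false(classify_lof("frameshift", "low"))
  expect_false(classify_lof("missense", "high"))
  expect_equal(classify_lof(c("stopgain", "stoploss", "splice_dinucleotide",
                              "synonymous"), rep("high", 4)),
               c(TRUE, TRUE, TRUE, FALSE))
})

test_that("cryptic-splice filter is inclusive at 0.5 and needs a transcribed site", {
  expect_true(cryptic_splice_filter(0.62, TRUE))
  expect_true(cryptic_splice_filter(0.5, TRUE))     # inclusive boundary
  expect_false(cryptic_splice_filter(0.49, TRUE))
  expect_false(cryptic_splice_filter(0.9, FALSE))   # intergenic
  expect_false(cryptic_splice_filter(NA, TRUE))
})

test_that("missense consensus needs >= 5 reporters and a strict majority", {
  expect_true(missense_consensus(7, 5))
  expect_false(missense_consensus(4, 4))   # too few reporters
  expect_false(missense_consensus(6, 3))   # exactly half is not a majority
  expect_true(missense_consensus(5, 3))
  expect_false(missense_consensus(NA, NA))
  expect_error(missense_consensus(5, 6), "exceeds")
})

test_that("zygosity concordance follows the inheritance mode", {
  expect_true(zygosity_concordance("het", "AD"))
  expect_true(zygosity_concordance("hom_alt", "AD"))
  expect_false(zygosity_concordance("het", "AR"))
  expect_true(zygosity_concordance("hom_alt", "AR"))
  expect_true(zygosity_concordance("het", "AR", compound_het = TRUE))
  expect_true(zygosity_concordance("hemi", "XL"))
  expect_false(zygosity_concordance("het", "XL"))
  expect_warning(res <- zygosity_concordance("het", "unknown"), "AD")
  expect_true(res)
  expect_error(zygosity_concordance("missing", "AD"), "missing")
})

make_panel_variants <- function(reg) {
  tier1_ad <- reg$symbol[reg$tier == "1" & reg$cmp_class == "primary" &
                           reg$inheritance == "AD"][1]
  tier2 <- reg$symbol[reg$tier == "2"][1]
  ar_gene <- reg$symbol[reg$inheritance == "AR" & reg$tier == "1" &
                          reg$cmp_class == "primary"][1]
  list(tier1_ad = tier1_ad, tier2 = tier2, ar_gene = ar_gene)
}

test_that("case coding classification applies rarity, tiers and zygosity", {
  reg <- load_gene_registry()
  g <- make_panel_variants(reg)
  samples <- data.frame(sample_id = paste0("S", 1:5), cohort = "case",
                        family_id = paste0("F", 1:5), phenotype = "DCM",
                        trio_complete = FALSE)
  v <- rbind(
    # S1: rare high-confidence LoF, tier-1 AD, het -> positive
    make_variants(1, sample_id = "S1", gene = g$tier1_ad,
                  consequence = "frameshift", lof_confidence = "high",
                  gnomad_af = 1e-6),
    # S2: rare LoF in tier-2 gene, ClinVar unreported -> negative
    make_variants(1, sample_id = "S2", gene = g$tier2,
                  consequence = "stopgain", lof_confidence = "high",
                  gnomad_af = 1e-6),
    # S3: common LoF in tier-1 -> negative
    make_variants(1, sample_id = "S3", gene = g$tier1_ad,
                  consequence = "frameshift", lof_confidence = "high",
                  gnomad_af = 0.05),
    # S4: single rare het LoF in AR gene -> zygosity discordant, negative
    make_variants(1, sample_id = "S4", gene = g$ar_gene,
                  consequence = "stopgain", lof_confidence = "high",
                  gnomad_af = 1e-6))
  out <- classify_case_coding(v, reg, samples)
  expect_equal(out$coding_positive,
               c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # tier-2 gene becomes positive with a reportable ClinVar status
  v2 <- v
  v2$clinvar_status[2] <- "likely_pathogenic"
  out2 <- classify_case_coding(v2, reg, samples)
  expect_true(out2$coding_positive[2])
})

test_that("compound heterozygotes satisfy AR zygosity", {
  reg <- load_gene_registry()
  g <- make_panel_variants(reg)
  samples <- data.frame(sample_id = "S1", cohort = "case",
                        family_id = "F1", phenotype = "DCM",
                        trio_complete = FALSE)
  two <- rbind(
    make_variants(1, sample_id = "S1", pos = 1001L, gene = g$ar_gene,
                  consequence = "frameshift", lof_confidence = "high",
                  gnomad_af = 1e-6),
    make_variants(1, sample_id = "S1", pos = 2002L, gene = g$ar_gene,
                  consequence = "stopgain", lof_confidence = "high",
                  gnomad_af = 1e-6))
  expect_true(classify_case_coding(two, reg, samples)$coding_positive)
  # a single one of the pair is not enough
  expect_false(classify_case_coding(two[1, ], reg, samples)$coding_positive)
})

test_that("no rare variants means zero coding positives", {
  reg <- load_gene_registry()
  g <- make_panel_variants(reg)
  samples <- data.frame(sample_id = paste0("S", 1:3), cohort = "case",
                        family_id = paste0("F", 1:3), phenotype = "HCM",
                        trio_complete = FALSE)
  v <- make_variants(3, sample_id = paste0("S", 1:3), gene = g$tier1_ad,
                     consequence = "frameshift", lof_confidence = "high",
                     gnomad_af = c(0.01, 0.2, 0.002))
  expect_false(any(classify_case_coding(v, reg, samples)$coding_positive))
})

test_that("the cascade is monotone in its thresholds", {
  reg <- load_gene_registry()
  samples <- data.frame(sample_id = sprintf("S%03d", 1:40), cohort = "case",
                        family_id = sprintf("F%03d", 1:40),
                        phenotype = "DCM", trio_complete = FALSE)
  set.seed(11)
  v <- make_variants(40, sample_id = samples$sample_id,
                     gene = sample(reg$symbol[reg$tier == "1" &
                                                reg$cmp_class == "primary" &
                                                reg$inheritance == "AD"],
                                   40, TRUE),
                     consequence = sample(c("frameshift", "missense",
                                            "intronic"), 40, TRUE),
                     lof_confidence = sample(c("high", "low"), 40, TRUE),
                     gnomad_af = 10^runif(40, -7, -2),
                     splice_delta = runif(40),
                     missense_n_tools = sample(4:9, 40, TRUE))
  v$missense_n_deleterious <- pmin(v$missense_n_tools, sample(0:9, 40, TRUE))
  loose <- classify_case_coding(v, reg, samples,
                                coding_thresholds(rare_af = 1e-3))
  tight <- classify_case_coding(v, reg, samples,
                                coding_thresholds(rare_af = 1e-5,
                                                  splice_delta_min = 0.8))
  expect_true(all(tight$coding_positive <= loose$coding_positive))
  expect_lte(sum(tight$n_coding), sum(loose$n_coding))
})

test_that("candidate LoF scan enforces family fraction on distinct families", {
  cand <- load_candidate_genes()
  heart_gene <- cand$symbol[cand$heart_expression == "high" &
                              cand$pli > 0.9][1]
  low_gene <- "LRRC10"
  # 209 case families; <1% of 209 allows at most 2 carrier families
  samples <- data.frame(sample_id = sprintf("S%03d", 1:209),
                        cohort = "case",
                        family_id = sprintf("F%03d", 1:209),
                        phenotype = "DCM", trio_complete = FALSE)
  # two samples of the SAME family: counts as one carrier family
  samples$family_id[2] <- samples$family_id[1]
  mk <- function(ids, gene, pos = 5000L)
    make_variants(length(ids), sample_id = ids, pos = rep(pos, length(ids)),
                  gene = gene, consequence = "frameshift",
                  lof_confidence = "high", gnomad_af = 5e-6)
  elusive <- samples$sample_id
  # 3 samples over 2 families -> kept (2/208 families < 1%)
  v2 <- mk(samples$sample_id[1:3], heart_gene)
  out2 <- candidate_lof_scan(v2, cand, samples, elusive)
  expect_equal(nrow(out2), 3)
  expect_true(all(out2$prioritized))
  expect_equal(unique(out2$carrier_families), 2L)
  # 3 distinct families -> removed (3/208 > 1%)
  v3 <- mk(samples$sample_id[c(1, 4, 5)], heart_gene)
  expect_equal(nrow(candidate_lof_scan(v3, cand, samples, elusive)), 0)
  # gene without heart expression is removed
  cand_mod <- cand
  cand_mod$heart_expression[cand_mod$symbol == heart_gene] <- "not_expressed"
  expect_equal(nrow(candidate_lof_scan(v2, cand_mod, samples, elusive)), 0)
  # low-pLI gene is retained but not prioritized
  vlow <- mk(samples$sample_id[1], "CMYA5")
  outlow <- candidate_lof_scan(vlow, cand, samples, elusive)
  expect_equal(nrow(outlow), 1)
  expect_false(outlow$prioritized)
  # carriers outside the gene-elusive set are ignored
  expect_equal(nrow(candidate_lof_scan(v2, cand, samples,
                                       character(0))), 0)
})
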