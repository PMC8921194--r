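test_that("reciprocal overlap matches base counting, with inclusive 0.5 boundary", {
  expect_equal(reciprocal_overlap(0, 100, 0, 100), c(frac1 = 1, frac2 = 1))
  ro <- reciprocal_overlap(0, 100, 50, 150)
  expect_equal(unname(ro), c(0.5, 0.5))
  expect_true(all(ro >= 0.5))   # boundary passes the consensus rule
  ro2 <- reciprocal_overlap(0, 100, 90, 300)
  expect_equal(unname(ro2), c(0.1, 10 / 210))
  set.seed(3)
  for (i in 1:25) {
    s1 <- sample(0:200, 1); e1 <- s1 + sample(1:100, 1)
    s2 <- sample(0:200, 1); e2 <- s2 + sample(1:100, 1)
    got <- reciprocal_overlap(s1, e1, s2, e2)
    want <- oracle_recip(s1, e1, s2, e2)
    expect_equal(unname(got), want)
    # symmetry under argument swap
    expect_equal(unname(reciprocal_overlap(s2, e2, s1, e1)),
                 rev(unname(got)))
  }
})

test_that("mask overlap fraction uses the merged mask union", {
  mask <- data.frame(chrom = "chr1", start = c(0, 500, 600),
                     end = c(700, 800, 900))
  expect_equal(mask_overlap_fraction("chr1", 0, 1000, mask), 0.9)
  expect_equal(mask_overlap_fraction("chr1", 0, 1000,
                                     data.frame(chrom = "chr1", start = 0,
                                                end = 700)), 0.7)
  expect_equal(mask_overlap_fraction("chr2", 0, 1000, mask), 0)
  expect_equal(mask_overlap_fraction("chr1", 100, 200,
                                     data.frame(chrom = "chr1", start = 0,
                                                end = 700)), 1)
})

mk_call <- function(sample_id, start, end, cn_type = "deletion",
                    chrom = "chr1")
  data.frame(sample_id = sample_id, chrom = chrom, start = start,
             end = end, cn_type = cn_type, stringsAsFactors = FALSE)

no_masks <- data.frame(name = character(0), chrom = character(0),
                       start = integer(0), end = integer(0))
no_panel <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0), freq = numeric(0))

test_that("consensus filter applies size, mask, frequency and caller-pair rules", {
  a <- mk_call("S1", 10000, 15000)
  b <- mk_call("S1", 10500, 15200)
  out <- cnv_consensus_filter(a, b, no_masks, no_panel)
  expect_equal(nrow(out), 1)
  expect_equal(c(out$start, out$end), c(10500, 15000))  # intersection
  # 900 bp consensus fails the > 1 kb rule (strict)
  expect_equal(nrow(cnv_consensus_filter(mk_call("S1", 0, 900),
                                         mk_call("S1", 0, 900),
                                         no_masks, no_panel)), 0)
  # exactly 1000 bp also fails; 1001 passes
  expect_equal(nrow(cnv_consensus_filter(mk_call("S1", 0, 1000),
                                         mk_call("S1", 0, 1000),
                                         no_masks, no_panel)), 0)
  expect_equal(nrow(cnv_consensus_filter(mk_call("S1", 0, 1001),
                                         mk_call("S1", 0, 1001),
                                         no_masks, no_panel)), 1)
  # mismatched cn_type is never consensus
  expect_equal(nrow(cnv_consensus_filter(a, mk_call("S1", 10500, 15200,
                                                    "duplication"),
                                         no_masks, no_panel)), 0)
  # one caller missing for the sample: no rescue
  expect_equal(nrow(cnv_consensus_filter(a, mk_call("S2", 10500, 15200),
                                         no_masks, no_panel)), 0)
  # mask overlap exactly 0.7 fails (strict), 0.69 passes
  m70 <- data.frame(name = "segdup", chrom = "chr1", start = 10500,
                    end = 10500 + 0.7 * 4500)
  expect_equal(nrow(cnv_consensus_filter(a, b, m70, no_panel)), 0)
  m69 <- data.frame(name = "segdup", chrom = "chr1", start = 10500,
                    end = 10500 + 0.69 * 4500)
  expect_equal(nrow(cnv_consensus_filter(a, b, m69, no_panel)), 1)
  # cn-prone bound is 0.3
  p30 <- data.frame(name = "cn_prone", chrom = "chr1", start = 10500,
                    end = 10500 + 0.3 * 4500)
  expect_equal(nrow(cnv_consensus_filter(a, b, p30, no_panel)), 0)
  # panel frequency 1.2% removes; 0.9% keeps (match at >= 50% reciprocal)
  panel_hi <- data.frame(chrom = "chr1", start = 10500, end = 15000,
                         freq = 0.012)
  expect_equal(nrow(cnv_consensus_filter(a, b, no_masks, panel_hi)), 0)
  panel_lo <- transform(panel_hi, freq = 0.009)
  expect_equal(nrow(cnv_consensus_filter(a, b, no_masks, panel_lo)), 1)
  # a panel region below 50% reciprocal overlap does not transfer its frequency
  panel_far <- data.frame(chrom = "chr1", start = 14000, end = 30000,
                          freq = 0.05)
  expect_equal(nrow(cnv_consensus_filter(a, b, no_masks, panel_far)), 1)
})

test_that("retained consensus calls obey every bound on random instances", {
  set.seed(19)
  for (rep in 1:10) {
    n <- 15
    st <- sample(seq(0, 2e5, by = 100), n)
    a <- mk_call(sample(paste0("S", 1:4), n, TRUE), st,
                 st + sample(500:8000, n, TRUE),
                 sample(c("deletion", "duplication"), n, TRUE))
    jit <- sample(-300:300, n, TRUE)
    b <- a
    b$start <- pmax(0, b$start + jit)
    b$end <- b$end + sample(-300:300, n, TRUE)
    b <- b[b$end > b$start, ]
    ms <- sample(seq(0, 2e5, by = 500), 8)
    masks <- data.frame(name = sample(c("telomere", "segdup", "cn_prone"),
                                      8, TRUE),
                        chrom = "chr1", start = ms,
                        end = ms + sample(500:5000, 8, TRUE))
    out <- cnv_consensus_filter(a, b, masks, no_panel)
    if (nrow(out) == 0) next
    expect_true(all(out$length > 1000))
    expect_true(all(out$mask_frac < 0.7))
    expect_true(all(out$cnprone_frac < 0.3))
    # verify mask fractions against brute-force base counting
    hard <- masks[masks$name != "cn_prone", ]
    for (i in seq_len(nrow(out))) {
      bases <- unlist(mapply(function(s, e) seq.int(s, e - 1),
                             hard$start, hard$end, SIMPLIFY = FALSE))
      want <- length(intersect(seq.int(out$start[i], out$end[i] - 1),
                               unique(bases))) / out$length[i]
      expect_equal(out$mask_frac[i], want)
    }
  }
})

test_that("shrinking a mask never removes a retained call", {
  set.seed(23)
  st <- sample(seq(0, 1e5, by = 100), 10)
  a <- mk_call("S1", st, st + sample(1500:6000, 10, TRUE))
  b <- a
  b$start <- b$start + sample(-200:200, 10, TRUE)
  b$end <- b$end + sample(-200:200, 10, TRUE)
  ms <- sample(seq(0, 1e5, by = 500), 6)
  big <- data.frame(name = "segdup", chrom = "chr1", start = ms,
                    end = ms + 4000)
  small <- transform(big, end = start + 1500)
  keep_big <- cnv_consensus_filter(a, b, big, no_panel)
  keep_small <- cnv_consensus_filter(a, b, small, no_panel)
  key <- function(x) paste(x$sample_id, x$start, x$end)
  expect_true(all(key(keep_big) %in% key(keep_small)))
})

test_that("CNV gene overlap labels exons and regulatory regions independently", {
  exons <- data.frame(chrom = "chr1", start = c(1000, 5000),
                      end = c(1200, 5200), gene = c("JPH2", "NEXN"))
  regions <- make_region(start = 800, end = 1000, genes = "JPH2")
  cnv <- mk_call("S1", 700, 1300)
  lab <- cnv_gene_overlap(cnv, exons, regions)
  expect_equal(lab$coding_genes, "JPH2")
  expect_equal(lab$regulatory_genes, "JPH2")
  intronic <- cnv_gene_overlap(mk_call("S1", 850, 950), exons, regions)
  expect_equal(intronic$coding_genes, "")
  expect_equal(intronic$regulatory_genes, "JPH2")
  nothing <- cnv_gene_overlap(mk_call("S1", 9e6, 9.1e6), exons, regions)
  expect_equal(nothing$coding_genes, "")
  expect_equal(nothing$regulatory_genes, "")
})
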