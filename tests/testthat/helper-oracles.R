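# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check: factorial/choose arithmetic instead of
# log-space dhyper, explicit sort-and-step instead of p.adjust, and base
# enumeration instead of IRanges.

# two-sided Fisher p by hypergeometric enumeration with choose()
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  p <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# two-sided binomial p by direct pmf enumeration
oracle_binom <- function(k, n, p0 = 9 / 84) {
  p <- vapply(0:n, function(j) choose(n, j) * p0^j * (1 - p0)^(n - j),
              numeric(1))
  min(1, sum(p[p <= p[k + 1] * (1 + 1e-7)]))
}

# Benjamini-Hochberg by explicit sort and step-up cummin
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# distinct covered bases of 0-based half-open intervals, by enumeration
oracle_covered_bp <- function(start, end) {
  if (length(start) == 0) return(0L)
  length(unique(unlist(mapply(function(s, e) seq.int(s, e - 1L),
                              start, end, SIMPLIFY = FALSE))))
}

# reciprocal overlap by base enumeration
oracle_recip <- function(s1, e1, s2, e2) {
  i <- length(intersect(seq.int(s1, e1 - 1L), seq.int(s2, e2 - 1L)))
  c(i / (e1 - s1), i / (e2 - s2))
}

# minimal valid variant table for filter tests
make_variants <- function(n = 1, ...) {
  n0 <- n
  n <- max(n, 1L)
  base <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                     chrom = "chr1", pos = 1000L + seq_len(n), ref = "A",
                     alt = "T", filter = "PASS", depth = 30L,
                     genotype = "het", gq = 60L,
                     gene = NA_character_, gnomad_af = NA_real_,
                     popmax_af = NA_real_, consequence = "other",
                     lof_confidence = "none", splice_delta = NA_real_,
                     in_transcribed_region = TRUE,
                     missense_n_tools = NA_integer_,
                     missense_n_deleterious = NA_integer_,
                     clinvar_status = "unreported",
                     tfbs_regulomedb = NA, tfbs_motifbreakr = NA,
                     tfbs_deepsea = NA, tfbs_fathmm_mkl = NA,
                     stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base[seq_len(n0), , drop = FALSE]
}

make_region <- function(chrom = "chr1", start = 0, end = 100,
                        kind = "promoter", genes = "GENE1",
                        lv_active = TRUE, in_regulatory_build = TRUE) {
  data.frame(chrom = chrom, start = start, end = end, kind = kind,
             genes = genes, lv_active = lv_active,
             in_regulatory_build = in_regulatory_build,
             stringsAsFactors = FALSE)
}
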