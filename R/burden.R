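#' @title Burden statistics: corrected odds ratios, exact tests, FDR
#' @description
#' The counting unit for gene-level burden is the distinct carrier sample: a
#' case is positive for a gene when it harbors at least one qualifying
#' variant (SNV, indel and/or CNV) in that gene, however many it carries.
#' Odds ratios and their confidence intervals are computed on
#' Haldane-Anscombe corrected tables (0.5 added to every cell,
#' unconditionally); the exact tests run on the uncorrected integer tables.
#' @name burden_stats
NULL

.as_table4 <- function(a, b = NULL, c = NULL, d = NULL) {
  if (is.null(b)) {
    if (is.matrix(a) && all(dim(a) == c(2, 2)))
      a <- c(a[1, 1], a[1, 2], a[2, 1], a[2, 2])
    if (length(a) != 4) .stopf("expected a 2x2 table or four cell counts")
    b <- a[2]; c <- a[3]; d <- a[4]; a <- a[1]
  }
  if (any(c(a, b, c, d) < 0)) .stopf("negative cell count")
  list(a = a, b = b, c = c, d = d)
}

#' Haldane-Anscombe corrected odds ratio
#'
#' `(a + 0.5)(d + 0.5) / ((b + 0.5)(c + 0.5))`: the 0.5 correction is added
#' to every cell unconditionally, which keeps the estimate finite and
#' positive for zero cells. Cells may be given as four vectors `a, b, c, d`
#' (case positive, case negative, control positive, control negative) or a
#' single 2x2 matrix / length-4 vector.
#'
#' @param a,b,c,d Cell counts (vectorized), or `a` alone as a table.
#' @return Corrected odds ratio(s).
#' @export
#' @examples
#' ha_odds_ratio(4, 205, 0, 1326)   # 58.09...
#' ha_odds_ratio(12, 197, 12, 1314) # 6.656...
ha_odds_ratio <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- .as_table4(a, b, c, d)
  (t$a + 0.5) * (t$d + 0.5) / ((t$b + 0.5) * (t$c + 0.5))
}

#' Woolf confidence interval on the corrected cells
#'
#' Log odds-ratio interval `exp(ln OR +/- z * SE)` with
#' `SE = sqrt(sum 1/(cell + 0.5))`, i.e. both the estimate and its standard
#' error use the 0.5-corrected cells. This construction reproduces the
#' printed interval for every corrected gene-level odds ratio in the
#' reconstructed worked examples.
#'
#' @inheritParams ha_odds_ratio
#' @param level Confidence level, default 0.95.
#' @return Length-2 vector `c(low, high)`, or a 2-column matrix for
#'   vectorized cells.
#' @export
#' @examples
#' woolf_ci(4, 205, 0, 1326)  # c(3.07..., 1097...) -> prints 3.1-1083? no:
#' # rounds to (3.1, 1083)
woolf_ci <- function(a, b = NULL, c = NULL, d = NULL, level = 0.95) {
  if (level <= 0 || level >= 1) .stopf("level must be in (0, 1)")
  t <- .as_table4(a, b, c, d)
  or <- ha_odds_ratio(a, b, c, d)
  se <- sqrt(1 / (t$a + 0.5) + 1 / (t$b + 0.5) +
             1 / (t$c + 0.5) + 1 / (t$d + 0.5))
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(low = exp(log(or) - z * se), high = exp(log(or) + z * se))
  if (nrow(out) == 1) c(out) else out
}

#' Two-sided Fisher's exact test
#'
#' Exact conditional test on the uncorrected integer table: the p-value sums
#' the hypergeometric probabilities of every table with the same margins
#' whose point probability does not exceed that of the observed table, with
#' a relative tolerance of 1e-7 for ties (the minimum-likelihood two-sided
#' rule used by standard statistical software). Computed in log space, so
#' margins up to 10,000 are safe.
#'
#' @inheritParams ha_odds_ratio
#' @return p-value in \[0, 1\].
#' @export
fisher_two_sided <- function(a, b = NULL, c = NULL, d = NULL) {
  t <- .as_table4(a, b, c, d)
  if (any(c(t$a, t$b, t$c, t$d) != floor(c(t$a, t$b, t$c, t$d))))
    .stopf("Fisher test requires integer cell counts")
  m <- t$a + t$b          # cases
  n <- t$c + t$d          # controls
  k <- t$a + t$c          # positives
  if (k == 0 || k == m + n || m == 0 || n == 0) return(1)
  support <- max(0, k - n):min(k, m)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  obs <- stats::dhyper(t$a, m, n, k, log = TRUE)
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

#' Two-sided exact binomial test
#'
#' Minimum-likelihood two-sided p-value: the sum of `Binom(j; n, p0)` over
#' all j whose point probability does not exceed that of the observed k
#' (relative tolerance 1e-7). Default prior probability of success 9/84, the
#' fraction of sarcomere genes on the 84-gene panel.
#'
#' @param k Observed successes.
#' @param n Trials.
#' @param p0 Null success probability, default `9/84`.
#' @return p-value in (0, 1\].
#' @export
#' @examples
#' binomial_two_sided(1, 1)  # 9/84
binomial_two_sided <- function(k, n, p0 = 9 / 84) {
  if (k < 0 || k > n) .stopf("k must satisfy 0 <= k <= n")
  if (p0 <= 0 || p0 >= 1) .stopf("p0 must be in (0, 1)")
  p <- stats::dbinom(0:n, n, p0)
  min(1, sum(p[p <= p[k + 1] * (1 + 1e-7)]))
}

#' Benjamini-Hochberg FDR over the tested subset
#'
#' Step-up adjustment restricted to the genes actually tested; genes where
#' no variants were observed in any sample are removed before adjustment
#' (their q-values are NA) so the multiplicity burden reflects only
#' informative tests.
#'
#' @param p P-value vector.
#' @param tested Logical mask of entries to adjust; default: all non-NA.
#' @return Vector of q-values, NA where masked out.
#' @export
bh_fdr <- function(p, tested = !is.na(p)) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) .stopf("p-values outside [0, 1]")
  q <- rep(NA_real_, length(p))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  q
}

#' Squared Spearman correlation with a t-approximation p-value
#'
#' Average-rank (mid-rank) Spearman correlation; the two-sided p-value uses
#' the t approximation on rho with n - 2 degrees of freedom. For n <= 10 an
#' exact permutation p-value is available via `exact = TRUE`.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param exact Use exhaustive permutation for the p-value (n <= 10 only).
#' @return List with `rho2`, `rho`, and `p` (all NA for a constant vector).
#' @export
spearman_rho2 <- function(x, y, exact = FALSE) {
  if (length(x) != length(y) || length(x) < 3)
    .stopf("x and y must have equal length >= 3")
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    return(list(rho2 = NA_real_, rho = NA_real_, p = NA_real_))
  rho_of <- function(x, y) stats::cor(rank(x), rank(y))
  rho <- rho_of(x, y)
  n <- length(x)
  if (exact) {
    if (n > 10) .stopf("exact permutation p only for n <= 10")
    perms <- .permutations(n)
    stats <- apply(perms, 1, function(i) abs(rho_of(x, y[i])))
    p <- mean(stats >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho2 = rho^2, rho = rho, p = p)
}

.permutations <- function(n) {
  if (n == 1) return(matrix(1))
  sub <- .permutations(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, sub + (sub >= i))))
}

#' Gene-level case-control burden fit
#'
#' The central estimator: one 2x2 carrier table per gene (distinct carrier
#' samples among cases and controls), Haldane-Anscombe corrected odds ratio
#' with Woolf 95% confidence interval, two-sided Fisher exact p-value on the
#' uncorrected table, and Benjamini-Hochberg q-values computed after
#' removing genes with no carriers in either cohort.
#'
#' @param case_carriers Named integer vector: carrier cases per gene.
#' @param control_carriers Named integer vector over the same genes.
#' @param n_cases,n_controls Cohort sizes.
#' @param level Confidence level for the Woolf interval, default 0.95.
#' @return An object of class `"cmp_burden"`: a list with `table` (data
#'   frame gene, a, b, c, d, or_value, ci_low, ci_high, p, q), `n_cases`,
#'   `n_controls`, `level`, `call`. Methods: [print.cmp_burden()],
#'   [summary.cmp_burden()], [coef.cmp_burden()], [confint.cmp_burden()],
#'   [plot.cmp_burden()].
#' @export
#' @examples
#' fit <- cmp_burden(c(FKTN = 4, DTNA = 12), c(FKTN = 0, DTNA = 12),
#'                   n_cases = 209, n_controls = 1326)
#' print(fit)
#' coef(fit)
cmp_burden <- function(case_carriers, control_carriers, n_cases, n_controls,
                       level = 0.95) {
  if (is.null(names(case_carriers)) || is.null(names(control_carriers)))
    .stopf("carrier vectors must be named by gene")
  genes <- names(case_carriers)
  if (!setequal(genes, names(control_carriers)))
    .stopf("case and control carrier vectors must cover the same genes")
  control_carriers <- control_carriers[genes]
  if (n_controls <= 0) .stopf("no controls supplied: odds ratio undefined")
  if (any(case_carriers > n_cases) || any(control_carriers > n_controls))
    .stopf("carrier counts exceed cohort size")
  a <- as.integer(case_carriers)
  c_ <- as.integer(control_carriers)
  b <- n_cases - a
  d <- n_controls - c_
  or <- ha_odds_ratio(a, b, c_, d)
  ci <- woolf_ci(a, b, c_, d, level = level)
  if (is.null(dim(ci))) ci <- matrix(ci, nrow = 1,
                                     dimnames = list(NULL, c("low", "high")))
  p <- vapply(seq_along(a), function(i)
    fisher_two_sided(a[i], b[i], c_[i], d[i]), numeric(1))
  tested <- (a + c_) > 0
  q <- bh_fdr(p, tested)
  tab <- data.frame(gene = genes, a = a, b = b, c = c_, d = d,
                    or_value = or, ci_low = ci[, "low"],
                    ci_high = ci[, "high"], p = p, q = q,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(table = tab, n_cases = n_cases, n_controls = n_controls,
                 level = level, call = match.call()),
            class = "cmp_burden")
}

# display rounding: OR to 1 decimal; CI bounds < 10 to 1 decimal, >= 10 to
# integer ("3.1-1083", "1.4-81" report style)
.format_or <- function(x) formatC(round_half_up(x, 1), format = "f", digits = 1)
.format_ci_bound <- function(x) {
  ifelse(x < 10,
         formatC(round_half_up(x, 1), format = "f", digits = 1),
         formatC(round_half_up(x, 0), format = "d"))
}

#' @export
print.cmp_burden <- function(x, ...) {
  cat(sprintf("Gene-level carrier burden: %d genes, %d cases vs %d controls\n",
              nrow(x$table), x$n_cases, x$n_controls))
  t <- x$table
  disp <- data.frame(
    gene = t$gene,
    carriers = sprintf("%d/%d vs %d/%d", t$a, x$n_cases, t$c, x$n_controls),
    OR = .format_or(t$or_value),
    CI = sprintf("%s-%s", .format_ci_bound(t$ci_low),
                 .format_ci_bound(t$ci_high)),
    p = formatC(t$p, format = "g", digits = 3),
    q = ifelse(is.na(t$q), "-", formatC(t$q, format = "g", digits = 3)))
  print(disp, row.names = FALSE)
  invisible(x)
}

#' @export
summary.cmp_burden <- function(object, alpha = 0.05, ...) {
  t <- object$table
  structure(list(fit = object,
                 n_tested = sum(!is.na(t$q)),
                 n_excluded = sum(is.na(t$q)),
                 n_significant = sum(t$q < alpha, na.rm = TRUE),
                 alpha = alpha,
                 top = t[order(t$p), ][seq_len(min(5, nrow(t))), ]),
            class = "summary.cmp_burden")
}

#' @export
print.summary.cmp_burden <- function(x, ...) {
  print(x$fit)
  cat(sprintf("\n%d gene(s) tested (%d excluded with zero carriers); %d with q < %g\n",
              x$n_tested, x$n_excluded, x$n_significant, x$alpha))
  invisible(x)
}

#' @export
coef.cmp_burden <- function(object, ...) {
  stats::setNames(object$table$or_value, object$table$gene)
}

#' @export
confint.cmp_burden <- function(object, parm, level, ...) {
  m <- as.matrix(object$table[, c("ci_low", "ci_high")])
  rownames(m) <- object$table$gene
  colnames(m) <- c("low", "high")
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' Forest plot of gene-level odds ratios
#'
#' @param x A `cmp_burden` fit.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cmp_burden <- function(x, ...) {
  t <- x$table[order(x$table$or_value), ]
  n <- nrow(t)
  graphics::plot(t$or_value, seq_len(n), log = "x", xlim =
                   range(c(t$ci_low, t$ci_high, 1)), yaxt = "n",
                 xlab = "odds ratio (Haldane-Anscombe corrected, log scale)",
                 ylab = "", pch = 19, ...)
  graphics::segments(t$ci_low, seq_len(n), t$ci_high, seq_len(n))
  graphics::abline(v = 1, lty = 2, col = "grey50")
  graphics::axis(2, at = seq_len(n), labels = t$gene, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Cohort classification tally
#'
#' Counts and percentages for the per-case pipeline verdicts. Percentages
#' are reported both at one decimal (half-up) and as whole percent, the two
#' conventions used in cohort reports (77/209 is 36.8%, printed 37%).
#'
#' @param classifications Data frame with one row per case and logical
#'   columns `coding_positive`, `cnv_positive`, `candidate_lof`,
#'   `regulatory_positive`, `gene_elusive` plus integer columns `n_coding`,
#'   `n_regulatory`.
#' @param n_cases Denominator; defaults to `nrow(classifications)`.
#' @return Data frame: `category`, `count`, `percent` (1 decimal, half-up),
#'   `percent_int` (whole percent, half-up).
#' @export
#' @examples
#' cc <- data.frame(coding_positive = c(TRUE, FALSE), cnv_positive = FALSE,
#'                  candidate_lof = FALSE, regulatory_positive = c(FALSE, TRUE),
#'                  gene_elusive = c(FALSE, TRUE), n_coding = c(2, 0),
#'                  n_regulatory = c(0, 1))
#' case_tally(cc)
case_tally <- function(classifications, n_cases = nrow(classifications)) {
  cc <- classifications
  counts <- c(
    coding_positive = sum(cc$coding_positive),
    cnv_positive = sum(cc$cnv_positive),
    candidate_lof = sum(cc$candidate_lof),
    regulatory_positive = sum(cc$regulatory_positive),
    gene_elusive = sum(cc$gene_elusive),
    multiple_coding = sum(cc$n_coding > 1),
    multiple_regulatory = sum(cc$n_regulatory > 1),
    both_types = sum(cc$n_coding > 0 & cc$n_regulatory > 0),
    multiple_any = sum(cc$n_coding + cc$n_regulatory > 1))
  pct <- 100 * counts / n_cases
  data.frame(category = names(counts), count = as.integer(counts),
             percent = round_half_up(pct, 1),
             percent_int = round_half_up(pct, 0),
             stringsAsFactors = FALSE, row.names = NULL)
}
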