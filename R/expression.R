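#' @title Expression-based functional support
#' @description
#' Two quantitative rules used to call a variant functionally supported from
#' expression data: percentile placement of a carrier's myocardial
#' expression against the remaining cohort, and the 2^-ddCt fold change
#' from qRT-PCR cycle thresholds.
#' @name expression_validation
NULL

#' Percentile of a carrier's expression within the cohort
#'
#' Mid-rank percentile of the carrier's value against the remaining samples
#' (the carrier is excluded from the reference distribution):
#' `100 * (#strictly below + 0.5 * #ties) / (n - 1)`. Values below the 25th
#' percentile are flagged `"low"` (consistent with nonsense-mediated decay
#' of a loss-of-function allele), above the 75th `"high"`; the rank is
#' invariant to any strictly monotone transform of the expression scale.
#'
#' @param expr Numeric matrix, genes x samples (e.g. scaled RPKM), with
#'   dimnames.
#' @param gene Gene symbol (row).
#' @param carrier Carrier sample id (column).
#' @return List with `percentile` in \[0, 100\] and `flag` ("low", "high"
#'   or "none").
#' @export
carrier_percentile <- function(expr, gene, carrier) {
  if (!gene %in% rownames(expr)) .stopf("gene '%s' absent from matrix", gene)
  if (!carrier %in% colnames(expr)) .stopf("sample '%s' absent from matrix", carrier)
  if (ncol(expr) < 4) .stopf("cohort too small (need >= 4 samples)")
  if (any(expr < 0)) .stopf("expression values must be non-negative")
  v <- expr[gene, carrier]
  rest <- expr[gene, setdiff(colnames(expr), carrier)]
  pct <- 100 * (sum(rest < v) + 0.5 * sum(rest == v)) / length(rest)
  flag <- if (pct < 25) "low" else if (pct > 75) "high" else "none"
  list(percentile = pct, flag = flag)
}

#' Relative expression fold change by the 2^-ddCt method
#'
#' Per group, dCt = mean target Ct - mean reference Ct; ddCt = dCt(case) -
#' dCt(control); the fold change is `2^-ddCt`. Replicate Ct values are
#' averaged before differencing, so adding a constant to both target and
#' reference leaves the fold change unchanged.
#'
#' @param case_target,case_reference Replicate Ct values for the case
#'   sample (target and housekeeping gene).
#' @param control_target,control_reference Replicate Ct values for the
#'   control group.
#' @return Fold change (1 = no change; 0.5 = one-cycle deficit).
#' @export
#' @examples
#' ddct_fold_change(26, 20, 25, 20)  # 0.5: case is one cycle behind
ddct_fold_change <- function(case_target, case_reference,
                             control_target, control_reference) {
  cts <- c(case_target, case_reference, control_target, control_reference)
  if (any(cts <= 0)) .stopf("Ct values must be positive")
  ddct <- (mean(case_target) - mean(case_reference)) -
    (mean(control_target) - mean(control_reference))
  2^(-ddct)
}
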