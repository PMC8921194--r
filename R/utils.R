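#' Round half away from zero
#'
#' Decimal rounding with ties going up (`0.5 -> 1`), the convention used for
#' all displayed percentages and odds ratios in this package. Base `round()`
#' uses banker's rounding and would print 4.25% as 4.2%.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 4.25), 0:1 * c(0, 1, 1))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# rounds to the number of decimals the target value is printed with,
# then tests equality at that precision
.matches_printed <- function(value, printed, digits) {
  isTRUE(all(round_half_up(value, digits) == printed))
}

# length of intersection of two half-open intervals [s1,e1) and [s2,e2)
.overlap_len <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

# run expr with a locally seeded RNG stream, restoring global state after
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
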