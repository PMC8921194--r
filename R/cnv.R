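#' @title CNV consensus filtering and overlap annotation
#' @description
#' Copy-number calls come from two read-depth callers per sample. A call is
#' retained only as a consensus: both callers report the same copy-number
#' type with at least 50% reciprocal overlap (inclusive), the consensus
#' (represented conservatively by the intersection interval) is longer than
#' 1 kb (strict), overlaps telomere/centromere/segmental-duplication masks
#' on less than 70% of its bases (strict), overlaps copy-number-prone
#' regions on less than 30% (strict), and occurs at under 1% frequency
#' (strict) in a reference CNV panel. All intervals are 0-based half-open.
#' @name cnv_prioritization
NULL

#' Reciprocal overlap of two intervals
#'
#' Returns the intersection length divided by each interval's own length.
#' Consensus between two callers requires both fractions to be at least 0.5
#' (inclusive) and matching copy-number type; intervals on different
#' chromosomes have overlap (0, 0).
#'
#' @param start1,end1 First interval, 0-based half-open.
#' @param start2,end2 Second interval.
#' @return Numeric vector `c(frac1, frac2)` (or a 2-column matrix for
#'   vector input).
#' @export
#' @examples
#' reciprocal_overlap(0, 100, 50, 150)  # 0.5 0.5
reciprocal_overlap <- function(start1, end1, start2, end2) {
  if (any(end1 <= start1) || any(end2 <= start2))
    .stopf("intervals must satisfy start < end")
  inter <- .overlap_len(start1, end1, start2, end2)
  out <- cbind(frac1 = inter / (end1 - start1),
               frac2 = inter / (end2 - start2))
  if (nrow(out) == 1)
    stats::setNames(c(out[1, 1], out[1, 2]), c("frac1", "frac2"))
  else out
}

#' Fraction of a CNV covered by a genomic mask
#'
#' Computes the fraction of the CNV's bases covered by the union of the
#' mask's intervals on the same chromosome (mask intervals are merged
#' before counting, so overlapping mask features are not double-counted).
#'
#' @param chrom,start,end CNV interval, 0-based half-open.
#' @param mask Data frame with columns `chrom`, `start`, `end`.
#' @return Fraction in \[0, 1\].
#' @export
mask_overlap_fraction <- function(chrom, start, end, mask) {
  if (end <= start) .stopf("CNV interval must satisfy start < end")
  m <- mask[mask$chrom == chrom, , drop = FALSE]
  if (nrow(m) == 0) return(0)
  ir <- IRanges::reduce(IRanges::IRanges(m$start + 1L, m$end))
  cov <- IRanges::intersect(ir, IRanges::IRanges(start + 1L, end))
  sum(IRanges::width(cov)) / (end - start)
}

# per-sample, per-type consensus pairs between two callsets; returns
# intersection intervals
.consensus_pairs <- function(a, b, min_recip) {
  if (nrow(a) == 0 || nrow(b) == 0) return(NULL)
  out <- NULL
  for (ch in intersect(a$chrom, b$chrom)) {
    ai <- a[a$chrom == ch, , drop = FALSE]
    bi <- b[b$chrom == ch, , drop = FALSE]
    hits <- IRanges::findOverlaps(IRanges::IRanges(ai$start + 1L, ai$end),
                                  IRanges::IRanges(bi$start + 1L, bi$end))
    if (length(hits) == 0) next
    qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
    ro <- reciprocal_overlap(ai$start[qa], ai$end[qa],
                             bi$start[qb], bi$end[qb])
    if (length(qa) == 1) ro <- matrix(ro, nrow = 1)
    ok <- ro[, 1] >= min_recip & ro[, 2] >= min_recip
    if (!any(ok)) next
    out <- rbind(out, data.frame(
      chrom = ch,
      start = pmax(ai$start[qa][ok], bi$start[qb][ok]),
      end = pmin(ai$end[qa][ok], bi$end[qb][ok]),
      stringsAsFactors = FALSE))
  }
  out
}

#' Consensus and context filter for CNV callsets
#'
#' Pairs calls from two callers within each sample and copy-number type,
#' keeps pairs with reciprocal overlap >= `min_recip` on both sides,
#' represents each consensus by the intersection interval, then applies the
#' size, mask, and panel-frequency rules. A sample present in only one
#' callset yields no consensus calls (no single-caller rescue). Panel
#' frequency is the maximum frequency among panel regions matching the
#' consensus at >= 50% reciprocal overlap; a consensus matching no panel
#' region has frequency 0.
#'
#' @param calls_a,calls_b Data frames with columns `sample_id`, `chrom`,
#'   `start`, `end`, `cn_type` ("deletion"/"duplication").
#' @param masks Data frame with columns `name` (telomere, centromere,
#'   segdup, cn_prone), `chrom`, `start`, `end`.
#' @param panel_freqs Data frame with columns `chrom`, `start`, `end`,
#'   `freq`: reference-panel CNV frequencies.
#' @param min_size Strict lower size bound in bp, default 1000.
#' @param max_mask_frac Strict upper bound on telomere/centromere/segdup
#'   overlap, default 0.7.
#' @param max_cnprone_frac Strict upper bound on copy-number-prone overlap,
#'   default 0.3.
#' @param max_panel_freq Strict upper bound on panel frequency, default 0.01.
#' @param min_recip Inclusive reciprocal-overlap bound, default 0.5.
#' @return Data frame of retained consensus calls (`sample_id`, `chrom`,
#'   `start`, `end`, `cn_type`, `length`, `mask_frac`, `cnprone_frac`,
#'   `panel_freq`), with per-rule drop counts in attribute `"dropped"`.
#' @export
cnv_consensus_filter <- function(calls_a, calls_b, masks, panel_freqs,
                                 min_size = 1000, max_mask_frac = 0.7,
                                 max_cnprone_frac = 0.3,
                                 max_panel_freq = 0.01, min_recip = 0.5) {
  hard_mask <- masks[masks$name %in% c("telomere", "centromere", "segdup"), ,
                     drop = FALSE]
  cn_prone <- masks[masks$name == "cn_prone", , drop = FALSE]
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      cn_type = character(0), length = integer(0),
                      mask_frac = numeric(0), cnprone_frac = numeric(0),
                      panel_freq = numeric(0))
  cons <- NULL
  for (s in intersect(unique(calls_a$sample_id), unique(calls_b$sample_id))) {
    for (ty in c("deletion", "duplication")) {
      a <- calls_a[calls_a$sample_id == s & calls_a$cn_type == ty, , drop = FALSE]
      b <- calls_b[calls_b$sample_id == s & calls_b$cn_type == ty, , drop = FALSE]
      p <- .consensus_pairs(a, b, min_recip)
      if (!is.null(p) && nrow(p)) {
        p$sample_id <- s; p$cn_type <- ty
        cons <- rbind(cons, p)
      }
    }
  }
  if (is.null(cons) || nrow(cons) == 0) {
    attr(empty, "dropped") <- c(size = 0L, mask = 0L, cn_prone = 0L, panel = 0L)
    return(empty)
  }
  cons <- cons[!duplicated(cons[c("sample_id", "chrom", "start", "end",
                                  "cn_type")]), , drop = FALSE]
  cons$length <- cons$end - cons$start
  cons$mask_frac <- vapply(seq_len(nrow(cons)), function(i)
    mask_overlap_fraction(cons$chrom[i], cons$start[i], cons$end[i],
                          hard_mask), numeric(1))
  cons$cnprone_frac <- vapply(seq_len(nrow(cons)), function(i)
    mask_overlap_fraction(cons$chrom[i], cons$start[i], cons$end[i],
                          cn_prone), numeric(1))
  cons$panel_freq <- vapply(seq_len(nrow(cons)), function(i) {
    p <- panel_freqs[panel_freqs$chrom == cons$chrom[i], , drop = FALSE]
    if (nrow(p) == 0) return(0)
    ro <- reciprocal_overlap(rep(cons$start[i], nrow(p)),
                             rep(cons$end[i], nrow(p)), p$start, p$end)
    if (nrow(p) == 1) ro <- matrix(ro, nrow = 1)
    hit <- ro[, 1] >= 0.5 & ro[, 2] >= 0.5
    if (any(hit)) max(p$freq[hit]) else 0
  }, numeric(1))

  ok_size <- cons$length > min_size
  ok_mask <- cons$mask_frac < max_mask_frac
  ok_prone <- cons$cnprone_frac < max_cnprone_frac
  ok_freq <- cons$panel_freq < max_panel_freq
  out <- cons[ok_size & ok_mask & ok_prone & ok_freq,
              c("sample_id", "chrom", "start", "end", "cn_type", "length",
                "mask_frac", "cnprone_frac", "panel_freq"), drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- c(size = sum(!ok_size),
                            mask = sum(ok_size & !ok_mask),
                            cn_prone = sum(ok_size & ok_mask & !ok_prone),
                            panel = sum(ok_size & ok_mask & ok_prone & !ok_freq))
  out
}

#' Label CNVs with overlapped coding exons and regulatory regions
#'
#' @param cnvs Retained consensus CNV table.
#' @param exons Data frame with columns `chrom`, `start`, `end`, `gene`
#'   (0-based half-open coding exons).
#' @param regions Regulatory region table (see [regulatory_regions]).
#' @return `cnvs` with added columns `coding_genes` and `regulatory_genes`
#'   (semicolon-joined, empty when nothing is overlapped).
#' @export
cnv_gene_overlap <- function(cnvs, exons, regions) {
  hits_for <- function(i, tab, genes_of) {
    t <- tab[tab$chrom == cnvs$chrom[i], , drop = FALSE]
    if (nrow(t) == 0) return("")
    ov <- .overlap_len(cnvs$start[i], cnvs$end[i], t$start, t$end) > 0
    paste(sort(unique(genes_of(t)[ov])), collapse = ";")
  }
  cnvs$coding_genes <- vapply(seq_len(nrow(cnvs)), hits_for, character(1),
                              tab = exons, genes_of = function(t) t$gene)
  cnvs$regulatory_genes <- vapply(seq_len(nrow(cnvs)), function(i) {
    t <- regions[regions$chrom == cnvs$chrom[i], , drop = FALSE]
    if (nrow(t) == 0) return("")
    ov <- .overlap_len(cnvs$start[i], cnvs$end[i], t$start, t$end) > 0
    paste(sort(unique(unlist(strsplit(t$genes[ov], ";", fixed = TRUE)))),
          collapse = ";")
  }, character(1))
  cnvs
}

#' Read / write CNV callsets as BED
#'
#' Dialect: chrom, start, end, sample_id, cn_type (+ any extra columns on
#' write). No header.
#'
#' @param path File path.
#' @return `read_cnv_bed` returns a CNV call table.
#' @export
read_cnv_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(b)[1:5] <- c("chrom", "start", "end", "sample_id", "cn_type")
  b[c("sample_id", "chrom", "start", "end", "cn_type")]
}

#' @rdname read_cnv_bed
#' @param calls CNV call table to write.
#' @export
write_cnv_bed <- function(calls, path) {
  out <- calls[c("chrom", "start", "end", "sample_id", "cn_type",
                 setdiff(names(calls), c("chrom", "start", "end",
                                         "sample_id", "cn_type")))]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
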