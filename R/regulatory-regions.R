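#' @title Regulatory regions: promoters, enhancers, and gene links
#' @description
#' Regulatory elements are data frames with columns `chrom`, `start`, `end`
#' (0-based, half-open — BED convention), `kind` ("promoter" or "enhancer"),
#' `genes` (semicolon-joined linked gene symbols, non-empty), `lv_active`
#' and `in_regulatory_build` (logicals). A variant at 1-based position p
#' overlaps a region \[s, e) iff s <= p - 1 < e.
#'
#' The experimentally derived heart region set (open-chromatin and histone
#' peaks) is consumed as a BED input; the fallback promoter window applies
#' only to genes with no provided regions.
#' @name regulatory_regions
NULL

.region_cols <- c("chrom", "start", "end", "kind", "genes", "lv_active",
                  "in_regulatory_build")

.check_regions <- function(regions) {
  missing_cols <- setdiff(.region_cols, names(regions))
  if (length(missing_cols))
    .stopf("region table lacks columns: %s", paste(missing_cols, collapse = ", "))
  if (nrow(regions) && any(regions$start >= regions$end))
    .stopf("regions must satisfy start < end (0-based half-open)")
  if (nrow(regions) && any(!nzchar(regions$genes)))
    .stopf("every region must link at least one gene")
  invisible(regions)
}

#' Fallback promoter window around a transcription start site
#'
#' For genes lacking experimentally derived regulatory regions, the promoter
#' is defined as 1.5 kb upstream and 1 kb downstream of the TSS. Upstream
#' and downstream follow the strand: on "+" the window is
#' \[tss - up, tss + down); on "-" it is \[tss - down, tss + up). Windows are
#' clipped at position 0 (chromosome start).
#'
#' @param tss TSS table with columns `gene`, `chrom`, `position` (0-based),
#'   `strand` ("+"/"-"); one row per gene.
#' @param up Upstream extent in bp (default 1500).
#' @param down Downstream extent in bp (default 1000).
#' @return Region table with one promoter per TSS row.
#' @export
#' @examples
#' tss <- data.frame(gene = "FKTN", chrom = "chr9", position = 10000,
#'                   strand = "+")
#' fallback_promoter(tss)  # [8500, 11000)
fallback_promoter <- function(tss, up = 1500, down = 1000) {
  if (up <= 0 || down <= 0) .stopf("up and down must be positive")
  if (!all(tss$strand %in% c("+", "-"))) .stopf("strand must be + or -")
  plus <- tss$strand == "+"
  start <- ifelse(plus, tss$position - up, tss$position - down)
  end <- ifelse(plus, tss$position + down, tss$position + up)
  start <- pmax(0, start)
  if (any(start >= end))
    .stopf("promoter window empty after clipping at chromosome start")
  data.frame(chrom = tss$chrom, start = start, end = end, kind = "promoter",
             genes = tss$gene, lv_active = FALSE, in_regulatory_build = FALSE,
             stringsAsFactors = FALSE)
}

#' Merge overlapping regulatory regions of the same kind
#'
#' Overlapping or book-ended (abutting under the half-open convention)
#' intervals of the same kind on the same chromosome are merged into maximal
#' elements; promoters and enhancers are never merged with each other. The
#' merged region links the union of the constituent gene sets, and the
#' `lv_active` / `in_regulatory_build` flags are OR-ed. Output is sorted and
#' non-overlapping within kind.
#'
#' @param regions Region table (see [regulatory_regions]).
#' @return Merged region table.
#' @export
merge_regions <- function(regions) {
  .check_regions(regions)
  if (nrow(regions) == 0) return(regions)
  parts <- split(regions, paste(regions$chrom, regions$kind))
  merged <- lapply(parts, function(p) {
    ir <- IRanges::IRanges(start = p$start + 1L, end = p$end)  # 1-based closed
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    data.frame(
      chrom = p$chrom[1],
      start = IRanges::start(red) - 1L,
      end = IRanges::end(red),
      kind = p$kind[1],
      genes = vapply(revmap, function(i) {
        paste(sort(unique(unlist(strsplit(p$genes[i], ";", fixed = TRUE)))),
              collapse = ";")
      }, character(1)),
      lv_active = vapply(revmap, function(i) any(p$lv_active[i]), logical(1)),
      in_regulatory_build = vapply(revmap, function(i)
        any(p$in_regulatory_build[i]), logical(1)),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$chrom, out$start, out$kind), ]
  rownames(out) <- NULL
  out
}

#' Link an enhancer to its target gene(s)
#'
#' A curated link table, when it covers the enhancer, takes precedence over
#' proximity. Otherwise the enhancer is assigned to the gene(s) whose TSS is
#' nearest to the enhancer midpoint, with ties returning all tied genes.
#'
#' @param enhancer One-row data frame or list with `chrom`, `start`, `end`.
#' @param tss TSS table (see [fallback_promoter]).
#' @param provided_links Optional named list or named character vector mapping
#'   enhancer ids (`chrom:start-end`) to gene symbols.
#' @return Character vector of gene symbols (empty, with a warning, when no
#'   TSS exists on the enhancer's chromosome).
#' @export
link_enhancer_to_gene <- function(enhancer, tss, provided_links = NULL) {
  if (nrow(as.data.frame(tss)) == 0) .stopf("tss table is empty")
  id <- sprintf("%s:%d-%d", enhancer$chrom, enhancer$start, enhancer$end)
  if (!is.null(provided_links) && id %in% names(provided_links))
    return(unlist(provided_links[[id]], use.names = FALSE))
  local <- tss[tss$chrom == enhancer$chrom, , drop = FALSE]
  if (nrow(local) == 0) {
    .warnf("no TSS on %s; enhancer %s left unlinked", enhancer$chrom, id)
    return(character(0))
  }
  mid <- (enhancer$start + enhancer$end) / 2
  d <- abs(local$position - mid)
  local$gene[d == min(d)]
}

#' Summarise a merged region set
#'
#' Per-gene region counts and covered base pairs (computed on the union of
#' that gene's intervals), plus global totals over distinct bases. Because a
#' region may link several genes, per-gene base counts can sum to more than
#' the global distinct-base total; both conventions are reported.
#'
#' @param regions Merged region table.
#' @param registry Optional gene registry; genes with no regions are then
#'   reported with zero counts.
#' @return List with `per_gene` (data frame: gene, n_regions, covered_bp),
#'   `total_regions`, `total_bp` (distinct bases), and `total_bp_per_gene_sum`.
#' @export
region_set_summary <- function(regions, registry = NULL) {
  .check_regions(regions)
  genes <- if (nrow(regions))
    sort(unique(unlist(strsplit(regions$genes, ";", fixed = TRUE))))
  else character(0)
  if (!is.null(registry)) genes <- sort(unique(c(genes, registry$symbol)))
  union_bp <- function(df) {
    if (nrow(df) == 0) return(0L)
    tot <- 0L
    for (ch in unique(df$chrom)) {
      p <- df[df$chrom == ch, ]
      ir <- IRanges::reduce(IRanges::IRanges(p$start + 1L, p$end))
      tot <- tot + sum(IRanges::width(ir))
    }
    tot
  }
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    hit <- vapply(strsplit(regions$genes, ";", fixed = TRUE),
                  function(x) g %in% x, logical(1))
    data.frame(gene = g, n_regions = sum(hit),
               covered_bp = union_bp(regions[hit, , drop = FALSE]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(per_gene))
    per_gene <- data.frame(gene = character(0), n_regions = integer(0),
                           covered_bp = integer(0))
  list(per_gene = per_gene,
       total_regions = nrow(regions),
       total_bp = union_bp(regions),
       total_bp_per_gene_sum = sum(per_gene$covered_bp))
}

#' Read / write regulatory regions as BED
#'
#' Dialect: BED3 plus columns 4-7 = kind, semicolon-joined linked genes,
#' lv_active (0/1), in_regulatory_build (0/1). No header.
#'
#' @param path File path.
#' @return `read_regions_bed` returns a region table.
#' @export
read_regions_bed <- function(path) {
  b <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                         col.names = .region_cols)
  b$lv_active <- as.logical(b$lv_active)
  b$in_regulatory_build <- as.logical(b$in_regulatory_build)
  .check_regions(b)
  b
}

#' @rdname read_regions_bed
#' @param regions Region table to write.
#' @export
write_regions_bed <- function(regions, path) {
  .check_regions(regions)
  out <- regions[, .region_cols]
  out$lv_active <- as.integer(out$lv_active)
  out$in_regulatory_build <- as.integer(out$in_regulatory_build)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
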