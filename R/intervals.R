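#' Construct a genomic interval
#'
#' Intervals are 0-based, half-open: a feature covering the first ten bases of
#' a contig is `start = 0, end = 10`.  The equivalent GFF3 record is
#' `start = 1, end = 10` (1-based, closed); [read_gene_models()] and
#' [write_gene_models()] convert at the boundary.
#'
#' @param contig contig/chromosome name (non-empty string).
#' @param start,end 0-based half-open coordinates with `0 <= start < end`.
#' @param strand one of `"+"`, `"-"`, `"*"` (unstranded).
#' @return a list with class `genomic_interval`.
#' @export
genomic_interval <- function(contig, start, end, strand = "*") {
  stopifnot(is.character(contig), nzchar(contig))
  start <- as.numeric(start); end <- as.numeric(end)
  if (!(start >= 0 && start < end))
    stop("invalid interval: need 0 <= start < end, got [", start, ", ", end, ")")
  if (!strand %in% c("+", "-", "*"))
    stop("strand must be one of '+', '-', '*'")
  structure(list(contig = contig, start = start, end = end, strand = strand),
            class = "genomic_interval")
}

interval_width <- function(x) x$end - x$start

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("<%s:%d-%d(%s)>\n", x$contig, x$start, x$end, x$strand))
  invisible(x)
}

## width of the overlap of [s1,e1) and [s2,e2); 0 when disjoint (vectorised)
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

## TRUE when [s1,e1) and [s2,e2) intersect
intervals_overlap <- function(s1, e1, s2, e2) overlap_width(s1, e1, s2, e2) > 0

## Overlap hits between two 0-based half-open interval tables (start, end
## columns).  Returns a data.frame of (query_idx, subject_idx) pairs.
interval_overlaps <- function(query, subject) {
  q <- IRanges::IRanges(start = query$start + 1L, end = query$end)
  s <- IRanges::IRanges(start = subject$start + 1L, end = subject$end)
  hits <- IRanges::findOverlaps(q, s)
  data.frame(query_idx = S4Vectors::queryHits(hits),
             subject_idx = S4Vectors::subjectHits(hits))
}

## Union (reduce) of a 0-based half-open interval table; abutting intervals
## merge.  Returns a sorted data.frame(start, end).
interval_union <- function(tbl) {
  if (nrow(tbl) == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  ir <- IRanges::reduce(IRanges::IRanges(start = tbl$start + 1L, end = tbl$end))
  data.frame(start = IRanges::start(ir) - 1, end = IRanges::end(ir))
}

## Complement of intervals within [lo, hi); input need not be disjoint.
interval_complement <- function(tbl, lo, hi) {
  u <- interval_union(tbl)
  u <- u[u$end > lo & u$start < hi, , drop = FALSE]
  starts <- c(lo, pmin(u$end, hi))
  ends <- c(pmax(u$start, lo), hi)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

## Subtract interval [s, e) from each row of tbl (exon arithmetic).
interval_subtract <- function(tbl, s, e) {
  out <- list()
  for (i in seq_len(nrow(tbl))) {
    a <- tbl$start[i]; b <- tbl$end[i]
    if (e <= a || s >= b) { out[[length(out) + 1L]] <- c(a, b); next }
    if (s > a) out[[length(out) + 1L]] <- c(a, min(s, b))
    if (e < b) out[[length(out) + 1L]] <- c(max(e, a), b)
  }
  if (!length(out)) return(data.frame(start = numeric(0), end = numeric(0)))
  m <- do.call(rbind, out)
  data.frame(start = m[, 1], end = m[, 2])
}
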