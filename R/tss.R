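#' Construct a TSS signal region
#'
#' A mapped transcription-start region: a per-base distribution of start
#' signal over an interval, plus flags for which of the three independent
#' mapping approaches support it.
#'
#' @param contig contig name.
#' @param start,end 0-based half-open interval.
#' @param signal numeric vector of per-base start counts, length `end - start`.
#' @param strand `"+"` or `"-"`.
#' @param evidence character subset of `c("approach_1","approach_2","approach_3")`.
#' @return a list with class `tss_region`.
#' @export
tss_region <- function(contig, start, end, signal, strand,
                       evidence = "approach_1") {
  stopifnot(length(signal) == end - start, all(signal >= 0),
            strand %in% c("+", "-"), length(evidence) >= 1)
  evidence <- unique(evidence)
  if (!all(evidence %in% paste0("approach_", 1:3)))
    stop("unknown TSS evidence type")
  structure(list(contig = contig, start = start, end = end,
                 signal = as.numeric(signal), strand = strand,
                 evidence = evidence),
            class = "tss_region")
}

#' Is a TSS region validated?
#'
#' A region is validated when supported by at least two of the three
#' independent mapping approaches.  Single-evidence regions are retained but
#' treated as low-confidence and not normally used to set transcript starts.
#'
#' @param region a [tss_region()].
#' @return logical flag.
#' @export
validate_tss_region <- function(region) {
  length(region$evidence) >= 2
}

#' The 90% TSS point of a start-signal region
#'
#' Start-signal distributions are complex and the 5'-most mapped start is
#' often a nonrepresentative outlier.  The annotated start is therefore the
#' point at which 90% of the start signal within the region is encompassed,
#' summing from the 3'-most signal-bearing base and moving 5'.  "Hits 0.9"
#' is read as the first base at which the cumulative fraction reaches >= 0.9
#' (ties resolve toward the 3' side, i.e. the least-extended start).  On the
#' minus strand the traversal direction is reversed.
#'
#' @param region a [tss_region()] with `sum(signal) > 0`.
#' @param fraction cumulative signal fraction to encompass (default 0.9).
#' @return 0-based coordinate of the selected start base.
#' @export
tss_90_percent_point <- function(region, fraction = 0.9) {
  total <- sum(region$signal)
  if (total <= 0) stop("TSS region ", region$contig, ":", region$start, "-",
                       region$end, " carries no start signal")
  pos <- region$start + seq_along(region$signal) - 1   # 0-based base coords
  keep <- region$signal > 0
  pos <- pos[keep]; sig <- region$signal[keep]
  if (region$strand == "+") {            # 3'-most = highest coordinate
    ord <- order(pos, decreasing = TRUE)
  } else {                               # 3'-most = lowest coordinate
    ord <- order(pos)
  }
  cum <- cumsum(sig[ord]) / total
  pos[ord][which(cum >= fraction)[1]]
}

#' Assign a transcript 5' end from the evidence hierarchy
#'
#' Evidence precedence: validated TSS region 90% point > short-capped
#' RNA/promoter-profiling signal > 5'-most cDNA end > robust coverage
#' estimate > translation-start fallback (no 5' UTR).  A TSS region is
#' applicable only when it overlaps the transcript's first exon or ends
#' within `upstream_window` bp upstream on the same strand.
#'
#' @param tx a [transcript()].
#' @param gene the parent [gene_model()].
#' @param tss_regions list of [tss_region()] (only validated ones are used).
#' @param alt_tss_signals optional data.frame of short-capped/promoter
#'   profiling starts with columns `contig`, `position`, `strand`.
#' @param cdnas optional list of [cdna_alignment()] objects.
#' @param coverage optional list of [coverage_track()] used for the coverage
#'   estimate.
#' @param params pipeline parameters, see [pipeline_config()]
#'   (`tss_upstream_window`, `coverage_floor`).
#' @return list with `transcript_id`, `assigned_position` (0-based base),
#'   `source`, and the possibly updated transcript under `transcript`.
#' @export
assign_transcript_start <- function(tx, gene, tss_regions = list(),
                                    alt_tss_signals = NULL, cdnas = list(),
                                    coverage = list(),
                                    params = pipeline_config()) {
  if (!gene$strand %in% c("+", "-"))
    stop("transcript ", tx$transcript_id, " lies on an unstranded contig")
  w <- params$tss_upstream_window
  cur5 <- transcript_5p(tx, gene$strand)
  first_exon <- if (gene$strand == "+") tx$exons[1, ] else
    tx$exons[nrow(tx$exons), ]

  applicable <- function(lo, hi) {
    ## overlaps the first exon, or lies within w bp upstream of the 5' end
    if (intervals_overlap(lo, hi, first_exon$start, first_exon$end))
      return(TRUE)
    if (gene$strand == "+") hi > cur5 - w && hi <= cur5 + 1
    else lo < cur5 + 1 + w && lo >= cur5
  }

  pick <- NULL
  for (r in tss_regions) {
    if (r$contig != gene$contig || r$strand != gene$strand) next
    if (!validate_tss_region(r)) next
    if (applicable(r$start, r$end)) { pick <- r; break }
  }
  if (!is.null(pick)) {
    p <- tss_90_percent_point(pick, params$tss_fraction)
    return(finish_assignment(tx, gene, p, "tss_90pct"))
  }
  if (!is.null(alt_tss_signals) && nrow(alt_tss_signals)) {
    sel <- alt_tss_signals$contig == gene$contig &
      alt_tss_signals$strand == gene$strand &
      vapply(alt_tss_signals$position, function(p) applicable(p, p + 1),
             logical(1))
    if (any(sel)) {
      p <- if (gene$strand == "+") min(alt_tss_signals$position[sel]) else
        max(alt_tss_signals$position[sel])
      return(finish_assignment(tx, gene, p, "short_capped_rampage"))
    }
  }
  ends5 <- numeric(0)
  for (cd in cdnas) {
    if (cd$contig != gene$contig) next
    p <- if (gene$strand == "+") cd$exons$start[1] else
      cd$exons$end[nrow(cd$exons)] - 1
    if (applicable(p, p + 1)) ends5 <- c(ends5, p)
  }
  if (length(ends5)) {
    p <- if (gene$strand == "+") min(ends5) else max(ends5)
    return(finish_assignment(tx, gene, p, "cdna_5prime"))
  }
  if (length(coverage)) {
    cov <- covered_intervals(coverage, gene$contig,
                             max(0, cur5 - w), cur5 + 1 + w,
                             floor = params$coverage_floor,
                             strand = gene$strand)
    hit <- which(cov$start <= cur5 & cov$end > cur5)
    if (length(hit)) {
      p <- if (gene$strand == "+") cov$start[hit[1]] else cov$end[hit[1]] - 1
      return(finish_assignment(tx, gene, p, "coverage_estimate"))
    }
  }
  ## no evidence of any kind: transcript model begins at the translation start
  if (!is.null(tx$cds)) {
    p <- if (gene$strand == "+") tx$cds[1] else tx$cds[2] - 1
    out <- finish_assignment(tx, gene, p, "cds_start_fallback")
    out$transcript$comments <- unique(c(out$transcript$comments,
                                        "tss_cds_start_fallback"))
    return(out)
  }
  finish_assignment(tx, gene, cur5, "unchanged")
}

## Move the transcript 5' boundary (first/last exon edge) to position p.
finish_assignment <- function(tx, gene, p, source) {
  ex <- tx$exons
  if (gene$strand == "+") {
    limit <- if (!is.null(tx$cds)) tx$cds[1] else ex$end[1] - 1
    ex$start[1] <- min(p, limit)
  } else {
    n <- nrow(ex)
    limit <- if (!is.null(tx$cds)) tx$cds[2] else ex$start[n] + 1
    ex$end[n] <- max(p + 1, limit)
  }
  tx$exons <- ex
  if (source != "unchanged") tx$five_prime_evidence <- source
  list(transcript_id = tx$transcript_id,
       assigned_position = if (gene$strand == "+") ex$start[1] else
         ex$end[nrow(ex)] - 1,
       source = source, transcript = tx)
}
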