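#' Construct a cDNA/EST alignment
#'
#' @param id identifier.
#' @param contig contig name.
#' @param exons data.frame (`start`, `end`), sorted, non-overlapping.
#' @param strand `"+"`, `"-"` or `"*"`.
#' @param polyadenylated logical: does the cDNA end in a poly(A) tail?
#' @return a list with class `cdna_alignment`.
#' @export
cdna_alignment <- function(id, contig, exons, strand = "*",
                           polyadenylated = FALSE) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons$start[-1] < exons$end[-nrow(exons)]))
    stop("cDNA ", id, ": overlapping exons")
  structure(list(id = id, contig = contig, exons = exons, strand = strand,
                 polyadenylated = polyadenylated),
            class = "cdna_alignment")
}

#' RPKM of a coverage track over a window
#'
#' reads-in-window x 1e9 / (window length x total mapped reads), with
#' reads-in-window recovered from the per-base signal as
#' `sum(signal) / read_length`.
#'
#' @param track a [coverage_track()].
#' @param contig,start,end the window (0-based half-open).
#' @param strand optional lane selector for stranded tracks.
#' @return RPKM value.
#' @export
window_rpkm <- function(track, contig, start, end, strand = NULL) {
  len <- end - start
  if (len <= 0) stop("zero-length window")
  reads <- track_interval_sum(track, contig, start, end, strand) /
    track$read_length
  reads * 1e9 / (len * track$total_mapped_reads)
}

## RPKM over a set of exonic intervals (summed signal over summed length)
intervals_rpkm <- function(track, contig, tbl, strand = NULL) {
  len <- sum(tbl$end - tbl$start)
  if (len <= 0) return(0)
  reads <- sum(vapply(seq_len(nrow(tbl)), function(i)
    track_interval_sum(track, contig, tbl$start[i], tbl$end[i], strand),
    numeric(1))) / track$read_length
  reads * 1e9 / (len * track$total_mapped_reads)
}

#' Scan intergenic space for unannotated transcription
#'
#' Steps fixed-size windows across the intergenic mask (the complement of
#' annotated gene extents).  A window qualifies in a track when its RPKM is
#' at least `rpkm_threshold`; qualifying windows sharing at least
#' `min_tracks` common qualifying tracks merge into candidate regions, which
#' are then trimmed to the covered extent.  Regions supported by fewer than
#' `min_tracks` tracks are discarded.
#'
#' @param models list of [gene_model()]s (define the intergenic mask).
#' @param tracks list of [coverage_track()]s.
#' @param contig_lengths named numeric vector of contig lengths.
#' @param params [pipeline_config()] (`window_size`, `window_step`,
#'   `rpkm_threshold`, `min_tracks`, `trim_floor`).
#' @return list of candidate regions: each a list with `contig`, `start`,
#'   `end`, `supporting_tracks` (named RPKM vector), `strand` (`NA` until
#'   [assign_strand()]), `classification` (`"unresolved"`).
#' @export
scan_intergenic <- function(models, tracks, contig_lengths,
                            params = pipeline_config()) {
  if (!length(tracks)) stop("intergenic scan requires coverage tracks")
  wsz <- params$window_size; stp <- params$window_step
  labels <- vapply(tracks, `[[`, character(1), "label")
  regions <- list()
  for (contig in names(contig_lengths)) {
    gl <- contig_lengths[[contig]]
    gene_tbl <- do.call(rbind, lapply(
      Filter(function(g) g$contig == contig, models),
      function(g) data.frame(start = g$start, end = g$end)))
    mask <- interval_complement(
      if (is.null(gene_tbl)) data.frame(start = numeric(0), end = numeric(0))
      else gene_tbl, 0, gl)
    for (k in seq_len(nrow(mask))) {
      lo <- mask$start[k]; hi <- mask$end[k]
      if (hi - lo < wsz) next
      starts <- seq(lo, hi - wsz, by = stp)
      cur <- NULL
      flush <- function(cur) {
        if (is.null(cur) || length(cur$tracks) < params$min_tracks)
          return(NULL)
        ## trim window edges to the covered extent of the supporting tracks
        ## (looking one window beyond the qualifying span, since edge
        ## windows straddling the signal boundary fall below threshold)
        cov <- covered_intervals(tracks[match(cur$tracks, labels)], contig,
                                 max(lo, cur$start - wsz),
                                 min(hi, cur$end + wsz),
                                 floor = params$trim_floor)
        if (!nrow(cov)) return(NULL)
        s <- min(cov$start); e <- max(cov$end)
        sup <- vapply(cur$tracks, function(lb)
          window_rpkm(tracks[[match(lb, labels)]], contig, s, e),
          numeric(1))
        list(contig = contig, start = s, end = e,
             supporting_tracks = sup, strand = NA_character_,
             classification = "unresolved")
      }
      for (ws in starts) {
        q <- labels[vapply(tracks, function(tr)
          window_rpkm(tr, contig, ws, ws + wsz) >= params$rpkm_threshold,
          logical(1))]
        if (length(q) >= params$min_tracks) {
          if (is.null(cur)) {
            cur <- list(start = ws, end = ws + wsz, tracks = q)
          } else if (ws <= cur$end &&
                     length(intersect(cur$tracks, q)) >= params$min_tracks) {
            cur$end <- ws + wsz
            cur$tracks <- intersect(cur$tracks, q)
          } else {
            r <- flush(cur); if (!is.null(r)) regions[[length(regions) + 1L]] <- r
            cur <- list(start = ws, end = ws + wsz, tracks = q)
          }
        } else if (!is.null(cur)) {
          r <- flush(cur); if (!is.null(r)) regions[[length(regions) + 1L]] <- r
          cur <- NULL
        }
      }
      r <- flush(cur); if (!is.null(r)) regions[[length(regions) + 1L]] <- r
    }
  }
  regions
}

#' Assign a strand to a candidate region from stranded coverage
#'
#' The strand carrying at least `strand_fraction` of the stranded signal over
#' the region wins; otherwise the region is retained but unresolved (and not
#' annotatable).
#'
#' @param region a candidate region from [scan_intergenic()].
#' @param tracks list of [coverage_track()]s (only stranded ones are used).
#' @param params [pipeline_config()] (`strand_fraction`).
#' @return the region with `strand` set to `"+"`, `"-"`, or
#'   `NA` (unresolved).
#' @export
assign_strand <- function(region, tracks, params = pipeline_config()) {
  plus <- 0; minus <- 0
  for (tr in tracks) {
    if (tr$strandedness != "stranded") next
    plus <- plus + track_interval_sum(tr, region$contig, region$start,
                                      region$end, "+")
    minus <- minus + track_interval_sum(tr, region$contig, region$start,
                                        region$end, "-")
  }
  tot <- plus + minus
  region$strand <- if (tot == 0) NA_character_
  else if (plus / tot >= params$strand_fraction) "+"
  else if (minus / tot >= params$strand_fraction) "-"
  else NA_character_
  region
}

#' Classify a stranded candidate region
#'
#' Classification order: `antisense_lncRNA` when the region overlaps an
#' annotated gene on the opposite strand; `utr3_extension_of:<gene>` when
#' same-strand coverage runs contiguously (no sub-threshold gap of
#' `utr3_gap` bp or more) from the closest upstream same-strand gene's stop
#' codon through the region; `dual_entity` when the extension contiguity
#' holds but the region also has its own validated TSS signal; otherwise
#' `new_lncRNA`.
#'
#' @param region a strand-assigned candidate region.
#' @param models list of [gene_model()]s.
#' @param tracks list of [coverage_track()]s.
#' @param tss_regions optional list of [tss_region()]s.
#' @param params [pipeline_config()] (`utr3_gap`, `gap_floor`).
#' @return the region with `classification` and optionally
#'   `emitted_comment` and `antisense_of`/`upstream_gene` set.
#' @export
classify_candidate <- function(region, models, tracks, tss_regions = list(),
                               params = pipeline_config()) {
  if (is.na(region$strand)) {
    region$classification <- "unresolved"
    return(region)
  }
  ## antisense: overlap with an opposite-strand gene
  for (g in models) {
    if (g$contig == region$contig && g$strand != region$strand &&
        intervals_overlap(g$start, g$end, region$start, region$end)) {
      region$classification <- "antisense_lncRNA"
      region$antisense_of <- g$gene_id
      region$so_term <- "SO:0000077"
      return(region)
    }
  }
  ## own TSS signal?
  own_tss <- any(vapply(tss_regions, function(r)
    r$contig == region$contig && identical(r$strand, region$strand) &&
      validate_tss_region(r) &&
      intervals_overlap(r$start, r$end, region$start, region$end),
    logical(1)))
  ## 3' extension contiguity from the closest upstream same-strand gene
  up <- NULL
  for (g in models) {
    if (g$contig != region$contig || g$strand != region$strand) next
    if (region$strand == "+" && g$end <= region$start) {
      if (is.null(up) || g$end > up$end) up <- g
    } else if (region$strand == "-" && g$start >= region$end) {
      if (is.null(up) || g$start < up$start) up <- g
    }
  }
  contiguous <- FALSE
  if (!is.null(up)) {
    ref <- reference_isoform(up)
    anchor <- if (!is.null(ref$cds)) {
      if (region$strand == "+") ref$cds[2] else ref$cds[1]
    } else if (region$strand == "+") up$end else up$start
    span <- if (region$strand == "+") c(anchor, region$end) else
      c(region$start, anchor)
    sup <- tracks[match(names(region$supporting_tracks),
                        vapply(tracks, `[[`, character(1), "label"))]
    cov <- covered_intervals(sup, region$contig, span[1], span[2],
                             floor = params$gap_floor,
                             strand = region$strand)
    gaps <- interval_complement(cov, span[1], span[2])
    contiguous <- !nrow(gaps) || max(gaps$end - gaps$start) < params$utr3_gap
  }
  if (contiguous && own_tss) {
    region$classification <- "dual_entity"
    region$upstream_gene <- up$gene_id
    region$emitted_comment <- "lncRNA_from_3utr"
  } else if (contiguous) {
    region$classification <- paste0("utr3_extension_of:", up$gene_id)
    region$upstream_gene <- up$gene_id
  } else {
    region$classification <- "new_lncRNA"
    region$emitted_comment <- "probable_lncRNA"
  }
  region
}

#' Set the 3' end of a transcript from cDNA and coverage evidence
#'
#' Precedence: polyadenylated cDNA 3' ends > coverage estimate > stop-codon
#' fallback.  Poly(A) cDNA ends within `polya_cluster` bases of each other
#' (single linkage) collapse to one terminus at the 3'-most member; clusters
#' further apart yield additional 3' isoforms.  Coverage support extending
#' beyond the longest cDNA adds (or extends) one transcript with an
#' explanatory comment; when several coverage-supported termini exist only
#' the longest is annotated.
#'
#' @param tx a [transcript()] (must have a stop codon or be non-coding).
#' @param gene the parent [gene_model()].
#' @param cdnas list of [cdna_alignment()]s.
#' @param tracks list of [coverage_track()]s.
#' @param params [pipeline_config()] (`polya_cluster`, `gap_floor`,
#'   `utr3_gap`, `utr3_max_extension`).
#' @return list with `transcripts` (the updated transcript first, additional
#'   3' isoforms after it) and `decision` (a [decision_record()] row).
#' @export
set_three_prime_end <- function(tx, gene, cdnas = list(), tracks = list(),
                                params = pipeline_config()) {
  plus <- gene$strand == "+"
  anchor <- if (!is.null(tx$cds)) { if (plus) tx$cds[2] else tx$cds[1] } else
    { if (plus) transcript_3p(tx, "+") + 1 else transcript_3p(tx, "-") }

  set_end <- function(tx, endpos, evidence) {
    ## endpos: half-open end (plus) / start (minus) of the terminal exon
    n <- nrow(tx$exons)
    if (plus) tx$exons$end[n] <- max(endpos, anchor)
    else tx$exons$start[1] <- min(endpos, anchor - 0)
    tx$three_prime_evidence <- evidence
    tx
  }

  ## poly(A) cDNA 3' ends compatible with this gene
  ends <- numeric(0)
  for (cd in cdnas) {
    if (!cd$polyadenylated || cd$contig != gene$contig) next
    if (!(cd$strand %in% c("*", gene$strand))) next
    span <- c(cd$exons$start[1], cd$exons$end[nrow(cd$exons)])
    if (!intervals_overlap(span[1], span[2], gene$start, gene$end + 1)) next
    e <- if (plus) cd$exons$end[nrow(cd$exons)] else cd$exons$start[1]
    ## a usable poly(A) end lies at or beyond the stop codon
    if (plus && e >= anchor) ends <- c(ends, e)
    if (!plus && e <= anchor) ends <- c(ends, e)
  }
  out_tx <- list()
  decision <- NULL
  if (length(ends)) {
    ends <- sort(unique(ends))
    gapbreak <- which(diff(ends) > params$polya_cluster)
    cl <- split(ends, cumsum(c(0, seq_along(ends)[-1] %in% (gapbreak + 1))))
    termini <- vapply(cl, function(v) if (plus) max(v) else min(v), numeric(1))
    termini <- if (plus) sort(termini) else sort(termini, decreasing = TRUE)
    ## primary transcript takes the first terminus; others become isoforms
    out_tx[[1]] <- set_end(tx, termini[1], "polyA_cdna")
    if (length(termini) > 1) {
      for (i in 2:length(termini)) {
        iso <- set_end(tx, termini[i], "polyA_cdna")
        iso$transcript_id <- sprintf("%s.3p%d", tx$transcript_id, i)
        out_tx[[i]] <- iso
      }
    }
    decision <- decision_record(tx$transcript_id, "set_3prime", "polyA_cdna",
                                params = list(cluster = params$polya_cluster,
                                              n_termini = length(termini)))
    ## coverage beyond the longest cDNA: extend the last isoform
    far <- if (plus) max(termini) else min(termini)
    covend <- coverage_terminus(gene, far, tracks, params)
    if (!is.null(covend) &&
        ((plus && covend > far) || (!plus && covend < far))) {
      k <- length(out_tx)
      out_tx[[k]] <- set_end(out_tx[[k]], covend, "polyA_cdna")
      out_tx[[k]]$comments <- unique(c(out_tx[[k]]$comments,
                                       "extended_3utr_coverage"))
    }
  } else {
    covend <- coverage_terminus(gene, anchor, tracks, params)
    if (!is.null(covend)) {
      out_tx[[1]] <- set_end(tx, covend, "coverage_estimate")
      decision <- decision_record(tx$transcript_id, "set_3prime",
                                  "coverage_estimate",
                                  params = list(gap = params$utr3_gap))
    } else if (!is.null(tx$cds)) {
      out_tx[[1]] <- set_end(tx, anchor, "stop_codon_fallback")
      decision <- decision_record(tx$transcript_id, "set_3prime",
                                  "stop_codon_fallback")
    } else {
      out_tx[[1]] <- tx
      decision <- decision_record(tx$transcript_id, "set_3prime", "unchanged")
    }
  }
  list(transcripts = out_tx, decision = decision)
}

## longest contiguous coverage-supported terminus downstream of `from`
## (NULL when no track covers the anchor)
coverage_terminus <- function(gene, from, tracks, params) {
  if (!length(tracks)) return(NULL)
  plus <- gene$strand == "+"
  span <- if (plus) c(max(0, from - 1), from + params$utr3_max_extension)
  else c(max(0, from - params$utr3_max_extension), from + 1)
  cov <- covered_intervals(tracks, gene$contig, span[1], span[2],
                           floor = params$gap_floor, strand = gene$strand)
  if (!nrow(cov)) return(NULL)
  ## walk contiguous blocks allowing gaps < utr3_gap
  if (plus) {
    hit <- which(cov$start <= from & cov$end >= from)
    if (!length(hit)) return(NULL)
    i <- hit[1]
    while (i < nrow(cov) && cov$start[i + 1] - cov$end[i] < params$utr3_gap)
      i <- i + 1
    cov$end[i]
  } else {
    hit <- which(cov$start <= from & cov$end >= from)
    if (!length(hit)) return(NULL)
    i <- hit[length(hit)]
    while (i > 1 && cov$start[i] - cov$end[i - 1] < params$utr3_gap)
      i <- i - 1
    cov$start[i]
  }
}
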