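#' Construct a coverage track
#'
#' A labelled expression signal: per-interval read depth (run-length encoded
#' as bedGraph-style intervals), with the track metadata needed for RPKM
#' (total mapped reads, read length) and for sex-bias classification.
#' Stranded tracks carry two signal lanes.
#'
#' @param label stage/tissue name.
#' @param signal data.frame with columns `contig`, `start`, `end`, `value`
#'   (0-based half-open, values >= 0).  For stranded tracks this is the plus
#'   lane.
#' @param minus_signal minus-strand lane (stranded tracks only).
#' @param sex one of `"male"`, `"female"`, `"mixed"`, `"na"`.
#' @param strandedness `"stranded"` or `"unstranded"`.
#' @param total_mapped_reads positive integer, the RPKM denominator.
#' @param read_length read length in bp used to convert summed per-base depth
#'   to read counts (default 75).
#' @param gonadal logical; `TRUE` for testis/ovary-type tracks.
#' @return a list with class `coverage_track`.
#' @export
coverage_track <- function(label, signal, minus_signal = NULL,
                           sex = "na", strandedness = "unstranded",
                           total_mapped_reads = 1e7, read_length = 75,
                           gonadal = FALSE) {
  stopifnot(sex %in% c("male", "female", "mixed", "na"),
            strandedness %in% c("stranded", "unstranded"),
            total_mapped_reads > 0, read_length > 0)
  check_sig <- function(sig, what) {
    if (nrow(sig) == 0) return(sig)
    if (any(sig$value < 0)) stop(what, ": negative coverage value")
    if (any(sig$start >= sig$end)) stop(what, ": start >= end")
    sig[order(sig$contig, sig$start), , drop = FALSE]
  }
  empty <- data.frame(contig = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0))
  signal <- check_sig(if (is.null(signal)) empty else signal, label)
  if (strandedness == "stranded") {
    minus_signal <- check_sig(if (is.null(minus_signal)) empty else
      minus_signal, paste0(label, " (minus lane)"))
  } else if (!is.null(minus_signal)) {
    stop("unstranded tracks carry a single lane")
  }
  structure(list(label = label, sex = sex, strandedness = strandedness,
                 total_mapped_reads = total_mapped_reads,
                 read_length = read_length, gonadal = gonadal,
                 signal = signal, minus_signal = minus_signal),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track '%s' (%s, %s%s), %g mapped reads\n", x$label,
              x$sex, x$strandedness, if (x$gonadal) ", gonadal" else "",
              x$total_mapped_reads))
  invisible(x)
}

#' Read a bedGraph file into a coverage track
#'
#' bedGraph coordinates are already 0-based half-open and pass through
#' unchanged.  Records with negative values or `start >= end` raise a parse
#' error naming the record.
#'
#' @param source path, connection, or character vector of bedGraph lines
#'   (plus lane for stranded tracks).
#' @param minus_source optional second bedGraph for the minus lane.
#' @inheritParams coverage_track
#' @return a [coverage_track()].
#' @export
read_coverage <- function(source, label, sex = "na",
                          strandedness = "unstranded",
                          total_mapped_reads = 1e7, read_length = 75,
                          gonadal = FALSE, minus_source = NULL) {
  parse_bedgraph <- function(src) {
    path <- as_input_path(src)
    lines <- readLines(path)
    lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
    if (!length(lines))
      return(data.frame(contig = character(0), start = numeric(0),
                        end = numeric(0), value = numeric(0)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 4)
    if (length(bad)) stop("bedGraph parse error at line ", bad[1])
    df <- data.frame(contig = vapply(parts, `[`, "", 1),
                     start = as.numeric(vapply(parts, `[`, "", 2)),
                     end = as.numeric(vapply(parts, `[`, "", 3)),
                     value = as.numeric(vapply(parts, `[`, "", 4)))
    bad <- which(is.na(df$start) | is.na(df$end) | is.na(df$value) |
                   df$value < 0 | df$start >= df$end)
    if (length(bad))
      stop("bedGraph parse error at line ", bad[1],
           ": need start < end and value >= 0")
    df
  }
  coverage_track(label, parse_bedgraph(source),
                 minus_signal = if (!is.null(minus_source))
                   parse_bedgraph(minus_source),
                 sex = sex, strandedness = strandedness,
                 total_mapped_reads = total_mapped_reads,
                 read_length = read_length, gonadal = gonadal)
}

#' Write one lane of a coverage track as bedGraph lines
#' @param track a [coverage_track()].
#' @param lane `"plus"` or `"minus"`.
#' @param path optional output path.
#' @return character vector of bedGraph lines.
#' @export
write_coverage <- function(track, lane = "plus", path = NULL) {
  sig <- if (lane == "minus") track$minus_signal else track$signal
  lines <- if (is.null(sig) || nrow(sig) == 0) character(0) else
    sprintf("%s\t%d\t%d\t%g", sig$contig, as.integer(sig$start),
            as.integer(sig$end), sig$value)
  if (!is.null(path)) { writeLines(lines, path); return(invisible(lines)) }
  lines
}

## Sum of per-base signal over [start, end).  strand NULL sums all lanes;
## "+"/"-" selects the lane of a stranded track.
track_interval_sum <- function(track, contig, start, end, strand = NULL) {
  lanes <- if (is.null(strand) || track$strandedness == "unstranded") {
    c(list(track$signal),
      if (!is.null(track$minus_signal)) list(track$minus_signal))
  } else if (strand == "+") list(track$signal) else list(track$minus_signal)
  total <- 0
  for (sig in lanes) {
    if (is.null(sig) || nrow(sig) == 0) next
    sel <- sig$contig == contig & sig$end > start & sig$start < end
    if (!any(sel)) next
    s <- sig[sel, , drop = FALSE]
    total <- total + sum(overlap_width(s$start, s$end, start, end) * s$value)
  }
  total
}

## intervals (within [lo, hi)) where the summed signal of `tracks` on `strand`
## is >= floor; used for contiguity and boundary-trimming decisions
covered_intervals <- function(tracks, contig, lo, hi, floor = 1,
                              strand = NULL) {
  pieces <- list()
  for (tr in tracks) {
    lanes <- if (is.null(strand) || tr$strandedness == "unstranded") {
      c(list(tr$signal), if (!is.null(tr$minus_signal)) list(tr$minus_signal))
    } else if (strand == "+") list(tr$signal) else list(tr$minus_signal)
    for (sig in lanes) {
      if (is.null(sig) || nrow(sig) == 0) next
      sel <- sig$contig == contig & sig$end > lo & sig$start < hi &
        sig$value >= floor
      if (any(sel))
        pieces[[length(pieces) + 1L]] <-
          data.frame(start = pmax(sig$start[sel], lo),
                     end = pmin(sig$end[sel], hi))
    }
  }
  if (!length(pieces)) return(data.frame(start = numeric(0), end = numeric(0)))
  interval_union(do.call(rbind, pieces))
}
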