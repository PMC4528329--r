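#' Find the longest ATG-initiated ORF in a spliced transcript sequence
#'
#' Scans the three forward frames of the transcript-sense sequence for
#' ATG-initiated open reading frames ending in a stop codon.  Only ATG
#' starts are considered (noncanonical starts are curated externally).
#' Ties are broken toward the 5'-most start.
#'
#' @param seq spliced transcript sequence (character scalar, transcript
#'   sense).
#' @return `NULL` when no complete ORF exists, otherwise a list with
#'   `start` (0-based offset of the A of ATG in the transcript), `end`
#'   (0-based half-open end, past the stop codon), and `length_aa` (number
#'   of encoded amino acids including the initiator Met, excluding the
#'   stop).
#' @export
find_longest_orf <- function(seq) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 6) return(NULL)
  best <- NULL
  for (frame in 0:2) {
    m <- (n - frame) %/% 3
    if (m < 2) next
    codons <- substring(seq, frame + 1 + 3 * (0:(m - 1)),
                        frame + 3 + 3 * (0:(m - 1)))
    atg <- which(codons == "ATG")
    stops <- which(codons %in% c("TAA", "TAG", "TGA"))
    if (!length(atg) || !length(stops)) next
    for (a in atg) {
      s <- stops[stops > a]
      if (!length(s)) next
      s <- s[1]
      aa <- s - a                       # codons from ATG up to (not incl.) stop
      start0 <- frame + 3 * (a - 1)
      cand <- list(start = start0, end = frame + 3 * s, length_aa = aa)
      if (is.null(best) || aa > best$length_aa ||
          (aa == best$length_aa && start0 < best$start))
        best <- cand
    }
  }
  best
}

#' Assess ORF conservation across an ortholog set
#'
#' Conservation in the close-relative sense used for new-gene calls: in
#' every supplied ortholog the initiator methionine must be conserved, no
#' in-frame internal stop may appear, and no indel of length not divisible
#' by 3 may fall within the ORF.
#'
#' @param ortholog_set list of pairwise alignments, each a list with
#'   elements `ref` and `seq`: equal-length aligned strings (gaps `-`),
#'   where `ref` is the reference ORF (ATG..stop).  See
#'   [simulate_ortholog_set()].
#' @param min_orthologs minimum number of orthologs required for an
#'   informative call (default 2); fewer returns `FALSE`.
#' @return logical: `TRUE` iff every ortholog conforms.
#' @export
assess_orf_conservation <- function(ortholog_set, min_orthologs = 2) {
  if (length(ortholog_set) < min_orthologs) return(FALSE)
  for (al in ortholog_set) {
    if (nchar(al$ref) != nchar(al$seq))
      stop("ortholog set must be aligned to the reference ORF")
    rc <- strsplit(al$ref, "")[[1]]
    sc <- strsplit(al$seq, "")[[1]]
    ## initiator Met: ortholog bases aligned to the first ref codon
    ref_pos <- cumsum(rc != "-")
    first_codon_cols <- which(rc != "-" & ref_pos <= 3)
    init <- paste0(sc[first_codon_cols], collapse = "")
    if (init != "ATG") return(FALSE)
    ## indels: gap runs in either row, length must be 0 mod 3
    gap_runs <- function(v) {
      r <- rle(v == "-")
      r$lengths[r$values]
    }
    if (any(c(gap_runs(rc), gap_runs(sc)) %% 3 != 0)) return(FALSE)
    ## internal stops: with frame preserved, translate the degapped ortholog
    orth <- paste0(sc[sc != "-"], collapse = "")
    aa <- translate_cds(orth, trim_stop = TRUE)
    if (grepl("*", aa, fixed = TRUE)) return(FALSE)
  }
  TRUE
}

#' Classify the coding status of a transcript
#'
#' An ORF longer than `orf_small_max` (50) aa is called coding outright; an
#' ORF in `(orf_small_min, orf_small_max]` aa is called coding only when its
#' conservation assessment passes (conservation is uninformative below
#' roughly 25-30 aa, hence the floor); anything else is a probable lncRNA
#' that may encode small polypeptide(s).
#'
#' @param orf_call result of [find_longest_orf()] (may be `NULL`).
#' @param conserved logical from [assess_orf_conservation()].
#' @param truncated_by_junction logical: do accepted junctions truncate the
#'   CDS (short-isoform flag)?
#' @param params [pipeline_config()] (`orf_small_min`, `orf_small_max`).
#' @return list: `classification` (`coding`, `coding_small_orf`,
#'   `non_coding_possible_small_peptide`), `length_aa`, `conserved`,
#'   `emitted_comment`.
#' @export
classify_transcript_coding_status <- function(orf_call, conserved = FALSE,
                                              truncated_by_junction = FALSE,
                                              params = pipeline_config()) {
  out <- list(length_aa = if (is.null(orf_call)) 0L else orf_call$length_aa,
              conserved = conserved, emitted_comment = NA_character_)
  if (is.null(orf_call)) {
    out$classification <- "non_coding_possible_small_peptide"
    out$emitted_comment <- "probable_lncRNA"
  } else if (orf_call$length_aa > params$orf_small_max) {
    out$classification <- "coding"
  } else if (orf_call$length_aa > params$orf_small_min && conserved) {
    out$classification <- "coding_small_orf"
  } else {
    out$classification <- "non_coding_possible_small_peptide"
    out$emitted_comment <- "probable_lncRNA"
  }
  if (truncated_by_junction && out$classification %in%
        c("coding", "coding_small_orf"))
    out$emitted_comment <- "may_not_produce_functional_polypeptide"
  out
}
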