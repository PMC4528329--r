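#' Construct a transcript
#'
#' @param transcript_id identifier.
#' @param exons data.frame with columns `start`, `end` (0-based half-open),
#'   sorted, non-overlapping, separated by introns of at least 1 base.
#' @param cds optional numeric length-2 vector `c(start, end)`: the genomic
#'   span from the first base of the start codon to the last base of the stop
#'   codon (spliced through the exons).
#' @param five_prime_evidence one of `"tss_90pct"`, `"short_capped_rampage"`,
#'   `"cdna_5prime"`, `"coverage_estimate"`, `"cds_start_fallback"`.
#' @param three_prime_evidence one of `"polyA_cdna"`, `"coverage_estimate"`,
#'   `"stop_codon_fallback"`.
#' @param comments character vector of comment codes (see
#'   [comment_vocabulary()]).
#' @return a list with class `transcript`.
#' @export
transcript <- function(transcript_id, exons, cds = NULL,
                       five_prime_evidence = "cds_start_fallback",
                       three_prime_evidence = "stop_codon_fallback",
                       comments = character()) {
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  tx <- structure(list(transcript_id = transcript_id, exons = exons,
                       cds = if (!is.null(cds)) as.numeric(cds),
                       five_prime_evidence = five_prime_evidence,
                       three_prime_evidence = three_prime_evidence,
                       comments = unique(comments)),
                  class = "transcript")
  validate_transcript(tx)
  tx
}

validate_transcript <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) == 0) stop("transcript ", tx$transcript_id, " has no exons")
  if (any(ex$start >= ex$end))
    stop("transcript ", tx$transcript_id, ": empty or inverted exon")
  if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)] + 1))
    stop("transcript ", tx$transcript_id,
         ": exons must be separated by introns of >= 1 base")
  if (!is.null(tx$cds)) {
    if (tx$cds[1] < ex$start[1] || tx$cds[2] > ex$end[nrow(ex)])
      stop("transcript ", tx$transcript_id, ": CDS outside exon span")
    len <- spliced_cds_length(tx)
    if (len %% 3 != 0)
      stop("transcript ", tx$transcript_id,
           ": spliced CDS length ", len, " is not a multiple of 3")
  }
  invisible(tx)
}

transcript_extent <- function(tx) c(tx$exons$start[1], tx$exons$end[nrow(tx$exons)])

spliced_length <- function(tx) sum(tx$exons$end - tx$exons$start)

## exonic bases of the CDS span (the spliced CDS length, including the stop)
spliced_cds_length <- function(tx) {
  if (is.null(tx$cds)) return(0)
  sum(overlap_width(tx$exons$start, tx$exons$end, tx$cds[1], tx$cds[2]))
}

## introns of a transcript as data.frame(start, end), 0-based half-open
transcript_introns <- function(tx) {
  ex <- tx$exons
  if (nrow(ex) < 2) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = ex$end[-nrow(ex)], end = ex$start[-1])
}

#' Construct a gene model
#'
#' A gene model is the set of transcripts (and their coding regions)
#' annotated for a gene.  The gene extent is the union of its transcript
#' extents; all transcripts share the gene's contig and strand.
#'
#' @param gene_id stable identifier.
#' @param contig contig name.
#' @param strand `"+"` or `"-"` (every annotated gene has a strand).
#' @param transcripts list of [transcript()] objects.
#' @param symbol display symbol (defaults to `gene_id`).
#' @param biotype one of `"protein_coding"`, `"lncRNA"`,
#'   `"antisense_lncRNA"`, `"pseudogene"`, `"polymorphic_pseudogene"`.
#' @param comments character vector of comment codes.
#' @param antisense_of for `biotype = "antisense_lncRNA"`, the id of the
#'   opposite-strand gene overlapped.
#' @return a list with class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, strand, transcripts,
                       symbol = gene_id, biotype = "protein_coding",
                       comments = character(), antisense_of = NULL) {
  if (!strand %in% c("+", "-"))
    stop("gene ", gene_id, ": gene models must be stranded")
  biotypes <- c("protein_coding", "lncRNA", "antisense_lncRNA",
                "pseudogene", "polymorphic_pseudogene")
  if (!biotype %in% biotypes)
    stop("gene ", gene_id, ": unknown biotype '", biotype, "'")
  if (biotype == "antisense_lncRNA" && is.null(antisense_of))
    stop("gene ", gene_id,
         ": antisense_lncRNA requires the overlapped opposite-strand gene id")
  if (!length(transcripts)) stop("gene ", gene_id, " has no transcripts")
  ext <- range(unlist(lapply(transcripts, transcript_extent)))
  structure(list(gene_id = gene_id, symbol = symbol, biotype = biotype,
                 contig = contig, start = ext[1], end = ext[2],
                 strand = strand, transcripts = transcripts,
                 comments = unique(comments), antisense_of = antisense_of),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s) %s %s:%d-%d(%s), %d transcript(s)\n",
              x$gene_id, x$symbol, x$biotype, x$contig, x$start, x$end,
              x$strand, length(x$transcripts)))
  invisible(x)
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("transcript %s: %d exon(s), %s\n", x$transcript_id,
              nrow(x$exons), if (is.null(x$cds)) "non-coding" else
                sprintf("CDS %d-%d", x$cds[1], x$cds[2])))
  invisible(x)
}

## union of exon intervals across all transcripts of a gene
gene_exon_union <- function(gene) {
  interval_union(do.call(rbind, lapply(gene$transcripts, `[[`, "exons")))
}

## distinct annotated introns across all transcripts
gene_introns <- function(gene) {
  ins <- do.call(rbind, lapply(gene$transcripts, transcript_introns))
  if (is.null(ins) || nrow(ins) == 0)
    return(data.frame(start = numeric(0), end = numeric(0)))
  unique(ins)
}

## transcript with the longest spliced CDS (reference isoform for frame tests)
reference_isoform <- function(gene) {
  lens <- vapply(gene$transcripts, spliced_cds_length, numeric(1))
  if (all(lens == 0)) return(gene$transcripts[[1]])
  gene$transcripts[[which.max(lens)]]
}

#' Spliced transcript sequence
#'
#' Concatenates the exon sequences in transcript orientation (reverse
#' complemented for minus-strand genes).
#'
#' @param tx a [transcript()].
#' @param gene the parent [gene_model()] (contig and strand).
#' @param genome named character vector of contig sequences.
#' @return character scalar.
#' @export
transcript_sequence <- function(tx, gene, genome) {
  pieces <- vapply(seq_len(nrow(tx$exons)), function(i)
    genome_subseq(genome, gene$contig, tx$exons$start[i], tx$exons$end[i]),
    character(1))
  s <- paste0(pieces, collapse = "")
  if (gene$strand == "-") s <- revcomp(s) else s
}

#' Spliced CDS sequence (start codon through stop codon)
#' @inheritParams transcript_sequence
#' @return character scalar (`""` for non-coding transcripts).
#' @export
cds_sequence <- function(tx, gene, genome) {
  if (is.null(tx$cds)) return("")
  pieces <- character(0)
  for (i in seq_len(nrow(tx$exons))) {
    s <- max(tx$exons$start[i], tx$cds[1]); e <- min(tx$exons$end[i], tx$cds[2])
    if (s < e) pieces <- c(pieces, genome_subseq(genome, gene$contig, s, e))
  }
  s <- paste0(pieces, collapse = "")
  if (gene$strand == "-") s <- revcomp(s) else s
}

## strand-aware 5' end base coordinate of a transcript (0-based base position)
transcript_5p <- function(tx, strand) {
  if (strand == "+") tx$exons$start[1] else tx$exons$end[nrow(tx$exons)] - 1
}

## strand-aware 3' end base coordinate of a transcript
transcript_3p <- function(tx, strand) {
  if (strand == "+") tx$exons$end[nrow(tx$exons)] - 1 else tx$exons$start[1]
}

validate_gene_model <- function(gene) {
  for (tx in gene$transcripts) validate_transcript(tx)
  ext <- range(unlist(lapply(gene$transcripts, transcript_extent)))
  if (gene$start > ext[1] || gene$end < ext[2])
    stop("gene ", gene$gene_id, ": extent does not cover its transcripts")
  invisible(gene)
}
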