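#' The controlled vocabulary of curation comments
#'
#' Curation decisions attach free-text comments to genes and transcripts from
#' a fixed, versioned vocabulary.  Codes are stable machine-readable
#' identifiers; texts are the curator-facing phrases.  Unknown comments read
#' from GFF3 are preserved verbatim under the code `unrecognized` and flagged.
#'
#' @return data.frame with columns `code`, `text`, `level` (gene/transcript).
#' @export
comment_vocabulary <- function() {
  data.frame(
    code = c(
      "low_frequency_junctions",
      "not_all_combinations",
      "unrepresented_5utr_splices",
      "may_not_produce_functional_polypeptide",
      "probable_lncRNA",
      "possible_non_coding",
      "lncRNA_from_3utr",
      "nonoverlapping_cds",
      "mutation_in_strain",
      "possible_mutation_in_strain",
      "polymorphic_pseudogene",
      "pseudogene_parental",
      "extended_3utr_coverage",
      "tss_cds_start_fallback"),
    text = c(
      "low-frequency RNA-Seq exon junction(s) not annotated",
      "annotated transcripts do not represent all possible combinations of alternative exons and/or alternative promoters",
      "annotated transcripts do not represent all supported alternative splices within the 5' UTR",
      "may or may not produce functional polypeptide",
      "probable lncRNA gene; may encode small polypeptide(s)",
      "possible non-coding RNA gene",
      "This lncRNA overlaps and may be derived from the long 3' UTR of the upstream gene",
      "Gene model includes transcripts encoding nonoverlapping portions of the full CDS.",
      "Mutation in sequenced strain",
      "Possible mutation in sequenced strain",
      "polymorphic pseudogene; mutant in strain",
      "Pseudogene similar to [parental gene]; proximate/transposed/retrotransposed",
      "3' UTR extension supported by RNA-Seq coverage data",
      "transcript model begins at the translation start site (no 5' UTR evidence)"),
    level = c("gene", "gene", "gene", "transcript", "gene", "gene", "gene",
              "gene", "gene", "gene", "gene", "gene", "transcript",
              "transcript"),
    stringsAsFactors = FALSE)
}

#' Look up the curator-facing text of a comment code
#' @param code comment code.
#' @return character scalar.
#' @export
comment_text <- function(code) {
  v <- comment_vocabulary()
  i <- match(code, v$code)
  if (is.na(i)) stop("unknown comment code: ", code)
  v$text[i]
}

## A decision record: one curation action with its reason and the thresholds
## in force.  `params` is collapsed to "name=value;..." for TSV round-trip.
decision_record <- function(subject_id, action, reason,
                            params = list(), emitted_comment = NA_character_) {
  stopifnot(nzchar(action), nzchar(reason))
  data.frame(subject_id = subject_id, action = action, reason = reason,
             params = paste(names(params), unlist(params), sep = "=",
                            collapse = ";"),
             emitted_comment = emitted_comment, stringsAsFactors = FALSE)
}
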