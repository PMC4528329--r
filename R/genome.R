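## Genome sequences are held as a named character vector (one element per
## contig, uppercase DNA).  Biostrings does the heavy lifting for translation
## and reverse complement.

#' Extract a genomic subsequence
#'
#' @param genome named character vector of contig sequences.
#' @param contig contig name.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` returns the top strand; `"-"` the reverse complement.
#' @return character scalar.
#' @export
genome_subseq <- function(genome, contig, start, end, strand = "+") {
  if (!contig %in% names(genome)) stop("unknown contig: ", contig)
  s <- substr(genome[[contig]], start + 1, end)
  if (strand == "-") s <- revcomp(s)
  s
}

#' Reverse complement of a DNA string
#' @param seq character scalar of DNA.
#' @return character scalar.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Translate a CDS to protein
#'
#' Translates in frame 1; a trailing partial codon is dropped.  The stop
#' codon, if present and terminal, is removed from the returned peptide.
#'
#' @param seq character scalar of DNA (coding strand).
#' @param trim_stop drop a trailing `*`.
#' @return character scalar of amino acids (`*` marks internal stops).
#' @export
translate_cds <- function(seq, trim_stop = TRUE) {
  n <- nchar(seq) - nchar(seq) %% 3
  if (n < 3) return("")
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(seq, 1, n)),
                          if.fuzzy.codon = "X")))
  if (trim_stop && nchar(aa) > 0 && substr(aa, nchar(aa), nchar(aa)) == "*")
    aa <- substr(aa, 1, nchar(aa) - 1)
  aa
}

#' Read a FASTA file into the internal genome representation
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write a genome to FASTA
#' @param genome named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

## splice-site dinucleotides of an intron [donor, acceptor) on `strand`;
## returns c(donor_dinucleotide, acceptor_dinucleotide) in transcript sense.
intron_dinucleotides <- function(genome, contig, donor, acceptor, strand) {
  left <- substr(genome[[contig]], donor + 1, donor + 2)
  right <- substr(genome[[contig]], acceptor - 1, acceptor)
  if (strand == "-") c(revcomp(right), revcomp(left)) else c(left, right)
}
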