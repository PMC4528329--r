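## Lesion detection and gene-integrity classification.  A strain's CDS is
## aligned to the reference CDS (global, affine gaps, via Biostrings) and
## every difference is typed; the two-lesion rule then classifies the gene.

align_cds_pair <- function(ref, strain) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ref), Biostrings::DNAString(strain),
    type = "global", substitutionMatrix = mat,
    gapOpening = 10, gapExtension = 0.5)
  list(ref = as.character(Biostrings::alignedPattern(pa)),
       strain = as.character(Biostrings::alignedSubject(pa)))
}

#' Detect coding lesions in a strain sequence
#'
#' Types every difference between a strain CDS and the reference CDS:
#' a substitution in the initiation codon is a `start_codon_loss`; an
#' in-frame stop gain is `nonsense`; an indel of length not divisible by 3
#' is a `frameshift_indel`; an in-frame missing segment is a `deletion`.
#' Splice-site dinucleotide changes and transposon insertions are detected
#' from the supplied overlays (the sites and insertion features themselves,
#' since transposon discovery from raw sequence is out of scope).
#' Transposon insertions inside the CDS are disabling; intronic/adjacent
#' ones are flagged possible (non-disabling).
#'
#' @param ref_cds reference (parental/wild-type) CDS sequence.
#' @param strain_cds the strain's CDS sequence.
#' @param splice_sites optional data.frame with columns `site`
#'   (an identifier), `ref_dinucleotide`, `strain_dinucleotide`,
#'   `position` (CDS-relative position used for reporting).
#' @param transposons optional data.frame with columns `position` and
#'   `location` (one of `"cds"`, `"intron"`, `"adjacent"`).
#' @return data.frame with columns `lesion_type`, `position`
#'   (1-based in the reference CDS), `disabling`.
#' @export
detect_lesions <- function(ref_cds, strain_cds, splice_sites = NULL,
                           transposons = NULL) {
  out <- list()
  emit <- function(type, pos, disabling = TRUE)
    out[[length(out) + 1L]] <<- data.frame(lesion_type = type, position = pos,
                                           disabling = disabling,
                                           stringsAsFactors = FALSE)
  if (!identical(toupper(ref_cds), toupper(strain_cds))) {
    al <- align_cds_pair(toupper(ref_cds), toupper(strain_cds))
    rc <- strsplit(al$ref, "")[[1]]
    sc <- strsplit(al$strain, "")[[1]]
    n <- length(rc)
    ref_pos <- cumsum(rc != "-")          # reference coordinate per column
    ## indel events: runs of gaps in either row
    runs <- rle(paste0(ifelse(rc == "-", "i", "."),
                       ifelse(sc == "-", "d", ".")))
    col <- 1
    frame_broken <- FALSE
    subst_cols <- integer(0)
    for (k in seq_along(runs$lengths)) {
      len <- runs$lengths[k]; v <- runs$values[k]
      cols <- col:(col + len - 1)
      if (v == "i.") {                    # insertion in strain
        pos <- if (ref_pos[cols[1]] >= 1) ref_pos[cols[1]] else 1
        if (len %% 3 != 0) { emit("frameshift_indel", pos); frame_broken <- TRUE }
        ## in-frame insertions are not treated as lesions
      } else if (v == ".d") {             # deletion in strain
        pos <- ref_pos[cols[1]]
        if (len %% 3 != 0) { emit("frameshift_indel", pos); frame_broken <- TRUE }
        else emit("deletion", pos)
      } else {
        subst_cols <- c(subst_cols, cols[rc[cols] != sc[cols] &
                                           rc[cols] != "-" & sc[cols] != "-"])
      }
      col <- col + len
    }
    ## substitutions: start-codon loss and nonsense (in reference frame)
    stops <- c("TAA", "TAG", "TGA")
    handled_codons <- integer(0)
    for (cc in subst_cols) {
      p <- ref_pos[cc]
      if (p <= 3) {
        strain_start <- paste0(sc[rc != "-"][1:3], collapse = "")
        if (strain_start != "ATG") { emit("start_codon_loss", p); next }
      }
      codon_idx <- (p - 1) %/% 3 + 1
      if (codon_idx %in% handled_codons) next
      ## strain bases aligned to this reference codon
      codon_cols <- which(rc != "-" & ref_pos >= 3 * codon_idx - 2 &
                            ref_pos <= 3 * codon_idx)
      strain_codon <- paste0(sc[codon_cols][sc[codon_cols] != "-"],
                             collapse = "")
      ref_codon <- paste0(rc[codon_cols], collapse = "")
      if (nchar(strain_codon) == 3 && strain_codon %in% stops &&
          !ref_codon %in% stops && codon_idx < ref_pos[n] / 3) {
        emit("nonsense", p)
        handled_codons <- c(handled_codons, codon_idx)
      }
    }
  }
  if (!is.null(splice_sites) && nrow(splice_sites)) {
    for (i in seq_len(nrow(splice_sites))) {
      if (splice_sites$ref_dinucleotide[i] !=
            splice_sites$strain_dinucleotide[i])
        emit("splice_site_point", splice_sites$position[i])
    }
  }
  if (!is.null(transposons) && nrow(transposons)) {
    for (i in seq_len(nrow(transposons))) {
      emit("transposon_insertion", transposons$position[i],
           disabling = transposons$location[i] == "cds")
    }
  }
  if (!length(out))
    return(data.frame(lesion_type = character(0), position = numeric(0),
                      disabling = logical(0)))
  res <- do.call(rbind, out)
  res[order(res$position), , drop = FALSE]
}

#' Classify gene integrity from per-strain lesions
#'
#' The two-lesion rule: pseudogene classification requires evidence of
#' neutral selection, taken as two disabling lesions.  Zero disabling
#' lesions in the annotated strain leaves the gene wild-type (or "possible
#' mutation in strain" when only non-disabling transposon features are
#' present); exactly one marks a coding gene as mutant in strain; two or
#' more make a pseudogene -- unless another supplied strain is clean, in
#' which case the gene is a polymorphic pseudogene (also marked mutant in
#' strain).
#'
#' @param lesions_by_strain named list: strain name -> lesion data.frame
#'   from [detect_lesions()].
#' @param annotated_strain name of the annotated (sequenced reference)
#'   strain; must be present in `lesions_by_strain`.
#' @param parental_gene optional parental gene symbol for the pseudogene
#'   comment.
#' @return list: `call`, `n_disabling`, `emitted_comment`.
#' @export
classify_gene_integrity <- function(lesions_by_strain, annotated_strain,
                                    parental_gene = NULL) {
  if (!annotated_strain %in% names(lesions_by_strain))
    stop("annotated strain '", annotated_strain,
         "' absent from the lesion map")
  les <- lesions_by_strain[[annotated_strain]]
  nd <- sum(les$disabling)
  others <- lesions_by_strain[setdiff(names(lesions_by_strain),
                                      annotated_strain)]
  clean_other <- length(others) > 0 &&
    any(vapply(others, function(l) sum(l$disabling) == 0, logical(1)))
  if (nd == 0) {
    if (nrow(les) > 0 && any(!les$disabling))
      return(list(call = "possible_mutation_in_strain", n_disabling = 0L,
                  emitted_comment = "possible_mutation_in_strain"))
    return(list(call = "wild_type", n_disabling = 0L,
                emitted_comment = NA_character_))
  }
  if (nd == 1)
    return(list(call = "mutation_in_strain", n_disabling = 1L,
                emitted_comment = "mutation_in_strain"))
  if (clean_other)
    return(list(call = "polymorphic_pseudogene", n_disabling = nd,
                emitted_comment = "polymorphic_pseudogene"))
  list(call = "pseudogene", n_disabling = nd,
       emitted_comment = "pseudogene_parental")
}

#' Restore the wild-type polypeptide of a mutant-in-strain gene
#'
#' The annotation presents the wild-type proteome: for a gene with a single
#' disabling lesion, the emitted polypeptide is the reference-corrected
#' translation (each detected lesion reverted to the reference allele),
#' while the transcript sequence remains the strain sequence.  Neutral
#' strain substitutions outside lesions are kept.
#'
#' @param ref_cds reference CDS sequence.
#' @param strain_cds strain CDS sequence.
#' @param call the integrity call from [classify_gene_integrity()].
#' @return list: `polypeptide` (corrected translation), `transcript_cds`
#'   (unchanged strain sequence), `note`.
#' @export
restore_wild_type_protein <- function(ref_cds, strain_cds, call) {
  if (call == "wild_type")
    return(list(polypeptide = translate_cds(strain_cds),
                transcript_cds = strain_cds, note = NA_character_))
  if (!nzchar(ref_cds))
    stop("gene flagged unresolvable: no reference CDS available")
  al <- align_cds_pair(toupper(ref_cds), toupper(strain_cds))
  rc <- strsplit(al$ref, "")[[1]]
  sc <- strsplit(al$strain, "")[[1]]
  corrected <- character(length(rc))
  lesions <- detect_lesions(ref_cds, strain_cds)
  stops <- c("TAA", "TAG", "TGA")
  ref_pos <- cumsum(rc != "-")
  lesion_cols <- logical(length(rc))
  for (i in seq_len(nrow(lesions))) {
    p <- lesions$position[i]
    if (lesions$lesion_type[i] %in% c("nonsense", "start_codon_loss")) {
      ci <- (p - 1) %/% 3 + 1
      lesion_cols[rc != "-" & ref_pos >= 3 * ci - 2 & ref_pos <= 3 * ci] <- TRUE
    } else if (lesions$lesion_type[i] %in% c("frameshift_indel", "deletion")) {
      lesion_cols[rc == "-" | sc == "-"] <- TRUE
    }
  }
  for (i in seq_along(rc)) {
    corrected[i] <- if (lesion_cols[i]) rc[i]
    else if (sc[i] != "-") sc[i] else ""
  }
  cds <- paste0(corrected[corrected != "-"], collapse = "")
  list(polypeptide = translate_cds(cds), transcript_cds = strain_cds,
       note = "polypeptide replaced with wild-type sequence; transcript reflects the strain genome")
}
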