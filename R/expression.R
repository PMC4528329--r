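#' Profile a gene's expression across labelled tracks
#'
#' RPKM over the gene's exonic extent (exon union) in every track, plus the
#' bin index under the configured monotone RPKM partition.
#'
#' @param gene a [gene_model()].
#' @param tracks list of [coverage_track()]s.
#' @param params [pipeline_config()] (`rpkm_bins`).
#' @return list with class `expression_profile`: `gene_id`, `rpkm` (named
#'   vector), `bin` (named integer vector), `max_male`, `max_female`,
#'   `max_male_gonad_free`, `max_female_gonad_free`.
#' @export
profile_gene_expression <- function(gene, tracks,
                                    params = pipeline_config()) {
  if (!length(tracks)) stop("expression profiling requires >= 1 track")
  exu <- gene_exon_union(gene)
  labels <- vapply(tracks, `[[`, character(1), "label")
  rpkm <- setNames(vapply(tracks, function(tr)
    intervals_rpkm(tr, gene$contig, exu, gene$strand), numeric(1)), labels)
  bins <- params$rpkm_bins
  bin <- setNames(findInterval(rpkm, bins), labels)
  sex <- vapply(tracks, `[[`, character(1), "sex")
  gonadal <- vapply(tracks, `[[`, logical(1), "gonadal")
  mx <- function(sel) if (any(sel)) max(rpkm[sel]) else 0
  structure(list(gene_id = gene$gene_id, rpkm = rpkm, bin = bin,
                 max_male = mx(sex == "male"),
                 max_female = mx(sex == "female"),
                 max_male_gonad_free = mx(sex == "male" & !gonadal),
                 max_female_gonad_free = mx(sex == "female" & !gonadal)),
            class = "expression_profile")
}

#' Classify sex-biased expression
#'
#' A gene is male-specific when its maximum female-track RPKM stays below
#' the specificity floor while some male track reaches the expressed level
#' (and symmetrically for female-specific).  Genes below the expressed
#' level everywhere are excluded as too weakly expressed to call.  The call
#' is additionally evaluated with gonadal tracks (testis/ovary) removed:
#' `gonad_independent = TRUE` when it still holds.
#'
#' @param profile an [profile_gene_expression()] result.
#' @param params [pipeline_config()] (`sex_floor_rpkm`,
#'   `sex_expressed_rpkm`, `sex_bias_ratio`).
#' @return list: `gene_id`, `call` (`male_specific`, `female_specific`,
#'   `male_biased`, `female_biased`, `unbiased`,
#'   `low_expression_excluded`), `gonad_independent`.
#' @export
classify_sex_bias <- function(profile, params = pipeline_config()) {
  if (profile$max_male == 0 && profile$max_female == 0 &&
      all(profile$rpkm == 0))
    return(list(gene_id = profile$gene_id, call = "low_expression_excluded",
                gonad_independent = FALSE))
  floor <- params$sex_floor_rpkm; expr <- params$sex_expressed_rpkm
  mm <- profile$max_male; mf <- profile$max_female
  if (max(mm, mf) < expr)
    return(list(gene_id = profile$gene_id, call = "low_expression_excluded",
                gonad_independent = FALSE))
  call <- if (mm >= expr && mf < floor) "male_specific"
  else if (mf >= expr && mm < floor) "female_specific"
  else if (mm >= expr && mm >= params$sex_bias_ratio * max(mf, floor))
    "male_biased"
  else if (mf >= expr && mf >= params$sex_bias_ratio * max(mm, floor))
    "female_biased"
  else "unbiased"
  gi <- FALSE
  if (call %in% c("male_specific", "male_biased"))
    gi <- profile$max_male_gonad_free >= expr
  if (call %in% c("female_specific", "female_biased"))
    gi <- profile$max_female_gonad_free >= expr
  list(gene_id = profile$gene_id, call = call, gonad_independent = gi)
}

#' Flag lncRNAs with very long genomic extents
#'
#' Non-coding genes transcribed from genomic regions longer than the
#' configured extent (default 72 kb) are uncommon and flagged.
#'
#' @param gene a [gene_model()] (lncRNA biotypes only).
#' @param params [pipeline_config()] (`long_extent`).
#' @return logical flag (strictly greater than the threshold).
#' @export
flag_long_extent_lncRNA <- function(gene, params = pipeline_config()) {
  if (!gene$biotype %in% c("lncRNA", "antisense_lncRNA")) return(FALSE)
  (gene$end - gene$start) > params$long_extent
}
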