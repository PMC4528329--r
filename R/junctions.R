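## Splice-junction triage.  Junctions arrive as a table (one row per observed
## junction); every junction receives exactly one decision.

#' Construct a junction table
#'
#' @param contig,donor,acceptor,strand,count,source vectors (recycled):
#'   `donor`/`acceptor` delimit the intron as a 0-based half-open interval
#'   `[donor, acceptor)` on the genome; `count` is the supporting read count;
#'   `source` is the dataset label.
#' @param genome optional genome; when supplied the intron boundary
#'   dinucleotides are recorded (strand-adjusted).
#' @return data.frame with class `junction_table`.
#' @export
junction_table <- function(contig, donor, acceptor, strand, count,
                           source = "rnaseq", genome = NULL) {
  df <- data.frame(contig = contig, donor = as.numeric(donor),
                   acceptor = as.numeric(acceptor), strand = strand,
                   count = as.numeric(count), source = source,
                   stringsAsFactors = FALSE)
  if (any(df$count < 0)) stop("junction read counts must be >= 0")
  if (any(df$donor >= df$acceptor)) stop("junction donor must precede acceptor")
  if (!is.null(genome)) {
    dn <- t(vapply(seq_len(nrow(df)), function(i)
      intron_dinucleotides(genome, df$contig[i], df$donor[i], df$acceptor[i],
                           df$strand[i]), character(2)))
    df$donor_dinucleotide <- dn[, 1]
    df$acceptor_dinucleotide <- dn[, 2]
  } else {
    df$donor_dinucleotide <- NA_character_
    df$acceptor_dinucleotide <- NA_character_
  }
  df$junction_id <- sprintf("%s:%d-%d(%s):%s", df$contig,
                            as.integer(df$donor), as.integer(df$acceptor),
                            df$strand, df$source)
  class(df) <- c("junction_table", "data.frame")
  df
}

#' Read a junction TSV (contig, donor, acceptor, strand, count, source)
#' @param source path, connection, or lines.
#' @param genome optional genome for boundary dinucleotides.
#' @return a [junction_table()].
#' @export
read_junctions <- function(source, genome = NULL) {
  df <- read.delim(as_input_path(source), header = TRUE,
                   stringsAsFactors = FALSE)
  junction_table(df$contig, df$donor, df$acceptor, df$strand, df$count,
                 df$source, genome = genome)
}

#' Assign junctions to genes
#'
#' A junction belongs to a gene when both intron ends fall within the gene's
#' extent on the same strand; a junction with its two ends in two different
#' same-strand genes is flagged for merge analysis; a junction with neither
#' end in a gene is intergenic.
#'
#' @param junctions a [junction_table()].
#' @param models list of [gene_model()] objects.
#' @return the junction table with columns `gene_id` (NA for intergenic),
#'   `spans_genes` (comma-separated pair for merge candidates), and
#'   `assignment` (`gene`, `merge_flag`, `intergenic`).
#' @export
assign_junction_to_gene <- function(junctions, models) {
  gtab <- data.frame(
    gene_id = vapply(models, `[[`, character(1), "gene_id"),
    contig = vapply(models, `[[`, character(1), "contig"),
    start = vapply(models, `[[`, numeric(1), "start"),
    end = vapply(models, `[[`, numeric(1), "end"),
    strand = vapply(models, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  n <- nrow(junctions)
  gene_id <- rep(NA_character_, n)
  spans <- rep(NA_character_, n)
  assignment <- rep("intergenic", n)
  for (i in seq_len(n)) {
    cand <- gtab[gtab$contig == junctions$contig[i] &
                   gtab$strand == junctions$strand[i], , drop = FALSE]
    if (!nrow(cand)) next
    ## bases flanking the intron (the junction's exonic anchors)
    d <- junctions$donor[i] - 1; a <- junctions$acceptor[i]
    in_d <- cand$gene_id[cand$start <= d & d < cand$end]
    in_a <- cand$gene_id[cand$start <= a & a < cand$end]
    both <- intersect(in_d, in_a)
    if (length(both)) {
      gene_id[i] <- both[1]
      assignment[i] <- "gene"
    } else if (length(in_d) && length(in_a)) {
      spans[i] <- paste(in_d[1], in_a[1], sep = ",")
      assignment[i] <- "merge_flag"
    }
  }
  junctions$gene_id <- gene_id
  junctions$spans_genes <- spans
  junctions$assignment <- assignment
  junctions
}

#' Relative junction frequency within a gene
#'
#' The read count of a junction divided by the highest junction read count
#' within the same gene (read-count-based frequency).
#'
#' @param count read count of the junction of interest.
#' @param gene_counts read counts of all junctions assigned to the gene
#'   (including annotated introns), must contain at least one positive count.
#' @return fraction in `[0, 1]`.
#' @export
relative_junction_frequency <- function(count, gene_counts) {
  m <- max(gene_counts)
  if (m <= 0) stop("undefined junction frequency: all counts are zero")
  count / m
}

## does junction row j exactly match an annotated intron of `gene`?
junction_is_annotated <- function(j, gene) {
  ins <- gene_introns(gene)
  any(ins$start == j$donor & ins$end == j$acceptor)
}

## Frame effect of applying intron [donor, acceptor) to the reference
## (longest-CDS) isoform: the new intron removes the exonic bases it covers.
## Frameshift when the removed CDS-exonic length is not a multiple of 3, or
## when the altered CDS gains a premature stop within `stop_window` codons of
## the junction (checked when a genome is supplied).
junction_frame_effect <- function(j, gene, genome = NULL, stop_window = 50) {
  ref <- reference_isoform(gene)
  if (is.null(ref$cds)) return(list(in_cds = FALSE, frameshift = FALSE))
  cds_exonic_removed <- sum(overlap_width(
    pmax(ref$exons$start, ref$cds[1]), pmin(ref$exons$end, ref$cds[2]),
    j$donor, j$acceptor))
  if (cds_exonic_removed == 0) return(list(in_cds = FALSE, frameshift = FALSE))
  fs <- (cds_exonic_removed %% 3) != 0
  if (!fs && !is.null(genome)) {
    ## frame-preserving removal can still create a junction-spanning stop
    new_exons <- interval_subtract(ref$exons, j$donor, j$acceptor)
    tx2 <- ref; tx2$exons <- new_exons
    keep <- new_exons$end > ref$cds[1] & new_exons$start < ref$cds[2]
    if (any(keep)) {
      pieces <- character(0)
      for (i in which(keep)) {
        s <- max(new_exons$start[i], ref$cds[1])
        e <- min(new_exons$end[i], ref$cds[2])
        pieces <- c(pieces, genome_subseq(genome, gene$contig, s, e))
      }
      cds_seq <- paste0(pieces, collapse = "")
      if (gene$strand == "-") cds_seq <- revcomp(cds_seq)
      aa <- translate_cds(cds_seq, trim_stop = FALSE)
      stops <- which(strsplit(aa, "")[[1]] == "*")
      if (length(stops) && min(stops) < nchar(aa)) fs <- TRUE
    }
  }
  list(in_cds = TRUE, frameshift = fs)
}

## context of a junction relative to the reference isoform CDS span
junction_context <- function(j, gene) {
  ref <- reference_isoform(gene)
  if (is.null(ref$cds)) return("utr_or_ncRNA_only")
  d_in <- j$donor > ref$cds[1] && j$donor < ref$cds[2]
  a_in <- j$acceptor > ref$cds[1] && j$acceptor < ref$cds[2]
  if (d_in && a_in) "cds_only" else if (!d_in && !a_in) "utr_or_ncRNA_only"
  else "mixed"
}

## is the junction a small (<= shift) donor/acceptor shift of an annotated
## splice, lying entirely within the 5' UTR?
is_minor_5utr_variant <- function(j, gene, shift = 6) {
  ref <- reference_isoform(gene)
  if (is.null(ref$cds)) return(FALSE)
  utr5 <- if (gene$strand == "+") c(gene$start, ref$cds[1]) else
    c(ref$cds[2], gene$end)
  if (!(j$donor >= utr5[1] && j$acceptor <= utr5[2])) return(FALSE)
  ins <- gene_introns(gene)
  if (!nrow(ins)) return(FALSE)
  any((ins$start == j$donor & abs(ins$end - j$acceptor) <= shift &
         ins$end != j$acceptor) |
        (ins$end == j$acceptor & abs(ins$start - j$donor) <= shift &
           ins$start != j$donor))
}

#' Classify a junction against its gene
#'
#' Decision order: (1) exact match to an annotated intron; (2) noncanonical
#' boundary dinucleotides without corroborating cDNA; (3) tandem-paralog
#' artifact (unless corroborated by a second source); (4) minor 5' UTR
#' donor/acceptor shift of an annotated splice; (5) frame-disrupting CDS
#' junction: incorporated (flagged) at relative frequency >= 10% or with
#' cDNA support, rejected below; (6) frame-preserving or UTR/ncRNA junction:
#' incorporated at relative frequency >= 1%, rejected below.
#'
#' @param j one junction (single-row data.frame or list with the
#'   junction-table fields).
#' @param gene the assigned [gene_model()].
#' @param gene_counts read counts of all junctions assigned to this gene.
#' @param genome optional genome (needed for the dinucleotide screen and the
#'   premature-stop check).
#' @param params [pipeline_config()] parameters.
#' @param cdna_support logical: is this junction corroborated by a cDNA exon
#'   boundary?
#' @param second_source logical: is the junction reported by a second
#'   independent dataset?
#' @param tandem logical: does the junction span a tandem-paralog pair (see
#'   [detect_tandem_artifact()])?  Only meaningful for gene-spanning
#'   junctions.
#' @param repeat_regions optional data.frame (`contig`, `start`, `end`) of
#'   declared repeat intervals; junctions inside are rejected.
#' @return single-row data.frame: `junction_id`, `gene_id`, `status`
#'   (`already_represented`, `incorporate`, `incorporate_flagged`,
#'   `rejected`), `reason`, `relative_frequency`, `context`.
#' @export
classify_junction <- function(j, gene, gene_counts, genome = NULL,
                              params = pipeline_config(),
                              cdna_support = FALSE, second_source = FALSE,
                              tandem = FALSE, repeat_regions = NULL) {
  j <- as.list(j)
  if (!is.null(gene) && j$strand != gene$strand)
    stop("junction ", j$junction_id, " strand conflicts with gene ",
         gene$gene_id)
  rf <- relative_junction_frequency(j$count, gene_counts)
  ctx <- if (is.null(gene)) "intergenic" else junction_context(j, gene)
  decide <- function(status, reason = "none") {
    data.frame(junction_id = j$junction_id,
               gene_id = if (is.null(gene)) NA_character_ else gene$gene_id,
               status = status, reason = reason, relative_frequency = rf,
               context = ctx, emitted_comment = NA_character_,
               stringsAsFactors = FALSE)
  }
  if (!is.null(gene) && junction_is_annotated(j, gene))
    return(decide("already_represented"))
  if (!is.null(repeat_regions) && nrow(repeat_regions)) {
    sel <- repeat_regions$contig == j$contig &
      intervals_overlap(repeat_regions$start, repeat_regions$end,
                        j$donor, j$acceptor)
    if (any(sel)) return(decide("rejected", "repeat_region"))
  }
  pair <- paste(j$donor_dinucleotide, j$acceptor_dinucleotide, sep = "-")
  if (!is.na(j$donor_dinucleotide) && !pair %in% params$canonical_splices &&
      !cdna_support)
    return(decide("rejected", "noncanonical_unverified"))
  if (tandem && !second_source && !cdna_support)
    return(decide("rejected", "tandem_artifact"))
  if (!is.null(gene) && is_minor_5utr_variant(j, gene, params$minor_utr_shift))
    return(decide("rejected", "minor_5utr_variant"))
  fe <- if (is.null(gene)) list(in_cds = FALSE, frameshift = FALSE) else
    junction_frame_effect(j, gene, genome, params$stop_window)
  if (fe$in_cds && fe$frameshift) {
    if (rf >= params$freq_frameshift || cdna_support) {
      out <- decide("incorporate_flagged")
      out$emitted_comment <- "may_not_produce_functional_polypeptide"
      return(out)
    }
    return(decide("rejected", "frameshift_below_threshold"))
  }
  if (rf >= params$freq_incorporate) decide("incorporate")
  else decide("rejected", "low_frequency")
}

#' Triage every junction of a gene
#'
#' @param gene a [gene_model()].
#' @param junctions junction-table rows assigned to this gene.
#' @param genome optional genome.
#' @param params [pipeline_config()].
#' @param cdna_junctions optional data.frame (`donor`, `acceptor`) of intron
#'   boundaries observed in cDNA alignments (corroboration).
#' @param repeat_regions optional declared repeat intervals.
#' @return data.frame of decisions, one row per junction.
#' @export
triage_gene_junctions <- function(gene, junctions, genome = NULL,
                                  params = pipeline_config(),
                                  cdna_junctions = NULL,
                                  repeat_regions = NULL) {
  if (!nrow(junctions)) return(NULL)
  ann <- gene_introns(gene)
  ann_counts <- numeric(0)
  if (nrow(ann)) {
    for (i in seq_len(nrow(ann))) {
      m <- junctions$donor == ann$start[i] & junctions$acceptor == ann$end[i]
      ann_counts <- c(ann_counts, if (any(m)) max(junctions$count[m]) else 0)
    }
  }
  gene_counts <- c(junctions$count, ann_counts)
  out <- list()
  for (i in seq_len(nrow(junctions))) {
    j <- junctions[i, , drop = FALSE]
    cdna_sup <- !is.null(cdna_junctions) && nrow(cdna_junctions) > 0 &&
      any(cdna_junctions$donor == j$donor &
            cdna_junctions$acceptor == j$acceptor)
    ## a second dataset reporting the same intron corroborates
    dup <- junctions$donor == j$donor & junctions$acceptor == j$acceptor &
      junctions$source != j$source
    out[[i]] <- classify_junction(j, gene, gene_counts, genome, params,
                                  cdna_support = cdna_sup,
                                  second_source = any(dup),
                                  repeat_regions = repeat_regions)
  }
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (!"emitted_comment" %in% names(res)) res$emitted_comment <- NA_character_
  res
}

#' Detect tandem-paralog artifact junctions
#'
#' Junctions spanning related tandem genes are among the most common
#' artifactual junction calls.  A spanning junction is flagged when the two
#' genes are a declared paralog pair, or when their CDSs share at least
#' `tandem_identity` identity over `tandem_min_len` aligned bases under the
#' package's k-mer seed and ungapped extension screen.
#'
#' @param j a gene-spanning junction row.
#' @param gene_a,gene_b the two spanned [gene_model()]s.
#' @param genome genome sequences.
#' @param paralog_pairs optional data.frame (`gene_a`, `gene_b`) of declared
#'   paralog pairs (order-insensitive).
#' @param params [pipeline_config()] (`tandem_identity`, `tandem_min_len`).
#' @return logical flag.
#' @export
detect_tandem_artifact <- function(j, gene_a, gene_b, genome = NULL,
                                   paralog_pairs = NULL,
                                   params = pipeline_config()) {
  a <- gene_a$gene_id; b <- gene_b$gene_id
  if (!is.null(paralog_pairs) && nrow(paralog_pairs)) {
    if (any((paralog_pairs$gene_a == a & paralog_pairs$gene_b == b) |
              (paralog_pairs$gene_a == b & paralog_pairs$gene_b == a)))
      return(TRUE)
  }
  if (is.null(genome)) return(FALSE)
  sa <- cds_sequence(reference_isoform(gene_a), gene_a, genome)
  sb <- cds_sequence(reference_isoform(gene_b), gene_b, genome)
  if (!nzchar(sa) || !nzchar(sb)) return(FALSE)
  kmer_identity_screen(sa, sb, min_len = params$tandem_min_len,
                       min_identity = params$tandem_identity)
}

#' K-mer seed / ungapped extension similarity screen
#'
#' Finds shared k-mers between two sequences, and for every seeded diagonal
#' scans windows of `min_len` aligned bases; returns `TRUE` when any window
#' reaches `min_identity` matches.
#'
#' @param seq_a,seq_b DNA strings.
#' @param k seed length.
#' @param min_len required aligned length (window size).
#' @param min_identity required identity fraction over the window.
#' @return logical flag.
#' @export
kmer_identity_screen <- function(seq_a, seq_b, k = 12, min_len = 200,
                                 min_identity = 0.8) {
  na <- nchar(seq_a); nb <- nchar(seq_b)
  if (na < k || nb < k) return(FALSE)
  ca <- strsplit(seq_a, "")[[1]]; cb <- strsplit(seq_b, "")[[1]]
  kmers_a <- substring(seq_a, 1:(na - k + 1), k:na)
  kmers_b <- substring(seq_b, 1:(nb - k + 1), k:nb)
  hits <- match(kmers_a, kmers_b)
  seeded <- which(!is.na(hits))
  if (!length(seeded)) return(FALSE)
  diagonals <- unique(seeded - hits[seeded])   # offset of a relative to b
  for (o in diagonals) {
    lo_a <- max(1, 1 + o); hi_a <- min(na, nb + o)
    len <- hi_a - lo_a + 1
    if (len < min(min_len, min(na, nb))) next
    w <- min(min_len, len)
    match_vec <- ca[lo_a:hi_a] == cb[(lo_a - o):(hi_a - o)]
    cs <- cumsum(c(0, match_vec))
    wins <- cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
    if (max(wins) >= min_identity * w) return(TRUE)
  }
  FALSE
}

#' Propose gene merges from spanning junctions
#'
#' A merge candidate is emitted for a gene pair joined by a same-strand
#' junction that is not a tandem artifact (a second independent source or
#' cDNA corroboration lifts the tandem veto) and whose relative frequency,
#' evaluated against the higher-expressed gene's maximum junction count,
#' meets the incorporation rule.
#'
#' @param junctions junction table after [assign_junction_to_gene()].
#' @param models named list of [gene_model()]s.
#' @param counts_by_gene named list: gene_id -> junction read counts.
#' @param genome,paralog_pairs,params see [detect_tandem_artifact()].
#' @return data.frame of merge candidates (possibly empty).
#' @export
propose_merge <- function(junctions, models, counts_by_gene, genome = NULL,
                          paralog_pairs = NULL, params = pipeline_config()) {
  span <- junctions[junctions$assignment == "merge_flag", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(span))) {
    j <- span[i, , drop = FALSE]
    pair <- strsplit(j$spans_genes, ",", fixed = TRUE)[[1]]
    ga <- models[[pair[1]]]; gb <- models[[pair[2]]]
    tandem <- detect_tandem_artifact(j, ga, gb, genome, paralog_pairs, params)
    dup <- junctions$donor == j$donor & junctions$acceptor == j$acceptor &
      junctions$source != j$source
    if (tandem && !any(dup)) next
    maxes <- c(max(c(0, counts_by_gene[[pair[1]]])),
               max(c(0, counts_by_gene[[pair[2]]])))
    denom <- max(maxes)
    if (denom <= 0) next
    rf <- j$count / denom
    if (rf >= params$freq_incorporate)
      out[[length(out) + 1L]] <- data.frame(
        gene_a = pair[1], gene_b = pair[2], junction_id = j$junction_id,
        relative_frequency = rf, tandem_rescued = tandem,
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      junction_id = character(0),
                      relative_frequency = numeric(0),
                      tandem_rescued = logical(0)))
  do.call(rbind, out)
}

#' Propose gene splits from expression discontinuities
#'
#' A split candidate at an internal intron boundary is emitted when (a) no
#' junction reads span the boundary and (b) the across-track expression
#' profiles (per-side RPKM vectors) of the two sides are discordant (Pearson
#' correlation below `split_cor`) with both sides expressed in at least one
#' track.
#'
#' @param gene a [gene_model()].
#' @param junctions junction rows assigned to the gene.
#' @param tracks list of at least two [coverage_track()]s.
#' @param params [pipeline_config()] (`split_cor`, `split_expressed_rpkm`).
#' @return data.frame of split candidates (possibly empty).
#' @export
propose_split <- function(gene, junctions, tracks,
                          params = pipeline_config()) {
  if (length(tracks) < 2)
    stop("split analysis requires expression profiles from >= 2 tracks")
  empty <- data.frame(gene_id = character(0), boundary = numeric(0),
                      correlation = numeric(0))
  ins <- gene_introns(gene)
  if (!nrow(ins)) return(empty)
  exu <- gene_exon_union(gene)
  out <- list()
  for (b in sort(unique(ins$end))) {   # candidate boundaries: intron 3' ends
    if (b <= gene$start || b >= gene$end) next
    spanning <- junctions$donor < b & junctions$acceptor >= b
    if (any(spanning) && sum(junctions$count[spanning]) > 0) next
    left <- exu[exu$start < b, , drop = FALSE]
    right <- exu[exu$end > b, , drop = FALSE]
    if (!nrow(left) || !nrow(right)) next
    left$end <- pmin(left$end, b); right$start <- pmax(right$start, b)
    side_rpkm <- function(side) vapply(tracks, function(tr) {
      len <- sum(side$end - side$start)
      reads <- sum(vapply(seq_len(nrow(side)), function(i)
        track_interval_sum(tr, gene$contig, side$start[i], side$end[i],
                           gene$strand), numeric(1))) / tr$read_length
      reads * 1e9 / (len * tr$total_mapped_reads)
    }, numeric(1))
    lr <- side_rpkm(left); rr <- side_rpkm(right)
    if (max(lr) < params$split_expressed_rpkm ||
        max(rr) < params$split_expressed_rpkm) next
    r <- suppressWarnings(cor(lr, rr))
    if (is.na(r)) r <- 1       # constant profile: no evidence of discordance
    if (r < params$split_cor)
      out[[length(out) + 1L]] <- data.frame(gene_id = gene$gene_id,
                                            boundary = b, correlation = r)
  }
  if (!length(out)) return(empty)
  do.call(rbind, out)
}
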