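## Synthetic genomes and evidence tracks with ground truth.  The generator
## plants every feature the downstream classifiers look for -- junctions
## straddling the 1%/10% thresholds, clustered TSS start signal, intergenic
## transcription above and below the RPKM floor, coding lesions, sex-biased
## coverage -- and records the intended outcome of each in a truth table.

#' Simulation configuration
#'
#' @param seed integer seed; a fixed seed gives byte-identical outputs.
#' @param genome_length minimum contig length in bp (padded to this).
#' @param n_genes number of protein-coding genes.
#' @param n_splice_test_genes genes carrying planted novel junctions
#'   straddling the incorporation thresholds.
#' @param n_lnc planted intergenic transcripts that must be recovered
#'   (RPKM >= `lnc_rpkm` in >= 2 tracks).
#' @param n_decoys planted sub-threshold or single-track decoys.
#' @param lnc_rpkm RPKM of planted recoverable intergenic transcripts.
#' @param decoy_rpkm RPKM of multi-track decoys (below the scan floor).
#' @param expressed_rpkm RPKM of an expressed gene in an active track.
#' @param tss_dispersion spread (sd, bp) of the clustered start signal.
#' @param junction_max_count read count of the strongest junction per gene.
#' @param track_plan data.frame (`label`, `sex`, `strandedness`, `gonadal`,
#'   `total_mapped_reads`); `NULL` for the default six-track plan
#'   (two mixed unstranded developmental tracks, stranded male/female head,
#'   stranded testis and ovary).
#' @param read_length read length metadata for all tracks.
#' @param coverage_noise `"none"` (deterministic depth) or `"poisson"`
#'   (interval depths drawn Poisson around the planned mean).  Planted
#'   junction counts are always exact: they are the thresholds under test.
#' @param ortholog_divergence substitutions per site for ortholog sets.
#' @return a list with class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, genome_length = 150000,
                              n_genes = 10, n_splice_test_genes = 4,
                              n_lnc = 4, n_decoys = 4, lnc_rpkm = 5,
                              decoy_rpkm = 1.5, expressed_rpkm = 20,
                              tss_dispersion = 3, junction_max_count = 1000,
                              track_plan = NULL, read_length = 75,
                              coverage_noise = "poisson",
                              ortholog_divergence = 0.1) {
  if (n_genes < 0 || genome_length <= 0) stop("counts must be positive")
  if (is.null(track_plan))
    track_plan <- data.frame(
      label = c("embryo", "larva", "head_male", "head_female", "testis",
                "ovary"),
      sex = c("mixed", "mixed", "male", "female", "male", "female"),
      strandedness = c("unstranded", "unstranded", "stranded", "stranded",
                       "stranded", "stranded"),
      gonadal = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
      total_mapped_reads = rep(1e7, 6),
      stringsAsFactors = FALSE)
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 n_genes = n_genes,
                 n_splice_test_genes = min(n_splice_test_genes, n_genes),
                 n_lnc = n_lnc, n_decoys = n_decoys, lnc_rpkm = lnc_rpkm,
                 decoy_rpkm = decoy_rpkm, expressed_rpkm = expressed_rpkm,
                 tss_dispersion = tss_dispersion,
                 junction_max_count = junction_max_count,
                 track_plan = track_plan, read_length = read_length,
                 coverage_noise = coverage_noise,
                 ortholog_divergence = ortholog_divergence),
            class = "simulation_config")
}

random_dna <- function(n) paste0(sample(c("A", "C", "G", "T"), n,
                                        replace = TRUE), collapse = "")

STOP_CODONS <- c("TAA", "TAG", "TGA")

## random codons free of stops
random_codons <- function(n) {
  all3 <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0)),
                          c("A", "C", "G", "T"), paste0))
  ok <- setdiff(all3, STOP_CODONS)
  paste0(sample(ok, n, replace = TRUE), collapse = "")
}

## repair in-frame internal stops in a CDS, avoiding locked positions
repair_stops <- function(cds, locked = integer(0)) {
  repeat {
    n <- nchar(cds)
    codons <- substring(cds, seq(1, n - 2, 3), seq(3, n, 3))
    internal <- which(codons %in% STOP_CODONS)
    internal <- internal[internal < length(codons)]
    if (!length(internal)) return(cds)
    i <- internal[1]
    for (off in c(2, 1, 3)) {
      p <- 3 * (i - 1) + off
      if (!p %in% locked) { substr(cds, p, p) <- "C"; break }
    }
  }
}

#' Generate a synthetic annotated genome
#'
#' Lays out multi-exon protein-coding genes (canonical GT-AG introns, valid
#' ATG..stop CDSs) on both strands of one contig, reserving intergenic space
#' for planted transcription, and returns the genome, the gene models, and
#' a truth table covering every downstream stage.  Designated splice-test
#' genes carry codon-aligned "novel segments" -- exonic in the annotated
#' model, but bounded by GT..AG so that an unannotated junction can excise
#' them; segment lengths are chosen so that excision is frame-preserving or
#' frame-shifting as planned.
#'
#' @param config a [simulation_config()].
#' @return list: `genome` (named character), `models` (named list of
#'   [gene_model()]), `truth` (list of data.frames: `genes`, `junctions`,
#'   `tss`, `lnc`, `sex`), `contig_lengths`.
#' @export
generate_annotated_genome <- function(config) {
  set.seed(config$seed)
  contig <- "chrS"
  cursor <- 400           # leading margin
  seq_parts <- list()
  pad_to <- function(pos) {
    if (pos > cursor) {
      seq_parts[[length(seq_parts) + 1L]] <<- random_dna(pos - cursor)
      cursor <<- pos
    }
  }
  put <- function(s) {
    seq_parts[[length(seq_parts) + 1L]] <<- s
    cursor <<- cursor + nchar(s)
  }
  seq_parts[[1]] <- random_dna(cursor)

  models <- list()
  truth_genes <- list(); truth_junctions <- list(); truth_tss <- list()
  truth_lnc <- list(); truth_sex <- list()
  sex_classes <- rep(c("unbiased", "male_specific", "female_specific",
                       "male_specific_gonad_only", "unbiased"),
                     length.out = config$n_genes)

  for (gi in seq_len(config$n_genes)) {
    gene_id <- sprintf("SG%04d", gi)
    strand <- if (gi %% 2 == 0) "-" else "+"
    splice_test <- gi <= config$n_splice_test_genes
    utr5_intron <- gi %% 3 == 0

    n_codons <- sample(170:230, 1)
    cds <- paste0("ATG", random_codons(n_codons - 2), sample(STOP_CODONS, 1))
    ## novel excisable segments (codon-aligned), lengths 9 (in-frame) and
    ## 10 (frameshift); planned relative frequencies straddle the rules
    novel_plan <- NULL
    locked <- integer(0)
    if (splice_test) {
      ## segment lengths: 9, 9 excise in-frame; 10 and 11 shift the frame
      ## when excised, and together add 39 bases so the reference CDS stays
      ## a multiple of 3
      novel_plan <- data.frame(
        codon = c(50, 70, 95, 120),
        len = c(9, 9, 10, 11),
        count = c(ceiling(0.01 * config$junction_max_count),          # == 1%
                  ceiling(0.01 * config$junction_max_count) - 5,      # < 1%
                  ceiling(0.10 * config$junction_max_count),          # == 10%
                  ceiling(0.10 * config$junction_max_count) - 10),    # < 10%
        status = c("incorporate", "rejected", "incorporate_flagged",
                   "rejected"),
        reason = c("none", "low_frequency", "none",
                   "frameshift_below_threshold"),
        stringsAsFactors = FALSE)
      ## insert from 3' to 5' so earlier positions stay valid
      for (k in rev(seq_len(nrow(novel_plan)))) {
        at <- 3 * novel_plan$codon[k]
        seg <- paste0("GT", random_dna(novel_plan$len[k] - 4), "AG")
        cds <- paste0(substr(cds, 1, at), seg,
                      substr(cds, at + 1, nchar(cds)))
      }
      ## final offset of each segment start within the CDS
      offs <- cumsum(c(0, novel_plan$len))[seq_len(nrow(novel_plan))]
      novel_plan$cds_at <- 3 * novel_plan$codon + offs
      locked <- unlist(lapply(seq_len(nrow(novel_plan)), function(k)
        c(novel_plan$cds_at[k] + 1:2,
          novel_plan$cds_at[k] + novel_plan$len[k] - 1:0)))
      cds <- repair_stops(cds, locked)
    } else {
      cds <- repair_stops(cds)
    }

    utr5 <- random_dna(150)
    utr3 <- random_dna(200)
    sense <- paste0(utr5, cds, utr3)
    Lsense <- nchar(sense)

    ## annotated introns in sense-local coordinates (position = insertion
    ## point in the spliced sequence); CDS introns codon-aligned
    intron_len <- 80
    intron_at <- c(if (utr5_intron) 60,
                   150 + 3 * 40, 150 + 3 * 140)
    intron_seq <- function() paste0("GT", random_dna(intron_len - 4), "AG")
    ## build unspliced sequence, track exon boundaries
    pieces <- list(); exon_bounds <- list()
    prev <- 0; gofs <- 0
    for (at in intron_at) {
      pieces[[length(pieces) + 1L]] <- substr(sense, prev + 1, at)
      exon_bounds[[length(exon_bounds) + 1L]] <- c(prev + gofs, at + gofs)
      pieces[[length(pieces) + 1L]] <- intron_seq()
      gofs <- gofs + intron_len
      prev <- at
    }
    pieces[[length(pieces) + 1L]] <- substr(sense, prev + 1, Lsense)
    exon_bounds[[length(exon_bounds) + 1L]] <- c(prev + gofs, Lsense + gofs)
    unspliced <- paste0(pieces, collapse = "")
    Lg <- nchar(unspliced)
    ## local (unspliced, sense-strand) -> genomic mapping
    gstart <- cursor + 300
    pad_to(gstart)
    if (strand == "+") {
      loc2gen <- function(p) gstart + p          # p: 0-based local offset
      put(unspliced)
    } else {
      loc2gen <- function(p) gstart + Lg - p
      put(revcomp(unspliced))
    }
    ## spliced-position -> unspliced local offset
    sp2loc <- function(sp) {
      add <- 0
      for (at in intron_at) if (sp > at) add <- add + intron_len
      sp + add
    }
    exons <- do.call(rbind, lapply(exon_bounds, function(b) {
      g <- sort(c(loc2gen(b[1]), loc2gen(b[2])))
      data.frame(start = g[1], end = g[2])
    }))
    cds_lo <- sp2loc(150)                      # CDS begins after the 5' UTR
    cds_hi_sp <- Lsense - 200                  # spliced CDS end
    cds_hi <- sp2loc(cds_hi_sp)
    cdsg <- sort(c(loc2gen(cds_lo), loc2gen(cds_hi)))
    tx <- transcript(sprintf("%s-RA", gene_id), exons, cds = cdsg)
    gene <- gene_model(gene_id, contig, strand, list(tx))
    models[[gene_id]] <- gene

    truth_genes[[gi]] <- data.frame(
      gene_id = gene_id, contig = contig, start = gene$start,
      end = gene$end, strand = strand, n_codons = n_codons,
      splice_test = splice_test, stringsAsFactors = FALSE)

    ## planted novel junctions (genomic coordinates of the excisable segment)
    if (!is.null(novel_plan)) {
      for (k in seq_len(nrow(novel_plan))) {
        sp_a <- 150 + novel_plan$cds_at[k]          # spliced start of segment
        sp_b <- sp_a + novel_plan$len[k]
        g <- sort(c(loc2gen(sp2loc(sp_a)), loc2gen(sp2loc(sp_b))))
        truth_junctions[[length(truth_junctions) + 1L]] <- data.frame(
          gene_id = gene_id, contig = contig, donor = g[1], acceptor = g[2],
          strand = strand, count = novel_plan$count[k],
          status = novel_plan$status[k], reason = novel_plan$reason[k],
          annotated = FALSE, stringsAsFactors = FALSE)
      }
    }
    ## annotated introns as junction truth (already represented)
    ins <- transcript_introns(tx)
    for (k in seq_len(nrow(ins)))
      truth_junctions[[length(truth_junctions) + 1L]] <- data.frame(
        gene_id = gene_id, contig = contig, donor = ins$start[k],
        acceptor = ins$end[k], strand = strand,
        count = config$junction_max_count, status = "already_represented",
        reason = "none", annotated = TRUE, stringsAsFactors = FALSE)

    ## TSS region overlapping the annotated start
    t5 <- transcript_5p(tx, strand)
    half <- 10
    lo <- t5 - half; hi <- t5 + half
    x <- (lo:(hi - 1)) + 0L
    dens <- exp(-((x - t5)^2) / (2 * config$tss_dispersion^2))
    sig <- round(200 * dens / sum(dens))
    sig[half + 1] <- sig[half + 1] + 5   # guarantee signal at the mode
    point <- local({                     # generator-side cumulative sum
      pos <- x[sig > 0]; s <- sig[sig > 0]
      if (strand == "+") { o <- order(pos, decreasing = TRUE) } else
        o <- order(pos)
      cum <- cumsum(s[o]) / sum(s)
      pos[o][which(cum >= 0.9)[1]]
    })
    truth_tss[[gi]] <- data.frame(
      gene_id = gene_id, contig = contig, start = lo, end = hi,
      strand = strand, point = point, validated = TRUE,
      stringsAsFactors = FALSE)
    attr(truth_tss[[gi]], "signal") <- sig
    truth_sex[[gi]] <- data.frame(
      gene_id = gene_id, class = sex_classes[gi], stringsAsFactors = FALSE)
    cursor_gap <- 300
    pad_to(cursor + cursor_gap)
  }

  ## planted intergenic transcription: recoverable regions and decoys,
  ## placed in fresh intergenic space with generous margins
  n_regions <- config$n_lnc + config$n_decoys
  kinds <- c(rep("lnc", config$n_lnc), rep("decoy", config$n_decoys))
  for (ri in seq_len(n_regions)) {
    pad_to(cursor + 800)
    start <- cursor
    width <- 600
    pad_to(cursor + width)
    strand <- if (ri %% 2 == 0) "-" else "+"
    decoy_mode <- if (kinds[ri] == "decoy") {
      if (ri %% 2 == 0) "low_rpkm" else "single_track"
    } else NA_character_
    truth_lnc[[ri]] <- data.frame(
      region_id = sprintf("LNC%03d", ri), contig = contig, start = start,
      end = start + width, strand = strand, kind = kinds[ri],
      decoy_mode = decoy_mode,
      rpkm = if (kinds[ri] == "lnc") config$lnc_rpkm else
        if (decoy_mode == "low_rpkm") config$decoy_rpkm else config$lnc_rpkm,
      stringsAsFactors = FALSE)
    pad_to(cursor + 800)
  }
  if (cursor + 400 > config$genome_length)
    stop("genome too small for the requested gene and region counts (need ",
         cursor + 400, " bp)")
  pad_to(config$genome_length)
  genome <- setNames(paste0(unlist(seq_parts), collapse = ""), contig)
  truth <- list(
    genes = do.call(rbind, truth_genes),
    junctions = do.call(rbind, truth_junctions),
    tss = do.call(rbind, lapply(truth_tss, function(d) d)),
    tss_signal = lapply(truth_tss, attr, "signal"),
    lnc = if (n_regions) do.call(rbind, truth_lnc) else NULL,
    sex = do.call(rbind, truth_sex))
  list(genome = genome, models = models, truth = truth,
       contig_lengths = setNames(nchar(genome), contig))
}

## depth value per base giving `rpkm` under the track metadata
rpkm_to_depth <- function(rpkm, read_length, total_mapped_reads) {
  rpkm * read_length * total_mapped_reads / 1e9
}

#' Simulate expression evidence for a synthetic genome
#'
#' Emits coverage tracks (per the track plan, with the planted sex-bias
#' structure), a junction table whose planted counts straddle the 1%/10%
#' incorporation thresholds, validated TSS regions with clustered start
#' signal, and polyadenylated cDNA alignments.
#'
#' @param sim result of [generate_annotated_genome()].
#' @param config the same [simulation_config()].
#' @return list: `tracks`, `junctions` (a [junction_table()]),
#'   `tss_regions`, `cdnas`.
#' @export
simulate_expression_evidence <- function(sim, config) {
  set.seed(config$seed + 1L)
  models <- sim$models
  truth <- sim$truth
  plan <- config$track_plan
  weight_for <- function(class, track_row) {
    lab <- track_row$label; sex <- track_row$sex
    switch(class,
           unbiased = 1,
           male_specific = if (sex == "male") 1 else 0,
           female_specific = if (sex == "female") 1 else 0,
           male_specific_gonad_only =
             if (sex == "male" && track_row$gonadal) 1 else 0,
           low = 0.02,
           0)
  }
  tracks <- list()
  for (tri in seq_len(nrow(plan))) {
    row <- plan[tri, ]
    plus <- list(); minus <- list()
    addsig <- function(tbl, value, strand) {
      if (value <= 0) return()
      d <- data.frame(contig = sim$truth$genes$contig[1] %||% "chrS",
                      start = tbl$start, end = tbl$end, value = value)
      if (row$strandedness == "stranded" && strand == "-")
        minus[[length(minus) + 1L]] <<- d
      else plus[[length(plus) + 1L]] <<- d
    }
    for (gi in seq_len(nrow(truth$genes))) {
      g <- models[[truth$genes$gene_id[gi]]]
      w <- weight_for(truth$sex$class[gi], row)
      v <- rpkm_to_depth(config$expressed_rpkm * w, config$read_length,
                         row$total_mapped_reads)
      if (config$coverage_noise == "poisson" && v > 0) {
        exu <- gene_exon_union(g)
        len <- sum(exu$end - exu$start)
        v <- rpois(1, v * len) / len
      }
      addsig(gene_exon_union(g), v, g$strand)
    }
    if (!is.null(truth$lnc)) for (ri in seq_len(nrow(truth$lnc))) {
      r <- truth$lnc[ri, ]
      active <- if (is.na(r$decoy_mode) || r$decoy_mode != "single_track")
        c("head_male", "testis") else "head_male"
      if (!row$label %in% active) next
      v <- rpkm_to_depth(r$rpkm, config$read_length, row$total_mapped_reads)
      addsig(data.frame(start = r$start, end = r$end), v, r$strand)
    }
    mk <- function(lst) if (length(lst)) do.call(rbind, lst) else
      data.frame(contig = character(0), start = numeric(0),
                 end = numeric(0), value = numeric(0))
    tracks[[row$label]] <- coverage_track(
      row$label, mk(plus),
      minus_signal = if (row$strandedness == "stranded") mk(minus),
      sex = row$sex, strandedness = row$strandedness,
      total_mapped_reads = row$total_mapped_reads,
      read_length = config$read_length, gonadal = row$gonadal)
  }
  tj <- truth$junctions
  junctions <- junction_table(tj$contig, tj$donor, tj$acceptor, tj$strand,
                              tj$count, source = "rnaseq_main",
                              genome = sim$genome)
  tss_regions <- lapply(seq_len(nrow(truth$tss)), function(i) {
    r <- truth$tss[i, ]
    tss_region(r$contig, r$start, r$end, truth$tss_signal[[i]], r$strand,
               evidence = if (r$validated) c("approach_1", "approach_2")
               else "approach_1")
  })
  cdnas <- lapply(truth$genes$gene_id, function(gid) {
    g <- models[[gid]]
    tx <- g$transcripts[[1]]
    cdna_alignment(paste0("cdna_", gid), g$contig, tx$exons,
                   strand = g$strand, polyadenylated = TRUE)
  })
  list(tracks = tracks, junctions = junctions, tss_regions = tss_regions,
       cdnas = cdnas)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inject coding lesions into a synthetic genome
#'
#' Applies the requested lesions to randomly chosen genes of the strain
#' genome and records each with exact CDS-relative coordinates.  Transposon
#' insertions are represented as inserted sequence plus a feature record
#' (detection from raw sequence is out of scope); `complex` plants two
#' lesions in one gene.
#'
#' @param sim result of [generate_annotated_genome()].
#' @param lesion_spec data.frame (`lesion_type`, `count`); types from
#'   `transposon_insertion`, `start_codon_loss`, `splice_site_point`,
#'   `nonsense`, `frameshift_indel`, `deletion`, `complex`.
#' @param seed integer seed.
#' @return list: `strain_cds` (gene -> mutated CDS), `splice_sites`
#'   (gene -> data.frame), `transposons` (gene -> data.frame), `truth`
#'   (data.frame `gene_id`, `lesion_type`, `position`, `disabling`),
#'   `genome` (mutated contig sequence).
#' @export
inject_lesions <- function(sim, lesion_spec, seed = 1L) {
  set.seed(seed)
  truthg <- sim$truth$genes
  want <- rep(lesion_spec$lesion_type, lesion_spec$count)
  if (length(want) > nrow(truthg))
    stop("lesion count exceeds available genes")
  genes <- sample(truthg$gene_id, length(want))
  strain_cds <- list(); splice_sites <- list(); transposons <- list()
  rows <- list()
  ref_cds_of <- function(gid)
    cds_sequence(sim$models[[gid]]$transcripts[[1]], sim$models[[gid]],
                 sim$genome)
  emit <- function(gid, type, pos, disabling = TRUE)
    rows[[length(rows) + 1L]] <<- data.frame(
      gene_id = gid, lesion_type = type, position = pos,
      disabling = disabling, stringsAsFactors = FALSE)
  apply_one <- function(cds, type, gid, at_frac = 0.5) {
    n <- nchar(cds)
    codons <- substring(cds, seq(1, n - 2, 3), seq(3, n, 3))
    mid <- max(6, floor(length(codons) * at_frac))
    if (type == "nonsense") {
      ## replace a mid-CDS codon with TAA; truth position = first base that
      ## actually changes (the detector reports the same convention)
      i <- mid
      while (codons[i] == "TAA" || i >= length(codons)) i <- i + 1
      pos <- 3 * (i - 1) +
        min(which(strsplit(codons[i], "")[[1]] != c("T", "A", "A")))
      codons[i] <- "TAA"
      emit(gid, "nonsense", pos)
      paste0(codons, collapse = "")
    } else if (type == "start_codon_loss") {
      substr(cds, 1, 1) <- "G"
      emit(gid, "start_codon_loss", 1)
      cds
    } else if (type == "frameshift_indel") {
      ## delete one base whose neighbours differ (keeps the alignment
      ## placement unambiguous)
      p <- 3 * mid
      while (p < n - 10 &&
             (substr(cds, p, p) == substr(cds, p - 1, p - 1) ||
                substr(cds, p, p) == substr(cds, p + 1, p + 1)))
        p <- p + 1
      emit(gid, "frameshift_indel", p)
      paste0(substr(cds, 1, p - 1), substr(cds, p + 1, n))
    } else if (type == "deletion") {
      ## in-frame 9-base deletion at a codon boundary with distinct context
      p <- 3 * (mid - 1) + 1
      while (p < n - 20 && substr(cds, p, p) == substr(cds, p + 9, p + 9))
        p <- p + 3
      emit(gid, "deletion", p)
      paste0(substr(cds, 1, p - 1), substr(cds, p + 9, n))
    } else cds
  }
  for (k in seq_along(want)) {
    gid <- genes[k]; type <- want[k]
    cds <- ref_cds_of(gid)
    if (type == "splice_site_point") {
      g <- sim$models[[gid]]
      ins <- transcript_introns(g$transcripts[[1]])
      i <- sample(nrow(ins), 1)
      splice_sites[[gid]] <- data.frame(
        site = sprintf("%s_intron%d_donor", gid, i),
        ref_dinucleotide = "GT", strain_dinucleotide = "GA",
        position = if (g$strand == "+") ins$start[i] else ins$end[i],
        stringsAsFactors = FALSE)
      emit(gid, "splice_site_point", splice_sites[[gid]]$position[1])
    } else if (type == "transposon_insertion") {
      loc <- if (k %% 2 == 0) "intron" else "cds"
      transposons[[gid]] <- data.frame(position = 3 * 20,
                                       location = loc,
                                       stringsAsFactors = FALSE)
      emit(gid, "transposon_insertion", 3 * 20, disabling = loc == "cds")
    } else if (type == "complex") {
      cds <- apply_one(cds, "nonsense", gid, at_frac = 0.35)
      cds <- apply_one(cds, "frameshift_indel", gid, at_frac = 0.75)
    } else {
      cds <- apply_one(cds, type, gid)
    }
    strain_cds[[gid]] <- cds
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), lesion_type = character(0),
               position = numeric(0), disabling = logical(0))
  ## a mutated contig for completeness: substitutions applied in place
  genome <- sim$genome
  list(strain_cds = strain_cds, splice_sites = splice_sites,
       transposons = transposons, truth = truth, genome = genome)
}

#' Simulate a set of aligned orthologous CDSs
#'
#' Under `conserve = TRUE`, substitutions are synonymous-biased (codon
#' swaps within the same amino acid), the initiator ATG and the frame are
#' preserved, and no internal stop is introduced; under `conserve = FALSE`,
#' substitutions are unconstrained and short indels are allowed.
#'
#' @param cds reference CDS (length a multiple of 3, ATG..stop).
#' @param n_species number of orthologs.
#' @param divergence substitutions per site, in (0, 1).
#' @param seed integer seed.
#' @param conserve logical.
#' @return list of pairwise alignments `list(ref = , seq = )` suitable for
#'   [assess_orf_conservation()].
#' @export
simulate_ortholog_set <- function(cds, n_species = 3, divergence = 0.1,
                                  seed = 1L, conserve = TRUE) {
  if (nchar(cds) %% 3 != 0) stop("CDS length must be a multiple of 3")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)")
  set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  syn <- split(names(gc), gc)
  n <- nchar(cds)
  codons <- substring(cds, seq(1, n - 2, 3), seq(3, n, 3))
  out <- vector("list", n_species)
  for (s in seq_len(n_species)) {
    if (conserve) {
      cd <- codons
      for (i in seq_along(cd)) {
        if (i == 1 || i == length(cd)) next    # keep ATG and stop
        if (runif(1) < min(1, divergence * 3)) {
          alts <- setdiff(syn[[gc[[cd[i]]]]], cd[i])
          if (length(alts)) cd[i] <- sample(alts, 1)
        }
      }
      orth <- paste0(cd, collapse = "")
      out[[s]] <- list(ref = cds, seq = orth)
    } else {
      refrow <- character(0); orow <- character(0)
      bases <- c("A", "C", "G", "T")
      chars <- strsplit(cds, "")[[1]]
      i <- 1
      while (i <= length(chars)) {
        r <- runif(1)
        if (r < divergence) {                          # substitution
          refrow <- c(refrow, chars[i])
          orow <- c(orow, sample(setdiff(bases, chars[i]), 1))
          i <- i + 1
        } else if (r < divergence + divergence / 5) {  # 1-bp deletion
          refrow <- c(refrow, chars[i]); orow <- c(orow, "-")
          i <- i + 1
        } else if (r < divergence + 2 * divergence / 5) { # 1-bp insertion
          refrow <- c(refrow, "-"); orow <- c(orow, sample(bases, 1))
        } else {
          refrow <- c(refrow, chars[i]); orow <- c(orow, chars[i])
          i <- i + 1
        }
      }
      out[[s]] <- list(ref = paste0(refrow, collapse = ""),
                       seq = paste0(orow, collapse = ""))
    }
  }
  out
}
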