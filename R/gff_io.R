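## GFF3 input/output for gene models.  Parsing and serialisation go through
## rtracklayer; this layer converts between GFF3's 1-based closed coordinates
## and the package's 0-based half-open convention, and (re)assembles the
## gene -> transcript -> exon/CDS hierarchy.

## Accept a path, a connection, or a character vector of lines; return a path.
as_input_path <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(x)
  tf <- tempfile(fileext = ".gff3")
  if (inherits(x, "connection")) writeLines(readLines(x), tf)
  else writeLines(as.character(x), tf)
  tf
}

#' Read gene models from GFF3
#'
#' Expects a `gene` / (`mRNA`|`ncRNA`|`pseudogenic_transcript`) / `exon`,
#' `CDS` hierarchy linked by `ID`/`Parent` attributes.  GFF3 coordinates
#' (1-based, closed) are converted to the internal 0-based half-open
#' convention.  Comment codes are read from the `curation_comments`
#' attribute; unrecognised codes are preserved but flagged with a warning.
#'
#' @param source path, connection, or character vector of GFF3 lines.
#' @return named list of [gene_model()] objects.
#' @export
read_gene_models <- function(source) {
  path <- as_input_path(source)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0) return(structure(list(), names = character(0)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$contig <- as.character(df$seqnames)
  df$start0 <- as.numeric(df$start) - 1   # internal 0-based half-open
  df$end0 <- as.numeric(df$end)
  df$type <- as.character(df$type)
  getattr <- function(col) {
    if (col %in% names(df)) as.character(df[[col]]) else rep(NA_character_, nrow(df))
  }
  ids <- getattr("ID")
  parents <- if ("Parent" %in% names(df)) {
    vapply(df$Parent, function(p) if (length(p)) as.character(p)[1] else NA_character_,
           character(1))
  } else rep(NA_character_, nrow(df))

  gene_rows <- which(df$type == "gene")
  tx_types <- c("mRNA", "ncRNA", "pseudogenic_transcript", "transcript")
  tx_rows <- which(df$type %in% tx_types)
  child_rows <- which(df$type %in% c("exon", "CDS"))
  known_ids <- ids[c(gene_rows, tx_rows)]
  for (i in c(tx_rows, child_rows)) {
    if (is.na(parents[i]) || !parents[i] %in% known_ids)
      stop("orphan ", df$type[i], " feature at record ", i,
           " (id ", ids[i], "): parent '", parents[i], "' not found")
  }

  vocab <- comment_vocabulary()$code
  parse_comments <- function(x) {
    if (is.na(x) || !nzchar(x)) return(character())
    codes <- strsplit(x, "|", fixed = TRUE)[[1]]
    bad <- setdiff(codes, vocab)
    if (length(bad))
      warning("unrecognized comment code(s) preserved verbatim: ",
              paste(bad, collapse = ", "))
    codes
  }

  models <- list()
  for (g in gene_rows) {
    gid <- ids[g]
    txs <- list()
    for (t in tx_rows[parents[tx_rows] == gid]) {
      tid <- ids[t]
      kids <- child_rows[parents[child_rows] == tid]
      exon_k <- kids[df$type[kids] == "exon"]
      cds_k <- kids[df$type[kids] == "CDS"]
      exons <- data.frame(start = df$start0[exon_k], end = df$end0[exon_k])
      cds <- if (length(cds_k)) c(min(df$start0[cds_k]), max(df$end0[cds_k]))
      fe <- getattr("five_prime_evidence")[t]
      te <- getattr("three_prime_evidence")[t]
      txs[[length(txs) + 1L]] <- transcript(
        tid, exons, cds = cds,
        five_prime_evidence = if (is.na(fe)) "cds_start_fallback" else fe,
        three_prime_evidence = if (is.na(te)) "stop_codon_fallback" else te,
        comments = parse_comments(getattr("curation_comments")[t]))
    }
    sym <- getattr("Name")[g]
    bt <- getattr("biotype")[g]
    aso <- getattr("antisense_of")[g]
    models[[gid]] <- gene_model(
      gid, contig = df$contig[g], strand = as.character(df$strand[g]),
      transcripts = txs,
      symbol = if (is.na(sym)) gid else sym,
      biotype = if (is.na(bt)) "protein_coding" else bt,
      comments = parse_comments(getattr("curation_comments")[g]),
      antisense_of = if (is.na(aso)) NULL else aso)
  }
  models
}

#' Write gene models to GFF3
#'
#' Features are emitted in deterministic order (contig, start, gene id);
#' internal 0-based half-open coordinates are converted back to GFF3's
#' 1-based closed convention.  Comment codes are serialised in the
#' `curation_comments` attribute, `|`-separated.
#'
#' @param models list of [gene_model()] objects.
#' @param path optional output path; when `NULL` the GFF3 lines are returned.
#' @return character vector of GFF3 lines, invisibly when `path` is given.
#' @export
write_gene_models <- function(models, path = NULL) {
  ord <- order(vapply(models, `[[`, character(1), "contig"),
               vapply(models, `[[`, numeric(1), "start"),
               vapply(models, `[[`, character(1), "gene_id"))
  rows <- list()
  add <- function(contig, start0, end0, strand, type, attrs) {
    rows[[length(rows) + 1L]] <<- data.frame(
      contig = contig, start = start0 + 1, end = end0, strand = strand,
      type = type, attrs = attrs, stringsAsFactors = FALSE)
  }
  enc <- function(x) gsub("([;=&,\t])", "", x)   # keep attributes GFF3-safe
  for (gene in models[ord]) {
    validate_gene_model(gene)
    ga <- c(sprintf("ID=%s", gene$gene_id),
            sprintf("Name=%s", enc(gene$symbol)),
            sprintf("biotype=%s", gene$biotype))
    if (!is.null(gene$antisense_of))
      ga <- c(ga, sprintf("antisense_of=%s", gene$antisense_of))
    if (length(gene$comments))
      ga <- c(ga, sprintf("curation_comments=%s",
                          paste(gene$comments, collapse = "|")))
    add(gene$contig, gene$start, gene$end, gene$strand, "gene",
        paste(ga, collapse = ";"))
    for (tx in gene$transcripts) {
      ext <- transcript_extent(tx)
      ta <- c(sprintf("ID=%s", tx$transcript_id),
              sprintf("Parent=%s", gene$gene_id),
              sprintf("five_prime_evidence=%s", tx$five_prime_evidence),
              sprintf("three_prime_evidence=%s", tx$three_prime_evidence))
      if (length(tx$comments))
        ta <- c(ta, sprintf("curation_comments=%s",
                            paste(tx$comments, collapse = "|")))
      ttype <- if (gene$biotype %in% c("pseudogene", "polymorphic_pseudogene"))
        "pseudogenic_transcript" else if (is.null(tx$cds)) "ncRNA" else "mRNA"
      add(gene$contig, ext[1], ext[2], gene$strand, ttype,
          paste(ta, collapse = ";"))
      for (i in seq_len(nrow(tx$exons)))
        add(gene$contig, tx$exons$start[i], tx$exons$end[i], gene$strand,
            "exon", sprintf("ID=%s:exon:%d;Parent=%s", tx$transcript_id, i,
                            tx$transcript_id))
      if (!is.null(tx$cds)) {
        phase <- 0
        k <- 0
        idx <- seq_len(nrow(tx$exons))
        if (gene$strand == "-") idx <- rev(idx)
        cds_parts <- list()
        for (i in idx) {
          s <- max(tx$exons$start[i], tx$cds[1])
          e <- min(tx$exons$end[i], tx$cds[2])
          if (s < e) {
            cds_parts[[length(cds_parts) + 1L]] <- c(s, e, (3 - k %% 3) %% 3)
            k <- k + (e - s)
          }
        }
        ## emit CDS rows in genomic order
        ords <- order(vapply(cds_parts, `[`, numeric(1), 1))
        for (j in seq_along(cds_parts)) {
          p <- cds_parts[[ords[j]]]
          rows[[length(rows) + 1L]] <- data.frame(
            contig = gene$contig, start = p[1] + 1, end = p[2],
            strand = gene$strand, type = "CDS",
            attrs = sprintf("ID=%s:cds;Parent=%s;phase=%d",
                            tx$transcript_id, tx$transcript_id, p[3]),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  lines <- "##gff-version 3"
  if (length(rows)) {
    tab <- do.call(rbind, rows)
    phase <- ifelse(tab$type == "CDS",
                    sub("^.*phase=(\\d).*$", "\\1", tab$attrs), ".")
    attrs <- sub(";phase=\\d", "", tab$attrs)
    lines <- c(lines, sprintf("%s\tannotriage\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                              tab$contig, tab$type, tab$start, tab$end,
                              tab$strand, phase, attrs))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
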