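## Shared builders for small fixtures; all fixtures are generated in code.

## NB: the default CDS gives a spliced length of 90 + 81 = 171 bases
simple_gene <- function(id = "G1", contig = "c", strand = "+",
                        exons = data.frame(start = c(0, 200),
                                           end = c(100, 300)),
                        cds = c(10, 281)) {
  gene_model(id, contig, strand,
             list(transcript(paste0(id, "-RA"), exons, cds = cds)))
}

flat_track <- function(label, blocks, value, contig = "c",
                       strandedness = "unstranded", minus_blocks = NULL,
                       sex = "na", gonadal = FALSE,
                       total_mapped_reads = 1e7, read_length = 75) {
  mk <- function(bl) if (is.null(bl) || !length(bl))
    data.frame(contig = character(0), start = numeric(0), end = numeric(0),
               value = numeric(0))
  else do.call(rbind, lapply(bl, function(b)
    data.frame(contig = contig, start = b[1], end = b[2], value = value)))
  coverage_track(label, mk(blocks),
                 minus_signal = if (strandedness == "stranded") mk(minus_blocks),
                 sex = sex, strandedness = strandedness,
                 total_mapped_reads = total_mapped_reads,
                 read_length = read_length, gonadal = gonadal)
}

## depth value that yields a given RPKM under default track metadata
depth_for_rpkm <- function(rpkm, read_length = 75, total = 1e7) {
  rpkm * read_length * total / 1e9
}

## a random multi-exon gene plus its observed junctions, for splice-graph
## property tests: a scaffold of `n_exons` exons with cassette choices
random_splice_gene <- function(id, n_exons = 5, p_skip = 0.4,
                               n_transcripts = 3) {
  width <- 100; gap <- 50
  starts <- (seq_len(n_exons) - 1) * (width + gap)
  scaffold <- data.frame(start = starts, end = starts + width)
  txs <- list()
  seen <- character(0)
  for (t in seq_len(n_transcripts)) {
    keep <- c(TRUE, runif(n_exons - 2) > p_skip, TRUE)
    key <- paste(keep, collapse = "")
    if (key %in% seen) next
    seen <- c(seen, key)
    txs[[length(txs) + 1L]] <- transcript(
      sprintf("%s-R%d", id, t), scaffold[keep, , drop = FALSE])
  }
  if (!length(txs)) txs <- list(transcript(paste0(id, "-R1"), scaffold))
  gene_model(id, "c", "+", txs)
}

## independent exhaustive path enumeration over a splice graph (DFS oracle)
dfs_count_paths <- function(graph, edge_filter = "all") {
  e <- graph$edges
  keep <- switch(edge_filter,
                 all = rep(TRUE, nrow(e)),
                 annotated_only = e$type == "adjacency" | e$annotated,
                 accepted = e$type == "adjacency" | e$accepted)
  e <- e[keep, , drop = FALSE]
  fwd <- graph$strand == "+"
  total <- 0L
  walk <- function(n) {
    if (n %in% graph$terminals) total <<- total + 1L
    nxt <- if (fwd) e$to[e$from == n] else e$from[e$to == n]
    for (m in nxt) walk(m)
  }
  for (p in graph$promoters) walk(p)
  total
}
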