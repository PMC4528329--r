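#' Build a per-gene splice graph
#'
#' Nodes are maximal exonic segments: the union of all exon intervals split
#' at every splice boundary (annotated intron ends and observed junction
#' ends).  Splice edges carry an `annotated` flag (does the intron occur in
#' an annotated transcript?), an `accepted` flag (annotated, or an observed
#' junction whose triage decision was to incorporate), and a read count.
#' Adjacency edges link genomically contiguous segments of the same exonic
#' block (read-through, no splice).  Promoters are the segments carrying a
#' transcript 5' end; terminals carry a transcript 3' end.
#'
#' @param gene a [gene_model()].
#' @param junctions optional junction rows for this gene (fields `donor`,
#'   `acceptor`, `count`, optionally `status` from triage: statuses
#'   `incorporate`/`incorporate_flagged` mark accepted unannotated edges).
#' @param tss_assignments optional vector of additional promoter base
#'   positions (e.g. newly validated TSSs).
#' @return a list with class `splice_graph`: `nodes` (data.frame `id`,
#'   `start`, `end`), `edges` (data.frame `from`, `to`, `type`, `annotated`,
#'   `accepted`, `read_count`), `promoters`, `terminals`, `strand`, `cds_span`.
#' @export
build_splice_graph <- function(gene, junctions = NULL,
                               tss_assignments = NULL) {
  exu <- gene_exon_union(gene)
  ann <- gene_introns(gene)
  jx <- if (!is.null(junctions) && nrow(junctions)) junctions else NULL
  ## splice boundaries: intron starts end exon segments, intron ends start them
  bstart <- c(ann$end, if (!is.null(jx)) jx$acceptor)
  bend <- c(ann$start, if (!is.null(jx)) jx$donor)
  ## every junction endpoint must be on (or create) an exonic boundary
  if (!is.null(jx)) {
    for (i in seq_len(nrow(jx))) {
      dok <- any(exu$start < jx$donor[i] & exu$end >= jx$donor[i])
      aok <- any(exu$start <= jx$acceptor[i] & exu$end > jx$acceptor[i])
      if (!dok || !aok)
        stop("junction ", jx$donor[i], "-", jx$acceptor[i],
             " of gene ", gene$gene_id,
             " is inconsistent with the exonic structure")
    }
  }
  nodes <- list()
  for (k in seq_len(nrow(exu))) {
    cuts <- sort(unique(c(exu$start[k], exu$end[k],
                          bstart[bstart > exu$start[k] & bstart < exu$end[k]],
                          bend[bend > exu$start[k] & bend < exu$end[k]])))
    for (i in seq_len(length(cuts) - 1))
      nodes[[length(nodes) + 1L]] <- data.frame(
        start = cuts[i], end = cuts[i + 1], block = k)
  }
  nodes <- do.call(rbind, nodes)
  nodes <- nodes[order(nodes$start), , drop = FALSE]
  nodes$id <- seq_len(nrow(nodes))
  node_ending_at <- function(p) nodes$id[nodes$end == p]
  node_starting_at <- function(p) nodes$id[nodes$start == p]

  edges <- list()
  add_edge <- function(from, to, type, annotated, accepted, count = 0) {
    edges[[length(edges) + 1L]] <<- data.frame(
      from = from, to = to, type = type, annotated = annotated,
      accepted = accepted, read_count = count)
  }
  ## adjacency within each exonic block
  for (k in unique(nodes$block)) {
    idx <- nodes$id[nodes$block == k]
    if (length(idx) > 1)
      for (i in seq_len(length(idx) - 1))
        add_edge(idx[i], idx[i + 1], "adjacency", TRUE, TRUE)
  }
  ## annotated introns
  seen <- character(0)
  for (i in seq_len(nrow(ann))) {
    f <- node_ending_at(ann$start[i]); t <- node_starting_at(ann$end[i])
    if (!length(f) || !length(t)) next
    cnt <- if (!is.null(jx)) {
      m <- jx$donor == ann$start[i] & jx$acceptor == ann$end[i]
      if (any(m)) max(jx$count[m]) else 0
    } else 0
    add_edge(f[1], t[1], "splice", TRUE, TRUE, cnt)
    seen <- c(seen, paste(ann$start[i], ann$end[i]))
  }
  ## observed, unannotated junctions
  if (!is.null(jx)) {
    for (i in seq_len(nrow(jx))) {
      key <- paste(jx$donor[i], jx$acceptor[i])
      if (key %in% seen) next
      seen <- c(seen, key)
      f <- node_ending_at(jx$donor[i]); t <- node_starting_at(jx$acceptor[i])
      accepted <- !is.null(jx$status) &&
        jx$status[i] %in% c("incorporate", "incorporate_flagged")
      add_edge(f[1], t[1], "splice", FALSE, accepted, jx$count[i])
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = integer(0), to = integer(0), type = character(0),
               annotated = logical(0), accepted = logical(0),
               read_count = numeric(0))
  node_containing <- function(p)
    nodes$id[nodes$start <= p & p < nodes$end][1]
  prom <- unique(c(
    vapply(gene$transcripts, function(tx)
      node_containing(transcript_5p(tx, gene$strand)), numeric(1)),
    if (!is.null(tss_assignments))
      vapply(tss_assignments, node_containing, numeric(1))))
  term <- unique(vapply(gene$transcripts, function(tx)
    node_containing(transcript_3p(tx, gene$strand)), numeric(1)))
  ref <- reference_isoform(gene)
  structure(list(nodes = nodes[, c("id", "start", "end", "block")],
                 edges = edges, promoters = prom[!is.na(prom)],
                 terminals = term[!is.na(term)], strand = gene$strand,
                 cds_span = ref$cds, gene_id = gene$gene_id),
            class = "splice_graph")
}

#' @export
print.splice_graph <- function(x, ...) {
  cat(sprintf("splice_graph %s: %d node(s), %d edge(s), %d promoter(s), %d terminal(s)\n",
              x$gene_id, nrow(x$nodes), nrow(x$edges), length(x$promoters),
              length(x$terminals)))
  invisible(x)
}

## edges usable under a filter; adjacency edges always pass
filter_edges <- function(graph, edge_filter) {
  e <- graph$edges
  switch(edge_filter,
         annotated_only = e[e$type == "adjacency" | e$annotated, , drop = FALSE],
         accepted = e[e$type == "adjacency" | e$accepted, , drop = FALSE],
         all = e,
         stop("edge_filter must be 'annotated_only', 'accepted' or 'all'"))
}

#' Count possible transcript isoforms of a splice graph
#'
#' The number of distinct promoter-to-terminal paths using only edges
#' passing the filter, computed by path counting in topological (genomic)
#' order.  This is the quantity behind the permutation problem: the count
#' can vastly exceed the number of annotated transcripts.
#'
#' @param graph a [build_splice_graph()] result.
#' @param edge_filter `"annotated_only"` (edges present in annotated
#'   transcripts), `"accepted"` (annotated plus incorporated junctions), or
#'   `"all"` (every observed splice choice, including excluded ones).
#' @return integer path count.
#' @export
count_isoforms <- function(graph, edge_filter = "annotated_only") {
  e <- filter_edges(graph, edge_filter)
  ids <- graph$nodes$id
  ord <- ids[order(graph$nodes$start)]
  if (graph$strand == "-") ord <- rev(ord)
  f <- setNames(numeric(length(ids)), ids)
  ## genomic order is a topological order: all edges advance coordinates
  for (n in ord) {
    f[as.character(n)] <- as.numeric(n %in% graph$promoters)
    inc <- if (graph$strand == "+") e[e$to == n, , drop = FALSE] else
      e[e$from == n, , drop = FALSE]
    src <- if (graph$strand == "+") inc$from else inc$to
    if (length(src)) f[as.character(n)] <- f[as.character(n)] +
      sum(f[as.character(src)])
  }
  total <- sum(f[as.character(graph$terminals)])
  if (total > .Machine$integer.max) total else as.integer(total)
}

## enumerate promoter->terminal paths (node id vectors); NULL when the count
## exceeds `cap`
enumerate_paths <- function(graph, edge_filter = "accepted", cap = 10000) {
  if (count_isoforms(graph, edge_filter) > cap) return(NULL)
  e <- filter_edges(graph, edge_filter)
  fwd <- graph$strand == "+"
  out_of <- function(n) if (fwd) e[e$from == n, , drop = FALSE] else
    e[e$to == n, , drop = FALSE]
  nxt <- function(ed) if (fwd) ed$to else ed$from
  paths <- list()
  walk <- function(node, acc) {
    if (node %in% graph$terminals)
      paths[[length(paths) + 1L]] <<- acc
    oe <- out_of(node)
    for (i in seq_len(nrow(oe))) walk(nxt(oe[i, ]), c(acc, nxt(oe[i, ])))
  }
  for (p in sort(graph$promoters)) walk(p, p)
  paths
}

## splice edges (by row index into graph$edges) that a node path uses
path_edge_rows <- function(graph, path, edge_table) {
  rows <- integer(0)
  fwd <- graph$strand == "+"
  for (i in seq_len(length(path) - 1)) {
    a <- if (fwd) path[i] else path[i + 1]
    b <- if (fwd) path[i + 1] else path[i]
    r <- which(edge_table$from == a & edge_table$to == b)
    rows <- c(rows, r[1])
  }
  rows
}

#' Select a representative transcript set
#'
#' A deterministic greedy set cover: the emitted set of promoter-to-terminal
#' paths must include every promoter and every accepted splice edge in the
#' CDS region (and, by default, outside it) at least once, preferring paths
#' through high-read-count edges.  When the full isoform count exceeds the
#' emitted set, the permutation comment is attached.
#'
#' @param graph a [build_splice_graph()] result.
#' @param cover_noncds also require coverage of accepted splices outside the
#'   CDS span (default `TRUE`).
#' @param params [pipeline_config()] (`isoform_cap`).
#' @return list: `paths` (list of node-id vectors), `transcripts`
#'   (exon tables derived from the paths), `n_possible` (accepted-edge
#'   isoform count), `emitted_comment` (`not_all_combinations` or `NA`),
#'   `decision`.
#' @export
select_representative_isoforms <- function(graph, cover_noncds = TRUE,
                                           params = pipeline_config()) {
  e <- graph$edges
  req_edges <- which(e$type == "splice" & e$accepted)
  if (!cover_noncds && !is.null(graph$cds_span)) {
    ns <- graph$nodes
    in_cds <- function(r) {
      a <- ns$end[ns$id == e$from[r]]; b <- ns$start[ns$id == e$to[r]]
      a > graph$cds_span[1] && b < graph$cds_span[2]
    }
    req_edges <- req_edges[vapply(req_edges, in_cds, logical(1))]
  }
  n_possible <- count_isoforms(graph, "accepted")
  paths <- enumerate_paths(graph, "accepted", cap = params$isoform_cap)
  acc <- filter_edges(graph, "accepted")
  chosen <- list()
  if (!is.null(paths)) {
    covered_e <- logical(nrow(e))
    covered_p <- setNames(logical(length(graph$promoters)),
                          graph$promoters)
    path_rows <- lapply(paths, function(p) path_edge_rows(graph, p, e))
    repeat {
      need_e <- req_edges[!covered_e[req_edges]]
      need_p <- names(covered_p)[!covered_p]
      if (!length(need_e) && !length(need_p)) break
      gain <- vapply(seq_along(paths), function(i) {
        length(intersect(path_rows[[i]], need_e)) +
          as.numeric(as.character(paths[[i]][1]) %in% need_p)
      }, numeric(1))
      best <- which(gain == max(gain))
      if (max(gain) == 0) break          # unreachable requirement
      if (length(best) > 1) {
        ## tie-break: highest-read-count uncovered edge, then leftmost start
        key <- vapply(best, function(i) {
          rows <- intersect(path_rows[[i]], need_e)
          if (length(rows)) max(e$read_count[rows]) else -1
        }, numeric(1))
        best <- best[key == max(key)]
        if (length(best) > 1) {
          lm <- vapply(best, function(i)
            graph$nodes$start[graph$nodes$id == paths[[i]][1]], numeric(1))
          best <- best[which.min(lm)]
        }
      }
      i <- best[1]
      chosen[[length(chosen) + 1L]] <- paths[[i]]
      covered_e[path_rows[[i]]] <- TRUE
      covered_p[as.character(paths[[i]][1])] <- TRUE
    }
  } else {
    ## graph too large to enumerate: route one path through each uncovered
    ## requirement along highest-count edges
    for (r in req_edges)
      chosen[[length(chosen) + 1L]] <- greedy_path_through(graph, acc, r)
    for (p in graph$promoters)
      chosen[[length(chosen) + 1L]] <- greedy_path_through(graph, acc, NULL, p)
    chosen <- unique(chosen)
  }
  txs <- lapply(chosen, function(p) path_to_exons(graph, p))
  comment <- if (n_possible > length(chosen)) "not_all_combinations" else
    NA_character_
  list(paths = chosen, transcripts = txs, n_possible = n_possible,
       emitted_comment = comment,
       decision = decision_record(graph$gene_id, "representative_set",
                                  "greedy_cover",
                                  params = list(n_emitted = length(chosen),
                                                n_possible = n_possible),
                                  emitted_comment = comment))
}

## build a path through required edge row `r` (or from promoter `from_p`)
## choosing at each branch the highest-read-count then leftmost edge
greedy_path_through <- function(graph, acc, r = NULL, from_p = NULL) {
  fwd <- graph$strand == "+"
  step <- function(n, backwards) {
    cand <- if (xor(fwd, backwards)) acc[acc$from == n, , drop = FALSE] else
      acc[acc$to == n, , drop = FALSE]
    if (!nrow(cand)) return(NA)
    cand <- cand[order(-cand$read_count, cand$from), , drop = FALSE]
    if (xor(fwd, backwards)) cand$to[1] else cand$from[1]
  }
  extend <- function(n, backwards, stop_set) {
    out <- integer(0)
    while (!n %in% stop_set) {
      n2 <- step(n, backwards)
      if (is.na(n2)) break
      out <- c(out, n2); n <- n2
    }
    out
  }
  if (!is.null(r)) {
    a <- graph$edges$from[r]; b <- graph$edges$to[r]
    if (!fwd) { tmp <- a; a <- b; b <- tmp }
    left <- rev(extend(a, TRUE, graph$promoters))
    right <- extend(b, FALSE, graph$terminals)
    c(left, a, b, right)
  } else {
    c(from_p, extend(from_p, FALSE, graph$terminals))
  }
}

## convert a node path back to an exon table (merging contiguous nodes)
path_to_exons <- function(graph, path) {
  ns <- graph$nodes
  segs <- ns[match(path, ns$id), c("start", "end")]
  segs <- segs[order(segs$start), , drop = FALSE]
  out <- segs[1, , drop = FALSE]
  for (i in seq_len(nrow(segs) - 1) + 1) {
    if (segs$start[i] == out$end[nrow(out)]) out$end[nrow(out)] <- segs$end[i]
    else out <- rbind(out, segs[i, ])
  }
  rownames(out) <- NULL
  out
}

#' Detect isoform pairs with nonoverlapping CDSs
#'
#' Reports pairs of coding transcripts whose CDS genomic projections are
#' disjoint, notes whether the transcripts themselves are also
#' nonoverlapping, and checks for a longer bridging isoform overlapping both
#' CDSs -- required for the pair to remain one gene.  Without a bridge the
#' pair is returned as a split candidate instead of a comment.
#'
#' @param gene a [gene_model()] with at least two coding transcripts.
#' @return list: `pairs` (data.frame `tx_a`, `tx_b`,
#'   `transcripts_nonoverlapping`, `bridged`), `emitted_comment`
#'   (`nonoverlapping_cds` when a bridged pair exists), `split_candidates`
#'   (unbridged pairs).
#' @export
detect_nonoverlapping_cds_pairs <- function(gene) {
  coding <- Filter(function(tx) !is.null(tx$cds), gene$transcripts)
  empty <- data.frame(tx_a = character(0), tx_b = character(0),
                      transcripts_nonoverlapping = logical(0),
                      bridged = logical(0))
  if (length(coding) < 2)
    return(list(pairs = empty, emitted_comment = NA_character_,
                split_candidates = empty))
  rows <- list()
  for (i in seq_len(length(coding) - 1)) for (j in (i + 1):length(coding)) {
    a <- coding[[i]]; b <- coding[[j]]
    if (intervals_overlap(a$cds[1], a$cds[2], b$cds[1], b$cds[2])) next
    exta <- transcript_extent(a); extb <- transcript_extent(b)
    bridged <- any(vapply(coding, function(tx)
      intervals_overlap(tx$cds[1], tx$cds[2], a$cds[1], a$cds[2]) &&
        intervals_overlap(tx$cds[1], tx$cds[2], b$cds[1], b$cds[2]),
      logical(1)))
    rows[[length(rows) + 1L]] <- data.frame(
      tx_a = a$transcript_id, tx_b = b$transcript_id,
      transcripts_nonoverlapping = !intervals_overlap(exta[1], exta[2],
                                                      extb[1], extb[2]),
      bridged = bridged, stringsAsFactors = FALSE)
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else empty
  list(pairs = pairs,
       emitted_comment = if (any(pairs$bridged)) "nonoverlapping_cds" else
         NA_character_,
       split_candidates = pairs[!pairs$bridged, , drop = FALSE])
}
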