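#' The AnxB9 worked example: a modularly organised splice graph
#'
#' Reconstructs the splice topology of the *Drosophila* gene *AnxB9* as a
#' [gene_model()] plus observed-junction table: RNA-Seq junction data
#' predict eight alternative splice donors from three different leading 5'
#' exons, of which four are annotated; alternative splicing in the last
#' intron offers three annotated acceptor choices, with one additional
#' low-frequency 3' junction excluded from annotation.  With the annotated
#' junctions twelve transcript isoforms are possible; with all observed
#' junctions, thirty-two.
#'
#' @return list: `gene` (a [gene_model()] whose transcripts cover every
#'   annotated splice), `junctions` (data.frame of all observed junctions
#'   with `donor`, `acceptor`, `count`, `status`), `graph` (the
#'   [build_splice_graph()] result).
#' @export
anxb9_example <- function() {
  contig <- "chr3R"
  ## three leading 5' exons; donor positions within each
  lead <- list(E1 = c(0, 300), E2 = c(400, 700), E3 = c(800, 1000))
  donors <- list(E1 = c(100, 200, 300), E2 = c(500, 600, 700),
                 E3 = c(900, 1000))
  ## four of the eight donors are annotated, including the farthest donor
  ## of each leading exon (so the annotated exons span all donor sites)
  annotated_donors <- c(100, 300, 700, 1000)
  body <- c(1200, 1500)                          # constitutive exon block
  last_donor <- 1500
  acceptors <- c(1600, 1650, 1700, 1750)         # last-intron alternatives
  annotated_acceptors <- c(1600, 1650, 1700)     # the excluded one: 1750
  final <- c(1600, 2000)

  exons_for <- function(donor, acceptor) {
    lead_exon <- lead[[which(vapply(lead, function(b)
      donor > b[1] && donor <= b[2], logical(1)))]]
    data.frame(start = c(lead_exon[1], body[1], acceptor),
               end = c(donor, last_donor, final[2]))
  }
  ## annotated transcripts: every annotated donor and acceptor used at
  ## least once (representative coverage, not all 12 combinations)
  combos <- data.frame(donor = annotated_donors,
                       acceptor = annotated_acceptors[c(1, 2, 3, 1)])
  ## exons_for() trims the leading exon at the donor; transcripts using the
  ## farthest donors keep their leading exons full-length
  txs <- lapply(seq_len(nrow(combos)), function(i)
    transcript(sprintf("AnxB9-R%s", LETTERS[i]),
               exons_for(combos$donor[i], combos$acceptor[i])))
  gene <- gene_model("AnxB9", contig, "+", txs, symbol = "AnxB9",
                     biotype = "protein_coding")

  all_donors <- unlist(donors)
  jrows <- rbind(
    data.frame(donor = all_donors, acceptor = body[1],
               count = ifelse(all_donors %in% annotated_donors, 500, 4)),
    data.frame(donor = last_donor, acceptor = acceptors,
               count = c(800, 700, 600, 3)))
  jrows$status <- ifelse(
    (jrows$acceptor == body[1] & jrows$donor %in% annotated_donors) |
      (jrows$donor == last_donor & jrows$acceptor %in% annotated_acceptors),
    "already_represented", "rejected")
  graph <- build_splice_graph(gene, jrows)
  list(gene = gene, junctions = jrows, graph = graph)
}
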