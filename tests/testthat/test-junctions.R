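## a coding gene whose CDS spans two exons, for frame-effect tests
frame_gene <- function() {
  ## exon1 [0,300), intron [300,400), exon2 [400,900); CDS 60..844
  ## (spliced CDS length 240 + 444 = 684, a multiple of 3)
  gene_model("FG", "c", "+",
             list(transcript("FG-RA",
                             data.frame(start = c(0, 400), end = c(300, 900)),
                             cds = c(60, 844))))
}

test_that("junctions are assigned to genes by their exonic anchors", {
  a <- simple_gene("A")
  b <- simple_gene("B", exons = data.frame(start = c(600, 900),
                                           end = c(700, 1000)),
                   cds = c(610, 993))
  models <- list(A = a, B = b)
  jt <- junction_table("c", c(100, 300, 650, 1500), c(200, 650, 900, 1600),
                       c("+", "+", "+", "+"), c(10, 5, 8, 2))
  jx <- assign_junction_to_gene(jt, models)
  expect_equal(jx$assignment, c("gene", "merge_flag", "gene", "intergenic"))
  expect_equal(jx$gene_id, c("A", NA, "B", NA))
  expect_equal(jx$spans_genes[2], "A,B")
})

test_that("relative junction frequency is count over the gene maximum", {
  expect_equal(relative_junction_frequency(1000, c(10, 1000)), 1)
  expect_equal(relative_junction_frequency(10, c(10, 1000)), 0.01)
  expect_equal(relative_junction_frequency(7, 7), 1)
  expect_error(relative_junction_frequency(0, c(0, 0)), "undefined")
})

test_that("the decision order and thresholds follow the curation rules", {
  g <- frame_gene()
  counts <- c(1000)    # the annotated intron dominates
  mkj <- function(d, a, count, dd = "GT", ad = "AG") {
    list(junction_id = sprintf("j%d_%d", d, a), contig = "c", donor = d,
         acceptor = a, strand = "+", count = count, source = "s",
         donor_dinucleotide = dd, acceptor_dinucleotide = ad)
  }
  dec <- function(j, ...) classify_junction(j, g, c(counts, j$count), ...)
  ## identity with the annotated intron
  expect_equal(dec(mkj(300, 400, 500))$status, "already_represented")
  ## noncanonical without corroboration, rejected; with cDNA, evaluated on
  expect_equal(dec(mkj(100, 202, 500, dd = "CT"))$status, "rejected")
  expect_equal(dec(mkj(100, 202, 500, dd = "CT"))$reason,
               "noncanonical_unverified")
  ## in-frame (multiple of 3 removed) at exactly 1% is incorporated
  d <- dec(mkj(100, 202, 10))     # removes 102 exonic bases, 102 %% 3 == 0
  expect_equal(d$status, "incorporate")
  expect_equal(d$relative_frequency, 0.01)
  expect_equal(d$context, "cds_only")
  ## one read fewer is rejected as low frequency
  expect_equal(dec(mkj(100, 202, 9))$status, "rejected")
  expect_equal(dec(mkj(100, 202, 9))$reason, "low_frequency")
  ## frame-disrupting at exactly 10% incorporated with the flag
  d2 <- dec(mkj(100, 201, 100))   # removes 101 bases
  expect_equal(d2$status, "incorporate_flagged")
  expect_equal(d2$emitted_comment, "may_not_produce_functional_polypeptide")
  ## 9% frameshift rejected
  d3 <- dec(mkj(100, 201, 90))
  expect_equal(d3$status, "rejected")
  expect_equal(d3$reason, "frameshift_below_threshold")
  ## frameshift below threshold but cDNA-supported is incorporated
  expect_equal(dec(mkj(100, 201, 20), cdna_support = TRUE)$status,
               "incorporate_flagged")
  ## strand conflict errors
  bad <- mkj(100, 202, 10); bad$strand <- "-"
  expect_error(classify_junction(bad, g, counts), "strand conflicts")
})

test_that("UTR-context junctions use the 1% rule regardless of frame", {
  g <- frame_gene()
  j <- list(junction_id = "u", contig = "c", donor = 850, acceptor = 880,
            strand = "+", count = 10, source = "s",
            donor_dinucleotide = "GT", acceptor_dinucleotide = "AG")
  d <- classify_junction(j, g, c(1000, 10))
  expect_equal(d$status, "incorporate")
  expect_equal(d$context, "utr_or_ncRNA_only")
})

test_that("minor 5' UTR donor/acceptor shifts are rejected", {
  ## gene with an annotated 5' UTR intron: exons [0,50), [130,400);
  ## CDS starts at 200
  g <- gene_model("U", "c", "+",
                  list(transcript("U-RA",
                                  data.frame(start = c(0, 130),
                                             end = c(50, 400)),
                                  cds = c(200, 392))))
  mkj <- function(d, a) list(junction_id = "m", contig = "c", donor = d,
                             acceptor = a, strand = "+", count = 500,
                             source = "s", donor_dinucleotide = "GT",
                             acceptor_dinucleotide = "AG")
  ## acceptor shifted by 4 bases from the annotated 5' UTR splice
  d <- classify_junction(mkj(50, 134), g, c(1000, 500))
  expect_equal(d$reason, "minor_5utr_variant")
  ## a 20-base shift is a genuine alternative, not a minor variant
  expect_equal(classify_junction(mkj(50, 150), g, c(1000, 500))$status,
               "incorporate")
})

test_that("junctions in declared repeat regions are rejected", {
  g <- frame_gene()
  j <- list(junction_id = "r", contig = "c", donor = 100, acceptor = 202,
            strand = "+", count = 500, source = "s",
            donor_dinucleotide = "GT", acceptor_dinucleotide = "AG")
  rep_iv <- data.frame(contig = "c", start = 90, end = 250)
  expect_equal(classify_junction(j, g, c(1000, 500),
                                 repeat_regions = rep_iv)$reason,
               "repeat_region")
})

test_that("raising a read count never flips incorporate to rejected", {
  g <- frame_gene()
  set.seed(41)
  geometries <- list(c(100, 202), c(100, 201), c(850, 880))
  rank <- c(rejected = 0, incorporate = 1, incorporate_flagged = 1,
            already_represented = 1)
  for (i in 1:300) {
    geo <- geometries[[sample(3, 1)]]
    c1 <- sample(1:500, 1)
    c2 <- c1 + sample(1:500, 1)
    mk <- function(count) list(junction_id = "m", contig = "c",
                               donor = geo[1], acceptor = geo[2],
                               strand = "+", count = count, source = "s",
                               donor_dinucleotide = "GT",
                               acceptor_dinucleotide = "AG")
    s1 <- classify_junction(mk(c1), g, c(1000, c1))$status
    s2 <- classify_junction(mk(c2), g, c(1000, c2))$status
    expect_gte(rank[[s2]], rank[[s1]])
  }
})

test_that("every junction of a gene receives exactly one decision", {
  cfg <- simulation_config(seed = 19, coverage_noise = "none")
  sim <- generate_annotated_genome(cfg)
  ev <- simulate_expression_evidence(sim, cfg)
  jx <- assign_junction_to_gene(ev$junctions, sim$models)
  for (gid in unique(jx$gene_id[!is.na(jx$gene_id)])) {
    sub <- jx[!is.na(jx$gene_id) & jx$gene_id == gid, , drop = FALSE]
    dec <- triage_gene_junctions(sim$models[[gid]], sub, sim$genome)
    expect_equal(nrow(dec), nrow(sub))
    expect_setequal(dec$junction_id, sub$junction_id)
  }
})

test_that("tandem-paralog spans are screened by identity or declared pairs", {
  cfg <- simulation_config(seed = 37, n_genes = 2, n_splice_test_genes = 0,
                           n_lnc = 0, n_decoys = 0)
  sim <- generate_annotated_genome(cfg)
  ga <- sim$models[[1]]; gb <- sim$models[[2]]
  j <- list(junction_id = "t", contig = "chrS", donor = ga$end - 10,
            acceptor = gb$start + 10, strand = "+", count = 50, source = "s")
  ## unrelated genes: no artifact
  expect_false(detect_tandem_artifact(j, ga, gb, sim$genome))
  ## declared paralogs: artifact
  expect_true(detect_tandem_artifact(
    j, ga, gb, sim$genome,
    paralog_pairs = data.frame(gene_a = ga$gene_id, gene_b = gb$gene_id)))
  ## identical duplicated CDS: artifact via the k-mer screen, and the
  ## screen agrees with a local-alignment oracle at the 80% boundary
  sa <- cds_sequence(reference_isoform(ga), ga, sim$genome)
  expect_true(kmer_identity_screen(sa, sa))
  ch <- strsplit(sa, "")[[1]]
  idx <- seq(3, 200, by = 5)                   # 40 mismatches in 200 bases
  ch[idx] <- vapply(ch[idx], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  sb <- paste0(ch, collapse = "")
  expect_true(kmer_identity_screen(sa, sb))    # exactly 80% over 200
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(substr(sa, 1, 200)),
    Biostrings::DNAString(substr(sb, 1, 200)),
    type = "global", substitutionMatrix = mat, gapOpening = 10)
  oracle_identity <- Biostrings::nmatch(pa) / 200
  expect_gte(oracle_identity, 0.8)
})

test_that("merge candidates respect the tandem veto and its corroboration lift", {
  a <- simple_gene("A")
  b <- simple_gene("B", exons = data.frame(start = c(600, 900),
                                           end = c(700, 1000)),
                   cds = c(610, 993))
  models <- list(A = a, B = b)
  counts <- list(A = 1000, B = 800)
  span <- junction_table("c", 300, 650, "+", 50, source = "src1")
  jx <- assign_junction_to_gene(span, models)
  ## clean span at 5% relative frequency: candidate
  mc <- propose_merge(jx, models, counts)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$relative_frequency, 0.05)
  ## declared paralogs, single source: vetoed
  pp <- data.frame(gene_a = "A", gene_b = "B")
  expect_equal(nrow(propose_merge(jx, models, counts,
                                  paralog_pairs = pp)), 0)
  ## two sources reporting the same span lift the veto
  span2 <- junction_table("c", c(300, 300), c(650, 650), "+", c(50, 40),
                          source = c("src1", "src2"))
  jx2 <- assign_junction_to_gene(span2, models)
  mc2 <- propose_merge(jx2, models, counts, paralog_pairs = pp)
  expect_equal(nrow(mc2), 2)
  expect_true(all(mc2$tandem_rescued))
})

test_that("split proposals need a silent boundary and discordant profiles", {
  g <- gene_model("F", "c", "+", list(
    transcript("F-RA", data.frame(start = c(0, 500, 1200, 1700),
                                  end = c(300, 800, 1500, 2000)))))
  early <- flat_track("early", list(c(0, 300), c(500, 800)), 3,
                      total_mapped_reads = 1e6)
  late <- flat_track("late", list(c(1200, 1500), c(1700, 2000)), 3,
                     total_mapped_reads = 1e6)
  jt <- junction_table("c", c(300, 1500), c(500, 1700), "+", c(100, 80))
  sp <- propose_split(g, jt, list(early, late))
  expect_equal(sp$boundary, 1200)
  ## any spanning read kills the split
  jt2 <- junction_table("c", c(300, 800, 1500), c(500, 1200, 1700), "+",
                        c(100, 1, 80))
  expect_equal(nrow(propose_split(g, jt2, list(early, late))), 0)
  ## concordant profiles kill the split
  both <- flat_track("both", list(c(0, 300), c(500, 800), c(1200, 1500),
                                  c(1700, 2000)), 3, total_mapped_reads = 1e6)
  expect_equal(nrow(propose_split(g, jt, list(both, both))), 0)
  expect_error(propose_split(g, jt, list(early)), ">= 2 tracks")
})
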