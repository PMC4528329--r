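test_that("window RPKM follows the formula and its scalings", {
  tr <- flat_track("t", list(c(0, 200)), depth_for_rpkm(3))
  expect_equal(window_rpkm(tr, "c", 0, 200), 3)
  ## 6 reads in 200 bp over 10M mapped reads is RPKM 3
  tr6 <- coverage_track("t", data.frame(contig = "c", start = 0, end = 200,
                                        value = 6 * 75 / 200),
                        total_mapped_reads = 1e7, read_length = 75)
  expect_equal(window_rpkm(tr6, "c", 0, 200), 3)
  ## doubling total mapped reads halves RPKM
  tr2 <- coverage_track("t", tr$signal, total_mapped_reads = 2e7)
  expect_equal(window_rpkm(tr2, "c", 0, 200), 1.5)
  ## zero signal, zero RPKM; zero-length windows error
  expect_equal(window_rpkm(tr, "c", 5000, 5200), 0)
  expect_error(window_rpkm(tr, "c", 10, 10), "zero-length")
})

test_that("the intergenic scan recovers planted blocks and drops decoys", {
  g <- simple_gene("G1", exons = data.frame(start = 0, end = 1000),
                   cds = c(100, 901))
  models <- list(G1 = g)
  lens <- c(c = 12000)
  v <- depth_for_rpkm(5)
  ## a 600-bp block at RPKM 5 in two tracks
  t1 <- flat_track("a", list(c(3000, 3600)), v)
  t2 <- flat_track("b", list(c(3000, 3600)), v)
  regions <- scan_intergenic(models, list(t1, t2), lens)
  expect_length(regions, 1)
  expect_equal(regions[[1]]$start, 3000)
  expect_equal(regions[[1]]$end, 3600)
  expect_setequal(names(regions[[1]]$supporting_tracks), c("a", "b"))
  ## the same block in one track only is discarded
  expect_length(scan_intergenic(models, list(t1, flat_track("b", list(), v)),
                                lens), 0)
  ## flat signal below threshold is never called
  low1 <- flat_track("a", list(c(0, 12000)), depth_for_rpkm(2.9))
  low2 <- flat_track("b", list(c(0, 12000)), depth_for_rpkm(2.9))
  expect_length(scan_intergenic(models, list(low1, low2), lens), 0)
  expect_error(scan_intergenic(models, list(), lens), "requires")
})

test_that("scan output never overlaps an annotated gene extent", {
  cfg <- simulation_config(seed = 29, coverage_noise = "none")
  sim <- generate_annotated_genome(cfg)
  ev <- simulate_expression_evidence(sim, cfg)
  regions <- scan_intergenic(sim$models, ev$tracks, sim$contig_lengths)
  for (r in regions) for (g in sim$models)
    expect_false(intervals_overlap(r$start, r$end, g$start, g$end))
})

test_that("strand assignment follows the stranded-signal fraction", {
  mk <- function(pfrac) {
    tot <- 100
    flat_track("s", if (pfrac > 0) list(c(0, 600)) else list(),
               pfrac * tot / 600 + 1e-12, strandedness = "stranded",
               minus_blocks = if (pfrac < 1) list(c(0, 600)),
               total_mapped_reads = 1e7)
  }
  region <- list(contig = "c", start = 0, end = 600)
  strand_of <- function(pv, mv) {
    tr <- coverage_track("s",
                         data.frame(contig = "c", start = 0, end = 600,
                                    value = pv),
                         minus_signal = data.frame(contig = "c", start = 0,
                                                   end = 600, value = mv),
                         strandedness = "stranded")
    assign_strand(region, list(tr))$strand
  }
  expect_equal(strand_of(10, 0), "+")
  expect_equal(strand_of(0, 10), "-")
  expect_true(is.na(strand_of(5, 5)))
  expect_equal(strand_of(85, 15), "+")      # 0.85 >= default 0.8
  expect_true(is.na(strand_of(75, 25)))
})

test_that("candidate classification separates antisense, extension, and new", {
  up <- simple_gene("UP", exons = data.frame(start = 1000, end = 2000),
                    cds = c(1100, 1601))
  anti <- simple_gene("AS", strand = "-",
                      exons = data.frame(start = 5000, end = 6000),
                      cds = c(5100, 5601))
  models <- list(UP = up, AS = anti)
  mkreg <- function(s, e, strand = "+", tracks = c("a", "b"))
    list(contig = "c", start = s, end = e, strand = strand,
         supporting_tracks = setNames(rep(5, length(tracks)), tracks))
  v <- depth_for_rpkm(5)
  ta <- flat_track("a", list(c(1100, 3000)), v)
  tb <- flat_track("b", list(c(1100, 3000)), v)
  ## opposite-strand overlap: antisense, SO term recorded
  r <- classify_candidate(mkreg(5200, 5800, "+"), models, list(ta, tb))
  expect_equal(r$classification, "antisense_lncRNA")
  expect_equal(r$antisense_of, "AS")
  expect_equal(r$so_term, "SO:0000077")
  ## contiguous coverage from the upstream stop codon: 3' UTR extension
  r2 <- classify_candidate(mkreg(2400, 3000, "+"), models, list(ta, tb))
  expect_equal(r2$classification, "utr3_extension_of:UP")
  ## contiguity plus an independent validated TSS: dual entity
  sig <- numeric(10); sig[5] <- 50
  own <- tss_region("c", 2400, 2410, sig, "+", c("approach_1", "approach_2"))
  r3 <- classify_candidate(mkreg(2400, 3000, "+"), models, list(ta, tb),
                           tss_regions = list(own))
  expect_equal(r3$classification, "dual_entity")
  expect_equal(r3$emitted_comment, "lncRNA_from_3utr")
  ## isolated block: new lncRNA with the probable-lncRNA comment
  tiso <- flat_track("a", list(c(8000, 8600)), v)
  tiso2 <- flat_track("b", list(c(8000, 8600)), v)
  r4 <- classify_candidate(mkreg(8000, 8600, "+"), models,
                           list(tiso, tiso2), tss_regions = list(own))
  expect_equal(r4$classification, "new_lncRNA")
  expect_equal(r4$emitted_comment, "probable_lncRNA")
  ## unresolved strand stays unclassified
  r5 <- classify_candidate(mkreg(8000, 8600, NA_character_), models,
                           list(tiso, tiso2))
  expect_equal(r5$classification, "unresolved")
})

test_that("a sub-threshold gap breaks 3' extension contiguity", {
  up <- simple_gene("UP", exons = data.frame(start = 1000, end = 2000),
                    cds = c(1100, 1601))
  v <- depth_for_rpkm(5)
  ## coverage with a 150-bp hole between the gene end and the region
  ta <- flat_track("a", list(c(1100, 2100), c(2250, 3000)), v)
  tb <- flat_track("b", list(c(1100, 2100), c(2250, 3000)), v)
  r <- classify_candidate(
    list(contig = "c", start = 2400, end = 3000, strand = "+",
         supporting_tracks = c(a = 5, b = 5)),
    list(UP = up), list(ta, tb))
  expect_equal(r$classification, "new_lncRNA")
})

test_that("poly(A) 3' ends cluster at 10 bases and order does not matter", {
  ex <- data.frame(start = 0, end = 1000)
  tx <- transcript("t1", ex, cds = c(100, 400))
  g <- gene_model("G1", "c", "+", list(tx))
  mk <- function(id, e) cdna_alignment(id, "c",
                                       data.frame(start = 50, end = e), "+",
                                       polyadenylated = TRUE)
  ## within 10 bases: one terminus at the 3'-most
  r <- set_three_prime_end(tx, g, list(mk("a", 500), mk("b", 508)))
  expect_length(r$transcripts, 1)
  expect_equal(r$transcripts[[1]]$exons$end[1], 508)
  expect_equal(r$transcripts[[1]]$three_prime_evidence, "polyA_cdna")
  ## 15 bases apart: two isoforms
  r2 <- set_three_prime_end(tx, g, list(mk("a", 500), mk("b", 515)))
  expect_length(r2$transcripts, 2)
  expect_setequal(vapply(r2$transcripts, function(t) t$exons$end[1],
                         numeric(1)), c(500, 515))
  ## order invariance over permuted inputs
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  cds_in <- list(mk("a", 500), mk("b", 508), mk("d", 530))
  ref <- set_three_prime_end(tx, g, cds_in)
  for (p in perms)
    expect_identical(set_three_prime_end(tx, g, cds_in[p])$transcripts,
                     ref$transcripts)
  ## no cDNA, no coverage: stop-codon fallback
  r3 <- set_three_prime_end(tx, g, list())
  expect_equal(r3$transcripts[[1]]$exons$end[1], 400)
  expect_equal(r3$transcripts[[1]]$three_prime_evidence,
               "stop_codon_fallback")
  ## coverage beyond the stop: coverage estimate at the covered end
  cov <- flat_track("cov", list(c(0, 700)), 2)
  r4 <- set_three_prime_end(tx, g, list(), list(cov))
  expect_equal(r4$transcripts[[1]]$exons$end[1], 700)
  expect_equal(r4$transcripts[[1]]$three_prime_evidence, "coverage_estimate")
})

test_that("minus-strand 3' ends mirror the plus-strand rules", {
  ex <- data.frame(start = 0, end = 1000)
  tx <- transcript("t1", ex, cds = c(600, 900))
  g <- gene_model("G1", "c", "-", list(tx))
  mk <- function(id, s) cdna_alignment(id, "c",
                                       data.frame(start = s, end = 950), "-",
                                       polyadenylated = TRUE)
  r <- set_three_prime_end(tx, g, list(mk("a", 500), mk("b", 493)))
  expect_length(r$transcripts, 1)
  expect_equal(r$transcripts[[1]]$exons$start[1], 493)
})
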