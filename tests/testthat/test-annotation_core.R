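test_that("genomic intervals enforce the half-open convention", {
  iv <- genomic_interval("chr1", 0, 10, "+")
  expect_equal(interval_width(iv), 10)
  expect_error(genomic_interval("chr1", 10, 10), "invalid interval")
  expect_error(genomic_interval("chr1", -1, 10), "invalid interval")
  expect_error(genomic_interval("chr1", 5, 10, "x"), "strand")
})

test_that("gene model invariants are enforced", {
  expect_error(transcript("t", data.frame(start = c(0, 90), end = c(100, 200))),
               "introns")
  expect_error(transcript("t", data.frame(start = 0, end = 100),
                          cds = c(10, 60)), "multiple of 3")
  expect_error(gene_model("g", "c", "*",
                          list(transcript("t", data.frame(start = 0, end = 9)))),
               "stranded")
  expect_error(gene_model("g", "c", "+",
                          list(transcript("t", data.frame(start = 0, end = 9))),
                          biotype = "antisense_lncRNA"),
               "antisense")
})

test_that("GFF3 coordinates convert exactly at the boundary", {
  lines <- c("##gff-version 3",
             "c\tx\tgene\t100\t200\t.\t+\t.\tID=g1;biotype=lncRNA",
             "c\tx\tncRNA\t100\t200\t.\t+\t.\tID=t1;Parent=g1",
             "c\tx\texon\t100\t200\t.\t+\t.\tID=e1;Parent=t1")
  m <- read_gene_models(lines)
  expect_equal(m$g1$start, 99)
  expect_equal(m$g1$end, 200)
  expect_equal(m$g1$transcripts[[1]]$exons$start, 99)
})

test_that("empty GFF3 gives an empty collection and vice versa", {
  expect_length(read_gene_models("##gff-version 3"), 0)
  expect_equal(write_gene_models(list()), "##gff-version 3")
})

test_that("a one-transcript one-exon model writes three feature lines", {
  g <- gene_model("g", "c", "+",
                  list(transcript("t", data.frame(start = 0, end = 300))),
                  biotype = "lncRNA")
  lines <- write_gene_models(list(g = g))
  expect_length(lines, 4)   # header + gene + ncRNA + exon
})

test_that("orphan child features raise a structured parse error", {
  lines <- c("##gff-version 3",
             "c\tx\tmRNA\t100\t200\t.\t+\t.\tID=t1;Parent=missing")
  expect_error(read_gene_models(lines), "orphan")
})

test_that("GFF3 round-trip is lossless on generated model sets", {
  cfg <- simulation_config(seed = 42, n_genes = 6, n_lnc = 0, n_decoys = 0)
  sim <- generate_annotated_genome(cfg)
  sim$models[[1]]$comments <- c("probable_lncRNA", "low_frequency_junctions")
  sim$models[[2]]$transcripts[[1]]$comments <- "may_not_produce_functional_polypeptide"
  lines <- write_gene_models(sim$models)
  back <- read_gene_models(lines)
  expect_setequal(names(back), names(sim$models))
  for (gid in names(sim$models)) {
    a <- sim$models[[gid]]; b <- back[[gid]]
    expect_equal(b$strand, a$strand)
    expect_equal(b$biotype, a$biotype)
    expect_equal(b$comments, a$comments)
    for (k in seq_along(a$transcripts)) {
      expect_equal(b$transcripts[[k]]$exons, a$transcripts[[k]]$exons)
      expect_equal(b$transcripts[[k]]$cds, a$transcripts[[k]]$cds)
      expect_equal(b$transcripts[[k]]$comments, a$transcripts[[k]]$comments)
    }
  }
  ## read-write idempotence
  expect_identical(write_gene_models(back), lines)
})

test_that("unknown comment codes are preserved but flagged", {
  g <- gene_model("g", "c", "+",
                  list(transcript("t", data.frame(start = 0, end = 300))))
  lines <- write_gene_models(list(g = g))
  lines[2] <- sub("biotype=protein_coding",
                  "biotype=protein_coding;curation_comments=mystery_code",
                  lines[2])
  expect_warning(m <- read_gene_models(lines), "unrecognized")
  expect_true("mystery_code" %in% m$g$comments)
})

test_that("bedGraph coverage sums match a per-base oracle", {
  trk <- read_coverage("chr1\t0\t200\t5", "t")
  expect_equal(track_interval_sum(trk, "chr1", 0, 200), 1000)
  ## random run-length signal vs per-base expansion
  set.seed(11)
  for (rep in 1:20) {
    n <- 12
    starts <- sort(sample(0:400, n))
    ends <- starts + sample(1:60, n, replace = TRUE)
    vals <- sample(0:8, n, replace = TRUE)
    trk <- coverage_track("r", data.frame(contig = "c", start = starts,
                                          end = ends, value = vals))
    per_base <- numeric(1000)
    for (i in seq_len(n))
      per_base[(starts[i] + 1):ends[i]] <-
        per_base[(starts[i] + 1):ends[i]] + vals[i]
    qs <- sort(sample(0:500, 2))
    expect_equal(track_interval_sum(trk, "c", qs[1], qs[2]),
                 sum(per_base[(qs[1] + 1):qs[2]]))
  }
})

test_that("malformed bedGraph records are rejected with a line number", {
  expect_error(read_coverage("chr1\t10\t5\t2", "t"), "line 1")
  expect_error(read_coverage(c("chr1\t0\t5\t2", "chr1\t5\t9\t-1"), "t"),
               "line 2")
})

test_that("interval overlap queries agree with an exhaustive pairwise oracle", {
  set.seed(99)
  a <- data.frame(start = sample(0:900, 300, TRUE))
  a$end <- a$start + sample(1:80, 300, TRUE)
  b <- data.frame(start = sample(0:900, 200, TRUE))
  b$end <- b$start + sample(1:80, 200, TRUE)
  hits <- interval_overlaps(a, b)
  brute <- which(outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j)
    a$start[i] < b$end[j] & b$start[j] < a$end[i]), arr.ind = TRUE)
  got <- paste(hits$query_idx, hits$subject_idx)
  want <- paste(brute[, 1], brute[, 2])
  expect_setequal(got, want)
})

test_that("junction TSVs and coverage lanes round-trip through their writers", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("contig\tdonor\tacceptor\tstrand\tcount\tsource",
               "c\t300\t400\t+\t57\trnaseq_a"), tf)
  jt <- read_junctions(tf)
  expect_equal(jt$donor, 300)
  expect_equal(jt$count, 57)
  expect_equal(jt$junction_id, "c:300-400(+):rnaseq_a")
  trk <- coverage_track("t", data.frame(contig = "c", start = c(0, 50),
                                        end = c(10, 70), value = c(2, 5)))
  lines <- write_coverage(trk)
  back <- read_coverage(lines, "t")
  expect_equal(back$signal, trk$signal)
})
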