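test_that("a fixed seed reproduces the genome and models byte for byte", {
  cfg <- simulation_config(seed = 5, n_genes = 4, n_lnc = 1, n_decoys = 1)
  a <- generate_annotated_genome(cfg)
  b <- generate_annotated_genome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(write_gene_models(a$models), write_gene_models(b$models))
  ea <- simulate_expression_evidence(a, cfg)
  eb <- simulate_expression_evidence(b, cfg)
  expect_identical(ea$junctions, eb$junctions)
  expect_identical(lapply(ea$tracks, `[[`, "signal"),
                   lapply(eb$tracks, `[[`, "signal"))
})

test_that("zero genes yields a genome with an empty model set", {
  cfg <- simulation_config(seed = 2, n_genes = 0, n_splice_test_genes = 0,
                           n_lnc = 0, n_decoys = 0, genome_length = 5000)
  sim <- generate_annotated_genome(cfg)
  expect_length(sim$models, 0)
  expect_gte(nchar(sim$genome), 5000)
})

test_that("an undersized genome request is refused", {
  cfg <- simulation_config(seed = 2, n_genes = 30, genome_length = 20000)
  expect_error(generate_annotated_genome(cfg), "too small")
})

test_that("every generated CDS translates without internal stops", {
  cfg <- simulation_config(seed = 17, n_genes = 8)
  sim <- generate_annotated_genome(cfg)
  for (g in sim$models) {
    aa <- translate_cds(cds_sequence(g$transcripts[[1]], g, sim$genome))
    expect_equal(substr(aa, 1, 1), "M")
    expect_false(grepl("*", aa, fixed = TRUE))
  }
})

test_that("generated introns and planted junctions carry canonical dinucleotides", {
  cfg <- simulation_config(seed = 23, n_genes = 6)
  sim <- generate_annotated_genome(cfg)
  tj <- sim$truth$junctions
  for (i in seq_len(nrow(tj))) {
    dn <- intron_dinucleotides(sim$genome, tj$contig[i], tj$donor[i],
                               tj$acceptor[i], tj$strand[i])
    expect_equal(dn, c("GT", "AG"))
  }
})

test_that("planted junction counts hit the planned relative frequencies", {
  cfg <- simulation_config(seed = 31)
  sim <- generate_annotated_genome(cfg)
  tj <- sim$truth$junctions
  for (gid in unique(tj$gene_id[tj$gene_id %in%
                                  tj$gene_id[!tj$annotated]])) {
    sub <- tj[tj$gene_id == gid, ]
    m <- max(sub$count)
    novel <- sub[!sub$annotated, ]
    rf <- novel$count / m
    expect_equal(sum(rf == 0.01), 1)          # exactly at the 1% bound
    expect_equal(sum(rf < 0.01), 1)           # just below it
    expect_equal(sum(rf == 0.10), 1)          # exactly at the 10% bound
    expect_equal(sum(rf > 0.05 & rf < 0.10), 1)
  }
})

test_that("the recomputed 90% point of each emitted TSS region matches truth", {
  cfg <- simulation_config(seed = 13)
  sim <- generate_annotated_genome(cfg)
  ev <- simulate_expression_evidence(sim, cfg)
  for (i in seq_along(ev$tss_regions)) {
    expect_equal(tss_90_percent_point(ev$tss_regions[[i]]),
                 sim$truth$tss$point[i])
  }
})

test_that("a zero-depth track plan entry yields all-zero coverage", {
  cfg <- simulation_config(seed = 3, n_genes = 2, n_lnc = 0, n_decoys = 0,
                           expressed_rpkm = 0, coverage_noise = "none")
  sim <- generate_annotated_genome(cfg)
  ev <- simulate_expression_evidence(sim, cfg)
  for (tr in ev$tracks) {
    expect_equal(nrow(tr$signal), 0)
  }
})

test_that("conserved ortholog sets pass and diverged unconstrained sets fail", {
  cfg <- simulation_config(seed = 7, n_genes = 1, n_lnc = 0, n_decoys = 0)
  sim <- generate_annotated_genome(cfg)
  cds <- cds_sequence(sim$models[[1]]$transcripts[[1]], sim$models[[1]],
                      sim$genome)
  expect_error(simulate_ortholog_set(cds, 2, 1.5), "divergence")
  expect_error(simulate_ortholog_set(substr(cds, 1, 10), 2, 0.1),
               "multiple of 3")
  ## divergence 0: identical
  os0 <- simulate_ortholog_set(cds, 2, 0, seed = 1, conserve = TRUE)
  expect_true(all(vapply(os0, function(a) a$seq == cds, logical(1))))
  ## conserve = TRUE always passes the downstream check
  for (s in 1:20)
    expect_true(assess_orf_conservation(
      simulate_ortholog_set(cds, 3, 0.1, seed = s, conserve = TRUE)))
  ## conserve = FALSE at divergence 0.3 fails nearly always
  fails <- vapply(1:200, function(s)
    !assess_orf_conservation(
      simulate_ortholog_set(cds, 3, 0.3, seed = s, conserve = FALSE)),
    logical(1))
  expect_gte(mean(fails), 0.95)
})

test_that("empty lesion specs leave the genome untouched", {
  cfg <- simulation_config(seed = 4, n_genes = 3, n_lnc = 0, n_decoys = 0)
  sim <- generate_annotated_genome(cfg)
  inj <- inject_lesions(sim, data.frame(lesion_type = character(0),
                                        count = integer(0)), seed = 1)
  expect_identical(inj$genome, sim$genome)
  expect_equal(nrow(inj$truth), 0)
})

test_that("planted nonsense codons translate to stops; frameshifts shift frame", {
  cfg <- simulation_config(seed = 9, n_genes = 4, n_lnc = 0, n_decoys = 0)
  sim <- generate_annotated_genome(cfg)
  inj <- inject_lesions(sim, data.frame(
    lesion_type = c("nonsense", "frameshift_indel"), count = c(1, 1)),
    seed = 8)
  non <- inj$truth[inj$truth$lesion_type == "nonsense", ]
  cds <- inj$strain_cds[[non$gene_id]]
  codon_idx <- (non$position - 1) %/% 3 + 1
  aa <- translate_cds(cds, trim_stop = FALSE)
  expect_equal(substr(aa, codon_idx, codon_idx), "*")
  fs <- inj$truth[inj$truth$lesion_type == "frameshift_indel", ]
  ref <- cds_sequence(sim$models[[fs$gene_id]]$transcripts[[1]],
                      sim$models[[fs$gene_id]], sim$genome)
  expect_equal((nchar(ref) - nchar(inj$strain_cds[[fs$gene_id]])) %% 3, 1)
})

test_that("lesion counts beyond the gene pool are refused", {
  cfg <- simulation_config(seed = 4, n_genes = 2, n_lnc = 0, n_decoys = 0)
  sim <- generate_annotated_genome(cfg)
  expect_error(inject_lesions(sim, data.frame(lesion_type = "nonsense",
                                              count = 5), seed = 1),
               "exceeds")
})
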