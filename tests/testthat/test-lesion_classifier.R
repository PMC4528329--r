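ref_cds_fixture <- function(seed = 1, n_codons = 120) {
  set.seed(seed)
  ok <- setdiff(mkAllTriplets(), c("TAA", "TAG", "TGA"))
  paste0("ATG", paste(sample(ok, n_codons - 2, TRUE), collapse = ""), "TAA")
}
mkAllTriplets <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
}

test_that("identical sequences yield no lesions", {
  cds <- ref_cds_fixture(2)
  expect_equal(nrow(detect_lesions(cds, cds)), 0)
})

test_that("a single substitution creating an in-frame stop is nonsense", {
  cds <- ref_cds_fixture(3)
  ## force codon 50 to CAA, then mutate C->T in the strain: TAA
  substr(cds, 148, 150) <- "CAA"
  strain <- cds
  substr(strain, 148, 148) <- "T"
  les <- detect_lesions(cds, strain)
  expect_equal(nrow(les), 1)
  expect_equal(les$lesion_type, "nonsense")
  expect_equal(les$position, 148)
  expect_true(les$disabling)
  ## oracle: the strain translation has a stop at codon 50
  aa <- translate_cds(strain, trim_stop = FALSE)
  expect_equal(substr(aa, 50, 50), "*")
})

test_that("indels are typed by their length modulo 3", {
  cds <- ref_cds_fixture(4)
  ## 2-bp deletion: frameshift
  strain2 <- paste0(substr(cds, 1, 150), substr(cds, 153, nchar(cds)))
  les2 <- detect_lesions(cds, strain2)
  expect_equal(les2$lesion_type, "frameshift_indel")
  ## 9-bp in-frame deletion: deletion
  strain9 <- paste0(substr(cds, 1, 150), substr(cds, 160, nchar(cds)))
  les9 <- detect_lesions(cds, strain9)
  expect_equal(les9$lesion_type, "deletion")
  expect_true(les9$disabling)
})

test_that("start-codon substitutions and splice/transposon overlays are typed", {
  cds <- ref_cds_fixture(5)
  strain <- cds; substr(strain, 1, 1) <- "G"
  les <- detect_lesions(cds, strain)
  expect_equal(les$lesion_type[1], "start_codon_loss")
  ss <- data.frame(site = "i1", ref_dinucleotide = "GT",
                   strain_dinucleotide = "GA", position = 300)
  les2 <- detect_lesions(cds, cds, splice_sites = ss)
  expect_equal(les2$lesion_type, "splice_site_point")
  tp <- data.frame(position = c(60, 90), location = c("cds", "intron"))
  les3 <- detect_lesions(cds, cds, transposons = tp)
  expect_equal(les3$lesion_type, rep("transposon_insertion", 2))
  expect_equal(les3$disabling, c(TRUE, FALSE))
})

test_that("gene integrity follows the two-lesion rule", {
  one <- data.frame(lesion_type = "nonsense", position = 10,
                    disabling = TRUE)
  two <- rbind(one, data.frame(lesion_type = "frameshift_indel",
                               position = 200, disabling = TRUE))
  none <- one[0, ]
  tp_only <- data.frame(lesion_type = "transposon_insertion", position = 5,
                        disabling = FALSE)
  expect_equal(classify_gene_integrity(list(iso = none), "iso")$call,
               "wild_type")
  expect_equal(classify_gene_integrity(list(iso = tp_only), "iso")$call,
               "possible_mutation_in_strain")
  r1 <- classify_gene_integrity(list(iso = one), "iso")
  expect_equal(r1$call, "mutation_in_strain")
  expect_equal(r1$emitted_comment, "mutation_in_strain")
  ## two disabling lesions in every strain: pseudogene
  r2 <- classify_gene_integrity(list(iso = two, wild = two), "iso")
  expect_equal(r2$call, "pseudogene")
  expect_equal(r2$emitted_comment, "pseudogene_parental")
  ## two lesions in the annotated strain, a clean second strain:
  ## polymorphic pseudogene
  r3 <- classify_gene_integrity(list(iso = two, wild = none), "iso")
  expect_equal(r3$call, "polymorphic_pseudogene")
  expect_error(classify_gene_integrity(list(iso = two), "other"), "absent")
})

test_that("integrity is monotone in the number of disabling lesions", {
  les <- data.frame(lesion_type = "nonsense", position = c(10, 100, 250),
                    disabling = TRUE)
  sev <- c(wild_type = 0, possible_mutation_in_strain = 0,
           mutation_in_strain = 1, polymorphic_pseudogene = 2,
           pseudogene = 2)
  calls <- vapply(0:3, function(k)
    classify_gene_integrity(list(iso = les[seq_len(k), , drop = FALSE]),
                            "iso")$call, character(1))
  expect_true(all(diff(sev[calls]) >= 0))
})

test_that("the wild-type polypeptide is restored over the lesions only", {
  cds <- ref_cds_fixture(6)
  ## nonsense lesion plus a harmless synonymous-ish substitution
  substr(cds, 148, 150) <- "CAA"
  strain <- cds
  substr(strain, 148, 148) <- "T"         # the lesion
  substr(strain, 300, 300) <- if (substr(strain, 300, 300) == "A") "G" else "A"
  fix1 <- restore_wild_type_protein(cds, strain, "mutation_in_strain")
  ref_aa <- translate_cds(cds)
  expect_equal(nchar(fix1$polypeptide), nchar(ref_aa))
  expect_false(grepl("*", fix1$polypeptide, fixed = TRUE))
  ## the neutral substitution at base 300 is retained (codon 100)
  expect_equal(fix1$transcript_cds, strain)
  ## wild-type genes pass through unchanged
  fix2 <- restore_wild_type_protein(cds, cds, "wild_type")
  expect_equal(fix2$polypeptide, ref_aa)
  ## frameshift restoration recovers the reference translation
  strainfs <- paste0(substr(cds, 1, 200), substr(cds, 202, nchar(cds)))
  fix3 <- restore_wild_type_protein(cds, strainfs, "mutation_in_strain")
  expect_equal(fix3$polypeptide, ref_aa)
  expect_error(restore_wild_type_protein("", strainfs, "mutation_in_strain"),
               "unresolvable")
})

test_that("injected lesions are recovered with exact type and position", {
  cfg <- simulation_config(seed = 61, n_genes = 9, n_splice_test_genes = 0,
                           n_lnc = 0, n_decoys = 0, genome_length = 60000)
  sim <- generate_annotated_genome(cfg)
  spec <- data.frame(lesion_type = c("nonsense", "frameshift_indel",
                                     "deletion", "start_codon_loss",
                                     "splice_site_point",
                                     "transposon_insertion", "complex"),
                     count = c(1, 1, 1, 1, 1, 1, 1))
  inj <- inject_lesions(sim, spec, seed = 21)
  for (gid in unique(inj$truth$gene_id)) {
    g <- sim$models[[gid]]
    ref <- cds_sequence(g$transcripts[[1]], g, sim$genome)
    det <- detect_lesions(ref, inj$strain_cds[[gid]],
                          splice_sites = inj$splice_sites[[gid]],
                          transposons = inj$transposons[[gid]])
    tr <- inj$truth[inj$truth$gene_id == gid, ]
    expect_equal(det[order(det$position),
                     c("lesion_type", "position", "disabling")],
                 tr[order(tr$position),
                    c("lesion_type", "position", "disabling")],
                 ignore_attr = TRUE)
  }
})
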