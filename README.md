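# annotriage

Evidence-based triage of gene model annotations against high-throughput
transcriptome data, in R.

## The problem

Manually curated genome annotations — the *Drosophila melanogaster* gene
model set is the archetype — are maintained by weighing heterogeneous
evidence: RNA-Seq coverage (stranded and unstranded), splice-junction read
counts, transcription start site (TSS) signal distributions, polyadenylated
cDNA/EST alignments, ortholog sequences, and strain-specific genomic
variants. Each curation decision follows explicit quantitative rules, but
published tooling for the rules themselves is scarce. `annotriage`
implements those rules as a deterministic, configurable pipeline, together
with a seeded synthetic-data generator that emulates each evidence type
with a ground-truth table, so that every classifier can be validated by
recovery of what was planted.

## The rules at its core

* **TSS refinement.** A mapped start region is *validated* when supported
  by ≥ 2 of 3 independent approaches. The annotated start is the **90%
  point**: the 5′-most base *p* at which the cumulative start signal,
  summed from the 3′-most signal-bearing base moving 5′, first reaches
  0.9 · Σs. Evidence precedence for a transcript 5′ end:
  validated 90% point > short-capped/promoter-profiling signal > 5′-most
  cDNA > coverage estimate > translation start (no 5′ UTR).
* **Junction triage.** For a junction *j* in gene *g*, the relative
  frequency is f = count(j) / max count over *g*'s junctions. A novel
  junction is incorporated when f ≥ 1%; if it disrupts the reading frame
  of the longest-CDS isoform, the bar rises to f ≥ 10% (or corroborating
  cDNA), and the new isoform carries a "may or may not produce functional
  polypeptide" flag. Noncanonical boundaries (outside GT–AG, GC–AG,
  AT–AC) without cDNA support, tandem-paralog spans (≥ 80% CDS identity
  over 200 bp, k-mer screen), declared repeat regions, and ≤ 6-base 5′ UTR
  donor/acceptor shifts are rejected with machine-readable reasons.
  Same-strand junctions spanning two genes propose merges; silent internal
  boundaries with discordant per-side RPKM profiles (Pearson r < 0.5)
  propose splits.
* **Intergenic scan.** 200-bp windows across unannotated space qualify at
  RPKM ≥ 3 (RPKM = reads · 10⁹ / (length · mapped reads)); qualifying
  windows sharing ≥ 2 supporting tracks merge into candidate regions,
  strand is assigned when ≥ 80% of stranded signal agrees, and candidates
  are classified as new lncRNA, antisense gene (SO:0000077), 3′-UTR
  extension of the upstream gene, or a dual entity.
* **3′ ends.** Polyadenylated-cDNA termini within 10 bases collapse to the
  3′-most position; termini further apart become distinct isoforms;
  coverage beyond the longest cDNA extends one transcript; otherwise the
  stop codon is the terminus.
* **Coding assessment.** The longest ATG-initiated ORF is called coding
  above 50 aa outright, and in (30, 50] aa only when conserved across
  close-relative orthologs (initiator Met kept, no in-frame stops, no
  frame-breaking indels).
* **Lesions and pseudogenes.** Strain-vs-reference CDS differences are
  typed (start-codon loss, splice-site point, nonsense, frameshift indel,
  in-frame deletion, transposon insertion, complex). One disabling lesion
  marks a coding gene "mutation in sequenced strain" (its polypeptide is
  restored to wild type); **two** disabling lesions make a pseudogene —
  unless another strain is clean, which makes a polymorphic pseudogene.
* **Splice graphs.** Exonic segments split at every splice boundary form a
  DAG; isoform counts are exact promoter→terminal path counts, and a
  minimal greedy representative transcript set covers every promoter and
  accepted CDS splice, with a "not all combinations annotated" comment
  when the possible count exceeds the emitted set.
* **Sex bias.** Binned exonic RPKM across sex-labelled tracks classifies
  genes as male/female-specific (opposite sex below RPKM 1, own sex ≥ 5),
  biased, unbiased, or excluded for low expression, with gonad-free
  re-evaluation and a > 72-kb long-extent lncRNA flag.

## Worked example

The gene *AnxB9* is the classic illustration of the "permutation problem":
RNA-Seq junctions support eight alternative donors from three leading 5′
exons (four annotated) and four last-intron acceptor choices (three
annotated, one excluded low-frequency junction).

```r
library(annotriage)
ex <- anxb9_example()
ex$graph
#> splice_graph AnxB9: 13 node(s), 20 edge(s), 3 promoter(s), 1 terminal(s)
count_isoforms(ex$graph, "annotated_only")
#> [1] 12
count_isoforms(ex$graph, "all")
#> [1] 32
```

Twelve isoforms are possible through the annotated splice choices alone
(4 donors × 3 acceptors); admitting every observed junction raises that to
32 (8 × 4) — which is why only a representative subset
(`select_representative_isoforms()` emits 4 transcripts here) is annotated.

A full synthetic run, with every planted feature recovered:

```r
cfg <- simulation_config(seed = 1, coverage_noise = "none")
sim <- generate_annotated_genome(cfg)
ev  <- simulate_expression_evidence(sim, cfg)
res <- run_pipeline(sim$models,
                    list(tracks = ev$tracks, junctions = ev$junctions,
                         tss_regions = ev$tss_regions, cdnas = ev$cdnas),
                    sim$genome)
res$summary$junctions
#> already_represented         incorporate incorporate_flagged            rejected
#>                  23                   4                   4                   8
res$summary$new_genes
#> [1] 4
res$summary$sex_bias
#> female_specific   male_specific        unbiased
#>               2               8               4
```

The 39 junctions partition exactly as planted: 23 match annotated introns,
4 in-frame junctions at the 1% bound and 4 frame-disrupting junctions at
the 10% bound are incorporated, and 8 sub-threshold junctions are rejected
(4 `low_frequency`, 4 `frameshift_below_threshold`). The four intergenic
transcription blocks planted at RPKM 5 in two stranded tracks become new
lncRNA genes; the four decoys do not.

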