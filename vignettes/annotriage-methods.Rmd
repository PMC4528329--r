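---
title: "Curation rules, parameters, and design choices in annotriage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curation rules, parameters, and design choices in annotriage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(annotriage)
```

# Scope and model of the data

`annotriage` treats genome annotation curation as a set of deterministic
triage rules over an annotation state and an evidence bundle. A *gene
model* is the set of transcripts and coding regions annotated for a gene;
evidence comes as coverage tracks (run-length per-base depth with track
metadata), splice junctions with read counts, per-base TSS start-signal
regions, cDNA/EST alignments with a polyadenylation flag, aligned ortholog
CDS sets, and strain CDS sequences with feature overlays. All internal
coordinates are 0-based half-open; GFF3 I/O converts at the boundary
(gff_start = internal_start + 1, gff_end = internal_end), and
bedGraph/BED coordinates pass through unchanged. A single convention
internally eliminates off-by-one drift between formats.

Every gene model is stranded; `"*"` is permitted only on evidence.
Comments attached to genes and transcripts come from a closed, versioned
vocabulary (`comment_vocabulary()`); unknown codes read from GFF3 are
preserved verbatim but flagged, since the upstream comment table is not
reproduced in full here.

# Stage-by-stage procedure

## Transcript 5′ ends

A TSS region is *validated* when at least two of the three mapping
approaches support it; single-approach regions are retained but never used
to set a start. The annotated start of a region is its **90% point**:
moving from the 3′-most signal-bearing base toward 5′, the first base at
which the cumulative fraction of start signal reaches 0.9. "Reaches" is
read as *first cumulative fraction ≥ 0.9*, with ties resolving toward the
3′ side — the least-extended start. The rule exists to exclude
nonrepresentative 5′ outliers, so overshooting 5′ward would defeat its
purpose. On the minus strand the traversal reverses; the strand-reflection
symmetry (reflecting the region maps the 90% point by coordinate
reflection) is property-tested.

Evidence precedence for a transcript start is fixed: validated 90% point,
then short-capped RNA / promoter-profiling starts, then the 5′-most cDNA,
then robust coverage, then the translation start (leaving no 5′ UTR, with
a comment). A region is *applicable* to a transcript when it overlaps the
first exon or ends within 500 bp upstream (`tss_upstream_window`); the
source material states no window, so this is a declared package choice.
Closely spaced alternative starts are represented by the single discrete
90% point of their region, mirroring the policy of annotating clustered
initiation to one location (`tss_cluster_radius`, default 10 bp). A
validated region only refines transcripts here; seeding brand-new
transcripts from TSS regions alone is left to the intergenic machinery
(which accepts TSS regions as dual-entity evidence), since the upstream
practice for TSS-only gene creation is not specified.

## Junction triage

Junction frequency is read-count based: count divided by the maximum
junction count within the gene — the only quantitative definition the
source rules offer. Denominators always use the *input* (pre-update)
junction set of the pass, so decisions are order-independent within a run.
The decision cascade is: exact annotated-intron match; declared repeat
regions; noncanonical boundary dinucleotides without cDNA corroboration;
tandem-paralog artifact (vetoed unless a second independent source or a
cDNA agrees); minor 5′ UTR shift (≤ 6 bases, `minor_utr_shift` — "a few
bases" made concrete); then the frequency rules — 10% for frame-disrupting
CDS junctions, 1% otherwise. Thresholds are inclusive: exactly 1% (or 10%)
is incorporated, one read fewer is not, and status is monotone in read
count.

Frame disruption is evaluated against the longest-CDS isoform (the
reference isoform for frame tests, since no reference isoform is defined
upstream): the novel intron excises the exonic bases it covers, and the
junction is frame-disrupting when the excised CDS-exonic length is not a
multiple of 3, or (when a genome is supplied) when the altered CDS gains a
premature stop. Rejection for "low frequency in very highly expressed
genes" is folded into the relative 1% rule rather than an absolute-depth
rule; an absolute rule would need a depth normalisation the rules never
state.

The tandem screen is the package's own k-mer seed (k = 12) plus ungapped
window scan: any seeded diagonal containing a 200-bp window at ≥ 80%
identity flags the pair (`tandem_min_len`, `tandem_identity`). A local
alignment oracle cross-checks it in the tests, but the screen itself has
no alignment dependency.

Merges are proposed for same-strand spanning junctions that survive the
tandem veto and meet the 1% rule against the higher-expressed gene's
maximum. Splits require a completely silent internal boundary (zero
spanning reads) *and* discordant per-side expression profiles: Pearson
correlation of per-side RPKM vectors < 0.5 (`split_cor`), both sides
expressed at ≥ 1 RPKM somewhere. A constant profile yields an undefined
correlation; it is treated as concordant (no split), the conservative
choice.

## Intergenic scan and new genes

Windows of 200 bp are stepped without overlap (`window_step` =
`window_size`; the step size is not stated upstream, and non-overlapping
windows make the merge step idempotent). A window qualifies per track at
RPKM ≥ 3; windows sharing at least two qualifying tracks merge while the
running intersection of supporting tracks stays ≥ 2. Region edges are then
trimmed to the covered extent of the supporting tracks, looking one window
beyond the qualifying span, because an edge window straddling the signal
boundary dilutes below threshold; with noise-free synthetic blocks this
recovers planted boundaries exactly, and the recovery tolerance asserted
in tests is one window (200 bp). RPKM needs a read length to convert
summed depth to read counts; it is required track metadata (default
75 bp).

Strand assignment demands ≥ 80% of stranded signal on one strand
(`strand_fraction`); anything less leaves the region unresolved —
retained, never annotated, matching the practice of abstaining without
strand information. Classification order: antisense (opposite-strand
overlap, SO:0000077); 3′-UTR extension when coverage runs from the
upstream gene's stop codon through the region with no sub-threshold gap of
≥ 100 bp (`utr3_gap`); dual entity when extension contiguity coexists with
an independent validated TSS; otherwise a new lncRNA with the
probable-lncRNA comment. The gap and trim parameters are explicit knobs,
not claims about the upstream project's internal values, which were never
published.

## 3′ ends

Poly(A) cDNA termini cluster by single linkage at 10 bases; each cluster
is annotated at its 3′-most member, and distinct clusters become distinct
3′ isoforms. Clustering is order-invariant by construction (ends are
sorted before linkage). Coverage extends beyond the longest cDNA on one
transcript only — multiple coverage-supported termini collapse to the
longest — and the stop codon is the final fallback. Extensions are capped
at 20 kb (`utr3_max_extension`), matching the longest extents the
reference corpus reports.

## Coding assessment

Only ATG-initiated ORFs are considered; noncanonical starts are treated
as externally curated exceptions. The longest ORF wins, ties to the
5′-most. Conservation across supplied orthologs requires the initiator
Met, no in-frame internal stop, and no indel of length ≢ 0 (mod 3) inside
the ORF, in *every* ortholog, with at least two orthologs required for an
informative call (`min_orthologs`; the ortholog count is a package
decision — the informal upstream assessments never fixed one). ORFs above
50 aa are coding outright; (30, 50] aa need conservation
(`orf_small_min` = 30, below which such analysis is uninformative);
everything else is a probable lncRNA that may encode small polypeptides.
Retained-intron isoforms require both cDNA and coverage support — a
dual-evidence gate.

## Lesions, pseudogenes, strain mutations

Strain and reference CDSs are aligned globally with affine gaps
(Biostrings `pairwiseAlignment`, match 2 / mismatch −3 / gap open 10 /
extend 0.5 — recorded here as the configuration of record). Differences
are typed; splice-site changes and transposon insertions come from
overlays, since discovering either from raw sequence is out of scope.
Nonsense lesions within the final codons still count as disabling — no
positional exemption is stated upstream, so none is applied. "Complex" is
a descriptor (≥ 2 lesions of mixed type in one gene), not a class: the
classification depends only on the disabling count. Zero disabling lesions
→ wild type (or "possible mutation in strain" when only non-disabling
transposon features exist); one → mutation in strain, and the emitted
polypeptide is the reference-corrected translation while the transcript
keeps the strain sequence; two or more → pseudogene, downgraded to
polymorphic pseudogene only when a supplied second strain is clean — the
package never infers polymorphism without one.

## Splice graphs and representative isoforms

Nodes are maximal exonic segments (the exon union split at every splice
boundary, including boundaries created by observed junctions inside
exons); splice edges carry annotated/accepted flags and read counts;
adjacency edges link contiguous segments of one exonic block. Genomic
order is a topological order, so path counting is a single linear pass and
exact in integers; it is verified against exhaustive DFS enumeration on
every graph small enough to enumerate. Variable regions separated by a
constitutive segment multiply independently — the worked example's
4 × 3 = 12 and 8 × 4 = 32 arithmetic is exactly this product rule.

The representative set is a greedy set cover over enumerated paths:
requirements are every promoter and every accepted splice edge (CDS and,
by default, non-CDS — 3′-terminal alternatives are covered unless
`cover_noncds = FALSE`, since the upstream policy is silent). Ties prefer
the path holding the highest-read-count uncovered edge, then the leftmost
start — determinism where the upstream practice left the choice to the
annotator. Graphs whose isoform count exceeds `isoform_cap` (1000, after
the observation that only ~50 genes exceed that capacity) are never
enumerated; paths are then routed greedily through each uncovered
requirement along highest-count edges.

## Sex-biased expression

Exonic RPKM per track is binned at {0, 1, 5, 25, 100, ∞} — the binning
boundaries are configuration, not a claim about the reference search
tool's internal bins, which are cited but not reproduced. Specific calls
require the opposite sex below 1 RPKM and the own sex at ≥ 5
("appreciable expression" made concrete); biased calls use a 10× ratio;
genes below 5 RPKM everywhere are excluded. Calls are re-evaluated with
gonadal tracks removed to separate gonad-dependent from gonad-independent
specificity, and lncRNAs spanning > 72 kb (strict inequality) are
flagged.

## Pipeline semantics

`run_pipeline()` runs TSS → junction triage/incorporation → merge/split
proposals → 3′ ends → intergenic scan and new genes → coding assessment →
lesion classification → expression bias → comment application. All
thresholds are evaluated against the input state of the pass (single-pass
semantics). The decision report records *changes*; the junction decision
table, merge/split candidates, integrity calls, and sex calls are separate
outputs. Two invariants are tested end-to-end: identical inputs give
byte-identical GFF3, and a second pass over the pipeline's own output
yields zero new decisions. Merge and split proposals are emitted as
candidates and never applied automatically — restructuring genes is a
curator decision, and auto-applying would also break the fixed-point
property for genuinely ambiguous loci.

# The synthetic-data generator

`generate_annotated_genome()` lays out multi-exon protein-coding genes on
both strands of one contig: valid ATG..stop CDSs (internal stops repaired
at generation), canonical GT–AG introns, 5′ UTR introns on every third
gene, and — on designated splice-test genes — codon-aligned "novel
segments" that are exonic in the annotated model but bounded by GT..AG so
an unannotated junction can excise them. Segment lengths (9, 9, 10, 11)
make two excisions frame-preserving and two frame-shifting while keeping
the reference CDS a multiple of 3; planted counts sit exactly at, and one
step below, the 1% and 10% bounds relative to the per-gene maximum of
1000. TSS regions get truncated discretised Gaussian start signal
(`tss_dispersion`, default sd 3 bp — no distributional form is given
upstream, so a clipped Gaussian is the declared choice); intergenic
transcription is planted at RPKM 5 in two stranded tracks, with decoys
either below threshold (RPKM 1.5) or single-track; sex structure follows a
six-track plan (two mixed unstranded developmental tracks, stranded
male/female heads, testis, ovary; 10⁷ mapped reads each, 75-bp reads).

Coverage depths default to Poisson noise around the planned mean
(`coverage_noise = "poisson"`), the simplest count model that exercises
thresholds; planted junction counts are always exact because they *are*
the thresholds under test. Recovery properties (recall and precision 1.0)
are asserted under `coverage_noise = "none"`, the noise-free setting those
properties are defined for.

What the generator does **not** emulate: read-level sequencing error,
alignment artifacts, mappability, overdispersion beyond Poisson, overlapping
gene structures, trans-splicing, and genuine repeat families. Passing
recovery tests therefore demonstrates that the rules are implemented
exactly as stated — not that the rules are robust to the full noise
spectrum of real libraries.

Lesion injection edits per-gene CDS space (substitution positions chosen
with locally unique context so global alignment placement is unambiguous)
and records 1-based reference-CDS positions; transposons are inserted as
features, and `complex` plants a nonsense plus a frameshift in one gene.
Ortholog simulation under conservation swaps codons within synonymous
families at ≈ 3 × divergence per codon, keeping ATG, the stop, and the
frame; unconstrained simulation substitutes per base and adds 1-bp indels,
which at divergence 0.3 fails the conservation gate in ≥ 95% of seeded
replicates.

# Numerical and degenerate-input choices

* 90% point on an all-zero region: an error, not a sentinel.
* Junction frequency with all-zero counts: an error (undefined).
* Split correlation on constant profiles: treated as concordant.
* Unresolved-strand candidates: retained, never annotated.
* Isoform counts are exact integers (path counts held as doubles are
  exact below 2⁵³; counts above `isoform_cap` are reported, not
  enumerated).
* GFF3 output order is deterministic: contig, start, gene id; attribute
  text is sanitised of GFF3 metacharacters.

# Problem sizes in the shipped tests

The test suite exercises: 1000 random TSS regions against a per-base
oracle (plus mirrored regions); 10,000 randomized junction classifications
for threshold monotonicity; 50 planted intergenic transcripts against 50
decoys on a 320-kb genome; 105 genes carrying 100 planted lesions across
the seven types; 200 random splice graphs against DFS enumeration; and a
full two-pass pipeline determinism check. These sizes were chosen so each
property is tested at a scale where failure modes (ties, boundary windows,
alignment ambiguity) actually occur.

# Known limitations

* Junction incorporation creates one isoform per junction from the
  reference isoform; combinatorial isoforms are accounted for via the
  splice graph and the permutation comment rather than emitted.
* Frame analysis models a novel junction as pure excision; junctions that
  *add* exonic sequence (e.g. entirely within an annotated intron) are
  treated as frame-neutral.
* The pseudogene parental-gene search is not performed; parents come from
  supplied paralog pairs or are named by the caller.
* PhyloCSF-style codon-substitution scoring, stop-codon readthrough, and
  trans-splicing are out of scope by design.
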