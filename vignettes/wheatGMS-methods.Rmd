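---
title: "wheatGMS methods: models, conventions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{wheatGMS methods: models, conventions and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical and algorithmic choices behind
wheatGMS: what each component computes, which parameters govern it, what the
synthetic-data generators do and do not cover, and where the methods are
deliberately simple.

## The six-allele fertility model

Bread wheat is allohexaploid: a typical gene is a homoeologous triplet with
one copy per subgenome (A, B, D), so a diploid plant carries six alleles of
the "same" gene. wheatGMS models genic male sterility as fully recessive
across the whole triplet:

* an allele is *functional* unless its coding consequence is frameshift,
  premature stop, splice-disruption or start-codon loss;
* a plant is *sterile* iff **zero** of its six alleles is functional
  (`callFertility`); one wild-type or in-frame allele anywhere maintains
  fertility.

This rule drives two diagnostic behaviors the test suite pins down: a plant
homozygous for 3-bp in-frame deletions in all three homoeologues is fertile,
and a plant with five knockout alleles plus one wild-type allele is fertile.
`predictRescueProgeny` follows the same logic for a cross to a wild-type
pollen donor: every T1 inherits a paternal wild-type allele per homoeologue,
so all rescue progeny are predicted fertile.

## Differential-expression triage

The stamen/pistil screen uses a deliberately simple exact test rather than a
negative-binomial GLM:

* **Low-count floor.** Genes with fewer than `min_total_reads` (default 10)
  summed reads across all six libraries are removed; a total equal to the
  floor is retained ("fewer than" is strict).
* **Exact conditional binomial test.** Replicates are summed per tissue.
  Conditional on the pooled count \(n = x_s + x_p\), under the Poisson null
  the stamen count is Binomial\((n, N_s/(N_s+N_p))\) where \(N_s, N_p\) are
  tissue sequencing depths. The two-sided p-value is the doubled smaller
  tail, clipped at 1; \(n = 0\) is defined as \(p = 1\).
* **Fold change** is computed from per-tissue mean counts-per-million with a
  pseudo-count of 0.5 in both numerator and denominator.
* **FDR** is Benjamini–Hochberg step-up (`stats::p.adjust`); the default
  significance cutoff is 0.05.

The exact test is correct under Poisson replicate variation and
**anticonservative under biological overdispersion**; `testDifferential`
warns when the within-tissue variance exceeds three times the mean for more
than 10% of genes. The null-calibration check in the acceptance suite
therefore runs the counts simulator at (near-)zero negative-binomial
dispersion, where the test's null model holds; the simulator's default
dispersion of 0.05 is kept for realistic-looking fixtures, not for
calibration claims.

Homoeologue-set codes (`annotateHomoeologueSets`) concatenate the sorted
subgenome letters of the set members that are significant in the configured
direction (default: stamen-higher), giving codes `ABD` > `AB`/`AD`/`BD` >
single letters; `rankCandidates` sorts by code completeness, then mean
significant log2 fold change, then set id.

## Family census and phylogeny

`enumerateFamily` counts loci per subgenome for a Pfam domain after
collapsing splice variants to one locus per `gene_id`; subgenome is the
trailing letter of the chromosome token (`7A` → A, `Un`/scaffolds → U). The
phylogeny is classical distance-based reconstruction: pairwise global
affine-gap alignments (match +1, mismatch −1, gap open −5, extension −1 per
base, a length-L gap costing \(5 + L\)), identity defined as identical
columns over all alignment columns (gaps included), distance \(1 -
\mathrm{identity}\), then Saitou–Nei neighbor joining (`ape::nj`) with input
validation (symmetry, zero diagonal) and negative branch lengths clamped to
zero with a warning. NJ is exact on additive matrices, which the test suite
verifies by round-tripping random trees; on real (non-additive) identity
distances it is a heuristic.

## Guide design

The target pattern is 5'-[A|G]N(20)GG-3': a 23-bp window whose first base is
A or G (protospacer position 1) and whose last two bases are the GG of an
NGG PAM; both strands are scanned and minus-strand hits are reported in
forward coordinates. The blunt Cas9 cut is placed 3 bp 5' of the PAM,
between protospacer positions 17 and 18. Filters, in order:

1. **Conservation:** the exact 20-mer protospacer followed by NGG (PAM N
   free) must occur exactly once in each homoeologue; multi-hit candidates
   are dropped as non-unique.
2. **Exonic:** the protospacer must overlap an exon by at least 1 bp in all
   three homoeologues.
3. **Screenability:** some restriction enzyme's recognition site (or its
   reverse complement) must lie within the 23-bp window at a position
   spanning the cut, so that a cut-site indel destroys the site and edits
   can be screened by digest.

Ranking minimizes the worst-case (max over homoeologues) spliced-CDS
distance of the cut from the CDS start — earlier cuts truncate more of the
protein — with lexicographic protospacer tie-breaks. Promoter slots (OsU3,
OsU6, TaU3, TaU6) are assigned greedily, preferring A-initial protospacers
for U3-type and G-initial for U6-type promoters (matching the +1 base those
Pol III promoters prefer); when fewer guides pass than slots exist, all are
returned with a warning that a promoter would need duplication.

At realistic homoeologue divergence, conservation *and* screenability rarely
co-occur by chance, so the triplet simulator supports *planted* targets:
23-bp windows composed of A/C filler, a 6-bp enzyme site spanning the cut
(protospacer positions 15–20) and a CGG PAM, kept identical in all three
homoeologues. The planted windows are T-free, so they cannot introduce stop
codons in any frame.

## Genotyping and consequence calling

Amplicons are aligned to homoeologue references with global affine-gap
Needleman–Wunsch (same scoring as above). Variant representation follows one
normalization convention everywhere: adjacent gap columns of one type merge
into single indel events, and indels are **left-aligned** (shifted maximally
5'-ward while the flanking context allows). Both the simulator's ground
truth and alignment-derived calls pass through `leftAlignVariants`, so
representations are directly comparable even for indels in repetitive
context.

Consequence rules, in order: variants destroying an intron's first or last
two bases are splice-disrupting; variants touching no CDS base are noncoding
(functional); a net CDS length change not divisible by 3 is a frameshift; an
in-frame change that deletes the CDS start base is treated as loss of
function; otherwise the edited spliced CDS is translated — a stop before the
final codon is a premature stop, and surviving in-frame indels are
functional by default (a strict mode marks in-frame deletions longer than
`max_inframe_aa` amino acids non-functional). Missense and synonymous
substitutions are functional.

Homoeologue assignment for unlabelled amplicons picks the
highest-scoring reference if it beats the runner-up by `min_margin`
(default 2, i.e. at least one diagnostic difference under the default
scoring), otherwise abstains as ambiguous. A homoeologue represented by a
single amplicon is assumed homozygous (logged).

## Synthetic-data generators

All simulators are pure functions of `(params, seed)`, using an isolated
RNG stream so package code never perturbs the caller's `.Random.seed`, and
are scoped to what the analysis chain needs:

* `simulateTriplet` builds one ancestral gene (clean ORF: ATG start, single
  terminal stop, GT..AG introns), plants optional enzyme sites/guide targets
  (overlaps must agree base-for-base or generation errors), then applies
  independent per-site substitutions at the divergence rate outside
  conserved positions. In-frame stops arising from planting or divergence
  are repaired by rewriting one unprotected codon base to C (which can
  complete no stop codon); if every base of such a codon is protected,
  generation fails loudly rather than emit a broken ORF. Homoeologue
  divergence is substitution-only by default so amplicon length differences
  are attributable to edits; an option adds small 3'-flank indels.
* `simulateCounts` draws lognormal baseline abundances, splits a designated
  DE fraction symmetrically by ±log2FC/2, and samples negative-binomial
  (Poisson at zero dispersion) counts at fixed library sizes.
* `simulateEditedPlants` edits each of the six alleles independently with
  `per_allele_edit_prob`, drawing indel sizes from a small-deletion-biased
  spectrum at the guide cut site, and derives per-allele truth consequences
  with the package's own normalization and consequence rules.

Not modeled: microhomology-mediated repair spectra, chimeric/mosaic T0
plants, sequencing errors in amplicons, inter-homoeologue structural
variation in the gene body, and transcript-level quantification ambiguity.

## Coordinate and format conventions

All internal coordinates are 1-based, fully closed intervals (IRanges
convention); GFF3 input/output uses the same 1-based closed system.
FASTA/GFF3 round-trips are deterministic and tested. Output TSVs carry
`#`-prefixed provenance headers (package version, seed, config digest).

## Limitations

* The exact binomial DE test trades power modeling for transparency; with
  strongly overdispersed replicates its p-values are optimistic and an
  edgeR/DESeq2-style GLM should be preferred for real screens.
* Identity distances ignore alignment uncertainty and multiple hits; NJ
  gives no support values.
* Guide scoring considers only cut position, conservation and
  screenability — no off-target search against a genome index and no
  on-target efficiency model.
* Consequence prediction evaluates the representative transcript only and
  treats all in-frame events ≤ `max_inframe_aa` as functional, which is a
  conservative default rather than a protein-structure judgment.
* The fertility rule is fully recessive and ignores dosage effects or
  partial sterility.
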