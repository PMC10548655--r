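---
title: "Coverage-aware gene-level assembly quality: the AG metric and parameter tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-aware gene-level assembly quality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agmetric)
```

## Model and assumptions

Diploid assembly can emit the two alleles of a heterozygous locus as two
sequences — a haplotypic duplication that mimics a paralogue pair.
Orthogroup completeness statistics cannot see this: the compound
"complete" category C = S + D is unchanged when an orthogroup moves from
single-copy (S) to duplicated (D), and optimizing N(S) alone rewards the
opposite error, merging genuine paralogues into chimeras.

The AG metric assumes a simple coverage model: reads are distributed over
the assembly such that a correctly collapsed locus receives the genome's
characteristic depth `D`, while each copy of an uncollapsed allele pair
receives about `D/2` (its reads are split between the two copies).
Genuine paralogues each attract their own reads at depth about `D`. The
per-gene statistic is the **median depth over exonic bases** of the
gene's complete copies:

* exons only, because introns can contain transposable-element copies
  whose misassembly elsewhere attracts or repels reads and distorts
  depth;
* only **primary** alignments are counted — duplicated loci attract
  secondary multi-mappings, and counting them would erase precisely the
  halved-coverage signal being measured (which alignment classes to count
  is our choice; we fix primaries-only and flag, but never count,
  secondaries);
* an alignment covers its full target span; CIGAR-level gaps are ignored,
  which cannot move a median materially at the depths involved;
* the median over bases (not the mean) makes the statistic robust to
  partial mis-mappings at gene edges; with an even number of bases the
  mean of the two middle values is used throughout.

`Cov(S)` is the median of the per-gene medians over single-copy
orthogroups, one gene each. A multicopy orthogroup with mean gene
coverage strictly above `tm_threshold * Cov(S)` is called true multicopy
(TM), otherwise false multicopy (FM), and

```
AG = (# genes in S orthogroups) + (# genes in TM orthogroups).
```

Fragmented genes never contribute to AG and never enter TM/FM means;
Cov(S) is likewise computed from complete single-copy genes only (the
treatment of fragmented genes in coverage summaries is ambiguous in
principle; restricting to complete genes is the coherent reading since
categories are defined by complete-gene counts).

### Tunable parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `tm_threshold` | 0.75 | fraction of Cov(S) | TM/FM decision point. Halfway between the two expected modes at Cov(S) and Cov(S)/2 would be 0.75; because Poisson-like depth distributions are narrower at Cov(S)/2, a slightly lower value could be argued, and the threshold is exposed for that reason. Coverage exactly at the threshold is called FM — the conservative direction when hunting haplotypic duplications. |
| `n_sigma` (length rule) | 2 | standard deviations | a gene is complete only if its protein is at least `length_cutoff - n_sigma * length_sigma` residues; the classifier otherwise rejects (below the score cutoff) or marks it fragmented. The exact dataset-specific length rule used by BUSCO is not restated anywhere we rely on; the two-sigma rule is an explicit, configurable stand-in. |
| `budget` | 10 | objective evaluations | golden-section budget; more points buy bracket width `((√5−1)/2)^(budget−2)` at the cost of one assembly per point. |
| `n` (conserved subset) | 1000 | orthogroups | number of most-conserved orthogroups used; smaller subsets save prediction time at slight sensitivity cost. |
| `evalue_max` | 1e-5 | — | e-value ceiling for calling a read a BUSCO read from translated protein hits. |

## Conservation ranking and dataset splits

Restricting analysis to well-conserved orthogroups reduces the chance a
gene goes undetected merely because its sequence diverged. Conservation
is scored as **mean positional relative entropy**: the mean over match
states of the Kullback–Leibler divergence (bits) between the emission
distribution and a background. The null model behind the classic
`hmmstat` relative-entropy column is not pinned down to our satisfaction,
so the package fixes a plain mean-KL definition with a **uniform 1/20
background** by default (reproducible and documented), overridable by any
amino-acid frequency table. Note the orientation: *low* entropy means
close to background, so the "most conserved" subset under this ranking is
the lowest-entropy one, matching the established convention for this
selection step; ties break lexicographically by id for cross-platform
determinism.

`split_dataset(catalog, n_assembly)` takes the `n_assembly` most
conserved orthogroups as the assembly-time part and leaves the disjoint
remainder for final quality assessment, so the same orthogroups are never
both optimized against and used as the yardstick. The split mechanism
(top-n by conservation vs. the rest) is our choice; it reproduces the
published partition arithmetic and matches the use of most-conserved
orthogroups during assembly.

## The optimizer

`golden_section_maximize()` works on the unit interval and maps
coordinates through the search space transform: identity for Hifiasm's
`-s` on `[0, 1]`, log10 for Flye's `max_divergence` on
`[0.0001, 0.5]` (log-transforming makes tuning fine at low divergence and
coarse at high divergence, matching read error-rate regimes). The first
two evaluations are the interior points 0.3819660 and 0.6180340; each
step discards the outer sub-interval beside the worse interior point and
evaluates one new point, shrinking the bracket by the inverse golden
ratio per evaluation.

Numerical choices, fixed and documented:

* AG is integer-valued and plateaus are common. On ties between interior
  values the **right sub-interval is dropped**, biasing toward smaller
  parameters — for Hifiasm's `-s`, the more aggressive
  duplication-removal side.
* The returned optimum is the **best over all evaluated points**, not the
  final bracket midpoint; observed AG-vs-parameter curves need not be
  perfectly unimodal and this choice is robust to that.
* Exactly `budget` objective calls are made; evaluations are memoized on
  the parameter rounded to 10 significant digits so a re-proposed point
  is never re-run.
* After the search the backend is invoked once more at the best parameter
  in final mode (all reads, no gene-only restriction) and that assembly
  is returned.

Backends for real assemblers are pure command constructors: they build
the exact argument lists (Hifiasm `-s` with a fixed output prefix so
intermediate files are reused across parameter values; Flye with
`assemble_ovlp_divergence = repeat_graph_ovlp_divergence = param`,
`assemble_divergence_relative = 0`, `--no-alt-contigs`, BUSCO-read subset
during optimization, all reads for the final run) but never execute
anything in the test suite. Flye's key=value overrides are a
configuration template because flag syntax differs across Flye versions.
Frameshift-fixing pseudopolishing of the gene-only objective assemblies
is out of scope here, so AG values measured on noisy-read assemblies
driven through these constructors will understate what a pipeline with
pseudopolishing achieves — a documented limitation.

## What the synthetic generator emulates — and what it does not

`generate_fixture()` builds the coverage structure the metric assumes:
single-copy genes and true-paralogue genes at expected exonic depth
`depth`, both copies of a false duplication at `depth/2`. Reads are
materialized as alignment records with Poisson-distributed starts
(uniform along the contig with overhang, so expected depth is flat);
candidate bit scores and protein lengths are set to pass the completeness
cutoffs. When `n_single = 0` an anchor single-copy gene is added so
Cov(S) is always defined; with `n_single > 0` no anchor is needed and the
configured counts are emitted exactly. Class proportions are structural,
not sampled: only per-base depth is random.

`mock_world()`/`mock_assemble()` add the assembler failure modes: a
heterozygous locus is collapsed iff its haplotype divergence is at most
the aggressiveness parameter (else two copies at half depth); a paralogue
pair is merged into one chimeric gene at double depth iff its paralogue
divergence is at most the aggressiveness (else two genes at full depth,
each subject to the haplotype rule). Expected AG as a function of
aggressiveness is therefore non-decreasing up to the largest haplotype
divergence and non-increasing past the smallest paralogue divergence;
`expected_ag()` evaluates these rules noise-free and is the oracle the
optimizer is tested against.

What the generator does **not** emulate: read error profiles and
frameshifts, mappability and GC bias, intron structure beyond fixed exon
blocks, transposable-element landscapes, fragmented or partially
assembled genes, and coverage overdispersion beyond Poisson. Passing
tests therefore demonstrate the correctness of the arithmetic and the
classification logic under the stated coverage model, not performance on
real sequencing data.

## Degenerate inputs and edge rules

* No single-copy genes but multicopy orthogroups present: Cov(S) — and
  hence AG — is undefined, and the pipeline raises a typed error rather
  than guessing a yardstick. No orthogroups at all yields AG = 0 with an
  empty report.
* Abutting or overlapping exon records of one gene canonicalize by
  merging; depth is invariant under the representation.
* Orthogroups with only rejected candidates, or none, are Missing;
  orthogroups with fragmented-only candidates are Fragmented even when
  rejected candidates coexist.
* Parsed HMMER3 emission rows are renormalized to exact distributions
  (stored values are rounded negative log probabilities; raw sums must
  still be within 1e-3 of 1 or the profile is rejected as malformed).
* Requesting more conserved orthogroups than the catalog holds returns
  the full ranked catalog (with a logged warning on the CLI).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on generated data:
worked-example AG arithmetic on encoded category counts (about 1400–2500
genes), splits on synthetic catalogs up to 5295 length-1 profiles, TM/FM
accuracy on 1000 synthetic multicopy orthogroups at depth 30 with
600-base genes, and optimizer parameter recovery on 100 seeded worlds of
6 single loci plus 3 paralogue pairs with a divergence gap
(haplotype ≤ 0.3, paralogue ≥ 0.6, 10-evaluation searches). These sizes
exercise every code path with stable statistics while keeping a full run
in the minutes range on one CPU.

## Known limitations

* AG is uninformative for comparing two nearly perfect assemblies of
  low-heterozygosity genomes: when all protein-coding genes are assembled
  correctly, the residual differences (centromeres, rDNA arrays) are
  invisible to any gene-based metric.
* The coverage model assumes roughly uniform sequencing; strong coverage
  biases could push true paralogues below the threshold or haplotypic
  duplicates above it.
* The 0.75 threshold is a simplicity choice; for very high depths the
  FM mode narrows and a slightly lower threshold may separate better.
* Gene prediction and profile search (MetaEuk/hmmsearch equivalents) are
  upstream of this package: it consumes their tabular outputs and does
  not deduplicate overlapping candidate loci.
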