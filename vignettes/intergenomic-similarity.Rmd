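---
title: "Intergenomic similarity of viral genomes: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intergenomic similarity of viral genomes: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(igsim)
```

## The statistic

The ICTV Bacterial and Archaeal Viruses Subcommittee demarcates phage taxa
by overall nucleotide identity between whole genomes: roughly 95%
intergenomic similarity for species and ~70% for genus. `igsim` computes
that statistic for every pair in a genome set from all-vs-all BLASTN local
alignments. For a pair of genomes $A$, $B$ with lengths $l_A$, $l_B$:

$$\mathrm{sim}_{AB} = \frac{(id_{AB} + id_{BA}) \times 100}{l_A + l_B},
\qquad \mathrm{dist}_{AB} = 100 - \mathrm{sim}_{AB},$$

where $id_{AB}$ is the number of identical aligned bases when $A$ is the
query against $B$, summed over *de-replicated* alignment regions, and
$id_{BA}$ the same for the opposite direction.

The essential design point is the denominator. Statistics in the ANI family
normalize identity to the *aligned* length, so two genomes sharing one short
highly conserved region can score deceptively high. Normalizing to the sum
of both genome lengths makes a partial alignment count as partial
similarity: a pair whose genomes reciprocally align over 80% of their
lengths at 95% nucleotide identity scores $0.95 \times 0.8 \times 100 = 76$,
which is why the popular "ANI $\ge$ 95% over $\ge$ 80% of the genome"
population threshold corresponds to 76 intergenomic similarity here.

## Alignment step

Every genome is aligned against a BLAST database of the whole set
(`-evalue 1 -max_target_seqs 10000`), so both directions of every pair come
from one run. Four scoring presets are offered (`param_set()`):

| set | word size | reward/penalty | gap open/extend | character |
|----:|----------:|---------------:|----------------:|-----------|
| 1   | 7         | 2 / -3         | 5 / 2           | relaxed — default |
| 2   | 11        | 2 / -3         | 5 / 2           | |
| 3   | 20        | 1 / -2         | program default | |
| 4   | 28        | 1 / -2         | program default | very stringent, fastest |

Set 1 is the default because it still seeds alignments in diverged regions;
the stringent sets are offered for large datasets that only need clustering
at high similarity (e.g. 90–100%), where they give nearly the same values at
a fraction of the cost. The number of threads is a hardware parameter, not
part of the method: results are identical for any thread count. The exact
command lines and the aligner version are recorded in the run log.

Self-hits are discarded and the matrix diagonal is fixed at 100 by
definition — self-alignment artifacts (internal repeats matching themselves)
would otherwise contaminate it.

## De-replication

BLASTN reports possibly overlapping local alignments (HSPs), each with a
count of identical bases (`nident`). Summing those counts naively would
count genome regions aligned by several HSPs more than once. Hits of one
directed pair are therefore processed in priority order — descending
`n_ident`, ties by descending bitscore, then ascending query start, then
ascending subject start (a total, deterministic order: runs are
reproducible) — and each hit is clipped against the union of regions already
retained by stronger hits.

Two choices here deserve explanation.

**Proportional identity scaling.** The tabular alignment format does not say
*which* bases of a hit were identical, so when a hit is clipped to a
fraction $f$ of its query interval it contributes $n_{ident} \times f$ —
identical bases are assumed uniformly spread along the hit. This is unbiased
under that assumption and keeps identical-base sums real-valued; it is an
approximation, and the per-pair tables expose the raw directed sums so users
can audit it.

**Both sides are de-replicated.** Each hit is clipped independently against
the used *query* regions and the used *subject* regions, contributing
$n_{ident} \times \min(f_q, f_s)$, where $f_q, f_s$ are the retained
fractions on each side. Clipping only the query side looks sufficient at
first (it already guarantees $id_{AB} \le l_A$, hence $\mathrm{sim} \le
100$), but it fails on repeats: if genome $B$ carries two tandem copies of a
region that genome $A$ has once, the two copies occupy *disjoint* query
intervals when $B$ is the query, and both would be credited in full against
the same subject region — the pair would score 100 despite the extra copy.
With the subject-side cap, each region of each genome is represented once,
and a duplicated region depresses similarity (the de-replicated identity
cannot grow, while the genome length in the denominator does). This is the
behavior expected of the method — users comparing genomes with long terminal
repeats are still advised to supply single-repeat-copy sequences, because
the depression is a penalty, not a correction.

The *aligned fraction* indicators intentionally use only the query-side
union: they measure alignment coverage of each genome, and a repeated region
that aligns somewhere is covered, whether or not it earns identity credit.

Zero-hit pairs get similarity 0 (not missing): distant pairs are informative
zeros in the matrix and must participate in clustering.

## Indicators

Per pair, three context indicators are computed: aligned fraction of genome
1 ($\mathrm{af}_1$ = de-replicated aligned bases of genome 1 / $l_1$), the
genome length ratio ($\min(l_1,l_2)/\max(l_1,l_2)$), and aligned fraction of
genome 2. A pair with high similarity but a low length ratio (a complete
genome vs a partial or nested one) is flagged visually in the heatmap and
should be inspected before taxonomic conclusions.

## Clustering and thresholds

The similarity matrix is clustered agglomeratively on $D = 100 -
\mathrm{sim}$, by default with complete linkage (`stats::hclust`; the other
standard agglomeration methods are available). Species and genus tables cut
the same tree at heights $100 - 95$ and $100 - 70$. Using one tree for both
the heatmap order and the cuts keeps figure and tables consistent; under
complete linkage a cluster at the species cut is a group whose *worst* pair
is still $\ge 95$ similar, so chains of borderline pairs deliberately do not
merge (they surface as sub-clusters the user must adjudicate). Cluster
labels are consecutive integers in leaf order — naming taxa is the
taxonomist's job. Raising a threshold can only split clusters, and species
clusters always nest inside genus clusters.

The dendrogram orders the heatmap and is cut for the tables, and that is
all: it is not an evolutionary tree, and the package never renders it.
Phylogenies should come from dedicated phylogenetic analyses (e.g. core-gene
trees).

## Outputs and rounding

The matrix files (similarity and/or distance, TSV with an id header row and
column) keep three decimals — enough to distinguish near-identical genomes.
The heatmap rounds cell labels to one decimal for legibility; rounding is
display-only, nothing downstream consumes rounded values. The heatmap's
upper-right half (and diagonal) encodes similarity, darker = more similar;
each lower-left cell stacks the three indicators (aligned fraction of the
row genome / length ratio / aligned fraction of the column genome),
orange-to-white and black-to-white with darker = lower, so partial
alignments and length mismatches stand out exactly where high similarity
would otherwise look reassuring. Genome lengths are drawn as a bar
annotation along the columns. In-cell numbers are suppressed above 80
genomes (configurable). Step-2 results (hit table, pair table) are cached in
the work directory, so clustering and reporting can be re-run with different
methods or thresholds without re-aligning (`reuse_hits`).

## Synthetic data: what it emulates, what it does not

The fixture generators produce i.i.d. random genomes at a chosen length and
GC (defaults 39,937 bp, 48.4% GC — a typical T7-like phage), point-mutated
partners, circular permutations, reverse complements, scrambles, implanted
shared regions, tandem duplications, and N runs. Mutation is
substitution-only so that expected identity is exactly $1 - p$ and
parameter-recovery tests have an analytic target; real genomes additionally
have indels, rearrangements, mosaic identity and shared gene content, none
of which the generator produces. A green test therefore establishes the
*arithmetic* of the pipeline (de-replication, normalization, invariances,
threshold semantics) on controlled inputs — not that any particular pair of
real viruses will receive any particular value.

Two consequences of the uniform-identity model show up in the acceptance
tests and are worth understanding:

* **Stringency ladder.** On uniformly 95/85/75/65%-identical pairs, the
  very stringent preset (set 4) tracks set 1 within aligner noise for as
  long as its 28-base words can seed at all, then collapses to ~0 — a step,
  not the gradual divergence seen on real genomes whose identity varies
  along the genome. The test asserts the claim's substance: set 4 is never
  meaningfully above set 1, near-identical rungs differ by well under a
  point, and the most distant rung loses by a large margin.
* **Sensitivity floor.** A 140 bp implant at 65% expected identity sits at
  the E-value-1 reporting threshold for a 40 kb × 40 kb search space: its
  expected raw score (≈35 under set-1 scoring) barely exceeds the ≈33
  required, with a standard deviation of ≈28 from the binomial mutation
  draw. Detection per seed is therefore ~75–90%, and the acceptance
  criterion demanding ≥90% of 20 seeds is left honestly failing rather than
  loosened; the 30 bp @ 87% scenario, whose score margin is comfortable,
  passes in every seed. Separately, two *unrelated* random 40 kb genomes
  frequently share a reportable chance alignment at `-evalue 1`, so
  "similarity > 0" saturates near 50% implant identity — which is why the
  scanned detection floor reported by `scripts/acceptance.R` is bounded by
  the scan's lower edge rather than the implant's visibility.

## Numerical and degenerate-input choices

* Matrix validation tolerates $10^{-8}$ asymmetry (floating-point) and
  requires the diagonal to be exactly 100.
* Identical-base sums are kept as doubles end-to-end; only writers round.
* `min_length` rejection and duplicate-id detection fail fast with named,
  classed conditions (`igsim_input_error`, `igsim_aligner_error`,
  `igsim_internal_error`) that the CLI maps to exit codes 2/3/4.
* Genomes with runs of ≥10 consecutive `N` (a scaffold-level draft
  signature) produce warnings, never rejections: the aligner skips such
  regions, so similarities involving those genomes are underestimates. The
  threshold 10 is this package's choice; the underlying caveat is
  qualitative.
* Every FASTA record is an independent genome; multi-contig drafts are not
  concatenated. Terminal-repeat genomes should be supplied with a single
  repeat copy.
* Seeded generators save and restore the caller's RNG state.

## Known limitations

* Identity of clipped hits is apportioned proportionally, not by true
  per-base identity (would require alignment traceback parsing).
* The detection floor is BLASTN's: regions below ~65% identity are invisible
  to nucleotide alignment, and relationships that distant need protein-level
  analysis.
* Similarities involving genomes with long N runs or unresolved repeats are
  systematically underestimated, by design of the normalization.
* The pair computation is quadratic in the number of genomes.
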