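# igsim — intergenomic similarity of viral genomes

`igsim` computes pairwise **intergenomic similarities** between viral
genomes (built with phages of *Bacteria* and *Archaea* in mind, applicable
to any monopartite viruses) the way the ICTV Bacterial and Archaeal Viruses
Subcommittee traditionally demarcates species and genera: from all-vs-all
BLASTN alignments, with identical bases normalized to **both whole genome
lengths** rather than to the aligned length. It is aimed at phage biologists
and taxonomists who need to place tens to thousands of genomes into putative
species (95 % similarity) and genus (70 %) clusters, and at pipeline authors
who need those numbers in plain tab-separated files.

## The statistic

For genomes *A*, *B* with lengths *l*<sub>A</sub>, *l*<sub>B</sub>:

```
sim_AB  = (id_AB + id_BA) * 100 / (l_A + l_B)
dist_AB = 100 - sim_AB
```

where *id*<sub>AB</sub> is the count of identical aligned bases with *A* as
query against *B*, summed over **de-replicated** alignment regions (each
region of each genome counted once; overlapping hits are clipped in priority
order with proportional identity scaling). Normalizing to both genome
lengths keeps partial alignments from inflating similarity — the classic
failure mode of ANI-style statistics for distantly related genomes. Three
indicators accompany every pair: aligned fraction of each genome and the
genome length ratio, flagging partial/nested-genome comparisons.

The workflow: (1) all-vs-all BLASTN (four scoring presets; default
`-word_size 7 -reward 2 -penalty -3 -gapopen 5 -gapextend 2`, core options
`-evalue 1 -max_target_seqs 10000`); (2) de-replication and the formulas
above; (3) complete-linkage hierarchical clustering of `100 - sim` with
threshold cuts; (4) ordered matrix TSV, composite heatmap PDF, cluster table
TSV, per-pair intermediates.

## Worked example

Entirely synthetic, no downloads: a random 20 kb genome, a partner mutated
at 5 % per base, and a circularly permuted plus a reverse-complemented copy
of that partner.

```r
library(igsim)
gs <- fixture_pair(length = 20000, p = 0.05, seed = 3, variants = TRUE)
fasta <- tempfile(fileext = ".fasta")
write_genomes(gs, fasta)
res <- run_pipeline(fasta, "readme_out", threads = 2)
round(res$result$sim, 3)
#>                base partner partner_perm partner_rc
#> base         100.00   94.77        94.77      94.77
#> partner       94.77  100.00       100.00     100.00
#> partner_perm  94.77  100.00       100.00     100.00
#> partner_rc    94.77  100.00       100.00     100.00
```

The 5 %-mutated partner scores 94.77 ≈ 100 × (1 − 0.05), and the permuted
and reverse-complemented variants score **identically** to the partner —
the statistic is invariant to genome rotation and orientation. The
intermediate pair table carries the indicators:

```r
res$result$pairs[1, c("id_a","id_b","sim","dist","af_1","length_ratio","af_2")]
#>   id_a    id_b   sim dist   af_1 length_ratio   af_2
#> 1 base partner 94.77 5.23 0.9999            1 0.9999
```

and the cluster table applies the default demarcations — at 94.77 the
mutant trio is a different putative species from `base` but the same genus:

```r
res$clusters
#>      genome_id species_cluster genus_cluster
#> 1         base               1             1
#> 2   partner_rc               2             1
#> 3      partner               2             1
#> 4 partner_perm               2             1
```

`run_pipeline()` also writes `similarity_matrix.tsv` (3 decimals),
`heatmap.pdf` (similarity upper-right, indicator bands lower-left, lengths
along the columns), `cluster_table.tsv`, `work/hits.tsv` +
`work/pairs.tsv` (reusable via `reuse_hits=` to re-cluster without
re-aligning), and `run.log` with the exact aligner command lines.

A command-line wrapper ships at `inst/cli/igsim.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","igsim.R",package="igsim"))')" \
  -i genomes.fasta -o outdir --species-thr 95 --genus-thr 70
```

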