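# hapflow

Population-level mitochondrial DNA surveys routinely start from one aligned
multi-FASTA of a marker gene (here, cytochrome *b*) and need the same chain
of results every time: which unique sequence variants (haplotypes) are
present, how they are shared among populations, how far apart they are, and
how they relate on a tree and a haplotype network. `hapflow` implements that
whole chain behind one input file, for researchers studying intraspecific
genetic structure (e.g. bumblebee populations sampled across sites), with
tidyverse-style tabular outputs and `ape`-compatible trees.

## What it computes

Given an aligned FASTA whose record labels encode populations as
`<Population>_<n>` or `<Population> <n>`:

* **Haplotype census** — identical sequences collapse into haplotypes
  H1..Hk (first-appearance order) with frequencies *hf* and percentages
  *pct*; the polymorphic columns form a variable-site table rendered in dot
  notation against a reference haplotype; per-population and per-group
  frequency matrices follow.
* **Distances** — exact Hamming counts
  d(x, y) = #\{i : x_i ≠ y_i\} between haplotypes, and Kimura
  two-parameter (K80) model distances between sequences,
  d = −½ ln(1 − 2P − Q) − ¼ ln(1 − 2Q), where P and Q are the
  transition (A↔G, C↔T) and transversion proportions.
* **Trees** — neighbor-joining (Saitou & Nei): join the pair minimising
  Q(i, j) = (r − 2) d(i, j) − R_i − R_j, with branch lengths
  v_i = d(i, j)/2 + (R_i − R_j)/(2(r − 2)); nonparametric bootstrap
  support by resampling alignment columns and counting bipartitions;
  support bins (strong/moderate/weak/poor at 85/70/50) via `cut()`
  semantics; Newick output with proper label quoting.
* **Haplotype network** — Kruskal minimum spanning tree over haplotype
  Hamming distances with deterministic tie-breaking, plus equal-cost
  alternative links; link weights are mutational steps.
* **Figures** — alignment panel beside the tree, clustered distance
  heatmap with marginal dendrograms, haplotype networks with pie
  compositions and mutation ticks, rectangular/circular trees colored by
  population, branch length, or bootstrap bin.

## Worked example

The package ships the printed reference tables of a 120-sequence cyt *b*
survey (20 haplotypes over 41 variable sites) and a synthetic stand-in
alignment built from them:

```r
library(hapflow)

al  <- synthetic_reference_alignment()   # 120 x 373 bp, 8 populations
hs  <- collapse_haplotypes(al)
glance(hs)
#> # A tibble: 1 × 5
#>   n_haplotypes n_samples modal_haplotype modal_hf modal_pct
#>          <int>     <int> <chr>              <int>     <dbl>
#> 1           20       120 H11                   55      45.8

vst  <- variable_sites(hs)
dots <- dot_notation(vst)
cat(paste(dots$haplotype[1:3], dots$pattern[1:3]), sep = "\n")
#> H1 ATAATGATATATATATACCAATTTATAACAAATATTTTCAT
#> H2 .....C....C.C.C....C...............CCA...
#> H3 .....CC.C.C.C.C....C......C........CCA...

d <- hamming_matrix(vst)
max(d)          # 35, the H5-H14 pair
min(d[d > 0])   # 1  (H9-H11, H10-H11, H12-H15, H15-H16)

net <- build_network(d, hs, build_population_map(al), level = "population")
net
#> Haplotype network: 20 haplotypes, 19 MST links (total weight 96),
#> 5 alternative links; composition by population
autoplot(net)

bt <- bootstrap_support(
  tibble::tibble(label = vst$haplotype, sequence = vst$sites),
  B = 100, seed = 1)
plot_tree(bt, mode = "support")
```

The modal haplotype accounts for 45.83% of all samples; the most divergent
haplotype pair differs at 35 of 41 variable sites; and the minimum spanning
backbone of the network implies at least 96 mutational steps connecting the
20 haplotypes.

The same chain runs end to end from a file:

```r
run_all("aligned.fasta", "results/", groups = "groups.tsv",
        bootstrap = 100, seed = 1)
```

or from a shell via the thin wrapper `exec/hapflow`:

```sh
Rscript exec/hapflow --input aligned.fasta --out results/ --seed 1
```

which writes the haplotype/dot-notation tables, frequency matrices,
Hamming and K80 matrices, plain and bootstrapped Newick trees, the network
link/node lists with a JSON dump, all figures, and a manifest recording the
configuration and input checksum.

## Acceptance script

`scripts/acceptance.R` re-runs the installed package's full pipeline from
scratch on the synthetic reference alignment (haplotype census, distance
matrices, 100-replicate bootstrapped NJ tree, haplotype network, figures)
and writes a JSON report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Scope

Input must already be aligned (only end-trimming is offered, via
`trim_ends()`); multiple sequence alignment itself, FASTQ/SAM/VCF input,
AMOVA/Fst/HWE statistics, and median-joining or statistical-parsimony
networks are out of scope. See the vignette (`vignettes/hapflow-methods.Rmd`)
for the models, conventions, and known limitations.
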