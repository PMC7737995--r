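---
title: "hapflow: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hapflow: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapflow)
```

`hapflow` turns one aligned multi-FASTA of a mitochondrial marker into the
standard set of population-genetic summaries: haplotype tables, frequency
matrices, distance matrices, neighbor-joining trees with bootstrap support,
and a minimum-spanning haplotype network. This vignette documents the
models and every convention a careful reader would want pinned down.

## Input model and label convention

The single input is an alignment: equal-length DNA sequences over
`A C G T - N` (plus IUPAC ambiguity codes), read by `read_fasta()`.
Sequences are uppercased and `U` is mapped to `T` at read time so that
every downstream stage sees one alphabet. Record order is preserved
throughout, because haplotype numbering is defined by first appearance.

Sample labels carry population membership as `<Population><sep><number>`
with an underscore or space separator (`Kumluca_6`, `Bayatbadem 24`).
`parse_population()` strips the final maximal run of digits plus the
single separator immediately before it — and nothing else — so interior
separators survive (`Geyik_bayir_3` → `Geyik_bayir`). A split-at-first-
separator rule would mangle such names; the stripping rule generalises
safely and is idempotent. Because labels may contain spaces, the FASTA
label is the full header line by default; a `first-token` mode is
available for conventional headers.

`trim_ends()` is the only alignment-editing operation: it removes leading
and trailing columns whose fraction of `-`/`N`/`?` exceeds a threshold
(default 0.5), never touches interior columns or surviving characters, and
records the left offset so 1-based site positions can be mapped back to
input coordinates. Alignment itself is out of scope: the package assumes
its input was aligned upstream.

## Haplotype census

Haplotype identity is **exact string equality**. Gaps and `N` are literal
fifth and sixth states, never wildcards: treating `N` as a wildcard would
make "identical" non-transitive and the partition ill-defined. Haplotypes
are labelled `H1..Hk` in order of first appearance in the alignment; the
ids are presentation only, and all cross-checks against reference tables
compare partitions, counts and distances rather than id assignment.

Percentages are rounded **half-up** to two decimals (`55/120` → `45.83`);
IEEE round-half-even would print `45.82` for some inputs and disagree with
how such tables are conventionally printed.

A *variable site* is any column with at least two distinct states among
the haplotype sequences, including gap/`N` differences; `acgt_only = TRUE`
restricts variability to definite bases. On gapless data the two
conventions coincide. The dot-notation rendering prints the reference row
verbatim and a `.` wherever another row matches it; `dot_expand()` is its
exact inverse, and the pair is property-tested as a round trip.

## Distances

**Hamming** distances compare all characters literally — this reproduces
printed haplotype difference tables exactly, including any gap
differences, and satisfies the metric axioms by construction. An
invariant worth knowing: Hamming on the variable-site strings equals
Hamming on the full sequences, because monomorphic columns contribute
nothing.

**K80** distances use the Kimura two-parameter closed form
$d = -\tfrac12\ln(1-2P-Q) - \tfrac14\ln(1-2Q)$ with transitions A↔G and
C↔T. Only definite bases enter: under the default **global deletion**,
every column containing any non-ACGT character in any sequence is dropped
before all comparisons (mirroring the default of the standard distance
routine in this field); `pairwise-deletion` is available. Saturation
($1-2P-Q \le 0$ or $1-2Q \le 0$) raises an informative error rather than
returning `NaN` silently. No gamma rate heterogeneity is applied — the
workflow this package implements uses plain K80. The implementation is
cross-checked in the tests against `ape::dist.dna(model = "K80")` on
simulated data.

## Neighbor joining

`nj_tree()` implements the Saitou–Nei agglomeration exactly as stated in
the docs: minimise $Q(i,j) = (r-2)\,d(i,j) - R_i - R_j$, attach branch
lengths $v_i = d(i,j)/2 + (R_i - R_j)/(2(r-2))$, reduce with
$d(u,m) = (d(i,m)+d(j,m)-d(i,j))/2$. Two choices were genuinely open and
are fixed as follows:

* **Tie-breaking.** Ties in $Q$ are resolved by the lowest $(i, j)$ index
  pair in the current node ordering (row-major scan). Library NJ
  implementations leave this to chance of memory layout; a fixed rule
  makes results identical across platforms and label orders (up to tree
  isomorphism).
* **Negative branch lengths are retained** by default. They are a known,
  legitimate artifact of NJ on non-additive matrices, and clamping them
  silently would break the additivity identity that the test suite
  checks (on tree-realizable matrices the output path lengths reproduce
  the input to 1e-9). `clamp_negative = TRUE` is available for display.

On $k\ge 3$ taxa the result is the standard unrooted binary tree with a
basal trifurcation; on 2 taxa the single distance is split evenly across
the two pendant edges.

## Bootstrap support

`bootstrap_support()` resamples alignment columns with replacement (same
length as the original), rebuilds the distance and the NJ tree per
replicate, and scores each internal edge of the reference tree by the
percentage of replicates containing the same unrooted bipartition of tip
labels (branch lengths ignored, support rounded to nearest integer).
A replicate whose K80 distance is undefined is redrawn up to 10 times and
the redraw count is recorded on the result — NA-propagation would silently
shrink the effective replicate count. The default of 100 replicates is
the convention of the workflow this package reproduces.

Support bins follow the `cut(support, c(0, 50, 70, 85, 100))` convention:
left-open right-closed, so 85 is *moderate* and 50 is *poor*; support 0 is
*poor* by continuity. The verbal convention "85 and above is strong" is
common in the literature describing the same thresholds and contradicts
the `cut()` intervals exactly at the boundaries; both are supported, with
the code convention as default and `closed_left = TRUE` switching to the
verbal one.

`write_newick()` emits internal-node supports as node labels and
single-quotes any label containing Newick metacharacters or whitespace
(doubling embedded quotes). The shipped parser wrapper strips those quotes
back off, making write→read the identity on topology, lengths and labels;
this matters because the label convention of this workflow includes
spaces.

## Haplotype network

The network backbone is a minimum spanning tree over the integer haplotype
distances, built with Kruskal's algorithm and deterministic tie-breaking
(weight, then lexicographic endpoint pair). *Alternative* links are the
non-tree pairs whose distance equals the weight of the edge that first
connected their components during the merge sequence — the natural
"equal-cost at merge time" notion, equivalent to matching the heaviest
link on the tree path between the endpoints. The tests verify the MST
weight against exhaustive enumeration of all spanning trees on small
graphs, and the cycle property on random instances.

Reference figures of this kind of survey often show many more links than
a spanning tree; the rule generating those denser link sets is library
internal and not recoverable from printed tables, so the package does not
pretend to reproduce a specific link count. Instead `alt_threshold = T`
admits every non-tree pair with weight ≤ T, flagged as alternative, for
exploration. The MST backbone is unaffected by the flag.

Link weights are mutational steps and are drawn as one tick per step; no
median (inferred) haplotypes are ever created — that is the domain of
median-joining methods, which are out of scope.

## Figures

All plot functions return ggplot objects; `save_plot()` renders PNG or
SVG. Conventions:

* Heatmap rows/columns are ordered by **complete-linkage** hierarchical
  clustering of the given distances (the linkage is not dictated by the
  upstream workflow; complete linkage is the base-R default for this
  figure and is fixed here), dark red = close, white = distant. Input
  labels are put in canonical sorted order before clustering because tied
  distances otherwise make the merge sequence — and hence the image —
  depend on input permutation.
* Network node size scales with **area** ∝ hf by default (radius mode
  available): radius-proportional scaling visually exaggerates a dominant
  haplotype that is half the sample. The layout is force-directed with a
  fixed seed; it is reproducible, not a reproduction of any particular
  published layout.
* Nucleotide colors in the alignment panel are rosybrown/sienna/
  lightgoldenrod/lightskyblue with gaps in a reserved grey; bootstrap bins
  use black/red/pink1/white ordered strong→poor. All palettes are
  arguments.

## Synthetic data

`generate_dataset()` emulates the input structure: a random ancestor, `k`
planted haplotypes each a distinct random substitution set away from it
(haplotype 1 **is** the ancestor — the dominant shared variant typical of
mtDNA surveys, which also guarantees the MST over haplotype distances
never exceeds the planted mutation total), and individuals assigned to
populations with a `mixing` parameter sliding between fully shared
(`mixing = 1`) and private-haplotype structure (`mixing = 0`, default
0.5). Defaults mirror the reference design: 8 populations × 15 samples,
373 bp. Every planted haplotype is guaranteed at least one carrier, so
the census is exactly recoverable — which is what the parameter-recovery
tests assert. The generator makes substitutions only (the reference data
are gapless), draws sites uniformly, and has no coalescent structure,
recombination, or rate heterogeneity: a green recovery test establishes
bookkeeping correctness of the pipeline, not realism of the evolutionary
model.

The package also ships, as plain TSV, the printed reference tables of a
120-sequence cytochrome *b* survey: 20 dot-notation haplotype strings over
41 variable sites with frequencies (`load_table1_fixture()`), the
haplotype-by-population counts (`load_table2_fixture()`), and the 20×20
Hamming matrix (`load_table3_fixture()`). Two notes:

* The haplotype-by-population table as originally printed is arithmetically
  inconsistent with the frequency column: two entries in the Geyikbayir
  column sit on the rows of H8 and H10 where the row sums then exceed the
  printed frequencies, while H9 and H11 fall short by exactly those
  amounts. The shipped fixture moves those two entries down one row each,
  which restores every identity simultaneously (row sums = hf, all column
  sums = 15, grand total 120) and agrees with every statement the
  accompanying text makes (seven haplotypes in the commercial population,
  two each in Demre/Kumluca/Termessos).
* The full 120 × 373 bp alignment itself is not redistributable, so
  `synthetic_reference_alignment()` reconstructs a **synthetic stand-in**:
  a fixed monomorphic backbone with the 41 variable-site columns planted
  at arbitrary (deterministic) positions and individuals laid out per the
  corrected count table. Haplotype-level results on it — census,
  frequencies, distances, network — are exact by construction;
  site coordinates and the invariant backbone are meaningless, and any
  sequence-level K80 quantity on it reflects the stand-in, not the
  original data.

## Degenerate inputs and numerical edges

* Single-haplotype input: `variable_sites()` returns an empty table, not
  an error; the network degenerates to one node.
* `k = 2` distance matrices: valid trees/networks with a single edge.
* All-gap columns in `trim_ends()` flanks are removable; removing every
  column is an error.
* K80 with zero usable sites for a pair is an error naming the pair.
* Support values outside [0, 100] are rejected rather than clamped.
* Floating-point ties in NJ are compared with a 1e-12 slack before the
  index rule applies.

## Limitations

Phasing/ambiguity-aware haplotype inference, indel coding, AMOVA, Fst,
HWE, linkage statistics, median-joining and statistical-parsimony
networks, maximum-likelihood or parsimony trees, and R Markdown reporting
are deliberately not provided. Figures aim for structural fidelity
(orderings, encodings, palettes), not pixel-level replication of any
published figure.
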