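---
title: "Methods: mutual-rank networks, clique-percolation modules and chromatin-state HMMs"
author: "omicsforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutual-rank networks, clique-percolation modules and chromatin-state HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models behind `omicsforge`, the parameters
that matter, the numerical conventions, and what the synthetic data
generators do and do not emulate. It states no empirical result beyond
what the test suite and `scripts/acceptance.R` themselves compute.

## Co-expression: PCC and mutual rank

For genes $x$ and $y$ measured over $n$ samples, the Pearson
correlation is

$$\mathrm{PCC}(x,y) = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
{\sqrt{\sum_i (x_i-\bar x)^2}\sqrt{\sum_i (y_i-\bar y)^2}}.$$

Expression values are FPKM-like and heavy-tailed, so `compute_pcc()`
correlates $\log_2(\mathrm{FPKM}+1)$ by default; `transform = "none"`
reproduces correlation on the raw scale. The choice matters: raw-scale
PCC is dominated by the few most highly expressed samples. Genes with
zero variance under the chosen transform have undefined PCC; they are
dropped from the matrix and listed in an attribute rather than
imputed.

`Rank(A→B)` is the position of B in A's partner list sorted by
descending PCC (self excluded). Because correlation is not symmetric in
rank — B may be A's best partner while A is far down B's list — the
mutual rank combines both directions:

$$\mathrm{MR}(A,B) = \sqrt{\mathrm{Rank}(A{\to}B)\cdot\mathrm{Rank}(B{\to}A)}.$$

The geometric mean is the default (`mode = "geometric_mean"`); the raw
product is available as `mode = "product"`. The geometric mean is the
form used throughout the mutual-rank co-expression literature, and it
is the form on which thresholds of the magnitude MR ≤ 55 are
meaningful — a raw product at the same quantile would be orders of
magnitude larger. Equal PCC values get ordinal ranks with ties broken
by lexicographic gene identifier; average ranks would make MR
non-integer-valued in ways that are harder to reason about, and the
lexicographic rule makes results bit-identical across platforms.

Network construction (`build_network()`) applies both filters at once:
a positive edge needs PCC ≥ `pcc_min_pos` **and** positive-tail
MR ≤ `mr_max`; a negative edge needs PCC ≤ `pcc_max_neg` and
negative-tail MR ≤ `mr_max`. Negative-tail ranks are computed
separately on ascending PCC — ranking anti-correlated partners inside
the descending list would assign them meaninglessly large ranks. The
presets (`network_thresholds()`) are PCC ≥ 0.8 / MR ≤ 55 for a global
network and PCC ≥ 0.8 / MR ≤ 50 for a conditional
(tissue-preferential) one, with −0.3 as the negative PCC bound; the
looser intervals (0.5, 1) and (−1, −0.3) define the sign vocabulary
only, the stricter bounds are what edges must pass. Whether negative
edges should face the same MR cutoff is an open convention; we apply
it symmetrically.

Sample QC (`qc_filter_samples()`) computes the sample–sample
correlation matrix, flags samples whose mean correlation with all
others falls below `min_mean_corr` (default 0.5), and returns the
hierarchical-clustering leaf order for visual inspection, mirroring the
cluster-analysis screening usually applied before network construction.

## Threshold tuning by AUROC

`label_pairs_from_go()` builds a labelled pair set from prior
knowledge: terms are first restricted to measured genes, and only terms
with 4–20 remaining members are kept — smaller terms carry no pair
information, larger ones are too unspecific to validate co-expression.
Positives are pairs co-annotated to a kept term. The negative class is
not defined by the prior, so we sample non-co-annotated pairs uniformly
(seeded), one per positive by default; balanced classes keep the AUROC
interpretable.

`select_thresholds()` scores each candidate (PCC, MR) cell as a binary
classifier — a labelled pair scores 1 iff it passes the cell's filter —
and reports the AUROC of that classifier per cell, computed by the
rank (Mann–Whitney) formulation with midrank tie handling. Cells
passing no labelled pair are recorded as `NA` and excluded from the
argmax; argmax ties break toward sparser networks (fewer induced
edges), then toward stricter cuts.

## Modules by clique percolation

A k-clique community is a connected component of the relation joining
k-cliques that share k − 1 nodes; a module is the union of its
cliques' nodes, so modules may overlap — a biological necessity, since
genes participate in several processes. The implementation percolates
over *maximal* cliques (size ≥ k, connected when the intersection has
≥ k − 1 nodes), which yields identical communities to raw k-clique
percolation: any two overlapping k-cliques lie in maximal cliques that
overlap at least as much, and conversely any two maximal cliques
sharing ≥ k − 1 nodes contain a pair of adjacent k-cliques. Maximal
cliques come from `igraph::max_cliques()`; the percolation itself is a
union-find over candidate pairs bucketed by shared nodes. The test
suite checks equivalence against a brute-force oracle that enumerates
k-cliques directly.

Defaults follow the community-detection practice for co-expression
resources: k = 6 and a minimum module size of 6 genes (modules with
exactly 6 are kept). Only positive edges enter by default — negative
correlation has no clique semantics — with `edge_sign = "all"`
available for unsigned graphs. Module identifiers are assigned by
descending size, then by lexicographically smallest member, so ids are
reproducible across runs and platforms.

## Gene-set enrichment

`fisher_enrich()` computes, per term, the upper-tail hypergeometric
probability $P(X \ge k \mid N, K, n)$ (via `phyper`), i.e. the
one-sided Fisher exact test for enrichment; depletion is deliberately
not tested. The universe defaults to all genes in the expression
matrix; the right background is analysis-specific and can be supplied.
Terms are tested only when the overlap is ≥ 1 and at least two term
genes are in the universe; zero-overlap terms appear with the p = 1
convention but do not inflate the multiple-testing burden, whose size
m is the number of tested terms. FDR is Benjamini–Hochberg
(`bh_fdr()`, a validated front end over `p.adjust`), with FDR ≤ 0.05
flagged significant by default.

## Promoter motif enrichment

Promoters are the 3,000 bp immediately upstream of the TSS,
strand-resolved: forward-strand genes take genomic
$[\mathrm{TSS}-3000, \mathrm{TSS})$, reverse-strand genes take
$[\mathrm{end}, \mathrm{end}+3000)$ reverse-complemented, truncated and
flagged at chromosome edges. Motifs are IUPAC consensus strings
(minimum length 4); matching expands each code to its base set and
counts overlapping occurrences on the promoter strand only. An `N` in
the *sequence* matches no motif position — an ambiguous base is never
evidence for a motif — while `N` in the *motif* matches any unambiguous
base. A `both_strands` flag adds reverse-complement matches for
unstranded motif semantics; the single-strand default avoids
double-counting palindromes.

The enrichment statistic compares the observed count $N$ in the $m$
query promoters against $n_\mathrm{draws} = 1000$ seeded draws of $m$
genes from the promoter universe (without replacement within a draw,
independent across draws):

$$Z = \frac{N - \mathrm{mean}}{\mathrm{stdev}}, \qquad
P = 1 - \Phi\!\left(\frac{N - \mathrm{mean}}{\mathrm{stdev}}\right),$$

with the *population* standard deviation (ddof = 0) over draws — at
1,000 draws the ddof choice is negligible, but it must be fixed for
bit-reproducibility. A motif absent from every draw (stdev 0) is
reported `NA` rather than as an infinite Z. Per-gene counts are
computed once and draw totals are subset sums, so the cost is one scan
of the universe per motif regardless of the number of draws.

## Chromatin states

**Binarization.** Signal tracks are summarized in 200-bp bins
(bedGraph input aggregates as mean coverage,
$\sum \mathrm{value}\times\mathrm{overlap}/\mathrm{binsize}$, with a
`counts` mode attributing values by interval midpoint — raw pipelines
differ in how reads were reduced to bins, so both are provided). Each
mark's background rate $\lambda$ is its genome-wide mean signal per
bin, and a bin is called present when its rounded count $c$ satisfies
$P(X \ge c; \lambda) \le 10^{-4}$ — the conventional Poisson-threshold
binarization with its standard default. No control track or local
background is supported; with strong, localized signal the global mean
approximates the background well, but when a mark occupies a large
genome fraction the mixture inflates $\lambda$ and attenuates presence
calls. The synthetic generator's defaults (present bins
Poisson(10), absent Poisson(0.2), a dominant low-signal background
state) keep this attenuation moderate; the HMM is robust to it because
it refits emissions to the calls it is given, but recovered emission
*probabilities* then describe the calls, not the generating marks.

**Model.** Given binary calls $x_{tm}$, state $s$ emits marks
independently: $P(x_t \mid s) = \prod_m E_{sm}^{x_{tm}}
(1-E_{sm})^{1-x_{tm}}$. Chromosomes are independent sequences sharing
parameters. `learn_chromatin_model()` runs Baum–Welch EM with the
scaled forward–backward recursions implemented in C++ (per-position
scaling constants; the emission row maximum is factored out before
exponentiation so likelihoods never underflow). Parameters are clamped
to $[10^{-6}, 1-10^{-6}]$ and transition rows renormalized after
flooring. Initialization is seeded: emissions uniform on (0.1, 0.9),
transitions near-uniform with a 0.5 self-transition bias (chromatin
states are strongly persistent at 200 bp), initial distribution
uniform. Three random restarts by default, keeping the best final
log-likelihood; convergence when the per-iteration improvement falls
below `tol = 1e-4` (absolute log-likelihood units), with a 200
iteration cap. A 1-state model is solved in closed form (emissions =
column means). After fitting, states are relabelled by descending
total emission mass so state ids are stable across runs.

**Decoding.** `segment_states()` assigns each bin its
maximum-posterior state by default (the behaviour of the standard
tooling), with Viterbi available; posterior rows sum to 1 and ties in
the argmax break to the lower state index. Segmentations export as
BED4 with adjacent same-state bins merged, losslessly reversible to
per-bin states.

**Model comparison.** With no likelihood-comparable reference, model
sweeps are judged by emission similarity: for each candidate state,
the maximum Pearson correlation of its emission vector over the
reference's states (constant vectors give `NA`). The published
practice of sweeping 10–50 states and picking "the best by similarity"
leaves the criterion open; `compare_model_sweep()` emits the full
table and recommends the *smallest* candidate whose median
max-correlation against the largest swept model reaches 0.95 — an
explicitly labelled heuristic, not a likelihood criterion.

**Fold enrichment.** Features rasterize to bins (≥ 1 bp overlap
counts), and
$\mathrm{fold}(s,f) = \frac{\mathrm{bins}(s\cap f)/\mathrm{bins}(s)}
{\mathrm{bins}(f)/\mathrm{bins}(\mathrm{genome})}$, with `NA` for
states holding no bins. Binarized marks can be scored as additional
feature columns with the same formula.

## Synthetic data: what it emulates, and what it does not

The generators produce every input the pipeline consumes, with planted
truth, so recovery is testable end to end at desk scale.

- `simulate_expression()` drives each planted module by a latent
  per-sample profile: member log-expression is
  $\mu_g + \sqrt\rho\,L + \sqrt{1-\rho}\,\varepsilon$, giving pairwise
  within-module correlation exactly $\rho$ in expectation (a
  latent-factor construction rather than copulas — simpler, and the
  correlation target is exact). Mapping to FPKM as $2^g - 1$ makes the
  pipeline's $\log_2(\mathrm{FPKM}+1)$ transform recover the latent
  scale identically. Defaults: 200 genes, 200 samples, 10 modules × 8
  genes, $\rho = 0.9$ — module sizes and correlations typical of tight
  co-expression clusters, with a background-dominated universe so decoy
  gene sets stay uncorrelated.
- `simulate_gene_sets()` yields one term per planted module
  (subsampled into the 4–20 window) plus random decoys.
- `simulate_promoters()` plants a fixed number of non-overlapping
  motif copies (default 2, default motif the G-box CACGTG) in each
  foreground promoter over i.i.d. background at 40% GC; 50 foreground
  / 450 background genes by default.
- `simulate_chromatin()` samples a state path from a known sticky
  3-state HMM over 4 marks (one near-silent background state occupying
  most bins), then mark presence from the emissions and counts from
  the two-level Poisson signal model; the truth carries the model, the
  path and the exact Bernoulli calls, so EM recovery can be tested
  separately from binarization.

What the generators do **not** emulate: mean–variance relationships
and replicate structure of real RNA-seq, spatial autocorrelation of
expression along chromosomes, GC- and mappability-dependent coverage
bias, correlated neighbouring bins within a chromatin mark beyond what
the state path induces, TF motif positional preference within
promoters, and overlapping/nested gene models. Passing recovery tests
on these simulations therefore demonstrates correctness of the
statistics and algorithms, not robustness to every artefact of real
data.

## Problem sizes and seeds

The suite's simulation-based checks use 200-gene expression matrices,
20,000-bin chromatin simulations, 500-promoter universes with 1,000
background draws, and 50 random graphs of up to 25 nodes for the
clique-percolation oracle — sizes at which brute-force oracles remain
exact and the full suite runs in well under a minute. All stochastic
steps take explicit seeds and restore the caller's RNG state, so every
reported number is bit-reproducible.

## Known limitations

- Mutual ranks are computed against all measured genes; restricting
  the rank universe (e.g. to coding genes only) changes MR values.
- The AUROC tuner scores thresholded networks, not raw PCC, so its
  resolution is limited by the grid supplied.
- Clique percolation is exact but exponential in the worst case; on
  dense graphs with thousands of large overlapping cliques the
  union-find stage dominates.
- The binarizer's global-mean background (discussed above) understates
  presence for very broad marks; a control-track or locally adaptive
  background is out of scope.
- Emission-similarity model choice is a heuristic; it cannot detect a
  state that the largest reference model itself failed to separate.
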