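---
title: "Multi-criteria codon design: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-criteria codon design: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonkit)
```

Heterologous protein expression is limited, among other things, by the
mismatch between a gene's codon usage and the tRNA economy of the production
host (*E. coli*, *S. cerevisiae*, CHO and the like). codonkit implements the
quantitative scaffolding of host-aware gene design: usage references
estimated from coding-sequence corpora, a multi-criteria scoring suite,
two reference design strategies, and tools for comparing families of
candidate sequences. This vignette is the package's own account of the
underlying models, the defaults, and the numerical decisions a user should
know before trusting a number.

## Usage references

All statistics are organized around **synonymous families**: the codons
encoding one amino acid under the standard genetic code (61 sense codons, 20
families). From a corpus of coding sequences, `codon_usage_table()` pools
in-frame codon counts $f_c$ and derives, within each family $A$,

$$p_c = \frac{f_c}{f_A}, \qquad
  w_c = \frac{f_c}{\max_{c' \in A} f_{c'}},$$

the family-normalized frequency and the relative adaptiveness. Terminal
stop codons are excluded from every count: they encode no amino acid, and
adaptiveness is undefined on them. Codons never observed in the corpus
receive a pseudocount (default 0.5) before $w$ is computed, so $w>0$
everywhere; without it, a single host-rare codon would drive the codon
adaptation index of any sequence containing it to exactly zero, which says
more about finite corpus size than about the sequence. The pseudocount does
not affect $p$, which is reported from raw counts.

`codon_pair_table()` does the analogous bookkeeping for ordered adjacent
codon pairs (counted within, never across, sequences) and scores each
observed pair with the codon-pair score

$$\mathrm{cps}(AB) \;=\;
  \ln\frac{F(AB)}{\dfrac{F(A)\,F(B)}{F(X)\,F(Y)}\;F(XY)},$$

the log-ratio of the observed pair count to the count expected if codons
combined independently given amino-acid-pair usage ($X$, $Y$ are the amino
acids of codons $A$, $B$). A corpus in which every amino acid is encoded by
a single codon is exactly pair-independent, and indeed scores
$\mathrm{cps} \equiv 0$ — the test suite uses this constructed null.

**Highly expressed references.** `select_highly_expressed()` subsets a
corpus to the top expression quantile before table building (conventionally
the top 10% for microbial hosts and 5% for mammalian ones, reflecting genome
size). The threshold is the expression value at rank
$\lceil \text{fraction} \times n\rceil$; every gene tying that value is
included, with deterministic ordering (expression descending, then id), so
re-runs are reproducible even with tied quantifications. The HE table is
**count-pooled** over the selected genes; a per-gene-averaged alternative
would down-weight long genes but has no support in common practice, so it
is not offered.

## The metric suite

For a candidate sequence with sense codons $c_1,\dots,c_N$:

* **CAI** $= \exp\!\big(\tfrac1N \sum_i \ln w_{c_i}\big)$, the geometric
  mean of relative adaptiveness, in $(0,1]$. Single-synonym codons (Met,
  Trp) count toward $N$ with $w=1$, matching the definition in which $N$ is
  the total codon count. The implementation is in log space; the test suite
  checks it against a direct product-of-roots oracle to $10^{-12}$.
* **GC content** is the plain percent of G+C over the full CDS, *including*
  a terminal stop codon when present: annotated CDS records include the
  stop, and published wild-type GC values are quoted on the full CDS.
  Positional GC (GC1/GC2/GC3) is computed over all codons with nothing
  excluded, so $\tfrac13(\mathrm{GC1}+\mathrm{GC2}+\mathrm{GC3})$ equals
  the overall GC exactly — an identity the suite verifies on 1,000 random
  sequences.
* **ICU** (individual codon usage fitness)
  $= -\sum_c |p^0_c - p^1_c|$, the negative Manhattan distance between host
  ($p^0$) and sequence ($p^1$) family-normalized frequencies, summed over
  the codons of amino acids present in the sequence (for an absent family
  $p^1$ is undefined, so it contributes nothing). 0 is optimal; each family
  contributes at least $-2$.
* **CC** (codon context fitness) is the same distance over adjacent-pair
  distributions $q$ normalized within amino-acid pairs, restricted to the
  amino-acid pairs present in the sequence. Host pairs never observed have
  $q^0 = 0$ on the union support.
* **CPB** is the arithmetic mean of host $\mathrm{cps}$ over the sequence's
  adjacent pairs. Pairs absent from the host table have no score: the
  default is to skip them and report how many were skipped; a hard-error
  mode exists for pipelines that must not silently lose pairs.
* **Restriction screening** reports every occurrence (overlapping included,
  0-based) of the configured motifs; EcoRI (GAATTC), ApaI (GGGCCC) and NcoI
  (CCATGG) are built in. Scanning is sense-strand by default — design
  workflows screen the coding strand — with an option to also scan motif
  reverse complements.

`score_sequence()` bundles the suite into one report row per sequence,
serializable as TSV or JSON. Values are stored at full precision;
percentages are rounded only at presentation time.

## Design strategies

`optimize_sequence()` implements the two strategies that bracket common
practice:

* **`max_cai`** (one amino acid-one codon): each residue gets its family's
  top-$w$ codon, ties broken alphabetically. CAI of the output is 1.0 by
  construction. Deterministic.
* **`sampled`**: each residue's codon is drawn from the family's host
  frequencies $p$, which matches the host distribution in expectation and
  drives ICU toward 0 as the design grows. Reproducible under a fixed seed
  (the seed is recorded in the result).

**Motif constraints.** Both strategies guarantee the returned sequence is
free of the forbidden motifs or fail loudly. For `max_cai` the repair is
deterministic: the leftmost offending window is examined, single-codon
substitutions are tried left-to-right within the window with synonyms in
descending $w$ (ties alphabetical), then pairs of codons; the first
substitution set that reduces the motif count is applied and logged in
`constraint_log`. A window no synonym combination can clear raises an error
naming the motif and position (Met-Trp runs are the canonical example: both
families have one codon). For `sampled`, the codons overlapping the window
are redrawn up to `max_resample_attempts` (default 100) times. The
`gc_window` option is advisory — a violation warns rather than fails —
because GC is a descriptive criterion, not a constraint-solver target, in
this framework.

The optimizer returns the protein-coding region only (translation fidelity
is exact: `translate_cds()` of the output is the input protein). The
synthetic generator's `sample_cds()`, by contrast, emits a complete CDS with
ATG start and a stop codon drawn uniformly from the three stops, because it
stands in for annotated host records. When the two are compared (one-hot
bias makes sampling degenerate to the max-CAI design) the comparison is on
the coding region minus the stop.

## Folding stability

`fold_mrna()` exposes folding through named engines. The `"rnafold"` engine
shells out to ViennaRNA's `RNAfold` and returns a thermodynamic MFE in
kcal/mol with its dot-bracket structure. The built-in `"fallback"` engine is
deliberately not thermodynamic: it maximizes weighted base pairing
(GC $=-3$, AU $=-2$, GU $=-1$, arbitrary units; minimum hairpin loop 3;
Nussinov-style dynamic programming) and is intended as a self-contained
stability proxy for tests and for ordering sequences by pairing potential.
Results always carry the engine name so proxy scores and free energies are
never mixed silently. Sequences under 8 nt return 0 with no structure — too
short for any pair given the loop minimum plus a margin. The fallback is
cubic in length; for full-length mRNAs use `"rnafold"`. Any engine matching
the contract (RNA string in, `delta_g` + structure out) can be added with
`register_fold_engine()`.

## Comparing sequence sets

`usage_matrix()` maps each sequence to its 61-dimensional vector of
family-normalized codon frequencies (fixed alphabetical codon order; absent
families 0-filled). PCA (`usage_pca()`) is a column-centered SVD with **no
column scaling**: scaling to unit variance would let codons of rare families
dominate purely through their noise. Component signs follow a fixed
convention (largest-magnitude loading positive). Explained-variance ratios
are relative to the total variance of the matrix, so they are comparable
across choices of $k$. Clustering (`usage_hclust()`) is average-linkage
(UPGMA) on Euclidean distances, checked in the suite against a textbook
brute-force implementation; the package reports the dendrogram and lets the
user supply $k$ for a flat cut — cluster count is a judgment call, not an
estimate. `correlation_report()` gives the pairwise Pearson matrix over
ICU, CC and CAI; a constant column (CAI is identically 1 across a set of
max-CAI designs) makes its correlations undefined, and the package flags
those entries as `NA` with warnings instead of fabricating zeros.

## The synthetic-data generator

`bias_spec()`/`random_bias()` define per-family codon distributions;
`make_corpus()` draws coding sequences from them (lengths uniform over
100–700 codons by default, spanning typical design targets from
hormone-sized to enzyme-sized proteins) with log-normal expression values,
optionally sampling the top-expressed fraction from a second bias so that
highly-expressed-gene selection has a genuine signal to recover. The
generator emulates codon bias structure and expression ranking — it does
**not** model real amino-acid composition, length distributions, GC
isochores, splice or UTR features, or noise in expression quantification.
Tests passing on this generator therefore validate the estimators and
algorithms, not claims about any particular organism.

## Problem sizes and convergence rates in the checks

Two checks deserve an explicit statement of their conditions, both of which
follow from the central-limit rate $\mathbb{E}\,|\hat p - p| \sim
\sqrt{p(1-p)/n}$ of empirical frequencies:

* **Bias recovery** is measured with `usage_bias_l1()`, the family-weighted
  L1 distance $\sum_A \frac{f_A}{N} \sum_{c\in A} |\hat p_c - p^*_c|$,
  i.e. the L1 distance between the observed joint codon distribution and
  the one the generating bias implies at the observed amino-acid
  composition. This weighting isolates codon-choice error from amino-acid
  sampling noise and converges at the $N^{-1/2}$ rate; at $N \ge 50{,}000$
  codons it sits well under 0.05. The *unweighted* sum of per-family L1
  errors does not share this property: with ~18 multi-codon families of
  ~2,500 draws each it plateaus near 0.5 regardless of how faithful the
  generator is, which makes it useless as a recovery criterion.
* **Sampling drives ICU to 0** is demonstrated on a 5,000-residue
  single-family design (a Lys homopolymer), where all draws accumulate in
  one two-codon family and $|\mathrm{ICU}|$ lands near
  $2\sqrt{2\,p(1-p)/(\pi n)} \approx 0.01$. With a full 20-amino-acid
  protein the same statistic is the *sum* of ~18 family errors of ~250
  draws each — about 1.0 at 5,000 codons, shrinking only like the square
  root of length. The homopolymer condition is what makes the convergence
  visible at a tractable problem size; the estimator itself is unchanged.

Other fixed choices: the folding-oracle comparison enumerates all
non-crossing pair subsets for 200 random sequences of 8–12 nt (beyond 12 nt
enumeration explodes combinatorially without adding coverage); the
clustering oracle runs on 6-row matrices, large enough for non-trivial merge
orders and small enough for the $O(n^3)$ brute force.

## Degenerate inputs and tie-breaking, collected

* Records failing CDS validation are excluded with logged reasons, never
  silently dropped; empty files and empty record sets are errors.
* A host family entirely absent from a corpus gets uniform sampling weight
  in the `sampled` strategy and $w = 1$ for all its codons (pseudocount over
  pseudocount), a neutral prior.
* HE selection ties at the quantile boundary are all included.
* Synonym order everywhere is descending $w$ with alphabetical tie-break;
  matrix columns are the 61 sense codons alphabetically; merge ties in
  clustering resolve to the lowest row index (the behaviour of
  `stats::hclust`, which backs the surface).
* Serialization carries a format version and the full 61-codon set; a
  missing codon row or an incompatible major version is an error, a newer
  minor version is accepted.

## Known limitations

* ICU/CC/CPB depend on the reference corpus; tables built from small
  corpora embed sampling noise that these metrics then treat as host truth.
  Compare tables from corpora of similar depth.
* The fallback folding score is a pairing proxy: correct for ordering
  hairpin potential in tests, wrong in absolute value, and blind to stacking
  and loop entropies. Thermodynamic statements require the `rnafold`
  engine.
* The optimizer's motif repair is greedy-minimal, not globally optimal in
  the number of substitutions; for the 6-nt motifs it targets this is
  almost always the true minimum (one substitution).
* No model of translation initiation regions, codon ramps, or local
  windowed GC — the GC window is sequence-global and advisory.
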