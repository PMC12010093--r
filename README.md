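# codonkit

Multi-criteria codon usage analysis and synthetic gene design in R.

Expressing a heterologous protein in *E. coli*, *S. cerevisiae* or CHO
cells usually means recoding the gene: the same protein admits an
astronomical number of synonymous coding sequences, and hosts translate
them very differently depending on how well the codon (and codon-pair)
usage matches their own. codonkit is for protein engineers and synthetic
biologists who want the quantitative machinery of that workflow under their
own control rather than inside a vendor's black box:

* **Host references** — codon usage tables ($p_c = f_c/f_A$, relative
  adaptiveness $w_c = f_c/\max_{c'\in A} f_{c'}$) and codon-pair tables
  (pair frequencies $q$ and codon-pair scores
  $\mathrm{cps}(AB)=\ln\frac{F(AB)}{F(A)F(B)/(F(X)F(Y))\cdot F(XY)}$)
  built from CDS corpora, with highly-expressed-gene subsetting by
  expression quantile.
* **Metric suite** — CAI (geometric mean of $w$), overall and positional
  GC (GC1/GC2/GC3), ICU and CC fitness (negative Manhattan distance between
  host and sequence codon / codon-pair distributions; 0 is optimal), CPB
  (mean codon-pair score), restriction-site screening (EcoRI, ApaI, NcoI
  built in), and mRNA folding ΔG via ViennaRNA's RNAfold or a built-in
  pairing-proxy fallback.
* **Design strategies** — `max_cai` (one amino acid-one codon; CAI = 1 by
  construction) and `sampled` (usage-matched sampling; ICU → 0), both with
  guaranteed removal of forbidden motifs and a logged intervention trail.
* **Set comparison** — 61-dimensional usage vectors, centered PCA,
  average-linkage clustering, and ICU/CC/CAI correlation matrices, for
  comparing the outputs of different design tools or strategies.
* **Synthetic data** — corpus and expression-table generators with
  controllable per-family codon bias, so every analysis here is
  reproducible offline.

## Worked example

Score the wild-type human preproinsulin CDS (shipped under
`inst/extdata/`) against a synthetic host reference, then recode it:

```r
library(codonkit)

ins <- read_cds_fasta(
  system.file("extdata", "insulin_wt_cds.fasta", package = "codonkit"),
  quiet = TRUE
)
round(gc_content(ins[[1]]), 2)      # 64.56  (% G+C of the full CDS)
nchar(translate_cds(ins[[1]]))      # 110    (preproinsulin residues)

host <- make_corpus(50, c(200, 500), bias = random_bias(0.8, seed = 101),
                    seed = 102)
tab <- codon_usage_table(host$sequences)
pt  <- codon_pair_table(host$sequences)

score_sequence(ins[[1]], tab, pair_table = pt,
               fold_engine = "rnafold", id = "INS_wt")
#> <metrics_report 'INS_wt'> (110 codons)
#>   CAI 0.2873 | GC 64.56% (GC1 69.37, GC2 44.14, GC3 80.18)
#>   ICU -18.5082 | CC -137.3400 | CPB 0.1379 | dG -147.20 [rnafold]
#>   restriction hits: 1

opt <- optimize_sequence(translate_cds(ins[[1]]), tab, strategy = "max_cai")
score_sequence(opt$nt, tab, pair_table = pt, id = "INS_max_cai")
#> <metrics_report 'INS_max_cai'> (110 codons)
#>   CAI 1.0000 | GC 49.09% (GC1 70.91, GC2 44.55, GC3 31.82)
#>   ICU -13.3629 | CC -92.7529 | CPB 0.0155 | dG NA
#>   restriction hits: 0
```

Reading the numbers: the wild type is poorly adapted to this (synthetic)
host — CAI 0.29 against a maximum of 1, ICU far from its optimum of 0, and
one restriction hit that would complicate cloning. The one-amino-acid-one-
codon design reaches CAI 1.0 exactly, moves ICU and CC toward 0, drops GC3
sharply (the third position is where synonymous recoding has freedom), and
is guaranteed free of EcoRI/ApaI/NcoI sites. `delta_g` is `NA` unless a
folding engine is requested.

A command-line wrapper with `build-table`, `score`, `optimize` and
`compare` subcommands is installed as `exec/codonkit`:

```sh
Rscript "$(Rscript -e 'cat(system.file("exec","codonkit",package="codonkit"))')" \
  build-table --corpus corpus.fasta --out tables/
```

For the models, defaults and numerical decisions, see
`vignettes/codon-design-methods.Rmd`.

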