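#' Specify a synthetic host codon bias
#'
#' A bias is a per-family codon probability vector: for every amino acid, a
#' distribution over its synonymous codons. [sample_cds()] and
#' [make_corpus()] draw codons from it, so a usage table built from the
#' resulting corpus converges to the bias as the corpus grows -- the
#' parameter-recovery property the test suite checks.
#'
#' @param p Optional named list, amino acid to probability vector named by
#'   codon (each summing to 1). Families omitted fall back to `default`.
#' @param default Fill-in for unspecified families: `"uniform"` (equal
#'   probability), `"gc3"` (all mass on the family's most G/C-rich codon,
#'   alphabetical tie-break), or `"at3"` (most A/T-rich codon). The one-hot
#'   fills emulate strongly biased hosts.
#' @param code A [genetic_code()].
#' @return A `bias_spec`: named list of per-family probability vectors.
#' @examples
#' b <- bias_spec(p = list(K = c(AAA = 0.7, AAG = 0.3)))
#' b$K
#' @export
bias_spec <- function(p = NULL, default = c("uniform", "gc3", "at3"),
                      code = genetic_code()) {
  default <- match.arg(default)
  out <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    if (!is.null(p) && aa %in% names(p)) {
      v <- p[[aa]]
      if (!setequal(names(v), fam)) {
        stop("bias for ", aa, " must be named by its codons: ",
             paste(fam, collapse = ", "))
      }
      v <- v[fam]
      if (any(v < 0) || abs(sum(v) - 1) > 1e-9) {
        stop("bias for ", aa, " must be a probability vector summing to 1")
      }
      return(v)
    }
    switch(default,
      uniform = stats::setNames(rep(1 / length(fam), length(fam)), fam),
      gc3 = one_hot(fam, decreasing = TRUE),
      at3 = one_hot(fam, decreasing = FALSE)
    )
  })
  names(out) <- names(code$families)
  structure(out, class = "bias_spec")
}

# One-hot on the codon with the most (or least) G/C bases.
one_hot <- function(fam, decreasing) {
  gc <- nchar(gsub("[AT]", "", fam))
  pick <- fam[order(if (decreasing) -gc else gc, fam)][1L]
  stats::setNames(as.numeric(fam == pick), fam)
}

#' Random bias with controllable concentration
#'
#' Draws each family's probability vector from a symmetric Dirichlet
#' (gamma-normalization); small `concentration` gives strongly skewed
#' biases, large gives near-uniform ones.
#'
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed Integer seed.
#' @param code A [genetic_code()].
#' @return A `bias_spec`.
#' @export
random_bias <- function(concentration = 1, seed = 1L, code = genetic_code()) {
  stopifnot(concentration > 0)
  with_seed(seed, {
    out <- lapply(code$families, function(fam) {
      g <- stats::rgamma(length(fam), shape = concentration)
      while (sum(g) == 0) g <- stats::rgamma(length(fam), shape = concentration)
      stats::setNames(g / sum(g), fam)
    })
    structure(out, class = "bias_spec")
  })
}

#' @export
print.bias_spec <- function(x, ...) {
  skew <- vapply(x, max, numeric(1))
  cat(sprintf(
    "<bias_spec>: %d families, mean max-codon probability %.2f\n",
    length(x), mean(skew)
  ))
  invisible(x)
}

#' Sample a coding sequence under a codon bias
#'
#' Draws one synonymous codon per residue from `bias`. When only a length is
#' given, a random protein is drawn first (uniform over the 20 amino acids,
#' forced to start with Met). The output is a complete, valid CDS: it starts
#' with ATG and ends with a stop codon drawn uniformly from the three stops.
#'
#' @param protein Protein string; mutually exclusive with `length`.
#' @param length Number of residues of a random protein (>= 1).
#' @param bias A `bias_spec`.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param code A [genetic_code()].
#' @return A single-element `cds_set`.
#' @export
sample_cds <- function(protein = NULL, length = NULL, bias = bias_spec(),
                       seed = 1L, code = genetic_code()) {
  stopifnot(inherits(bias, "bias_spec"))
  if (is.null(protein) == is.null(length)) {
    stop("give exactly one of protein or length")
  }
  with_seed(seed, {
    if (is.null(protein)) {
      stopifnot(length >= 1L)
      protein <- paste(
        c("M", sample(names(code$families), length - 1L, replace = TRUE)),
        collapse = ""
      )
    }
    aas <- strsplit(toupper(protein), "")[[1L]]
    bad <- setdiff(aas, names(code$families))
    if (length(bad)) stop("non-standard residue(s): ", paste(unique(bad), collapse = ""))
    if (aas[1L] != "M") {
      aas <- c("M", aas) # ATG-prepended so the record is a valid CDS start
    }
    codons <- vapply(aas, function(a) {
      fam <- names(bias[[a]])
      if (length(fam) == 1L) fam else sample(fam, 1L, prob = bias[[a]])
    }, character(1), USE.NAMES = FALSE)
    stop_codon <- sample(code$stops, 1L)
    as_cds_set(stats::setNames(
      paste(c(codons, stop_codon), collapse = ""), "synthetic_cds"
    ))
  })
}

#' Generate a synthetic host corpus with an expression table
#'
#' Emulates the reference input of a host codon-usage analysis: `n_genes`
#' coding sequences with lengths drawn uniformly from `length_range` (in
#' codons; the default 100-700 spans typical target genes), codons drawn
#' from `bias`, and a log-normal expression value per gene. When `he_bias`
#' is supplied, the top `he_fraction` of genes by expression are sampled
#' from it instead, so [select_highly_expressed()] has a real signal to
#' recover: the highly expressed subset genuinely has a different codon
#' usage, as in real transcriptomes.
#'
#' This generator emulates bias and expression structure only -- not genome
#' length distributions, amino-acid composition, GC isochores or noise in
#' expression quantification.
#'
#' @param n_genes Number of genes (>= 1).
#' @param length_range Codon-count range, inclusive.
#' @param bias Background `bias_spec`.
#' @param he_bias Optional `bias_spec` for the highly expressed genes.
#' @param he_fraction Fraction of genes treated as highly expressed.
#' @param expr_meanlog,expr_sdlog Log-normal expression parameters.
#' @param seed Integer seed; output is byte-identical for a fixed seed.
#' @param code A [genetic_code()].
#' @return List with `sequences` (a `cds_set`) and `expression` (data frame
#'   `gene_id`, `expression`).
#' @export
make_corpus <- function(n_genes, length_range = c(100L, 700L),
                        bias = bias_spec(), he_bias = NULL,
                        he_fraction = 0.10,
                        expr_meanlog = 3, expr_sdlog = 1,
                        seed = 1L, code = genetic_code()) {
  stopifnot(n_genes >= 1L, length_range[1L] >= 1L,
            length_range[1L] <= length_range[2L])
  with_seed(seed, {
    ids <- sprintf("gene_%04d", seq_len(n_genes))
    lens <- sample(length_range[1L]:length_range[2L], n_genes, replace = TRUE)
    expr <- stats::rlnorm(n_genes, meanlog = expr_meanlog, sdlog = expr_sdlog)
    n_he <- if (is.null(he_bias)) 0L else ceiling(he_fraction * n_genes)
    he_ids <- if (n_he > 0L) ids[order(-expr, ids)][seq_len(n_he)] else character(0)
    seqs <- vapply(seq_len(n_genes), function(i) {
      b <- if (ids[i] %in% he_ids) he_bias else bias
      sub_seed <- sample.int(.Machine$integer.max, 1L)
      as.character(sample_cds(length = lens[i], bias = b, seed = sub_seed,
                              code = code))
    }, character(1))
    list(
      sequences = as_cds_set(stats::setNames(seqs, ids)),
      expression = data.frame(
        gene_id = ids, expression = expr, stringsAsFactors = FALSE
      )
    )
  })
}

#' Empirical per-family codon frequencies of a usage table as a bias
#'
#' Convenience for comparing a recovered table against a generating
#' [bias_spec()] (e.g. in L1 distance).
#'
#' @param table A [codon_usage_table()].
#' @return A `bias_spec` (families absent from the table become uniform).
#' @export
bias_from_table <- function(table) {
  stopifnot(inherits(table, "codon_usage_table"))
  code <- table$code
  out <- lapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    tot <- sum(table$counts[fam])
    if (tot == 0) {
      stats::setNames(rep(1 / length(fam), length(fam)), fam)
    } else {
      table$counts[fam] / tot
    }
  })
  names(out) <- names(code$families)
  structure(out, class = "bias_spec")
}

#' Family-weighted L1 between a usage table and a generating bias
#'
#' L1 distance between the joint codon distribution observed in a table and
#' the distribution a [bias_spec()] implies at the table's own amino-acid
#' composition:
#' \deqn{\sum_A \frac{f_A}{N} \sum_{c \in A} |p_c - bias_A(c)|}
#' This isolates codon-choice error from amino-acid sampling noise, so it
#' converges to 0 as the corpus grows regardless of protein composition.
#'
#' @param table A [codon_usage_table()].
#' @param bias The generating `bias_spec`.
#' @return Non-negative number in \[0, 2\].
#' @export
usage_bias_l1 <- function(table, bias) {
  stopifnot(inherits(table, "codon_usage_table"), inherits(bias, "bias_spec"))
  code <- table$code
  n <- sum(table$counts)
  sum(vapply(names(code$families), function(aa) {
    fam <- code$families[[aa]]
    fa <- sum(table$counts[fam])
    if (fa == 0) return(0)
    (fa / n) * sum(abs(table$counts[fam] / fa - bias[[aa]][fam]))
  }, numeric(1)))
}

#' L1 distance between two biases
#'
#' Sum over families of the L1 distance between per-family probability
#' vectors, optionally restricted to families named in `families`.
#'
#' @param a,b `bias_spec` objects over the same code.
#' @param families Optional subset of amino acids.
#' @return Non-negative number; 0 iff identical on the compared families.
#' @export
bias_l1 <- function(a, b, families = NULL) {
  stopifnot(inherits(a, "bias_spec"), inherits(b, "bias_spec"))
  fams <- if (is.null(families)) names(a) else families
  sum(vapply(fams, function(aa) sum(abs(a[[aa]] - b[[aa]][names(a[[aa]])])),
             numeric(1)))
}
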