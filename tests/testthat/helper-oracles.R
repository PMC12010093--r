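# Independent oracles and tiny fixtures used across the suite. These stay
# deliberately naive: direct products, explicit subset enumeration, textbook
# UPGMA -- structurally different from the implementations they check.

# Geometric mean of w by direct product of per-codon N-th roots (the plain
# product underflows past a few hundred codons).
oracle_cai <- function(nt, table) {
  cod <- substring(nt, seq(1, nchar(nt) - 2, 3), seq(3, nchar(nt), 3))
  aa <- table$code$table[cod]
  cod <- cod[aa != "*"]
  prod(table$w[cod]^(1 / length(cod)))
}

# Maximum weighted non-crossing pairing by exhaustive enumeration of pair
# subsets (valid = index-disjoint and non-crossing), for sequences <= 12 nt.
oracle_fold_score <- function(rna, min_hairpin = 3L) {
  bases <- strsplit(rna, "")[[1L]]
  n <- length(bases)
  wt <- function(a, b) {
    switch(paste0(a, b),
      GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1, 0
    )
  }
  cand <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i > min_hairpin && wt(bases[i], bases[j]) > 0) {
        cand[[length(cand) + 1L]] <- c(i, j, wt(bases[i], bases[j]))
      }
    }
  }
  if (length(cand) == 0L) return(0)
  nc <- length(cand)
  compat <- matrix(FALSE, nc, nc)
  for (a in seq_len(nc)) {
    for (b in seq_len(nc)) {
      if (a == b) next
      p <- cand[[a]]; q <- cand[[b]]
      disjoint <- length(intersect(p[1:2], q[1:2])) == 0L
      # non-crossing: nested or side-by-side
      nested <- (p[1] < q[1] && q[2] < p[2]) || (q[1] < p[1] && p[2] < q[2])
      apart <- p[2] < q[1] || q[2] < p[1]
      compat[a, b] <- disjoint && (nested || apart)
    }
  }
  best <- max(vapply(cand, `[`, numeric(1), 3L))
  max_size <- min(nc, n %/% 2L)
  for (size in 2:max_size) {
    if (size > nc) break
    for (idx in utils::combn(nc, size, simplify = FALSE)) {
      ok <- TRUE
      for (a in seq_along(idx)) {
        for (b in seq_along(idx)) {
          if (a < b && !compat[idx[a], idx[b]]) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) {
        s <- sum(vapply(idx, function(i) cand[[i]][3L], numeric(1)))
        if (s > best) best <- s
      }
    }
  }
  best
}

# Textbook UPGMA on a Euclidean distance matrix: returns merge heights
# (sorted) and the flat partitions at every k, for comparison with hclust.
oracle_upgma <- function(m) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))
  active <- seq_len(n)
  heights <- numeric(0)
  partitions <- list()
  cdist <- function(a, b) {
    mean(d[clusters[[a]], clusters[[b]], drop = FALSE])
  }
  while (length(active) > 1L) {
    best <- c(NA, NA); bd <- Inf
    for (ai in seq_along(active)) {
      for (bi in seq_along(active)) {
        if (ai < bi) {
          dd <- cdist(active[ai], active[bi])
          if (dd < bd - 1e-12) { bd <- dd; best <- c(active[ai], active[bi]) }
        }
      }
    }
    heights <- c(heights, bd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active <- setdiff(active, best[2])
    part <- integer(n)
    for (ai in seq_along(active)) part[clusters[[active[ai]]]] <- ai
    partitions[[length(partitions) + 1L]] <- part
  }
  list(heights = heights, partitions = partitions)
}

# Canonical form of a flat partition (label by first appearance), so two
# labelings of the same grouping compare equal.
canon_partition <- function(p) {
  as.integer(factor(p, levels = unique(p)))
}

# Random valid CDS (no motif guarantees) for fuzzing.
random_cds <- function(n_codons, seed) {
  set.seed(seed)
  code <- genetic_code()
  paste(sample(code$codons, n_codons, replace = TRUE), collapse = "")
}

# A tiny two-family usage table with known w values:
# K: AAA x3, AAG x1 -> w = 1, 1/3; N: AAT x2, AAC x2 -> w = 1, 1.
tiny_table <- function(pseudocount = 0.5) {
  codon_usage_table(
    c(g1 = "ATGAAAAAAAAAAAGAATAATAACAACTAA"),
    pseudocount = pseudocount
  )
}

write_tmp_fasta <- function(lines) {
  fa <- tempfile(fileext = ".fasta")
  writeLines(lines, fa)
  fa
}
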