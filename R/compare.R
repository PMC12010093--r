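#' Codon usage matrix of a sequence set
#'
#' One row per sequence, one column per sense codon (61 under the standard
#' code, fixed alphabetical order), entries the sequence's own
#' family-normalized codon frequencies `p`; codons of amino acids absent
#' from a sequence are 0. This is the feature matrix behind the PCA and
#' clustering comparisons of optimization outputs.
#'
#' @param seqs A `cds_set` or named character vector of coding sequences.
#' @param code A [genetic_code()].
#' @return Numeric matrix, rows named by sequence id, 61 columns.
#' @export
usage_matrix <- function(seqs, code = genetic_code()) {
  if (length(seqs) == 0L) stop("empty sequence set")
  rows <- t(vapply(unclass(seqs), function(nt) {
    cod <- sense_codons(nt, code)
    counts <- table(factor(cod, levels = code$codons))
    counts <- stats::setNames(as.integer(counts), code$codons)
    p <- numeric(length(code$codons))
    names(p) <- code$codons
    for (aa in unique(code$table[cod])) {
      fam <- code$families[[aa]]
      p[fam] <- counts[fam] / sum(counts[fam])
    }
    p
  }, numeric(length(code$codons))))
  rownames(rows) <- names(seqs)
  rows
}

#' Principal component analysis of a usage matrix
#'
#' Column-centered singular value decomposition (no column scaling: unit
#' variance would overweight rare families). Component signs follow a fixed
#' convention -- the largest-magnitude loading of each component is positive
#' -- so results are reproducible across platforms.
#'
#' @param m Matrix from [usage_matrix()] (rows >= 2).
#' @param k Number of components, `<= min(nrow(m) - 1, ncol(m))`.
#' @return A `usage_pca`: list with `scores` (rows x k), `loadings`
#'   (columns x k), `explained_variance_ratio` (length k, non-increasing,
#'   sums to <= 1), `center`.
#' @export
usage_pca <- function(m, k = 2L) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L) stop("need at least 2 rows")
  if (k < 1L || k > min(nrow(m) - 1L, ncol(m))) {
    stop("k must be in [1, ", min(nrow(m) - 1L, ncol(m)), "]")
  }
  total_var <- sum(apply(m, 2L, stats::var))
  if (total_var == 0) stop("zero variance: all rows identical")
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k_avail <- min(k, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k_avail), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k_avail), drop = FALSE]
  for (j in seq_len(k_avail)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      scores = scores,
      loadings = loadings,
      explained_variance_ratio = pc$sdev[seq_len(k_avail)]^2 / total_var,
      center = pc$center
    ),
    class = "usage_pca"
  )
}

#' @export
print.usage_pca <- function(x, ...) {
  cat(sprintf(
    "<usage_pca>: %d sequences, %d component(s); variance explained %s\n",
    nrow(x$scores), ncol(x$scores),
    paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio), collapse = ", ")
  ))
  invisible(x)
}

#' Hierarchical clustering of a usage matrix
#'
#' Average-linkage (UPGMA) agglomeration on Euclidean distances between
#' usage rows, as used to group optimization tools by their codon
#' preferences. Merge order is deterministic; equal-distance ties resolve to
#' the lowest row index first (the behaviour of [stats::hclust()], which
#' backs this function).
#'
#' @param m Matrix from [usage_matrix()] (rows >= 2).
#' @param method Linkage passed to [stats::hclust()].
#' @param k Optional number of flat clusters to cut; cluster count is never
#'   estimated automatically.
#' @return The `hclust` object, with an added `clusters` component (named
#'   integer vector) when `k` is given.
#' @export
usage_hclust <- function(m, method = "average", k = NULL) {
  stopifnot(is.matrix(m))
  if (nrow(m) < 2L) stop("need at least 2 rows")
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = method)
  if (!is.null(k)) {
    hc$clusters <- stats::cutree(hc, k = k)
  }
  hc
}

#' Pearson product-moment correlation
#'
#' [stats::cor()] with the preconditions this package's comparisons assume
#' made explicit: equal length >= 3 and non-constant input (the coefficient
#' is undefined on constant vectors, a situation that genuinely arises when
#' every sequence in a set was built by the max-CAI strategy).
#'
#' @param x,y Numeric vectors.
#' @return r in \[-1, 1\].
#' @examples
#' pearson_r(c(1, 2, 3), c(1, 3, 2)) # 0.5
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined on constant input")
  }
  stats::cor(x, y, method = "pearson")
}

#' Correlation matrix of the ICU, CC and CAI metrics
#'
#' Pairwise Pearson correlations over a set of per-sequence metric reports,
#' mirroring the standard cross-metric analysis of optimized sequence sets.
#' A constant metric column (e.g. CAI identically 1 across max-CAI outputs)
#' makes its correlations undefined: those entries are `NA` and flagged with
#' a warning rather than silently zeroed.
#'
#' @param reports List of `metrics_report` objects, or the data frame from
#'   [as_report_frame()]. At least 3 sequences.
#' @param metrics Columns to correlate.
#' @return Symmetric matrix with unit diagonal.
#' @export
correlation_report <- function(reports, metrics = c("icu", "cc", "cai")) {
  df <- if (is.data.frame(reports)) reports else as_report_frame(reports)
  if (nrow(df) < 3L) stop("need at least 3 reports")
  missing_cols <- setdiff(metrics, names(df))
  if (length(missing_cols)) {
    stop("unknown metric column(s): ", paste(missing_cols, collapse = ", "))
  }
  k <- length(metrics)
  r <- matrix(NA_real_, k, k, dimnames = list(metrics, metrics))
  diag(r) <- 1
  constant <- vapply(metrics, function(mm) stats::sd(df[[mm]]) == 0, logical(1))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      if (constant[i] || constant[j]) {
        warning(sprintf(
          "correlation %s-%s undefined: constant column", metrics[i], metrics[j]
        ))
      } else {
        r[i, j] <- r[j, i] <- stats::cor(df[[metrics[i]]], df[[metrics[j]]])
      }
    }
  }
  r
}
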