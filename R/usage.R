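#' Build a codon usage table from a CDS corpus
#'
#' Pools in-frame codon counts over all sequences of a corpus (terminal stop
#' codons excluded -- stops encode no amino acid) and derives, within each
#' synonymous family, the normalized frequency `p` and the relative
#' adaptiveness `w`:
#'
#' \deqn{p_c = f_c / f_A, \qquad w_c = f_c / \max_{c' \in A} f_{c'}}
#'
#' where `f_c` is the codon count and `f_A` the count of its amino acid.
#' Codons with zero count are given `pseudocount` before `w` is computed, so
#' `w > 0` everywhere and the codon adaptation index of a sequence never
#' collapses to zero because one rare codon was unobserved in the reference.
#' `p` is reported from the raw counts (codons of amino acids absent from the
#' corpus have `p = 0`).
#'
#' @param corpus A `cds_set` or named character vector of coding sequences.
#' @param code A [genetic_code()].
#' @param pseudocount Substitute for zero counts before computing `w`.
#' @param source_label Free label recorded in the table, conventionally
#'   `"genome"` or `"HE"` (highly expressed subset).
#' @return A `codon_usage_table` with components `counts`, `aa_totals`, `p`,
#'   `w` (all named over the 61 sense codons / 20 amino acids in alphabetical
#'   order), `pseudocount`, `source_label`, `code`.
#' @examples
#' tab <- codon_usage_table(c(g1 = "ATGAAAAAATAA"))
#' tab$counts[["AAA"]] # 2
#' tab$w[["AAG"]]      # 0.25 with the default pseudocount 0.5
#' @export
codon_usage_table <- function(corpus, code = genetic_code(),
                              pseudocount = 0.5, source_label = "genome") {
  if (length(corpus) == 0L) stop("empty corpus")
  stopifnot(pseudocount > 0)
  cods <- unlist(lapply(unclass(corpus), sense_codons, code = code),
    use.names = FALSE
  )
  if (length(cods) == 0L) stop("corpus contains zero sense codons")
  counts <- table(factor(cods, levels = code$codons))
  counts <- stats::setNames(as.integer(counts), code$codons)

  aa_of <- code$table[code$codons]
  aa_totals <- vapply(
    code$families, function(f) sum(counts[f]), integer(1)
  )

  p <- ifelse(aa_totals[aa_of] > 0, counts / aa_totals[aa_of], 0)
  f_sub <- ifelse(counts == 0L, pseudocount, counts)
  fam_max <- vapply(code$families, function(f) max(f_sub[f]), numeric(1))
  w <- f_sub / fam_max[aa_of]

  structure(
    list(
      counts = counts,
      aa_totals = aa_totals,
      p = stats::setNames(as.numeric(p), code$codons),
      w = stats::setNames(as.numeric(w), code$codons),
      pseudocount = pseudocount,
      source_label = source_label,
      code = code
    ),
    class = "codon_usage_table"
  )
}

#' @export
print.codon_usage_table <- function(x, ...) {
  cat(sprintf(
    "<codon_usage_table '%s'>: %d codons counted over %d sense codons, pseudocount %g\n",
    x$source_label, sum(x$counts), length(x$counts), x$pseudocount
  ))
  invisible(x)
}

#' @export
summary.codon_usage_table <- function(object, ...) {
  aa <- object$code$table[names(object$counts)]
  df <- data.frame(
    codon = names(object$counts), aa = unname(aa),
    count = unname(object$counts), p = unname(object$p),
    w = unname(object$w), stringsAsFactors = FALSE
  )
  df[order(df$aa, df$codon), ]
}

#' Build a codon-pair table from a CDS corpus
#'
#' Counts adjacent in-frame ordered codon pairs within each sequence (pairs
#' never span two sequences), normalizes within amino-acid-pair families
#' (`q = f_{c1c2} / f_{A1A2}`), and scores each observed pair with the
#' codon-pair score: the log ratio of its observed count to the count
#' expected if codons paired independently given amino-acid-pair usage,
#'
#' \deqn{cps(AB) = \ln\frac{F(AB)}{\frac{F(A)\,F(B)}{F(X)\,F(Y)}\,F(XY)}}
#'
#' with `F(A)`, `F(B)` codon counts, `F(X)`, `F(Y)` amino-acid counts and
#' `F(XY)` the amino-acid-pair count, all from the same corpus. `cps = 0`
#' when a pair is used exactly as often as expected; positive means
#' over-represented.
#'
#' @inheritParams codon_usage_table
#' @return A `codon_pair_table` with `pair_counts`, `aapair_totals`, `q`,
#'   `cps` (named by 6-letter codon pair / 2-letter amino-acid pair; only
#'   observed pairs are stored), plus the per-codon `counts` and `aa_totals`
#'   that the score is based on.
#' @examples
#' pt <- codon_pair_table(c(g1 = "ATGAAATAA"))
#' pt$pair_counts # ATGAAA = 1
#' pt$q           # 1
#' @export
codon_pair_table <- function(corpus, code = genetic_code()) {
  if (length(corpus) == 0L) stop("empty corpus")
  per_seq <- lapply(unclass(corpus), sense_codons, code = code)
  per_seq <- per_seq[lengths(per_seq) >= 2L]
  if (length(per_seq) == 0L) {
    stop("no sequence with at least 2 sense codons")
  }
  pairs <- unlist(lapply(per_seq, function(cod) {
    paste0(cod[-length(cod)], cod[-1L])
  }), use.names = FALSE)
  pair_counts <- table(pairs)
  pair_counts <- stats::setNames(as.integer(pair_counts), names(pair_counts))

  c1 <- substr(names(pair_counts), 1L, 3L)
  c2 <- substr(names(pair_counts), 4L, 6L)
  aapair <- paste0(code$table[c1], code$table[c2])
  aapair_totals <- tapply(pair_counts, aapair, sum)
  aapair_totals <- stats::setNames(as.integer(aapair_totals), names(aapair_totals))
  q <- pair_counts / aapair_totals[aapair]

  # per-codon counts over the same corpus, for the independence expectation
  cods <- unlist(per_seq, use.names = FALSE)
  counts <- table(factor(cods, levels = code$codons))
  counts <- stats::setNames(as.integer(counts), code$codons)
  aa_totals <- vapply(code$families, function(f) sum(counts[f]), integer(1))

  expected <- counts[c1] * counts[c2] /
    (aa_totals[code$table[c1]] * aa_totals[code$table[c2]]) *
    aapair_totals[aapair]
  cps <- log(pair_counts / expected)

  structure(
    list(
      pair_counts = pair_counts,
      aapair_totals = aapair_totals,
      q = stats::setNames(as.numeric(q), names(pair_counts)),
      cps = stats::setNames(as.numeric(cps), names(pair_counts)),
      counts = counts,
      aa_totals = aa_totals,
      code = code
    ),
    class = "codon_pair_table"
  )
}

#' @export
print.codon_pair_table <- function(x, ...) {
  cat(sprintf(
    "<codon_pair_table>: %d distinct pairs (%d occurrences), %d amino-acid pairs\n",
    length(x$pair_counts), sum(x$pair_counts), length(x$aapair_totals)
  ))
  invisible(x)
}

#' Select the highly expressed subset of a corpus
#'
#' Returns the genes in the top expression quantile: with `fraction = f` and
#' `n` matched genes, the `ceiling(f * n)` highest-expressed genes define the
#' threshold, and every gene whose expression ties the threshold value is
#' included (ties are never split arbitrarily). Corpus ids missing from the
#' expression table are dropped with a message.
#'
#' @param corpus A `cds_set` or named character vector of coding sequences.
#' @param expr Data frame with columns `gene_id`, `expression` (see
#'   [read_expression_table()]).
#' @param fraction Top fraction to keep, in (0, 1]. Conventional choices are
#'   0.10 for microbial hosts and 0.05 for mammalian ones.
#' @param quiet Suppress messages about unmatched ids and tie expansion.
#' @return The selected subsequences, ordered by (expression descending,
#'   gene id ascending).
#' @export
select_highly_expressed <- function(corpus, expr, fraction = 0.10,
                                    quiet = FALSE) {
  if (!is.data.frame(expr) || !all(c("gene_id", "expression") %in% names(expr))) {
    stop("expr must have columns gene_id, expression")
  }
  if (anyDuplicated(expr$gene_id)) stop("duplicate gene_id in expression table")
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  ids <- names(corpus)
  missing <- setdiff(ids, expr$gene_id)
  if (length(missing) > 0L && !quiet) {
    message(
      "select_highly_expressed: ", length(missing),
      " corpus id(s) missing from expression table, dropped"
    )
  }
  keep <- setdiff(ids, missing)
  if (length(keep) == 0L) stop("no corpus id matches the expression table")
  e <- expr$expression[match(keep, expr$gene_id)]
  ord <- order(-e, keep)
  keep <- keep[ord]
  e <- e[ord]
  k <- ceiling(fraction * length(keep))
  threshold <- e[k]
  sel <- which(e >= threshold)
  if (length(sel) > k && !quiet) {
    message(
      "select_highly_expressed: ", length(sel) - k,
      " tie(s) at the threshold included"
    )
  }
  out <- unclass(corpus)[keep[sel]]
  structure(out,
    rejected = data.frame(id = character(0), reason = character(0)),
    class = "cds_set"
  )
}

#' Read an expression table
#'
#' Two-column TSV (`gene_id`, `expression`), with or without a header line.
#'
#' @param path TSV file.
#' @return Data frame with columns `gene_id` (character) and `expression`
#'   (numeric, non-negative).
#' @export
read_expression_table <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("^gene_id\t", first)
  df <- utils::read.table(path,
    sep = "\t", header = has_header,
    stringsAsFactors = FALSE,
    col.names = c("gene_id", "expression")
  )
  df$gene_id <- as.character(df$gene_id)
  if (!is.numeric(df$expression) || any(df$expression < 0)) {
    stop("expression values must be non-negative numbers")
  }
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in expression table")
  df
}

#' Write an expression table
#' @param expr Data frame with `gene_id`, `expression`.
#' @param path Output TSV.
#' @export
write_expression_table <- function(expr, path) {
  utils::write.table(expr[, c("gene_id", "expression")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

table_format_version <- "1.0"

#' Serialize a codon usage table to TSV
#'
#' Fixed 61-row layout (sense codons in alphabetical order), header comment
#' lines carrying the format version, source label and pseudocount.
#' [read_usage_table()] inverts this exactly.
#'
#' @param table A `codon_usage_table`.
#' @param path Output TSV.
#' @export
write_usage_table <- function(table, path) {
  stopifnot(inherits(table, "codon_usage_table"))
  df <- data.frame(
    codon = names(table$counts),
    aa = unname(table$code$table[names(table$counts)]),
    count = unname(table$counts),
    p = unname(table$p),
    w = unname(table$w),
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# codonkit usage_table v%s", table_format_version), con)
  writeLines(sprintf(
    "# source_label=%s pseudocount=%s code=%s",
    table$source_label, format(table$pseudocount), table$code$id
  ), con)
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Load a codon usage table written by [write_usage_table()]
#'
#' Accepts any file of the same major format version whose codon set matches
#' the genetic code; a missing or unknown codon row is an error.
#'
#' @param path TSV file.
#' @return A `codon_usage_table`.
#' @export
read_usage_table <- function(path) {
  hdr <- readLines(path, n = 2L)
  if (length(hdr) < 2L || !grepl("^# codonkit usage_table v1\\.", hdr[1L]) &&
    !grepl("^# codonkit usage_table v1$", hdr[1L])) {
    if (!grepl("^# codonkit usage_table v1(\\.|$)", hdr[1L])) {
      stop("not a codonkit usage table (or incompatible major version): ", path)
    }
  }
  meta <- parse_header_kv(hdr[2L])
  code <- genetic_code(meta[["code"]])
  pseudocount <- as.numeric(meta[["pseudocount"]])
  df <- utils::read.table(path,
    sep = "\t", header = TRUE,
    comment.char = "#", stringsAsFactors = FALSE
  )
  if (!setequal(df$codon, code$codons) || nrow(df) != length(code$codons)) {
    stop("codon set in ", path, " does not match the ", code$id, " code")
  }
  counts <- stats::setNames(as.integer(df$count), df$codon)[code$codons]
  tab <- codon_usage_table_from_counts(
    counts, code, pseudocount, meta[["source_label"]]
  )
  # stored derived fields must agree with what the counts imply
  stored_w <- stats::setNames(df$w, df$codon)[code$codons]
  if (max(abs(stored_w - tab$w)) > 1e-6) {
    stop("stored w values inconsistent with counts in ", path)
  }
  tab
}

# Rebuild a usage table from a counts vector (shared by read_usage_table and
# the synthetic-data checks).
codon_usage_table_from_counts <- function(counts, code = genetic_code(),
                                          pseudocount = 0.5,
                                          source_label = "genome") {
  stopifnot(setequal(names(counts), code$codons))
  counts <- counts[code$codons]
  aa_of <- code$table[code$codons]
  aa_totals <- vapply(code$families, function(f) sum(counts[f]), integer(1))
  p <- ifelse(aa_totals[aa_of] > 0, counts / aa_totals[aa_of], 0)
  f_sub <- ifelse(counts == 0L, pseudocount, counts)
  fam_max <- vapply(code$families, function(f) max(f_sub[f]), numeric(1))
  structure(
    list(
      counts = counts, aa_totals = aa_totals,
      p = stats::setNames(as.numeric(p), code$codons),
      w = stats::setNames(as.numeric(f_sub / fam_max[aa_of]), code$codons),
      pseudocount = pseudocount, source_label = source_label, code = code
    ),
    class = "codon_usage_table"
  )
}

#' Serialize a codon-pair table to TSV
#'
#' Stores the observed pairs only (zero rows omitted) plus the per-codon
#' counts block needed to reconstruct the scores.
#'
#' @param table A `codon_pair_table`.
#' @param path Output TSV.
#' @export
write_pair_table <- function(table, path) {
  stopifnot(inherits(table, "codon_pair_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# codonkit pair_table v%s", table_format_version), con)
  writeLines(sprintf("# code=%s", table$code$id), con)
  writeLines(paste0(
    "# codon_counts=",
    paste(sprintf("%s:%d", names(table$counts), table$counts), collapse = ",")
  ), con)
  df <- data.frame(
    codon1 = substr(names(table$pair_counts), 1L, 3L),
    codon2 = substr(names(table$pair_counts), 4L, 6L),
    count = unname(table$pair_counts),
    q = unname(table$q),
    cps = unname(table$cps),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' Load a codon-pair table written by [write_pair_table()]
#' @param path TSV file.
#' @return A `codon_pair_table`.
#' @export
read_pair_table <- function(path) {
  hdr <- readLines(path, n = 3L)
  if (!grepl("^# codonkit pair_table v1(\\.|$)", hdr[1L])) {
    stop("not a codonkit pair table (or incompatible major version): ", path)
  }
  code <- genetic_code(parse_header_kv(hdr[2L])[["code"]])
  cc <- strsplit(sub("^# codon_counts=", "", hdr[3L]), ",")[[1L]]
  cc <- strsplit(cc, ":")
  counts <- stats::setNames(
    vapply(cc, function(x) as.integer(x[2L]), integer(1)),
    vapply(cc, `[[`, character(1), 1L)
  )
  if (!setequal(names(counts), code$codons)) {
    stop("codon set in ", path, " does not match the ", code$id, " code")
  }
  counts <- counts[code$codons]
  df <- utils::read.table(path,
    sep = "\t", header = TRUE,
    comment.char = "#", stringsAsFactors = FALSE
  )
  pair_counts <- stats::setNames(
    as.integer(df$count), paste0(df$codon1, df$codon2)
  )
  aa_totals <- vapply(code$families, function(f) sum(counts[f]), integer(1))
  aapair <- paste0(code$table[df$codon1], code$table[df$codon2])
  aapair_totals <- tapply(pair_counts, aapair, sum)
  aapair_totals <- stats::setNames(as.integer(aapair_totals), names(aapair_totals))
  q <- pair_counts / aapair_totals[aapair]
  expected <- counts[df$codon1] * counts[df$codon2] /
    (aa_totals[code$table[df$codon1]] * aa_totals[code$table[df$codon2]]) *
    aapair_totals[aapair]
  structure(
    list(
      pair_counts = pair_counts,
      aapair_totals = aapair_totals,
      q = stats::setNames(as.numeric(q), names(pair_counts)),
      cps = stats::setNames(as.numeric(log(pair_counts / expected)), names(pair_counts)),
      counts = counts,
      aa_totals = aa_totals,
      code = code
    ),
    class = "codon_pair_table"
  )
}

parse_header_kv <- function(line) {
  kv <- strsplit(strsplit(sub("^# *", "", line), " ")[[1L]], "=")
  stats::setNames(
    vapply(kv, function(x) paste(x[-1L], collapse = "="), character(1)),
    vapply(kv, `[[`, character(1), 1L)
  )
}
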