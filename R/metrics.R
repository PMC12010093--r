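#' Codon adaptation index
#'
#' Geometric mean of the relative adaptiveness `w` of a sequence's codons
#' against a host usage reference:
#' \deqn{CAI = \exp\left(\frac{1}{N}\sum_{i=1}^{N} \ln w_i\right)}
#' where `N` is the total number of sense codons. Single-synonym codons
#' (Met, Trp) count toward `N` with `w = 1`. Computed in log space; the
#' direct product formulation underflows on long genes.
#'
#' CAI lies in (0, 1]; 1 means every codon is its family's most frequent
#' codon in the reference.
#'
#' @param nt A coding sequence.
#' @param table A [codon_usage_table()] for the host.
#' @return CAI in (0, 1].
#' @examples
#' tab <- codon_usage_table(c(g = "ATGAAAAAATAA"))
#' cai("ATGAAA", tab) # 1: both codons are family maxima
#' @export
cai <- function(nt, table) {
  stopifnot(inherits(table, "codon_usage_table"))
  cod <- sense_codons(nt, table$code)
  exp(mean(log(table$w[cod])))
}

#' Overall GC content
#'
#' Percentage of G and C bases over the whole sequence (including the
#' terminal stop codon when present: annotated CDS records include it, and
#' wild-type GC values are conventionally quoted on the full CDS).
#'
#' @param nt Non-empty A/C/G/T string.
#' @return Percent in \[0, 100\].
#' @examples
#' gc_content("ATGC") # 50
#' @export
gc_content <- function(nt) {
  nt <- normalize_nt(nt)
  n <- nchar(nt)
  if (n == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", nt)) stop("sequence contains non-ACGT characters")
  100 * nchar(gsub("[AT]", "", nt)) / n
}

#' Positional GC content (GC1, GC2, GC3)
#'
#' Percent G+C among the first, second and third bases of the codons of a
#' CDS, with the complementary AT percentages. No codon is excluded, so the
#' identity `mean(GC1, GC2, GC3) == gc_content(nt)` holds exactly on any
#' in-frame sequence.
#'
#' @param nt A coding sequence (length a multiple of 3).
#' @return Named list with `gc` = c(gc1, gc2, gc3) and `at` = 100 - gc.
#' @examples
#' positional_gc("ATGGCA")$gc # 50 50 50
#' @export
positional_gc <- function(nt) {
  nt <- normalize_nt(nt)
  if (nchar(nt) == 0L || nchar(nt) %% 3L != 0L) {
    stop("need a non-empty in-frame sequence")
  }
  if (grepl("[^ACGT]", nt)) stop("sequence contains non-ACGT characters")
  base <- strsplit(nt, "")[[1L]]
  pos <- rep_len(1:3, length(base))
  gc <- vapply(1:3, function(k) {
    100 * mean(base[pos == k] %in% c("G", "C"))
  }, numeric(1))
  list(gc = stats::setNames(gc, c("gc1", "gc2", "gc3")),
       at = stats::setNames(100 - gc, c("at1", "at2", "at3")))
}

#' Individual codon usage fitness
#'
#' Negative Manhattan distance between the host's family-normalized codon
#' frequencies `p0` and those of the target sequence `p1`:
#' \deqn{ICU = -\sum_c |p0_c - p1_c|}
#' summed over the codons of every amino acid present in the target (absent
#' families are skipped: `p1` is undefined there). 0 is optimal -- the
#' sequence uses codons in exactly the host's proportions; each family can
#' contribute at most -2.
#'
#' @param nt A coding sequence.
#' @param table Host [codon_usage_table()].
#' @return ICU, a real number <= 0.
#' @export
icu <- function(nt, table) {
  stopifnot(inherits(table, "codon_usage_table"))
  code <- table$code
  cod <- sense_codons(nt, code)
  counts <- table(factor(cod, levels = code$codons))
  counts <- stats::setNames(as.integer(counts), code$codons)
  aas <- unique(code$table[cod])
  total <- 0
  for (a in aas) {
    fam <- code$families[[a]]
    p1 <- counts[fam] / sum(counts[fam])
    total <- total + sum(abs(table$p[fam] - p1))
  }
  -total
}

#' Codon context fitness
#'
#' The codon-pair analogue of [icu()]: negative Manhattan distance between
#' host and target codon-pair distributions `q`, normalized within
#' amino-acid-pair families and summed over the amino-acid pairs present in
#' the target's adjacent (in-frame) codon pairs.
#'
#' @param nt A coding sequence with at least 2 sense codons.
#' @param pair_table Host [codon_pair_table()].
#' @return CC, a real number <= 0; 0 means the target's pair usage matches
#'   the host's exactly.
#' @export
cc <- function(nt, pair_table) {
  stopifnot(inherits(pair_table, "codon_pair_table"))
  code <- pair_table$code
  cod <- sense_codons(nt, code)
  if (length(cod) < 2L) stop("need at least 2 sense codons")
  pairs <- paste0(cod[-length(cod)], cod[-1L])
  cnt <- table(pairs)
  cnt <- stats::setNames(as.integer(cnt), names(cnt))

  host_aapair <- paste0(
    code$table[substr(names(pair_table$q), 1L, 3L)],
    code$table[substr(names(pair_table$q), 4L, 6L)]
  )
  seq_aapair_of <- paste0(
    code$table[substr(names(cnt), 1L, 3L)],
    code$table[substr(names(cnt), 4L, 6L)]
  )
  seq_aapair_tot <- tapply(cnt, seq_aapair_of, sum)

  total <- 0
  for (ap in unique(seq_aapair_of)) {
    keys <- union(
      names(pair_table$q)[host_aapair == ap],
      names(cnt)[seq_aapair_of == ap]
    )
    q0 <- ifelse(keys %in% names(pair_table$q), pair_table$q[keys], 0)
    q1 <- ifelse(keys %in% names(cnt), cnt[keys] / seq_aapair_tot[[ap]], 0)
    total <- total + sum(abs(q0 - q1))
  }
  -total
}

#' Codon-pair bias of a sequence
#'
#' Arithmetic mean of the host codon-pair scores over the sequence's
#' adjacent codon pairs. Pairs never observed in the host reference have no
#' score; by default they are skipped (their count is returned in the
#' `n_unscored` attribute), or made a hard error with `missing = "error"`.
#'
#' @param nt A coding sequence with at least 2 sense codons.
#' @param pair_table Host [codon_pair_table()].
#' @param missing `"skip"` (default) or `"error"` for host-unseen pairs.
#' @return Mean codon-pair score, with attribute `n_unscored`.
#' @export
cpb <- function(nt, pair_table, missing = c("skip", "error")) {
  stopifnot(inherits(pair_table, "codon_pair_table"))
  missing <- match.arg(missing)
  cod <- sense_codons(nt, pair_table$code)
  if (length(cod) < 2L) stop("need at least 2 sense codons")
  pairs <- paste0(cod[-length(cod)], cod[-1L])
  scored <- pairs %in% names(pair_table$cps)
  if (any(!scored)) {
    if (missing == "error") {
      stop(
        sum(!scored), " codon pair(s) absent from the host table, e.g. ",
        pairs[!scored][1L]
      )
    }
  }
  if (!any(scored)) stop("no codon pair of the sequence is scorable")
  structure(mean(pair_table$cps[pairs[scored]]), n_unscored = sum(!scored))
}

#' Built-in restriction enzyme motifs
#'
#' The three enzymes screened by default in this package's design workflow.
#'
#' @param names Optional subset of enzyme names.
#' @return Named character vector of recognition motifs.
#' @examples
#' restriction_enzymes() # EcoRI, ApaI, NcoI
#' @export
restriction_enzymes <- function(names = NULL) {
  motifs <- c(EcoRI = "GAATTC", ApaI = "GGGCCC", NcoI = "CCATGG")
  if (is.null(names)) return(motifs)
  unknown <- setdiff(names, names(motifs))
  if (length(unknown)) stop("unknown enzyme(s): ", paste(unknown, collapse = ", "))
  motifs[names]
}

#' Find restriction sites on the sense strand
#'
#' Reports every occurrence of each motif, overlapping matches included,
#' with 0-based start positions.
#'
#' @param nt Sequence to scan.
#' @param enzymes Named character vector of motifs (default
#'   [restriction_enzymes()]).
#' @param both_strands Also scan the reverse complement of each motif
#'   against the sense strand. Off by default: design workflows screen the
#'   coding strand.
#' @return Data frame with columns `enzyme`, `motif`, `position` (0-based).
#' @examples
#' find_restriction_sites("AAGAATTCAA")$position # 2
#' @export
find_restriction_sites <- function(nt, enzymes = restriction_enzymes(),
                                   both_strands = FALSE) {
  nt <- normalize_nt(nt)
  if (any(!nzchar(enzymes))) stop("empty motif")
  if (both_strands) {
    rc <- vapply(enzymes, revcomp, character(1))
    extra <- rc[!(rc %in% enzymes)]
    names(extra) <- paste0(names(extra), "_rc")
    enzymes <- c(enzymes, extra)
  }
  hits <- lapply(seq_along(enzymes), function(i) {
    m <- gregexpr(paste0("(?=", enzymes[[i]], ")"), nt, perl = TRUE)[[1L]]
    pos <- as.integer(m)
    pos <- pos[pos > 0L]
    if (length(pos) == 0L) return(NULL)
    data.frame(
      enzyme = names(enzymes)[i], motif = unname(enzymes[[i]]),
      position = pos - 1L, stringsAsFactors = FALSE
    )
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits)) {
    hits <- data.frame(
      enzyme = character(0), motif = character(0), position = integer(0),
      stringsAsFactors = FALSE
    )
  }
  hits[order(hits$position, hits$enzyme), , drop = FALSE]
}

revcomp <- function(nt) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", nt), "")[[1L]]), collapse = "")
}

#' Score one sequence against a host reference
#'
#' Aggregates the full metric suite for one coding sequence: CAI, overall
#' and positional GC, ICU, CC, CPB, restriction sites, and (when a folding
#' engine is supplied) the mRNA folding stability.
#'
#' @param nt A coding sequence.
#' @param table Host [codon_usage_table()].
#' @param pair_table Optional host [codon_pair_table()]; CC and CPB are `NA`
#'   without it or when the sequence has fewer than 2 sense codons.
#' @param enzymes Restriction motifs to screen (see
#'   [find_restriction_sites()]); `NULL` to skip.
#' @param fold_engine Optional engine name for [fold_mrna()] (`"fallback"`
#'   or `"rnafold"`); `delta_g` is absent (`NA`) when `NULL`.
#' @param id Label carried into the report.
#' @return A `metrics_report`: list with fields `id`, `n_codons`, `cai`,
#'   `gc_percent`, `gc1`, `gc2`, `gc3`, `icu`, `cc`, `cpb`, `delta_g`,
#'   `fold_engine`, `restriction_hits` (data frame).
#' @export
score_sequence <- function(nt, table, pair_table = NULL,
                           enzymes = restriction_enzymes(),
                           fold_engine = NULL, id = "seq") {
  nt <- normalize_nt(nt)
  cod <- sense_codons(nt, table$code)
  pg <- positional_gc(nt)
  pair_ok <- !is.null(pair_table) && length(cod) >= 2L
  fold <- if (!is.null(fold_engine)) fold_mrna(nt, engine = fold_engine)
  structure(
    list(
      id = id,
      n_codons = length(cod),
      cai = cai(nt, table),
      gc_percent = gc_content(nt),
      gc1 = pg$gc[["gc1"]], gc2 = pg$gc[["gc2"]], gc3 = pg$gc[["gc3"]],
      icu = icu(nt, table),
      cc = if (pair_ok) cc(nt, pair_table) else NA_real_,
      cpb = if (pair_ok) as.numeric(cpb(nt, pair_table)) else NA_real_,
      delta_g = if (is.null(fold)) NA_real_ else fold$delta_g,
      fold_engine = if (is.null(fold)) NA_character_ else fold$engine,
      restriction_hits = if (is.null(enzymes)) NULL else {
        find_restriction_sites(nt, enzymes)
      }
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  cat(sprintf("<metrics_report '%s'> (%d codons)\n", x$id, x$n_codons))
  cat(sprintf(
    "  CAI %.*f | GC %.2f%% (GC1 %.2f, GC2 %.2f, GC3 %.2f)\n",
    digits, x$cai, x$gc_percent, x$gc1, x$gc2, x$gc3
  ))
  cat(sprintf(
    "  ICU %.*f | CC %s | CPB %s | dG %s%s\n",
    digits, x$icu,
    if (is.na(x$cc)) "NA" else formatC(x$cc, digits = digits, format = "f"),
    if (is.na(x$cpb)) "NA" else formatC(x$cpb, digits = digits, format = "f"),
    if (is.na(x$delta_g)) "NA" else formatC(x$delta_g, digits = 2, format = "f"),
    if (is.na(x$fold_engine)) "" else sprintf(" [%s]", x$fold_engine)
  ))
  nh <- if (is.null(x$restriction_hits)) NA_integer_ else nrow(x$restriction_hits)
  cat(sprintf("  restriction hits: %s\n", nh))
  invisible(x)
}

#' Convert metrics reports to a data frame
#'
#' One row per report; restriction hits are collapsed to a count plus a
#' semicolon-separated `enzyme:position` list. Percentages are reported at
#' full precision; round at the presentation layer.
#'
#' @param reports A `metrics_report` or list of them.
#' @return Data frame with one row per sequence.
#' @export
as_report_frame <- function(reports) {
  if (inherits(reports, "metrics_report")) reports <- list(reports)
  do.call(rbind, lapply(reports, function(r) {
    hits <- r$restriction_hits
    data.frame(
      id = r$id, n_codons = r$n_codons, cai = r$cai,
      gc_percent = r$gc_percent, gc1 = r$gc1, gc2 = r$gc2, gc3 = r$gc3,
      icu = r$icu, cc = r$cc, cpb = r$cpb, delta_g = r$delta_g,
      fold_engine = r$fold_engine,
      n_restriction_hits = if (is.null(hits)) NA_integer_ else nrow(hits),
      restriction_hits = if (is.null(hits) || nrow(hits) == 0L) "" else {
        paste(sprintf("%s:%d", hits$enzyme, hits$position), collapse = ";")
      },
      stringsAsFactors = FALSE
    )
  }))
}

#' Write metrics reports as TSV or JSON
#'
#' @param reports A `metrics_report` or list of them.
#' @param path Output file.
#' @param format `"tsv"` (one row per sequence) or `"json"`.
#' @export
write_report <- function(reports, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- as_report_frame(reports)
  if (format == "tsv") {
    utils::write.table(df, path,
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = TRUE
    )
  } else {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  }
  invisible(path)
}
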