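#' Design an optimized coding sequence for a protein
#'
#' Two reference strategies:
#'
#' * `"max_cai"` -- the one-amino-acid-one-codon strategy: every residue is
#'   encoded by its family's highest-`w` codon (ties broken alphabetically),
#'   so the output's codon adaptation index is exactly 1 by construction.
#'   Deterministic.
#' * `"sampled"` -- usage-matched sampling: each residue's codon is drawn
#'   from the family's host frequencies `p`, so the output's individual
#'   codon usage fitness tends to 0 as the protein grows. Reproducible for a
#'   fixed `seed`.
#'
#' Forbidden motifs (restriction sites) are removed after sequence
#' construction: for `max_cai`, the minimal number of codon positions is
#' switched to next-best synonyms (leftmost window first, substitutions
#' tried in descending `w`, ties alphabetical), each intervention logged;
#' for `"sampled"`, the codons overlapping an offending window are redrawn
#' up to `max_resample_attempts` times. The returned sequence is guaranteed
#' motif-free on the sense strand or an error is raised naming the window.
#'
#' The output encodes exactly the input protein and carries no terminal stop
#' codon; append one (e.g. `"TAA"`) when building a full CDS for synthesis.
#'
#' @param protein Protein string over the 20 standard amino acids.
#' @param table Host [codon_usage_table()].
#' @param strategy `"max_cai"` or `"sampled"`.
#' @param seed Integer seed for the `"sampled"` strategy; recorded in the
#'   result.
#' @param forbidden_motifs Named character vector of motifs that must not
#'   appear (default [restriction_enzymes()]); `NULL` disables screening.
#' @param gc_window Optional `c(min, max)` GC percent band; violation is a
#'   warning (GC is a descriptive criterion here, not a hard constraint).
#' @param max_resample_attempts Resampling budget per offending window for
#'   the sampled strategy.
#' @return An `optimized_sequence`: list with `nt`, `protein`, `strategy`,
#'   `seed`, `constraint_log` (data frame of interventions: codon position,
#'   original and replacement codon) and `gc_percent`.
#' @examples
#' tab <- codon_usage_table(c(g = "ATGAAAAAGTAA"))
#' optimize_sequence("MKK", tab)$nt # "ATGAAAAAA"
#' @export
optimize_sequence <- function(protein, table,
                              strategy = c("max_cai", "sampled"),
                              seed = 1L,
                              forbidden_motifs = restriction_enzymes(),
                              gc_window = NULL,
                              max_resample_attempts = 100L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(table, "codon_usage_table"))
  code <- table$code
  aas <- strsplit(toupper(protein), "")[[1L]]
  if (length(aas) == 0L) stop("empty protein")
  bad <- setdiff(aas, names(code$families))
  if (length(bad)) {
    stop("protein contains non-standard residue(s): ", paste(unique(bad), collapse = ""))
  }
  if (!is.null(gc_window)) stopifnot(length(gc_window) == 2L, gc_window[1L] < gc_window[2L])
  stopifnot(max_resample_attempts >= 1L)

  if (strategy == "max_cai") {
    res <- design_max_cai(aas, table, forbidden_motifs)
  } else {
    res <- with_seed(seed, design_sampled(aas, table, forbidden_motifs, max_resample_attempts))
  }
  nt <- paste(res$codons, collapse = "")
  gc <- gc_content(nt)
  if (!is.null(gc_window) && (gc < gc_window[1L] || gc > gc_window[2L])) {
    warning(sprintf(
      "GC content %.2f%% outside the advisory window [%g%%, %g%%]",
      gc, gc_window[1L], gc_window[2L]
    ))
  }
  structure(
    list(
      nt = nt, protein = paste(aas, collapse = ""), strategy = strategy,
      seed = if (strategy == "sampled") seed else NA_integer_,
      constraint_log = res$log, gc_percent = gc
    ),
    class = "optimized_sequence"
  )
}

#' @export
print.optimized_sequence <- function(x, ...) {
  cat(sprintf(
    "<optimized_sequence> %d aa, strategy=%s%s, GC %.2f%%, %d motif intervention(s)\n",
    nchar(x$protein), x$strategy,
    if (!is.na(x$seed)) sprintf(" (seed %d)", x$seed) else "",
    x$gc_percent, nrow(x$constraint_log)
  ))
  invisible(x)
}

# Run expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) {
    assign(".Random.seed", old, envir = globalenv())
  } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

empty_log <- function() {
  data.frame(
    position = integer(0), from = character(0), to = character(0),
    motif = character(0), stringsAsFactors = FALSE
  )
}

# Synonyms of `aa` ordered by descending w, ties alphabetical (determinism).
synonyms_by_w <- function(aa, table) {
  fam <- table$code$families[[aa]]
  fam[order(-table$w[fam], fam)]
}

# Codon positions whose 3-nt window overlaps [start, end] (1-based nt).
codons_overlapping <- function(start, end, n_codons) {
  lo <- max(1L, (start + 2L) %/% 3L)
  hi <- min(n_codons, (end + 2L) %/% 3L)
  lo:hi
}

motif_hits <- function(nt, motifs) {
  if (is.null(motifs) || length(motifs) == 0L) {
    return(empty_log()[, c("position", "motif")][0, ])
  }
  find_restriction_sites(nt, motifs)
}

design_max_cai <- function(aas, table, motifs) {
  best <- vapply(aas, function(a) synonyms_by_w(a, table)[1L], character(1))
  codons <- unname(best)
  log <- empty_log()
  if (is.null(motifs) || length(motifs) == 0L) {
    return(list(codons = codons, log = log))
  }
  guard <- 0L
  repeat {
    hits <- find_restriction_sites(paste(codons, collapse = ""), motifs)
    if (nrow(hits) == 0L) break
    guard <- guard + 1L
    if (guard > length(aas) + 100L) stop("motif removal did not converge")
    hit <- hits[1L, ] # leftmost first
    window <- codons_overlapping(
      hit$position + 1L, hit$position + nchar(hit$motif), length(aas)
    )
    fix <- fix_window(codons, window, aas, table, motifs, hit)
    if (is.null(fix)) {
      stop(sprintf(
        "cannot remove motif %s (%s) at position %d: no synonym combination avoids it",
        hit$enzyme, hit$motif, hit$position
      ))
    }
    log <- rbind(log, fix$log)
    codons <- fix$codons
  }
  list(codons = codons, log = log)
}

# Try substitutions within `window`: single codons first (leftmost, then by
# descending w), then pairs -- the minimal number of switched positions that
# removes the hit without creating a new one.
fix_window <- function(codons, window, aas, table, motifs, hit) {
  n_before <- nrow(find_restriction_sites(paste(codons, collapse = ""), motifs))
  choices <- lapply(window, function(i) {
    setdiff(synonyms_by_w(aas[i], table), codons[i])
  })
  try_set <- function(idx, repl) {
    cand <- codons
    cand[idx] <- repl
    if (nrow(find_restriction_sites(paste(cand, collapse = ""), motifs)) < n_before) {
      list(
        codons = cand,
        log = data.frame(
          position = idx, from = codons[idx], to = repl,
          motif = rep(hit$enzyme, length(idx)), stringsAsFactors = FALSE
        )
      )
    }
  }
  for (wi in seq_along(window)) {
    for (repl in choices[[wi]]) {
      res <- try_set(window[wi], repl)
      if (!is.null(res)) return(res)
    }
  }
  if (length(window) >= 2L) {
    for (wi in seq_along(window)[-length(window)]) {
      for (wj in (wi + 1L):length(window)) {
        for (ri in choices[[wi]]) {
          for (rj in choices[[wj]]) {
            res <- try_set(window[c(wi, wj)], c(ri, rj))
            if (!is.null(res)) return(res)
          }
        }
      }
    }
  }
  NULL
}

design_sampled <- function(aas, table, motifs, max_attempts) {
  draw <- function(aa) {
    fam <- table$code$families[[aa]]
    pr <- table$p[fam]
    if (sum(pr) <= 0) pr <- rep(1, length(fam)) # family unseen in host
    if (length(fam) == 1L) fam else sample(fam, 1L, prob = pr)
  }
  codons <- vapply(aas, draw, character(1), USE.NAMES = FALSE)
  log <- empty_log()
  if (!is.null(motifs) && length(motifs) > 0L) {
    guard <- 0L
    repeat {
      hits <- find_restriction_sites(paste(codons, collapse = ""), motifs)
      if (nrow(hits) == 0L) break
      hit <- hits[1L, ]
      window <- codons_overlapping(
        hit$position + 1L, hit$position + nchar(hit$motif), length(aas)
      )
      n_before <- nrow(hits)
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        cand <- codons
        cand[window] <- vapply(aas[window], draw, character(1), USE.NAMES = FALSE)
        if (nrow(find_restriction_sites(paste(cand, collapse = ""), motifs)) < n_before) {
          log <- rbind(log, data.frame(
            position = window, from = codons[window], to = cand[window],
            motif = rep(hit$enzyme, length(window)), stringsAsFactors = FALSE
          ))
          codons <- cand
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop(sprintf(
          "resampling budget (%d) exhausted removing motif %s at position %d",
          max_attempts, hit$enzyme, hit$position
        ))
      }
      guard <- guard + 1L
      if (guard > length(aas) + 100L) stop("motif removal did not converge")
    }
  }
  list(codons = codons, log = log)
}
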