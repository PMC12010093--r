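# Pluggable folding engines. An engine is a function(rna_string) returning
# list(delta_g = <numeric <= 0>, structure = <dot-bracket or NA>). Results
# always carry the engine name so reports from different engines are never
# mixed silently.
.fold_engines <- new.env(parent = emptyenv())

#' Register a folding engine
#'
#' Any function matching the engine contract -- input an RNA string, output
#' `list(delta_g, structure)` -- can be registered under a name and then
#' selected in [fold_mrna()] and [score_sequence()].
#'
#' @param name Engine name.
#' @param fun Function of one RNA string argument.
#' @export
register_fold_engine <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .fold_engines)
  invisible(name)
}

#' List registered folding engines
#' @return Character vector of engine names.
#' @export
fold_engines <- function() sort(ls(.fold_engines))

#' Predict mRNA folding stability
#'
#' Computes a folding free energy for an mRNA (T is converted to U
#' internally). Two engines are built in:
#'
#' * `"rnafold"` invokes the ViennaRNA `RNAfold` executable and returns the
#'   thermodynamic minimum free energy in kcal/mol with its dot-bracket
#'   structure.
#' * `"fallback"` is a self-contained, non-thermodynamic stability proxy:
#'   maximum weighted base pairing (Watson-Crick plus GU wobble, weights
#'   GC = -3, AU = -2, GU = -1 in arbitrary units, minimum hairpin loop of 3
#'   unpaired bases) computed by dynamic programming. It orders sequences by
#'   pairing potential but its values are not free energies; use it where a
#'   thermodynamic engine is not required, e.g. in tests. Sequences shorter
#'   than 8 nt return 0 with no structure. Cubic in sequence length --
#'   intended for short sequences.
#'
#' @param nt Non-empty sequence (DNA or RNA alphabet).
#' @param engine Engine name: `"fallback"`, `"rnafold"`, or any name
#'   registered with [register_fold_engine()].
#' @return A `folding_result`: list with `delta_g` (<= 0), `engine`, and
#'   `structure` (dot-bracket string, or `NA` when the engine does not
#'   report one).
#' @examples
#' fold_mrna("GGGGAAAACCCC", engine = "fallback") # proxy -12, ((((....))))
#' @export
fold_mrna <- function(nt, engine = "fallback") {
  nt <- normalize_nt(nt)
  if (nchar(nt) == 0L) stop("empty sequence")
  if (grepl("[^ACGT]", nt)) stop("sequence contains non-ACGT characters")
  if (!exists(engine, envir = .fold_engines, inherits = FALSE)) {
    stop(
      "unknown folding engine '", engine, "'; registered: ",
      paste(fold_engines(), collapse = ", ")
    )
  }
  rna <- chartr("T", "U", nt)
  res <- get(engine, envir = .fold_engines)(rna)
  if (!is.na(res$structure)) {
    stopifnot(nchar(res$structure) == nchar(rna))
    op <- lengths(regmatches(res$structure, gregexpr("(", res$structure, fixed = TRUE)))
    cl <- lengths(regmatches(res$structure, gregexpr(")", res$structure, fixed = TRUE)))
    stopifnot(op == cl)
  }
  structure(
    list(delta_g = res$delta_g, engine = engine, structure = res$structure),
    class = "folding_result"
  )
}

#' @export
print.folding_result <- function(x, ...) {
  cat(sprintf(
    "<folding_result> engine=%s delta_g=%.2f%s\n", x$engine, x$delta_g,
    if (x$engine == "fallback") " (pairing proxy, not kcal/mol)" else " kcal/mol"
  ))
  if (!is.na(x$structure)) cat(" ", x$structure, "\n")
  invisible(x)
}

pair_weight <- function(a, b) {
  key <- paste0(a, b)
  w <- c(
    GC = 3, CG = 3, AU = 2, UA = 2, GU = 1, UG = 1
  )[key]
  ifelse(is.na(w), 0, w)
}

# Maximum weighted non-crossing base pairing (Nussinov-style DP with pair
# weights and a minimum hairpin loop). Returns list(score, pairs) where
# pairs is a 2-column matrix of 1-based indices.
max_pairing <- function(bases, min_hairpin = 3L) {
  n <- length(bases)
  m <- matrix(0, n, n)
  if (n >= min_hairpin + 2L) {
    for (span in (min_hairpin + 1L):(n - 1L)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- m[i, j - 1L] # j unpaired
        for (k in i:(j - min_hairpin - 1L)) {
          w <- pair_weight(bases[k], bases[j])
          if (w > 0) {
            left <- if (k > i) m[i, k - 1L] else 0
            inner <- if (k + 1L <= j - 1L) m[k + 1L, j - 1L] else 0
            cand <- left + w + inner
            if (cand > best) best <- cand
          }
        }
        m[i, j] <- best
      }
    }
  }
  pairs <- matrix(integer(0), ncol = 2)
  if (n >= 2L) {
    stack <- list(c(1L, n))
    while (length(stack) > 0L) {
      ij <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      i <- ij[1L]; j <- ij[2L]
      if (i >= j || m[i, j] == 0) next
      if (m[i, j] == m[i, j - 1L]) {
        stack[[length(stack) + 1L]] <- c(i, j - 1L)
        next
      }
      for (k in i:(j - min_hairpin - 1L)) {
        w <- pair_weight(bases[k], bases[j])
        if (w > 0) {
          left <- if (k > i) m[i, k - 1L] else 0
          inner <- if (k + 1L <= j - 1L) m[k + 1L, j - 1L] else 0
          if (left + w + inner == m[i, j]) {
            pairs <- rbind(pairs, c(k, j))
            if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
            if (k + 1L <= j - 1L) stack[[length(stack) + 1L]] <- c(k + 1L, j - 1L)
            break
          }
        }
      }
    }
  }
  list(score = if (n >= 2L) m[1L, n] else 0, pairs = pairs)
}

fold_fallback <- function(rna) {
  n <- nchar(rna)
  if (n < 8L) {
    return(list(delta_g = 0, structure = NA_character_))
  }
  bases <- strsplit(rna, "")[[1L]]
  res <- max_pairing(bases)
  db <- rep(".", n)
  if (nrow(res$pairs) > 0L) {
    db[res$pairs[, 1L]] <- "("
    db[res$pairs[, 2L]] <- ")"
  }
  list(delta_g = -res$score, structure = paste(db, collapse = ""))
}

fold_rnafold <- function(rna) {
  exe <- Sys.which("RNAfold")
  if (exe == "") stop("RNAfold executable not found on PATH")
  out <- suppressWarnings(system2(exe, c("--noPS"), input = rna, stdout = TRUE))
  if (length(out) < 2L) stop("unexpected RNAfold output")
  line <- out[2L]
  m <- regmatches(line, regexec("^([.()]+)\\s+\\(\\s*(-?[0-9.]+)\\)", line))[[1L]]
  if (length(m) != 3L) stop("could not parse RNAfold output: ", line)
  list(delta_g = as.numeric(m[3L]), structure = m[2L])
}

register_fold_engine("fallback", fold_fallback)
register_fold_engine("rnafold", fold_rnafold)
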