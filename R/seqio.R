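#' Read and validate coding sequences from FASTA
#'
#' Reads a multi-record FASTA file and keeps only records that pass coding
#' sequence validation: frame (length a multiple of 3), no internal stop
#' codon, at most one terminal stop, only unambiguous bases (unless
#' `allow_ambiguous`), and optionally an ATG start. Records that fail are not
#' silently dropped: they are excluded, counted in a message, and returned
#' with their reasons in the `"rejected"` attribute.
#'
#' Lowercase and RNA (U) input is normalized to uppercase DNA before
#' validation.
#'
#' @param path FASTA file.
#' @param require_atg Keep only sequences whose first codon is ATG, the
#'   filter used when assembling host reference corpora.
#' @param allow_ambiguous Keep records containing N. Off by default: the
#'   usage statistics are undefined on ambiguous codons.
#' @param quiet Suppress the rejection-count message.
#' @return A `cds_set`: named character vector of sequences (names are the
#'   first word of each description line), with attribute `rejected`, a
#'   data.frame of `id`, `reason`.
#' @seealso [write_cds_fasta()], [write_rejections()]
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">ok", "ATGAAATAA", ">bad", "ATGAA"), fa)
#' s <- read_cds_fasta(fa, quiet = TRUE)
#' length(s)                 # 1
#' attr(s, "rejected")$reason
#' @export
read_cds_fasta <- function(path, require_atg = FALSE, allow_ambiguous = FALSE,
                           quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(raw), "[ \t]"), `[[`, character(1), 1L)
  nt <- normalize_nt(as.character(raw))
  names(nt) <- ids

  reason <- vapply(nt, cds_problem,
    character(1),
    require_atg = require_atg, allow_ambiguous = allow_ambiguous
  )
  keep <- reason == ""
  rejected <- data.frame(
    id = ids[!keep], reason = unname(reason[!keep]),
    stringsAsFactors = FALSE
  )
  if (!quiet) {
    message(sprintf(
      "read_cds_fasta: %d record(s) kept, %d rejected", sum(keep), sum(!keep)
    ))
  }
  structure(nt[keep], rejected = rejected, class = "cds_set")
}

# One-line validation verdict; "" means valid.
cds_problem <- function(nt, require_atg = FALSE, allow_ambiguous = FALSE) {
  if (grepl("[^ACGTN]", nt)) return("characters outside {A,C,G,T,N}")
  if (!allow_ambiguous && grepl("N", nt, fixed = TRUE)) {
    return("ambiguous base N")
  }
  if (nchar(nt) == 0L) return("empty sequence")
  if (nchar(nt) %% 3L != 0L) return("length not multiple of 3")
  cod <- split_codons(nt)
  code <- genetic_code()
  aa <- code$table[cod]
  aa[is.na(aa)] <- "X" # N-containing codon, only reachable with allow_ambiguous
  stops <- which(aa == "*")
  if (length(stops) > 0L && any(stops < length(aa))) {
    return("internal stop codon")
  }
  if (require_atg && cod[1L] != "ATG") return("does not start with ATG")
  ""
}

#' @export
print.cds_set <- function(x, ...) {
  rej <- attr(x, "rejected")
  cat(sprintf(
    "<cds_set>: %d sequence(s), %d to %d nt%s\n",
    length(x),
    if (length(x)) min(nchar(x)) else 0L,
    if (length(x)) max(nchar(x)) else 0L,
    if (!is.null(rej) && nrow(rej)) sprintf(" (%d rejected)", nrow(rej)) else ""
  ))
  invisible(x)
}

#' Coerce sequences to a cds_set
#'
#' Validates a named character vector of sequences and returns a `cds_set`.
#' Unlike [read_cds_fasta()] this errors on the first invalid record, since
#' programmatic input is expected to be clean.
#'
#' @param nt Named character vector of coding sequences.
#' @return A `cds_set`.
#' @export
as_cds_set <- function(nt) {
  if (length(nt) == 0L) stop("empty sequence set")
  if (is.null(names(nt)) || anyNA(names(nt)) || any(names(nt) == "")) {
    names(nt) <- sprintf("seq_%04d", seq_along(nt))
  }
  nt <- vapply(nt, normalize_nt, character(1))
  bad <- vapply(nt, cds_problem, character(1))
  if (any(bad != "")) {
    i <- which(bad != "")[1L]
    stop("invalid CDS '", names(nt)[i], "': ", bad[i])
  }
  structure(nt,
    rejected = data.frame(id = character(0), reason = character(0)),
    class = "cds_set"
  )
}

#' Translate a coding sequence
#'
#' @param nt A coding sequence (length a multiple of 3). A terminal stop
#'   codon is not represented in the protein; an internal stop is an error.
#' @param code A [genetic_code()].
#' @return Protein string, one letter per sense codon.
#' @examples
#' translate_cds("ATGAAATAA") # "MK"
#' @export
translate_cds <- function(nt, code = genetic_code()) {
  paste(code$table[sense_codons(nt, code)], collapse = "")
}

#' Write coding sequences to FASTA
#'
#' Round-trips with [read_cds_fasta()]: reading a written file recovers the
#' same ids and sequences.
#'
#' @param x Named character vector (or `cds_set`) of sequences.
#' @param path Output file.
#' @param line_width Maximum sequence characters per line.
#' @export
write_cds_fasta <- function(x, path, line_width = 60L) {
  if (length(x) == 0L) stop("no records to write")
  stopifnot(line_width >= 1L)
  set <- Biostrings::BStringSet(as.character(unclass(x)))
  names(set) <- names(x)
  Biostrings::writeXStringSet(set, path, width = line_width)
  invisible(path)
}

#' Write the rejection report of a cds_set
#'
#' TSV with columns `id`, `reason`, one row per record excluded by
#' [read_cds_fasta()].
#'
#' @param x A `cds_set`.
#' @param path Output TSV.
#' @export
write_rejections <- function(x, path) {
  rej <- attr(x, "rejected")
  if (is.null(rej)) rej <- data.frame(id = character(0), reason = character(0))
  utils::write.table(rej, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
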