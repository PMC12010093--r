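#' Genetic code with synonymous codon families
#'
#' Wraps a codon-to-amino-acid translation table together with the derived
#' synonymous families (the set of codons encoding each amino acid), which is
#' the structure every usage statistic in this package normalizes within.
#'
#' @param id Code identifier. Only `"standard"` (NCBI transl_table 1) is
#'   built in; any identifier accepted by
#'   [Biostrings::getGeneticCode()] also works.
#' @return An object of class `genetic_code` with components:
#'   \describe{
#'     \item{table}{named character vector, codon (DNA alphabet) to one-letter
#'       amino acid, `"*"` for stop.}
#'     \item{families}{named list, amino acid to its synonymous codons in
#'       alphabetical order.}
#'     \item{codons}{the sense codons in fixed alphabetical order (61 under
#'       the standard code); this is the column order of every usage matrix.}
#'     \item{stops}{the stop codons.}
#'   }
#' @examples
#' code <- genetic_code()
#' length(code$codons)        # 61
#' code$families[["K"]]       # "AAA" "AAG"
#' @export
genetic_code <- function(id = "standard") {
  tab <- if (identical(id, "standard")) {
    Biostrings::GENETIC_CODE
  } else {
    Biostrings::getGeneticCode(id)
  }
  tab <- tab[order(names(tab))]
  stopifnot(length(tab) == 64L)
  sense <- names(tab)[tab != "*"]
  fams <- split(sense, tab[sense])
  fams <- lapply(fams, sort)
  structure(
    list(
      id = id,
      table = tab,
      families = fams,
      codons = sort(sense),
      stops = sort(names(tab)[tab == "*"])
    ),
    class = "genetic_code"
  )
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf(
    "<genetic_code '%s'>: %d sense codons, %d stops, %d amino acids\n",
    x$id, length(x$codons), length(x$stops), length(x$families)
  ))
  invisible(x)
}

# Uppercase, RNA->DNA. Input records mix cases and alphabets (NCBI, tool
# output); everything downstream assumes upper-case DNA.
normalize_nt <- function(nt) {
  chartr("u", "T", chartr("acgtn", "ACGTN", nt))
}

# In-frame codons of a sequence whose length is a multiple of 3.
split_codons <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return(character(0))
  stopifnot(n %% 3L == 0L)
  substring(nt, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
}

# Sense codons of a CDS: terminal stop (if any) dropped, internal stop is an
# error -- an internal stop means the record is not a coding sequence.
sense_codons <- function(nt, code = genetic_code()) {
  cod <- split_codons(normalize_nt(nt))
  if (length(cod) == 0L) stop("sequence has zero codons")
  aa <- code$table[cod]
  if (is.na(aa[length(aa)])) stop("sequence contains non-ACGT codons")
  if (aa[length(aa)] == "*") {
    cod <- cod[-length(cod)]
    aa <- aa[-length(aa)]
  }
  if (anyNA(aa)) stop("sequence contains non-ACGT codons")
  if (any(aa == "*")) {
    stop("internal stop codon at codon ", which(aa == "*")[1L])
  }
  if (length(cod) == 0L) stop("sequence has zero sense codons")
  cod
}
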