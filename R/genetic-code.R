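#' Load a genetic code table
#'
#' Builds the genetic-code model used throughout the package: the 64-entry
#' codon-to-amino-acid map, the ordered list of sense codons, and the
#' synonymous codon families.  Six-fold degenerate amino acids (Leu, Ser,
#' Arg) are kept as whole families, the convention under which the standard
#' code has degeneracy classes \{1-fold: 2, 2-fold: 9, 3-fold: 1,
#' 4-fold: 5, 6-fold: 3\} and Wright's Nc spans \[20, 61\].
#'
#' @param table_name name of the code table. Only `"standard"` is supported.
#' @return An object of class `genetic_code`: a list with elements
#'   `codon_to_aa` (named character over all 64 codons, `"*"` for stops),
#'   `sense_codons` (61 codons, lexicographic), `stop_codons`, `families`
#'   (named list amino acid -> codon set) and `degeneracy` (named integer,
#'   family size per amino acid).
#' @examples
#' code <- load_genetic_code()
#' length(code$sense_codons)  # 61
#' @export
load_genetic_code <- function(table_name = "standard") {
  if (!identical(table_name, "standard")) {
    stop("unknown genetic code table: ", table_name,
         " (only \"standard\" is supported)")
  }
  if (!is.null(.pkg_env$standard_code)) return(.pkg_env$standard_code)
  bases <- c("A", "C", "G", "T")
  codons <- paste0(rep(bases, each = 16L),
                   rep(rep(bases, each = 4L), times = 4L),
                   rep(bases, times = 16L))
  aa <- Biostrings::GENETIC_CODE[codons]
  names(aa) <- codons
  sense <- codons[aa != "*"]
  stops <- codons[aa == "*"]
  fams <- split(sense, aa[sense])
  code <- structure(
    list(name = "standard",
         codon_to_aa = aa,
         sense_codons = sense,
         stop_codons = stops,
         families = fams,
         degeneracy = vapply(fams, length, integer(1))),
    class = "genetic_code")
  .pkg_env$standard_code <- code
  code
}

#' @export
print.genetic_code <- function(x, ...) {
  cat("Genetic code:", x$name, "-", length(x$sense_codons), "sense codons,",
      length(x$stop_codons), "stops,", length(x$families), "families\n")
  invisible(x)
}

#' Count families per degeneracy class
#'
#' @param code a `genetic_code`.
#' @return Named integer vector: number of synonymous families of each
#'   degeneracy (1, 2, 3, 4, 6 for the standard code).
#' @export
degeneracy_class_counts <- function(code = load_genetic_code()) {
  tab <- table(code$degeneracy)
  setNames(as.integer(tab), names(tab))
}

#' Translate an in-frame coding sequence
#' @param nt nucleotide string (length divisible by 3) or `coding_sequence`.
#' @param code a `genetic_code`.
#' @return Amino-acid string; stop codons translate to `"*"`.
#' @export
translate_cds <- function(nt, code = load_genetic_code()) {
  if (inherits(nt, "coding_sequence")) nt <- nt$nucleotides
  paste(code$codon_to_aa[chop_codons(nt)], collapse = "")
}
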