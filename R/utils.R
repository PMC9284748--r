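#' @keywords internal
"_PACKAGE"

#' @useDynLib codonevol, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor.test optim pchisq runif rnorm setNames wilcox.test
#'   median quantile
#' @importFrom utils combn read.delim write.table
NULL

.pkg_env <- new.env(parent = emptyenv())

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals do not
#' disturb the caller's random number stream.
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Derive a stream of sub-seeds from one run seed, kept within 32-bit range.
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1000003L * seq_len(n)) %% 2147483647L
}

#' Write a data frame as TSV with a header row
#' @param x data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

log_msg <- function(...) message(...)

chop_codons <- function(nt) {
  n <- nchar(nt)
  if (n == 0L) return(character(0))
  substring(nt, seq(1L, n, 3L), seq(3L, n, 3L))
}
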