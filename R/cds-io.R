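#' Construct a coding sequence
#'
#' A validated in-frame CDS: length divisible by 3, alphabet \{A,C,G,T\},
#' no internal stop codon.  A terminal stop codon is trimmed.
#'
#' @param id sequence identifier.
#' @param nucleotides nucleotide string.
#' @param code a `genetic_code`.
#' @return Object of class `coding_sequence` (list with `id`, `nucleotides`).
#' @export
coding_sequence <- function(id, nucleotides, code = load_genetic_code()) {
  nucleotides <- toupper(nucleotides)
  bad <- .cds_violation(nucleotides, code, trim = TRUE)
  if (!is.null(bad$reason)) stop("invalid CDS '", id, "': ", bad$reason)
  structure(list(id = id, nucleotides = bad$nt), class = "coding_sequence")
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat("<coding_sequence>", x$id, "-", nchar(x$nucleotides) / 3, "codons\n")
  invisible(x)
}

## Returns list(nt = possibly trimmed sequence, reason = NULL or string).
.cds_violation <- function(nt, code, trim) {
  if (grepl("[^ACGT]", nt)) return(list(nt = nt, reason = "ambiguity or non-ACGT character"))
  if (nchar(nt) %% 3L != 0L) return(list(nt = nt, reason = "length not divisible by 3"))
  cods <- chop_codons(nt)
  is_stop <- cods %in% code$stop_codons
  if (trim && length(cods) > 0L && is_stop[length(cods)]) {
    cods <- cods[-length(cods)]
    is_stop <- is_stop[-length(is_stop)]
    nt <- paste(cods, collapse = "")
  }
  if (any(is_stop)) {
    where <- if (is_stop[length(is_stop)]) "terminal" else "internal"
    return(list(nt = nt, reason = paste(where, "stop codon")))
  }
  list(nt = nt, reason = NULL)
}

#' Read coding sequences from a FASTA file
#'
#' Records are validated as in-frame CDS.  Records carrying ambiguity codes
#' (N, R, Y, ...) are always dropped with a logged warning, keeping all
#' downstream codon counts integral.  Frame and stop violations are handled
#' according to `stop_policy`:
#' \describe{
#'   \item{`trim_terminal`}{(default) a terminal stop codon is trimmed;
#'     any remaining violation (internal stop, broken frame) drops the
#'     record with a warning.}
#'   \item{`drop_record`}{violating records (including terminal stops) are
#'     dropped with a warning.}
#'   \item{`error`}{any violation aborts with an error.}
#' }
#'
#' @param path FASTA file.
#' @param stop_policy one of `"trim_terminal"`, `"drop_record"`, `"error"`.
#' @param code a `genetic_code`.
#' @return Named list of `coding_sequence` objects.
#' @export
read_cds_fasta <- function(path,
                           stop_policy = c("trim_terminal", "drop_record", "error"),
                           code = load_genetic_code()) {
  stop_policy <- match.arg(stop_policy)
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  out <- vector("list", length(ss))
  keep <- logical(length(ss))
  for (i in seq_along(ss)) {
    nt <- toupper(as.character(ss[[i]]))
    if (grepl("[^ACGT]", nt)) {
      warning("dropping record '", ids[i], "': ambiguity or non-ACGT character")
      next
    }
    chk <- .cds_violation(nt, code, trim = identical(stop_policy, "trim_terminal"))
    if (!is.null(chk$reason)) {
      if (identical(stop_policy, "error")) {
        stop("record '", ids[i], "': ", chk$reason)
      }
      warning("dropping record '", ids[i], "': ", chk$reason)
      next
    }
    out[[i]] <- structure(list(id = ids[i], nucleotides = chk$nt),
                          class = "coding_sequence")
    keep[i] <- TRUE
  }
  out <- out[keep]
  names(out) <- ids[keep]
  out
}

#' Write coding sequences to FASTA
#' @param seqs list of `coding_sequence` (or named character vector).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(seqs, path) {
  if (is.character(seqs)) {
    ids <- names(seqs)
    nts <- unname(seqs)
  } else {
    ids <- vapply(seqs, function(s) s$id, character(1))
    nts <- vapply(seqs, function(s) s$nucleotides, character(1))
  }
  writeLines(paste0(">", ids, "\n", nts), path)
  invisible(path)
}

#' Count codon usage of a coding sequence
#'
#' @param seq a `coding_sequence` (or plain nucleotide string).
#' @param code a `genetic_code`.
#' @param gene_id identifier used when `seq` is a plain string.
#' @return Object of class `codon_counts`: list with `gene_id`, `counts`
#'   (named non-negative integer vector over the 61 sense codons) and
#'   `total` (= number of codons).
#' @export
count_codons <- function(seq, code = load_genetic_code(), gene_id = NULL) {
  if (inherits(seq, "coding_sequence")) {
    nt <- seq$nucleotides
    gene_id <- gene_id %||% seq$id
  } else {
    nt <- toupper(seq)
    gene_id <- gene_id %||% "gene"
  }
  cods <- chop_codons(nt)
  if (any(cods %in% code$stop_codons)) stop("stop codon in sequence '", gene_id, "'")
  counts <- setNames(integer(length(code$sense_codons)), code$sense_codons)
  if (length(cods)) {
    tab <- table(factor(cods, levels = code$sense_codons))
    counts[] <- as.integer(tab)
  }
  structure(list(gene_id = gene_id, counts = counts, total = length(cods)),
            class = "codon_counts")
}

#' @export
print.codon_counts <- function(x, ...) {
  cat("<codon_counts>", x$gene_id, "-", x$total, "codons\n")
  invisible(x)
}

#' Construct a codon alignment
#'
#' Rows are equal-length gapped codon strings; gaps occur only as
#' whole-codon `"---"` units (mixed-frame gaps are an error, as guaranteed
#' by codon-model alignments).
#'
#' @param ids sequence identifiers.
#' @param rows gapped sequences (same order as `ids`).
#' @return Object of class `codon_alignment`: list with `ids`, `rows`,
#'   `n_codon_columns`.
#' @export
codon_alignment <- function(ids, rows) {
  rows <- toupper(rows)
  stopifnot(length(ids) == length(rows), length(rows) >= 1L)
  if (anyDuplicated(ids)) stop("duplicate sequence ids in alignment")
  len <- unique(nchar(rows))
  if (length(len) != 1L) stop("alignment rows differ in length")
  if (len %% 3L != 0L) stop("alignment length not divisible by 3")
  for (i in seq_along(rows)) {
    cods <- chop_codons(rows[i])
    gappy <- grepl("-", cods, fixed = TRUE)
    if (any(gappy & cods != "---")) {
      stop("row '", ids[i], "' has a gap that is not a whole-codon '---' unit")
    }
  }
  structure(list(ids = as.character(ids), rows = unname(rows),
                 n_codon_columns = len %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("<codon_alignment>", length(x$ids), "sequences x",
      x$n_codon_columns, "codon columns\n")
  invisible(x)
}

#' Read a codon alignment from gapped FASTA
#' @param path FASTA file.
#' @return A `codon_alignment`.
#' @export
read_codon_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  codon_alignment(sub("\\s.*$", "", names(ss)),
                  vapply(seq_along(ss), function(i) as.character(ss[[i]]),
                         character(1)))
}

#' Write a codon alignment to gapped FASTA
#' @param aln a `codon_alignment`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  writeLines(paste0(">", aln$ids, "\n", aln$rows), path)
  invisible(path)
}

#' Extract ungapped coding sequences from an alignment
#' @param aln a `codon_alignment`.
#' @param code a `genetic_code`.
#' @return Named list of `coding_sequence` objects (gap codons removed).
#' @export
alignment_to_cds <- function(aln, code = load_genetic_code()) {
  out <- lapply(seq_along(aln$ids), function(i) {
    nt <- gsub("-", "", aln$rows[i], fixed = TRUE)
    structure(list(id = aln$ids[i], nucleotides = nt),
              class = "coding_sequence")
  })
  names(out) <- aln$ids
  out
}
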