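## Codon-usage-bias battery: Wright's effective number of codons (Nc),
## GC/GC3 content, data-driven optimal-codon detection and Fop.

## Per-family codon homozygosity F-hat.
##   plugin:    F = S = sum(p_i^2)
##   corrected: F = (n*S - 1) / (n - 1)   (Wright's small-sample correction)
## Returns NA when the family is unusable (n = 0, or n < 2 for corrected).
.family_F <- function(counts, homozygosity) {
  n <- sum(counts)
  if (n == 0L) return(NA_real_)
  s <- sum((counts / n)^2)
  if (homozygosity == "plugin") return(s)
  if (n < 2L) return(NA_real_)
  (n * s - 1) / (n - 1)
}

#' Effective number of codons (Nc)
#'
#' Wright-style Nc with six-fold families (Leu, Ser, Arg) kept whole:
#' per synonymous family the codon homozygosity F-hat is estimated, class
#' averages are taken over families of equal degeneracy, and
#' `Nc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6`.  Nc is 20 for a gene that uses a
#' single codon per amino acid and 61 (under the plug-in estimator) for a
#' gene that uses all synonymous codons equally.
#'
#' When the single 3-fold family (Ile) is unobserved its class average is
#' imputed as `(F2 + F4)/2`.  If any other degeneracy class is entirely
#' unobserved, its term is dropped and the result rescaled by the
#' represented family count (logged).  The result is capped at 61; values
#' below 20 are possible for the corrected estimator on short genes and are
#' reported uncapped.
#'
#' @param counts a `codon_counts`.
#' @param code a `genetic_code`.
#' @param homozygosity `"corrected"` (Wright's `(nS-1)/(n-1)`, default) or
#'   `"plugin"` (`sum(p^2)`; the estimator under which equal usage gives
#'   exactly 61).
#' @return Nc as a single numeric; `NA` (with a warning) when undefined
#'   (empty gene, or no usable multi-codon family).
#' @export
compute_enc <- function(counts, code = load_genetic_code(),
                        homozygosity = c("corrected", "plugin")) {
  homozygosity <- match.arg(homozygosity)
  if (counts$total == 0L) {
    warning("Nc undefined for empty gene '", counts$gene_id, "'")
    return(NA_real_)
  }
  deg <- code$degeneracy
  fam_F <- vapply(names(code$families), function(aa) {
    if (deg[[aa]] < 2L) return(NA_real_)
    .family_F(counts$counts[code$families[[aa]]], homozygosity)
  }, numeric(1))
  class_sizes <- c(`2` = 9, `3` = 1, `4` = 5, `6` = 3)
  Fbar <- vapply(names(class_sizes), function(k) {
    v <- fam_F[deg[names(fam_F)] == as.integer(k)]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  if (all(is.na(Fbar)) || all(Fbar[!is.na(Fbar)] <= 0)) {
    warning("Nc undefined for gene '", counts$gene_id,
            "': no usable synonymous family")
    return(NA_real_)
  }
  if (is.na(Fbar[["3"]]) && !is.na(Fbar[["2"]]) && !is.na(Fbar[["4"]])) {
    Fbar[["3"]] <- (Fbar[["2"]] + Fbar[["4"]]) / 2
  }
  present <- !is.na(Fbar)
  terms <- class_sizes[present] / Fbar[present]
  nc <- 2 + sum(terms)
  if (!all(present)) {
    max_possible <- 2 + sum(class_sizes[present] * as.integer(names(class_sizes)[present]))
    log_msg("Nc for '", counts$gene_id, "': degeneracy class(es) ",
            paste(names(class_sizes)[!present], collapse = ","),
            " unobserved; rescaling by represented family count")
    nc <- nc * 61 / max_possible
  }
  min(nc, 61)
}

#' GC and GC3 content of a coding sequence
#'
#' @param seq a `coding_sequence` or nucleotide string.
#' @return Named numeric `c(gc = , gc3 = )`: G+C fraction over all positions
#'   and over third codon positions.  `NA` with a warning for an empty
#'   sequence.
#' @export
compute_gc_gc3 <- function(seq) {
  nt <- if (inherits(seq, "coding_sequence")) seq$nucleotides else toupper(seq)
  n <- nchar(nt)
  if (n == 0L) {
    warning("GC content undefined for empty sequence")
    return(c(gc = NA_real_, gc3 = NA_real_))
  }
  ch <- strsplit(nt, "", fixed = TRUE)[[1]]
  third <- ch[seq(3L, n, 3L)]
  c(gc = mean(ch %in% c("G", "C")), gc3 = mean(third %in% c("G", "C")))
}

#' Per-gene codon-bias profiles
#'
#' Convenience wrapper computing Nc, GC, GC3 (and Fop once an optimal-codon
#' table is available) for a set of genes.
#'
#' @param seqs list of `coding_sequence` objects.
#' @param code a `genetic_code`.
#' @param homozygosity passed to [compute_enc()].
#' @param optimal_table optional `optimal_codon_table` for Fop.
#' @param min_len_codons genes shorter than this are flagged (`flag_short`).
#' @return Data frame with columns `gene_id`, `nc`, `gc`, `gc3`, `fop`,
#'   `length_codons`, `flag_short`.
#' @export
codon_bias_profiles <- function(seqs, code = load_genetic_code(),
                                homozygosity = "corrected",
                                optimal_table = NULL,
                                min_len_codons = 50L) {
  rows <- lapply(seqs, function(s) {
    cc <- count_codons(s, code)
    g <- compute_gc_gc3(s)
    fop <- if (is.null(optimal_table)) NA_real_ else
      suppressWarnings(compute_fop(cc, optimal_table,
                                   min_len_codons = min_len_codons))
    data.frame(gene_id = cc$gene_id,
               nc = suppressWarnings(compute_enc(cc, code, homozygosity)),
               gc = unname(g["gc"]), gc3 = unname(g["gc3"]),
               fop = as.numeric(fop), length_codons = cc$total,
               flag_short = cc$total < min_len_codons,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Detect optimal codons from the frequency-vs-Nc correlation
#'
#' For every synonymous family (degeneracy >= 2) and every codon in it, the
#' within-family relative frequency across genes is Spearman-correlated with
#' the genes' overall bias Nc.  The optimal codon of a family is the codon
#' with the strongest (most negative) correlation among those significant at
#' `alpha / n`, where `n` is the family's codon count.  Genes shorter than
#' `min_len_codons` are removed, and a gene contributes a family's
#' frequencies only when it uses that family at least `min_family_count`
#' times (per-gene reading; a dataset-wide reading is available via
#' `family_filter = "dataset"`).
#'
#' @param genes list of `codon_counts`.
#' @param profiles data frame with `gene_id`, `nc`, `length_codons`
#'   (as from [codon_bias_profiles()]).
#' @param code a `genetic_code`.
#' @param min_len_codons minimum gene length in codons (default 50).
#' @param min_family_count minimum within-gene family usage (default 10).
#' @param alpha family-wise significance level; per-codon threshold is
#'   `alpha / n_family` (default 0.05).
#' @param family_filter `"per_gene"` (default) or `"dataset"` for the
#'   usage filter.
#' @return Object of class `optimal_codon_table`: data frame with one row
#'   per family (`family`, `optimal_codon` (`NA` if none), `rho`, `p_value`,
#'   `n_family`, `n_genes_used`).
#' @export
detect_optimal_codons <- function(genes, profiles, code = load_genetic_code(),
                                  min_len_codons = 50L, min_family_count = 10L,
                                  alpha = 0.05,
                                  family_filter = c("per_gene", "dataset")) {
  family_filter <- match.arg(family_filter)
  ids <- vapply(genes, function(g) g$gene_id, character(1))
  prof <- profiles[match(ids, profiles$gene_id), ]
  keep <- !is.na(prof$nc) & prof$length_codons >= min_len_codons
  genes <- genes[keep]
  nc <- prof$nc[keep]
  if (length(genes) < 3L) stop("fewer than 3 usable genes after filtering")
  const_nc <- isTRUE(all.equal(min(nc), max(nc)))
  if (const_nc) {
    warning("Nc is constant across genes; all correlations undefined")
  }
  fams <- code$families[code$degeneracy >= 2L]
  rows <- lapply(names(fams), function(aa) {
    codons <- fams[[aa]]
    k <- length(codons)
    usage <- vapply(genes, function(g) sum(g$counts[codons]), numeric(1))
    elig <- if (family_filter == "per_gene") usage >= min_family_count
            else rep(sum(usage) >= min_family_count, length(usage))
    elig <- elig & usage > 0
    n_used <- sum(elig)
    best <- data.frame(family = aa, optimal_codon = NA_character_,
                       rho = NA_real_, p_value = NA_real_, n_family = k,
                       n_genes_used = n_used, stringsAsFactors = FALSE)
    if (const_nc || n_used < 3L) return(best)
    nc_sub <- nc[elig]
    stats <- vapply(codons, function(cod) {
      freq <- vapply(genes[elig], function(g) g$counts[[cod]], numeric(1)) /
        usage[elig]
      if (isTRUE(all.equal(min(freq), max(freq)))) return(c(NA_real_, NA_real_))
      ct <- tryCatch(
        suppressWarnings(cor.test(freq, nc_sub, method = "spearman",
                                  exact = length(freq) < 10L)),
        error = function(e) NULL)
      if (is.null(ct)) c(NA_real_, NA_real_)
      else c(unname(ct$estimate), ct$p.value)
    }, numeric(2))
    rho <- stats[1, ]
    p <- stats[2, ]
    ok <- !is.na(rho) & !is.na(p) & rho < 0 & p <= alpha / k
    if (any(ok)) {
      j <- which(ok)[which.min(rho[ok])]
      best$optimal_codon <- codons[j]
      best$rho <- rho[j]
      best$p_value <- p[j]
    }
    best
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("optimal_codon_table", "data.frame")
  out
}

#' Frequency of optimal codons (Fop)
#'
#' `Fop = optimal codon occurrences / (optimal + non-optimal occurrences)`.
#' By the classic Fop convention the denominator counts only codons from
#' families that have a defined optimal codon; the literal all-codon
#' denominator is available via `denominator = "all"`.  One-fold families
#' (Met, Trp) never participate.
#'
#' @param counts a `codon_counts`.
#' @param table an `optimal_codon_table`.
#' @param code a `genetic_code`.
#' @param denominator `"optimal_families"` (default) or `"all"`.
#' @param min_len_codons genes shorter than this get attribute
#'   `flag_short = TRUE`.
#' @return Fop in \[0, 1\]; `NA` with a warning when no optimal codon is
#'   applicable to the gene (zero denominator).
#' @export
compute_fop <- function(counts, table, code = load_genetic_code(),
                        denominator = c("optimal_families", "all"),
                        min_len_codons = 50L) {
  denominator <- match.arg(denominator)
  if (!nrow(table)) stop("empty optimal-codon table")
  opt <- table[!is.na(table$optimal_codon), , drop = FALSE]
  num <- sum(counts$counts[opt$optimal_codon])
  den <- if (denominator == "all") {
    multi <- unlist(code$families[code$degeneracy >= 2L], use.names = FALSE)
    sum(counts$counts[multi])
  } else {
    sum(counts$counts[unlist(code$families[opt$family], use.names = FALSE)])
  }
  if (den == 0) {
    warning("Fop undefined for gene '", counts$gene_id,
            "': no applicable codons")
    return(structure(NA_real_, flag_short = counts$total < min_len_codons))
  }
  structure(num / den, flag_short = counts$total < min_len_codons)
}
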