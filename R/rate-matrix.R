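## MG94xHKY codon rate matrix with pi-symmetrized eigendecomposition.

## Position-specific nucleotide frequencies (4 x 3, rows ACGT) from a
## character vector of ungapped codons.
.position_nuc_freqs <- function(codons) {
  ch <- do.call(rbind, strsplit(codons, ""))
  out <- vapply(1:3, function(p) {
    tab <- table(factor(ch[, p], levels = .base_chars))
    as.numeric(tab) / sum(tab)
  }, numeric(4))
  rownames(out) <- .base_chars
  out
}

## Sense-codon nucleotide index matrix (61 x 3), cached per code.
.codon_nuc_idx <- function(code) {
  key <- paste0("nucidx_", code$name)
  if (is.null(.pkg_env[[key]])) {
    ch <- do.call(rbind, strsplit(code$sense_codons, ""))
    .pkg_env[[key]] <- matrix(match(ch, .base_chars), ncol = 3)
  }
  .pkg_env[[key]]
}

.codon_freqs_from_positions <- function(pos_freqs, code) {
  idx <- .codon_nuc_idx(code)
  f <- pos_freqs[cbind(idx[, 1], 1L)] * pos_freqs[cbind(idx[, 2], 2L)] *
    pos_freqs[cbind(idx[, 3], 3L)]
  setNames(f / sum(f), code$sense_codons)
}

#' F3x4 codon frequencies from an alignment or sequence set
#'
#' Estimates position-specific nucleotide frequencies over all ungapped
#' codons and returns them together with the implied (normalized product)
#' sense-codon frequencies.
#'
#' @param x a `codon_alignment`, a list of `coding_sequence`, or a
#'   character vector of codons.
#' @param code a `genetic_code`.
#' @return List with `pos_freqs` (4 x 3 matrix, rows ACGT) and `pi`
#'   (named numeric over the 61 sense codons).
#' @export
f3x4_frequencies <- function(x, code = load_genetic_code()) {
  codons <- if (inherits(x, "codon_alignment")) {
    unlist(lapply(x$rows, chop_codons), use.names = FALSE)
  } else if (is.list(x)) {
    unlist(lapply(x, function(s) chop_codons(s$nucleotides)), use.names = FALSE)
  } else {
    as.character(x)
  }
  codons <- codons[codons %in% code$sense_codons]
  if (!length(codons)) stop("no ungapped sense codons for F3x4 estimation")
  pf <- .position_nuc_freqs(codons)
  list(pos_freqs = pf, pi = .codon_freqs_from_positions(pf, code))
}

## Single-nucleotide substitution skeleton over sense codons, cached:
## data.frame(i, j, pos, target (nt index), ts, nonsyn).
.q_skeleton <- function(code) {
  key <- paste0("qskel_", code$name)
  if (!is.null(.pkg_env[[key]])) return(.pkg_env[[key]])
  sense <- code$sense_codons
  graph <- .codon_graph(code)$neighbors
  rows <- lapply(seq_along(sense), function(i) {
    tab <- graph[[sense[i]]]
    tab <- tab[!tab$is_stop, , drop = FALSE]
    data.frame(i = i, j = match(tab$to, sense), pos = tab$pos,
               target = match(substr(tab$to, tab$pos, tab$pos), .base_chars),
               ts = tab$ts, nonsyn = !tab$syn)
  })
  out <- do.call(rbind, rows)
  .pkg_env[[key]] <- out
  out
}

#' Build an MG94xHKY codon rate matrix
#'
#' Generator over the 61 sense codons with
#' `q_ij = pi-factor * kappa^[transition] * omega^[nonsynonymous]` for
#' single-nucleotide changes and 0 otherwise, scaled so that the expected
#' number of substitutions per codon per unit time is 1.  The pi-factor is
#' the target-nucleotide frequency (MG94) when `pi` is a 4 x 3
#' position-frequency matrix (e.g. from [f3x4_frequencies()]), or the
#' target-codon frequency when `pi` is a 61-vector of codon frequencies;
#' both choices are time-reversible with the stated stationary
#' distribution.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param omega nonsynonymous/synonymous rate ratio (>= 0).
#' @param pi 4 x 3 position-nucleotide frequency matrix, a 61-simplex of
#'   codon frequencies, or `"uniform"`.
#' @param code a `genetic_code`.
#' @return Object of class `codon_rate_matrix`: list with `q` (61 x 61),
#'   `kappa`, `omega`, `pi` (stationary codon frequencies) and the cached
#'   symmetrized eigendecomposition used by
#'   [transition_probabilities()].
#' @export
build_rate_matrix <- function(kappa, omega, pi = "uniform",
                              code = load_genetic_code()) {
  .build_qm(kappa, omega, .rate_template(pi, code))
}

## Precompute everything pi-dependent once; reused across (kappa, omega)
## evaluations inside an optimizer loop.
.rate_template <- function(pi, code = load_genetic_code()) {
  if (inherits(pi, "rate_template")) return(pi)
  sense <- code$sense_codons
  ns <- length(sense)
  skel <- .q_skeleton(code)
  if (identical(pi, "uniform")) {
    pi <- matrix(0.25, 4, 3, dimnames = list(.base_chars, NULL))
  }
  if (is.matrix(pi)) {
    if (!all(dim(pi) == c(4, 3))) stop("pi matrix must be 4 x 3 (ACGT x position)")
    pos <- sweep(pi, 2, colSums(pi), "/")
    if (any(pos <= 0)) {
      log_msg("flooring zero position-nucleotide frequencies at 1e-6")
      pos <- pmax(pos, 1e-6)
      pos <- sweep(pos, 2, colSums(pos), "/")
    }
    pi_codon <- .codon_freqs_from_positions(pos, code)
    factor_vec <- pos[cbind(skel$target, skel$pos)]
  } else {
    if (length(pi) != ns) stop("pi must be a 4x3 matrix or a 61-vector")
    if (any(pi <= 0)) {
      log_msg("flooring zero codon frequencies at 1e-8")
      pi <- pmax(pi, 1e-8)
    }
    pi_codon <- setNames(as.numeric(pi) / sum(pi), sense)
    factor_vec <- unname(pi_codon[skel$j])
  }
  d <- sqrt(pi_codon)
  structure(list(ns = ns, sense = sense,
                 idx = cbind(skel$i, skel$j),
                 ts = skel$ts, nonsyn = skel$nonsyn,
                 factor_vec = factor_vec, pi_codon = pi_codon,
                 d = d, dinv_outer = unname(d %o% (1 / d))),
            class = "rate_template")
}

.build_qm <- function(kappa, omega, tmpl) {
  stopifnot(kappa > 0, omega >= 0)
  ns <- tmpl$ns
  val <- tmpl$factor_vec
  val[tmpl$ts] <- val[tmpl$ts] * kappa
  val[tmpl$nonsyn] <- val[tmpl$nonsyn] * omega
  q <- matrix(0, ns, ns, dimnames = list(tmpl$sense, tmpl$sense))
  q[tmpl$idx] <- val
  diag(q) <- -rowSums(q)
  rate <- -sum(tmpl$pi_codon * diag(q))
  if (rate <= 0) stop("degenerate rate matrix (zero total rate)")
  q <- q / rate
  ## eigendecomposition in the pi-symmetrized basis (real by reversibility)
  B <- q * tmpl$dinv_outer
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  A <- e$vectors / tmpl$d
  Ainv <- t(e$vectors) * rep(tmpl$d, each = ns)
  structure(list(q = q, kappa = kappa, omega = omega, pi = tmpl$pi_codon,
                 eig = list(A = A, Ainv = Ainv, values = e$values)),
            class = "codon_rate_matrix")
}

#' @export
print.codon_rate_matrix <- function(x, ...) {
  cat(sprintf("<codon_rate_matrix> kappa=%.3g omega=%.3g (61 x 61, rate-1 scaled)\n",
              x$kappa, x$omega))
  invisible(x)
}

#' Codon transition probability matrix P(t) = exp(Qt)
#'
#' @param qm a `codon_rate_matrix`.
#' @param t elapsed time (expected substitutions per codon), `t >= 0`.
#' @return 61 x 61 row-stochastic matrix.
#' @export
transition_probabilities <- function(qm, t) {
  if (t < 0) stop("t must be non-negative")
  e <- qm$eig
  P <- e$A %*% (exp(e$values * t) * e$Ainv)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(qm$q)
  P
}
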