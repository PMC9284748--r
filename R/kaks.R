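## Pairwise Ka/Ks: NG86 counting and a kappa/frequency-corrected
## Yang-Nielsen-style estimator.

.base_chars <- c("A", "C", "G", "T")
.is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

## Per sense codon: 3x3 neighbor table (position x substitution), with
## amino-acid, stop and transition annotation.  Cached per code.
.codon_graph <- function(code) {
  key <- paste0("graph_", code$name)
  if (!is.null(.pkg_env[[key]])) return(.pkg_env[[key]])
  sense <- code$sense_codons
  aa <- code$codon_to_aa
  g <- lapply(sense, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    do.call(rbind, lapply(1:3, function(p) {
      alt <- setdiff(.base_chars, ch[p])
      nb <- vapply(alt, function(b) {
        x <- ch; x[p] <- b; paste(x, collapse = "")
      }, character(1))
      data.frame(pos = p, to = nb,
                 is_stop = aa[nb] == "*",
                 syn = aa[nb] == aa[cod],
                 ts = .is_transition(ch[p], alt),
                 stringsAsFactors = FALSE)
    }))
  })
  names(g) <- sense
  ## per-position count of synonymous substitutions (degeneracy type)
  degpos <- t(vapply(g, function(tab) {
    vapply(1:3, function(p) sum(tab$syn[tab$pos == p]), numeric(1))
  }, numeric(3)))
  out <- list(neighbors = g, degpos = degpos)
  .pkg_env[[key]] <- out
  out
}

#' NG86 synonymous and nonsynonymous site counts of a codon
#'
#' Each codon position contributes one site, split into a synonymous
#' fraction (synonymous single-nucleotide neighbors over non-stop
#' neighbors at that position) and a nonsynonymous remainder: `n = 3 - s`.
#'
#' @param codon a sense codon string, e.g. `"TTT"`.
#' @param code a `genetic_code`.
#' @return Named numeric `c(s = , n = )`.
#' @export
ng86_sites <- function(codon, code = load_genetic_code()) {
  codon <- toupper(codon)
  if (codon %in% code$stop_codons) stop("stop codon: ", codon)
  if (!codon %in% code$sense_codons) stop("not a sense codon: ", codon)
  tab <- .codon_graph(code)$neighbors[[codon]]
  s <- sum(vapply(1:3, function(p) {
    at <- tab[tab$pos == p & !tab$is_stop, , drop = FALSE]
    if (!nrow(at)) 0 else sum(at$syn) / nrow(at)
  }, numeric(1)))
  c(s = s, n = 3 - s)
}

## All orderings of 1..d (d <= 3).
.orderings <- list(
  `1` = list(1L),
  `2` = list(c(1L, 2L), c(2L, 1L)),
  `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
             c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

## Pathway-averaged difference counts between two sense codons.
## Pathways through stop codons are excluded; if every pathway is blocked
## the full set is used as a fallback.  `freq`: optional named codon
## frequencies; pathways are then weighted by the product of intermediate
## codon frequencies (YN convention) instead of equally.
## Returns c(sd, nd, sd_ts, sd_tv, nd_ts, nd_tv).
.pair_diff_stats <- function(c1, c2, code, freq = NULL) {
  out <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  if (c1 == c2) return(out)
  ch1 <- strsplit(c1, "")[[1]]
  ch2 <- strsplit(c2, "")[[1]]
  diffpos <- which(ch1 != ch2)
  d <- length(diffpos)
  aa <- code$codon_to_aa
  paths <- lapply(.orderings[[d]], function(ord) {
    cur <- ch1
    steps <- matrix(0, nrow = d, ncol = 4,
                    dimnames = list(NULL, c("syn", "ts", "stop", "w")))
    wt <- 1
    for (k in seq_len(d)) {
      p <- diffpos[ord[k]]
      nxt <- cur
      nxt[p] <- ch2[p]
      from <- paste(cur, collapse = "")
      to <- paste(nxt, collapse = "")
      steps[k, "syn"] <- as.numeric(aa[to] == aa[from])
      steps[k, "ts"] <- as.numeric(.is_transition(cur[p], nxt[p]))
      steps[k, "stop"] <- as.numeric(aa[to] == "*")
      if (k < d && !is.null(freq)) {
        fw <- unname(freq[to])
        wt <- wt * if (is.na(fw)) 0 else fw
      }
      cur <- nxt
    }
    list(steps = steps, blocked = any(steps[, "stop"] > 0), w = wt)
  })
  ok <- !vapply(paths, `[[`, logical(1), "blocked")
  use <- if (any(ok)) paths[ok] else paths
  w <- vapply(use, `[[`, numeric(1), "w")
  if (is.null(freq) || sum(w) <= 0) w <- rep(1, length(use))
  w <- w / sum(w)
  for (i in seq_along(use)) {
    st <- use[[i]]$steps
    syn <- st[, "syn"] == 1
    ts <- st[, "ts"] == 1
    out["sd"] <- out["sd"] + w[i] * sum(syn)
    out["nd"] <- out["nd"] + w[i] * sum(!syn)
    out["sd_ts"] <- out["sd_ts"] + w[i] * sum(syn & ts)
    out["sd_tv"] <- out["sd_tv"] + w[i] * sum(syn & !ts)
    out["nd_ts"] <- out["nd_ts"] + w[i] * sum(!syn & ts)
    out["nd_tv"] <- out["nd_tv"] + w[i] * sum(!syn & !ts)
  }
  out
}

## NG86 per-pair Sd/Nd lookup matrices (equal pathway weights), cached.
.ng86_tables <- function(code) {
  key <- paste0("ng86_", code$name)
  if (!is.null(.pkg_env[[key]])) return(.pkg_env[[key]])
  sense <- code$sense_codons
  n <- length(sense)
  SD <- ND <- matrix(0, n, n, dimnames = list(sense, sense))
  sites <- t(vapply(sense, function(cod) ng86_sites(cod, code), numeric(2)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i >= j) next
      st <- .pair_diff_stats(sense[i], sense[j], code)
      SD[i, j] <- SD[j, i] <- st[["sd"]]
      ND[i, j] <- ND[j, i] <- st[["nd"]]
    }
  }
  out <- list(SD = SD, ND = ND, sites = sites)
  .pkg_env[[key]] <- out
  out
}

## Split two (possibly gapped, aligned) sequences into comparable sense
## codon pairs; gapped or ambiguous codons are masked pairwise.
.comparable_codons <- function(a, b, code) {
  nta <- if (inherits(a, "coding_sequence")) a$nucleotides else toupper(a)
  ntb <- if (inherits(b, "coding_sequence")) b$nucleotides else toupper(b)
  ida <- if (inherits(a, "coding_sequence")) a$id else "seq1"
  idb <- if (inherits(b, "coding_sequence")) b$id else "seq2"
  if (nchar(nta) != nchar(ntb)) stop("sequences differ in length")
  if (nchar(nta) %% 3L != 0L) stop("sequence length not divisible by 3")
  ca <- chop_codons(nta)
  cb <- chop_codons(ntb)
  if (any(ca %in% code$stop_codons) || any(cb %in% code$stop_codons)) {
    stop("stop codon in aligned sequences")
  }
  keep <- ca %in% code$sense_codons & cb %in% code$sense_codons
  list(a = ca[keep], b = cb[keep], ids = c(ida, idb))
}

.jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

.kaks_result <- function(ids, method, S, N, Sd, Nd, ka, ks, kappa, flags,
                         n_codons) {
  undef <- is.na(ks) || ks <= 0
  ratio <- if (!undef && !is.na(ka)) ka / ks else NA_real_
  structure(list(gene1 = ids[1], gene2 = ids[2], method = method,
                 S = S, N = N, Sd = Sd, Nd = Nd, ka = ka, ks = ks,
                 ratio = ratio, kappa = kappa,
                 undefined_ratio = undef, flags = flags,
                 n_codons = n_codons),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<kaks_result %s> %s vs %s: Ka=%.4g Ks=%.4g Ka/Ks=%s\n",
              x$method, x$gene1, x$gene2, x$ka, x$ks,
              if (x$undefined_ratio) "undefined" else sprintf("%.4g", x$ratio)))
  invisible(x)
}

#' Pairwise Ka/Ks by Nei-Gojobori (1986) counting
#'
#' Synonymous/nonsynonymous sites are counted per codon (averaged over the
#' two sequences), differences are resolved by averaging over all minimal
#' mutational pathways with equal weights (stop-passing pathways excluded),
#' and the proportions are Jukes-Cantor corrected:
#' `d = -(3/4) log(1 - 4p/3)`.
#'
#' @param a,b aligned, equal-length `coding_sequence` objects or strings;
#'   gapped codons (`"---"`) are masked pairwise.
#' @param code a `genetic_code`.
#' @return A `kaks_result` with fields `S`, `N`, `Sd`, `Nd`, `ka`, `ks`,
#'   `ratio` (`NA` with `undefined_ratio = TRUE` when `ks = 0`).
#' @export
kaks_ng86 <- function(a, b, code = load_genetic_code()) {
  cc <- .comparable_codons(a, b, code)
  if (!length(cc$a)) stop("zero comparable codons")
  tabs <- .ng86_tables(code)
  ia <- match(cc$a, code$sense_codons)
  ib <- match(cc$b, code$sense_codons)
  S <- (sum(tabs$sites[ia, "s"]) + sum(tabs$sites[ib, "s"])) / 2
  N <- 3 * length(cc$a) - S
  idx <- cbind(ia, ib)
  Sd <- sum(tabs$SD[idx])
  Nd <- sum(tabs$ND[idx])
  pS <- Sd / S
  pN <- Nd / N
  ks <- .jc_correct(pS)
  ka <- .jc_correct(pN)
  flags <- character(0)
  if (is.na(ks) && pS >= 0.75) flags <- c(flags, "ks_saturated")
  if (is.na(ka) && pN >= 0.75) flags <- c(flags, "ka_saturated")
  .kaks_result(cc$ids, "NG86", S, N, Sd, Nd, ka, ks, NA_real_, flags,
               length(cc$a))
}

## Kimura two-parameter distance from transition (P) and transversion (Q)
## difference proportions; list(d, A, B) or NA on saturation.
.k2p <- function(P, Q) {
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  if (a1 <= 0 || a2 <= 0) return(list(d = NA_real_, A = NA_real_, B = NA_real_))
  A <- -0.5 * log(a1) + 0.25 * log(a2)
  B <- -0.25 * log(a2)
  list(d = A + 2 * B, A = A, B = B)
}

#' Pairwise Ka/Ks by a kappa- and frequency-corrected (YN-style) estimator
#'
#' An approximate counting method in the style of Yang & Nielsen's yn00:
#' the transition/transversion ratio kappa is estimated from
#' fourfold-degenerate and nondegenerate positions via Kimura's
#' two-parameter model, synonymous/nonsynonymous sites are counted with
#' mutation-opportunity weights `kappa^[transition] * pi[target codon]`
#' (F3x4 frequencies from the pair), multi-hit pathways are weighted by the
#' frequencies of their intermediate codons, and distances are corrected
#' with the kappa-aware K2P formula applied separately to synonymous and
#' nonsynonymous differences.  With `kappa = 1` and uniform frequencies the
#' site counts reduce exactly to NG86's.
#'
#' @param a,b aligned `coding_sequence` objects or strings.
#' @param code a `genetic_code`.
#' @param kappa optional fixed kappa; estimated from the pair when `NULL`.
#' @param pi `"f3x4"` (default) or `"uniform"` codon frequencies.
#' @param max_iter,tol fixed-point iteration control for the site counts.
#' @return A `kaks_result` (with `kappa`); falls back to NG86 with a
#'   warning if the iteration fails to converge.
#' @export
kaks_yn <- function(a, b, code = load_genetic_code(), kappa = NULL,
                    pi = c("f3x4", "uniform"), max_iter = 100L, tol = 1e-9) {
  pi <- match.arg(pi)
  cc <- .comparable_codons(a, b, code)
  if (!length(cc$a)) stop("zero comparable codons")
  graph <- .codon_graph(code)
  sense <- code$sense_codons
  ia <- match(cc$a, sense)
  ib <- match(cc$b, sense)

  freq <- if (pi == "uniform") {
    setNames(rep(1 / length(sense), length(sense)), sense)
  } else {
    pn <- .position_nuc_freqs(c(cc$a, cc$b))
    .codon_freqs_from_positions(pn, code)
  }

  est_kappa <- is.null(kappa)
  if (est_kappa) {
    dp <- graph$degpos
    ch_a <- do.call(rbind, strsplit(cc$a, ""))
    ch_b <- do.call(rbind, strsplit(cc$b, ""))
    k_est <- function(deg) {
      sel <- dp[ia, , drop = FALSE] == deg & dp[ib, , drop = FALSE] == deg
      x <- ch_a[sel]
      y <- ch_b[sel]
      if (!length(x)) return(NULL)
      diffs <- x != y
      list(n = length(x),
           P = mean(diffs & .is_transition(x, y)),
           Q = mean(diffs & !.is_transition(x, y)))
    }
    cls <- Filter(Negate(is.null), list(k_est(0), k_est(3)))
    kappa <- 1
    if (length(cls)) {
      ntot <- sum(vapply(cls, `[[`, numeric(1), "n"))
      P <- sum(vapply(cls, function(z) z$n * z$P, numeric(1))) / ntot
      Q <- sum(vapply(cls, function(z) z$n * z$Q, numeric(1))) / ntot
      k2 <- .k2p(P, Q)
      if (!is.na(k2$A) && k2$B > 1e-9) kappa <- max(0.02, min(99, k2$A / k2$B))
    }
  }

  ## kappa/frequency-weighted site counts; fixed point over (S, N)
  site_counts <- function(kap) {
    s_codon <- vapply(sense, function(cod) {
      tab <- graph$neighbors[[cod]]
      sum(vapply(1:3, function(p) {
        at <- tab[tab$pos == p & !tab$is_stop, , drop = FALSE]
        if (!nrow(at)) return(0)
        w <- ifelse(at$ts, kap, 1) * freq[at$to]
        if (sum(w) <= 0) return(0)
        sum(w[at$syn]) / sum(w)
      }, numeric(1)))
    }, numeric(1))
    S <- (sum(s_codon[ia]) + sum(s_codon[ib])) / 2
    c(S = S, N = 3 * length(ia) - S)
  }
  sn <- site_counts(kappa)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    sn_new <- site_counts(kappa)
    if (max(abs(sn_new - sn)) < tol) {
      sn <- sn_new
      converged <- TRUE
      break
    }
    sn <- sn_new
  }
  if (!converged) {
    warning("YN site counting did not converge; falling back to NG86")
    return(kaks_ng86(a, b, code))
  }

  ## pathway-weighted differences, split into transitions/transversions
  pair_key <- paste(cc$a, cc$b)
  agg <- c(sd = 0, nd = 0, sd_ts = 0, sd_tv = 0, nd_ts = 0, nd_tv = 0)
  tab <- table(pair_key)
  first <- !duplicated(pair_key)
  for (i in which(first)) {
    st <- .pair_diff_stats(cc$a[i], cc$b[i], code, freq = freq)
    agg <- agg + st * tab[[pair_key[i]]]
  }
  S <- sn[["S"]]
  N <- sn[["N"]]
  ks2 <- .k2p(agg[["sd_ts"]] / S, agg[["sd_tv"]] / S)
  ka2 <- .k2p(agg[["nd_ts"]] / N, agg[["nd_tv"]] / N)
  flags <- character(0)
  if (is.na(ks2$d)) flags <- c(flags, "ks_saturated")
  if (is.na(ka2$d)) flags <- c(flags, "ka_saturated")
  .kaks_result(cc$ids, "YN", S, N, agg[["sd"]], agg[["nd"]],
               ka2$d, ks2$d, kappa, flags, length(cc$a))
}

#' Within-group pairwise Ka/Ks for a gene family
#'
#' Computes all within-group pairs (foreground pairs and background pairs
#' separately) on an aligned gene family and returns a long pair table plus
#' a per-group five-number summary of the Ka/Ks ratios (boxplot-ready).
#' Undefined ratios (`ks = 0`) are flagged and excluded from summaries.
#'
#' @param aln a `codon_alignment` of one gene family.
#' @param group_table data frame with `gene_id` and `group` columns.
#' @param method `"NG86"` or `"YN"`.
#' @param code a `genetic_code`.
#' @return List with `pairs` (long data frame) and `summary` (per group:
#'   `n_pairs`, `n_defined`, `mean`, `min`, `q1`, `median`, `q3`, `max`).
#' @export
group_pairwise_kaks <- function(aln, group_table,
                                method = c("NG86", "YN"),
                                code = load_genetic_code()) {
  method <- match.arg(method)
  fun <- if (method == "NG86") kaks_ng86 else kaks_yn
  grp <- group_table$group[match(aln$ids, group_table$gene_id)]
  if (anyNA(grp)) {
    stop("gene(s) absent from group table: ",
         paste(aln$ids[is.na(grp)], collapse = ", "))
  }
  rows <- list()
  for (g in unique(grp)) {
    members <- which(grp == g)
    if (length(members) < 2L) {
      warning("group '", g, "' has fewer than 2 genes; no pairs computed")
      next
    }
    prs <- combn(members, 2L)
    for (k in seq_len(ncol(prs))) {
      i <- prs[1, k]
      j <- prs[2, k]
      r <- fun(structure(list(id = aln$ids[i], nucleotides = aln$rows[i]),
                         class = "coding_sequence"),
               structure(list(id = aln$ids[j], nucleotides = aln$rows[j]),
                         class = "coding_sequence"),
               code)
      rows[[length(rows) + 1L]] <- data.frame(
        gene1 = r$gene1, gene2 = r$gene2, group = g, method = method,
        S = r$S, N = r$N, Sd = r$Sd, Nd = r$Nd, ka = r$ka, ks = r$ks,
        ratio = r$ratio, kappa = r$kappa,
        flags = paste(c(if (r$undefined_ratio) "undefined_ratio", r$flags),
                      collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene1 = character(0), gene2 = character(0),
               group = character(0), method = character(0),
               S = numeric(0), N = numeric(0), Sd = numeric(0),
               Nd = numeric(0), ka = numeric(0), ks = numeric(0),
               ratio = numeric(0), kappa = numeric(0), flags = character(0))
  summ <- do.call(rbind, lapply(unique(pairs$group), function(g) {
    r <- pairs$ratio[pairs$group == g]
    ok <- r[!is.na(r)]
    data.frame(group = g, n_pairs = length(r), n_defined = length(ok),
               mean = if (length(ok)) mean(ok) else NA_real_,
               min = if (length(ok)) min(ok) else NA_real_,
               q1 = if (length(ok)) unname(quantile(ok, 0.25)) else NA_real_,
               median = if (length(ok)) median(ok) else NA_real_,
               q3 = if (length(ok)) unname(quantile(ok, 0.75)) else NA_real_,
               max = if (length(ok)) max(ok) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(pairs = pairs, summary = summ)
}
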