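# Independent oracles used to cross-check the package's estimators.

.oracle_bases <- c("A", "C", "G", "T")

oracle_code <- function() {
  aa <- Biostrings::GENETIC_CODE
  list(aa = aa, sense = names(aa)[aa != "*"])
}

# Exhaustive-pathway NG86 difference counts for one codon pair, written as
# a depth-first recursion over "which differing position mutates next"
# (distinct from the package's fixed-permutation walk).  Returns c(sd, nd).
# Pathways through stop codons are excluded; if all are blocked the full
# set is used.
oracle_pair_diffs <- function(c1, c2, aa) {
  recurse <- function(cur, target) {
    dpos <- which(strsplit(cur, "")[[1]] != strsplit(target, "")[[1]])
    if (!length(dpos)) {
      return(list(list(sd = 0, nd = 0, stops = 0)))
    }
    out <- list()
    for (p in dpos) {
      ch <- strsplit(cur, "")[[1]]
      ch[p] <- strsplit(target, "")[[1]][p]
      nxt <- paste(ch, collapse = "")
      syn <- aa[[nxt]] != "*" && aa[[cur]] != "*" && aa[[nxt]] == aa[[cur]]
      hit_stop <- aa[[nxt]] == "*"
      for (tail in recurse(nxt, target)) {
        out[[length(out) + 1L]] <- list(sd = tail$sd + as.numeric(syn),
                                        nd = tail$nd + as.numeric(!syn),
                                        stops = tail$stops + hit_stop)
      }
    }
    out
  }
  paths <- recurse(c1, c2)
  ok <- vapply(paths, function(p) p$stops == 0, logical(1))
  if (any(ok)) paths <- paths[ok]
  c(sd = mean(vapply(paths, `[[`, numeric(1), "sd")),
    nd = mean(vapply(paths, `[[`, numeric(1), "nd")))
}

# Per-codon synonymous site count by direct neighbor enumeration.
oracle_codon_sites <- function(codon, aa) {
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    nb <- vapply(setdiff(.oracle_bases, ch[p]), function(b) {
      x <- ch
      x[p] <- b
      paste(x, collapse = "")
    }, character(1))
    keep <- aa[nb] != "*"
    if (any(keep)) s <- s + sum(aa[nb][keep] == aa[[codon]]) / sum(keep)
  }
  c(s = s, n = 3 - s)
}

# Full NG86 on two codon vectors assembled purely from the oracle pieces
# (memoized per codon pair).
oracle_env <- new.env()
oracle_ng86 <- function(codons1, codons2) {
  oc <- oracle_code()
  if (is.null(oracle_env$sites)) {
    oracle_env$sites <- t(vapply(oc$sense,
                                 function(cd) oracle_codon_sites(cd, oc$aa),
                                 numeric(2)))
    oracle_env$diffs <- new.env()
  }
  S <- (sum(oracle_env$sites[codons1, "s"]) +
        sum(oracle_env$sites[codons2, "s"])) / 2
  N <- 3 * length(codons1) - S
  sd <- nd <- 0
  for (i in seq_along(codons1)) {
    key <- paste0(codons1[i], codons2[i])
    val <- oracle_env$diffs[[key]]
    if (is.null(val)) {
      val <- oracle_pair_diffs(codons1[i], codons2[i], oc$aa)
      oracle_env$diffs[[key]] <- val
    }
    sd <- sd + val[["sd"]]
    nd <- nd + val[["nd"]]
  }
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = sd, Nd = nd, ks = jc(sd / S), ka = jc(nd / N))
}

# Brute-force phylogenetic likelihood: explicit summation over all
# internal-node codon assignments.  Transition matrices are taken from the
# package (the oracle targets the pruning recursion, not the matrix
# exponential).
oracle_loglik <- function(alignment, tree, omega, kappa, pi = "uniform") {
  code <- load_genetic_code()
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  qms <- lapply(omega, function(w) build_rate_matrix(kappa, w, pi, code))
  P <- lapply(seq_len(nrow(phy$edge)), function(e) {
    transition_probabilities(qms[[tree$edge_class[e] + 1L]],
                             phy$edge.length[e])
  })
  rows <- alignment$rows[match(phy$tip.label, alignment$ids)]
  tipstates <- lapply(rows, function(r) {
    match(chop_codons_oracle(r), code$sense_codons)
  })
  root <- ntip + 1L
  pi_codon <- qms[[1]]$pi
  grid <- as.matrix(expand.grid(rep(list(seq_len(61)), nint)))
  total <- 0
  for (site in seq_len(alignment$n_codon_columns)) {
    state_of <- function(node, comb) {
      if (node <= ntip) tipstates[[node]][site] else comb[node - ntip]
    }
    lik <- 0
    for (g in seq_len(nrow(grid))) {
      comb <- grid[g, ]
      term <- pi_codon[comb[root - ntip]]
      for (e in seq_len(nrow(phy$edge))) {
        term <- term * P[[e]][state_of(phy$edge[e, 1], comb),
                              state_of(phy$edge[e, 2], comb)]
      }
      lik <- lik + unname(term)
    }
    total <- total + log(lik)
  }
  total
}

chop_codons_oracle <- function(nt) {
  substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
}

# Small fixed trees reused across tests.
tree_8tax <- function() {
  parse_labeled_newick(paste0(
    "(((t1:0.1,t2:0.1):0.1 #1,(t3:0.1,t4:0.1):0.1 #1):0.1 #1,",
    "((t5:0.1,t6:0.1):0.1,t7:0.2):0.1,t8:0.3);"))
}

tree_12tax <- function() {
  parse_labeled_newick(paste0(
    "((((t1:0.12,t2:0.12):0.08,(t3:0.12,t4:0.12):0.08):0.08,",
    "((t5:0.12,t6:0.12):0.08,(t7:0.12,t8:0.12):0.08):0.08):0.08,",
    "((t9:0.12,t10:0.12):0.08,(t11:0.12,t12:0.12):0.08):0.12);"))
}

tree_12tax_deep <- function() {
  parse_labeled_newick(paste0(
    "((((t1:0.25,t2:0.25):0.15,(t3:0.25,t4:0.25):0.15):0.15,",
    "((t5:0.25,t6:0.25):0.15,(t7:0.25,t8:0.25):0.15):0.15):0.15,",
    "((t9:0.25,t10:0.25):0.15,(t11:0.25,t12:0.25):0.15):0.25);"))
}

tree_2tax <- function(t = 0.15) {
  parse_labeled_newick(sprintf("(a:%g,b:%g);", t, t))
}

random_sense_codons <- function(n) {
  sample(load_genetic_code()$sense_codons, n, replace = TRUE)
}
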