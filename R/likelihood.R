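## Phylogenetic codon likelihood: site-pattern preparation and Felsenstein
## pruning (C++ core), shared by branch models, site models and the LRTs.

## Precompute pruning inputs for one (alignment, tree) pair:
## postorder edge matrix (0-based), tip pattern states, pattern weights.
.prep_pruning <- function(alignment, tree, code = load_genetic_code()) {
  stopifnot(inherits(alignment, "codon_alignment"), inherits(tree, "labeled_tree"))
  phy <- tree$phylo
  tips <- phy$tip.label
  miss <- setdiff(tips, alignment$ids)
  if (length(miss)) {
    stop("tree tip(s) missing from alignment: ", paste(miss, collapse = ", "))
  }
  rows <- alignment$rows[match(tips, alignment$ids)]
  sense <- code$sense_codons
  states <- do.call(rbind, lapply(rows, function(r) {
    cods <- chop_codons(r)
    if (any(cods %in% code$stop_codons)) stop("stop codon in alignment")
    match(cods, sense)  # NA for gaps / ambiguity -> missing data
  }))
  ## compress identical columns into patterns
  key <- apply(states, 2, paste, collapse = ".")
  upat <- !duplicated(key)
  pat_of_site <- match(key, key[upat])
  tipstate <- states[, upat, drop = FALSE]
  tipstate[is.na(tipstate)] <- 0L
  tipstate <- tipstate - 1L  # 0-based; missing -> -1
  po <- ape::reorder.phylo(phy, "postorder")
  eidx <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(phy$edge[, 1], phy$edge[, 2]))
  list(tipstate = tipstate,
       weights = as.numeric(tabulate(pat_of_site, nbins = sum(upat))),
       pat_of_site = pat_of_site,
       edge = po$edge - 1L,
       edge_index = eidx,      # postorder position -> original edge row
       eclass = tree$edge_class[eidx],
       tlen0 = phy$edge.length[eidx],
       nnode = length(tips) + phy$Nnode,
       root = length(tips),    # ape root node (ntip+1), 0-based
       ntip = length(tips),
       n_sites = alignment$n_codon_columns)
}

## Per-pattern log-likelihood given per-class rate matrices and branch
## lengths (in postorder order).
.pattern_loglik <- function(prep, qms, tlen) {
  cpp_pattern_loglik(prep$tipstate, prep$edge, tlen,
                     as.integer(prep$eclass),
                     lapply(qms, function(q) q$eig$A),
                     lapply(qms, function(q) q$eig$Ainv),
                     lapply(qms, function(q) q$eig$values),
                     qms[[1]]$pi, prep$nnode, prep$root)
}

#' Phylogenetic log-likelihood of a codon alignment
#'
#' Felsenstein pruning under the MG94xHKY codon model on a
#' branch-class-labeled tree: every branch uses the omega of its class,
#' kappa and the equilibrium frequencies are shared, and gap codons are
#' treated as missing data.  The likelihood is computed at the tree's root
#' under stationarity; by time-reversibility it is invariant to root
#' placement.
#'
#' @param alignment a `codon_alignment` whose ids cover the tree tips.
#' @param tree a `labeled_tree`.
#' @param omega numeric vector of omega values, one per branch class
#'   (class 0 first).
#' @param kappa transition/transversion rate ratio.
#' @param pi `"f3x4"` (estimated from the alignment, default),
#'   `"uniform"`, a 4 x 3 position-frequency matrix or a 61-vector.
#' @param code a `genetic_code`.
#' @param by_site return the per-site log-likelihood vector instead of the
#'   sum.
#' @return Total log-likelihood (or per-site vector).
#' @export
log_likelihood <- function(alignment, tree, omega, kappa, pi = "f3x4",
                           code = load_genetic_code(), by_site = FALSE) {
  if (length(omega) < tree$n_classes) {
    stop("need one omega per branch class (", tree$n_classes, ")")
  }
  prep <- .prep_pruning(alignment, tree, code)
  if (identical(pi, "f3x4")) pi <- f3x4_frequencies(alignment, code)$pos_freqs
  qms <- lapply(omega[seq_len(tree$n_classes)], function(w) {
    build_rate_matrix(kappa, w, pi, code)
  })
  ll <- .pattern_loglik(prep, qms, prep$tlen0)
  if (by_site) ll[prep$pat_of_site] else sum(ll * prep$weights)
}
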