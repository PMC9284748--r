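## Synthetic-data generators: codon alignments evolved under per-branch-
## class omega on a labeled tree, and gene sets with planted optimal-codon
## gradients.  Every generator is a pure function of its config (seed
## included) and writes its ground truth alongside the data.

#' Build a codon-alignment simulation recipe
#'
#' @param tree a `labeled_tree`.
#' @param omega numeric vector: omega per branch class (class 0 first).
#' @param kappa transition/transversion rate ratio (default 2).
#' @param pi `"uniform"`, a 4 x 3 position-frequency matrix, or a
#'   61-vector of codon frequencies.
#' @param n_codons alignment length in codons (>= 1).
#' @param seed mandatory integer seed.
#' @param site_classes optional data frame with columns `proportion` and
#'   `omega` for site-heterogeneous simulation (proportions must sum to 1;
#'   site-class omegas then replace the branch-class omegas).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(tree, omega, kappa = 2, pi = "uniform",
                              n_codons, seed, site_classes = NULL) {
  stopifnot(inherits(tree, "labeled_tree"))
  if (missing(seed)) stop("seed is mandatory")
  if (n_codons < 1L) stop("n_codons must be >= 1")
  if (length(omega) < tree$n_classes) {
    stop("need one omega per branch class (", tree$n_classes, ")")
  }
  if (any(omega < 0) || kappa <= 0) stop("invalid omega/kappa")
  if (!is.null(site_classes)) {
    stopifnot(is.data.frame(site_classes),
              all(c("proportion", "omega") %in% names(site_classes)))
    if (abs(sum(site_classes$proportion) - 1) > 1e-8) {
      stop("site-class proportions must sum to 1")
    }
  }
  structure(list(tree = tree, omega = omega, kappa = kappa, pi = pi,
                 n_codons = as.integer(n_codons), seed = as.integer(seed),
                 site_classes = site_classes),
            class = "simulation_config")
}

#' Simulate a codon alignment on a labeled tree
#'
#' Root codons are drawn from the stationary distribution; each branch
#' evolves its sites by drawing child states from the rows of
#' `P(t) = exp(Qt)` under the branch's class omega (exact under the model;
#' no event-by-event simulation is needed since only endpoint states are
#' observed).  With `site_classes`, each site is first assigned an omega
#' class with the stated proportions and all branches use the site's
#' omega.
#'
#' @param cfg a `simulation_config`.
#' @param code a `genetic_code`.
#' @return List with `alignment` (a `codon_alignment` over the tree tips)
#'   and `truth` (all parameters plus per-site class assignments).
#' @export
simulate_codon_alignment <- function(cfg, code = load_genetic_code()) {
  stopifnot(inherits(cfg, "simulation_config"))
  phy <- cfg$tree$phylo
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")
  eidx <- match(paste(po$edge[, 1], po$edge[, 2]),
                paste(phy$edge[, 1], phy$edge[, 2]))
  preorder_edges <- rev(seq_len(nrow(po$edge)))
  sense <- code$sense_codons

  with_seed(cfg$seed, {
    if (is.null(cfg$site_classes)) {
      site_omega_idx <- rep(1L, cfg$n_codons)
      omegas_used <- cfg$omega
      per_branch <- TRUE
    } else {
      site_omega_idx <- sample.int(nrow(cfg$site_classes), cfg$n_codons,
                                   replace = TRUE,
                                   prob = cfg$site_classes$proportion)
      omegas_used <- cfg$site_classes$omega
      per_branch <- FALSE
    }
    qm_of <- function(w) build_rate_matrix(cfg$kappa, w, cfg$pi, code)
    uniq_w <- sort(unique(if (per_branch) cfg$omega else omegas_used))
    qms <- lapply(uniq_w, qm_of)
    names(qms) <- as.character(uniq_w)
    pi_codon <- qms[[1]]$pi

    states <- matrix(NA_integer_, nnode, cfg$n_codons)
    root <- ntip + 1L
    states[root, ] <- sample.int(61L, cfg$n_codons, replace = TRUE,
                                 prob = pi_codon)
    for (e in preorder_edges) {
      par <- po$edge[e, 1]
      child <- po$edge[e, 2]
      tlen <- po$edge.length[e]
      w_branch <- cfg$omega[cfg$tree$edge_class[eidx[e]] + 1L]
      site_w <- if (per_branch) rep(w_branch, cfg$n_codons)
                else omegas_used[site_omega_idx]
      for (w in unique(site_w)) {
        P <- transition_probabilities(qms[[as.character(w)]], tlen)
        sel <- which(site_w == w)
        ps <- states[par, sel]
        for (u in unique(ps)) {
          here <- sel[ps == u]
          states[child, here] <- sample.int(61L, length(here), replace = TRUE,
                                            prob = P[u, ])
        }
      }
    }
    rows <- vapply(seq_len(ntip), function(i) {
      paste(sense[states[i, ]], collapse = "")
    }, character(1))
    aln <- codon_alignment(phy$tip.label, rows)
    truth <- list(kappa = cfg$kappa, omega = cfg$omega,
                  site_classes = cfg$site_classes,
                  site_class_of_site = if (per_branch) NULL else site_omega_idx,
                  site_omega = if (per_branch) NULL else omegas_used[site_omega_idx],
                  n_codons = cfg$n_codons, seed = cfg$seed,
                  pi = if (is.character(cfg$pi)) cfg$pi else "explicit")
    list(alignment = aln, truth = truth)
  })
}

#' Build a biased-gene-set simulation recipe
#'
#' Defines a gene set with a planted monotone relationship between usage
#' of designated optimal codons and overall codon bias: each gene carries
#' a bias level `b` in \[0, 1\]; within every designated family the
#' optimal codon's probability rises linearly from the uniform `1/k` at
#' `b = 0` to `boost_max` at `b = 1`, while non-designated families stay
#' uniform.  Codons are drawn on family simplices, so generated sequences
#' are stop-free by construction.
#'
#' @param n_genes number of genes (default 200).
#' @param len_range codon-length range, inclusive (default `c(200, 500)`;
#'   lengths >= 50 so genes survive the short-gene filter).
#' @param optimal named character vector: family amino acid -> designated
#'   optimal codon.  Default: the alphabetically first codon of every
#'   family with degeneracy >= 2.
#' @param boost_max optimal-codon probability at `b = 1` (default 0.9).
#' @param b optional numeric vector of per-gene bias levels; default
#'   `runif(n_genes)`.  Use `rep(0, n_genes)` for a null (no-gradient) set.
#' @param seed mandatory integer seed.
#' @param code a `genetic_code`.
#' @return Object of class `bias_sim_config`.
#' @export
bias_sim_config <- function(n_genes = 200L, len_range = c(200L, 500L),
                            optimal = NULL, boost_max = 0.9, b = NULL,
                            seed, code = load_genetic_code()) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(optimal)) {
    fams <- code$families[code$degeneracy >= 2L]
    optimal <- vapply(fams, function(x) sort(x)[1], character(1))
  }
  for (aa in names(optimal)) {
    if (!optimal[[aa]] %in% code$families[[aa]]) {
      stop("designated codon ", optimal[[aa]], " is not in family ", aa)
    }
  }
  if (!is.null(b)) stopifnot(length(b) == n_genes, all(b >= 0 & b <= 1))
  stopifnot(len_range[1] >= 1L, len_range[2] >= len_range[1],
            boost_max > 0, boost_max <= 1)
  structure(list(n_genes = as.integer(n_genes),
                 len_range = as.integer(len_range), optimal = optimal,
                 boost_max = boost_max, b = b, seed = as.integer(seed)),
            class = "bias_sim_config")
}

#' Simulate a gene set with a planted optimal-codon gradient
#'
#' @param cfg a `bias_sim_config`.
#' @param code a `genetic_code`.
#' @return List with `genes` (named list of `coding_sequence`) and `truth`
#'   (designated optimal codons and per-gene bias levels).
#' @export
simulate_biased_gene_set <- function(cfg, code = load_genetic_code()) {
  stopifnot(inherits(cfg, "bias_sim_config"))
  fams <- code$families
  aas <- names(fams)
  with_seed(cfg$seed, {
    b <- cfg$b %||% runif(cfg$n_genes)
    genes <- lapply(seq_len(cfg$n_genes), function(g) {
      lens <- seq.int(cfg$len_range[1], cfg$len_range[2])
      L <- lens[sample.int(length(lens), 1L)]
      fam_draw <- sample(aas, L, replace = TRUE)
      cods <- vapply(fam_draw, function(aa) {
        members <- fams[[aa]]
        k <- length(members)
        if (k == 1L) return(members)
        if (aa %in% names(cfg$optimal) && !is.na(cfg$optimal[[aa]])) {
          p_opt <- 1 / k + b[g] * (cfg$boost_max - 1 / k)
          probs <- rep((1 - p_opt) / (k - 1), k)
          probs[members == cfg$optimal[[aa]]] <- p_opt
        } else {
          probs <- rep(1 / k, k)
        }
        sample(members, 1L, prob = probs)
      }, character(1))
      structure(list(id = sprintf("gene_%03d", g),
                     nucleotides = paste(cods, collapse = "")),
                class = "coding_sequence")
    })
    names(genes) <- vapply(genes, `[[`, character(1), "id")
    list(genes = genes,
         truth = list(optimal = cfg$optimal, b = b, seed = cfg$seed,
                      boost_max = cfg$boost_max))
  })
}

#' Generate a miniature foreground/background study bundle
#'
#' Emits a toy study shaped like the sorbitol analysis: 3 gene families
#' over 7 pseudo-species (4 foreground, 3 background), with one family
#' ("famA") evolved at an elevated foreground omega (0.5 vs background
#' 0.15) and the others homogeneous, plus the labeled trees and the
#' gene-group table.  Small enough for the full pipeline to run in
#' minutes.
#'
#' @param seed integer seed.
#' @param n_codons codons per family alignment (default 300, of the order
#'   of the real gene families the study emulates).
#' @return List with `alignments` (named list of `codon_alignment`),
#'   `trees` (named list of `labeled_tree`), `group_table` (data frame),
#'   `truth`.
#' @export
make_toy_study <- function(seed, n_codons = 300L) {
  species <- c(paste0("fg", 1:4), paste0("bg", 1:3))
  groups <- c(rep("foreground", 4), rep("background", 3))
  newick <- paste0("(((fg1:0.08,fg2:0.08):0.05 #1,(fg3:0.09,fg4:0.09):0.05 #1)",
                   ":0.08 #1,((bg1:0.12,bg2:0.12):0.06,bg3:0.15):0.08);")
  fam_omega <- list(famA = c(0.15, 0.5), famB = c(0.15, 0.15),
                    famC = c(0.15, 0.15))
  seeds <- derive_seeds(seed, length(fam_omega))
  alignments <- list()
  trees <- list()
  gt <- list()
  for (i in seq_along(fam_omega)) {
    fam <- names(fam_omega)[i]
    tree <- parse_labeled_newick(newick)
    gene_ids <- paste0(species, "_", fam)
    tree$phylo$tip.label <- paste0(tree$phylo$tip.label, "_", fam)
    cfg <- simulation_config(tree, omega = fam_omega[[fam]], kappa = 2,
                             pi = "uniform", n_codons = n_codons,
                             seed = seeds[i])
    sim <- simulate_codon_alignment(cfg)
    alignments[[fam]] <- sim$alignment
    trees[[fam]] <- tree
    gt[[fam]] <- data.frame(gene_id = gene_ids, species = species,
                            family = fam, group = groups,
                            clade = ifelse(groups == "foreground", "A", ""),
                            stringsAsFactors = FALSE)
  }
  group_table <- do.call(rbind, gt)
  rownames(group_table) <- NULL
  list(alignments = alignments, trees = trees, group_table = group_table,
       truth = list(seed = seed, kappa = 2, omega = fam_omega,
                    n_codons = n_codons, elevated_family = "famA"))
}

#' Write a toy study bundle to disk
#'
#' Writes per-family gapped FASTA alignments, labeled Newick trees, the
#' group table (TSV) and the ground-truth record (JSON) in the dialects
#' the package's readers consume.
#'
#' @param bundle result of [make_toy_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_toy_study <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (fam in names(bundle$alignments)) {
    write_codon_alignment(bundle$alignments[[fam]],
                          file.path(dir, paste0(fam, ".aln.fasta")))
    write_labeled_newick(bundle$trees[[fam]],
                         file.path(dir, paste0(fam, ".nwk")))
  }
  write_tsv(bundle$group_table, file.path(dir, "groups.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
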