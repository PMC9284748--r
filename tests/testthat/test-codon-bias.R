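make_counts <- function(codon_vec, id = "g") {
  count_codons(paste(codon_vec, collapse = ""), gene_id = id)
}

test_that("Nc hits its theoretical extremes", {
  code <- load_genetic_code()
  one_per_aa <- unlist(lapply(code$families, function(x) rep(sort(x)[1], 10)))
  cc <- make_counts(one_per_aa)
  expect_equal(compute_enc(cc, homozygosity = "corrected"), 20)
  expect_equal(compute_enc(cc, homozygosity = "plugin"), 20)
  equal_usage <- make_counts(rep(code$sense_codons, each = 12))
  expect_equal(compute_enc(equal_usage, homozygosity = "plugin"), 61)
})

test_that("family homozygosity matches the hand-evaluated correction", {
  # two-fold family with counts (3, 1): S = 0.625, F = (4*0.625-1)/3 = 0.5
  expect_equal(codonevol:::.family_F(c(3, 1), "corrected"), 0.5)
  expect_equal(codonevol:::.family_F(c(3, 1), "plugin"), 0.625)
  expect_true(is.na(codonevol:::.family_F(c(1, 0), "corrected")))
})

test_that("Nc is undefined for empty genes", {
  expect_warning(v <- compute_enc(make_counts(character(0))), "undefined")
  expect_true(is.na(v))
})

test_that("GC and GC3 content match direct position counts", {
  expect_equal(unname(compute_gc_gc3("GGGCCC")), c(1, 1))
  expect_equal(unname(compute_gc_gc3("ATG")), c(1 / 3, 1))
  expect_equal(unname(compute_gc_gc3("ATTGCA")), c(1 / 3, 0))
  expect_equal(unname(compute_gc_gc3("AAGGGA")), c(1 / 2, 0.5))
  expect_warning(v <- compute_gc_gc3(""), "undefined")
  expect_true(all(is.na(v)))
})

test_that("plugin Nc is invariant to codon order and multiset duplication", {
  set.seed(11)
  cods <- random_sense_codons(200)
  nc1 <- compute_enc(make_counts(cods), homozygosity = "plugin")
  nc2 <- compute_enc(make_counts(sample(cods)), homozygosity = "plugin")
  nc3 <- compute_enc(make_counts(rep(cods, 5)), homozygosity = "plugin")
  expect_identical(nc1, nc2)
  expect_identical(nc1, nc3)
  # corrected estimator converges to the plugin value under duplication
  ncc <- vapply(c(1, 10, 100), function(k) {
    compute_enc(make_counts(rep(cods, k)), homozygosity = "corrected")
  }, numeric(1))
  expect_lt(abs(ncc[3] - nc1), abs(ncc[1] - nc1))
  expect_lt(abs(ncc[3] - nc1), 0.1)
})

test_that("concentrating a family's usage never increases Nc", {
  code <- load_genetic_code()
  set.seed(23)
  for (rep in 1:20) {
    cods <- random_sense_codons(300)
    cc <- make_counts(cods)
    fams <- code$families[code$degeneracy >= 2]
    fam <- fams[[sample(length(fams), 1)]]
    cnt <- cc$counts[fam]
    if (sum(cnt > 0) < 2) next
    lo <- names(which.min(replace(cnt, cnt == 0, NA)))
    hi <- names(which.max(cnt))
    if (lo == hi) next
    cc2 <- cc
    cc2$counts[lo] <- cc2$counts[lo] - 1L
    cc2$counts[hi] <- cc2$counts[hi] + 1L
    for (h in c("plugin", "corrected")) {
      expect_lte(compute_enc(cc2, homozygosity = h),
                 compute_enc(cc, homozygosity = h) + 1e-12)
    }
  }
})

test_that("a planted frequency gradient makes GAA the Glu optimal codon", {
  cfg <- bias_sim_config(n_genes = 80, optimal = c(E = "GAA"), seed = 42)
  sim <- simulate_biased_gene_set(cfg)
  counts <- lapply(sim$genes, count_codons)
  prof <- codon_bias_profiles(sim$genes)
  tab <- detect_optimal_codons(counts, prof)
  row <- tab[tab$family == "E", ]
  expect_identical(row$optimal_codon, "GAA")
  expect_lt(row$rho, 0)
  expect_lte(row$p_value, 0.05 / 2)
})

test_that("identical codon usage across genes yields no optimal codons", {
  nt <- paste(rep(c("AAA", "AAG", "GAA", "GGG", "TTT"), each = 12), collapse = "")
  genes <- lapply(1:5, function(i) {
    structure(list(id = paste0("g", i), nucleotides = nt),
              class = "coding_sequence")
  })
  names(genes) <- paste0("g", 1:5)
  counts <- lapply(genes, count_codons)
  prof <- codon_bias_profiles(genes)
  expect_warning(tab <- detect_optimal_codons(counts, prof), "constant")
  expect_true(all(is.na(tab$optimal_codon)))
})

test_that("families used fewer than 10 times contribute no observation", {
  cfg <- bias_sim_config(n_genes = 30, len_range = c(60, 60), seed = 5)
  sim <- simulate_biased_gene_set(cfg)
  counts <- lapply(sim$genes, count_codons)
  prof <- codon_bias_profiles(sim$genes)
  tab <- detect_optimal_codons(counts, prof, min_len_codons = 50,
                               min_family_count = 10)
  for (i in seq_len(nrow(tab))) {
    fam_codons <- load_genetic_code()$families[[tab$family[i]]]
    n_elig <- sum(vapply(counts, function(cc) {
      sum(cc$counts[fam_codons]) >= 10
    }, logical(1)))
    expect_identical(tab$n_genes_used[i], n_elig)
  }
})

test_that("optimal-codon detection needs at least 3 usable genes", {
  cfg <- bias_sim_config(n_genes = 2, seed = 1)
  sim <- simulate_biased_gene_set(cfg)
  expect_error(detect_optimal_codons(lapply(sim$genes, count_codons),
                                     codon_bias_profiles(sim$genes)),
               "fewer than 3")
})

fake_table <- function(families, codons) {
  structure(data.frame(family = families, optimal_codon = codons,
                       rho = -0.9, p_value = 1e-6,
                       n_family = lengths(load_genetic_code()$families[families]),
                       n_genes_used = 50, stringsAsFactors = FALSE),
            class = c("optimal_codon_table", "data.frame"))
}

test_that("Fop follows its defining ratio", {
  tab <- fake_table("K", "AAA")
  expect_equal(as.numeric(compute_fop(make_counts(rep("AAA", 60)), tab)), 1)
  expect_equal(as.numeric(compute_fop(make_counts(rep("AAG", 60)), tab)), 0)
  cc <- make_counts(c(rep("AAA", 30), rep("AAG", 70)))
  expect_equal(as.numeric(compute_fop(cc, tab)), 0.30)
  # denominator excludes families with no defined optimum by default
  cc2 <- make_counts(c(rep("AAA", 30), rep("AAG", 70), rep("GGG", 100)))
  expect_equal(as.numeric(compute_fop(cc2, tab)), 0.30)
  expect_equal(as.numeric(compute_fop(cc2, tab, denominator = "all")),
               30 / 200)
  # undefined when no applicable codons
  expect_warning(v <- compute_fop(make_counts(rep("GGG", 60)), tab),
                 "undefined")
  expect_true(is.na(v))
})

test_that("Fop of a concatenation lies between the genes' Fop values", {
  tab <- fake_table(c("K", "E"), c("AAA", "GAA"))
  set.seed(9)
  for (i in 1:10) {
    a <- random_sense_codons(80)
    b <- random_sense_codons(120)
    fa <- as.numeric(compute_fop(make_counts(a), tab))
    fb <- as.numeric(compute_fop(make_counts(b), tab))
    fab <- as.numeric(compute_fop(make_counts(c(a, b)), tab))
    expect_gte(fab, min(fa, fb) - 1e-12)
    expect_lte(fab, max(fa, fb) + 1e-12)
  }
})
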