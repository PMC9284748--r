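test_that("NG86 per-codon site counts match neighbor enumeration", {
  expect_equal(unname(ng86_sites("TTT")), c(1 / 3, 8 / 3))
  expect_equal(unname(ng86_sites("ATG")), c(0, 3))
  expect_gte(ng86_sites("GGG")[["s"]], 1)  # 4-fold third position
  expect_error(ng86_sites("TAA"), "stop")
  # against the independent oracle for every sense codon
  oc <- oracle_code()
  for (cod in oc$sense) {
    expect_equal(unname(ng86_sites(cod)),
                 unname(oracle_codon_sites(cod, oc$aa)), tolerance = 1e-12)
  }
})

test_that("identical sequences give zero distances and an undefined ratio", {
  nt <- paste(rep(c("ATG", "AAA", "GGG"), 20), collapse = "")
  r <- kaks_ng86(nt, nt)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(r$undefined_ratio)
  expect_true(is.na(r$ratio))
  ry <- kaks_yn(nt, nt)
  expect_equal(ry$ka, 0)
  expect_equal(ry$ks, 0)
})

test_that("a single synonymous difference counts as Sd = 1, Nd = 0", {
  a <- rep("AAA", 100)
  b <- a
  b[100] <- "AAG"  # Lys -> Lys, third-position transition
  r <- kaks_ng86(paste(a, collapse = ""), paste(b, collapse = ""))
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$ka, 0)
  expect_gt(r$ks, 0)
})

test_that("NG86 equals the exhaustive-pathway oracle on random pairs", {
  set.seed(101)
  for (i in 1:300) {
    n <- sample(3:8, 1)
    c1 <- random_sense_codons(n)
    c2 <- random_sense_codons(n)
    r <- kaks_ng86(paste(c1, collapse = ""), paste(c2, collapse = ""))
    o <- oracle_ng86(c1, c2)
    expect_equal(r$S, o$S, tolerance = 1e-12)
    expect_equal(r$N, o$N, tolerance = 1e-12)
    expect_equal(r$Sd, o$Sd, tolerance = 1e-12)
    expect_equal(r$Nd, o$Nd, tolerance = 1e-12)
  }
})

test_that("Ka/Ks estimators are symmetric and conserve S + N", {
  set.seed(55)
  tre <- tree_2tax()
  for (i in 1:5) {
    cfg <- simulation_config(tre, omega = 0.4, kappa = 2.5, pi = "uniform",
                             n_codons = 150, seed = 900 + i)
    sim <- simulate_codon_alignment(cfg)
    a <- sim$alignment$rows[1]
    b <- sim$alignment$rows[2]
    r1 <- kaks_ng86(a, b)
    r2 <- kaks_ng86(b, a)
    expect_identical(r1[c("S", "N", "Sd", "Nd", "ka", "ks")],
                     r2[c("S", "N", "Sd", "Nd", "ka", "ks")])
    expect_equal(r1$S + r1$N, 3 * r1$n_codons, tolerance = 1e-9)
    y1 <- kaks_yn(a, b)
    y2 <- kaks_yn(b, a)
    expect_equal(y1$ka, y2$ka, tolerance = 1e-9)
    expect_equal(y1$ks, y2$ks, tolerance = 1e-9)
    expect_equal(y1$S + y1$N, 3 * y1$n_codons, tolerance = 1e-9)
  }
})

test_that("gapped codons are masked pairwise", {
  a <- "AAA---GGG"
  b <- "AAAAAGGGG"
  r <- kaks_ng86(a, b)
  expect_identical(r$n_codons, 2L)
  expect_equal(r$Sd + r$Nd, 0)
})

test_that("YN with kappa = 1 and uniform frequencies reduces to NG86 sites", {
  tre <- tree_2tax()
  cfg <- simulation_config(tre, omega = 0.5, kappa = 3, pi = "uniform",
                           n_codons = 200, seed = 9)
  sim <- simulate_codon_alignment(cfg)
  a <- sim$alignment$rows[1]
  b <- sim$alignment$rows[2]
  r_ng <- kaks_ng86(a, b)
  r_yn <- kaks_yn(a, b, kappa = 1, pi = "uniform")
  expect_equal(r_yn$S, r_ng$S, tolerance = 1e-9)
  expect_equal(r_yn$N, r_ng$N, tolerance = 1e-9)
})

test_that("YN recovers omega from kappa-skewed simulated pairs", {
  # 10 replicate pairs at omega 0.2, kappa 2, t = 0.3 (scaled-down check;
  # the 50-replicate run backs the same bound in the acceptance suite)
  tre <- tree_2tax(0.15)
  rats <- vapply(1:10, function(s) {
    cfg <- simulation_config(tre, omega = 0.2, kappa = 2, pi = "uniform",
                             n_codons = 1000, seed = 100 + s)
    sim <- simulate_codon_alignment(cfg)
    kaks_yn(sim$alignment$rows[1], sim$alignment$rows[2])$ratio
  }, numeric(1))
  expect_lt(abs(mean(rats) - 0.2), 0.05)
})

test_that("group-wise Ka/Ks enumerates within-group pairs", {
  tre <- parse_labeled_newick("((a:0.1,b:0.1):0.05,(c:0.1,d:0.1):0.05);")
  cfg <- simulation_config(tre, omega = 0.3, kappa = 2, pi = "uniform",
                           n_codons = 120, seed = 77)
  sim <- simulate_codon_alignment(cfg)
  gt <- data.frame(gene_id = c("a", "b", "c", "d"),
                   group = rep("SPG", 4), stringsAsFactors = FALSE)
  res <- group_pairwise_kaks(sim$alignment, gt)
  expect_identical(nrow(res$pairs), 6L)
  gt2 <- data.frame(gene_id = c("a", "b", "c", "d"),
                    group = c("SPG", "SPG", "SPG", "SAG"),
                    stringsAsFactors = FALSE)
  expect_warning(res2 <- group_pairwise_kaks(sim$alignment, gt2),
                 "fewer than 2")
  expect_identical(nrow(res2$pairs), 3L)
  expect_error(group_pairwise_kaks(sim$alignment,
                                   data.frame(gene_id = "a", group = "SPG")),
               "absent")
})

test_that("elevated foreground omega orders group mean Ka/Ks", {
  # foreground genes evolved at omega 0.24, background at 0.12
  tre_fg <- parse_labeled_newick("((f1:0.15,f2:0.15):0.05,f3:0.2);")
  tre_bg <- parse_labeled_newick("((b1:0.15,b2:0.15):0.05,b3:0.2);")
  ok <- 0
  for (s in 1:10) {
    sim_fg <- simulate_codon_alignment(
      simulation_config(tre_fg, omega = 0.24, kappa = 2, pi = "uniform",
                        n_codons = 300, seed = 4000 + s))
    sim_bg <- simulate_codon_alignment(
      simulation_config(tre_bg, omega = 0.12, kappa = 2, pi = "uniform",
                        n_codons = 300, seed = 5000 + s))
    aln <- codon_alignment(c(sim_fg$alignment$ids, sim_bg$alignment$ids),
                           c(sim_fg$alignment$rows, sim_bg$alignment$rows))
    gt <- data.frame(gene_id = aln$ids,
                     group = rep(c("SPG", "SAG"), each = 3),
                     stringsAsFactors = FALSE)
    res <- group_pairwise_kaks(aln, gt)
    m <- res$summary$mean[match(c("SPG", "SAG"), res$summary$group)]
    ok <- ok + (m[1] > m[2])
  }
  expect_gte(ok, 9)
})

test_that("undefined ratios are flagged, not infinite, and excluded from means", {
  aln <- codon_alignment(c("x", "y"),
                         c(paste(rep("AAA", 60), collapse = ""),
                           paste(c(rep("AAA", 59), "AGA"), collapse = "")))
  gt <- data.frame(gene_id = c("x", "y"), group = "G",
                   stringsAsFactors = FALSE)
  res <- group_pairwise_kaks(aln, gt)
  expect_true(grepl("undefined_ratio", res$pairs$flags[1]))
  expect_true(is.na(res$pairs$ratio[1]))
  expect_identical(res$summary$n_defined, 0L)
  expect_true(is.na(res$summary$mean))
})
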