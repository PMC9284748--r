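fake_fit <- function(ln_l, n_free) {
  structure(list(ln_l = ln_l, n_free_params = n_free),
            class = "branch_model_fit")
}

test_that("likelihood ratio test follows the chi-square recipe", {
  r0 <- likelihood_ratio_test(fake_fit(-100, 5), fake_fit(-100, 6))
  expect_equal(r0$stat, 0)
  expect_equal(r0$p_value, 1)
  # 2*dlnL = 3.84 on 1 df sits at the classical 5% point
  r1 <- likelihood_ratio_test(fake_fit(-100, 5), fake_fit(-98.08, 6))
  expect_equal(r1$stat, 3.84, tolerance = 1e-9)
  expect_identical(r1$df, 1L)
  expect_lt(abs(r1$p_value - 0.05), 1e-3)
  # multi-ratio df from parameter counting
  r2 <- likelihood_ratio_test(fake_fit(-100, 5), fake_fit(-95, 7))
  expect_identical(r2$df, 2L)
  expect_error(likelihood_ratio_test(fake_fit(-100, 6), fake_fit(-99, 5)),
               "nested")
  expect_warning(likelihood_ratio_test(fake_fit(-99, 5), fake_fit(-100, 6)),
                 "worse")
})

test_that("requesting extra classes on an unlabeled tree reduces to one-ratio", {
  tre <- parse_labeled_newick("((a:0.15,b:0.15):0.1,c:0.2,d:0.25);")
  cfg <- simulation_config(tre, omega = 0.3, kappa = 2, pi = "uniform",
                           n_codons = 80, seed = 61)
  sim <- simulate_codon_alignment(cfg)
  f1 <- fit_branch_model(sim$alignment, tre, n_classes = 1, seed = 2)
  f2 <- fit_branch_model(sim$alignment, tre, n_classes = 2, seed = 2)
  expect_equal(f1$ln_l, f2$ln_l, tolerance = 1e-6)
  expect_true(is.na(f2$omegas[["omega_1"]]))
  expect_identical(f1$n_free_params, f2$n_free_params)
})

test_that("nested branch models never lose log-likelihood", {
  tre <- tree_8tax()
  cfg <- simulation_config(tre, omega = c(0.15, 0.5), kappa = 2,
                           pi = "uniform", n_codons = 120, seed = 71)
  sim <- simulate_codon_alignment(cfg)
  f0 <- fit_branch_model(sim$alignment, tre, n_classes = 1, seed = 3)
  f1 <- fit_branch_model(sim$alignment, tre, n_classes = 2, seed = 3,
                         init = f0)
  expect_gte(f1$ln_l, f0$ln_l - 1e-6)
  expect_identical(f1$n_free_params, f0$n_free_params + 1L)
  lrt <- likelihood_ratio_test(f0, f1)
  expect_identical(lrt$df, 1L)
  expect_gte(lrt$stat, 0)
})

test_that("branch-model fits are deterministic given data and seed", {
  tre <- tree_8tax()
  cfg <- simulation_config(tre, omega = c(0.15, 0.5), kappa = 2,
                           pi = "uniform", n_codons = 90, seed = 81)
  sim <- simulate_codon_alignment(cfg)
  f1 <- fit_branch_model(sim$alignment, tre, n_classes = 2, seed = 4)
  f2 <- fit_branch_model(sim$alignment, tre, n_classes = 2, seed = 4)
  expect_identical(f1$ln_l, f2$ln_l)
  expect_identical(f1$omegas, f2$omegas)
  expect_identical(f1$branch_lengths, f2$branch_lengths)
})

test_that("strong purifying simulations estimate omega below one", {
  tre <- parse_labeled_newick("((a:0.15,b:0.15):0.1,c:0.2,d:0.25);")
  for (s in 1:8) {
    cfg <- simulation_config(tre, omega = 0.1, kappa = 2, pi = "uniform",
                             n_codons = 100, seed = 6000 + s)
    sim <- simulate_codon_alignment(cfg)
    fit <- fit_branch_model(sim$alignment, tre, n_classes = 1, seed = s)
    expect_lt(fit$omegas[[1]], 1)
  }
})

test_that("site-class posteriors are proper and classes sort ascending", {
  tre <- parse_labeled_newick("((a:0.2,b:0.2):0.1,c:0.25,d:0.3);")
  sc <- data.frame(proportion = c(0.7, 0.3), omega = c(0.1, 1.2))
  cfg <- simulation_config(tre, omega = 0.3, kappa = 2, pi = "uniform",
                           n_codons = 120, seed = 91, site_classes = sc)
  sim <- simulate_codon_alignment(cfg)
  fit <- fit_site_model_m3(sim$alignment, tre, k_classes = 2, seed = 6)
  expect_equal(rowSums(fit$posteriors), rep(1, 120), tolerance = 1e-10)
  expect_equal(sum(fit$proportions), 1, tolerance = 1e-12)
  expect_true(all(diff(fit$omegas) >= 0))
  expect_identical(fit$n_free_params,
                   1L + 2L + 1L + nrow(tre$phylo$edge))
})

test_that("single-omega data collapses the site-class mixture", {
  tre <- parse_labeled_newick("(((a:0.2,b:0.2):0.1,c:0.25):0.05,(d:0.2,e:0.2):0.1,f:0.3);")
  cfg <- simulation_config(tre, omega = 0.25, kappa = 2, pi = "uniform",
                           n_codons = 150, seed = 101)
  sim <- simulate_codon_alignment(cfg)
  m0 <- fit_branch_model(sim$alignment, tre, n_classes = 1, seed = 7)
  m3 <- suppressMessages(fit_site_model_m3(sim$alignment, tre, k_classes = 3,
                                           seed = 7))
  expect_lt(m3$ln_l - m0$ln_l, 2)
  # and no spurious positive-selection sites are called
  expect_identical(nrow(positive_sites(m3)), 0L)
})

test_that("planted positive-selection sites are recovered by NEB", {
  # purifying background with a small omega = 3 class; a deep 12-taxon
  # tree gives each site enough substitutions for NEB discrimination
  tre <- tree_12tax_deep()
  sc <- data.frame(proportion = c(0.95, 0.05), omega = c(0.1, 3))
  cfg <- simulation_config(tre, omega = 0.3, kappa = 2, pi = "uniform",
                           n_codons = 210, seed = 111, site_classes = sc)
  sim <- simulate_codon_alignment(cfg)
  planted <- which(sim$truth$site_omega > 1)
  expect_gt(length(planted), 4)
  fit <- fit_site_model_m3(sim$alignment, tre, k_classes = 3, seed = 8)
  expect_gt(max(fit$omegas), 1)
  ps <- positive_sites(fit, threshold = 0.5)
  expect_true(all(diff(ps$site) > 0))
  expect_true(all(ps$posterior > 0.5 & ps$posterior <= 1))
  expect_gte(sum(planted %in% ps$site), ceiling(0.6 * length(planted)))
  # a threshold above 1 can never be exceeded by a posterior
  expect_identical(nrow(positive_sites(fit, threshold = 1.1)), 0L)
})

test_that("positive-site report is empty without an omega > 1 class", {
  fit <- structure(list(omegas = c(0.1, 0.4, 0.9),
                        posteriors = matrix(1 / 3, 10, 3)),
                   class = "site_model_fit")
  expect_identical(nrow(positive_sites(fit)), 0L)
})
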