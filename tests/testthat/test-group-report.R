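test_that("family-size means reproduce from per-species counts", {
  fs <- family_size_summary(paper_style_table())
  s <- fs$summary
  expect_equal(s$mean[s$family == "SOT" & s$group == "SPG"], 13.75)
  expect_equal(s$mean[s$family == "SDH" & s$group == "SPG"], 7.5)
  # means recompute exactly from the emitted per-species counts
  for (i in seq_len(nrow(s))) {
    cnt <- fs$counts[fs$counts$family == s$family[i] &
                     fs$counts$group == s$group[i], ]
    expect_equal(s$mean[i], sum(cnt$n) / nrow(cnt))
  }
})

test_that("species with zero genes in a family count as zero", {
  tbl <- data.frame(gene_id = c("a1", "a2", "b1"),
                    species = c("sp1", "sp1", "sp2"),
                    family = c("F1", "F1", "F2"),
                    group = c("G1", "G1", "G1"))
  fs <- family_size_summary(tbl)
  # sp2 has no F1 genes but belongs to the group: mean = 2 / 2
  s <- fs$summary
  expect_equal(s$mean[s$family == "F1"], 1)
  expect_equal(s$mean[s$family == "F2"], 0.5)
  # an empty family x group cell keeps a zero mean
  tbl2 <- rbind(tbl, data.frame(gene_id = "c1", species = "sp3",
                                family = "F3", group = "G2"))
  fs2 <- family_size_summary(tbl2)
  s2 <- fs2$summary
  expect_equal(s2$mean[s2$family == "F1" & s2$group == "G2"], 0)
})

test_that("group tables validate uniqueness and group membership", {
  f <- tempfile(fileext = ".tsv")
  write_tsv(data.frame(gene_id = c("a", "a"), species = "s", family = "F",
                       group = "G"), f)
  expect_error(read_group_table(f), "duplicate")
  tbl <- data.frame(gene_id = c("a", "b"), species = c("s1", "s1"),
                    family = "F", group = c("G1", "G2"))
  expect_error(family_size_summary(tbl), "more than one group")
})

test_that("extreme group separation yields a tiny Mann-Whitney p", {
  df <- data.frame(ratio = c(seq(0.5, 0.69, length.out = 20),
                             seq(0.1, 0.29, length.out = 20)),
                   group = rep(c("SPG", "SAG"), each = 20))
  cmp <- group_metric_comparison(df, "ratio")
  expect_lt(cmp$p_value, 0.001)
  expect_identical(cmp$summary$n, c(20L, 20L))
  # invariant to within-group row order
  cmp2 <- group_metric_comparison(df[sample(nrow(df)), ], "ratio")
  expect_identical(cmp$p_value, cmp2$p_value)
})

test_that("identical group distributions rarely reject", {
  keep <- 0
  for (s in 1:20) {
    set.seed(8000 + s)
    df <- data.frame(fop = rnorm(40), group = rep(c("A", "B"), 20))
    cmp <- group_metric_comparison(df, "fop")
    keep <- keep + (cmp$p_value > 0.05)
  }
  expect_gte(keep, 18)
})

test_that("undefined values and tiny groups are handled with flags", {
  df <- data.frame(nc = c(55, 54, NA, 52), group = c("A", "A", "A", "B"))
  expect_warning(cmp <- group_metric_comparison(df, "nc"), "skipped")
  expect_null(cmp$test)
  expect_identical(cmp$n_excluded, 1L)
  expect_error(group_metric_comparison(df, "absent_metric"), "not found")
})

write_toy_inputs <- function(seed = 99) {
  b <- make_toy_study(seed = seed)
  d <- tempfile()
  write_toy_study(b, d)
  fams <- lapply(names(b$alignments), function(f) {
    list(alignment = file.path(d, paste0(f, ".aln.fasta")),
         tree = file.path(d, paste0(f, ".nwk")))
  })
  names(fams) <- names(b$alignments)
  list(dir = d, families = fams,
       group_table = file.path(d, "groups.tsv"))
}

test_that("the pipeline runs end to end and reruns byte-identically", {
  inp <- write_toy_inputs()
  out1 <- file.path(tempfile(), "run1")
  cfg <- list(group_table = inp$group_table, families = inp$families,
              out_dir = out1, seed = 11,
              stages = c("bias", "kaks", "summary"))
  res <- suppressWarnings(run_pipeline(cfg))
  expect_true(file.exists(file.path(out1, "manifest.json")))
  expect_true(file.exists(file.path(out1, "bias_profiles.tsv")))
  expect_true(file.exists(file.path(out1, "kaks_pairs.tsv")))
  expect_true(file.exists(file.path(out1, "family_sizes.tsv")))
  expect_false(file.exists(file.path(out1, "branch_tests.tsv")))
  st <- vapply(res$manifest$stages, `[[`, character(1), "status")
  expect_true(all(st == "ok"))
  # rerun: byte-identical TSVs
  out2 <- file.path(tempfile(), "run2")
  cfg$out_dir <- out2
  suppressWarnings(run_pipeline(cfg))
  for (f in list.files(out1, pattern = "\\.tsv$")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)))
  }
})

test_that("the pipeline's model stages emit table-shaped reports", {
  inp <- write_toy_inputs(seed = 101)
  out <- tempfile()
  cfg <- list(group_table = inp$group_table,
              families = inp$families["famA"],
              out_dir = out, seed = 13, stages = c("branch", "site"))
  res <- suppressWarnings(run_pipeline(cfg))
  bt <- read.delim(file.path(out, "branch_tests.tsv"))
  expect_setequal(bt$model, c("one_ratio", "two_ratio"))
  expect_true(all(is.finite(bt$minus_ln_l)))
  expect_true(is.finite(bt$lrt_p[bt$model == "two_ratio"]))
  st <- read.delim(file.path(out, "site_tests.tsv"))
  expect_identical(nrow(st), 1L)
  expect_match(st$model, "M3")
})

test_that("pipeline input validation precedes any stage", {
  inp <- write_toy_inputs(seed = 103)
  out <- tempfile()
  cfg <- list(group_table = inp$group_table, families = inp$families,
              out_dir = out, seed = 11)
  cfg$families$famA$alignment <- "/nonexistent/file.fasta"
  expect_error(run_pipeline(cfg), "missing input")
  expect_false(file.exists(file.path(out, "bias_profiles.tsv")))
  # a gene absent from the group table is named in the error
  inp2 <- write_toy_inputs(seed = 105)
  gt <- read_group_table(inp2$group_table)
  gt <- gt[gt$gene_id != "fg1_famA", ]
  f2 <- tempfile(fileext = ".tsv")
  write_tsv(gt, f2)
  cfg2 <- list(group_table = f2, families = inp2$families,
               out_dir = tempfile(), seed = 11)
  expect_error(run_pipeline(cfg2), "fg1_famA")
})
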