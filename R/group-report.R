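## Group-level summaries and pipeline orchestration: family-size statistics
## per species group, per-group metric contrasts, and report assembly.

#' Read a gene-group table
#'
#' TSV with header columns `gene_id`, `species`, `family`, `group` and
#' optionally `clade`.  Every gene maps to exactly one family and group.
#'
#' @param path TSV file.
#' @return Data frame.
#' @export
read_group_table <- function(path) {
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "species", "family", "group")
  miss <- setdiff(req, names(tbl))
  if (length(miss)) stop("group table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(tbl$gene_id)) {
    stop("duplicate gene_id in group table: ",
         tbl$gene_id[duplicated(tbl$gene_id)][1])
  }
  tbl
}

#' Gene-family size summary per species group
#'
#' Counts genes per family, group and species (species with zero genes in
#' a family count as 0) and reports per family x group the total and the
#' mean over the group's species.  This reproduces summaries such as "mean
#' foreground family size 13.75" from per-species counts.
#'
#' @param table gene-group data frame (`gene_id`, `species`, `family`,
#'   `group`).
#' @return Object of class `family_size_summary`: list with `counts`
#'   (family, group, species, n) and `summary` (family, group, total,
#'   n_species, mean).
#' @export
family_size_summary <- function(table) {
  if (!nrow(table)) stop("empty gene-group table")
  sp_group <- unique(table[, c("species", "group")])
  if (anyDuplicated(sp_group$species)) {
    stop("species assigned to more than one group: ",
         sp_group$species[duplicated(sp_group$species)][1])
  }
  fams <- unique(table$family)
  counts <- do.call(rbind, lapply(fams, function(f) {
    do.call(rbind, lapply(unique(sp_group$group), function(g) {
      sps <- sp_group$species[sp_group$group == g]
      n <- vapply(sps, function(s) {
        sum(table$family == f & table$species == s)
      }, numeric(1))
      data.frame(family = f, group = g, species = sps, n = as.integer(n),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(counts) <- NULL
  summ <- do.call(rbind, lapply(split(counts, paste(counts$family, counts$group)),
                                function(d) {
    data.frame(family = d$family[1], group = d$group[1],
               total = sum(d$n), n_species = nrow(d),
               mean = sum(d$n) / nrow(d), stringsAsFactors = FALSE)
  }))
  summ <- summ[order(summ$family, summ$group), ]
  rownames(summ) <- NULL
  structure(list(counts = counts, summary = summ),
            class = "family_size_summary")
}

#' @export
print.family_size_summary <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Compare a metric between species groups
#'
#' Produces boxplot-ready per-group summaries (n, mean, median, quartiles,
#' min/max) and a two-sided Mann-Whitney U test of the group contrast.
#' Undefined (NA) values are excluded and counted.  The test is skipped
#' with a warning when any group has fewer than 2 observations, and when
#' more than two groups are present only the summaries are returned.
#'
#' @param df data frame holding the metric and a group column (e.g. joined
#'   codon-bias profiles, or a Ka/Ks pair table).
#' @param metric column name: one of the data's numeric metrics
#'   (`"ratio"`, `"fop"`, `"nc"`, `"gc"`, `"gc3"`, ...).
#' @param group_col grouping column name (default `"group"`).
#' @return List with `summary` (per-group data frame), `test`
#'   (an `htest` from [stats::wilcox.test()] or `NULL`), `p_value`,
#'   `n_excluded`.
#' @export
group_metric_comparison <- function(df, metric, group_col = "group") {
  if (!metric %in% names(df)) stop("metric column '", metric, "' not found")
  x <- df[[metric]]
  g <- as.character(df[[group_col]])
  keep <- !is.na(x) & !is.na(g)
  n_excluded <- sum(!keep)
  x <- x[keep]
  g <- g[keep]
  groups <- sort(unique(g))
  summ <- do.call(rbind, lapply(groups, function(gg) {
    v <- x[g == gg]
    data.frame(group = gg, metric = metric, n = length(v),
               mean = mean(v), min = min(v),
               q1 = unname(quantile(v, 0.25)), median = median(v),
               q3 = unname(quantile(v, 0.75)), max = max(v),
               stringsAsFactors = FALSE)
  }))
  test <- NULL
  if (length(groups) == 2L && all(summ$n >= 2L)) {
    test <- suppressWarnings(wilcox.test(x[g == groups[1]], x[g == groups[2]],
                                         alternative = "two.sided"))
  } else {
    warning("group contrast test skipped (need exactly 2 groups with >= 2 ",
            "observations each)")
  }
  list(summary = summ, test = test,
       p_value = if (is.null(test)) NA_real_ else test$p.value,
       n_excluded = n_excluded)
}

## Resolve the pipeline config: a list or a YAML file path.
.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config$stages <- config$stages %||% c("bias", "kaks", "branch", "site",
                                        "summary")
  config$seed <- config$seed %||% 1L
  config$method <- config$method %||% "NG86"
  config$homozygosity <- config$homozygosity %||% "corrected"
  config$site_k <- config$site_k %||% 3L
  config$n_starts <- config$n_starts %||% 3L
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  config
}

#' Run the comparative molecular-evolution pipeline
#'
#' Executes the configured stages -- codon bias, within-group pairwise
#' Ka/Ks, branch-model tests, site-model tests, and group summaries -- on
#' per-family codon alignments with labeled trees and a gene-group table,
#' writing TSV outputs plus a manifest (inputs, seed, versions,
#' parameters) into the output directory.  Reruns with the same config and
#' seed produce byte-identical TSV outputs.
#'
#' @param config list or YAML path with entries: `group_table` (path or
#'   data frame), `families` (named list, each with `alignment` and `tree`
#'   paths or objects), `out_dir`, and optionally `stages` (subset of
#'   `bias`, `kaks`, `branch`, `site`, `summary`), `seed`, `method`
#'   (`"NG86"`/`"YN"`), `homozygosity`, `site_k`, `n_starts`.
#' @param code a `genetic_code`.
#' @return Invisibly, a list with per-stage results and the manifest.
#' @export
run_pipeline <- function(config, code = load_genetic_code()) {
  cfg <- .load_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  ## ---- load and validate all inputs before any stage runs
  input_paths <- character(0)
  grab <- function(x, loader) {
    if (is.character(x)) {
      if (!file.exists(x)) stop("missing input file: ", x)
      input_paths <<- c(input_paths, x)
      loader(x)
    } else x
  }
  group_table <- grab(cfg$group_table, read_group_table)
  if (is.null(cfg$families) || !length(cfg$families)) {
    stop("config must name at least one family")
  }
  fams <- lapply(cfg$families, function(f) {
    list(alignment = grab(f$alignment, read_codon_alignment),
         tree = grab(f$tree, read_labeled_newick))
  })
  for (fam in names(fams)) {
    ids <- fams[[fam]]$alignment$ids
    absent <- setdiff(ids, group_table$gene_id)
    if (length(absent)) {
      stop("gene '", absent[1], "' (family ", fam,
           ") is absent from the group table")
    }
  }

  manifest <- list(
    package = "codonevol",
    version = as.character(utils::packageVersion("codonevol")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = cfg$seed,
    parameters = cfg[c("stages", "method", "homozygosity", "site_k",
                       "n_starts")],
    inputs = if (length(input_paths))
      as.list(tools::md5sum(unique(input_paths))) else list(),
    stages = list(), outputs = character(0))
  out <- list()
  emit <- function(name, df) {
    p <- file.path(cfg$out_dir, paste0(name, ".tsv"))
    write_tsv(df, p)
    manifest$outputs <<- c(manifest$outputs, basename(p))
    df
  }
  run_stage <- function(name, fun) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      warning("stage '", name, "' failed: ", conditionMessage(res))
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      out[[name]] <<- res
    }
  }

  profiles <- NULL
  kaks <- NULL

  run_stage("bias", function() {
    genes <- unlist(lapply(fams, function(f) alignment_to_cds(f$alignment, code)),
                    recursive = FALSE)
    names(genes) <- vapply(genes, `[[`, character(1), "id")
    counts <- lapply(genes, count_codons, code = code)
    prof <- codon_bias_profiles(genes, code, homozygosity = cfg$homozygosity)
    opt <- tryCatch(
      detect_optimal_codons(counts, prof, code),
      error = function(e) {
        warning("optimal-codon detection skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(opt) && any(!is.na(opt$optimal_codon))) {
      prof$fop <- vapply(counts, function(cc) {
        as.numeric(suppressWarnings(compute_fop(cc, opt, code)))
      }, numeric(1))[match(prof$gene_id, names(counts))]
      emit("optimal_codons", as.data.frame(opt))
    }
    prof$family <- group_table$family[match(prof$gene_id, group_table$gene_id)]
    prof$group <- group_table$group[match(prof$gene_id, group_table$gene_id)]
    profiles <<- prof
    emit("bias_profiles", prof)
    prof
  })

  run_stage("kaks", function() {
    res <- lapply(names(fams), function(fam) {
      r <- group_pairwise_kaks(fams[[fam]]$alignment, group_table,
                               method = cfg$method, code = code)
      r$pairs$family <- if (nrow(r$pairs)) fam else character(0)
      r$summary$family <- if (nrow(r$summary)) fam else character(0)
      r
    })
    pairs <- do.call(rbind, lapply(res, `[[`, "pairs"))
    summ <- do.call(rbind, lapply(res, `[[`, "summary"))
    kaks <<- pairs
    emit("kaks_pairs", pairs)
    emit("kaks_summary", summ)
    list(pairs = pairs, summary = summ)
  })

  run_stage("branch", function() {
    seeds <- derive_seeds(cfg$seed, length(fams))
    rows <- do.call(rbind, lapply(seq_along(fams), function(i) {
      fam <- names(fams)[i]
      aln <- fams[[fam]]$alignment
      tree <- fams[[fam]]$tree
      fit0 <- fit_branch_model(aln, tree, n_classes = 1L, seed = seeds[i],
                               n_starts = cfg$n_starts, code = code)
      r0 <- data.frame(family = fam, model = "one_ratio",
                       omega_setting = "entire tree: omega_0",
                       minus_ln_l = -fit0$ln_l,
                       estimates = sprintf("omega_0 = %.3f", fit0$omegas[1]),
                       lrt_p = NA_real_, stringsAsFactors = FALSE)
      if (tree$n_classes < 2L) return(r0)
      fit1 <- fit_branch_model(aln, tree, n_classes = tree$n_classes,
                               seed = seeds[i], n_starts = cfg$n_starts,
                               code = code)
      lrt <- likelihood_ratio_test(fit0, fit1)
      est <- paste(sprintf("omega_%d = %.3f", seq_along(fit1$omegas) - 1L,
                           fit1$omegas), collapse = "; ")
      rbind(r0, data.frame(family = fam, model = fit1$model,
                           omega_setting = "foreground classes vs background",
                           minus_ln_l = -fit1$ln_l, estimates = est,
                           lrt_p = lrt$p_value, stringsAsFactors = FALSE))
    }))
    emit("branch_tests", rows)
    rows
  })

  run_stage("site", function() {
    seeds <- derive_seeds(cfg$seed + 7L, length(fams))
    rows <- do.call(rbind, lapply(seq_along(fams), function(i) {
      fam <- names(fams)[i]
      fit <- fit_site_model_m3(fams[[fam]]$alignment, fams[[fam]]$tree,
                               k_classes = cfg$site_k, seed = seeds[i],
                               n_starts = cfg$n_starts, code = code)
      ps <- positive_sites(fit)
      data.frame(family = fam, model = sprintf("M3(k=%d)", fit$k_classes),
                 minus_ln_l = -fit$ln_l,
                 proportions = paste(sprintf("%.3f", fit$proportions),
                                     collapse = " "),
                 omegas = paste(sprintf("%.3f", fit$omegas), collapse = " "),
                 positive_sites = paste(ps$site, collapse = ", "),
                 stringsAsFactors = FALSE)
    }))
    emit("site_tests", rows)
    rows
  })

  run_stage("summary", function() {
    fs <- family_size_summary(group_table)
    emit("family_sizes", fs$summary)
    emit("family_size_counts", fs$counts)
    comps <- list()
    if (!is.null(profiles)) {
      for (m in intersect(c("fop", "nc", "gc", "gc3"), names(profiles))) {
        if (all(is.na(profiles[[m]]))) next
        cmp <- suppressWarnings(group_metric_comparison(profiles, m))
        comps[[m]] <- cbind(cmp$summary, p_value = cmp$p_value)
      }
    }
    if (!is.null(kaks) && nrow(kaks)) {
      cmp <- suppressWarnings(group_metric_comparison(kaks, "ratio"))
      comps[["ratio"]] <- cbind(cmp$summary, p_value = cmp$p_value)
    }
    if (length(comps)) emit("group_comparisons", do.call(rbind, comps))
    list(family_sizes = fs, comparisons = comps)
  })

  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(out, list(manifest = manifest)))
}
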