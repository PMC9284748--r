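## Branch-specific and site-class omega models with likelihood ratio tests
## and naive-empirical-Bayes positive-site identification.
##
## Optimization: bounded quasi-Newton (L-BFGS-B) on log-scale parameters.
## Branch-length gradients are analytic (C++ up/down pruning passes, and
## Fisher's identity for the site-class mixture); kappa/omega gradients use
## central differences that rebuild only the affected rate matrix.

.OMEGA_BOUNDS <- c(1e-4, 20)
.KAPPA_BOUNDS <- c(0.1, 20)
.TLEN_BOUNDS <- c(1e-7, 50)

.logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.eig_lists <- function(qms) {
  list(A = lapply(qms, function(q) q$eig$A),
       Ainv = lapply(qms, function(q) q$eig$Ainv),
       values = lapply(qms, function(q) q$eig$values))
}

## Shared L-BFGS-B multi-start driver.  The first start is polished hard;
## later (jittered) starts get a cheaper pass, and the winner is
## re-polished if it was not the first.
.multi_start_optim <- function(fn, gr, starts, lower, upper) {
  best <- NULL
  for (i in seq_along(starts)) {
    ctl <- if (i == 1L) list(maxit = 250L, factr = 1e7)
           else list(maxit = 50L, factr = 1e8)
    fit <- tryCatch(
      optim(.clamp(starts[[i]], lower, upper), fn, gr, method = "L-BFGS-B",
            lower = lower, upper = upper, control = ctl),
      error = function(e) NULL)
    if (is.null(fit)) next
    fit$start_index <- i
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("optimizer failed on all restarts")
  if (best$start_index != 1L) {
    pol <- tryCatch(
      optim(best$par, fn, gr, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 250L, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value) {
      pol$start_index <- best$start_index
      best <- pol
    }
  }
  best
}

#' Fit a branch-specific omega model
#'
#' Maximizes the MG94xHKY log-likelihood over a per-branch-class omega
#' vector, a shared kappa, and all branch lengths (input lengths serve as
#' initial values), using bounded quasi-Newton with seeded random
#' restarts.  `n_classes = 1` is the one-ratio model (a single omega for
#' the entire tree, branch labels ignored); `n_classes = 2` the two-ratio
#' model (foreground branches, class 1, versus background, class 0);
#' larger `n_classes` give multiple-ratio models.  Multi-class fits are
#' initialized from a one-ratio fit (supplied via `init` or computed
#' internally), which also guarantees that the fitted log-likelihood is
#' monotone along the nested model sequence.
#'
#' Classes requested but absent from the tree are reported as `NA` and do
#' not count as free parameters (so requesting two classes on an
#' all-background tree reduces to the one-ratio fit).
#'
#' @param alignment a `codon_alignment`.
#' @param tree a `labeled_tree` with branch classes `0..n_classes-1`.
#' @param n_classes number of omega classes (default: classes in the tree).
#' @param seed integer seed for the random restarts.
#' @param n_starts number of restarts (default 3).
#' @param pi frequency specification as in [log_likelihood()].
#' @param init optional one-ratio `branch_model_fit` on the same data used
#'   to initialize a multi-class fit (avoids refitting the null model when
#'   both are needed, as in a likelihood ratio test).
#' @param code a `genetic_code`.
#' @return Object of class `branch_model_fit`: `model`, `ln_l`, `omegas`
#'   (one per class, `NA` for classes absent from the tree), `kappa`,
#'   `branch_lengths` (original edge order), `n_free_params`, `at_bound`,
#'   `convergence`.
#' @export
fit_branch_model <- function(alignment, tree, n_classes = tree$n_classes,
                             seed = 1L, n_starts = 3L, pi = "f3x4",
                             init = NULL, code = load_genetic_code()) {
  stopifnot(n_classes >= 1L)
  ## one-ratio ignores branch labels; multi-ratio requires them to fit
  if (n_classes > 1L && tree$n_classes > n_classes) {
    stop("tree uses branch classes beyond 0..", n_classes - 1L)
  }
  prep <- .prep_pruning(alignment, tree, code)
  if (identical(pi, "f3x4")) pi <- f3x4_frequencies(alignment, code)$pos_freqs
  tmpl <- .rate_template(pi, code)

  if (n_classes == 1L) prep$eclass <- rep(0L, length(prep$eclass))
  present <- sort(unique(prep$eclass))
  K <- length(present)
  prep$eclass <- match(prep$eclass, present) - 1L
  E <- length(prep$tlen0)
  w <- prep$weights

  build_all <- function(kappa, om) lapply(om, function(x) .build_qm(kappa, x, tmpl))
  nll_of <- function(qms, tlen) {
    ll <- sum(.pattern_loglik(prep, qms, tlen) * w)
    if (!is.finite(ll)) 1e10 else -ll
  }
  unpack <- function(par) list(kappa = exp(par[1]),
                               om = exp(par[1 + seq_len(K)]),
                               tlen = exp(par[-seq_len(1 + K)]))
  fn <- function(par) {
    p <- unpack(par)
    nll_of(build_all(p$kappa, p$om), p$tlen)
  }
  gr <- function(par) {
    p <- unpack(par)
    qms <- build_all(p$kappa, p$om)
    el <- .eig_lists(qms)
    res <- cpp_loglik_grad(prep$tipstate, prep$edge, p$tlen,
                           as.integer(prep$eclass), el$A, el$Ainv, el$values,
                           qms[[1]]$pi, prep$nnode, prep$root, w)
    g_t <- -res$grad * p$tlen          # chain rule to log scale
    h <- 1e-4
    g_k <- (nll_of(build_all(p$kappa * exp(h), p$om), p$tlen) -
            nll_of(build_all(p$kappa * exp(-h), p$om), p$tlen)) / (2 * h)
    g_o <- vapply(seq_len(K), function(k) {
      up <- qms; up[[k]] <- .build_qm(p$kappa, p$om[k] * exp(h), tmpl)
      dn <- qms; dn[[k]] <- .build_qm(p$kappa, p$om[k] * exp(-h), tmpl)
      (nll_of(up, p$tlen) - nll_of(dn, p$tlen)) / (2 * h)
    }, numeric(1))
    c(g_k, g_o, g_t)
  }
  lower <- log(c(.KAPPA_BOUNDS[1], rep(.OMEGA_BOUNDS[1], K),
                 rep(.TLEN_BOUNDS[1], E)))
  upper <- log(c(.KAPPA_BOUNDS[2], rep(.OMEGA_BOUNDS[2], K),
                 rep(.TLEN_BOUNDS[2], E)))

  t0 <- pmax(prep$tlen0, 1e-4)
  base_start <- if (K > 1L) {
    pre <- init %||% fit_branch_model(alignment, tree, n_classes = 1L,
                                      seed = seed, n_starts = n_starts,
                                      pi = pi, code = code)
    log(c(pre$kappa, rep(max(pre$omegas[[1]], .OMEGA_BOUNDS[1] * 2), K),
          pmax(pre$branch_lengths[prep$edge_index], 1e-6)))
  } else {
    log(c(2, rep(0.2, K), t0))
  }
  starts <- with_seed(seed, {
    c(list(base_start),
      lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
        base_start + c(rnorm(1, 0, 0.5), rnorm(K, 0, 0.8), rnorm(E, 0, 0.3))
      }))
  })

  best <- .multi_start_optim(fn, gr, starts, lower, upper)
  p <- unpack(best$par)
  bl <- numeric(E)
  bl[prep$edge_index] <- p$tlen
  omegas <- rep(NA_real_, n_classes)
  omegas[present + 1L] <- p$om
  names(omegas) <- paste0("omega_", seq_len(n_classes) - 1L)
  at_bound <- p$om <= .OMEGA_BOUNDS[1] * 1.01 | p$om >= .OMEGA_BOUNDS[2] * 0.99
  if (any(at_bound)) log_msg("omega estimate at bound for class(es) ",
                             paste(present[at_bound], collapse = ","))
  structure(list(model = switch(min(n_classes, 3L), "one_ratio", "two_ratio",
                                "multi_ratio"),
                 n_classes = n_classes, ln_l = -best$value, omegas = omegas,
                 kappa = p$kappa, branch_lengths = bl,
                 n_free_params = 1L + K + E,
                 at_bound = at_bound, convergence = best$convergence,
                 seed = seed, pi = pi),
            class = "branch_model_fit")
}

#' @export
print.branch_model_fit <- function(x, ...) {
  cat(sprintf("<branch_model_fit %s> lnL = %.3f, kappa = %.3f\n",
              x$model, x$ln_l, x$kappa))
  print(round(x$omegas, 4))
  invisible(x)
}

#' Likelihood ratio test between nested model fits
#'
#' `stat = 2 (lnL1 - lnL0)` compared with a chi-square whose degrees of
#' freedom equal the difference in free parameter counts (two-ratio vs
#' one-ratio: df = 1; three-ratio: df = 2; four-ratio: df = 3).  A small
#' negative statistic (optimizer tolerance) is clamped to 0.
#'
#' @param fit0 null-model fit (`branch_model_fit` or `site_model_fit`).
#' @param fit1 alternative-model fit nesting `fit0`.
#' @return Object of class `lrt_result`: `stat`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(fit0, fit1) {
  if (fit0$n_free_params >= fit1$n_free_params) {
    stop("fit0 must be nested in fit1 (fewer free parameters)")
  }
  stat <- 2 * (fit1$ln_l - fit0$ln_l)
  if (stat < -1e-6) {
    warning("alternative model fit worse than null beyond tolerance (2*dlnL = ",
            signif(stat, 4), "); check optimizer convergence")
  }
  stat <- max(stat, 0)
  df <- as.integer(fit1$n_free_params - fit0$n_free_params)
  structure(list(stat = stat, df = df,
                 p_value = pchisq(stat, df, lower.tail = FALSE)),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("<lrt_result> 2*dlnL = %.4f, df = %d, p = %.4g\n",
              x$stat, x$df, x$p_value))
  invisible(x)
}

#' Fit a discrete site-class (M3-style) omega model
#'
#' Sites fall into `k_classes` omega classes with estimated proportions:
#' the likelihood of a site is `sum_k p_k L(site | omega_k)`.  Maximizes
#' over softmax-parameterized proportions, the class omegas, kappa and all
#' branch lengths; site posteriors follow by Bayes' rule (naive empirical
#' Bayes).  Classes are reported in ascending omega order.  Branch-class
#' labels on the tree are ignored (site-class models are
#' branch-homogeneous); `k_classes = 4` gives the M3-plus-one-extra-class
#' fit.
#'
#' @param alignment a `codon_alignment`.
#' @param tree a `labeled_tree` (branch lengths used as initial values).
#' @param k_classes number of omega classes (2, 3 or 4; default 3).
#' @param seed integer seed for the random restarts.
#' @param n_starts number of restarts (default 3).
#' @param pi frequency specification as in [log_likelihood()].
#' @param code a `genetic_code`.
#' @return Object of class `site_model_fit`: `k_classes`, `proportions`,
#'   `omegas` (ascending), `kappa`, `ln_l`, `posteriors` (site x class),
#'   `branch_lengths`, `n_free_params`, `collapsed`, `effective_classes`.
#' @export
fit_site_model_m3 <- function(alignment, tree, k_classes = 3L, seed = 1L,
                              n_starts = 3L, pi = "f3x4",
                              code = load_genetic_code()) {
  if (!k_classes %in% 2:4) stop("k_classes must be 2, 3 or 4")
  prep <- .prep_pruning(alignment, tree, code)
  prep$eclass <- rep(0L, length(prep$eclass))
  if (identical(pi, "f3x4")) pi <- f3x4_frequencies(alignment, code)$pos_freqs
  tmpl <- .rate_template(pi, code)
  k <- as.integer(k_classes)
  E <- length(prep$tlen0)
  w <- prep$weights
  npat <- length(w)

  ## par = [log kappa, log omega_1..k, alpha_1..k-1, log t_1..E]
  unpack <- function(par) {
    alpha <- c(par[1 + k + seq_len(k - 1L)], 0)
    props <- exp(alpha - max(alpha))
    list(kappa = exp(par[1]), omegas = exp(par[1 + seq_len(k)]),
         props = props / sum(props), tlen = exp(par[-seq_len(2L * k)]))
  }
  class_ll <- function(kappa, omegas, tlen) {
    vapply(omegas, function(x) {
      .pattern_loglik(prep, list(.build_qm(kappa, x, tmpl)), tlen)
    }, numeric(npat))
  }
  mix_nll <- function(llm, props) {
    ll <- sum(.logsumexp(sweep(llm, 2, log(props), "+")) * w)
    if (!is.finite(ll)) 1e10 else -ll
  }
  fn <- function(par) {
    p <- unpack(par)
    mix_nll(class_ll(p$kappa, p$omegas, p$tlen), p$props)
  }
  gr <- function(par) {
    p <- unpack(par)
    qms <- lapply(p$omegas, function(x) .build_qm(p$kappa, x, tmpl))
    llm <- vapply(qms, function(qm) .pattern_loglik(prep, list(qm), p$tlen),
                  numeric(npat))
    lp <- sweep(llm, 2, log(p$props), "+")
    post <- exp(lp - .logsumexp(lp))          # pattern x class posteriors
    ## branch lengths via Fisher's identity: sum_k posterior-weighted grads
    g_t <- numeric(E)
    ecl <- as.integer(prep$eclass)
    for (kk in seq_len(k)) {
      el <- .eig_lists(qms[kk])
      res <- cpp_loglik_grad(prep$tipstate, prep$edge, p$tlen, ecl,
                             el$A, el$Ainv, el$values, qms[[1]]$pi,
                             prep$nnode, prep$root, w * post[, kk])
      g_t <- g_t + res$grad
    }
    g_t <- -g_t * p$tlen
    ## proportions via the softmax identity
    g_a <- -colSums((post - rep(p$props, each = npat)) * w)[seq_len(k - 1L)]
    h <- 1e-4
    g_k <- (mix_nll(class_ll(p$kappa * exp(h), p$omegas, p$tlen), p$props) -
            mix_nll(class_ll(p$kappa * exp(-h), p$omegas, p$tlen), p$props)) /
      (2 * h)
    g_o <- vapply(seq_len(k), function(kk) {
      pert <- function(s) {
        l2 <- llm
        l2[, kk] <- .pattern_loglik(
          prep, list(.build_qm(p$kappa, p$omegas[kk] * exp(s), tmpl)), p$tlen)
        mix_nll(l2, p$props)
      }
      (pert(h) - pert(-h)) / (2 * h)
    }, numeric(1))
    c(g_k, g_o, g_a, g_t)
  }
  lower <- c(log(.KAPPA_BOUNDS[1]), rep(log(.OMEGA_BOUNDS[1]), k),
             rep(-20, k - 1L), rep(log(.TLEN_BOUNDS[1]), E))
  upper <- c(log(.KAPPA_BOUNDS[2]), rep(log(.OMEGA_BOUNDS[2]), k),
             rep(20, k - 1L), rep(log(.TLEN_BOUNDS[2]), E))

  om0 <- switch(k - 1L, c(0.1, 1.0), c(0.05, 0.3, 1.5), c(0.03, 0.2, 0.8, 2.5))
  base_start <- c(log(2), log(om0), rep(0, k - 1L), log(pmax(prep$tlen0, 1e-4)))
  starts <- with_seed(seed, {
    c(list(base_start),
      lapply(seq_len(max(0L, n_starts - 1L)), function(i) {
        base_start + c(rnorm(1, 0, 0.5), rnorm(k, 0, 0.8),
                       rnorm(k - 1L, 0, 1), rnorm(E, 0, 0.3))
      }))
  })
  best <- .multi_start_optim(fn, gr, starts, lower, upper)
  p <- unpack(best$par)
  ord <- order(p$omegas)
  omegas <- p$omegas[ord]
  props <- p$props[ord]
  llm <- class_ll(p$kappa, omegas, p$tlen)
  logpost <- sweep(llm, 2, log(props), "+")
  post_pat <- exp(logpost - .logsumexp(logpost))
  posteriors <- post_pat[prep$pat_of_site, , drop = FALSE]
  colnames(posteriors) <- paste0("class_", seq_len(k))
  collapsed <- any(diff(omegas) < 1e-4)
  eff <- 1L + sum(diff(omegas) >= 1e-4)
  if (collapsed) log_msg("site-class collapse: ", eff,
                         " effective omega class(es)")
  bl <- numeric(E)
  bl[prep$edge_index] <- p$tlen
  structure(list(k_classes = k, proportions = props, omegas = omegas,
                 kappa = p$kappa, ln_l = -best$value,
                 posteriors = posteriors, branch_lengths = bl,
                 n_free_params = 1L + k + (k - 1L) + E,
                 collapsed = collapsed, effective_classes = eff,
                 convergence = best$convergence, seed = seed),
            class = "site_model_fit")
}

#' @export
print.site_model_fit <- function(x, ...) {
  cat(sprintf("<site_model_fit M3 k=%d> lnL = %.3f, kappa = %.3f\n",
              x$k_classes, x$ln_l, x$kappa))
  print(round(rbind(proportion = x$proportions, omega = x$omegas), 4))
  invisible(x)
}

#' Identify positively selected sites (naive empirical Bayes)
#'
#' Reports the 1-based codon columns whose posterior probability of
#' belonging to an omega > 1 class exceeds `threshold`.  If no fitted
#' class has omega > 1 the report is empty.
#'
#' @param fit a `site_model_fit`.
#' @param threshold posterior probability cutoff (default 0.5).
#' @return Object of class `positive_site_report`: data frame with `site`
#'   (ascending) and `posterior`.
#' @export
positive_sites <- function(fit, threshold = 0.5) {
  sel <- which(fit$omegas > 1)
  out <- if (length(sel)) {
    post <- rowSums(fit$posteriors[, sel, drop = FALSE])
    idx <- which(post > threshold)
    data.frame(site = idx, posterior = post[idx])
  } else {
    data.frame(site = integer(0), posterior = numeric(0))
  }
  rownames(out) <- NULL
  class(out) <- c("positive_site_report", "data.frame")
  out
}
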