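# Resampling, trend and enrichment statistics. All Monte-Carlo p-values
# follow the add-one rule p = (b + 1) / (B + 1) with ties counted as "at
# least as extreme" (conservative); exact enumerations report the exact
# proportion instead.

new_resampling_result <- function(method, statistic, p_value, n_resamples,
                                  seed, sidedness, extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, n_resamples = n_resamples,
                   seed = seed, sidedness = sidedness), extra),
            class = "resampling_test_result")
}

#' @export
print.resampling_test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic=%.4g, p=%.4g (%s, B=%s)\n", x$method,
              x$statistic, x$p_value, x$sidedness,
              format(x$n_resamples)))
  invisible(x)
}

#' One-sided permutation test for a difference in means
#'
#' Tests whether the mean of `x_in` exceeds the mean of `x_out` by
#' permuting group labels. The observed statistic is
#' `mean(x_in) - mean(x_out)`; the one-sided p-value counts permuted
#' statistics at least as large (add-one rule). With `exact = TRUE` (or
#' automatically when the number of label assignments is at most
#' `exact_limit`) all assignments are enumerated and the exact proportion
#' returned.
#'
#' @param x_in,x_out numeric vectors (both nonempty).
#' @param R number of resamples (>= 1000 unless exact).
#' @param seed integer RNG seed.
#' @param exact force or forbid exhaustive enumeration; `NULL` = auto.
#' @param exact_limit maximum number of assignments enumerated.
#' @return a `resampling_test_result`.
#' @export
permutation_mean_difference_test <- function(x_in, x_out, R = 10000L,
                                             seed = 1L, exact = NULL,
                                             exact_limit = 1e5) {
  if (!length(x_in) || !length(x_out))
    stop("both groups must be nonempty")
  n1 <- length(x_in); pool <- c(x_in, x_out); n <- length(pool)
  obs <- mean(x_in) - mean(x_out)
  n_arr <- choose(n, n1)
  do_exact <- if (is.null(exact)) n_arr <= exact_limit else exact
  if (do_exact) {
    idx <- utils::combn(n, n1)
    stats_all <- apply(idx, 2L, function(i) mean(pool[i]) - mean(pool[-i]))
    p <- mean(stats_all >= obs - 1e-12)
    return(new_resampling_result("permutation_mean_difference", obs, p,
                                 n_arr, seed, "greater",
                                 list(mode = "exact")))
  }
  if (R < 1000L) stop("R must be >= 1000")
  set.seed(seed)
  tot <- sum(pool); n2 <- n - n1
  s1 <- vapply(seq_len(R), function(r) sum(pool[sample.int(n, n1)]),
               numeric(1))
  stat_r <- s1 / n1 - (tot - s1) / n2
  b <- sum(stat_r >= obs - 1e-12)
  new_resampling_result("permutation_mean_difference", obs,
                        (b + 1) / (R + 1), R, seed, "greater",
                        list(mode = "monte_carlo"))
}

#' Patient-resampling permutation test for group frequency differences
#'
#' Sample-level variant for cohort genotype matrices: permutes the marker
#' status across samples, re-derives the per-gene alteration-frequency
#' differences, and compares the mean difference of in-pathway genes to
#' out-of-pathway genes. One-sided (pathway genes show the larger mean
#' difference), add-one rule.
#'
#' @param matrix a [gene_cn_matrix()] including the marker gene row.
#' @param marker_gene the grouping gene (e.g. `"MYC"`).
#' @param pathway_labels named character vector; label `pathway` marks the
#'   co-occurrence set.
#' @param pathway label value defining the in-set genes.
#' @param R number of resamples.
#' @param seed integer RNG seed.
#' @param comparison passed to [group_frequency_difference()].
#' @return a `resampling_test_result`.
#' @export
permutation_cooccurrence_test <- function(matrix, marker_gene,
                                          pathway_labels,
                                          pathway = "PI3K_RAS", R = 10000L,
                                          seed = 1L,
                                          comparison = "neutral") {
  stopifnot(inherits(matrix, "gene_cn_matrix"))
  acn <- matrix$acn
  mcat <- categorize_acn(acn[marker_gene, ])
  altered <- mcat %in% c("gain", "amplification")
  neutral <- if (comparison == "neutral") mcat == "neutral"
             else !altered
  if (!any(altered) || !any(neutral))
    stop("cannot run: marker ", marker_gene, " grouping leaves an empty ",
         "group (altered n=", sum(altered), ", comparison n=",
         sum(neutral), ")")
  genes <- setdiff(rownames(acn), marker_gene)
  in_set <- genes[pathway_labels[genes] == pathway]
  out_set <- setdiff(genes, in_set)
  if (!length(in_set) || !length(out_set))
    stop("pathway split leaves an empty gene set")
  alt_frac <- function(cols) {
    sub <- acn[genes, cols, drop = FALSE]
    rowMeans(sub >= 2.5, na.rm = TRUE) * 100
  }
  stat_for <- function(grp_alt, grp_neu) {
    d <- alt_frac(grp_alt) - alt_frac(grp_neu)
    mean(d[in_set]) - mean(d[out_set])
  }
  obs <- stat_for(which(altered), which(neutral))
  set.seed(seed)
  n <- ncol(acn)
  n_alt <- sum(altered)
  elig <- which(altered | neutral)
  b <- 0L
  for (r in seq_len(R)) {
    perm_alt <- sample(elig, n_alt)
    perm_neu <- setdiff(elig, perm_alt)
    if (stat_for(perm_alt, perm_neu) >= obs - 1e-12) b <- b + 1L
  }
  new_resampling_result("permutation_cooccurrence", obs, (b + 1) / (R + 1),
                        R, seed, "greater")
}

#' Bootstrap test comparing two sets of correlations
#'
#' Resamples each set with replacement `B` times and reports the one-sided
#' percentile-bootstrap p-value for the hypothesis that the mean of
#' `within` exceeds the mean of `cross`: the (add-one) fraction of
#' bootstrap mean differences at or below zero.
#'
#' @param within,cross numeric vectors (e.g. Spearman correlations within
#'   and across a drug-pathway group).
#' @param B bootstrap samples.
#' @param seed integer RNG seed.
#' @return a `resampling_test_result`.
#' @export
bootstrap_correlation_set_test <- function(within, cross, B = 25000L,
                                           seed = 1L) {
  if (!length(within) || !length(cross))
    stop("both sets must be nonempty")
  if (length(within) == 1L || length(cross) == 1L)
    warning("a set of size 1 gives degenerate resampling")
  obs <- mean(within) - mean(cross)
  set.seed(seed)
  n1 <- length(within); n2 <- length(cross)
  mw <- colMeans(matrix(within[sample.int(n1, n1 * B, replace = TRUE)],
                        n1, B))
  mc <- colMeans(matrix(cross[sample.int(n2, n2 * B, replace = TRUE)],
                        n2, B))
  d <- mw - mc
  p <- (sum(d <= 0) + 1) / (B + 1)
  new_resampling_result("bootstrap_correlation_set", obs, p, B, seed,
                        "greater")
}

# Jonckheere-Terpstra statistic: sum over ordered group pairs (i < j) of
# Mann-Whitney counts, ties counted 1/2
jt_statistic <- function(groups) {
  k <- length(groups)
  s <- 0
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    xi <- groups[[i]]; xj <- groups[[j]]
    cmp <- outer(xi, xj, function(a, b) (a < b) + 0.5 * (a == b))
    s <- s + sum(cmp)
  }
  s
}

# enumerate all assignments of the pooled values into groups of the given
# sizes, applying `f` to each assignment's group list
enumerate_assignments <- function(pool, sizes, f) {
  out <- numeric(0)
  recurse <- function(remaining, si, groups) {
    if (si == length(sizes)) {
      groups[[si]] <- pool[remaining]
      out[[length(out) + 1L]] <<- f(groups)
      return(invisible())
    }
    cmb <- utils::combn(length(remaining), sizes[si])
    for (c_i in seq_len(ncol(cmb))) {
      pick <- remaining[cmb[, c_i]]
      groups[[si]] <- pool[pick]
      recurse(setdiff(remaining, pick), si + 1L, groups)
    }
  }
  recurse(seq_along(pool), 1L, vector("list", length(sizes)))
  out
}

#' Jonckheere-Terpstra test for an ordered trend
#'
#' Rank-based test for a monotone trend across ordered groups. The
#' statistic is the sum over group pairs `(i < j)` of Mann-Whitney counts
#' (ties counted 1/2). The p-value is exact (full enumeration of all
#' distinct assignments) when the number of arrangements is at most
#' `exact_limit`, otherwise a Monte-Carlo permutation (add-one rule) or a
#' tie-corrected normal approximation, per `mode`.
#'
#' @param groups list of numeric vectors in increasing hypothesised order.
#' @param alternative `"increasing"` (values rise with group order) or
#'   `"decreasing"`.
#' @param mode `"auto"` (exact when feasible, else permutation),
#'   `"exact"`, `"permutation"` or `"normal"`.
#' @param B permutation resamples when `mode` resolves to permutation.
#' @param seed integer RNG seed.
#' @param exact_limit largest arrangement count enumerated under
#'   `mode = "auto"`.
#' @return a `resampling_test_result`.
#' @export
jonckheere_terpstra <- function(groups,
                                alternative = c("increasing", "decreasing"),
                                mode = c("auto", "exact", "permutation",
                                         "normal"),
                                B = 10000L, seed = 1L, exact_limit = 1e5) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (length(groups) < 2L || any(!lengths(groups)))
    stop("need >= 2 nonempty ordered groups")
  if (alternative == "decreasing") groups <- rev(groups)
  sizes <- lengths(groups)
  pool <- unlist(groups)
  n <- length(pool)
  obs <- jt_statistic(groups)
  n_arr <- exp(lgamma(n + 1) - sum(lgamma(sizes + 1)))
  if (mode == "auto") mode <- if (n_arr <= exact_limit) "exact"
                              else "permutation"
  if (mode == "exact") {
    stats_all <- enumerate_assignments(pool, sizes, jt_statistic)
    p <- mean(stats_all >= obs - 1e-9)
    return(new_resampling_result("jonckheere_terpstra", obs, p,
                                 round(n_arr), seed, alternative,
                                 list(mode = "exact")))
  }
  if (mode == "permutation") {
    set.seed(seed)
    pm <- vapply(seq_len(B), function(i) sample(pool), pool)
    idx <- split(seq_len(n), rep(seq_along(sizes), sizes))
    stat_b <- numeric(B)
    k <- length(sizes)
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      Xj <- pm[idx[[j]], , drop = FALSE]
      for (a in idx[[i]]) {
        xa <- matrix(pm[a, ], nrow(Xj), B, byrow = TRUE)
        stat_b <- stat_b + colSums(Xj > xa) + 0.5 * colSums(Xj == xa)
      }
    }
    b <- sum(stat_b >= obs - 1e-9)
    return(new_resampling_result("jonckheere_terpstra", obs,
                                 (b + 1) / (B + 1), B, seed, alternative,
                                 list(mode = "permutation")))
  }
  # tie-corrected normal approximation
  mu <- (n^2 - sum(sizes^2)) / 4
  tie <- table(pool)
  v <- (n * (n - 1) * (2 * n + 5) - sum(sizes * (sizes - 1) *
          (2 * sizes + 5)) - sum(tie * (tie - 1) * (2 * tie + 5))) / 72 +
    sum(sizes * (sizes - 1) * (sizes - 2)) *
      sum(tie * (tie - 1) * (tie - 2)) /
      (36 * n * (n - 1) * (n - 2)) +
    sum(sizes * (sizes - 1)) * sum(tie * (tie - 1)) /
      (8 * n * (n - 1))
  z <- (obs - mu) / sqrt(v)
  p <- stats::pnorm(z, lower.tail = FALSE)
  new_resampling_result("jonckheere_terpstra", obs, p, NA_integer_, seed,
                        alternative, list(mode = "normal", z = z))
}

#' Null simulation study for gene-drug correlation pre-registration
#'
#' Draws independent drug-response (standard normal) and copy-number
#' (uniform over `cn_states`) matrices for a cohort, computes all pairwise
#' drug x gene Pearson correlations per replicate, and summarises the span
#' of their absolute values. Under independence with a small cohort, the
#' largest absolute correlation per replicate is substantial, quantifying
#' the risk of spurious gene-drug associations.
#'
#' @param n_patients,n_drugs cohort dimensions (defaults 20 and 12).
#' @param genes_range inclusive range of the per-replicate number of copy
#'   number changes (default 5-10).
#' @param reps replicates (>= 100).
#' @param seed integer RNG seed.
#' @param cn_states discrete copy-number support for the null generator.
#' @return list with `per_replicate` (data.frame: min, max, mean absolute
#'   correlation) and `summary` (means across replicates).
#' @export
null_simulation_study <- function(n_patients = 20L, n_drugs = 12L,
                                  genes_range = c(5L, 10L), reps = 1000L,
                                  seed = 1L, cn_states = 1:6) {
  if (n_patients < 4L) stop("n_patients must be >= 4")
  if (reps < 100L) stop("reps must be >= 100")
  set.seed(seed)
  res <- matrix(NA_real_, reps, 3L,
                dimnames = list(NULL, c("min_abs_r", "max_abs_r",
                                        "mean_abs_r")))
  for (r in seq_len(reps)) {
    g <- sample(seq(genes_range[1], genes_range[2]), 1L)
    drugs <- matrix(stats::rnorm(n_patients * n_drugs), n_patients)
    cn <- matrix(sample(cn_states, n_patients * g, replace = TRUE),
                 n_patients)
    cc <- abs(stats::cor(drugs, cn))
    res[r, ] <- c(min(cc), max(cc), mean(cc))
  }
  list(per_replicate = as.data.frame(res),
       summary = colMeans(res))
}

#' Kolmogorov-Smirnov uniformity test with random-set sensitivity
#'
#' Tests the observed association p-values against Uniform(0, 1) with a
#' one-sample KS test, then situates the observed KS p-value within the
#' null distribution of KS p-values obtained from random same-size sets of
#' candidate p-values.
#'
#' @param observed_pvalues numeric vector in (0, 1], length >= 3.
#' @param candidate_universe pool of p-values from which random sets are
#'   drawn (must be larger than the observed set).
#' @param n_random_sets number of random sets (default 1000).
#' @param seed integer RNG seed.
#' @return list with `ks_statistic`, `ks_p`, `random_ks_p` (vector) and
#'   `observed_quantile` (position of the observed KS p among the random
#'   ones).
#' @export
ks_uniformity_sensitivity <- function(observed_pvalues, candidate_universe,
                                      n_random_sets = 1000L, seed = 1L) {
  if (length(observed_pvalues) < 3L) stop("need >= 3 observed p-values")
  if (any(observed_pvalues <= 0 | observed_pvalues > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(observed_pvalues)
  if (length(candidate_universe) <= m)
    stop("candidate universe too small to draw same-size sets")
  ks <- suppressWarnings(stats::ks.test(observed_pvalues, "punif"))
  set.seed(seed)
  rand <- vapply(seq_len(n_random_sets), function(i) {
    s <- sample(candidate_universe, m)
    suppressWarnings(stats::ks.test(s, "punif")$p.value)
  }, numeric(1))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       random_ks_p = rand,
       observed_quantile = mean(rand < ks$p.value))
}

# classic weighted Kolmogorov-Smirnov running sum (weight exponent 1)
gsea_running_es <- function(stat_sorted, in_set_sorted) {
  nr <- sum(abs(stat_sorted[in_set_sorted]))
  n_miss <- sum(!in_set_sorted)
  if (nr == 0 || n_miss == 0) return(0)
  inc <- ifelse(in_set_sorted, abs(stat_sorted) / nr, -1 / n_miss)
  run <- cumsum(inc)
  unname(run[which.max(abs(run))])
}

#' GSEA running-sum enrichment score with permutation p-value
#'
#' Classic weighted gene-set enrichment: genes are ordered by the ranking
#' statistic (descending), the running sum increments by
#' `|statistic| / sum(|statistic| in set)` at set members and decrements by
#' `1 / (N - N_set)` elsewhere; the enrichment score (ES) is the running
#' sum's maximal deviation from zero. The normalised score (NES) divides ES
#' by the mean absolute value of same-sign permutation scores; the
#' two-sided p-value is the (add-one) fraction of same-sign permutation
#' scores at least as extreme.
#'
#' @param ranking named numeric vector of ranking statistics (gene
#'   universe).
#' @param gene_set character vector of member genes (must intersect the
#'   universe and not contain it entirely).
#' @param n_perm gene-label permutations.
#' @param seed integer RNG seed.
#' @return a `resampling_test_result` with `es`, `nes` entries.
#' @export
gsea_enrichment <- function(ranking, gene_set, n_perm = 1000L, seed = 1L) {
  stopifnot(!is.null(names(ranking)), all(is.finite(ranking)))
  universe <- names(ranking)
  members <- intersect(gene_set, universe)
  if (!length(members)) stop("gene set does not intersect the universe")
  if (length(members) == length(universe))
    stop("gene set contains the whole universe (empty complement)")
  ord <- order(ranking, decreasing = TRUE)
  stat_sorted <- ranking[ord]
  in_set <- names(stat_sorted) %in% members
  es <- gsea_running_es(stat_sorted, in_set)
  set.seed(seed)
  k <- length(members); n <- length(universe)
  perm_es <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, k)
    gsea_running_es(stat_sorted, seq_len(n) %in% idx)
  }, numeric(1))
  same <- perm_es[sign(perm_es) == sign(es)]
  nes <- if (length(same)) es / mean(abs(same)) else NA_real_
  b <- sum(abs(same) >= abs(es) - 1e-12)
  p <- (b + 1) / (length(same) + 1)
  new_resampling_result("gsea_enrichment", es, p, n_perm, seed,
                        "two_sided", list(es = es, nes = nes,
                                          n_set = k))
}

#' Rank genes by a two-sample t-statistic with a low-count filter
#'
#' Removes genes whose counts-per-million fall below `cpm_cutoff` in more
#' than `max_low_fraction` of the samples, then ranks the remaining genes
#' by the two-sample t-statistic (Welch) of log2(CPM + 0.5) between the
#' high and low groups, descending.
#'
#' @param counts genes x samples matrix of nonnegative counts.
#' @param group_low,group_high column indices or names of the two groups
#'   (>= 2 samples each).
#' @param cpm_cutoff,max_low_fraction the low-count filter (defaults 0.5
#'   and 0.9).
#' @return data.frame with `gene` and `t`, ordered by decreasing `t`.
#' @export
rank_genes_by_group_t <- function(counts, group_low, group_high,
                                  cpm_cutoff = 0.5,
                                  max_low_fraction = 0.9) {
  stopifnot(is.matrix(counts))
  if (length(group_low) < 2L || length(group_high) < 2L)
    stop("both groups need >= 2 samples")
  cpm <- edgeR::cpm(counts)
  keep <- rowMeans(cpm < cpm_cutoff) <= max_low_fraction
  lx <- log2(cpm[keep, group_low, drop = FALSE] + 0.5)
  hx <- log2(cpm[keep, group_high, drop = FALSE] + 0.5)
  m1 <- rowMeans(hx); m2 <- rowMeans(lx)
  v1 <- apply(hx, 1L, stats::var); v2 <- apply(lx, 1L, stats::var)
  n1 <- ncol(hx); n2 <- ncol(lx)
  se <- sqrt(v1 / n1 + v2 / n2)
  t <- (m1 - m2) / se
  bad <- !is.finite(t)
  if (any(bad))
    warning(sum(bad), " gene(s) with zero variance in both groups dropped")
  out <- data.frame(gene = rownames(cpm)[keep][!bad], t = t[!bad],
                    stringsAsFactors = FALSE)
  out[order(out$t, decreasing = TRUE), , drop = FALSE]
}

#' Copy-number / expression correlation with group comparisons
#'
#' Computes the per-gene Spearman correlation between expression and copy
#' number across samples, then compares the correlation distributions of
#' the supplied gene groups by pairwise two-sided Wilcoxon rank-sum tests.
#'
#' @param expr,cn matched genes x samples matrices.
#' @param gene_groups named character vector of group labels per gene.
#' @return list with `rho` (named vector, `NA` where expression or CN is
#'   constant) and `pairwise_p` (matrix of rank-sum p-values).
#' @export
cn_expression_correlation_groups <- function(expr, cn, gene_groups) {
  stopifnot(identical(dim(expr), dim(cn)),
            identical(rownames(expr), rownames(cn)))
  rho <- vapply(seq_len(nrow(expr)), function(i) {
    e <- expr[i, ]; c_ <- cn[i, ]
    if (stats::sd(e) == 0 || stats::sd(c_) == 0) return(NA_real_)
    stats::cor(e, c_, method = "spearman")
  }, numeric(1))
  names(rho) <- rownames(expr)
  groups <- gene_groups[names(rho)]
  lv <- unique(groups)
  pw <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
  for (i in seq_along(lv)) for (j in seq_along(lv)) if (i < j) {
    a <- rho[groups == lv[i]]; b <- rho[groups == lv[j]]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    if (length(a) && length(b))
      pw[i, j] <- pw[j, i] <-
        suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }
  list(rho = rho, pairwise_p = pw)
}

#' Normal-quantile transform
#'
#' Maps values to standard-normal quantiles of their probability points
#' (mid-rank convention), the normalization applied before fitting
#' prediction ellipses.
#'
#' @param x numeric vector.
#' @return transformed vector with the same order as `x`.
#' @export
normal_quantile_transform <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 0.5) / length(x))
}

#' Bivariate normal prediction ellipse
#'
#' The `level` prediction ellipse of a bivariate sample:
#' `{v : (v - mu)' Sigma^{-1} (v - mu) <= q}` with `q` the `level` quantile
#' of chi-square with 2 degrees of freedom and `mu`, `Sigma` the sample
#' mean and covariance.
#'
#' @param x,y paired numeric vectors (>= 3 points).
#' @param level coverage level (default 0.95).
#' @param n_points number of polygon points returned.
#' @return list with `center`, `radii` (semi-axes), `angle` (radians of
#'   the major axis), `cov`, `degenerate` flag and `polygon` (n x 2
#'   matrix).
#' @export
prediction_ellipse <- function(x, y, level = 0.95, n_points = 181L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  mu <- c(mean(x), mean(y))
  S <- stats::cov(cbind(x, y))
  q <- stats::qchisq(level, df = 2)
  ev <- eigen(S, symmetric = TRUE)
  degenerate <- ev$values[2] <= .Machine$double.eps * ev$values[1]
  radii <- sqrt(pmax(ev$values, 0) * q)
  angle <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  th <- seq(0, 2 * pi, length.out = n_points)
  circ <- cbind(radii[1] * cos(th), radii[2] * sin(th))
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  poly <- sweep(circ %*% t(rot), 2L, mu, `+`)
  if (degenerate)
    warning("singular covariance: ellipse degenerates to a segment")
  list(center = mu, radii = radii, angle = angle, cov = S,
       degenerate = degenerate, polygon = poly)
}

#' Association between two ordered copy-number factors
#'
#' For a contingency table of gene ACN level x marker ACN level: the
#' Pearson chi-square p-value treating levels as unordered, and the
#' linear-by-linear ordered association `M^2 = (N - 1) r^2` with equally
#' spaced integer scores on both margins, referred to chi-square with 1
#' degree of freedom.
#'
#' @param table matrix of nonnegative integer counts (>= 2 x 2 after
#'   dropping zero margins, which are removed with a warning).
#' @return list with `chisq_p`, `ordered_statistic`, `ordered_p`.
#' @export
ordered_cn_association <- function(table) {
  stopifnot(is.matrix(table), all(table >= 0))
  zr <- rowSums(table) == 0; zc <- colSums(table) == 0
  if (any(zr) || any(zc)) {
    warning("dropping zero-margin level(s)")
    table <- table[!zr, !zc, drop = FALSE]
  }
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need a >= 2 x 2 table after dropping zero margins")
  chisq_p <- suppressWarnings(stats::chisq.test(table)$p.value)
  ri <- seq_len(nrow(table)); ci <- seq_len(ncol(table))
  N <- sum(table)
  # expand (row score, col score) pairs weighted by cell counts
  cells <- expand.grid(row = ri, col = ci)
  rs <- rep(cells$row, as.vector(table))
  cs <- rep(cells$col, as.vector(table))
  r <- stats::cor(rs, cs)
  stat <- (N - 1) * r^2
  list(chisq_p = chisq_p, ordered_statistic = stat,
       ordered_p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Test pre-specified gene-drug associations
#'
#' For each pre-registered (gene, drug, direction) association: a
#' one-sided Wald t-test of the linear-regression slope of drug AUC on the
#' gene's relative copy number (log2-ratio scale), and a one-sided
#' Jonckheere-Terpstra test of AUC across the 3-level adjusted copy-number
#' factor ("2" < "3" < "4+"). A sensitizing direction expects response
#' (lower AUC) at higher copy number, i.e. a negative slope / decreasing
#' trend; a resistance direction the reverse.
#'
#' @param specs data.frame with `gene`, `drug`, `direction`
#'   (`"sensitizing"` or `"resistant"`).
#' @param rcn genes x samples matrix of relative copy numbers (log scale).
#' @param acn genes x samples matrix of integer adjusted copy numbers.
#' @param auc samples x drugs matrix of AUC values.
#' @param exclude_samples character vector of samples removed before
#'   testing (non-independent repeats, high-variability samples).
#' @param jt_seed seed passed to the JT test when it resamples.
#' @param jt_mode,jt_B mode and resample count forwarded to
#'   [jonckheere_terpstra()].
#' @return data.frame: one row per spec with `trend_p`, `jt_p`, `n`,
#'   `note`.
#' @export
test_prespecified_associations <- function(specs, rcn, acn, auc,
                                           exclude_samples = character(0),
                                           jt_seed = 1L, jt_mode = "auto",
                                           jt_B = 10000L) {
  stopifnot(all(c("gene", "drug", "direction") %in% names(specs)))
  out <- specs
  out$trend_p <- NA_real_; out$jt_p <- NA_real_
  out$n <- NA_integer_; out$note <- ""
  for (i in seq_len(nrow(specs))) {
    g <- specs$gene[i]; d <- specs$drug[i]
    if (!g %in% rownames(rcn) || !d %in% colnames(auc)) {
      out$note[i] <- "gene or drug absent"
      next
    }
    samples <- setdiff(intersect(colnames(rcn), rownames(auc)),
                       exclude_samples)
    x <- rcn[g, samples]; y <- auc[samples, d]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    out$n[i] <- length(x)
    if (length(x) < 4L) {
      out$note[i] <- "untestable: fewer than 4 samples after exclusions"
      next
    }
    fit <- stats::lm(y ~ x)
    tt <- summary(fit)$coefficients
    tval <- tt["x", "t value"]; df <- fit$df.residual
    sens <- specs$direction[i] == "sensitizing"
    out$trend_p[i] <- if (sens) stats::pt(tval, df)
                      else stats::pt(tval, df, lower.tail = FALSE)
    lev <- acn_to_levels(round(acn[g, samples[ok]]))
    gl <- split(y, lev, drop = TRUE)
    if (length(gl) >= 2L) {
      jt <- jonckheere_terpstra(gl,
                                alternative = if (sens) "decreasing"
                                              else "increasing",
                                mode = jt_mode, B = jt_B,
                                seed = jt_seed)
      out$jt_p[i] <- jt$p_value
    } else {
      out$note[i] <- paste0(out$note[i], "single ACN level: JT skipped")
    }
  }
  out
}
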