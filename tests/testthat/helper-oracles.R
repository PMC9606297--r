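# Independent brute-force oracles, deliberately written with different
# algorithms than the package implementations they check.

# GSEA running sum by explicit position-by-position loop
oracle_gsea_es <- function(ranking, gene_set) {
  ord <- order(ranking, decreasing = TRUE)
  s <- ranking[ord]
  hit <- names(s) %in% gene_set
  nr <- sum(abs(s[hit]))
  nm <- sum(!hit)
  run <- 0
  best <- 0
  for (i in seq_along(s)) {
    run <- run + if (hit[i]) abs(s[i]) / nr else -1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Jonckheere-Terpstra statistic via pairwise rank counting (not outer)
oracle_jt_stat <- function(groups) {
  s <- 0
  k <- length(groups)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    for (a in groups[[i]]) {
      s <- s + sum(a < groups[[j]]) + 0.5 * sum(a == groups[[j]])
    }
  }
  s
}

# all permutations of 1..n as a matrix (rows)
oracle_all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- oracle_all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(pos) {
    left <- if (pos > 1) sub[, seq_len(pos - 1), drop = FALSE] else NULL
    right <- if (pos < n) sub[, pos:(n - 1), drop = FALSE] else NULL
    cbind(left, n, right)
  }))
}

# exact one-sided JT p-value by enumerating every ordering of the pooled
# values (each multinomial assignment is counted equally often)
oracle_jt_p <- function(groups) {
  sizes <- lengths(groups)
  pool <- unlist(groups)
  obs <- oracle_jt_stat(groups)
  pm <- oracle_all_perms(length(pool))
  lab <- rep(seq_along(sizes), sizes)
  hits <- 0
  for (r in seq_len(nrow(pm))) {
    g <- split(pool[pm[r, ]], lab)
    if (oracle_jt_stat(g) >= obs - 1e-9) hits <- hits + 1
  }
  hits / nrow(pm)
}

# exact one-sided permutation p for a mean difference by enumerating all
# subsets (independent loop over combn columns with explicit sums)
oracle_perm_mean_p <- function(x_in, x_out) {
  pool <- c(x_in, x_out)
  n1 <- length(x_in)
  obs <- mean(x_in) - mean(x_out)
  cols <- utils::combn(length(pool), n1)
  hits <- 0
  for (j in seq_len(ncol(cols))) {
    sel <- cols[, j]
    d <- sum(pool[sel]) / n1 - sum(pool[-sel]) / (length(pool) - n1)
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  hits / ncol(cols)
}

# naive complete-linkage agglomeration; returns sorted merge heights
oracle_complete_linkage_heights <- function(d) {
  m <- as.matrix(d)
  diag(m) <- Inf
  active <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (i in seq_along(active)) for (j in seq_along(active)) if (i < j) {
      h <- max(m[active[[i]], active[[j]]])
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    heights <- c(heights, bh)
    active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
    active[[best[2]]] <- NULL
  }
  sort(heights)
}

# trapezoid integration of a fitted curve on a fine grid
oracle_trapezoid_auc <- function(fit, n = 20001) {
  a <- fit$boundary[1]; b <- fit$boundary[2]
  x <- seq(a, b, length.out = n)
  y <- predict(fit, x)
  sum((y[-1] + y[-n]) / 2 * diff(x)) / (b - a)
}

# brute-force frequency recount for cohort profiles
oracle_category_fraction <- function(acn_row, lo, hi) {
  v <- acn_row[!is.na(acn_row)]
  100 * sum(v >= lo & v < hi) / length(v)
}
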