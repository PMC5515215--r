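# Independent oracles, deliberately naive, used to validate the fast
# implementations on small instances.

# Degenerate-primer matching by exhaustive expansion: expand every ambiguous
# position into all concrete ACGT strings and run plain fixed substring
# search for each.
oracle_match_expand <- function(sequence, primer) {
  iupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
  options <- lapply(strsplit(primer, "")[[1]], function(ch) iupac[[ch]])
  concrete <- Reduce(function(acc, opts) {
    unlist(lapply(acc, function(prefix) paste0(prefix, opts)))
  }, options, accumulate = FALSE, init = "")
  hits <- integer(0)
  for (pat in concrete) {
    m <- gregexpr(pat, sequence, fixed = TRUE)[[1]]
    if (m[1] != -1) hits <- c(hits, as.integer(m))
  }
  sort(unique(hits))
}

# Two-pass covariance Pearson correlation.
oracle_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# First-order SSE minimisation by coarse grid plus Nelder-Mead polish,
# independent of lm/nls.
oracle_first_order_sse <- function(time_h, conc) {
  sse <- function(par) sum((conc - par[1] * exp(-par[2] * time_h))^2)
  grid <- expand.grid(
    c0 = seq(0.5 * max(conc), 2 * max(conc), length.out = 30),
    k = exp(seq(log(0.01), log(5), length.out = 60))
  )
  vals <- apply(grid, 1, sse)
  start <- as.numeric(grid[which.min(vals), ])
  fit <- optim(start, sse, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  fit <- optim(fit$par, sse, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  list(c0 = fit$par[1], k = fit$par[2])
}

# Brute-force complete-linkage agglomeration: at each step recompute all
# pairwise max-linkage distances between current clusters and merge the
# closest pair. Returns merge heights (sorted) and the flat k-clustering.
oracle_complete_linkage <- function(mat, k) {
  d <- as.matrix(dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  flat <- seq_len(nrow(mat))
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1)) {
        dij <- max(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(j, i) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
    if (length(clusters) == k) {
      flat <- integer(nrow(mat))
      for (ci in seq_along(clusters)) flat[clusters[[ci]]] <- ci
    }
  }
  attr(heights, "flat_k") <- flat
  heights
}

# Partition equality up to label renaming.
same_partition <- function(a, b) {
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

random_tag <- function(n = 33) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
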