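# Independent brute-force oracles used to cross-check the implementation.

# O(n^3) average-linkage agglomeration straight from the definition: cluster
# distance = mean over all cross pairs of the original point distances.
bf_average_linkage_heights <- function(d) {
  D <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(D)))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        h <- mean(D[clusters[[i]], clusters[[j]]])
        if (h < best_h - 1e-12) {
          best_h <- h; best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# Benjamini-Hochberg step-up from the definition: q_(i) = min_{j >= i}
# p_(j) * m / j on the ascending order statistics, capped at 1.
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(p[ord][i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# Two-sided Fisher exact p by exhaustive enumeration of all 2x2 tables with
# the observed margins, hypergeometric probabilities from choose().
bf_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- choose(m, support) * choose(n, k - support) / choose(m + n, k)
  p_obs <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# A small NB count matrix with two groups and planted fold changes.
make_test_counts <- function(n_genes = 50, n_a = 6, n_b = 6, lfc = NULL,
                             mu = NULL, alpha = 0.1, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(mu)) mu <- rlnorm(n_genes, log(200), 0.8)
    if (is.null(lfc)) lfc <- rep(0, n_genes)
    gene_ids <- sprintf("g%03d", seq_len(n_genes))
    sample_ids <- sprintf("s%02d", seq_len(n_a + n_b))
    mean_mat <- cbind(
      matrix(rep(mu * 2^lfc, n_a), ncol = n_a),
      matrix(rep(mu, n_b), ncol = n_b)
    )
    cnt <- matrix(rnbinom(length(mean_mat), mu = mean_mat, size = 1 / alpha),
                  nrow = n_genes, dimnames = list(gene_ids, sample_ids))
    count_matrix(cnt)
  })
}

two_group_assignment <- function(sample_ids, n_a) {
  tibble::tibble(sample_id = sample_ids,
                 label = rep(c("A", "B"), c(n_a, length(sample_ids) - n_a)))
}

as_vst <- function(m) structure(m, class = c("endo_vst", "matrix", "array"))
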