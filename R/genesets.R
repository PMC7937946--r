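# Gene-set statistics: hypergeometric over-representation, Fisher's exact
# overlap of two gene lists, a self-contained rotation test of a set-level
# contrast statistic, and a competitive test with an inter-gene-correlation
# variance-inflation adjustment.

#' Hypergeometric over-representation analysis
#'
#' For each set of a collection (intersected with the universe), tests whether
#' the query list overlaps the set more than expected when drawing
#' `|query|` genes from the universe without replacement: the upper-tail
#' hypergeometric p-value of the observed overlap, adjusted across sets by
#' Benjamini-Hochberg; significance is flagged at FDR <= 0.05.
#'
#' @param query Character vector of gene ids (must lie within `universe`).
#' @param universe Character vector: the background gene ids.
#' @param collection An `endo_gsc` gene-set collection.
#' @return A tibble with one row per set: `name`, `overlap`, `set_size`
#'   (within the universe), `query_size`, `universe_size`, `p_value`,
#'   `q_value`, `significant`.
#' @export
ora <- function(query, universe, collection) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("Empty universe.", class = "endoseq_contract_error")
  query <- unique(query)
  if (!all(query %in% universe)) {
    abort("`query` must be a subset of `universe`.", class = "endoseq_contract_error")
  }
  n_u <- length(universe); n_q <- length(query)
  res <- purrr::map2_dfr(collection$name, collection$genes, function(nm, g) {
    set_u <- intersect(g, universe)
    k <- length(intersect(query, set_u))
    m <- length(set_u)
    p <- phyper(k - 1, m, n_u - m, n_q, lower.tail = FALSE)
    tibble(name = nm, overlap = k, set_size = m,
           query_size = n_q, universe_size = n_u, p_value = p)
  })
  res$q_value <- bh_fdr(res$p_value)
  res$significant <- res$q_value <= 0.05
  res
}

#' Fisher's exact overlap of two gene lists
#'
#' Cross-tabulates membership of `list_a` and `list_b` over the universe and
#' reports the sample odds ratio `ad/bc` (with a Haldane 0.5 correction to
#' every cell when any cell is zero) and the two-sided Fisher exact p-value
#' (probability-mass rule: the sum over tables with the same margins whose
#' hypergeometric probability does not exceed the observed table's).
#'
#' @param list_a,list_b Character vectors of gene ids, subsets of `universe`.
#' @param universe Character vector: the background gene ids.
#' @return A list classed `endo_overlap`: `table` (2x2 matrix), `odds_ratio`,
#'   `p_value`.
#' @export
fisher_overlap <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  list_a <- unique(list_a); list_b <- unique(list_b)
  if (!all(c(list_a, list_b) %in% universe)) {
    abort("Both lists must be subsets of the universe.",
          class = "endoseq_contract_error")
  }
  in_a <- universe %in% list_a
  in_b <- universe %in% list_b
  a <- sum(in_a & in_b); b <- sum(in_a & !in_b)
  c_ <- sum(!in_a & in_b); d <- sum(!in_a & !in_b)
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  or <- if (any(c(a, b, c_, d) == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    (a * d) / (b * c_)
  }
  structure(list(table = tab, odds_ratio = or,
                 p_value = fisher_two_sided_p(a, b, c_, d)),
            class = "endo_overlap")
}

# Two-sided Fisher p for a 2x2 table with fixed margins, probability-mass rule.
fisher_two_sided_p <- function(a, b, c_, d) {
  m <- a + b          # size of list_a
  n <- c_ + d         # complement
  k <- a + c_         # size of list_b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Orthonormal basis of the two-group design: q1 = intercept direction,
# q2 = contrast direction (A minus B). Used by roast and camera.
.contrast_basis <- function(n, is_a) {
  q1 <- rep(1 / sqrt(n), n)
  cvec <- ifelse(is_a, 1 / sum(is_a), -1 / sum(!is_a))
  cvec <- cvec - mean(cvec)
  q2 <- cvec / sqrt(sum(cvec^2))
  list(q1 = q1, q2 = q2)
}

# Per-gene moderated z statistics for an arbitrary unit direction r in the
# residual space (orthogonal to the intercept): coefficient b = Y_c r, residual
# variance from what is left, shrunk toward the across-gene mean with a prior
# weight of d0 pseudo-genes.
.moderated_z <- function(yc, r, df, d0 = 4) {
  b <- drop(yc %*% r)
  rss <- pmax(rowSums(yc^2) - b^2, 0)
  s2 <- rss / df
  s0 <- mean(s2)
  s2_mod <- (d0 * s0 + df * s2) / (d0 + df)
  b / sqrt(pmax(s2_mod, .Machine$double.eps))
}

#' Rotation (self-contained) gene-set test
#'
#' Tests whether a gene set shows a coordinated expression difference between
#' endotypes A and B. The observed statistic is the mean moderated z (per-gene
#' contrast coefficient over a variance shrunk toward the across-gene mean
#' with prior weight 4 pseudo-genes) over the set genes. The null is built by
#' replacing the contrast direction with random unit vectors in the residual
#' space orthogonal to the intercept — under the null of no group effect the
#' observed direction is exchangeable with the rotated ones — and
#' `p = (#{|rotated| >= |observed|} + 1) / (B + 1)`.
#'
#' @param vst An `endo_vst` (or numeric) genes-by-samples matrix.
#' @param assignment An `endo_assignment`; only A/B samples are used.
#' @param gene_set Character vector of gene ids (>= 2 present in `vst`).
#' @param B Number of rotations (default 9999).
#' @param seed Integer seed making the rotations reproducible.
#' @return A list classed `endo_roast`: `set_size`, `observed`, `B`,
#'   `p_value`, `seed`.
#' @export
roast_test <- function(vst, assignment, gene_set, B = 9999, seed = 1) {
  ab <- assignment[assignment$label %in% c("A", "B"), , drop = FALSE]
  if (sum(ab$label == "A") < 2 || sum(ab$label == "B") < 2) {
    abort("Both endotypes need >= 2 samples.", class = "endoseq_contract_error")
  }
  y <- unclass(vst)[, ab$sample_id, drop = FALSE]
  set_idx <- which(rownames(y) %in% gene_set)
  if (length(set_idx) < 2) {
    abort("Fewer than 2 set genes present in the matrix.",
          class = "endoseq_contract_error")
  }
  n <- ncol(y)
  basis <- .contrast_basis(n, ab$label == "A")
  yc <- y - tcrossprod(rowSums(y) / n, rep(1, n))  # remove intercept projection
  df <- n - 2
  obs <- mean(.moderated_z(yc, basis$q2, df)[set_idx])
  rot <- withr::with_seed(seed, {
    vapply(seq_len(B), function(i) {
      r <- rnorm(n)
      r <- r - mean(r)                 # into the residual space
      r <- r / sqrt(sum(r^2))
      mean(.moderated_z(yc, r, df)[set_idx])
    }, numeric(1))
  })
  p <- (sum(abs(rot) >= abs(obs)) + 1) / (B + 1)
  structure(list(set_size = length(set_idx), observed = obs, B = B,
                 p_value = p, seed = seed),
            class = "endo_roast")
}

#' Competitive gene-set test with correlation adjustment
#'
#' Compares the mean moderated z of the set genes against the mean over the
#' remaining genes. Because co-expressed set genes carry correlated
#' statistics, the variance of the set mean is inflated by
#' `VIF = 1 + (m - 1) * rho_bar` (floored at 1), where `rho_bar` is the mean
#' pairwise correlation of the set genes' residuals after removing the group
#' effect. The two-sided p-value comes from the VIF-adjusted two-sample z
#' comparison of set vs non-set gene statistics.
#'
#' @inheritParams roast_test
#' @return A list classed `endo_camera`: `set_size`, `rho_bar`, `vif`,
#'   `z`, `p_value`.
#' @export
camera_test <- function(vst, assignment, gene_set) {
  ab <- assignment[assignment$label %in% c("A", "B"), , drop = FALSE]
  if (sum(ab$label == "A") < 2 || sum(ab$label == "B") < 2) {
    abort("Both endotypes need >= 2 samples.", class = "endoseq_contract_error")
  }
  y <- unclass(vst)[, ab$sample_id, drop = FALSE]
  in_set <- rownames(y) %in% gene_set
  m <- sum(in_set)
  if (m < 2) abort("Fewer than 2 set genes present.", class = "endoseq_contract_error")
  if (sum(!in_set) < 2) {
    abort("Competitive test needs >= 2 genes outside the set.",
          class = "endoseq_contract_error")
  }
  n <- ncol(y)
  basis <- .contrast_basis(n, ab$label == "A")
  yc <- y - tcrossprod(rowSums(y) / n, rep(1, n))
  z <- .moderated_z(yc, basis$q2, n - 2)
  # residuals after removing both intercept and group effect
  res <- yc - tcrossprod(drop(yc %*% basis$q2), basis$q2)
  cors <- suppressWarnings(cor(t(res[in_set, , drop = FALSE])))
  rho_bar <- mean(cors[upper.tri(cors)], na.rm = TRUE)
  if (!is.finite(rho_bar)) rho_bar <- 0
  vif <- max(1, 1 + (m - 1) * rho_bar)
  m2 <- sum(!in_set)
  delta <- mean(z[in_set]) - mean(z[!in_set])
  sigma <- sd(z)
  stat <- delta / (sigma * sqrt(vif / m + 1 / m2))
  structure(list(set_size = m, rho_bar = rho_bar, vif = vif, z = stat,
                 p_value = 2 * pnorm(-abs(stat))),
            class = "endo_camera")
}

#' @export
print.endo_roast <- function(x, ...) {
  cat(sprintf("Rotation gene-set test: %d genes, observed mean z = %.3f, p = %.4g (B = %d)\n",
              x$set_size, x$observed, x$p_value, x$B))
  invisible(x)
}

#' @export
print.endo_camera <- function(x, ...) {
  cat(sprintf("Competitive gene-set test: %d genes, rho_bar = %.3f, VIF = %.2f, z = %.3f, p = %.4g\n",
              x$set_size, x$rho_bar, x$vif, x$z, x$p_value))
  invisible(x)
}

#' @export
print.endo_overlap <- function(x, ...) {
  cat("Gene-list overlap (Fisher's exact test)\n")
  print(x$table)
  cat(sprintf("  odds ratio = %.3g, two-sided p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}
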