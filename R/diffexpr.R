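# Differential expression between the two major endotypes: per-gene
# negative-binomial Wald statistics on normalized counts with Benjamini-
# Hochberg FDR control, and threshold extraction of up-in-A / up-in-B lists.

#' Negative-binomial Wald differential expression
#'
#' Contrasts endotypes A and B per gene on size-factor-normalized counts
#' (samples labeled `"other"` are excluded). With group means `mu_A`, `mu_B`
#' (each with pseudocount 0.5), the effect is `log2FC = log2(mu_A / mu_B)`
#' (positive = higher in A). Its standard error comes from the NB delta
#' method with per-gene dispersion `alpha_g`
#' (`Var(mean) = (mu + alpha * mu^2) / n` per group), giving a Wald z and a
#' two-sided normal p-value, adjusted across genes by Benjamini-Hochberg.
#'
#' @param counts A count matrix.
#' @param sf Size factors from [size_factors()].
#' @param assignment An `endo_assignment` with labels A/B (and possibly other).
#' @param dispersion An `endo_dispersion` model for the same genes.
#' @return A tibble (classed `endo_de`) with columns `gene`, `base_mean`,
#'   `log2fc`, `se`, `wald_z`, `p_value`, `q_value`.
#' @export
nb_wald_de <- function(counts, sf, assignment,
                       dispersion = estimate_dispersion(counts, sf)) {
  ids_a <- assignment$sample_id[assignment$label == "A"]
  ids_b <- assignment$sample_id[assignment$label == "B"]
  if (length(ids_a) < 2 || length(ids_b) < 2) {
    abort("Both endotypes need >= 2 samples for differential expression.",
          class = "endoseq_contract_error")
  }
  norm <- sweep(unclass(counts), 2, sf, "/")
  na <- length(ids_a); nb <- length(ids_b)
  ya <- norm[, ids_a, drop = FALSE]
  yb <- norm[, ids_b, drop = FALSE]
  mu_a_raw <- rowMeans(ya); mu_b_raw <- rowMeans(yb)
  mu_a <- mu_a_raw + 0.5; mu_b <- mu_b_raw + 0.5
  alpha <- dispersion$alpha[rownames(counts)]
  log2fc <- log2(mu_a / mu_b)
  var_log2 <- ((mu_a + alpha * mu_a^2) / (na * mu_a^2) +
               (mu_b + alpha * mu_b^2) / (nb * mu_b^2)) / log(2)^2
  se <- sqrt(var_log2)
  z <- log2fc / se
  p <- 2 * pnorm(-abs(z))
  # degenerate contract: a gene observed in neither group carries no evidence
  zero <- mu_a_raw == 0 & mu_b_raw == 0
  log2fc[zero] <- 0; z[zero] <- 0; p[zero] <- 1
  out <- tibble(
    gene = rownames(counts),
    base_mean = rowMeans(norm[, c(ids_a, ids_b), drop = FALSE]),
    log2fc = unname(log2fc),
    se = unname(se),
    wald_z = unname(z),
    p_value = unname(p),
    q_value = bh_fdr(unname(p))
  )
  class(out) <- c("endo_de", class(out))
  attr(out, "n_a") <- na
  attr(out, "n_b") <- nb
  out
}

#' Benjamini-Hochberg step-up q-values
#'
#' `q_(i) = min_{j >= i} p_(j) * m / j` over the ascending order statistics,
#' capped at 1 — the step-up adjusted p-values controlling the false
#' discovery rate under independence.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1].", class = "endoseq_contract_error")
  }
  m <- length(p_values)
  ord <- order(p_values)
  q_sorted <- rev(cummin(rev(p_values[ord] * m / seq_len(m))))
  q <- numeric(m)
  q[ord] <- pmin(q_sorted, 1)
  q
}

#' Extract differentially expressed gene lists
#'
#' Splits significant genes into up-in-A (fold change at least `fc_min`) and
#' up-in-B (fold change at most `1/fc_min`) at `q <= fdr_max`.
#'
#' @param de An `endo_de` tibble from [nb_wald_de()].
#' @param fc_min Fold-change threshold (default 1.5).
#' @param fdr_max FDR threshold (default 0.05).
#' @return A list with character vectors `up_in_a` and `up_in_b` (disjoint).
#' @export
de_genes <- function(de, fc_min = 1.5, fdr_max = 0.05) {
  if (fc_min <= 0 || fdr_max <= 0) abort("Thresholds must be > 0.")
  sig <- de$q_value <= fdr_max
  up_a <- sig & 2^de$log2fc >= fc_min
  up_b <- sig & 2^de$log2fc <= 1 / fc_min & !up_a  # boundary gene (fc_min = 1) goes to A
  list(up_in_a = de$gene[up_a], up_in_b = de$gene[up_b])
}
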