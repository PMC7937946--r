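# Count preprocessing: globin removal, median-of-ratios size factors,
# method-of-moments NB dispersion, closed-form variance-stabilizing
# transformation, and parametric empirical-Bayes batch adjustment.

#' Remove globin genes from a count matrix
#'
#' Whole-blood RNA-seq libraries are dominated by hemoglobin transcripts;
#' these are removed bioinformatically before normalization.
#'
#' @param counts A count matrix.
#' @param globin_ids Character vector of globin gene ids
#'   (default [default_globin_genes()]).
#' @return The count matrix without rows whose gene id is in `globin_ids`.
#' @export
remove_globin <- function(counts, globin_ids = default_globin_genes()) {
  if (length(globin_ids) == 0) abort("`globin_ids` must be non-empty.")
  keep <- !(rownames(counts) %in% globin_ids)
  if (!any(keep)) {
    abort("Globin removal would leave 0 genes.", class = "endoseq_degenerate_error")
  }
  out <- counts[keep, , drop = FALSE]
  class(out) <- class(counts)
  out
}

#' Median-of-ratios size factors
#'
#' Per-sample library-size factors: for each sample, the median over reference
#' genes (genes with nonzero counts in every sample) of the ratio of the
#' sample's count to the gene's geometric mean across samples. Factors are
#' re-anchored to geometric mean 1.
#'
#' @param counts A count matrix.
#' @return A named numeric vector of positive size factors, geometric mean 1.
#' @export
size_factors <- function(counts) {
  ref <- rowSums(counts > 0) == ncol(counts)
  if (!any(ref)) {
    abort(paste0("No gene has nonzero counts in every sample; ",
                 "size factors cannot be estimated from reference genes."),
          class = "endoseq_estimation_error")
  }
  logc <- log(counts[ref, , drop = FALSE])
  loggeo <- rowMeans(logc)
  sf <- apply(logc, 2, function(lc) exp(median(lc - loggeo)))
  sf <- sf / exp(mean(log(sf)))  # anchor: geometric mean 1
  sf
}

#' Method-of-moments negative-binomial dispersion
#'
#' For normalized counts with NB variance `mu + alpha * mu^2`, the per-gene
#' moments estimator is `alpha_g = max(0, (var - mean) / mean^2)`. The pooled
#' dispersion, used by the variance-stabilizing transformation, is the median
#' of the positive per-gene estimates, floored at `1e-4`.
#'
#' @param counts A count matrix.
#' @param sf Size factors from [size_factors()].
#' @return A list with `alpha` (named per-gene vector) and `pooled` (scalar),
#'   classed `endo_dispersion`.
#' @export
estimate_dispersion <- function(counts, sf = size_factors(counts)) {
  if (ncol(counts) < 2) abort("Dispersion estimation needs >= 2 samples.")
  norm <- sweep(unclass(counts), 2, sf, "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, var)
  alpha <- ifelse(m > 0, pmax(0, (v - m) / m^2), 0)
  names(alpha) <- rownames(counts)
  pos <- alpha[alpha > 0]
  pooled <- if (length(pos) > 0) max(median(pos), 1e-4) else 1e-4
  structure(list(alpha = alpha, pooled = pooled), class = "endo_dispersion")
}

#' Closed-form NB variance-stabilizing transformation
#'
#' Applies `g(x) = (2 / sqrt(alpha)) * asinh(sqrt(alpha * x))` to size-factor
#' normalized counts, with the pooled dispersion `alpha`. For NB counts with
#' common dispersion this makes the variance approximately independent of the
#' mean; it is monotone, `g(0) = 0`, and tends to `2 * sqrt(x)` as
#' `alpha -> 0` (the Poisson/Anscombe limit) and to a shifted `log` for large
#' `alpha * x`.
#'
#' @param counts A count matrix.
#' @param sf Size factors; default estimated from `counts`.
#' @param dispersion An `endo_dispersion` model; default estimated.
#' @return A genes-by-samples matrix of variance-stabilized values, classed
#'   `endo_vst`, with attributes `pooled_alpha`, `globin_removed`,
#'   `batch_adjusted`.
#' @export
vst_transform <- function(counts, sf = size_factors(counts),
                          dispersion = estimate_dispersion(counts, sf)) {
  alpha <- dispersion$pooled
  if (!is.finite(alpha) || alpha <= 0) abort("Pooled dispersion must be > 0.")
  norm <- sweep(unclass(counts), 2, sf, "/")
  out <- vst_value(norm, alpha)
  dimnames(out) <- dimnames(counts)
  structure(out,
            class = c("endo_vst", "matrix", "array"),
            pooled_alpha = alpha,
            globin_removed = isTRUE(attr(counts, "globin_removed")),
            batch_adjusted = FALSE)
}

#' Variance-stabilizing transform of a normalized count value
#'
#' The scalar transform used by [vst_transform()]; exposed for closed-form
#' checks: `vst_value(0, a) == 0`, `vst_value(1, 1) == 2 * asinh(1)`.
#'
#' @param x Normalized count value(s), `>= 0`.
#' @param alpha Pooled NB dispersion, `> 0`.
#' @return Transformed value(s), same shape as `x`.
#' @export
vst_value <- function(x, alpha) {
  (2 / sqrt(alpha)) * asinh(sqrt(alpha * x))
}

#' Parametric empirical-Bayes batch adjustment
#'
#' Location/scale batch correction of a variance-stabilized matrix: each gene
#' is standardized, per-batch means and variances are estimated and shrunk
#' toward across-gene priors (normal prior on locations, inverse-gamma on
#' scales, hyperparameters by method of moments, joint estimates by the usual
#' iterative conditional scheme), the shrunken batch effects are subtracted
#' and rescaled out, and the gene-level scale restored. With a single batch
#' the input is returned unchanged.
#'
#' @param vst An `endo_vst` matrix.
#' @param samples A data frame with columns `sample_id` and `batch` covering
#'   every column of `vst`.
#' @return The adjusted `endo_vst` matrix with `batch_adjusted = TRUE`.
#' @export
batch_adjust <- function(vst, samples) {
  if (!all(colnames(vst) %in% samples$sample_id)) {
    abort("Every sample in `vst` must appear in `samples`.",
          class = "endoseq_contract_error")
  }
  batch <- samples$batch[match(colnames(vst), samples$sample_id)]
  batch <- as.factor(as.character(batch))
  if (nlevels(batch) < 2) {
    attr(vst, "batch_adjusted") <- TRUE
    return(vst)
  }
  nb <- table(batch)
  if (any(nb < 2)) {
    abort(sprintf("Batch '%s' has a single sample; its scale cannot be estimated.",
                  names(nb)[which(nb < 2)[1]]),
          class = "endoseq_contract_error")
  }
  x <- unclass(vst)
  n <- ncol(x)
  levs <- levels(batch)
  idx <- lapply(levs, function(b) which(batch == b))

  # gene-wise grand mean (batch-size weighted) and pooled within-gene variance
  batch_means <- vapply(idx, function(j) rowMeans(x[, j, drop = FALSE]),
                        numeric(nrow(x)))
  w <- as.numeric(nb[levs]) / n
  grand <- drop(batch_means %*% w)
  resid <- x - batch_means[, as.integer(batch)]
  pooled_var <- rowSums(resid^2) / n
  pooled_var[pooled_var <= 0] <- min(pooled_var[pooled_var > 0], 1e-8)
  z <- (x - grand) / sqrt(pooled_var)

  out <- matrix(0, nrow(x), n, dimnames = dimnames(x))
  for (k in seq_along(levs)) {
    j <- idx[[k]]
    zb <- z[, j, drop = FALSE]
    g_hat <- rowMeans(zb)                              # batch location per gene
    d_hat <- apply(zb, 1, var)                         # batch scale per gene
    d_hat[!is.finite(d_hat) | d_hat <= 0] <- 1e-8
    g_bar <- mean(g_hat); t2 <- var(g_hat)
    m <- mean(d_hat); s2 <- var(d_hat)
    a_pr <- (2 * s2 + m^2) / s2                        # inverse-gamma moments
    b_pr <- (m * s2 + m^3) / s2
    nk <- length(j)
    g_star <- g_hat; d_star <- d_hat
    for (it in 1:100) {
      g_new <- (nk * t2 * g_hat + d_star * g_bar) / (nk * t2 + d_star)
      ss <- rowSums((zb - g_new)^2)
      d_new <- (0.5 * ss + b_pr) / (nk / 2 + a_pr - 1)
      if (max(abs(g_new - g_star), abs(d_new - d_star)) < 1e-8) {
        g_star <- g_new; d_star <- d_new; break
      }
      g_star <- g_new; d_star <- d_new
    }
    out[, j] <- (zb - g_star) / sqrt(d_star)
  }
  out <- out * sqrt(pooled_var) + grand
  structure(out,
            class = class(vst),
            pooled_alpha = attr(vst, "pooled_alpha"),
            globin_removed = attr(vst, "globin_removed"),
            batch_adjusted = TRUE)
}

#' Full preprocessing chain
#'
#' Convenience wrapper: globin removal, size factors, dispersion, VST, then
#' batch adjustment if `samples` carries more than one batch.
#'
#' @param counts A count matrix.
#' @param samples Optional sample table with `sample_id` and `batch`.
#' @param globin_ids Globin gene ids to drop; `NULL` to skip removal.
#' @return A list with `vst`, `counts` (post-globin), `sf`, `dispersion`.
#' @export
preprocess_counts <- function(counts, samples = NULL,
                              globin_ids = default_globin_genes()) {
  if (!is.null(globin_ids)) {
    counts <- remove_globin(counts, globin_ids)
    attr(counts, "globin_removed") <- TRUE
  }
  sf <- size_factors(counts)
  disp <- estimate_dispersion(counts, sf)
  v <- vst_transform(counts, sf, disp)
  if (!is.null(samples) && "batch" %in% names(samples) &&
      length(unique(samples$batch[match(colnames(v), samples$sample_id)])) > 1) {
    v <- batch_adjust(v, samples)
  }
  list(vst = v, counts = counts, sf = sf, dispersion = disp)
}
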