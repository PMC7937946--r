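# Minimal-signature selection: a conjunctive filter chain over significance,
# fold change, within-cluster variance and abundance, ranked by a
# signal-to-noise divergence score, plus re-clustering validation of the
# selected genes on an independent cohort.

#' Select a minimal endotype signature
#'
#' Builds the candidate set of genes that pass four conjunctive filters and
#' returns the `k` most divergent:
#' \describe{
#'   \item{passed_de}{significantly differential: `q <= 0.05` and fold change
#'     `> 1.5` between endotypes;}
#'   \item{passed_fc2}{absolute fold change of at least `fc_min` (default 2)
#'     between the normalized-count cluster means;}
#'   \item{passed_var50}{within-cluster variance of variance-stabilized values
#'     in the lowest `var_quantile` (default 50\%) of genes, in both clusters
#'     separately;}
#'   \item{passed_count100}{overall mean size-factor-normalized count of at
#'     least `min_mean_count` (default 100) across the A/B samples.}
#' }
#' Candidates are ranked by the divergence score
#' `|mean_A - mean_B| / pooled within-cluster SD` of vst values (large
#' between-cluster separation, small within-cluster spread); ties break
#' lexicographically by gene id.
#'
#' @param vst An `endo_vst` matrix.
#' @param counts The count matrix the vst was derived from (same genes).
#' @param assignment An `endo_assignment` with non-empty A and B.
#' @param de An `endo_de` result on the same genes.
#' @param k Maximum signature size (default 20).
#' @param fc_min Fold-change filter threshold (default 2).
#' @param var_quantile Within-cluster variance quantile (default 0.5).
#' @param min_mean_count Abundance filter threshold (default 100).
#' @param sf Size factors for `counts`; default re-estimated.
#' @return A tibble (classed `endo_signature`) of at most `k` rows with
#'   columns `gene`, `direction` (+1 up-in-A, -1 up-in-B), `score`, and the
#'   four `passed_*` provenance flags; the full per-gene filter table is
#'   attached as attribute `filter_table`.
#' @export
select_signature <- function(vst, counts, assignment, de, k = 20,
                             fc_min = 2, var_quantile = 0.5,
                             min_mean_count = 100, sf = size_factors(counts)) {
  ids_a <- assignment$sample_id[assignment$label == "A"]
  ids_b <- assignment$sample_id[assignment$label == "B"]
  if (length(ids_a) == 0 || length(ids_b) == 0) {
    abort("Both endotypes must be non-empty.", class = "endoseq_contract_error")
  }
  genes <- rownames(vst)
  de_row <- match(genes, de$gene)
  if (anyNA(de_row)) {
    abort("`de` must cover every gene of `vst`.", class = "endoseq_contract_error")
  }
  v <- unclass(vst)
  va <- v[, ids_a, drop = FALSE]; vb <- v[, ids_b, drop = FALSE]
  norm <- sweep(unclass(counts)[genes, , drop = FALSE], 2, sf, "/")
  mu_a <- rowMeans(norm[, ids_a, drop = FALSE]) + 0.5
  mu_b <- rowMeans(norm[, ids_b, drop = FALSE]) + 0.5
  fc <- mu_a / mu_b

  var_a <- apply(va, 1, var)
  var_b <- apply(vb, 1, var)
  na <- length(ids_a); nb <- length(ids_b)
  pooled_sd <- sqrt(((na - 1) * var_a + (nb - 1) * var_b) / (na + nb - 2))
  score <- abs(rowMeans(va) - rowMeans(vb)) / pmax(pooled_sd, .Machine$double.eps)

  ft <- tibble(
    gene = genes,
    direction = ifelse(de$log2fc[de_row] >= 0, 1L, -1L),
    score = unname(score),
    passed_de = de$q_value[de_row] <= 0.05 & pmax(fc, 1 / fc) > 1.5,
    passed_fc2 = pmax(fc, 1 / fc) >= fc_min,
    passed_var50 = var_a <= quantile(var_a, var_quantile) &
                   var_b <= quantile(var_b, var_quantile),
    passed_count100 = rowMeans(norm[, c(ids_a, ids_b), drop = FALSE]) >= min_mean_count
  )
  candidates <- ft |>
    filter(.data$passed_de, .data$passed_fc2, .data$passed_var50,
           .data$passed_count100)
  if (nrow(candidates) == 0) {
    kills <- vapply(c("passed_de", "passed_fc2", "passed_var50", "passed_count100"),
                    function(f) sum(!ft[[f]]), numeric(1))
    abort(sprintf("No gene passes all signature filters; most exclusions from '%s' (%d genes).",
                  names(which.max(kills)), max(kills)),
          class = "endoseq_selection_error")
  }
  out <- candidates |> arrange(desc(.data$score), .data$gene) |> head(k)
  if (nrow(out) < k) {
    warn(sprintf("Only %d genes pass all filters; signature smaller than k = %d.",
                 nrow(out), k))
  }
  class(out) <- c("endo_signature", class(out))
  attr(out, "filter_table") <- ft
  attr(out, "params") <- list(k = k, fc_min = fc_min, var_quantile = var_quantile,
                              min_mean_count = min_mean_count)
  out
}

#' Validate a signature on a new cohort
#'
#' Re-clusters the new cohort on the signature genes alone (average linkage,
#' Euclidean distance, two flat clusters, anchor orientation from the
#' signature's up-in-A genes) and reports concordance against a reference
#' assignment restricted to its A/B samples.
#'
#' @param sig An `endo_signature` from [select_signature()].
#' @param vst_new A variance-stabilized matrix for the validation cohort.
#' @param reference An `endo_assignment` for (a superset of) the same samples.
#' @return An `endo_concordance` (see [concordance()]); the induced
#'   assignment is attached as attribute `assignment`.
#' @export
validate_signature <- function(sig, vst_new, reference) {
  present <- intersect(sig$gene, rownames(vst_new))
  if (length(present) < 2) {
    abort("Fewer than 2 signature genes are present in the new matrix.",
          class = "endoseq_contract_error")
  }
  if (length(present) < nrow(sig)) {
    inform(sprintf("%d of %d signature genes present in the validation matrix.",
                   length(present), nrow(sig)))
  }
  sub <- unclass(vst_new)[present, , drop = FALSE]
  dend <- cluster_samples(sub)
  assign_new <- assign_endotypes(dend, n_clusters = 2, vst = sub)
  up_a <- sig$gene[sig$direction > 0]
  anchors <- intersect(up_a, present)
  if (length(anchors) > 0) {
    assign_new <- label_endotypes(assign_new, sub, anchor_genes = anchors)
  }
  ref_ab <- reference[reference$label %in% c("A", "B"), , drop = FALSE]
  rep <- concordance(assign_new, ref_ab)
  attr(rep, "assignment") <- assign_new
  rep
}
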