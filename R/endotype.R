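# Endotype discovery: average-linkage hierarchical clustering of samples on
# Euclidean distances of variance-stabilized expression, flat-cut assignment
# into two major endotypes plus "other", anchor-gene labeling, partition
# concordance, and per-endotype clinical summaries.

#' Cluster samples by average-linkage on Euclidean distances
#'
#' Agglomerative average-linkage (UPGMA) clustering of the samples of a
#' variance-stabilized matrix, using Euclidean distances between sample
#' columns. Columns are ordered lexicographically by sample id first, so the
#' result is invariant to input column order and merge ties resolve
#' deterministically.
#'
#' @param vst A genes-by-samples numeric matrix (typically `endo_vst`).
#' @return An `hclust` object (classed `c("endo_dendro", "hclust")`).
#' @export
cluster_samples <- function(vst) {
  if (ncol(vst) < 3) abort("Clustering needs >= 3 samples.",
                           class = "endoseq_contract_error")
  if (anyNA(vst) || any(!is.finite(vst))) {
    abort("Expression matrix contains NA/non-finite values.",
          class = "endoseq_contract_error")
  }
  m <- unclass(vst)[, order(colnames(vst)), drop = FALSE]
  hc <- hclust(dist(t(m), method = "euclidean"), method = "average")
  heights <- hc$height
  if (any(diff(heights) < -1e-8)) {
    abort("Average-linkage dendrogram has a height inversion (internal error).")
  }
  class(hc) <- c("endo_dendro", "hclust")
  hc
}

#' Cut the dendrogram into endotype clusters
#'
#' Cuts into `n_clusters` flat clusters; the two largest become the major
#' endotypes (provisionally labeled A and B in dendrogram order — use
#' [label_endotypes()] to orient them biologically), all remaining samples are
#' labeled `"other"`. Size ties are broken by lower mean within-cluster
#' distance, then by dendrogram order.
#'
#' @param dend An `endo_dendro`/`hclust` object from [cluster_samples()].
#' @param n_clusters Number of flat clusters to cut (default 3: two major plus
#'   one minor).
#' @param vst Optional matrix used only to break size ties by within-cluster
#'   distance.
#' @return A tibble `sample_id`, `cluster` (integer), `label` in
#'   `{"A","B","other"}`, classed `endo_assignment`.
#' @export
assign_endotypes <- function(dend, n_clusters = 3, vst = NULL) {
  if (n_clusters < 2) abort("`n_clusters` must be >= 2.",
                            class = "endoseq_contract_error")
  n <- length(dend$labels)
  if (n_clusters > n) abort("`n_clusters` exceeds the number of samples.",
                            class = "endoseq_contract_error")
  cl <- cutree(dend, k = n_clusters)
  sizes <- table(cl)
  ord <- order(-as.vector(sizes), seq_along(sizes))
  top2 <- as.integer(names(sizes)[ord[1:2]])
  # break an exact size tie by mean within-cluster distance, if resolvable
  if (!is.null(vst) && sizes[as.character(top2[1])] == sizes[as.character(top2[2])]) {
    tied <- as.integer(names(sizes)[sizes == sizes[as.character(top2[1])]])
    if (length(tied) >= 2) {
      mwd <- vapply(tied, function(k) {
        ids <- names(cl)[cl == k]
        if (length(ids) < 2) return(Inf)
        mean(dist(t(unclass(vst)[, ids, drop = FALSE])))
      }, numeric(1))
      top2 <- tied[order(mwd, tied)][1:2]
    }
  }
  label <- rep("other", n)
  label[cl == top2[1]] <- "A"
  label[cl == top2[2]] <- "B"
  out <- tibble(sample_id = names(cl), cluster = unname(cl), label = label)
  class(out) <- c("endo_assignment", class(out))
  out
}

#' Orient endotype labels with anchor genes
#'
#' Relabels the two major clusters so that the one with the higher mean
#' variance-stabilized expression of the anchor genes (by default neutrophil
#' degranulation markers such as S100A8/S100A9) is endotype A; the other
#' becomes B. Also records a per-sample anchor score (mean anchor-gene vst).
#'
#' @param assignment An `endo_assignment` tibble.
#' @param vst The variance-stabilized matrix the assignment was derived from.
#' @param anchor_genes Character vector of anchor gene ids
#'   (default [default_anchor_genes()]).
#' @return The assignment with labels oriented and an `anchor_score` column.
#' @export
label_endotypes <- function(assignment, vst, anchor_genes = default_anchor_genes()) {
  anchors <- intersect(anchor_genes, rownames(vst))
  if (length(anchors) == 0) {
    abort(paste0("None of the anchor genes are present in the expression ",
                 "matrix; supply `anchor_genes` that overlap its gene ids."),
          class = "endoseq_labeling_error")
  }
  score <- colMeans(unclass(vst)[anchors, assignment$sample_id, drop = FALSE])
  assignment$anchor_score <- unname(score)
  mean_a <- mean(score[assignment$label == "A"])
  mean_b <- mean(score[assignment$label == "B"])
  if (mean_b > mean_a) {
    lab <- assignment$label
    assignment$label[lab == "A"] <- "B"
    assignment$label[lab == "B"] <- "A"
  }
  assignment
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return The adjusted Rand index in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_i * sum_j / n2
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Concordance between two endotype assignments
#'
#' Agreement of two assignments over their shared samples: the A/B agreement
#' fraction maximized over the two possible matchings of major labels, and the
#' adjusted Rand index of the full three-label partitions. Both are invariant
#' to permuting either input's labels.
#'
#' @param a,b `endo_assignment` tibbles (or data frames with `sample_id`,
#'   `label`).
#' @return A list classed `endo_concordance`: `agreement_fraction`, `ari`,
#'   `discordant` (sample ids), `n_shared`.
#' @export
concordance <- function(a, b) {
  shared <- intersect(a$sample_id, b$sample_id)
  if (length(shared) == 0) abort("Assignments share no samples.",
                                 class = "endoseq_contract_error")
  if (length(shared) < length(union(a$sample_id, b$sample_id))) {
    inform(sprintf("Concordance computed on %d shared samples.", length(shared)))
  }
  la <- a$label[match(shared, a$sample_id)]
  lb <- b$label[match(shared, b$sample_id)]
  ab <- la %in% c("A", "B") & lb %in% c("A", "B")
  if (any(ab)) {
    direct <- mean(la[ab] == lb[ab])
    flipped <- mean(la[ab] == ifelse(lb[ab] == "A", "B", "A"))
    use_flip <- flipped > direct
    agreement <- max(direct, flipped)
    lb_m <- if (use_flip) ifelse(lb == "A", "B", ifelse(lb == "B", "A", lb)) else lb
    discordant <- shared[ab][la[ab] != lb_m[ab]]
  } else {
    agreement <- NA_real_
    discordant <- character(0)
  }
  structure(list(agreement_fraction = agreement,
                 ari = adjusted_rand_index(la, lb),
                 discordant = discordant,
                 n_shared = length(shared)),
            class = "endo_concordance")
}

#' @export
print.endo_concordance <- function(x, ...) {
  cat(sprintf("Endotype concordance over %d samples\n", x$n_shared))
  cat(sprintf("  A/B agreement (best label matching): %.3f\n", x$agreement_fraction))
  cat(sprintf("  Adjusted Rand index (3-label):       %.3f\n", x$ari))
  if (length(x$discordant) > 0) {
    cat("  Discordant:", paste(x$discordant, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Per-endotype clinical summary
#'
#' Summarizes a clinical table by endotype: patient count, sex counts, ANCA
#' status counts (PR3-positive, MPO-positive, ANCA-negative), mean activity
#' score rounded to the nearest integer (PVAS/BVAS are reported at integer
#' precision), and the number with active disease (activity score > 2).
#' Clinical-classification (EMA) counts are nested in the `ema` list-column.
#'
#' @param clin A clinical tibble (see [load_clinical_fixture()]) with at least
#'   `endotype`, `sex`, `anca`, `ema_class`, `activity_score`.
#' @return A tibble with one row per endotype.
#' @export
clinical_summary <- function(clin) {
  if (nrow(clin) == 0) {
    return(tibble(endotype = character(0), n = integer(0),
                  female = integer(0), male = integer(0),
                  anca_pr3 = integer(0), anca_mpo = integer(0),
                  anca_neg = integer(0), mean_activity = integer(0),
                  active = integer(0), ema = list()))
  }
  if (!all(clin$endotype %in% c("A", "B", "other"))) {
    abort("Unknown endotype label in clinical table.",
          class = "endoseq_contract_error")
  }
  clin |>
    group_by(.data$endotype) |>
    summarise(
      n = dplyr::n(),
      female = sum(.data$sex == "F"),
      male = sum(.data$sex == "M"),
      anca_pr3 = sum(grepl("PR3", .data$anca)),
      anca_mpo = sum(grepl("MPO", .data$anca)),
      anca_neg = sum(.data$anca == "NEG"),
      mean_activity = as.integer(round(mean(.data$activity_score))),
      active = sum(.data$activity_score > 2),
      ema = list({
        tb <- table(.data$ema_class)
        tibble(ema_class = names(tb), n = as.integer(tb))
      }),
      .groups = "drop"
    ) |>
    arrange(factor(.data$endotype, levels = c("A", "B", "other")))
}
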