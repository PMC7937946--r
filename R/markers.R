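# T-cell marker expression ratios per sample and their between-endotype
# Wilcoxon rank-sum comparisons.

#' Default T-cell marker ratio pairs
#'
#' The headline comparisons: Th1:Th2 balance (TBX21:GATA3), Treg fraction
#' relative to all T cells (FOXP3:CD3E) and the Th2 marker relative to all T
#' cells (GATA3:CD3E).
#'
#' @return A tibble with columns `numerator`, `denominator`.
#' @export
default_marker_pairs <- function() {
  tibble(numerator = c("TBX21", "FOXP3", "GATA3"),
         denominator = c("GATA3", "CD3E", "CD3E"))
}

#' The seven T-cell marker genes
#'
#' CD3E (all T cells), CD8A (CD8+), CD4 (CD4+), TBX21 (Th1), GATA3 (Th2),
#' FOXP3 (Treg), RORC (Th17).
#'
#' @return A character vector.
#' @export
tcell_markers <- function() {
  c("CD3E", "CD8A", "CD4", "TBX21", "GATA3", "FOXP3", "RORC")
}

#' Marker expression ratios between endotypes
#'
#' For each (numerator, denominator) gene pair, computes the per-sample ratio
#' of variance-stabilized values, `(vst_num + eps) / (vst_den + eps)` with
#' `eps = 0.01` guarding zero denominators (a log-ratio variant,
#' `vst_num - vst_den`, is available via `type = "difference"`). Ratios are
#' grouped by endotype and compared A vs B with the two-sided Wilcoxon
#' rank-sum test.
#'
#' @param vst A genes-by-samples matrix of variance-stabilized values.
#' @param assignment An `endo_assignment`; only A/B samples are compared.
#' @param pairs A data frame with columns `numerator`, `denominator`
#'   (default [default_marker_pairs()]).
#' @param type `"ratio"` (quotient, default) or `"difference"` (log-ratio on
#'   the vst scale).
#' @param eps Pseudo-value added to numerator and denominator (ratio type).
#' @return A list classed `endo_markers`: `summary` (tibble per pair with
#'   endotype medians and Wilcoxon p) and `samples` (long tibble of
#'   per-sample ratios).
#' @export
marker_ratios <- function(vst, assignment, pairs = default_marker_pairs(),
                          type = c("ratio", "difference"), eps = 0.01) {
  type <- match.arg(type)
  needed <- unique(c(pairs$numerator, pairs$denominator))
  absent <- setdiff(needed, rownames(vst))
  if (length(absent) > 0) {
    abort(paste0("Marker genes absent from the matrix: ",
                 paste(absent, collapse = ", ")),
          class = "endoseq_contract_error")
  }
  ab <- assignment[assignment$label %in% c("A", "B"), , drop = FALSE]
  v <- unclass(vst)[, ab$sample_id, drop = FALSE]
  per_sample <- purrr::pmap_dfr(pairs, function(numerator, denominator, ...) {
    ratio <- if (type == "ratio") {
      (v[numerator, ] + eps) / (v[denominator, ] + eps)
    } else {
      v[numerator, ] - v[denominator, ]
    }
    tibble(pair = paste0(numerator, ":", denominator),
           sample_id = colnames(v), label = ab$label,
           ratio = unname(ratio))
  })
  summary <- per_sample |>
    group_by(.data$pair) |>
    summarise(
      median_a = median(.data$ratio[.data$label == "A"]),
      median_b = median(.data$ratio[.data$label == "B"]),
      p_value = wilcoxon_rank_sum(.data$ratio[.data$label == "A"],
                                  .data$ratio[.data$label == "B"]),
      .groups = "drop"
    ) |>
    left_join(tibble(pair = paste0(pairs$numerator, ":", pairs$denominator),
                     order = seq_len(nrow(pairs))), by = "pair") |>
    arrange(.data$order) |> select(-"order")
  structure(list(summary = summary, samples = per_sample, type = type),
            class = "endo_markers")
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration of all rank allocations when the combined sample size is
#' at most 12 and there are no ties; otherwise the normal approximation with
#' tie correction and continuity correction.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return The two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) {
    abort("Both samples must be non-empty.", class = "endoseq_contract_error")
  }
  nx <- length(x); ny <- length(y); n <- nx + ny
  combined <- c(x, y)
  has_ties <- anyDuplicated(combined) > 0
  r <- rank(combined)
  w <- sum(r[seq_len(nx)])               # rank sum of x
  if (n <= 12 && !has_ties) {
    # exact: enumerate every allocation of ranks to the x sample
    allocs <- utils::combn(n, nx)
    sums <- colSums(matrix(seq_len(n)[allocs], nrow = nx))
    mu <- nx * (n + 1) / 2
    p <- mean(abs(sums - mu) >= abs(w - mu) - 1e-9)
    return(p)
  }
  mu <- nx * (n + 1) / 2
  tie_counts <- table(combined)
  sigma2 <- nx * ny / 12 * ((n + 1) - sum(tie_counts^3 - tie_counts) / (n * (n - 1)))
  if (sigma2 <= 0) return(1)             # all values tied
  z <- (abs(w - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  min(1, 2 * pnorm(-z))
}

#' @export
print.endo_markers <- function(x, ...) {
  cat("Marker expression ratios (A vs B, Wilcoxon rank-sum)\n")
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}
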