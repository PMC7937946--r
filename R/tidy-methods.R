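# broom-style tidiers and ggplot2 autoplot methods for the result classes.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_segment geom_tile
#'   geom_boxplot geom_hline geom_vline scale_fill_gradient2 labs theme_minimal
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a differential-expression result
#' @param x An `endo_de` tibble.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @export
tidy.endo_de <- function(x, ...) as_tibble(x)

#' One-row summary of a differential-expression result
#' @param x An `endo_de` tibble.
#' @param fc_min,fdr_max Thresholds used for counting significant genes.
#' @param ... Unused.
#' @return A one-row tibble: group sizes, significant up-in-A/up-in-B counts.
#' @export
glance.endo_de <- function(x, fc_min = 1.5, fdr_max = 0.05, ...) {
  lists <- de_genes(x, fc_min, fdr_max)
  tibble(n_genes = nrow(x), n_a = attr(x, "n_a"), n_b = attr(x, "n_b"),
         n_up_in_a = length(lists$up_in_a), n_up_in_b = length(lists$up_in_b))
}

#' Tidy an endotype assignment
#' @param x An `endo_assignment`.
#' @param ... Unused.
#' @return The per-sample tibble.
#' @export
tidy.endo_assignment <- function(x, ...) as_tibble(x)

#' Tidy a signature
#' @param x An `endo_signature`.
#' @param ... Unused.
#' @return The per-gene tibble with filter provenance.
#' @export
tidy.endo_signature <- function(x, ...) as_tibble(x)

#' One-row summary of a signature
#' @param x An `endo_signature`.
#' @param ... Unused.
#' @return A one-row tibble with size and direction split.
#' @export
glance.endo_signature <- function(x, ...) {
  tibble(n_genes = nrow(x), n_up_in_a = sum(x$direction > 0),
         n_up_in_b = sum(x$direction < 0),
         min_score = min(x$score), max_score = max(x$score))
}

#' Tidy a concordance report
#' @param x An `endo_concordance`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.endo_concordance <- function(x, ...) {
  tibble(agreement_fraction = x$agreement_fraction, ari = x$ari,
         n_shared = x$n_shared, n_discordant = length(x$discordant))
}

#' Tidy a rotation gene-set test
#' @param x An `endo_roast`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.endo_roast <- function(x, ...) {
  tibble(set_size = x$set_size, observed = x$observed, B = x$B,
         p_value = x$p_value)
}

#' Tidy a competitive gene-set test
#' @param x An `endo_camera`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.endo_camera <- function(x, ...) {
  tibble(set_size = x$set_size, rho_bar = x$rho_bar, vif = x$vif,
         z = x$z, p_value = x$p_value)
}

#' Volcano plot of a differential-expression result
#' @param object An `endo_de` tibble.
#' @param fc_min,fdr_max Thresholds drawn as guide lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.endo_de <- function(object, fc_min = 1.5, fdr_max = 0.05, ...) {
  df <- as_tibble(object) |>
    mutate(neglog_q = -log10(pmax(.data$q_value, 1e-300)),
           significant = .data$q_value <= fdr_max &
             pmax(2^.data$log2fc, 2^-.data$log2fc) >= fc_min)
  ggplot(df, aes(x = .data$log2fc, y = .data$neglog_q,
                 colour = .data$significant)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)), linetype = 2) +
    geom_hline(yintercept = -log10(fdr_max), linetype = 2) +
    labs(x = "log2 fold change (A over B)", y = "-log10 q-value",
         colour = "significant") +
    theme_minimal()
}

#' Dendrogram plot of a sample clustering
#' @param object An `endo_dendro`.
#' @param ... Unused.
#' @return A ggplot of the merge tree.
#' @export
autoplot.endo_dendro <- function(object, ...) {
  hc <- object
  class(hc) <- "hclust"
  dd <- stats::as.dendrogram(hc)
  # leaf x-positions in plotting order
  xpos <- setNames(seq_along(hc$order), hc$labels[hc$order])
  segs <- .dendro_segments(dd, xpos)$segs
  ggplot(segs) +
    geom_segment(aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = unname(xpos), labels = names(xpos)) +
    labs(x = NULL, y = "height (Euclidean distance)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

# recursive segment extraction for a dendrogram
.dendro_segments <- function(node, xpos) {
  if (is.leaf(node)) {
    lab <- attr(node, "label")
    return(list(x = xpos[[lab]],
                segs = tibble(x = numeric(0), y = numeric(0),
                              xend = numeric(0), yend = numeric(0))))
  }
  h <- attr(node, "height")
  kids <- lapply(seq_along(node), function(i) .dendro_segments(node[[i]], xpos))
  xs <- vapply(kids, function(k) k$x, numeric(1))
  child_h <- vapply(seq_along(node),
                    function(i) attr(node[[i]], "height") %||% 0, numeric(1))
  segs <- bind_rows(
    lapply(kids, function(k) k$segs),
    tibble(x = min(xs), y = h, xend = max(xs), yend = h),          # crossbar
    tibble(x = xs, y = child_h, xend = xs, yend = h)               # drops
  )
  list(x = mean(range(xs)), segs = segs)
}

#' Expression heatmap of a signature
#' @param object An `endo_signature`.
#' @param vst The variance-stabilized matrix to draw values from.
#' @param assignment Optional assignment used to order samples by endotype.
#' @param ... Unused.
#' @return A ggplot tile heatmap of per-gene z-scored vst values.
#' @export
autoplot.endo_signature <- function(object, vst, assignment = NULL, ...) {
  genes <- object$gene
  m <- unclass(vst)[genes, , drop = FALSE]
  m <- t(scale(t(m)))
  df <- as_tibble(m, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "sample_id", values_to = "z")
  if (!is.null(assignment)) {
    ord <- assignment$sample_id[order(assignment$label)]
    df$sample_id <- factor(df$sample_id, levels = ord)
  }
  df$gene <- factor(df$gene, levels = rev(genes))
  ggplot(df, aes(x = .data$sample_id, y = .data$gene, fill = .data$z)) +
    geom_tile() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = "z(vst)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' Boxplots of marker expression ratios by endotype
#' @param object An `endo_markers` result.
#' @param ... Unused.
#' @return A ggplot of per-sample ratios, one facet per marker pair.
#' @export
autoplot.endo_markers <- function(object, ...) {
  ggplot(object$samples, aes(x = .data$label, y = .data$ratio,
                             fill = .data$label)) +
    geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~pair, scales = "free_y") +
    labs(x = "endotype",
         y = if (object$type == "ratio") "vst ratio" else "vst difference") +
    theme_minimal()
}
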