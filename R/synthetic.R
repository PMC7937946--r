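# Synthetic cohort generator: negative-binomial counts with gene-specific
# dispersion, two latent endotypes differing in a planted fraction of DE
# genes, a small "other" group with its own profile, multiplicative batch
# effects, log-normal library sizes, a high-abundance globin block, a
# T-cell-marker block, planted neutrophil anchor genes, and gene sets
# enriched for planted DE genes — with a truth object for recovery testing.

#' Simulation configuration
#'
#' Defaults mirror the discovery cohort structure this pipeline targets:
#' 13 + 14 samples in the two major endotypes plus 3 "other" samples, 2000
#' genes of which 10\% are differentially expressed with |log2FC| drawn from
#' [1, 3] (straddling the 1.5x and 2x analysis thresholds), gene-specific NB
#' dispersions in [0.05, 0.5], two sequencing batches with log-normal
#' multiplicative per-gene effects, log-normal library sizes, a 5-gene globin
#' block carrying 20\% of reads, and 20 gene sets of 20-100 genes of which
#' the first `n_enriched_sets` are enriched for planted DE genes.
#'
#' @param n_genes Number of background genes.
#' @param n_a,n_b,n_other Samples per group.
#' @param n_batches Number of sequencing batches.
#' @param pi_de Fraction of genes differentially expressed between A and B.
#' @param lfc_range Range of |log2FC| for DE genes.
#' @param alpha_range Range of NB dispersions.
#' @param libsize_sdlog Log-normal sd of library-size factors.
#' @param batch_sdlog Log-normal sd of per-gene batch factors.
#' @param n_globin Globin block size.
#' @param globin_fraction Fraction of total reads carried by the globin block.
#' @param n_gene_sets,set_size_range,n_enriched_sets,enrich_fraction Gene-set
#'   collection shape: number of sets, size range, how many sets are enriched
#'   and what fraction of an enriched set is drawn from planted DE genes.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean counts.
#' @param pvas_a,pvas_b,pvas_other Mean/sd pairs for the simulated activity
#'   scores per group.
#' @return A validated list classed `endo_sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_a = 13, n_b = 14, n_other = 3,
                       n_batches = 2, pi_de = 0.10, lfc_range = c(1, 3),
                       alpha_range = c(0.05, 0.5), libsize_sdlog = 0.3,
                       batch_sdlog = 0.15, n_globin = 5, globin_fraction = 0.2,
                       n_gene_sets = 20, set_size_range = c(20, 100),
                       n_enriched_sets = 5, enrich_fraction = 0.7,
                       baseline_meanlog = log(150), baseline_sdlog = 1,
                       pvas_a = c(21, 7), pvas_b = c(14, 5),
                       pvas_other = c(17, 6)) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_genes >= 10, cfg$n_a >= 2, cfg$n_b >= 2, cfg$n_other >= 0,
            cfg$n_batches >= 1, cfg$pi_de >= 0, cfg$pi_de <= 1,
            cfg$lfc_range[1] <= cfg$lfc_range[2], all(cfg$alpha_range > 0),
            cfg$alpha_range[1] <= cfg$alpha_range[2],
            cfg$globin_fraction >= 0, cfg$globin_fraction < 1,
            cfg$enrich_fraction >= 0, cfg$enrich_fraction <= 1,
            cfg$set_size_range[1] <= cfg$set_size_range[2])
  structure(cfg, class = "endo_sim_config")
}

# marker block: planted log2FC (A over B) for the seven T-cell markers and
# the neutrophil anchor genes
.marker_lfc <- function() {
  c(CD3E = -0.6, CD8A = -0.5, CD4 = -0.8, TBX21 = 0.8, GATA3 = -1.5,
    FOXP3 = -1.0, RORC = -0.4,
    S100A8 = 1.8, S100A9 = 1.8, S100A12 = 1.5, PADI4 = 1.5, FCGR2A = 1.2,
    ITGAM = 1.0, CEACAM8 = 1.4, MPO = 1.2, ELANE = 1.3, LCN2 = 1.2)
}

#' Simulate a synthetic vasculitis cohort
#'
#' Draws `count[g, j] ~ NB(mean = s_j * b[batch(j), g] * mu_g *
#' 2^(lfc_g * I[group(j) = A]) , dispersion = alpha_g)`, with the "other"
#' group following its own perturbed mean profile. Deterministic given
#' `seed`.
#'
#' @param config An `endo_sim_config` (see [sim_config()]).
#' @param seed Integer seed; all randomness flows from it.
#' @param gene_truth Optional `genes` tibble from a previous run's `truth`:
#'   reuses the planted gene-level parameters (baseline means, dispersions,
#'   DE log2FCs, "other"-profile shifts, globin block) so a second cohort can
#'   be drawn from the same generative truth with fresh sampling noise,
#'   batches and library sizes.
#' @return A list classed `endo_sim` with `counts` (count matrix), `samples`
#'   (sample table tibble), `sets` (gene-set collection) and `truth` (planted
#'   groups, batches, DE flags and log2FCs, dispersions, globin flags,
#'   library-size factors).
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1, gene_truth = NULL) {
  cfg <- config
  withr::with_seed(seed, {
    marker_lfc <- .marker_lfc()
    n_marker <- length(marker_lfc)
    globin_ids <- c("HBB", "HBA1", "HBA2", "HBG1", "HBD")[seq_len(cfg$n_globin)]
    if (!is.null(gene_truth)) {
      reuse <- gene_truth[!gene_truth$is_globin, , drop = FALSE]
      gene_ids <- reuse$gene
      n_gene <- length(gene_ids)
      mu <- setNames(reuse$mu, gene_ids)
      alpha <- setNames(reuse$alpha, gene_ids)
      lfc <- setNames(reuse$log2fc, gene_ids)
      lfc_other <- setNames(reuse$lfc_other, gene_ids)
      is_de <- setNames(reuse$is_de, gene_ids)
      globin_ids <- gene_truth$gene[gene_truth$is_globin]
      cfg$n_globin <- length(globin_ids)
    } else {
      n_bg <- cfg$n_genes - n_marker
      gene_ids <- c(sprintf("G%05d", seq_len(n_bg)), names(marker_lfc))
      n_gene <- length(gene_ids)

      mu <- rlnorm(n_gene, cfg$baseline_meanlog, cfg$baseline_sdlog)
      names(mu) <- gene_ids
      # markers sit comfortably above the abundance filter
      mu[names(marker_lfc)] <- rlnorm(n_marker, log(400), 0.3)
      alpha <- runif(n_gene, cfg$alpha_range[1], cfg$alpha_range[2])
      names(alpha) <- gene_ids

      # planted DE genes among the background, plus the marker block
      n_de_bg <- round(cfg$pi_de * n_bg)
      de_bg <- sample(gene_ids[seq_len(n_bg)], n_de_bg)
      lfc <- setNames(rep(0, n_gene), gene_ids)
      lfc[de_bg] <- sample(c(-1, 1), n_de_bg, replace = TRUE) *
        runif(n_de_bg, cfg$lfc_range[1], cfg$lfc_range[2])
      lfc[names(marker_lfc)] <- marker_lfc
      is_de <- lfc != 0

      # "other" group: its own profile, perturbing a random 10% of genes
      n_other_de <- round(0.1 * n_gene)
      other_genes <- sample(gene_ids, n_other_de)
      lfc_other <- setNames(rep(0, n_gene), gene_ids)
      lfc_other[other_genes] <- sample(c(-1, 1), n_other_de, replace = TRUE) *
        runif(n_other_de, 1, 3)
    }

    groups <- c(rep("A", cfg$n_a), rep("B", cfg$n_b), rep("other", cfg$n_other))
    n_samp <- length(groups)
    sample_ids <- sprintf("S%02d", seq_len(n_samp))
    batch <- paste0("batch", rep_len(seq_len(cfg$n_batches), n_samp))
    batch <- sample(batch)  # shuffle so batch is not confounded with group
    libsize <- rlnorm(n_samp, 0, cfg$libsize_sdlog)
    libsize <- libsize / exp(mean(log(libsize)))

    # per-gene multiplicative batch factors (batch 1 is the reference)
    bfac <- matrix(1, n_gene, cfg$n_batches,
                   dimnames = list(gene_ids, paste0("batch", seq_len(cfg$n_batches))))
    if (cfg$n_batches > 1) {
      for (b in 2:cfg$n_batches) {
        bfac[, b] <- rlnorm(n_gene, 0, cfg$batch_sdlog)
      }
    }

    # globin block appended, sized to carry globin_fraction of total reads
    if (cfg$n_globin > 0) {
      if (!is.null(gene_truth)) {
        grows <- gene_truth[gene_truth$is_globin, , drop = FALSE]
        mu_globin <- setNames(grows$mu, grows$gene)
        alpha_globin <- setNames(grows$alpha, grows$gene)
      } else {
        total_mu <- sum(mu)
        globin_total <- total_mu * cfg$globin_fraction / (1 - cfg$globin_fraction)
        share <- c(0.40, 0.25, 0.15, 0.12, 0.08)[seq_len(cfg$n_globin)]
        share <- share / sum(share)
        mu_globin <- setNames(globin_total * share, globin_ids)
        alpha_globin <- setNames(runif(cfg$n_globin, 0.05, 0.2), globin_ids)
      }
      mu <- c(mu, mu_globin)
      alpha <- c(alpha, alpha_globin)
      lfc <- c(lfc, setNames(rep(0, cfg$n_globin), globin_ids))
      lfc_other <- c(lfc_other, setNames(rep(0, cfg$n_globin), globin_ids))
      is_de <- c(is_de, setNames(rep(FALSE, cfg$n_globin), globin_ids))
      bfac <- rbind(bfac, matrix(1, cfg$n_globin, cfg$n_batches,
                                 dimnames = list(globin_ids, colnames(bfac))))
      gene_ids <- c(gene_ids, globin_ids)
    }

    mean_mat <- matrix(0, length(gene_ids), n_samp,
                       dimnames = list(gene_ids, sample_ids))
    for (j in seq_len(n_samp)) {
      shift <- switch(groups[j],
                      A = 2^lfc,
                      B = rep(1, length(gene_ids)),
                      other = 2^lfc_other)
      mean_mat[, j] <- libsize[j] * bfac[, batch[j]] * mu * shift
    }
    counts <- matrix(
      rnbinom(length(mean_mat), mu = mean_mat,
              size = 1 / rep(alpha, times = n_samp)),
      nrow = length(gene_ids), dimnames = dimnames(mean_mat))

    samples <- tibble(sample_id = sample_ids, batch = batch,
                      cohort = "synthetic", sex = sample(c("F", "M"), n_samp,
                                                         replace = TRUE),
                      timepoint = "Diagnosis", group = groups)

    # gene sets: the first n_enriched_sets draw enrich_fraction of members
    # from planted DE genes
    de_pool <- names(lfc)[is_de]
    non_de_pool <- setdiff(gene_ids, de_pool)
    sets <- list()
    for (s in seq_len(cfg$n_gene_sets)) {
      sz <- sample(cfg$set_size_range[1]:cfg$set_size_range[2], 1)
      if (s <= cfg$n_enriched_sets && length(de_pool) > 0) {
        n_from_de <- min(round(cfg$enrich_fraction * sz), length(de_pool))
        members <- c(sample(de_pool, n_from_de),
                     sample(non_de_pool, sz - n_from_de))
      } else {
        members <- sample(non_de_pool, min(sz, length(non_de_pool)))
      }
      sets[[sprintf("SET%02d", s)]] <- unique(members)
    }
    gsc <- gene_set_collection(sets,
      descriptions = c(rep("enriched for planted DE genes", cfg$n_enriched_sets),
                       rep("background set", cfg$n_gene_sets - cfg$n_enriched_sets)))

    truth <- list(
      samples = tibble(sample_id = sample_ids, group = groups, batch = batch,
                       size_factor = libsize),
      genes = tibble(gene = gene_ids, is_de = unname(is_de),
                     log2fc = unname(lfc), alpha = unname(alpha[gene_ids]),
                     mu = unname(mu[gene_ids]),
                     lfc_other = unname(lfc_other[gene_ids]),
                     is_globin = gene_ids %in% globin_ids),
      seed = seed
    )
    structure(list(counts = count_matrix(counts), samples = samples,
                   sets = gsc, truth = truth, config = cfg),
              class = "endo_sim")
  })
}

#' Simulate a clinical table for a synthetic cohort
#'
#' Activity scores are drawn per group (rounded normal, truncated at 0):
#' endotype A around 21 (sd 7), B around 14 (sd 5), "other" around 17
#' (sd 6) by default. Sex, clinical classification and ANCA status are drawn
#' from per-group categorical frequencies matching the discovery cohort's
#' composition.
#'
#' @param truth The `truth` element of an [simulate_cohort()] result (or any
#'   list with a `samples` tibble carrying `sample_id` and `group`).
#' @param config An `endo_sim_config` (activity-score parameters are read
#'   from it).
#' @param seed Integer seed.
#' @return A clinical tibble with the same columns as the packaged fixtures.
#' @export
simulate_clinical <- function(truth, config = sim_config(), seed = 1) {
  freq <- list(
    A = list(ema = c(GPA = 9, uAAV = 4), anca = c(PR3 = 9, MPO = 4),
             sex = c(F = 9, M = 4)),
    B = list(ema = c(GPA = 5, MPA = 4, PAN = 2, uAAV = 2, UCV = 1),
             anca = c(PR3 = 5, MPO = 6, NEG = 3), sex = c(F = 9, M = 5)),
    other = list(ema = c(GPA = 2, uAAV = 1), anca = c(PR3 = 1, MPO = 2),
                 sex = c(F = 2, M = 1))
  )
  pvas <- list(A = config$pvas_a, B = config$pvas_b, other = config$pvas_other)
  withr::with_seed(seed, {
    rows <- purrr::map2_dfr(truth$samples$sample_id, truth$samples$group,
      function(id, g) {
        fr <- freq[[g]]; pv <- pvas[[g]]
        score <- max(0L, as.integer(round(rnorm(1, pv[1], pv[2]))))
        tibble(
          patient_id = id, endotype = g,
          ema_class = sample(names(fr$ema), 1, prob = fr$ema),
          anca = sample(names(fr$anca), 1, prob = fr$anca),
          timepoint = "Diagnosis",
          sex = sample(names(fr$sex), 1, prob = fr$sex),
          organ_systems = "",
          activity_score = score)
      })
    class(rows) <- c("endo_clinical", class(rows))
    rows
  })
}
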