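# A hand-built 6-gene scenario where exactly 3 genes pass all four filters.
make_toy_signature_data <- function() {
  ids <- sprintf("s%02d", 1:8)
  asg <- two_group_assignment(ids, 4)
  # per-gene construction (A-mean counts, B-mean counts, noise):
  #  g1: strong DE, high counts, low variance      -> passes everything
  #  g2: strong DE, high counts, low variance      -> passes everything
  #  g3: strong DE, high counts, low variance      -> passes everything
  #  g4: strong DE but mean count < 100            -> fails abundance
  #  g5: DE with fold change ~1.7 (< 2)            -> fails the FC >= 2 filter
  #  g6: strong DE but high within-cluster variance-> fails the variance filter
  a_means <- c(400, 600, 800, 40, 170, 500)
  b_means <- c(100, 150, 150, 10, 100, 125)
  cnt <- matrix(0, 6, 8, dimnames = list(sprintf("g%d", 1:6), ids))
  withr::with_seed(71, {
    for (g in 1:6) {
      jitter_a <- if (g == 6) c(-200, 200, -180, 180) else c(-2, 2, -1, 1)
      jitter_b <- if (g == 6) c(-60, 60, -50, 50) else c(-2, 2, -1, 1)
      cnt[g, 1:4] <- round(a_means[g] + jitter_a)
      cnt[g, 5:8] <- round(b_means[g] + jitter_b)
    }
  })
  cm <- count_matrix(cnt)
  sf <- setNames(rep(1, 8), ids)
  disp <- estimate_dispersion(cm, sf)
  v <- vst_transform(cm, sf, disp)
  de <- nb_wald_de(cm, sf, asg, disp)
  list(cm = cm, sf = sf, vst = v, asg = asg, de = de)
}

test_that("the filter chain matches the hand-evaluated toy example", {
  toy <- make_toy_signature_data()
  expect_warning(
    sig <- select_signature(toy$vst, toy$cm, toy$asg, toy$de, k = 20,
                            sf = toy$sf),
    "smaller than k")
  expect_setequal(sig$gene, c("g1", "g2", "g3"))
  expect_true(all(sig$direction == 1L))
  # sorted by descending divergence, ties by gene id
  expect_equal(sig$score, sort(sig$score, decreasing = TRUE))

  ft <- attr(sig, "filter_table")
  expect_false(ft$passed_count100[ft$gene == "g4"])
  expect_true(ft$passed_de[ft$gene == "g4"])
  expect_false(ft$passed_fc2[ft$gene == "g5"])
  expect_false(ft$passed_var50[ft$gene == "g6"])
})

test_that("vacuous thresholds reduce the candidates to the significant genes", {
  toy <- make_toy_signature_data()
  sig <- suppressWarnings(
    select_signature(toy$vst, toy$cm, toy$asg, toy$de, k = 20, fc_min = 1,
                     var_quantile = 1, min_mean_count = 0, sf = toy$sf))
  sig_de <- toy$de$gene[toy$de$q_value <= 0.05 &
                          pmax(2^toy$de$log2fc, 2^-toy$de$log2fc) > 1.5]
  expect_setequal(sig$gene, sig_de)
})

test_that("raising a threshold never adds a candidate", {
  sim <- simulate_cohort(sim_config(n_genes = 500), seed = 61)
  prep <- preprocess_counts(sim$counts, sim$samples)
  asg <- assign_endotypes(cluster_samples(prep$vst), 3, prep$vst) |>
    label_endotypes(prep$vst)
  de <- nb_wald_de(prep$counts, prep$sf, asg, prep$dispersion)
  base <- suppressWarnings(
    select_signature(prep$vst, prep$counts, asg, de, k = 1000, sf = prep$sf))
  stricter_fc <- suppressWarnings(
    select_signature(prep$vst, prep$counts, asg, de, k = 1000, fc_min = 3,
                     sf = prep$sf))
  stricter_count <- suppressWarnings(
    select_signature(prep$vst, prep$counts, asg, de, k = 1000,
                     min_mean_count = 300, sf = prep$sf))
  expect_true(all(stricter_fc$gene %in% base$gene))
  expect_true(all(stricter_count$gene %in% base$gene))
  # determinism
  again <- suppressWarnings(
    select_signature(prep$vst, prep$counts, asg, de, k = 1000, sf = prep$sf))
  expect_identical(base$gene, again$gene)
})

test_that("the default signature is 20 planted-DE genes separating cohorts", {
  sim <- simulate_cohort(sim_config(), seed = 1)
  prep <- preprocess_counts(sim$counts, sim$samples)
  asg <- assign_endotypes(cluster_samples(prep$vst), 3, prep$vst) |>
    label_endotypes(prep$vst)
  de <- nb_wald_de(prep$counts, prep$sf, asg, prep$dispersion)
  sig <- select_signature(prep$vst, prep$counts, asg, de, sf = prep$sf)
  expect_equal(nrow(sig), 20)
  planted <- sim$truth$genes$gene[sim$truth$genes$is_de]
  expect_true(all(sig$gene %in% planted))

  # resubstitution: the signature re-separates its own cohort perfectly
  self_rep <- validate_signature(sig, prep$vst, asg)
  expect_equal(self_rep$agreement_fraction, 1)

  # cross-cohort: a new cohort from the same truth, new noise
  sim2 <- simulate_cohort(sim_config(), seed = 202, gene_truth = sim$truth$genes)
  prep2 <- preprocess_counts(sim2$counts, sim2$samples)
  ref2 <- tibble::tibble(sample_id = sim2$truth$samples$sample_id,
                         label = sim2$truth$samples$group)
  val <- suppressMessages(validate_signature(sig, prep2$vst, ref2))
  expect_gte(val$agreement_fraction, 0.9)
})

test_that("an uninformative signature has null concordance", {
  aris <- vapply(1:30, function(s) {
    withr::with_seed(1000 + s, {
      m <- matrix(rnorm(2 * 24, 5), 2, 24,
                  dimnames = list(c("n1", "n2"), sprintf("s%02d", 1:24)))
    })
    fake_sig <- structure(
      tibble::tibble(gene = c("n1", "n2"), direction = c(1L, -1L),
                     score = c(1, 1)),
      class = c("endo_signature", class(tibble::tibble())))
    ref <- two_group_assignment(colnames(m), 12)
    suppressMessages(validate_signature(fake_sig, m, ref))$ari
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.15)
})

test_that("missing genes and degenerate inputs raise contract errors", {
  toy <- make_toy_signature_data()
  sig <- suppressWarnings(select_signature(toy$vst, toy$cm, toy$asg, toy$de,
                                           sf = toy$sf))
  other_m <- matrix(rnorm(4 * 6, 5), 4, 6,
                    dimnames = list(c("zz1", "zz2", "zz3", "zz4"),
                                    sprintf("t%d", 1:6)))
  expect_error(validate_signature(sig, other_m, toy$asg),
               class = "endoseq_contract_error")
  expect_error(
    select_signature(toy$vst, toy$cm, toy$asg, toy$de, min_mean_count = 1e9,
                     sf = toy$sf),
    class = "endoseq_selection_error")
})
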