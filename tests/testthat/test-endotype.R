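test_that("average-linkage merges match the hand-computed example", {
  # 4 samples as 1-D points 0, 1, 10, 11
  m <- matrix(c(0, 1, 10, 11), nrow = 1,
              dimnames = list("g1", c("s1", "s2", "s3", "s4")))
  dend <- cluster_samples(m)
  expect_equal(sort(dend$height), c(1, 1, 10))

  # duplicated sample column -> first merge at height 0
  m2 <- matrix(c(0, 0, 5), nrow = 1, dimnames = list("g1", c("s1", "s2", "s3")))
  expect_equal(min(cluster_samples(m2)$height), 0)
})

test_that("dendrogram agrees with a brute-force average-linkage oracle", {
  for (seed in 1:5) {
    withr::with_seed(seed, {
      m <- matrix(rnorm(10 * 8), 10, 8,
                  dimnames = list(sprintf("g%02d", 1:10), sprintf("s%d", 1:8)))
    })
    dend <- cluster_samples(m)
    oracle <- bf_average_linkage_heights(dist(t(m)))
    expect_equal(sort(dend$height), sort(oracle), tolerance = 1e-10)
    # monotone heights: no inversions
    expect_true(all(diff(dend$height) >= -1e-12))
  }
})

test_that("clustering is invariant to sample column order", {
  withr::with_seed(8, {
    m <- matrix(rnorm(20 * 9), 20, 9,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:9)))
  })
  d1 <- cluster_samples(m)
  d2 <- cluster_samples(m[, sample(ncol(m))])
  expect_equal(d1$height, d2$height)
  expect_equal(cutree(d1, 3)[sort(names(cutree(d1, 3)))],
               cutree(d2, 3)[sort(names(cutree(d2, 3)))])
})

test_that("endotype assignment finds two majors plus other", {
  # two well-separated clouds, k = 2 -> perfect split, no other
  withr::with_seed(12, {
    m <- cbind(matrix(rnorm(50 * 10, 0), 50, 10),
               matrix(rnorm(50 * 10, 6), 50, 10))
    dimnames(m) <- list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:20))
  })
  asg <- assign_endotypes(cluster_samples(m), n_clusters = 2, vst = m)
  expect_equal(sum(asg$label == "other"), 0)
  expect_equal(sort(table(asg$label)), sort(table(rep(c("A", "B"), each = 10))))
  split_ok <- length(unique(asg$label[1:10])) == 1 &&
    length(unique(asg$label[11:20])) == 1
  expect_true(split_ok)

  # 13 + 14 + 3 planted structure, k = 3 -> majors 13 and 14, 3 other
  withr::with_seed(13, {
    m3 <- cbind(matrix(rnorm(50 * 13, 0), 50, 13),
                matrix(rnorm(50 * 14, 5), 50, 14),
                matrix(rnorm(50 * 3, -6), 50, 3))
    dimnames(m3) <- list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:30))
  })
  asg3 <- assign_endotypes(cluster_samples(m3), n_clusters = 3, vst = m3)
  expect_equal(sort(as.vector(table(asg3$label))), c(3, 13, 14))
  expect_equal(sum(asg3$label == "other"), 3)

  # boundary: every sample its own cluster, still deterministic
  asg_n <- assign_endotypes(cluster_samples(m3), n_clusters = 30, vst = m3)
  expect_equal(sum(asg_n$label == "A"), 1)
  expect_equal(sum(asg_n$label == "B"), 1)
  asg_n2 <- assign_endotypes(cluster_samples(m3), n_clusters = 30, vst = m3)
  expect_identical(asg_n, asg_n2)

  expect_error(assign_endotypes(cluster_samples(m3), n_clusters = 1),
               class = "endoseq_contract_error")
})

test_that("anchor genes orient the A/B labels deterministically", {
  withr::with_seed(14, {
    base <- matrix(rnorm(30 * 20, 5), 30, 20,
                   dimnames = list(c(sprintf("g%02d", 1:27), "S100A8", "S100A9",
                                     "PADI4"),
                                   sprintf("s%02d", 1:20)))
    base[1:10, 1:10] <- base[1:10, 1:10] + 4   # separate the clusters
    base[28:30, 1:10] <- base[28:30, 1:10] + 2 # anchors higher in cluster 1
  })
  asg <- assign_endotypes(cluster_samples(base), 2, base)
  lab <- label_endotypes(asg, base, c("S100A8", "S100A9", "PADI4"))
  expect_true(all(lab$label[1:10] == "A"))
  expect_true(all(lab$label[11:20] == "B"))

  # anchors planted in the other direction flip the labels
  flipped <- base
  flipped[28:30, 1:10] <- flipped[28:30, 1:10] - 2
  flipped[28:30, 11:20] <- flipped[28:30, 11:20] + 2
  lab2 <- label_endotypes(asg, flipped, c("S100A8", "S100A9", "PADI4"))
  expect_true(all(lab2$label[1:10] == "B"))
  expect_true(all(lab2$label[11:20] == "A"))

  expect_error(label_endotypes(asg, base, c("NOPE1", "NOPE2")),
               class = "endoseq_labeling_error")
})

test_that("anchor labeling recovers the planted group across seeds", {
  hits <- vapply(1:20, function(s) {
    sim <- simulate_cohort(sim_config(n_genes = 400, n_other = 0), seed = s)
    prep <- preprocess_counts(sim$counts, sim$samples)
    asg <- assign_endotypes(cluster_samples(prep$vst), 2, prep$vst) |>
      label_endotypes(prep$vst)
    truth_a <- sim$truth$samples$sample_id[sim$truth$samples$group == "A"]
    mean(asg$label[asg$sample_id %in% truth_a] == "A") > 0.5
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("concordance is permutation invariant with a calibrated null", {
  a <- tibble::tibble(sample_id = sprintf("s%03d", 1:40),
                      label = rep(c("A", "B"), 20))
  expect_equal(concordance(a, a)$agreement_fraction, 1)
  expect_equal(concordance(a, a)$ari, 1)

  b <- a
  b$label <- ifelse(a$label == "A", "B", "A")
  expect_equal(concordance(a, b)$agreement_fraction, 1)
  expect_equal(concordance(a, b)$ari, 1)

  # ARI matches the mclust reference on a 3-label partition
  withr::with_seed(17, {
    x <- sample(c("A", "B", "other"), 60, replace = TRUE)
    y <- sample(c("A", "B", "other"), 60, replace = TRUE)
  })
  expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y))

  # independent random labelings at n = 1000 -> ARI near 0
  withr::with_seed(18, {
    big_a <- tibble::tibble(sample_id = sprintf("s%04d", 1:1000),
                            label = sample(c("A", "B"), 1000, replace = TRUE))
    big_b <- big_a
    big_b$label <- sample(c("A", "B"), 1000, replace = TRUE)
  })
  expect_lt(abs(concordance(big_a, big_b)$ari), 0.05)

  expect_error(
    concordance(a, tibble::tibble(sample_id = "zz", label = "A")),
    class = "endoseq_contract_error")
})

test_that("clinical summary reproduces the printed cohort characteristics", {
  ped <- load_clinical_fixture("pediatric_cohort1")
  cs <- clinical_summary(ped)
  expect_equal(cs$endotype, c("A", "B", "other"))
  expect_equal(cs$n, c(13L, 14L, 3L))
  expect_equal(cs$mean_activity[cs$endotype == "A"], 21L)
  expect_equal(cs$mean_activity[cs$endotype == "B"], 14L)
  expect_equal(cs$anca_pr3[cs$endotype == "A"], 9L)
  expect_equal(cs$female[cs$endotype == "A"], 9L)
  expect_equal(cs$male[cs$endotype == "B"], 5L)
  # conservation: totals equal row count
  expect_equal(sum(cs$n), nrow(ped))
  expect_equal(sum(purrr::map_int(cs$ema, ~sum(.x$n))), nrow(ped))
  # every sampled patient had active disease (score > 2)
  expect_equal(sum(cs$active), 30L)

  empty <- clinical_summary(ped[0, ])
  expect_equal(nrow(empty), 0)

  bad <- ped
  bad$endotype[1] <- "Q"
  expect_error(clinical_summary(bad), class = "endoseq_contract_error")
})
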