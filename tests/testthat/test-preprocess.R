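test_that("globin removal is an exact set difference conserving other counts", {
  cm <- make_test_counts(n_genes = 5, n_a = 2, n_b = 2, seed = 3)
  # no globin present -> identity
  expect_equal(unclass(remove_globin(cm, c("HBB", "HBA1"))), unclass(cm))

  rownames(cm)[1:2] <- c("HBB", "HBA1")
  out <- remove_globin(cm, c("HBB", "HBA1"))
  expect_equal(nrow(out), 3)
  expect_equal(unclass(out), unclass(cm)[3:5, ])
  expect_equal(colnames(out), colnames(cm))

  expect_error(remove_globin(cm, rownames(cm)),
               class = "endoseq_degenerate_error")
})

test_that("planted globin block removal reduces totals by exactly its sum", {
  sim <- simulate_cohort(sim_config(n_genes = 300), seed = 11)
  globins <- sim$truth$genes$gene[sim$truth$genes$is_globin]
  block_sum <- sum(unclass(sim$counts)[globins, ])
  post <- remove_globin(sim$counts, default_globin_genes())
  expect_equal(sum(sim$counts) - sum(post), block_sum)
  # the block is genuinely high-abundance: a substantial share of all reads
  expect_gt(block_sum / sum(sim$counts), 0.10)
})

test_that("size factors implement anchored median-of-ratios", {
  # identical columns -> all 1
  m <- matrix(rep(c(10L, 20L, 30L), 3), nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_equal(size_factors(count_matrix(m)), c(s1 = 1, s2 = 1, s3 = 1))

  # doubling one column doubles its factor relative to the others
  m2 <- m; m2[, 2] <- m2[, 2] * 2L
  sf <- size_factors(count_matrix(m2))
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(exp(mean(log(sf))), 1)

  # 3x3 hand-computed median of ratios
  m3 <- matrix(c(10L, 100L, 40L,
                 20L, 200L, 80L,
                 10L, 50L, 40L), nrow = 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  geo <- exp(rowMeans(log(m3)))
  raw <- apply(m3 / geo, 2, median)
  expect_equal(size_factors(count_matrix(m3)), raw / exp(mean(log(raw))))

  # no common reference gene -> estimation error
  m4 <- matrix(c(0L, 5L, 5L, 0L), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(size_factors(count_matrix(m4)), class = "endoseq_estimation_error")
})

test_that("moment dispersion recovers the truth and degenerates safely", {
  # constant gene -> alpha = 0
  m <- matrix(c(5L, 5L, 5L, 1L, 9L, 3L), nrow = 2, byrow = TRUE,
              dimnames = list(c("gc", "gv"), paste0("s", 1:3)))
  d <- estimate_dispersion(count_matrix(m), setNames(rep(1, 3), paste0("s", 1:3)))
  expect_equal(unname(d$alpha["gc"]), 0)

  # NB genes with true alpha = 0.2, n = 200 -> pooled within +/- 0.05
  withr::with_seed(21, {
    cnt <- matrix(rnbinom(200 * 200, mu = 100, size = 1 / 0.2), nrow = 200,
                  dimnames = list(sprintf("g%03d", 1:200), sprintf("s%03d", 1:200)))
  })
  d2 <- estimate_dispersion(count_matrix(cnt))
  expect_lt(abs(d2$pooled - 0.2), 0.05)

  # Poisson genes -> pooled dispersion at the floor
  withr::with_seed(22, {
    cntp <- matrix(rpois(200 * 500, 100), nrow = 200,
                   dimnames = list(sprintf("g%03d", 1:200), sprintf("s%03d", 1:500)))
  })
  d3 <- estimate_dispersion(count_matrix(cntp))
  expect_lt(d3$pooled, 0.005)
})

test_that("vst closed forms, monotonicity and variance stabilization hold", {
  expect_equal(vst_value(0, 1), 0)
  expect_equal(vst_value(1, 1), 2 * asinh(1))
  expect_lt(abs(vst_value(4, 1e-8) - 2 * sqrt(4)), 1e-3)

  # monotone: vst preserves within-sample count ranking exactly
  cm <- make_test_counts(n_genes = 100, n_a = 3, n_b = 3, seed = 5)
  v <- vst_transform(cm)
  for (j in seq_len(ncol(cm))) {
    expect_equal(order(unclass(v)[, j]), order(unclass(cm)[, j]))
  }

  # stabilization: binned variance of vst values varies < 2x across two
  # orders of magnitude of mean, vs > 10x for raw counts
  withr::with_seed(31, {
    mu <- 10^runif(2000, 1, 3)
    cnt <- matrix(rnbinom(2000 * 50, mu = rep(mu, 50), size = 1 / 0.2),
                  nrow = 2000,
                  dimnames = list(sprintf("g%04d", 1:2000), sprintf("s%02d", 1:50)))
  })
  cmb <- count_matrix(cnt)
  vb <- vst_transform(cmb)
  bins <- cut(log10(mu), breaks = seq(1, 3, by = 0.5), include.lowest = TRUE)
  var_vst <- tapply(apply(unclass(vb), 1, var), bins, median)
  var_raw <- tapply(apply(unclass(cmb), 1, var), bins, median)
  expect_lt(max(var_vst) / min(var_vst), 2)
  expect_gt(max(var_raw) / min(var_raw), 10)
})

test_that("batch adjustment removes planted location and scale effects", {
  set.seed(55)
  G <- 500; nb <- 80
  ids <- sprintf("s%03d", 1:(2 * nb))
  y <- matrix(rnorm(G * 2 * nb, 8, 1), G, 2 * nb,
              dimnames = list(sprintf("g%03d", 1:G), ids))
  samples <- tibble::tibble(sample_id = ids,
                            batch = rep(c("b1", "b2"), each = nb))
  b2 <- (nb + 1):(2 * nb)

  # single batch -> identity
  s1 <- tibble::tibble(sample_id = ids, batch = "b1")
  expect_equal(unclass(batch_adjust(as_vst(y), s1)), y, ignore_attr = TRUE)

  # planted per-gene mean shift of 2
  y_shift <- y
  y_shift[, b2] <- y_shift[, b2] + rnorm(G, 2, 0.3)
  adj <- batch_adjust(as_vst(y_shift), samples)
  delta_post <- rowMeans(unclass(adj)[, b2]) - rowMeans(unclass(adj)[, -b2])
  expect_lt(mean(abs(delta_post)), 0.1)

  # planted scale factor 3 on batch 2
  y_scale <- y
  y_scale[, b2] <- (y_scale[, b2] - rowMeans(y_scale[, b2])) * 3 +
    rowMeans(y_scale[, b2])
  adj3 <- batch_adjust(as_vst(y_scale), samples)
  ratio <- apply(unclass(adj3)[, b2], 1, var) / apply(unclass(adj3)[, -b2], 1, var)
  expect_gt(mean(ratio), 0.8)
  expect_lt(mean(ratio), 1.25)

  # contraction: a second pass moves values an order of magnitude less than
  # the first pass did
  first_change <- sqrt(mean((unclass(adj) - y_shift)^2))
  second_change <- sqrt(mean((unclass(batch_adjust(adj, samples)) -
                              unclass(adj))^2))
  expect_lt(second_change, first_change / 10)

  # a singleton batch cannot be scale-adjusted
  bad <- tibble::tibble(sample_id = ids,
                        batch = c(rep("b1", 2 * nb - 1), "b3"))
  expect_error(batch_adjust(as_vst(y), bad), class = "endoseq_contract_error")
})
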