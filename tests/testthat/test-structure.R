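test_that("PCA separates identical-genotype clusters on PC1", {
  g <- rbind(matrix(0L, 4, 30), matrix(2L, 4, 30))
  gm <- toy_gm(g)
  pc <- gm_pca(gm, n_axes = 2)
  s1 <- pc$scores[1:4, 1]; s2 <- pc$scores[5:8, 1]
  expect_lt(max(abs(s1 - mean(s1))), 1e-9)   # zero within-cluster variance
  expect_lt(max(abs(s2 - mean(s2))), 1e-9)
  expect_gt(abs(mean(s1) - mean(s2)), 1)
})

test_that("PCA scores are invariant to sample order up to sign", {
  set.seed(5)
  g <- matrix(sample(0:2, 10 * 80, TRUE), 10, 80)
  g[sample(length(g), 40)] <- NA
  g[, 1] <- 0L
  gm <- toy_gm(g)
  perm <- sample(10)
  p1 <- gm_pca(gm, 3)$scores
  p2 <- gm_pca(gm_subset(gm, samples = perm), 3)$scores
  for (ax in 1:3) {
    v1 <- p1[perm, ax]; v2 <- p2[, ax]
    expect_true(isTRUE(all.equal(v1, v2, tolerance = 1e-6)) ||
                  isTRUE(all.equal(v1, -v2, tolerance = 1e-6)))
  }
})

test_that("k-means on leading PCs recovers island labels", {
  sim <- simulate_dataset(sim_config(n_clusters = 3, meadows_per_cluster = 1,
                                     fst_between = 0.1, fst_within = 0,
                                     loci = 1000, ramets_per_meadow = 20,
                                     genets_per_meadow = 20,
                                     inbreeding_f = 0, beta_shape = c(2, 2),
                                     replicates_per_meadow = 0, seed = 14))
  pc <- gm_pca(sim$gm, 2)
  set.seed(1)
  km <- kmeans(pc$scores, centers = 3, nstart = 10)
  truth <- sim$sample_meta$meadow[match(sim$gm$samples,
                                        sim$sample_meta$sample)]
  expect_gte(adjusted_rand(truth, km$cluster), 0.95)
})

test_that("masked NMF finds no structure in a panmictic deme", {
  sim <- simulate_dataset(sim_config(n_clusters = 1, meadows_per_cluster = 1,
                                     loci = 400, ramets_per_meadow = 25,
                                     genets_per_meadow = 25,
                                     inbreeding_f = 0, beta_shape = c(2, 2),
                                     replicates_per_meadow = 0, seed = 15))
  anc <- ancestry_nmf(sim$gm, k_values = 1:3, n_runs = 3, seed = 2)
  expect_equal(anc$best_k, 1)
  expect_true(all(abs(rowSums(anc$Q) - 1) < 1e-8))
  ce <- anc$mean_cross_entropy
  expect_gte(ce[["2"]], ce[["1"]] - 0.02)
})

test_that("masked NMF recovers two-island memberships", {
  sim <- simulate_dataset(sim_config(n_clusters = 2, meadows_per_cluster = 1,
                                     fst_between = 0.1, fst_within = 0,
                                     loci = 1000, ramets_per_meadow = 25,
                                     genets_per_meadow = 25,
                                     inbreeding_f = 0, beta_shape = c(2, 2),
                                     replicates_per_meadow = 0, seed = 16))
  anc <- ancestry_nmf(sim$gm, k_values = 2, n_runs = 3, seed = 3)
  expect_true(all(anc$Q >= -1e-12))
  expect_true(all(abs(rowSums(anc$Q) - 1) < 1e-8))
  truth <- sim$sample_meta$meadow[match(rownames(anc$Q),
                                        sim$sample_meta$sample)]
  assigned <- max.col(anc$Q)
  expect_gte(adjusted_rand(truth, assigned), 0.9)
  expect_gte(mean(apply(anc$Q, 1, max)), 0.8)
})

test_that("the ALS objective decreases monotonically within tolerance", {
  sim <- simulate_dataset(sim_config(n_clusters = 2, meadows_per_cluster = 1,
                                     fst_between = 0.1, fst_within = 0,
                                     loci = 300, ramets_per_meadow = 15,
                                     genets_per_meadow = 15,
                                     inbreeding_f = 0, beta_shape = c(2, 2),
                                     replicates_per_meadow = 0, seed = 17))
  anc <- ancestry_nmf(sim$gm, k_values = 2, n_runs = 2, seed = 4)
  tr <- anc$runs[["2"]]$rmse_trace
  expect_true(all(diff(tr) <= 1e-6 * pmax(tr[-length(tr)], 1e-9)))
})

test_that("DAPC memberships are confident for separable groups", {
  set.seed(6)
  g <- rbind(matrix(sample(0:1, 6 * 60, TRUE, prob = c(.9, .1)), 6, 60),
             matrix(sample(1:2, 6 * 60, TRUE, prob = c(.1, .9)), 6, 60))
  gm <- toy_gm(g)
  grp <- rep(c("A", "B"), each = 6)
  dp <- dapc_memberships(gm, grp, n_pc = 2)
  own <- mapply(function(i, gl) dp$membership[i, gl], seq_len(12), grp)
  expect_true(all(own > 0.99))
  expect_identical(dp$assigned, grp)
  expect_error(dapc_memberships(gm, grp, n_pc = 12), "smaller")
})

test_that("meadow assignment flags conflicts and ties", {
  Q <- rbind(c(.9, .1), c(.8, .2), c(.2, .8), c(.3, .7), c(.5, .5))
  rownames(Q) <- paste0("s", 1:5)
  colnames(Q) <- c("C1", "C2")
  meta <- data.frame(sample = paste0("s", 1:5),
                     meadow = c("A", "A", "B", "B", "T"))
  out <- assign_meadows(Q, meta)
  expect_equal(out$label[out$meadow == "A"], "C1")
  expect_equal(out$label[out$meadow == "B"], "C2")
  expect_true(out$tie[out$meadow == "T"])
  expect_true(is.na(out$label[out$meadow == "T"]))

  out2 <- assign_meadows(Q, meta,
                         second_labels = c(A = "C2", B = "C2", T = "C1"))
  expect_true(out2$conflict[out2$meadow == "A"])
  expect_true(is.na(out2$label[out2$meadow == "A"]))
  expect_equal(out2$label[out2$meadow == "B"], "C2")
})
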