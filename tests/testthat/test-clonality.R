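test_that("pairwise distances match hand counts and a brute-force oracle", {
  # identical genotypes -> 0; full mismatch at a single locus -> bitwise 1
  gm1 <- toy_gm(rbind(c(0, 2), c(0, 2)))
  expect_equal(unname(pairwise_distance(gm1)$d[1, 2]), 0)
  gm2 <- toy_gm(matrix(c(0L, 2L), 2, 1))
  expect_equal(unname(pairwise_distance(gm2)$d[1, 2]), 1)
  expect_equal(unname(pairwise_distance(gm2, "euclidean")$d[1, 2]), 2)

  # 100 loci, two het/hom single-allele mismatches -> bitwise 0.01
  a <- rep(0L, 100); b <- a; b[c(10, 60)] <- 1L
  gm3 <- toy_gm(rbind(a, b))
  expect_equal(unname(pairwise_distance(gm3)$d[1, 2]), 0.01)

  # random matrix with missingness: vectorized path equals explicit loops
  set.seed(42)
  g <- matrix(sample(c(0L, 1L, 2L, NA), 60, TRUE,
                     prob = c(.4, .2, .3, .1)), 5, 12)
  g[, 1] <- 0L  # guarantee shared loci for all pairs
  gm4 <- toy_gm(g)
  for (metric in c("bitwise", "euclidean")) {
    fast <- pairwise_distance(gm4, metric)$d
    expect_equal(fast, brute_distance(gm4, metric), tolerance = 1e-12)
  }
})

test_that("zero shared loci raises an error naming the pair", {
  g <- rbind(c(0L, NA), c(NA, 1L), c(0L, 1L))
  expect_error(pairwise_distance(toy_gm(g)), "share no called loci")
})

test_that("threshold lands in the clone/non-clone gap and degenerate input errors", {
  set.seed(7)
  # two tight clone pairs among unrelated samples
  base <- matrix(sample(0:2, 8 * 200, TRUE), 8, 200)
  base[2, ] <- base[1, ]; base[2, 1:2] <- 2 - base[2, 1:2]   # near-clone
  base[4, ] <- base[3, ]; base[4, 3] <- 1L
  gm <- toy_gm(base, rad_tag = paste0("t", 1:200))
  d <- pairwise_distance(gm)
  thr <- predict_threshold(d, "average")
  clone_d <- max(d$d[1, 2], d$d[3, 4])
  other <- min(d$d[upper.tri(d$d)][d$d[upper.tri(d$d)] > clone_d])
  expect_gt(thr$threshold, clone_d)
  expect_lt(thr$threshold, other)

  same <- toy_gm(matrix(1L, 4, 5))
  expect_error(predict_threshold(pairwise_distance(same)),
               "no clone/non-clone gap")
  expect_error(predict_threshold(pairwise_distance(toy_gm(rbind(c(0, 1),
                                                                c(1, 0))))),
               "too few")
})

test_that("replicate validation passes below and fails above the threshold", {
  d <- structure(list(d = matrix(c(0, .002, .2, .002, 0, .2, .2, .2, 0), 3,
                                 dimnames = list(c("a", "a_r", "b"),
                                                 c("a", "a_r", "b"))),
                      metric = "bitwise"), class = "distance_matrix")
  meta <- data.frame(sample = c("a", "a_r", "b"), meadow = "M",
                     replicate_group = c("g1", "g1", "g2"))
  ok <- validate_with_replicates(d, meta, 0.01)
  expect_true(ok$passed)
  expect_equal(ok$max_replicate_distance, 0.002)
  bad <- validate_with_replicates(d, meta, 0.001)
  expect_false(bad$passed)
  expect_equal(bad$failing_pairs$sample1, "a")
  norep <- data.frame(sample = c("a", "a_r", "b"), meadow = "M",
                      replicate_group = c("g1", "g2", "g3"))
  expect_warning(validate_with_replicates(d, norep, 0.01), "no technical")
})

test_that("MLL assignment is deterministic and handles the no-clone case", {
  set.seed(3)
  g <- matrix(sample(0:2, 6 * 300, TRUE), 6, 300)
  gm <- toy_gm(g)
  d <- pairwise_distance(gm)
  mll <- assign_mll(d, 1e-6)   # below every distance -> all singletons
  expect_equal(mll$n_mll, 6)
  expect_identical(unname(mll$mll), gm$samples)  # named by smallest member
})

test_that("MLL partition is invariant to metric and linkage on separated data", {
  sim <- simulate_dataset(sim_config(n_clusters = 1, meadows_per_cluster = 3,
                                     loci = 1500, ramets_per_meadow = 12,
                                     genets_per_meadow = 6, seed = 31))
  parts <- list()
  for (metric in c("bitwise", "euclidean"))
    for (linkage in c("single", "average", "complete")) {
      d <- pairwise_distance(sim$gm, metric)
      thr <- predict_threshold(d, linkage)
      parts[[paste(metric, linkage)]] <- assign_mll(d, thr$threshold,
                                                    linkage)$mll
    }
  ref <- parts[[1]]
  for (p in parts[-1])
    expect_equal(adjusted_rand(ref, p[names(ref)]), 1)
  expect_equal(length(unique(ref)), length(unique(sim$truth$genet)))
})

test_that("clone correction keeps one genotype per MLL per meadow", {
  # 3 meadows: M1 monoclonal, M2 no clones, one MLL spans M2 and M3;
  # sample a2r is a technical replicate of a2
  ids <- c("a1", "a2", "a2r", "b1", "b2", "c1")
  mll_ids <- c("a1", "a1", "a1", "b1", "shared", "shared")
  meta <- data.frame(sample = ids,
                     meadow = c("M1", "M1", "M1", "M2", "M2", "M3"),
                     replicate_group = c("a1", "a2", "a2", "b1", "b2", "c1"),
                     stringsAsFactors = FALSE)
  g <- matrix(0L, 6, 4); g[5, 1] <- NA  # b2 has worse missingness than c1
  gm <- toy_gm(g, samples = ids)
  mll <- structure(list(mll = setNames(mll_ids, ids), threshold = .1,
                        linkage = "average", n_mll = 3),
                   class = "mll_assignment")
  cc <- clone_correct(gm, mll, meta)
  # M1 collapses to one sample; the shared MLL keeps one sample in each
  # of M2 and M3; replicate a2r never survives
  expect_setequal(cc$samples, c("a1", "b1", "b2", "c1"))
})

test_that("per-meadow counts never grow under clone correction", {
  sim <- simulate_dataset(sim_config(n_clusters = 1, meadows_per_cluster = 2,
                                     loci = 400, ramets_per_meadow = 10,
                                     genets_per_meadow = 5, seed = 9))
  d <- pairwise_distance(sim$gm)
  mll <- assign_mll(d, predict_threshold(d)$threshold)
  cc <- clone_correct(sim$gm, mll, sim$sample_meta)
  before <- table(sim$sample_meta$meadow)
  after <- table(sim$sample_meta$meadow[match(cc$samples,
                                              sim$sample_meta$sample)])
  expect_true(all(after <= before[names(after)]))
})
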