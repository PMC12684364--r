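test_that("theta is near zero under the null and invariant to allele relabelling", {
  set.seed(8)
  p <- runif(1000, 0.2, 0.8)
  # two pops of 2 samples drawn from one frequency vector
  g <- matrix(rbinom(4 * 1000, 2, rep(p, each = 4)), 4)
  lab <- c("A", "A", "B", "B")
  th <- wc_theta(g, lab)
  expect_lt(abs(th), 0.02)

  # swapping ref/alt at every locus leaves theta unchanged
  th_flip <- wc_theta(2L - g, lab)
  expect_equal(th, th_flip, tolerance = 1e-12)
})

test_that("theta recovers the Balding-Nichols simulation target", {
  cfg <- sim_config(n_clusters = 2, meadows_per_cluster = 1,
                    fst_between = 0.05, fst_within = 0, loci = 5000,
                    ramets_per_meadow = 50, genets_per_meadow = 50,
                    inbreeding_f = 0, genotyping_error = 0,
                    missing_rate = 0, replicates_per_meadow = 0,
                    beta_shape = c(2, 2), seed = 101)
  sim <- simulate_dataset(cfg)
  meadow <- sim$sample_meta$meadow[match(sim$gm$samples,
                                         sim$sample_meta$sample)]
  th <- wc_theta(sim$gm$geno, meadow)
  expect_gt(th, 0.03)
  expect_lt(th, 0.07)
})

test_that("pairwise FST reports sensible permutation p and monotone q", {
  sim <- simulate_dataset(sim_config(n_clusters = 3, meadows_per_cluster = 1,
                                     fst_between = 0.08, fst_within = 0,
                                     loci = 400, ramets_per_meadow = 12,
                                     genets_per_meadow = 12,
                                     inbreeding_f = 0, beta_shape = c(2, 2),
                                     replicates_per_meadow = 0, seed = 22))
  fst <- pairwise_fst(sim$gm, sim$sample_meta, n_perm = 99, seed = 1)
  expect_true(isSymmetric(fst$theta))
  expect_true(all(diag(fst$theta) == 0))
  up <- upper.tri(fst$theta)
  expect_true(all(fst$theta[up] > 0))
  expect_true(all(fst$p[up] <= 0.05))       # strong divergence detected
  expect_true(all(fst$q[up] >= fst$p[up] - 1e-12))
})

test_that("AMOVA components sum to the total and recover simulated shares", {
  # oracle identity on a tiny fixture: SS terms reconcile exactly
  g <- rbind(c(0, 0, 1), c(0, 1, 1), c(2, 2, 1), c(2, 1, 1),
             c(1, 1, 0), c(1, 0, 0))
  gm <- toy_gm(g)
  meta <- data.frame(sample = gm$samples,
                     meadow = rep(c("m1", "m2", "m3"), each = 2),
                     replicate_group = gm$samples)
  am <- amova(gm, meta, c(m1 = "X", m2 = "X", m3 = "Y"), n_perm = 0)
  expect_equal(unname(am$ss["total"]),
               unname(sum(am$ss[c("among_clusters", "among_meadows",
                                  "within_meadows")])))
  expect_true(all(am$phi >= -1 & am$phi <= 1, na.rm = TRUE))

  # structured simulation: among-cluster share dominates the null
  sim <- simulate_dataset(sim_config(n_clusters = 3, meadows_per_cluster = 2,
                                     fst_between = 0.10, fst_within = 0.01,
                                     loci = 600, ramets_per_meadow = 10,
                                     genets_per_meadow = 10,
                                     inbreeding_f = 0, beta_shape = c(2, 2),
                                     replicates_per_meadow = 0,
                                     missing_rate = 0, seed = 23))
  am2 <- amova(sim$gm, sim$sample_meta, sim$truth$cluster, n_perm = 99,
               seed = 2)
  shares <- am2$sigma2 / sum(am2$sigma2)
  expect_gt(shares[["a"]], shares[["b"]])
  expect_lt(am2$p[["phi_st"]], 0.05)
  expect_equal(unname(am2$ss["total"]), unname(sum(am2$ss[1:3])))
})

test_that("waterway distances detour around land and match the grid oracle", {
  lat <- seq(58.04, 58.00, length.out = 5)
  lon <- seq(11.00, 11.06, length.out = 7)
  open <- list(sea = matrix(TRUE, 5, 7), lat = lat, lon = lon)
  coords <- data.frame(code = c("A", "B"), lat = c(58.04, 58.04),
                       lon = c(11.00, 11.06))
  straight <- geosphere::distHaversine(c(11.00, 58.04),
                                       c(11.06, 58.04)) / 1000
  d_open <- waterway_distance(coords, open)
  expect_lt(abs(d_open$km["A", "B"] - straight), straight * 0.05)

  # wall across column 4, open only at the southern row: forced detour
  wall <- open
  wall$sea[1:4, 4] <- FALSE
  d_wall <- waterway_distance(coords, wall)
  expect_gt(d_wall$km["A", "B"], straight)
  oracle <- oracle_grid_distance(wall$sea, lat, lon, c(1, 1), c(1, 7))
  expect_equal(unname(d_wall$km["A", "B"]), oracle, tolerance = 1e-9)

  # a point on land is snapped into the water and logged
  onland <- wall
  onland$sea[3, 2] <- FALSE
  coords2 <- data.frame(code = "L", lat = lat[3], lon = lon[2])
  snap <- waterway_distance(rbind(coords, coords2), onland)
  expect_true(snap$snapped$moved[snap$snapped$code == "L"])

  # disconnected basins raise an error naming the pair
  split <- open
  split$sea[, 4] <- FALSE
  expect_error(waterway_distance(coords, split), "disconnected|isolated")
})

test_that("Mantel IBD finds perfect association and rejects mismatched order", {
  set.seed(9)
  km <- matrix(0, 5, 5, dimnames = list(LETTERS[1:5], LETTERS[1:5]))
  km[upper.tri(km)] <- runif(10, 10, 200)
  km <- km + t(km)
  fst <- km / (km + 1000)   # monotone transform: fst/(1-fst) linear in km
  # the fixture is exactly linear, so lm warns about a perfect fit
  out <- suppressWarnings(mantel_ibd(fst, km, n_perm = 199, seed = 1))
  expect_gt(out$r, 0.99)
  expect_lt(out$p, 0.05)
  expect_gt(out$r_squared, 0.9)

  km2 <- km[c(2:5, 1), c(2:5, 1)]
  expect_error(mantel_ibd(fst, km2), "identical unit order")
})
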