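test_that("ld_ne handles boundary cases and guards under-powered input", {
  wf <- simulate_wf_ld(ne = 500, generations = 4, sample_size = 40,
                       loci = 400, seed = 51)
  small <- gm_subset(wf$gm, samples = 1:5)
  expect_error(ld_ne(small), "under-powered")
  expect_error(ld_ne(wf$gm, min_loci = 1e5), "under-powered")

  one_chr <- wf$gm
  one_chr$loci$chrom <- "chr1"
  expect_error(ld_ne(one_chr), "2 chromosomes")
})

test_that("ld_ne is invariant to locus order", {
  wf <- simulate_wf_ld(ne = 100, generations = 10, sample_size = 40,
                       loci = 600, seed = 52)
  e1 <- ld_ne(wf$gm)
  # positions must stay increasing within chromosomes, so reorder whole
  # chromosomes instead of single loci
  ord <- order(match(wf$gm$loci$chrom,
                     rev(unique(wf$gm$loci$chrom))),
               wf$gm$loci$pos)
  gm3 <- genotype_matrix(wf$gm$geno[, ord], wf$gm$samples,
                         wf$gm$loci[ord, ])
  e3 <- ld_ne(gm3)
  expect_equal(e1$ne, e3$ne, tolerance = 1e-9)
  expect_equal(e1$r2_drift, e3$r2_drift, tolerance = 1e-12)
})

test_that("a very large population yields a near-zero drift signal", {
  wf <- simulate_wf_ld(ne = 5000, generations = 3, sample_size = 50,
                       loci = 800, seed = 53)
  est <- ld_ne(wf$gm)
  expect_lt(abs(est$r2_drift), 5e-3)
  expect_gt(est$ne, 500)   # large or Inf-flagged
})

test_that("Ne/Nc ratios follow the hectare conversion", {
  out <- ne_nc(754, 31.6, 55)
  expect_equal(out$nc, 31.6 * 1e4 * 55)
  expect_equal(out$ne_nc, 754 / (31.6 * 1e4 * 55), tolerance = 1e-12)
  expect_equal(round(out$ne_nc, 7), 4.34e-05, tolerance = 1e-7)
  expect_true(out$ne_nc > 1e-6 && out$ne_nc < 9.18e-4)

  with_r <- ne_nc(754, 31.6, 55, richness = 1)
  expect_equal(with_r$ne_nc_mll, with_r$ne_nc)
  half <- ne_nc(754, 31.6, 55, richness = 0.5)
  expect_equal(half$ne_nc_mll, 2 * half$ne_nc)

  na_out <- ne_nc(754, NA)
  expect_true(is.na(na_out$nc) && is.na(na_out$ne_nc))
  expect_error(ne_nc(754, -1), "positive")
})

test_that("the Ne>500 indicator counts exceedances in both modes", {
  ne <- c(754, rep(100, 17))
  expect_equal(round(indicator_ne500(ne, "point"), 2), 0.06)
  expect_equal(indicator_ne500(rep(1000, 4), "point"), 1)
  expect_equal(indicator_ne500(rep(10, 5), "point"), 0)
  expect_error(indicator_ne500(numeric(0)), "no units")

  ests <- list(
    structure(list(ne = 400, ci_low = 200, ci_high = 700), class = "ne_estimate"),
    structure(list(ne = 600, ci_low = 450, ci_high = 900), class = "ne_estimate"),
    structure(list(ne = 100, ci_low = 50, ci_high = 200), class = "ne_estimate"))
  expect_equal(indicator_ne500(ests, "point"), 1 / 3)
  expect_equal(indicator_ne500(ests, "ci_overlap"), 2 / 3)
  # point mode can never exceed CI-overlap mode
  expect_lte(indicator_ne500(ests, "point"),
             indicator_ne500(ests, "ci_overlap"))
})

test_that("populations-maintained indicator applies the loss threshold", {
  changes <- c(rep(-99.5, 18), runif(146, -90, 20))
  expect_equal(round(indicator_pm(changes), 2), 0.89)
  expect_equal(indicator_pm(rep(10, 5)), 1)
  expect_equal(indicator_pm(rep(-100, 5)), 0)
  expect_error(indicator_pm(numeric(0)), "no units")
  # lowering the loss threshold can only lower PM
  expect_lte(indicator_pm(changes, 0.90), indicator_pm(changes, 0.99))
})

test_that("correlations with areal change behave for known relationships", {
  mm <- data.frame(code = sprintf("M%02d", 1:10),
                   areal_change_pct = seq(-90, 0, 10))
  lin <- data.frame(meadow = mm$code, linear = 2 * mm$areal_change_pct + 1,
                    curved = exp(mm$areal_change_pct / 30))
  out <- correlate_with_change(lin, mm)
  expect_equal(out$pearson_r[out$metric == "linear"], 1, tolerance = 1e-12)
  expect_equal(out$spearman_rho[out$metric == "curved"], 1,
               tolerance = 1e-12)
  expect_lt(out$pearson_r[out$metric == "curved"], 1)

  few <- correlate_with_change(lin[1:3, ], mm)
  expect_true(all(is.na(few$pearson_r)))
})

test_that("built-in inbreeding/areal-change correlation is recoverable", {
  hits <- 0
  for (s in 1:10) {
    set.seed(s)
    sim <- simulate_dataset(sim_config(
      n_clusters = 1, meadows_per_cluster = 18, loci = 50,
      ramets_per_meadow = 4, genets_per_meadow = 4,
      inbreeding_f = runif(18, 0.4, 0.95), areal_change_cor_f = -0.7,
      replicates_per_meadow = 0, seed = 400 + s))
    met <- data.frame(meadow = names(sim$truth$realized_f),
                      f = unname(sim$truth$realized_f))
    out <- correlate_with_change(met, sim$meadow_meta)
    if (out$pearson_r[out$metric == "f"] < 0 &&
        out$pearson_p[out$metric == "f"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 8)
})
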