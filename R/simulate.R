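#' Configuration for the synthetic regional dataset
#'
#' Defaults emulate the statistical structure of a northern-European
#' eelgrass survey: 18 meadows in 5 genetic clusters, moderate
#' between-cluster divergence (Balding-Nichols FST 0.10 with 0.02 within
#' clusters), a rare-allele-heavy ancestral frequency spectrum combined
#' with high autozygosity (F = 0.75) giving per-site observed
#' heterozygosity around 0.025, partial clonality (13 genets behind 20
#' sampled shoots per meadow), two technical replicates per meadow, a 0.5\%
#' genotyping error rate and a 1e-4 per-locus somatic mutation rate.
#' Autozygous tracts have exponentially distributed lengths (mean 2 Mb) on
#' a 6 x 40 Mb genome. Areal change per meadow is drawn normal with a
#' target correlation of -0.7 to the meadow inbreeding level.
#'
#' @param n_clusters number of genetic clusters.
#' @param meadows_per_cluster integer vector (recycled) of meadows per
#'   cluster.
#' @param fst_between,fst_within Balding-Nichols FST at the two levels.
#' @param loci number of SNPs.
#' @param chromosomes named numeric vector of chromosome lengths in bp.
#' @param beta_shape length-2 shape of the ancestral allele-frequency beta.
#' @param ramets_per_meadow shoots sampled per meadow.
#' @param genets_per_meadow genets (true clones) per meadow; scalar or
#'   vector over meadows.
#' @param somatic_rate per-locus somatic mutation probability per ramet.
#' @param genotyping_error per-call probability that a genotype is re-called
#'   from the meadow allele frequency.
#' @param replicates_per_meadow technical replicates per meadow.
#' @param inbreeding_f autozygosity fraction per meadow; scalar or vector.
#' @param tract_mean_bp mean autozygous tract length.
#' @param missing_rate per-call missing probability.
#' @param areal_change_mean,areal_change_sd areal change (\%) distribution.
#' @param areal_change_cor_f target correlation between areal change and
#'   meadow inbreeding (negative: declining areas more inbred).
#' @param seed integer seed (mandatory).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clusters = 5,
                       meadows_per_cluster = c(4, 2, 2, 2, 8),
                       fst_between = 0.10, fst_within = 0.02,
                       loci = 2000,
                       chromosomes = stats::setNames(rep(4e7, 6),
                                                     paste0("chr", 1:6)),
                       beta_shape = c(0.2, 2.3),
                       ramets_per_meadow = 20, genets_per_meadow = 13,
                       somatic_rate = 1e-4, genotyping_error = 0.005,
                       replicates_per_meadow = 2,
                       inbreeding_f = 0.75, tract_mean_bp = 2e6,
                       missing_rate = 0.02,
                       areal_change_mean = -45, areal_change_sd = 30,
                       areal_change_cor_f = -0.7,
                       seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  mpc <- rep_len(meadows_per_cluster, n_clusters)
  n_meadows <- sum(mpc)
  gpm <- rep_len(genets_per_meadow, n_meadows)
  fvec <- rep_len(inbreeding_f, n_meadows)
  rates <- c(fst_between, fst_within, somatic_rate, genotyping_error,
             missing_rate, fvec)
  if (any(rates < 0 | rates >= 1) || fst_between <= 0)
    stop("rates must lie in [0, 1) and fst_between in (0, 1)", call. = FALSE)
  if (any(gpm > ramets_per_meadow))
    stop("more genets than ramets in a meadow", call. = FALSE)
  if (any(gpm < 1)) stop("each meadow needs at least one genet",
                         call. = FALSE)
  structure(list(n_clusters = n_clusters, meadows_per_cluster = mpc,
                 fst_between = fst_between, fst_within = fst_within,
                 loci = loci, chromosomes = chromosomes,
                 beta_shape = beta_shape,
                 ramets_per_meadow = ramets_per_meadow,
                 genets_per_meadow = gpm, somatic_rate = somatic_rate,
                 genotyping_error = genotyping_error,
                 replicates_per_meadow = replicates_per_meadow,
                 inbreeding_f = fvec, tract_mean_bp = tract_mean_bp,
                 missing_rate = missing_rate,
                 areal_change_mean = areal_change_mean,
                 areal_change_sd = areal_change_sd,
                 areal_change_cor_f = areal_change_cor_f,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Expected observed heterozygosity under a configuration
#'
#' Analytic expectation of per-site Ho:
#' `2 E[pq] * (1 - FST_total) * (1 - F)` with `E[pq]` from the ancestral
#' beta and `FST_total = fst_between + (1 - fst_between) * fst_within`.
#'
#' @param config a [sim_config()].
#' @return Expected Ho (scalar, using the mean of per-meadow F).
#' @export
expected_ho <- function(config) {
  a <- config$beta_shape[1]; b <- config$beta_shape[2]
  epq <- a * b / ((a + b) * (a + b + 1))
  fst_tot <- config$fst_between + (1 - config$fst_between) * config$fst_within
  2 * epq * (1 - fst_tot) * (1 - mean(config$inbreeding_f))
}

# Balding-Nichols draw of subpopulation frequencies around p with given FST
bn_draw <- function(p, fst) {
  if (fst <= 0) return(p)
  shape1 <- p * (1 - fst) / fst
  shape2 <- (1 - p) * (1 - fst) / fst
  q <- stats::rbeta(length(p), shape1, shape2)
  pmin(pmax(q, 1e-6), 1 - 1e-6)
}

# exponential-tract tiling of one chromosome: returns matrix of autozygous
# intervals [start, end] covering ~fraction f
draw_tracts <- function(chrom_len, f, mean_bp) {
  if (f <= 0) return(matrix(numeric(0), ncol = 2))
  if (f >= 1) return(matrix(c(1, chrom_len), ncol = 2))
  gap_mean <- mean_bp * (1 - f) / f
  pos <- if (stats::runif(1) < f) 0 else stats::rexp(1, 1 / gap_mean)
  out <- NULL
  while (pos < chrom_len) {
    len <- stats::rexp(1, 1 / mean_bp)
    s <- pos + 1; e <- min(pos + len, chrom_len)
    if (e >= s) out <- rbind(out, c(s, e))
    pos <- e + stats::rexp(1, 1 / gap_mean)
  }
  if (is.null(out)) matrix(numeric(0), ncol = 2) else out
}

#' Simulate a regional clonal SNP dataset with ground truth
#'
#' Generates, under a [sim_config()]: cluster and meadow allele frequencies
#' by nested Balding-Nichols draws; genet genotypes with autozygous tracts
#' forced homozygous; ramets copying their genet with somatic mutations;
#' technical replicates re-called with genotyping error only; missing calls
#' at the configured rate. Everything is deterministic under the seed.
#'
#' @param config a [sim_config()].
#' @return A list: `gm` (the [genotype_matrix()]), `sample_meta`,
#'   `meadow_meta`, `truth` (list: `genet` sample -> genet id, `cluster`
#'   meadow -> cluster, `realized_f`, `realized_richness`, `tracts`
#'   per-genet autozygous intervals, `meadow_freq` loci x meadows).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$loci
  chrom_len <- config$chromosomes
  n_chr <- length(chrom_len)

  # locus map: loci spread over chromosomes proportionally to length
  n_per_chr <- round(L * chrom_len / sum(chrom_len))
  n_per_chr[n_chr] <- L - sum(n_per_chr[-n_chr])
  loci <- do.call(rbind, lapply(seq_len(n_chr), function(ci) {
    pos <- sort(sample.int(chrom_len[ci], n_per_chr[ci]))
    data.frame(chrom = names(chrom_len)[ci], pos = pos, ref = "A",
               alt = "G", rad_tag = paste0(names(chrom_len)[ci], "_",
                                           seq_along(pos)),
               stringsAsFactors = FALSE)
  }))

  p_anc <- stats::rbeta(L, config$beta_shape[1], config$beta_shape[2])
  p_anc <- pmin(pmax(p_anc, 1e-4), 1 - 1e-4)

  mpc <- config$meadows_per_cluster
  n_meadows <- sum(mpc)
  meadow_codes <- sprintf("M%02d", seq_len(n_meadows))
  cluster_of <- rep(paste0("C", seq_along(mpc)), mpc)

  geno <- NULL; samples <- character(0)
  sample_meta <- NULL
  truth_genet <- character(0)
  tracts <- list()
  realized_f <- numeric(n_meadows)
  realized_richness <- numeric(n_meadows)
  meadow_freq <- matrix(NA_real_, L, n_meadows,
                        dimnames = list(NULL, meadow_codes))

  cluster_freq <- lapply(seq_along(mpc), function(k)
    bn_draw(p_anc, config$fst_between))

  mi <- 0
  for (k in seq_along(mpc)) for (m in seq_len(mpc[k])) {
    mi <- mi + 1
    code <- meadow_codes[mi]
    p_m <- bn_draw(cluster_freq[[k]], config$fst_within)
    meadow_freq[, mi] <- p_m
    G <- config$genets_per_meadow[mi]
    Rn <- config$ramets_per_meadow
    f_m <- config$inbreeding_f[mi]

    # genet genotypes: HWE draws, then autozygous tracts forced homozygous
    genet_geno <- matrix(stats::rbinom(G * L, 1, rep(p_m, each = G)) +
                           stats::rbinom(G * L, 1, rep(p_m, each = G)),
                         nrow = G, byrow = FALSE)
    f_real <- numeric(G)
    for (gi in seq_len(G)) {
      gid <- paste0(code, "_g", gi)
      auto <- logical(L)
      trl <- list()
      for (ci in seq_len(n_chr)) {
        tr <- draw_tracts(chrom_len[ci], f_m, config$tract_mean_bp)
        if (nrow(tr)) {
          on_chr <- loci$chrom == names(chrom_len)[ci]
          pos <- loci$pos
          for (ti in seq_len(nrow(tr)))
            auto <- auto | (on_chr & pos >= tr[ti, 1] & pos <= tr[ti, 2])
          trl[[names(chrom_len)[ci]]] <-
            data.frame(chrom = names(chrom_len)[ci], start = tr[, 1],
                       end = tr[, 2])
        }
      }
      tracts[[gid]] <- if (length(trl)) do.call(rbind, trl) else
        data.frame(chrom = character(), start = numeric(), end = numeric())
      f_real[gi] <- sum(vapply(trl, function(d) sum(d$end - d$start + 1),
                               numeric(1))) / sum(chrom_len)
      if (any(auto))
        genet_geno[gi, auto] <- 2L * stats::rbinom(sum(auto), 1, p_m[auto])
    }
    realized_f[mi] <- mean(f_real)

    # ramets: every genet sampled at least once, remainder uniform
    genet_of_ramet <- c(seq_len(G),
                        if (Rn > G) sample.int(G, Rn - G, replace = TRUE))
    genet_of_ramet <- sample(genet_of_ramet)  # shuffle order
    realized_richness[mi] <- (length(unique(genet_of_ramet)) - 1) / (Rn - 1)

    ramet_geno <- genet_geno[genet_of_ramet, , drop = FALSE]
    # somatic mutations: single allele resampled at mutated loci
    mut <- matrix(stats::runif(Rn * L) < config$somatic_rate, Rn, L)
    if (any(mut)) {
      idx <- which(mut)
      cur <- ramet_geno[idx]
      shift <- ifelse(cur == 0L, 1L, ifelse(cur == 2L, -1L,
                                            sample(c(-1L, 1L), length(cur),
                                                   replace = TRUE)))
      ramet_geno[idx] <- cur + shift
    }

    emit_call <- function(g) {
      # genotyping error: re-call from meadow frequency
      err <- stats::runif(L) < config$genotyping_error
      if (any(err))
        g[err] <- stats::rbinom(sum(err), 1, p_m[err]) +
          stats::rbinom(sum(err), 1, p_m[err])
      g[stats::runif(L) < config$missing_rate] <- NA_integer_
      as.integer(g)
    }
    ramet_ids <- sprintf("%s_%02d", code, seq_len(Rn))
    obs <- t(vapply(seq_len(Rn), function(ri) emit_call(ramet_geno[ri, ]),
                    integer(L)))
    rep_n <- min(config$replicates_per_meadow, Rn)
    rep_ids <- if (rep_n > 0) paste0(ramet_ids[seq_len(rep_n)], "r") else
      character(0)
    rep_obs <- if (rep_n > 0)
      t(vapply(seq_len(rep_n), function(ri) emit_call(ramet_geno[ri, ]),
               integer(L))) else NULL

    geno <- rbind(geno, obs, rep_obs)
    samples <- c(samples, ramet_ids, rep_ids)
    truth_genet <- c(truth_genet,
                     paste0(code, "_g", genet_of_ramet),
                     if (rep_n > 0) paste0(code, "_g",
                                           genet_of_ramet[seq_len(rep_n)]))
    lat0 <- 59 - 0.1 * mi
    sample_meta <- rbind(sample_meta, data.frame(
      sample = c(ramet_ids, rep_ids), meadow = code,
      replicate_group = c(ramet_ids, ramet_ids[seq_len(rep_n)]),
      lat = lat0, lon = 11.2 + 0.02 * (mi %% 4), stringsAsFactors = FALSE))
  }

  gm <- genotype_matrix(geno, samples, loci)

  # meadow metadata: areal change correlated with realized inbreeding
  rho <- config$areal_change_cor_f
  zf <- as.numeric(scale(realized_f))
  if (any(!is.finite(zf))) zf <- rep(0, n_meadows)
  z <- rho * zf + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_meadows)
  areal <- config$areal_change_mean + config$areal_change_sd * z
  size_ha <- round(exp(stats::rnorm(n_meadows, log(15), 1)), 1)
  meadow_meta <- data.frame(
    code = meadow_codes,
    size_ha = size_ha,
    impact = rep(c("impacted", "reference"), length.out = n_meadows),
    cluster = cluster_of,
    areal_change_pct = round(areal, 1),
    waterbody = paste0("WB_", cluster_of),
    stringsAsFactors = FALSE)
  meadow_meta$size_class <- ifelse(meadow_meta$size_ha < 20, "small",
                                   "large")

  names(truth_genet) <- samples
  list(gm = gm, sample_meta = sample_meta, meadow_meta = meadow_meta,
       truth = list(genet = truth_genet,
                    cluster = stats::setNames(cluster_of, meadow_codes),
                    realized_f = stats::setNames(realized_f, meadow_codes),
                    realized_richness = stats::setNames(realized_richness,
                                                        meadow_codes),
                    tracts = tracts, meadow_freq = meadow_freq))
}

#' Simulate Wright-Fisher genotypes for LD-based Ne recovery
#'
#' Discrete-generation Wright-Fisher reproduction of `ne` diploids from
#' beta-distributed starting allele frequencies, with unlinked loci
#' assigned to chromosomes round-robin; a sample of the final generation is
#' returned. Mating is random union of gametes from two parents drawn with
#' replacement.
#'
#' @param ne effective (census) population size, >= 2.
#' @param generations number of generations (default 20, enough for the
#'   drift LD of unlinked loci to equilibrate).
#' @param sample_size individuals sampled from the final generation.
#' @param loci number of loci.
#' @param n_chromosomes chromosomes to spread loci over (default 6).
#' @param seed integer seed.
#' @param beta_shape starting-frequency beta shape (default `c(2, 2)`).
#' @return A list: `gm` (a [genotype_matrix()]), `truth` (list with `ne`,
#'   `generations`).
#' @export
simulate_wf_ld <- function(ne, generations = 20, sample_size = 50,
                           loci = 2000, n_chromosomes = 6, seed,
                           beta_shape = c(2, 2)) {
  if (ne < 2) stop("ne must be >= 2", call. = FALSE)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  set.seed(as.integer(seed))
  p0 <- stats::rbeta(loci, beta_shape[1], beta_shape[2])
  p0 <- pmin(pmax(p0, 0.02), 0.98)
  pop <- matrix(stats::rbinom(ne * loci, 1, rep(p0, each = ne)) +
                  stats::rbinom(ne * loci, 1, rep(p0, each = ne)),
                nrow = ne)
  for (g in seq_len(generations)) {
    mothers <- sample.int(ne, ne, replace = TRUE)
    fathers <- sample.int(ne, ne, replace = TRUE)
    gam_m <- matrix(stats::rbinom(ne * loci, 1, pop[mothers, ] / 2), ne)
    gam_f <- matrix(stats::rbinom(ne * loci, 1, pop[fathers, ] / 2), ne)
    pop <- gam_m + gam_f
  }
  take <- sample.int(ne, min(sample_size, ne))
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), length.out = loci)
  ord <- order(chrom)
  loci_df <- data.frame(chrom = chrom[ord],
                        pos = as.integer(stats::ave(seq_len(loci),
                                                    chrom[ord],
                                                    FUN = seq_along) * 1e5),
                        ref = "A", alt = "G",
                        rad_tag = paste0("wf_", seq_len(loci)),
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(pop[take, ord, drop = FALSE],
                        sprintf("wf_%03d", seq_along(take)), loci_df)
  list(gm = gm, truth = list(ne = ne, generations = generations))
}
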