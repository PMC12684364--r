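#' Genotypic richness
#'
#' `R = (nMLL - 1) / (nInd - 1)`: 1 when every sampled shoot is a distinct
#' lineage, 0 when the whole sample is one clone.
#'
#' @param n_mll number of multilocus lineages in the sample.
#' @param n_ind number of sampled individuals (ramets), `>= 2`.
#' @return Genotypic richness in `[0, 1]`.
#' @export
genotypic_richness <- function(n_mll, n_ind) {
  if (any(n_ind < 2)) stop("genotypic richness undefined for n_ind < 2",
                           call. = FALSE)
  if (any(n_mll < 1 | n_mll > n_ind))
    stop("n_mll must be in [1, n_ind]", call. = FALSE)
  (n_mll - 1) / (n_ind - 1)
}

#' Small-sample correction factor
#'
#' Multiplies a diversity statistic by `2n / (2n - 1)` where `n` is the
#' number of lineages, compensating the downward bias of plug-in estimates
#' at small sample size (the same factor that turns He into unbiased He).
#'
#' @param x statistic (vector ok).
#' @param n_mll number of MLLs behind the estimate.
#' @return Corrected statistic.
#' @export
apply_sample_correction <- function(x, n_mll) {
  if (any(n_mll < 1)) stop("n_mll must be >= 1", call. = FALSE)
  x * (2 * n_mll) / (2 * n_mll - 1)
}

#' Per-meadow genetic diversity table
#'
#' Computes, per meadow on clone-corrected data: `n_mll` (samples retained),
#' `ho` (mean observed heterozygosity over loci), `uhe` (mean unbiased
#' expected heterozygosity, `2p(1-p) * 2n/(2n-1)` per locus), `fis`
#' (`1 - mean(Ho)/mean(uHe)`, a ratio of means so near-monomorphic loci do
#' not blow up), `pol`/`upol` (count of polymorphic sites, raw and
#' sample-corrected, plus `upol_round`), `pa` (private alleles: alleles seen
#' in exactly one meadow, counted for that meadow), `pi`/`upi` (mean
#' per-site pairwise nucleotide diversity over retained sites, raw and
#' corrected). Meadows with fewer than `min_mll` lineages get `NA`
#' statistics and `computed = FALSE` (matching how a nearly monoclonal
#' meadow is excluded from diversity summaries).
#'
#' @param gm_cc clone-corrected [genotype_matrix()].
#' @param sample_meta sample metadata for the retained samples.
#' @param n_ind optional named vector of pre-correction sample counts per
#'   meadow (for the richness column); taken from `sample_meta` of the full
#'   data when available.
#' @param min_mll minimum lineages for statistics (default 2).
#' @param pi_sites `"all"` (default) averages nucleotide diversity over all
#'   retained sites; `"polymorphic"` over within-meadow polymorphic sites.
#' @return Data frame, one row per meadow, of class `diversity_table`.
#' @export
diversity_table <- function(gm_cc, sample_meta, n_ind = NULL, min_mll = 2,
                            pi_sites = c("all", "polymorphic")) {
  stopifnot(inherits(gm_cc, "genotype_matrix"))
  pi_sites <- match.arg(pi_sites)
  meadow <- sample_meta$meadow[match(gm_cc$samples, sample_meta$sample)]
  meadows <- sort(unique(meadow))
  L <- nrow(gm_cc$loci)

  # allele presence per meadow for private-allele accounting
  pres_ref <- matrix(FALSE, length(meadows), L)
  pres_alt <- matrix(FALSE, length(meadows), L)
  rows <- vector("list", length(meadows))
  for (k in seq_along(meadows)) {
    g <- gm_cc$geno[meadow == meadows[k], , drop = FALSE]
    n_mll <- nrow(g)
    called <- colSums(!is.na(g))
    alt <- colSums(g, na.rm = TRUE)
    pres_ref[k, ] <- (2 * called - alt) > 0
    pres_alt[k, ] <- alt > 0

    if (n_mll < min_mll) {
      rows[[k]] <- data.frame(meadow = meadows[k], n_mll = n_mll,
                              ho = NA_real_, uhe = NA_real_, fis = NA_real_,
                              pol = NA_integer_, upol = NA_real_,
                              upol_round = NA_integer_, pa = NA_integer_,
                              pi = NA_real_, upi = NA_real_,
                              computed = FALSE, stringsAsFactors = FALSE)
      next
    }
    use <- called > 0
    p <- alt[use] / (2 * called[use])
    ho_l <- colMeans(g[, use, drop = FALSE] == 1L, na.rm = TRUE)
    n_l <- called[use]
    uhe_l <- 2 * p * (1 - p) * (2 * n_l) / (2 * n_l - 1)
    ho <- mean(ho_l)
    uhe <- mean(uhe_l)
    fis <- if (uhe > 0) 1 - ho / uhe else NA_real_
    pol <- sum(p > 0 & p < 1)
    # per-site pairwise nucleotide diversity: 2*x_ref*x_alt / (n*(n-1))
    x_alt <- alt[use]; x_ref <- 2 * n_l - x_alt
    pi_l <- ifelse(2 * n_l > 1,
                   2 * x_ref * x_alt / ((2 * n_l) * (2 * n_l - 1)), 0)
    pi_val <- if (pi_sites == "all") mean(pi_l) else
      if (pol > 0) mean(pi_l[p > 0 & p < 1]) else 0
    rows[[k]] <- data.frame(meadow = meadows[k], n_mll = n_mll, ho = ho,
                            uhe = uhe, fis = fis, pol = pol,
                            upol = apply_sample_correction(pol, n_mll),
                            upol_round = NA_integer_, pa = NA_integer_,
                            pi = pi_val,
                            upi = apply_sample_correction(pi_val, n_mll),
                            computed = TRUE, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$upol_round <- ifelse(is.na(tab$upol), NA_integer_,
                           as.integer(round(tab$upol)))
  # private alleles: allele (locus x {ref,alt}) present in exactly one meadow
  for (al in list(pres_ref, pres_alt)) {
    only_one <- colSums(al) == 1L
    if (any(only_one)) {
      owner <- apply(al[, only_one, drop = FALSE], 2, which.max)
      cnt <- tabulate(owner, nbins = length(meadows))
      tab$pa <- ifelse(is.na(tab$pa), 0L, tab$pa) + cnt
    }
  }
  tab$pa[is.na(tab$pa)] <- 0L
  if (!is.null(n_ind)) {
    tab$n_ind <- unname(n_ind[tab$meadow])
    tab$richness <- ifelse(tab$n_ind >= 2,
                           genotypic_richness(tab$n_mll, tab$n_ind), NA_real_)
  }
  class(tab) <- c("diversity_table", "data.frame")
  tab
}

#' Group means of diversity statistics with Welch t-tests
#'
#' Averages per-meadow statistics (unweighted) within groups defined by the
#' meadow metadata: `impact` (impacted/reference), `size`
#' (small/large) or `cluster`. Meadows lacking the grouping label are
#' excluded and listed. For two-level groupings a two-sided Welch t-test per
#' statistic is reported.
#'
#' @param div_table a [diversity_table()] (or any data frame with a `meadow`
#'   column and numeric statistic columns, e.g. including `richness`).
#' @param meadow_meta meadow metadata from [read_meadow_metadata()].
#' @param grouping `"impact"`, `"size"` or `"cluster"`.
#' @return A list: `means` (group x statistic data frame), `tests` (Welch
#'   t-test p-values per statistic, `NULL` unless exactly 2 groups),
#'   `excluded` (meadow codes without a label).
#' @export
mean_richness_by_group <- function(div_table,
                                   meadow_meta,
                                   grouping = c("impact", "size", "cluster")) {
  grouping <- match.arg(grouping)
  col <- switch(grouping, impact = "impact", size = "size_class",
                cluster = "cluster")
  lab <- meadow_meta[[col]][match(div_table$meadow, meadow_meta$code)]
  excluded <- div_table$meadow[is.na(lab)]
  keep <- !is.na(lab)
  tab <- div_table[keep, , drop = FALSE]
  lab <- lab[keep]
  stat_cols <- names(tab)[vapply(tab, is.numeric, logical(1))]
  stat_cols <- setdiff(stat_cols, c("n_mll", "n_ind"))
  means <- aggregate(tab[stat_cols], by = list(group = lab),
                     FUN = function(x) mean(x, na.rm = TRUE))
  tests <- NULL
  if (length(unique(lab)) == 2) {
    tests <- vapply(stat_cols, function(s) {
      x <- split(tab[[s]], lab)
      ok <- vapply(x, function(v) sum(!is.na(v)) >= 2, logical(1))
      if (!all(ok)) return(NA_real_)
      stats::t.test(x[[1]], x[[2]])$p.value
    }, numeric(1))
  }
  list(means = means, tests = tests, excluded = excluded)
}
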