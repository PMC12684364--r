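#' LD-based effective population size
#'
#' Classical linkage-disequilibrium Ne estimation: the Burrows composite
#' correlation r is computed between all locus pairs on different
#' chromosomes (pairs within a chromosome are excluded to avoid physical
#' linkage), the mean squared correlation is corrected for the sampling
#' contribution (`1/S` for harmonic-mean sample size `S >= 30`, else
#' `1/S + 3.19/S^2`), and Ne is obtained from the drift expectation
#' `r2_drift = 1/(3Ne) + 0.69/Ne^2` inverted as
#' `Ne = (1/3 + sqrt(1/9 - 2.76 r2_drift)) / (2 r2_drift)`. Confidence
#' intervals come from a leave-one-chromosome-out jackknife on the corrected
#' mean r-squared. Loci with minor-allele frequency below `maf_min` are
#' excluded (rare alleles inflate r-squared).
#'
#' @param gm_cc clone-corrected [genotype_matrix()] for one unit (meadow or
#'   cluster), with at least `min_samples` samples and `min_loci` usable
#'   loci spread over >= 2 chromosomes.
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param min_samples,min_loci under-powered guards (defaults 10 and 200).
#' @param max_pairs cap on locus pairs; when exceeded, loci are thinned
#'   evenly (default 5e6).
#' @return A list of class `ne_estimate`: `ne` (point estimate, `Inf` when
#'   the corrected r-squared is non-positive), `ci_low`, `ci_high`,
#'   `r2_drift`, `r2_mean`, `S` (harmonic mean sample size), `n_pairs`,
#'   `n_loci`, `infinite` flag.
#' @export
ld_ne <- function(gm_cc, maf_min = 0.05, min_samples = 10, min_loci = 200,
                  max_pairs = 5e6) {
  stopifnot(inherits(gm_cc, "genotype_matrix"))
  n <- length(gm_cc$samples)
  if (n < min_samples)
    stop("under-powered: need >= ", min_samples, " samples, have ", n,
         call. = FALSE)
  g <- gm_cc$geno
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  called <- colSums(!is.na(g))
  use <- which(!is.na(maf) & maf >= maf_min & called >= 2)
  if (length(use) < min_loci)
    stop("under-powered: need >= ", min_loci, " usable loci, have ",
         length(use), call. = FALSE)
  chrom <- gm_cc$loci$chrom[use]
  if (length(unique(chrom)) < 2)
    stop("need loci on >= 2 chromosomes for cross-chromosome pairs",
         call. = FALSE)
  L <- length(use)
  if (L * (L - 1) / 2 > max_pairs) {
    keep <- round(seq(1, L, length.out = floor((1 + sqrt(1 + 8 * max_pairs))
                                               / 2)))
    use <- use[unique(keep)]
    chrom <- gm_cc$loci$chrom[use]
    L <- length(use)
  }
  gs <- g[, use, drop = FALSE]
  # Burrows composite r via pairwise-complete genotype correlation
  r <- suppressWarnings(stats::cor(gs, use = "pairwise.complete.obs"))
  cross <- outer(chrom, chrom, "!=") & upper.tri(r) & is.finite(r)
  S <- 1 / mean(1 / pmax(colSums(!is.na(gs)), 2))

  chroms <- unique(chrom)
  r2 <- r^2
  mean_r2_excluding <- function(drop_ch) {
    m <- cross
    if (!is.null(drop_ch)) {
      inch <- chrom == drop_ch
      m <- m & !outer(inch, inch, "|")
    }
    mean(r2[m])
  }
  r2_mean <- mean_r2_excluding(NULL)
  corr <- if (S >= 30) 1 / S else 1 / S + 3.19 / S^2
  r2_drift <- r2_mean - corr
  ne_from <- function(r2d) {
    if (is.na(r2d) || r2d <= 0) return(Inf)
    disc <- 1 / 9 - 2.76 * r2d
    if (disc < 0) disc <- 0
    (1 / 3 + sqrt(disc)) / (2 * r2d)
  }
  ne <- ne_from(r2_drift)
  # jackknife over chromosomes on the corrected mean r2
  jk <- vapply(chroms, function(ch) mean_r2_excluding(ch) - corr, numeric(1))
  k <- length(jk)
  jk_mean <- mean(jk)
  jk_se <- sqrt((k - 1) / k * sum((jk - jk_mean)^2))
  ci_r2 <- c(r2_drift - 1.96 * jk_se, r2_drift + 1.96 * jk_se)
  ci <- sort(c(ne_from(ci_r2[2]), ne_from(ci_r2[1])))
  structure(list(ne = ne, ci_low = ci[1], ci_high = ci[2],
                 r2_drift = r2_drift, r2_mean = r2_mean, S = S,
                 n_pairs = sum(cross), n_loci = L,
                 infinite = !is.finite(ne)),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat("<ne_estimate> Ne =", if (x$infinite) "Inf" else round(x$ne, 1),
      " CI [", round(x$ci_low, 1), ",", round(x$ci_high, 1), "]",
      " (S =", round(x$S, 1), ",", x$n_pairs, "locus pairs)\n")
  invisible(x)
}

#' Ne/Nc ratios for a meadow
#'
#' Census size `Nc = size_ha * 1e4 * plants_per_m2` (hectares to square
#' metres times plant density). When genotypic richness is supplied, the
#' clonality-corrected ratio `Ne/Nc_MLL = Ne / (Nc * R)` is added.
#'
#' @param ne effective population size (scalar).
#' @param size_ha meadow size in hectares (`NA` allowed, yields NA ratios).
#' @param plants_per_m2 plant density per square metre (default 55: 550
#'   shoots/m2 at 10 shoots per plant).
#' @param richness optional genotypic richness R.
#' @return Named list: `nc`, `ne_nc`, `ne_nc_mll` (NA when `richness`
#'   missing).
#' @export
ne_nc <- function(ne, size_ha, plants_per_m2 = 55, richness = NULL) {
  if (is.na(size_ha))
    return(list(nc = NA_real_, ne_nc = NA_real_, ne_nc_mll = NA_real_))
  if (size_ha <= 0) stop("meadow size must be positive", call. = FALSE)
  nc <- size_ha * 1e4 * plants_per_m2
  out <- list(nc = nc, ne_nc = ne / nc, ne_nc_mll = NA_real_)
  if (!is.null(richness) && !is.na(richness) && richness > 0)
    out$ne_nc_mll <- ne / (nc * richness)
  out
}

#' GBF indicator: proportion of units with Ne above 500
#'
#' @param ne_by_unit named numeric vector of Ne point estimates, or a list
#'   of `ne_estimate` objects (needed for `ci_overlap` mode).
#' @param mode `"point"` (point estimate > threshold) or `"ci_overlap"`
#'   (upper CI bound >= threshold).
#' @param threshold Ne threshold (default 500).
#' @return Proportion in `[0, 1]` (full precision; round to 2 dp for
#'   reports).
#' @export
indicator_ne500 <- function(ne_by_unit, mode = c("point", "ci_overlap"),
                            threshold = 500) {
  mode <- match.arg(mode)
  if (length(ne_by_unit) == 0) stop("no units supplied", call. = FALSE)
  if (mode == "point") {
    ne <- if (is.list(ne_by_unit))
      vapply(ne_by_unit, function(x) x$ne, numeric(1)) else ne_by_unit
    mean(ne > threshold)
  } else {
    if (!is.list(ne_by_unit))
      stop("ci_overlap mode needs ne_estimate objects", call. = FALSE)
    hi <- vapply(ne_by_unit, function(x) x$ci_high, numeric(1))
    mean(hi >= threshold)
  }
}

#' GBF indicator: proportion of populations maintained
#'
#' A unit counts as lost when its areal reduction exceeds `loss_threshold`
#' (fraction, default 0.99 i.e. > 99% loss). `PM = 1 - lost/assessed`.
#'
#' @param areal_changes numeric vector of areal change per unit, as
#'   fractions (e.g. -0.995 for a 99.5\% reduction) or percentages (values
#'   outside `[-1, 1]` are interpreted as percent and divided by 100).
#' @param loss_threshold reduction fraction defining loss (default 0.99).
#' @return Proportion maintained in `[0, 1]`.
#' @export
indicator_pm <- function(areal_changes, loss_threshold = 0.99) {
  if (length(areal_changes) == 0) stop("no units supplied", call. = FALSE)
  x <- areal_changes
  if (any(abs(x) > 1, na.rm = TRUE)) x <- x / 100
  lost <- sum(x < -loss_threshold, na.rm = TRUE)
  1 - lost / sum(!is.na(x))
}

#' Correlate genetic metrics with areal change
#'
#' For each supplied per-meadow metric, Pearson and Spearman correlations
#' against areal change (pairwise deletion of missing meadows). Metrics
#' with fewer than `min_pairs` complete pairs are flagged `NA`.
#'
#' @param metrics data frame with a `meadow` column and numeric metric
#'   columns (e.g. `ho`, `fis`, `froh_1mb`, `ne`).
#' @param meadow_meta meadow metadata with `code` and `areal_change_pct`.
#' @param min_pairs minimum complete pairs (default 4).
#' @return Data frame: `metric`, `n`, `pearson_r`, `pearson_p`,
#'   `spearman_rho`, `spearman_p`.
#' @export
correlate_with_change <- function(metrics, meadow_meta, min_pairs = 4) {
  change <- meadow_meta$areal_change_pct[match(metrics$meadow,
                                               meadow_meta$code)]
  stat_cols <- setdiff(names(metrics)[vapply(metrics, is.numeric,
                                             logical(1))],
                       c("n_mll", "n_ind"))
  rows <- lapply(stat_cols, function(s) {
    x <- metrics[[s]]
    ok <- !is.na(x) & !is.na(change)
    if (sum(ok) < min_pairs)
      return(data.frame(metric = s, n = sum(ok), pearson_r = NA_real_,
                        pearson_p = NA_real_, spearman_rho = NA_real_,
                        spearman_p = NA_real_, stringsAsFactors = FALSE))
    pe <- suppressWarnings(stats::cor.test(x[ok], change[ok],
                                           method = "pearson"))
    sp <- suppressWarnings(stats::cor.test(x[ok], change[ok],
                                           method = "spearman"))
    data.frame(metric = s, n = sum(ok), pearson_r = unname(pe$estimate),
               pearson_p = pe$p.value, spearman_rho = unname(sp$estimate),
               spearman_p = sp$p.value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
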