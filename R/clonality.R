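#' Pairwise genetic distances between samples
#'
#' Two missing-aware metrics over dosage genotypes:
#' \describe{
#'   \item{`bitwise`}{mean per-locus allele mismatch over the loci called in
#'     both samples, `mean(|g_i - g_j| / 2)`; ranges 0 (identical) to 1
#'     (opposite homozygotes at every shared locus).}
#'   \item{`euclidean`}{`sqrt(sum((g_i - g_j)^2) * n_loci / n_shared)`, the
#'     squared-difference distance rescaled so samples with different
#'     missingness are comparable.}
#' }
#'
#' @param gm a [genotype_matrix()] with at least 2 samples.
#' @param metric `"bitwise"` (default) or `"euclidean"`.
#' @return A list of class `distance_matrix`: `d` (symmetric matrix with
#'   sample dimnames), `metric`, `n_shared` (matrix of shared called loci).
#' @export
pairwise_distance <- function(gm, metric = c("bitwise", "euclidean")) {
  stopifnot(inherits(gm, "genotype_matrix"))
  metric <- match.arg(metric)
  n <- length(gm$samples)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  g <- gm$geno
  called <- !is.na(g)
  shared <- tcrossprod(called * 1)  # n x n counts of loci called in both
  zero <- which(shared == 0 & row(shared) < col(shared), arr.ind = TRUE)
  if (nrow(zero))
    stop("sample pair(s) share no called loci: ",
         paste(gm$samples[zero[1, 1]], gm$samples[zero[1, 2]], sep = "/"),
         call. = FALSE)

  # indicator matrices per genotype code; crossprod gives pair counts n_xy
  g0 <- (called & g == 0L) * 1; g1 <- (called & g == 1L) * 1
  g2 <- (called & g == 2L) * 1
  n01 <- tcrossprod(g0, g1); n12 <- tcrossprod(g1, g2)
  n02 <- tcrossprod(g0, g2)
  abs_sum  <- n01 + t(n01) + n12 + t(n12) + 2 * (n02 + t(n02))
  sq_sum   <- n01 + t(n01) + n12 + t(n12) + 4 * (n02 + t(n02))

  d <- if (metric == "bitwise") {
    abs_sum / (2 * shared)
  } else {
    sqrt(sq_sum * ncol(g) / shared)
  }
  diag(d) <- 0
  dimnames(d) <- list(gm$samples, gm$samples)
  structure(list(d = d, metric = metric, n_shared = shared),
            class = "distance_matrix")
}

#' Predict the clone-calling distance threshold
#'
#' Agglomerative clustering of the distance matrix under the requested
#' linkage produces a set of merge heights; when clones are present these are
#' bimodal (tiny clone-level merges, larger between-genotype merges). The
#' threshold is placed at the midpoint of the largest gap in the sorted merge
#' heights — the valley between the two modes.
#'
#' @param dist a `distance_matrix` from [pairwise_distance()].
#' @param linkage `"average"` (UPGMA, default), `"single"` or `"complete"`.
#' @return A list: `threshold`, `linkage`, `heights` (sorted merge heights),
#'   `gap` (width of the largest gap), `gap_low`/`gap_high` (its edges).
#' @export
predict_threshold <- function(dist,
                              linkage = c("average", "single", "complete")) {
  stopifnot(inherits(dist, "distance_matrix"))
  linkage <- match.arg(linkage)
  hc <- stats::hclust(stats::as.dist(dist$d), method = linkage)
  h <- sort(hc$height)
  if (length(h) < 3)
    stop("too few samples to calibrate a threshold (< 3 merge heights)",
         call. = FALSE)
  if (max(h) - min(h) < .Machine$double.eps^0.5)
    stop("merge heights are constant; no clone/non-clone gap to calibrate",
         call. = FALSE)
  gaps <- diff(h)
  i <- which.max(gaps)
  list(threshold = (h[i] + h[i + 1]) / 2, linkage = linkage, heights = h,
       gap = gaps[i], gap_low = h[i], gap_high = h[i + 1])
}

#' Validate a clone threshold against technical replicates
#'
#' Technical replicates differ only by genotyping error, so the largest
#' replicate-pair distance bounds the error-induced distance between true
#' clones. Validation passes when every replicate pair would stay in one MLL
#' at the candidate threshold.
#'
#' @param dist a `distance_matrix`.
#' @param sample_meta sample metadata with `sample` and `replicate_group`.
#' @param threshold candidate distance threshold.
#' @return A list: `passed`, `max_replicate_distance`, `n_pairs`, and
#'   `failing_pairs` (data frame of offending pairs, empty when passed).
#' @export
validate_with_replicates <- function(dist, sample_meta, threshold) {
  stopifnot(inherits(dist, "distance_matrix"))
  ids <- rownames(dist$d)
  grp <- sample_meta$replicate_group[match(ids, sample_meta$sample)]
  pairs <- NULL
  for (g in unique(grp[duplicated(grp)])) {
    m <- which(grp == g & !is.na(grp))
    if (length(m) > 1) {
      cmb <- utils::combn(m, 2)
      pairs <- rbind(pairs, t(cmb))
    }
  }
  if (is.null(pairs)) {
    warning("no technical replicate pairs present; threshold not validated")
    return(list(passed = NA, max_replicate_distance = NA_real_, n_pairs = 0L,
                failing_pairs = data.frame()))
  }
  dd <- dist$d[pairs]
  fail <- dd > threshold
  failing <- data.frame(sample1 = ids[pairs[fail, 1]],
                        sample2 = ids[pairs[fail, 2]],
                        distance = dd[fail], stringsAsFactors = FALSE)
  list(passed = !any(fail), max_replicate_distance = max(dd),
       n_pairs = nrow(pairs), failing_pairs = failing)
}

#' Assign samples to multilocus lineages
#'
#' Cuts the linkage tree at the given distance threshold; each resulting
#' cluster is one multilocus lineage (MLL). MLL ids are deterministic: the
#' lexicographically smallest member sample id names the lineage.
#'
#' @param dist a `distance_matrix`.
#' @param threshold distance threshold (from [predict_threshold()] or
#'   user-supplied).
#' @param linkage linkage used for the tree; must match the threshold's.
#' @return A list of class `mll_assignment`: `mll` (named character vector,
#'   sample -> MLL id), `threshold`, `linkage`, `n_mll`.
#' @export
assign_mll <- function(dist, threshold,
                       linkage = c("average", "single", "complete")) {
  stopifnot(inherits(dist, "distance_matrix"))
  linkage <- match.arg(linkage)
  hc <- stats::hclust(stats::as.dist(dist$d), method = linkage)
  cl <- stats::cutree(hc, h = threshold)
  ids <- rownames(dist$d)
  mll_name <- vapply(split(ids, cl), function(s) min(s), character(1))
  mll <- stats::setNames(mll_name[as.character(cl)], ids)
  structure(list(mll = mll, threshold = threshold, linkage = linkage,
                 n_mll = length(unique(mll))),
            class = "mll_assignment")
}

#' @export
print.mll_assignment <- function(x, ...) {
  cat("<mll_assignment> ", length(x$mll), " samples -> ", x$n_mll,
      " MLLs (threshold ", signif(x$threshold, 4), ", ", x$linkage,
      " linkage)\n", sep = "")
  invisible(x)
}

#' Clone-correct a genotype matrix
#'
#' Removes technical replicates (one sample kept per replicate group), then
#' keeps one representative per MLL within each meadow. An MLL spanning two
#' meadows keeps one representative in each, so shared clones remain visible
#' in between-meadow statistics. The retained sample is the one with least
#' missingness; ties break on the lexicographically smallest id.
#'
#' @param gm a [genotype_matrix()].
#' @param mll an `mll_assignment` covering `gm`'s samples.
#' @param sample_meta sample metadata (`sample`, `meadow`,
#'   `replicate_group`).
#' @return A `genotype_matrix` of clone-corrected samples.
#' @export
clone_correct <- function(gm, mll, sample_meta) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(mll, "mll_assignment"))
  meta <- sample_meta[match(gm$samples, sample_meta$sample), ]
  miss <- sample_missingness(gm)
  pick <- function(ids) ids[order(miss[ids], ids)][1]

  # replicates first: one sample per replicate_group
  keep1 <- vapply(split(gm$samples, meta$replicate_group), pick, character(1))
  g1 <- gm_subset(gm, samples = sort(match(keep1, gm$samples)))

  meta1 <- sample_meta[match(g1$samples, sample_meta$sample), ]
  key <- paste(mll$mll[g1$samples], meta1$meadow, sep = "\r")
  keep2 <- vapply(split(g1$samples, key), pick, character(1))
  gm_subset(g1, samples = sort(match(keep2, g1$samples)))
}

#' Export an MLL table
#'
#' @param mll an `mll_assignment`.
#' @param sample_meta sample metadata.
#' @param gm_cc optional clone-corrected matrix to flag representatives.
#' @return Data frame with `sample`, `meadow`, `mll_id`, `representative`.
#' @export
mll_table <- function(mll, sample_meta, gm_cc = NULL) {
  ids <- names(mll$mll)
  data.frame(sample = ids,
             meadow = sample_meta$meadow[match(ids, sample_meta$sample)],
             mll_id = unname(mll$mll),
             representative = if (is.null(gm_cc)) NA else ids %in% gm_cc$samples,
             stringsAsFactors = FALSE)
}
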