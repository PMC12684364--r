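#' Pairwise Weir-Cockerham FST between meadows
#'
#' Multi-locus theta for every meadow pair as the ratio of sums of the 1984
#' variance components, `sum(a) / sum(a + b + c)` over loci. Significance by
#' permutation of sample labels within the pair (add-one correction), with
#' Benjamini-Hochberg FDR across all pairs. Negative estimates are reported
#' as-is.
#'
#' @param gm_cc clone-corrected [genotype_matrix()].
#' @param sample_meta sample metadata (`sample`, `meadow`).
#' @param n_perm label permutations per pair (default 999; 0 skips testing).
#' @param seed integer seed for the permutations.
#' @return A list of class `fst_matrix`: `theta` (symmetric matrix, 0
#'   diagonal), `p` and `q` (permutation p-values and BH q-values, `NA` when
#'   `n_perm = 0`), `n_perm`.
#' @export
pairwise_fst <- function(gm_cc, sample_meta, n_perm = 999, seed = 1) {
  stopifnot(inherits(gm_cc, "genotype_matrix"))
  meadow <- sample_meta$meadow[match(gm_cc$samples, sample_meta$sample)]
  meadows <- sort(unique(meadow))
  m <- length(meadows)
  theta <- matrix(NA_real_, m, m, dimnames = list(meadows, meadows))
  pmat <- matrix(NA_real_, m, m, dimnames = list(meadows, meadows))
  diag(theta) <- 0
  set.seed(as.integer(seed))
  for (i in seq_len(m - 1)) for (j in (i + 1):m) {
    sel <- meadow %in% meadows[c(i, j)]
    g <- gm_cc$geno[sel, , drop = FALSE]
    lab <- meadow[sel]
    if (min(table(lab)) < 2) next  # pair flagged NA: too few samples
    obs <- wc_theta(g, lab)
    theta[i, j] <- theta[j, i] <- obs
    if (n_perm > 0) {
      ge <- vapply(seq_len(n_perm), function(b)
        wc_theta(g, sample(lab)) >= obs, logical(1))
      pv <- (1 + sum(ge, na.rm = TRUE)) / (n_perm + 1)
      pmat[i, j] <- pmat[j, i] <- pv
    }
  }
  qmat <- pmat
  up <- upper.tri(pmat)
  qmat[up] <- stats::p.adjust(pmat[up], method = "BH")
  qmat[lower.tri(qmat)] <- t(qmat)[lower.tri(qmat)]
  structure(list(theta = theta, p = pmat, q = qmat, n_perm = n_perm),
            class = "fst_matrix")
}

#' Multi-locus Weir-Cockerham theta for labelled genotypes
#'
#' The 1984 estimator from per-locus variance components a (among
#' populations), b (among individuals within populations) and c (within
#' individuals), combined as a ratio of sums over loci. Exported for reuse
#' and for direct checks on toy data.
#'
#' @param g dosage matrix (samples x loci, `{0,1,2,NA}`).
#' @param lab population label per sample (>= 2 populations).
#' @return Multi-locus theta (scalar; `NaN` when no locus is informative).
#' @export
wc_theta <- function(g, lab) {
  lab <- as.factor(lab)
  r <- nlevels(lab)
  if (r < 2) stop("need at least 2 populations", call. = FALSE)
  called <- !is.na(g)
  # per-pop per-locus: sample size, allele freq, het freq
  n_il <- rowsum(called * 1, lab)                    # pops x loci, counts
  x_il <- rowsum(ifelse(called, g, 0), lab)          # alt allele sums (x2)
  h_il <- rowsum((called & g == 1L) * 1, lab)
  use <- colSums(n_il >= 1) == r & colSums(n_il) > r  # every pop called
  if (!any(use)) return(NaN)
  n_il <- n_il[, use, drop = FALSE]
  p_il <- x_il[, use, drop = FALSE] / (2 * n_il)
  h_il <- h_il[, use, drop = FALSE] / n_il

  nbar <- colMeans(n_il)
  nc <- (r * nbar - colSums(n_il^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_il * p_il) / (r * nbar)
  s2 <- colSums(n_il * sweep(p_il, 2, pbar)^2) / ((r - 1) * nbar)
  hbar <- colSums(n_il * h_il) / (r * nbar)

  ok <- nbar > 1 & nc > 0
  nbar <- nbar[ok]; nc <- nc[ok]; pbar <- pbar[ok]; s2 <- s2[ok]
  hbar <- hbar[ok]
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions squared Euclidean inter-individual genetic distances into
#' variance among clusters, among meadows within clusters and within
#' meadows, with Phi statistics and permutation tests that respect the
#' tested level (whole meadows permuted among clusters; individuals permuted
#' among meadows within clusters).
#'
#' @param gm_cc clone-corrected [genotype_matrix()].
#' @param sample_meta sample metadata (`sample`, `meadow`).
#' @param meadow_cluster named vector meadow -> cluster label.
#' @param n_perm permutations per level (default 999; 0 skips tests).
#' @param seed integer seed.
#' @return A list of class `amova_result`: `ss` (sums of squares per level
#'   and total), `df`, `sigma2` (variance components `a`, `b`, `c`),
#'   `phi` (`phi_ct`, `phi_sc`, `phi_st`), `p` (permutation p-values),
#'   `underpowered` (clusters with a single meadow).
#' @export
amova <- function(gm_cc, sample_meta, meadow_cluster, n_perm = 999,
                  seed = 1) {
  stopifnot(inherits(gm_cc, "genotype_matrix"))
  meadow <- sample_meta$meadow[match(gm_cc$samples, sample_meta$sample)]
  cluster <- unname(meadow_cluster[meadow])
  keep <- !is.na(cluster)
  g <- gm_cc$geno[keep, , drop = FALSE]
  meadow <- meadow[keep]; cluster <- cluster[keep]
  d2 <- squared_euclidean(g)

  res <- amova_components(d2, meadow, cluster)
  p <- c(phi_ct = NA_real_, phi_sc = NA_real_, phi_st = NA_real_)
  if (n_perm > 0) {
    set.seed(as.integer(seed))
    obs <- res$phi
    # level a: permute whole meadows among clusters
    mlist <- split(seq_along(meadow), meadow)
    mcl <- vapply(mlist, function(i) cluster[i[1]], character(1))
    cnt_ct <- 0L; cnt_st <- 0L; cnt_sc <- 0L
    for (b in seq_len(n_perm)) {
      perm_cl <- stats::setNames(sample(unname(mcl)), names(mcl))
      cl_b <- unname(perm_cl[meadow])
      rb <- amova_components(d2, meadow, cl_b)
      if (!is.na(rb$phi["phi_ct"]) && rb$phi["phi_ct"] >= obs["phi_ct"])
        cnt_ct <- cnt_ct + 1L
      # level c: permute individuals among meadows within clusters
      idx <- seq_along(meadow)
      for (cl in unique(cluster)) {
        w <- which(cluster == cl)
        idx[w] <- w[sample(length(w))]
      }
      rc <- amova_components(d2[idx, idx], meadow, cluster)
      if (!is.na(rc$phi["phi_sc"]) && rc$phi["phi_sc"] >= obs["phi_sc"])
        cnt_sc <- cnt_sc + 1L
      # overall: permute individuals freely
      idx <- sample(seq_along(meadow))
      rs <- amova_components(d2[idx, idx], meadow, cluster)
      if (!is.na(rs$phi["phi_st"]) && rs$phi["phi_st"] >= obs["phi_st"])
        cnt_st <- cnt_st + 1L
    }
    p <- c(phi_ct = (1 + cnt_ct) / (n_perm + 1),
           phi_sc = (1 + cnt_sc) / (n_perm + 1),
           phi_st = (1 + cnt_st) / (n_perm + 1))
  }
  single <- names(which(table(vapply(split(cluster, meadow), `[`, character(1),
                                     1)) < 2))
  structure(c(res, list(p = p, underpowered = single)),
            class = "amova_result")
}

squared_euclidean <- function(g) {
  called <- !is.na(g)
  shared <- tcrossprod(called * 1)
  g0 <- ifelse(called, g, 0)
  # cross and self terms restricted to loci called in both samples
  cross <- tcrossprod(g0)
  self1 <- tcrossprod(g0^2, called * 1)   # sum gi^2 over loci called in both
  d2 <- self1 + t(self1) - 2 * cross
  d2 <- d2 * ncol(g) / pmax(shared, 1)
  diag(d2) <- 0
  d2
}

# variance components from a squared-distance matrix and 2-level hierarchy
amova_components <- function(d2, meadow, cluster) {
  N <- nrow(d2)
  ss_of <- function(idx) if (length(idx) < 2) 0 else
    sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  ss_total <- ss_of(seq_len(N))
  groups_m <- split(seq_len(N), meadow)
  groups_c <- split(seq_len(N), cluster)
  ss_wp <- sum(vapply(groups_m, ss_of, numeric(1)))           # within meadows
  ss_wc <- sum(vapply(groups_c, ss_of, numeric(1)))           # within clusters
  ss_ap <- ss_wc - ss_wp      # among meadows within clusters
  ss_ac <- ss_total - ss_wc   # among clusters

  n_meadow <- lengths(groups_m)
  n_cluster <- lengths(groups_c)
  a <- length(groups_c); mpop <- length(groups_m)
  df_ac <- a - 1; df_ap <- mpop - a; df_wp <- N - mpop

  # expected-mean-square coefficients for unequal sizes (Excoffier et al.)
  cl_of_meadow <- vapply(groups_m, function(i) cluster[i[1]], character(1))
  sum_n2_by_cl <- vapply(names(groups_c), function(cl) {
    sum(n_meadow[cl_of_meadow == cl]^2)
  }, numeric(1))
  n1 <- (N - sum(sum_n2_by_cl / n_cluster[names(groups_c)])) / df_ap
  n2 <- (sum(sum_n2_by_cl / n_cluster[names(groups_c)]) -
           sum(n_meadow^2) / N) / df_ac
  n3 <- (N - sum(n_cluster^2) / N) / df_ac

  ms_wp <- if (df_wp > 0) ss_wp / df_wp else 0
  ms_ap <- if (df_ap > 0) ss_ap / df_ap else NA_real_
  ms_ac <- if (df_ac > 0) ss_ac / df_ac else NA_real_
  sig_c <- ms_wp
  sig_b <- if (is.na(ms_ap)) 0 else (ms_ap - sig_c) / n1
  sig_a <- if (is.na(ms_ac)) 0 else (ms_ac - sig_c - n2 * sig_b) / n3
  tot <- sig_a + sig_b + sig_c
  phi <- c(phi_ct = if (tot > 0) sig_a / tot else NA_real_,
           phi_sc = if (sig_b + sig_c > 0) sig_b / (sig_b + sig_c)
                    else NA_real_,
           phi_st = if (tot > 0) (sig_a + sig_b) / tot else NA_real_)
  list(ss = c(among_clusters = ss_ac, among_meadows = ss_ap,
              within_meadows = ss_wp, total = ss_total),
       df = c(among_clusters = df_ac, among_meadows = df_ap,
              within_meadows = df_wp),
       sigma2 = c(a = sig_a, b = sig_b, c = sig_c), phi = phi)
}

#' Shortest in-water distances between meadows
#'
#' Meadow coordinates are snapped to the nearest sea cell of a land/sea
#' grid (snaps are logged), then shortest paths are computed over the sea
#' cells with 8-neighbourhood moves and great-circle edge lengths.
#'
#' @param coords data frame with `code`, `lat`, `lon` (decimal degrees).
#' @param sea_grid a list describing the mask: `sea` (logical matrix, rows =
#'   latitude bands from north to south, cols = longitude), `lat` (vector of
#'   row-centre latitudes), `lon` (vector of column-centre longitudes).
#' @return A list of class `geo_distance_matrix`: `km` (symmetric matrix),
#'   `snapped` (data frame logging moved coordinates), `resolution_deg`.
#' @export
waterway_distance <- function(coords, sea_grid) {
  sea <- sea_grid$sea
  lat <- sea_grid$lat; lon <- sea_grid$lon
  nr <- nrow(sea); nc <- ncol(sea)
  stopifnot(length(lat) == nr, length(lon) == nc)
  cell_id <- matrix(seq_len(nr * nc), nr, nc)
  sea_cells <- which(sea)

  # graph over sea cells, 8-neighbour connectivity
  edges <- NULL; weights <- NULL
  shifts <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts[s, 1]; dc <- shifts[s, 2]
    rows_from <- seq_len(nr - dr)
    if (dc >= 0) { cols_from <- seq_len(nc - dc) } else
      { cols_from <- seq(1 - dc, nc) }
    from <- as.vector(cell_id[rows_from, cols_from, drop = FALSE])
    to <- as.vector(cell_id[rows_from + dr, cols_from + dc, drop = FALSE])
    ok <- sea[from] & sea[to]
    from <- from[ok]; to <- to[ok]
    if (!length(from)) next
    p1 <- cbind(lon[(from - 1) %/% nr + 1], lat[(from - 1) %% nr + 1])
    p2 <- cbind(lon[(to - 1) %/% nr + 1], lat[(to - 1) %% nr + 1])
    w <- geosphere::distHaversine(p1, p2) / 1000
    edges <- c(edges, rbind(from, to))
    weights <- c(weights, w)
  }
  gr <- igraph::graph_from_edgelist(matrix(as.character(edges), ncol = 2,
                                           byrow = TRUE), directed = FALSE)
  igraph::E(gr)$weight <- weights

  # snap each meadow to the nearest sea cell
  snap <- lapply(seq_len(nrow(coords)), function(i) {
    pt <- c(coords$lon[i], coords$lat[i])
    ri <- which.min(abs(lat - coords$lat[i]))
    ci <- which.min(abs(lon - coords$lon[i]))
    moved <- !sea[ri, ci]
    if (moved) {
      cand <- sea_cells
      cl <- cbind(lon[(cand - 1) %/% nr + 1], lat[(cand - 1) %% nr + 1])
      k <- which.min(geosphere::distHaversine(pt, cl))
      cell <- cand[k]
    } else cell <- cell_id[ri, ci]
    list(cell = cell, moved = moved,
         snap_lat = lat[(cell - 1) %% nr + 1],
         snap_lon = lon[(cell - 1) %/% nr + 1])
  })
  cells <- vapply(snap, `[[`, numeric(1), "cell")
  vnames <- igraph::V(gr)$name
  vidx <- match(as.character(cells), vnames)
  if (anyNA(vidx))
    stop("meadow(s) snapped to isolated sea cell: ",
         paste(coords$code[is.na(vidx)], collapse = ", "), call. = FALSE)
  dm <- igraph::distances(gr, v = vidx, to = vidx)
  dimnames(dm) <- list(coords$code, coords$code)
  if (any(!is.finite(dm))) {
    bad <- which(!is.finite(dm) & upper.tri(dm), arr.ind = TRUE)
    stop("sea grid is disconnected; unreachable pair(s): ",
         paste(coords$code[bad[, 1]], coords$code[bad[, 2]], sep = "-",
               collapse = ", "), call. = FALSE)
  }
  snapped <- data.frame(code = coords$code,
                        moved = vapply(snap, `[[`, logical(1), "moved"),
                        snap_lat = vapply(snap, `[[`, numeric(1), "snap_lat"),
                        snap_lon = vapply(snap, `[[`, numeric(1), "snap_lon"))
  structure(list(km = dm, snapped = snapped,
                 resolution_deg = c(lat = mean(abs(diff(lat))),
                                    lon = mean(abs(diff(lon))))),
            class = "geo_distance_matrix")
}

#' Mantel test of isolation by distance
#'
#' Linearizes genetic differentiation as `FST / (1 - FST)` and tests its
#' association with in-water geographic distance by a Mantel test
#' (row/column permutations, via \pkg{vegan}); the OLS R-squared of the
#' pairwise regression is reported alongside.
#'
#' @param fst an `fst_matrix` (or plain symmetric FST matrix).
#' @param geo a `geo_distance_matrix` (or plain symmetric km matrix) with
#'   the same units in the same order.
#' @param n_perm Mantel permutations (default 999).
#' @param seed integer seed.
#' @return A list: `r` (Mantel correlation), `p`, `r_squared` (OLS),
#'   `slope`, `n_perm`.
#' @export
mantel_ibd <- function(fst, geo, n_perm = 999, seed = 1) {
  th <- if (inherits(fst, "fst_matrix")) fst$theta else fst
  km <- if (inherits(geo, "geo_distance_matrix")) geo$km else geo
  if (!identical(rownames(th), rownames(km)))
    stop("FST and geographic matrices must have identical unit order",
         call. = FALSE)
  lin <- th / (1 - th)
  set.seed(as.integer(seed))
  mt <- vegan::mantel(stats::as.dist(km), stats::as.dist(lin),
                      permutations = n_perm)
  x <- km[upper.tri(km)]; y <- lin[upper.tri(lin)]
  fitlm <- stats::lm(y ~ x)
  list(r = unname(mt$statistic), p = mt$signif,
       r_squared = summary(fitlm)$r.squared,
       slope = unname(stats::coef(fitlm)[2]), n_perm = n_perm)
}
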