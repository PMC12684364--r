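#' PCA of genotypes
#'
#' Allele dosages are mean-imputed per locus, centred, and not scaled — the
#' convention for genotype PCA in population structure analysis.
#'
#' @param gm_cc clone-corrected [genotype_matrix()].
#' @param n_axes number of leading axes to return (default 10, capped at
#'   the matrix rank).
#' @return A list: `scores` (samples x axes), `explained` (fraction of
#'   variance per axis), `center` (locus means used for imputation).
#' @export
gm_pca <- function(gm_cc, n_axes = 10) {
  stopifnot(inherits(gm_cc, "genotype_matrix"))
  n <- length(gm_cc$samples)
  if (n < 2) stop("need at least 2 samples for PCA", call. = FALSE)
  x <- impute_center(gm_cc$geno)
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  k <- min(n_axes, ncol(pc$x))
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x[, seq_len(k), drop = FALSE], explained = expl[seq_len(k)],
       center = attr(x, "center_used"))
}

impute_center <- function(g) {
  mu <- colMeans(g, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(g))
  if (length(idx)) g[idx] <- mu[(idx - 1) %/% nrow(g) + 1]
  out <- sweep(g, 2, mu)
  attr(out, "center_used") <- mu
  out
}

#' Ancestry estimation by masked non-negative matrix factorization
#'
#' Estimates admixture proportions Q (individuals x K, rows on the
#' simplex) and ancestral allele frequencies F (K x loci) from allele
#' dosages, in the spirit of sparse-NMF ancestry estimation. The optimizer
#' is alternating least squares with EM-style imputation of unobserved
#' entries, a simplex projection of Q rows and clipping of F to (0, 1).
#' Model choice uses a masked holdout: a fraction of called genotypes is
#' hidden from the fit and the cross-entropy (mean negative binomial
#' log-likelihood per held-out allele) of those entries scores each run.
#' The best run per K is the one with lowest cross-entropy; `best_k` is the
#' K with the overall lowest mean cross-entropy.
#'
#' @param gm_cc clone-corrected [genotype_matrix()].
#' @param k_values integer vector of K values to scan (default `1:8`).
#' @param n_runs independent runs per K (default 5).
#' @param mask_fraction fraction of called entries held out, in (0, 0.2]
#'   (default 0.05).
#' @param seed integer seed; run r at K uses `seed + 1000*K + r`.
#' @param max_iter iteration cap per run (default 200).
#' @param tol relative change in training RMSE below which a run stops.
#' @return A list of class `ancestry_result`: `Q` (best run at `best_k`),
#'   `F`, `best_k`, `cross_entropy` (data frame K x run), `runs` (per-K best
#'   Q matrices), `converged` flags.
#' @export
ancestry_nmf <- function(gm_cc, k_values = 1:8, n_runs = 5,
                         mask_fraction = 0.05, seed = 1, max_iter = 200,
                         tol = 1e-5) {
  stopifnot(inherits(gm_cc, "genotype_matrix"))
  if (mask_fraction <= 0 || mask_fraction > 0.2)
    stop("mask_fraction must be in (0, 0.2]", call. = FALSE)
  g <- gm_cc$geno
  n <- nrow(g); L <- ncol(g)
  called <- which(!is.na(g))

  ce_tab <- expand.grid(k = k_values, run = seq_len(n_runs))
  ce_tab$cross_entropy <- NA_real_
  ce_tab$converged <- NA
  best_per_k <- vector("list", length(k_values))
  names(best_per_k) <- as.character(k_values)

  for (ki in seq_along(k_values)) {
    k <- k_values[ki]
    best_ce <- Inf
    for (r in seq_len(n_runs)) {
      set.seed(as.integer(seed + 1000 * k + r))
      mask <- sample(called, size = max(1L, round(mask_fraction *
                                                    length(called))))
      fit <- nmf_fit_one(g, k, mask, max_iter, tol)
      row <- which(ce_tab$k == k & ce_tab$run == r)
      ce_tab$cross_entropy[row] <- fit$cross_entropy
      ce_tab$converged[row] <- fit$converged
      if (fit$cross_entropy < best_ce) {
        best_ce <- fit$cross_entropy
        best_per_k[[ki]] <- fit
      }
    }
  }
  mean_ce <- tapply(ce_tab$cross_entropy, ce_tab$k, mean)
  best_k <- k_values[which.min(mean_ce[as.character(k_values)])]
  best <- best_per_k[[as.character(best_k)]]
  rownames(best$Q) <- gm_cc$samples
  structure(list(Q = best$Q, F = best$F, best_k = best_k,
                 cross_entropy = ce_tab, mean_cross_entropy = mean_ce,
                 runs = best_per_k, seed = seed),
            class = "ancestry_result")
}

# one NMF run: X = dosages/2 in [0,1]; masked + missing entries imputed
# from the current reconstruction each sweep.
nmf_fit_one <- function(g, k, mask, max_iter, tol) {
  n <- nrow(g); L <- ncol(g)
  X_obs <- g / 2
  obs <- !is.na(X_obs)
  obs[mask] <- FALSE          # holdout treated as unobserved during fitting
  mu <- colMeans(X_obs, na.rm = TRUE); mu[is.nan(mu)] <- 0.5
  X <- X_obs
  X[!obs] <- matrix(mu, n, L, byrow = TRUE)[!obs]

  Q <- matrix(stats::runif(n * k), n, k)
  Q <- Q / rowSums(Q)
  F <- matrix(stats::runif(k * L, 0.05, 0.95), k, L)
  eps <- 1e-6
  prev_rmse <- Inf
  converged <- FALSE
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    # Q update: least squares rows projected to simplex
    if (k == 1) {
      Q <- matrix(1, n, 1)
    } else {
      FFt <- tcrossprod(F) + diag(eps, k)
      Q <- t(solve(FFt, F %*% t(X)))
      Q <- t(apply(Q, 1, project_simplex))
    }
    # F update: least squares clipped to (0,1)
    QtQ <- crossprod(Q) + diag(eps, k)
    F <- solve(QtQ, crossprod(Q, X))
    F[F < eps] <- eps; F[F > 1 - eps] <- 1 - eps
    # impute unobserved entries from the reconstruction
    R <- Q %*% F
    X[!obs] <- R[!obs]
    rmse <- sqrt(mean((X_obs[obs] - R[obs])^2))
    trace <- c(trace, rmse)
    if (is.finite(prev_rmse) &&
        abs(prev_rmse - rmse) <= tol * max(prev_rmse, 1e-12)) {
      converged <- TRUE
      break
    }
    prev_rmse <- rmse
  }
  pred <- Q %*% F
  pred <- pmin(pmax(pred, eps), 1 - eps)
  gm_mask <- g[mask]
  keep <- !is.na(gm_mask)
  p <- pred[mask][keep]; gmv <- gm_mask[keep]
  ce <- -mean(gmv * log(p) + (2 - gmv) * log(1 - p)) / 2
  list(Q = Q, F = F, cross_entropy = ce, converged = converged,
       rmse_trace = trace)
}

# Euclidean projection of a vector onto the probability simplex
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u + (1 - css) / seq_along(u) > 0))
  theta <- (1 - css[rho]) / rho
  pmax(v + theta, 0)
}

#' Discriminant analysis of principal components (DAPC-style memberships)
#'
#' Reduces the genotypes by PCA and fits a multiclass linear discriminant on
#' the retained axes, returning per-individual membership probabilities for
#' the supplied groups.
#'
#' @param gm_cc clone-corrected [genotype_matrix()].
#' @param groups factor/character of group labels per sample (e.g. the
#'   best-K ancestry clusters).
#' @param n_pc number of principal components; default: the smallest number
#'   explaining >= 80\% of variance, capped at `n/3`.
#' @param n_da number of discriminant axes (default `nlevels - 1`).
#' @return A list: `membership` (samples x groups probabilities),
#'   `assigned` (argmax label), `n_pc`, `lda` (the fitted model).
#' @export
dapc_memberships <- function(gm_cc, groups, n_pc = NULL, n_da = NULL) {
  stopifnot(inherits(gm_cc, "genotype_matrix"))
  groups <- factor(groups)
  n <- length(gm_cc$samples)
  if (length(groups) != n) stop("one group label per sample required",
                                call. = FALSE)
  pc <- gm_pca(gm_cc, n_axes = max(2L, n - 1L))
  if (is.null(n_pc)) {
    cum <- cumsum(pc$explained)
    n_pc <- min(max(which(cum >= 0.8)[1], 1L, na.rm = TRUE),
                max(1L, floor(n / 3)))
    if (is.na(n_pc)) n_pc <- max(1L, floor(n / 3))
  }
  if (n_pc >= n) stop("n_pc must be smaller than the number of samples",
                      call. = FALSE)
  scores <- pc$scores[, seq_len(min(n_pc, ncol(pc$scores))), drop = FALSE]
  fit <- MASS::lda(scores, grouping = groups)
  pred <- stats::predict(fit, scores)
  list(membership = pred$posterior, assigned = as.character(pred$class),
       n_pc = n_pc, lda = fit)
}

#' Assign meadows to genetic clusters
#'
#' Averages per-individual assignment vectors (ancestry Q or DAPC
#' memberships) within each meadow; the meadow is labelled with the argmax
#' cluster. If a second method's meadow labels are supplied and disagree,
#' the meadow is flagged conflicted and left unlabelled — likewise for
#' within-method ties.
#'
#' @param Q matrix of per-individual assignment probabilities (samples x
#'   clusters; rownames are sample ids).
#' @param sample_meta sample metadata (`sample`, `meadow`).
#' @param second_labels optional named character vector meadow -> label from
#'   an independent method.
#' @return Data frame with `meadow`, `label` (NA when conflicted/tied),
#'   `conflict`, `tie`, plus the mean assignment matrix as attribute
#'   `"mean_assignment"`.
#' @export
assign_meadows <- function(Q, sample_meta, second_labels = NULL) {
  ids <- rownames(Q)
  if (is.null(ids)) stop("Q must carry sample ids as rownames", call. = FALSE)
  meadow <- sample_meta$meadow[match(ids, sample_meta$sample)]
  agg <- rowsum(Q, meadow) / as.vector(table(meadow)[sort(unique(meadow))])
  if (is.null(colnames(agg))) colnames(agg) <- paste0("C", seq_len(ncol(agg)))
  lab <- character(nrow(agg)); tie <- logical(nrow(agg))
  for (i in seq_len(nrow(agg))) {
    m <- max(agg[i, ])
    top <- which(agg[i, ] >= m - 1e-12)
    tie[i] <- length(top) > 1
    lab[i] <- if (tie[i]) NA_character_ else colnames(agg)[top]
  }
  out <- data.frame(meadow = rownames(agg), label = lab, conflict = FALSE,
                    tie = tie, stringsAsFactors = FALSE)
  if (!is.null(second_labels)) {
    other <- second_labels[out$meadow]
    disagree <- !is.na(out$label) & !is.na(other) & out$label != other
    out$conflict <- disagree
    out$label[disagree] <- NA_character_
  }
  out$label[out$tie] <- NA_character_
  attr(out, "mean_assignment") <- agg
  out
}
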