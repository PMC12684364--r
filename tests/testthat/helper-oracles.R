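# Shared fixtures and independent oracles used across the suite.

# small genotype matrix from a plain matrix; loci placed on one chromosome
toy_gm <- function(geno, chrom = "chr1", pos = NULL, rad_tag = NULL,
                   alt = NULL, samples = NULL) {
  geno <- as.matrix(geno)
  L <- ncol(geno)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  if (is.null(rad_tag)) rad_tag <- paste0("t", seq_len(L))
  if (is.null(alt)) alt <- rep("G", L)
  if (is.null(samples)) samples <- paste0("s", seq_len(nrow(geno)))
  genotype_matrix(geno, samples,
                  data.frame(chrom = rep_len(chrom, L), pos = pos,
                             ref = "A", alt = alt, rad_tag = rad_tag,
                             stringsAsFactors = FALSE))
}

toy_meta <- function(gm, meadow = "M01") {
  data.frame(sample = gm$samples, meadow = rep_len(meadow,
                                                   length(gm$samples)),
             replicate_group = gm$samples, lat = 58, lon = 11,
             stringsAsFactors = FALSE)
}

# adjusted Rand index between two label vectors (contingency-table formula)
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# brute-force pairwise distances by explicit per-locus loops
brute_distance <- function(gm, metric) {
  n <- length(gm$samples)
  d <- matrix(0, n, n, dimnames = list(gm$samples, gm$samples))
  L <- ncol(gm$geno)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    acc <- 0; acc2 <- 0; ns <- 0
    for (l in seq_len(L)) {
      gi <- gm$geno[i, l]; gj <- gm$geno[j, l]
      if (!is.na(gi) && !is.na(gj)) {
        ns <- ns + 1
        acc <- acc + abs(gi - gj) / 2
        acc2 <- acc2 + (gi - gj)^2
      }
    }
    d[i, j] <- d[j, i] <- if (metric == "bitwise") acc / ns else
      sqrt(acc2 * L / ns)
  }
  d
}

# exhaustive ROH oracle: naive window scan, then enumeration of maximal
# candidate intervals respecting gap/length/SNP-count/het rules
oracle_roh_one <- function(g, pos, params) {
  L <- length(g)
  w <- params$window_snps
  if (L < w) return(data.frame())
  het <- !is.na(g) & g == 1
  mis <- is.na(g)
  pass <- logical(L - w + 1)
  for (s in seq_len(L - w + 1)) {
    win <- s:(s + w - 1)
    pass[s] <- sum(het[win]) <= params$max_het_per_window &&
      sum(mis[win]) <= params$max_missing_per_window
  }
  cand <- logical(L)
  for (i in seq_len(L)) {
    wins <- intersect(seq_len(L - w + 1), (i - w + 1):i)
    cand[i] <- mean(pass[wins]) >= params$hit_fraction
  }
  ok_int <- function(i, j) {
    idx <- i:j
    all(cand[idx]) &&
      all(diff(pos[idx]) <= params$max_gap_kb * 1000) &&
      sum(het[idx]) <= params$max_het_per_roh
  }
  segs <- NULL
  for (i in seq_len(L)) for (j in i:L) {
    if (!ok_int(i, j)) next
    maximal <- (i == 1 || !ok_int(i - 1, j)) && (j == L || !ok_int(i, j + 1))
    if (!maximal) next
    len <- pos[j] - pos[i] + 1
    if (len >= params$min_length_kb * 1000 &&
        (j - i + 1) >= params$min_snps_per_roh)
      segs <- rbind(segs, data.frame(start_bp = pos[i], end_bp = pos[j],
                                     length_bp = len, n_snps = j - i + 1,
                                     n_het = sum(het[i:j])))
  }
  if (is.null(segs)) data.frame() else segs
}

# exhaustive shortest path over a sea grid by Bellman-Ford-style relaxation
oracle_grid_distance <- function(sea, lat, lon, from_cell, to_cell) {
  nr <- nrow(sea); nc <- ncol(sea)
  dist <- matrix(Inf, nr, nc)
  dist[from_cell[1], from_cell[2]] <- 0
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!sea[r, cc]) next
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc || !sea[r2, c2]) next
        step <- geosphere::distHaversine(c(lon[cc], lat[r]),
                                         c(lon[c2], lat[r2])) / 1000
        cand <- dist[r, cc] + step
        if (cand < dist[r2, c2] - 1e-12) {
          dist[r2, c2] <- cand
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  dist[to_cell[1], to_cell[2]]
}

# bp-level Jaccard between truth tracts and detected segments, on a grid
tract_jaccard <- function(truth, segs, chrom_len, res = 1e4) {
  chroms <- names(chrom_len)
  n_cells <- sum(ceiling(chrom_len / res))
  offs <- c(0, cumsum(ceiling(chrom_len / res)))[seq_along(chroms)]
  names(offs) <- chroms
  mark <- function(df, sc, ec) {
    out <- rep(FALSE, n_cells)
    if (!nrow(df)) return(out)
    for (i in seq_len(nrow(df))) {
      a <- ceiling(df[[sc]][i] / res) + offs[df$chrom[i]]
      b <- floor(df[[ec]][i] / res) + offs[df$chrom[i]]
      if (b >= a) out[a:b] <- TRUE
    }
    out
  }
  gt <- mark(truth, "start", "end")
  ob <- mark(segs, "start_bp", "end_bp")
  if (!any(gt | ob)) return(1)
  sum(gt & ob) / sum(gt | ob)
}
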