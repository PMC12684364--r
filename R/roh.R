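#' Parameters for runs-of-homozygosity detection
#'
#' Defaults follow a PLINK `--homozyg` style configuration for a
#' reduced-representation eelgrass dataset: minimum ROH length 300 kb,
#' maximum inter-SNP gap 400 kb, scanning window of 7 SNPs, at least 10
#' SNPs per ROH, 1 heterozygous and 2 missing calls allowed per window, at
#' most 1 heterozygous call per ROH, and a per-SNP hit-fraction threshold
#' of 0.05.
#'
#' @param min_length_kb minimum segment length in kb.
#' @param max_gap_kb maximum gap between consecutive SNPs inside a segment.
#' @param window_snps scanning window size in SNPs.
#' @param min_snps_per_roh minimum SNP count per segment.
#' @param max_het_per_window heterozygous calls allowed per window.
#' @param max_missing_per_window missing calls allowed per window.
#' @param max_het_per_roh heterozygous calls allowed per segment.
#' @param hit_fraction minimum fraction of passing windows covering a SNP.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_length_kb = 300, max_gap_kb = 400,
                       window_snps = 7, min_snps_per_roh = 10,
                       max_het_per_window = 1, max_missing_per_window = 2,
                       max_het_per_roh = 1, hit_fraction = 0.05) {
  p <- list(min_length_kb = min_length_kb, max_gap_kb = max_gap_kb,
            window_snps = as.integer(window_snps),
            min_snps_per_roh = as.integer(min_snps_per_roh),
            max_het_per_window = max_het_per_window,
            max_missing_per_window = max_missing_per_window,
            max_het_per_roh = max_het_per_roh, hit_fraction = hit_fraction)
  if (any(unlist(p) <= 0))
    stop("all ROH parameters must be positive", call. = FALSE)
  if (p$window_snps > p$min_snps_per_roh)
    stop("window_snps must not exceed min_snps_per_roh", call. = FALSE)
  class(p) <- "roh_params"
  p
}

#' Detect runs of homozygosity
#'
#' Sliding-window scan per individual and chromosome on the full
#' (pre-monomorphic-filter) SNP set. A window of `window_snps` consecutive
#' SNPs passes when it contains at most `max_het_per_window` heterozygous
#' and `max_missing_per_window` missing calls. Each SNP's hit fraction is
#' the share of windows containing it that pass; SNPs at or above
#' `hit_fraction` form candidate stretches, which are split where the
#' inter-SNP gap exceeds `max_gap_kb`. A stretch is reported as a ROH when
#' it spans at least `min_length_kb`, contains at least `min_snps_per_roh`
#' SNPs and at most `max_het_per_roh` heterozygous calls. Missing calls
#' inside a stretch never break it.
#'
#' @param gm a [genotype_matrix()] of all sites (monomorphic included),
#'   positions sorted.
#' @param params a [roh_params()].
#' @return Data frame of segments: `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `length_bp`, `n_snps`, `n_het`.
#' @export
detect_roh <- function(gm, params = roh_params()) {
  stopifnot(inherits(gm, "genotype_matrix"), inherits(params, "roh_params"))
  out <- vector("list", 0)
  for (ch in unique(gm$loci$chrom)) {
    li <- which(gm$loci$chrom == ch)
    pos <- gm$loci$pos[li]
    if (is.unsorted(pos, strictly = TRUE))
      stop("positions not sorted on chromosome ", ch, call. = FALSE)
    for (s in gm$samples) {
      g <- gm$geno[s, li]
      segs <- roh_scan_one(g, pos, params)
      if (nrow(segs)) {
        segs$sample <- s; segs$chrom <- ch
        out[[length(out) + 1]] <- segs
      }
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snps = integer(),
                      n_het = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[, c("sample", "chrom", "start_bp", "end_bp", "length_bp", "n_snps",
          "n_het")]
}

# scan one individual on one chromosome; vectorized with running sums
roh_scan_one <- function(g, pos, params) {
  empty <- data.frame(start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), n_snps = integer(),
                      n_het = integer())
  L <- length(g)
  w <- params$window_snps
  if (L < w) return(empty)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- cumsum(c(0L, het)); cm <- cumsum(c(0L, mis))
  nwin <- L - w + 1L
  win_het <- ch[(w + 1):(L + 1)] - ch[1:nwin]
  win_mis <- cm[(w + 1):(L + 1)] - cm[1:nwin]
  pass <- win_het <= params$max_het_per_window &
    win_mis <= params$max_missing_per_window
  # SNP i is in windows max(1, i-w+1) .. min(nwin, i); hit fraction over them
  cp <- cumsum(c(0L, as.integer(pass)))
  i <- seq_len(L)
  lo <- pmax(1L, i - w + 1L); hi <- pmin(nwin, i)
  n_win <- hi - lo + 1L
  n_pass <- cp[hi + 1L] - cp[lo]
  cand <- n_pass / n_win >= params$hit_fraction

  if (!any(cand)) return(empty)
  # maximal runs of candidate SNPs, split at large gaps, then split again
  # at heterozygous calls beyond the per-ROH allowance (greedy left-to-right)
  r <- rle(cand)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  segs <- empty
  for (k in which(r$values)) {
    idx <- starts[k]:ends[k]
    gap_break <- which(diff(pos[idx]) > params$max_gap_kb * 1000)
    piece_start <- c(idx[1], idx[gap_break + 1])
    piece_end <- c(idx[gap_break], idx[length(idx)])
    for (pc in seq_along(piece_start)) {
      ii <- piece_start[pc]:piece_end[pc]
      for (jj in split_at_het(ii, het, params$max_het_per_roh)) {
        len <- pos[jj[length(jj)]] - pos[jj[1]] + 1L
        nh <- sum(het[jj])
        if (len >= params$min_length_kb * 1000 &&
            length(jj) >= params$min_snps_per_roh &&
            nh <= params$max_het_per_roh) {
          segs <- rbind(segs, data.frame(start_bp = pos[jj[1]],
                                         end_bp = pos[jj[length(jj)]],
                                         length_bp = len,
                                         n_snps = length(jj), n_het = nh))
        }
      }
    }
  }
  segs
}

# split a run of SNP indices so each piece carries at most max_het
# heterozygous calls; the het call that would exceed the allowance is
# dropped from both pieces
split_at_het <- function(idx, het, max_het) {
  out <- list()
  cur <- integer(0)
  nh <- 0L
  for (i in idx) {
    if (het[i] == 1L && nh >= max_het) {
      if (length(cur)) out[[length(out) + 1]] <- cur
      cur <- integer(0)
      nh <- 0L
    } else {
      cur <- c(cur, i)
      nh <- nh + het[i]
    }
  }
  if (length(cur)) out[[length(out) + 1]] <- cur
  out
}

#' Genome coverage attainable by ROH detection
#'
#' Converts every call to homozygous, reruns [detect_roh()] and divides the
#' mean per-individual total segment length by the genome size — the upper
#' bound on FRoH given the SNP density of the data.
#'
#' @param gm a [genotype_matrix()] of all sites.
#' @param params a [roh_params()].
#' @param genome_mb genome size in Mb used as denominator (default 240.2,
#'   the eelgrass assembly with scaffolds < 300 kb excluded).
#' @return Named list: `per_sample` coverage fractions and `mean`.
#' @export
genome_coverage <- function(gm, params = roh_params(), genome_mb = 240.2) {
  stopifnot(inherits(gm, "genotype_matrix"))
  g2 <- gm
  g2$geno[] <- 0L
  segs <- detect_roh(g2, params)
  tot <- stats::setNames(rep(0, length(gm$samples)), gm$samples)
  if (nrow(segs)) {
    agg <- tapply(segs$length_bp, segs$sample, sum)
    tot[names(agg)] <- agg
  }
  frac <- tot / (genome_mb * 1e6)
  list(per_sample = frac, mean = mean(frac))
}

#' Genomic inbreeding coefficient from ROH segments
#'
#' `FRoH = sum(length of segments >= min_len_mb) / denominator`.
#'
#' @param segments data frame from [detect_roh()] (one individual's rows, or
#'   use [roh_report()] for all).
#' @param min_len_mb segment length class in Mb (1 or 5 in the defaults).
#' @param denominator_mb denominator genome size in Mb (229.6 for the 1 Mb
#'   class, 228.4 for the 5 Mb class in eelgrass).
#' @return FRoH (scalar).
#' @export
froh <- function(segments, min_len_mb = 1, denominator_mb = 229.6) {
  if (denominator_mb <= 0) stop("denominator must be positive", call. = FALSE)
  keep <- segments$length_bp >= min_len_mb * 1e6
  sum(segments$length_bp[keep]) / (denominator_mb * 1e6)
}

#' Per-individual ROH report
#'
#' Runs [detect_roh()] and summarises per individual: `froh_1mb`,
#' `froh_5mb`, number of segments and total ROH length, plus the attainable
#' genome coverage.
#'
#' @param gm a [genotype_matrix()] of all sites.
#' @param params a [roh_params()].
#' @param genome_mb genome size for the coverage denominator.
#' @param denom_1mb,denom_5mb FRoH denominators in Mb for the two length
#'   classes (defaults 229.6 and 228.4).
#' @return A list of class `roh_report`: `segments` (all segments),
#'   `summary` (per-individual data frame), `coverage`.
#' @export
roh_report <- function(gm, params = roh_params(), genome_mb = 240.2,
                       denom_1mb = 229.6, denom_5mb = 228.4) {
  segs <- detect_roh(gm, params)
  summ <- do.call(rbind, lapply(gm$samples, function(s) {
    mine <- segs[segs$sample == s, , drop = FALSE]
    data.frame(sample = s, n_roh = nrow(mine),
               total_bp = sum(mine$length_bp),
               froh_1mb = froh(mine, 1, denom_1mb),
               froh_5mb = froh(mine, 5, denom_5mb),
               stringsAsFactors = FALSE)
  }))
  cov <- genome_coverage(gm, params, genome_mb)
  structure(list(segments = segs, summary = summ, coverage = cov),
            class = "roh_report")
}

#' Write ROH segments as a BED file
#'
#' 0-based half-open intervals, one row per segment, with the sample id in
#' the name column.
#'
#' @param segments data frame from [detect_roh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roh_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom, start = segments$start_bp - 1L,
                    end = segments$end_bp, name = segments$sample)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
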