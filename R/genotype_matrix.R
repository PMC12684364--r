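#' Construct a genotype matrix object
#'
#' The central container of the package: an individuals-by-loci matrix of
#' alt-allele dosages together with a locus map. Genotypes are coded as the
#' number of non-reference alleles carried (`0`, `1`, `2`) with `NA` for
#' missing calls, the usual dosage coding for diploid biallelic SNPs.
#'
#' @param geno integer/numeric matrix, samples in rows, loci in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param samples character vector of unique sample ids (row labels).
#' @param loci data frame with one row per locus and columns `chrom`,
#'   `pos` (1-based bp, strictly increasing within a chromosome), `ref`,
#'   `alt` (comma-separated when multiallelic) and `rad_tag` (id of the
#'   RAD locus the SNP sits on). An optional logical column `multiallelic`
#'   is derived from `alt` when absent.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, samples, loci) {
  geno <- as.matrix(geno)
  if (length(samples) != nrow(geno))
    stop("`samples` must have one entry per row of `geno`", call. = FALSE)
  if (anyDuplicated(samples))
    stop("sample ids must be unique", call. = FALSE)
  if (nrow(loci) != ncol(geno))
    stop("`loci` must have one row per column of `geno`", call. = FALSE)
  required <- c("chrom", "pos", "ref", "alt", "rad_tag")
  missing_cols <- setdiff(required, names(loci))
  if (length(missing_cols))
    stop("`loci` lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad))
    stop("genotype codes must be 0, 1, 2 or NA", call. = FALSE)
  if (is.null(loci$multiallelic))
    loci$multiallelic <- grepl(",", loci$alt, fixed = TRUE)
  # positions strictly increasing within each chromosome
  for (ch in unique(loci$chrom)) {
    p <- loci$pos[loci$chrom == ch]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch,
           call. = FALSE)
  }
  storage.mode(geno) <- "integer"
  rownames(geno) <- samples
  rownames(loci) <- NULL
  structure(list(geno = geno, samples = as.character(samples), loci = loci),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", length(x$samples), " samples x ",
      nrow(x$loci), " loci\n", sep = "")
  cat("  chromosomes:", length(unique(x$loci$chrom)),
      " missing calls:", sprintf("%.1f%%", 100 * mean(is.na(x$geno))), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Subset a genotype matrix by samples and/or loci
#'
#' @param gm a [genotype_matrix()].
#' @param samples sample ids or logical/integer index over samples.
#' @param loci logical/integer index over loci.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  si <- seq_along(gm$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples) else
      si[samples]
    if (anyNA(si)) stop("unknown sample id(s)", call. = FALSE)
  }
  li <- seq_len(nrow(gm$loci))
  if (!is.null(loci)) li <- li[loci]
  genotype_matrix(gm$geno[si, li, drop = FALSE], gm$samples[si],
                  gm$loci[li, , drop = FALSE])
}

#' Per-sample missingness
#'
#' @param gm a [genotype_matrix()].
#' @return Named numeric vector, fraction of missing calls per sample.
#' @export
sample_missingness <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  rowMeans(is.na(gm$geno))
}
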