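#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses the GT field of a VCF 4.x file (plain or gzipped) with
#' \pkg{vcfR} and converts calls to alt-allele dosages. Multiallelic sites
#' are retained and flagged (`loci$multiallelic`); their dosage counts any
#' non-reference allele, and the downstream [filter_cascade()] removes them
#' at its first step. Missing calls (`./.` or `.`) become `NA`.
#'
#' The RAD-tag id of each SNP is taken from the INFO key given in
#' `tag_info_key` when present; otherwise tags are derived by binning
#' positions into `tag_bp` windows per chromosome, which mirrors the fixed
#' read length of reduced-representation tags.
#'
#' @param path path to a `.vcf` or `.vcf.gz` file.
#' @param tag_info_key INFO key holding the RAD-tag id (default `"TAG"`).
#' @param tag_bp window used to derive tags when the key is absent
#'   (default 36 bp, a 2bRAD tag length).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, tag_info_key = "TAG", tag_bp = 36) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  # light sanity check before handing the file to the parser
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  head_lines <- tryCatch(readLines(con, n = 1000L, warn = FALSE),
                         finally = close(con))
  if (!any(startsWith(head_lines, "#CHROM")))
    stop("malformed VCF: no #CHROM header line found in ", path,
         call. = FALSE)
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF (", conditionMessage(e),
                                         ")", call. = FALSE))
  fix <- v@fix
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  gt <- v@gt
  if (is.null(gt) || ncol(gt) < 2)
    stop("VCF contains no sample genotype columns", call. = FALSE)
  samples <- colnames(gt)[-1]
  # GT is the first colon-separated field per VCF spec ordering
  gt_only <- sub(":.*$", "", gt[, -1, drop = FALSE])
  alleles <- strsplit(gsub("\\|", "/", gt_only), "/", fixed = FALSE)
  dosage <- vapply(alleles, function(a) {
    if (length(a) == 0 || anyNA(a) || any(a == "." | a == ""))
      return(NA_integer_)
    sum(a != "0")
  }, integer(1))
  geno <- matrix(dosage, nrow = nrow(gt), ncol = length(samples))
  geno <- t(geno)  # samples x loci

  info <- fix[, "INFO"]
  tag <- rep(NA_character_, nrow(fix))
  if (!is.null(info)) {
    m <- regmatches(info, regexpr(paste0("(^|;)", tag_info_key, "=[^;]+"),
                                  info))
    has <- lengths(regmatches(info,
      gregexpr(paste0("(^|;)", tag_info_key, "="), info))) > 0
    tag[has] <- sub(paste0(".*", tag_info_key, "="), "", m)
  }
  pos <- as.integer(fix[, "POS"])
  derived <- paste0(fix[, "CHROM"], "_t", (pos - 1L) %/% as.integer(tag_bp))
  tag[is.na(tag)] <- derived[is.na(tag)]

  loci <- data.frame(chrom = fix[, "CHROM"], pos = pos,
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     rad_tag = tag, stringsAsFactors = FALSE)
  genotype_matrix(geno, samples, loci)
}

#' Write a genotype matrix as a VCF file
#'
#' Emits an uncompressed VCF 4.2 text file with GT-only genotype columns
#' and the RAD-tag id in INFO, so that [read_vcf()] round-trips exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=TAG,Number=1,Type=String,Description=\"RAD tag id\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gm$samples), collapse = "\t"))
  code2gt <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow = nrow(gm$loci), ncol = length(gm$samples))
  g <- t(gm$geno)  # loci x samples
  ok <- !is.na(g)
  gt[ok] <- code2gt[as.character(g[ok])]
  body <- paste(gm$loci$chrom, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
                ".", "PASS", paste0("TAG=", gm$loci$rad_tag), "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read sample metadata
#'
#' Expects a UTF-8 CSV with a header row and at least the columns `sample`,
#' `meadow`, `replicate_group`, `lat`, `lon`. Technical replicates of the
#' same extraction share a `replicate_group` id.
#'
#' @param path CSV file path.
#' @param gm optional [genotype_matrix()]; when given, every sample in `gm`
#'   must have a metadata row.
#' @return A data frame of sample metadata.
#' @export
read_sample_metadata <- function(path, gm = NULL) {
  sm <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample", "meadow", "replicate_group", "lat", "lon")
  miss <- setdiff(required, names(sm))
  if (length(miss))
    stop("sample metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!nzchar(sm$replicate_group)))
    stop("replicate_group must be non-empty for every sample", call. = FALSE)
  if (!is.null(gm)) {
    absent <- setdiff(gm$samples, sm$sample)
    if (length(absent))
      stop("samples without metadata: ", paste(absent, collapse = ", "),
           call. = FALSE)
  }
  sm
}

#' Read meadow metadata
#'
#' Expects a CSV with columns `code`, `size_ha` (may be NA), `impact`
#' (`impacted`/`reference`), `cluster` (may be NA), `areal_change_pct`,
#' `waterbody`. A `size_class` column (`small` < 20 ha, else `large`) is
#' derived when absent and checked for consistency when present.
#'
#' @param path CSV file path.
#' @param small_max_ha size below which a meadow is classed `small`
#'   (default 20).
#' @return A data frame of meadow metadata.
#' @export
read_meadow_metadata <- function(path, small_max_ha = 20) {
  mm <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("code", "size_ha", "impact", "waterbody")
  miss <- setdiff(required, names(mm))
  if (length(miss))
    stop("meadow metadata lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- !(tolower(mm$impact) %in% c("impacted", "reference"))
  if (any(bad))
    stop("impact class must be 'impacted' or 'reference'; offending rows: ",
         paste(mm$code[bad], collapse = ", "), call. = FALSE)
  mm$impact <- tolower(mm$impact)
  derived <- ifelse(is.na(mm$size_ha), NA_character_,
                    ifelse(mm$size_ha < small_max_ha, "small", "large"))
  if (is.null(mm$size_class)) {
    mm$size_class <- derived
  } else {
    conflict <- !is.na(derived) & !is.na(mm$size_class) &
      mm$size_class != derived
    if (any(conflict))
      stop("size_class inconsistent with size_ha for: ",
           paste(mm$code[conflict], collapse = ", "), call. = FALSE)
  }
  if (is.null(mm$cluster)) mm$cluster <- NA_character_
  mm$cluster[!is.na(mm$cluster) & !nzchar(mm$cluster)] <- NA_character_
  mm
}

#' Post-calling SNP and sample filter cascade
#'
#' Applies, in order: (1) keep biallelic SNPs; (2) site missingness
#' <= `site_miss`; (3) drop sites with heterozygote fraction >
#' `max_het_frac` (fraction among non-missing calls); (4) drop samples with
#' missingness >= `sample_miss1`; (5) thin to one SNP per RAD tag keeping
#' the highest minor-allele frequency (ties broken by lowest position);
#' (6) drop monomorphic sites; (7) drop samples with missingness >
#' `sample_miss2`. Every step is recorded in a filter report.
#'
#' @param gm a [genotype_matrix()].
#' @param site_miss maximum site missingness (default 0.10).
#' @param max_het_frac maximum heterozygote fraction per site (default 0.5).
#' @param sample_miss1 first sample-missingness cut, applied as `>=`
#'   (default 0.40).
#' @param sample_miss2 final sample-missingness cut, applied as `>`
#'   (default 0.25).
#' @param keep_monomorphic set `TRUE` to skip step 6 — needed when the
#'   output feeds runs-of-homozygosity detection, which uses all sites.
#' @return A list with elements `gm` (filtered matrix) and `report`
#'   (data frame with `step`, `sites_in`, `sites_out`, `samples_in`,
#'   `samples_out`).
#' @export
filter_cascade <- function(gm, site_miss = 0.10, max_het_frac = 0.5,
                           sample_miss1 = 0.40, sample_miss2 = 0.25,
                           keep_monomorphic = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  report <- data.frame(step = character(), sites_in = integer(),
                       sites_out = integer(), samples_in = integer(),
                       samples_out = integer(), stringsAsFactors = FALSE)
  note <- function(step, before, after) {
    report[nrow(report) + 1L, ] <<- list(step, ncol(before$geno),
                                         ncol(after$geno), nrow(before$geno),
                                         nrow(after$geno))
    if (ncol(after$geno) == 0L)
      stop("filter cascade removed all sites at step '", step, "'",
           call. = FALSE)
    after
  }

  g1 <- gm_subset(gm, loci = !gm$loci$multiallelic)
  g1 <- note("biallelic", gm, g1)

  miss <- colMeans(is.na(g1$geno))
  g2 <- note("site_missingness", g1, gm_subset(g1, loci = miss <= site_miss))

  het <- colMeans(g2$geno == 1L, na.rm = TRUE)
  het[is.nan(het)] <- 0
  g3 <- note("het_fraction", g2, gm_subset(g2, loci = het <= max_het_frac))

  smiss <- sample_missingness(g3)
  g4 <- note("sample_missingness_40", g3,
             gm_subset(g3, samples = smiss < sample_miss1))

  g5 <- note("thin_rad_tags", g4, thin_rad_tags(g4))

  if (keep_monomorphic) {
    g6 <- g5
  } else {
    poly <- site_is_polymorphic(g5)
    g6 <- note("monomorphic", g5, gm_subset(g5, loci = poly))
  }

  smiss <- sample_missingness(g6)
  g7 <- note("sample_missingness_25", g6,
             gm_subset(g6, samples = smiss <= sample_miss2))

  list(gm = g7, report = report)
}

# one SNP per rad_tag: highest MAF wins, tie -> lowest position
thin_rad_tags <- function(gm) {
  p <- colMeans(gm$geno, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  ord <- order(gm$loci$rad_tag, -maf, gm$loci$pos)
  keep_first <- !duplicated(gm$loci$rad_tag[ord])
  keep <- sort(ord[keep_first])
  gm_subset(gm, loci = keep)
}

site_is_polymorphic <- function(gm) {
  g <- gm$geno
  has_alt <- colSums(g > 0L, na.rm = TRUE) > 0L
  has_ref <- colSums(g < 2L, na.rm = TRUE) > 0L
  n_called <- colSums(!is.na(g))
  has_alt & has_ref & n_called > 0L
}

#' Write a filter report as CSV
#'
#' @param report the `report` element of [filter_cascade()]'s result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
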