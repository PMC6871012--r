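#' Read a VCF file into a variant matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into alt-allele dosages. Only
#' biallelic SNP records are kept: multiallelic records (comma in ALT) are
#' skipped with a warning. Genotypes must carry a GT field; \code{./.} and
#' \code{.} become missing. If the INFO column provides DP it is stored as
#' per-variant mean depth for the depth filter.
#'
#' @param path VCF file path (plain or bgzipped).
#' @param population optional per-sample labels, in file sample order.
#' @return a [variant_matrix()].
#' @export
read_vcf <- function(path, population = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (nrow(fix) == 0) stop("VCF contains no variant records")
  fmt <- v@gt[, "FORMAT"]
  if (!all(grepl("(^|:)GT(:|$)", fmt)))
    stop("VCF records without a GT field are not supported")
  chrom <- fix[, "CHROM"]; pos <- as.integer(fix[, "POS"])
  # sortedness: positions must be non-decreasing within each chromosome block
  bad <- which(c(FALSE, pos[-1] < pos[-length(pos)] &
                 chrom[-1] == chrom[-length(chrom)]))
  if (length(bad))
    stop(sprintf("VCF is not coordinate-sorted: first offending record %s:%d",
                 chrom[bad[1]], pos[bad[1]]))
  multi <- grepl(",", fix[, "ALT"]) | is.na(fix[, "ALT"])
  if (any(multi))
    warning(sprintf("skipping %d multiallelic record(s)", sum(multi)))
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[keep, , drop = FALSE]
  alleles1 <- substr(gt, 1, 1)
  alleles2 <- ifelse(nchar(gt) >= 3, substr(gt, 3, 3), alleles1)
  dose <- (alleles1 == "1") + (alleles2 == "1")
  dose[alleles1 == "." | alleles2 == "." | is.na(gt)] <- NA
  dose <- t(matrix(dose, nrow = nrow(gt), dimnames = dimnames(gt)))
  depth <- suppressWarnings(
    as.numeric(vcfR::extract.info(v, "DP")[keep]))
  if (all(is.na(depth))) depth <- NULL
  variant_matrix(dose,
                 chrom = chrom[keep], pos = pos[keep],
                 ref = fix[keep, "REF"], alt = fix[keep, "ALT"],
                 sample_ids = colnames(v@gt)[-1],
                 population = population,
                 mean_depth = depth)
}

#' Write a variant matrix as VCF 4.2
#'
#' Emits a GT-only VCF: dosage 0 becomes \code{0/0}, 1 becomes \code{0/1},
#' 2 becomes \code{1/1} and missing becomes \code{./.}. One \code{##contig}
#' line is written per chromosome (lengths from \code{chrom_length} when
#' available, otherwise the largest position).
#'
#' @param vm a [variant_matrix()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vcf <- function(vm, path) {
  stopifnot(inherits(vm, "variant_matrix"))
  chroms <- unique(vm$chrom)
  clen <- vapply(chroms, function(ch) {
    if (!is.null(vm$chrom_length) && ch %in% names(vm$chrom_length))
      as.numeric(vm$chrom_length[[ch]])
    else if (any(vm$chrom == ch)) max(vm$pos[vm$chrom == ch]) else 0
  }, numeric(1))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%.0f>", chroms, clen),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vm$sample_ids), collapse = "\t"))
  gt_codes <- c("0/0", "0/1", "1/1")
  n_var <- ncol(vm$dosage)
  body <- character(n_var)
  for (j in seq_len(n_var)) {
    d <- vm$dosage[, j]
    gt <- ifelse(is.na(d), "./.", gt_codes[d + 1])
    body[j] <- paste(c(vm$chrom[j], vm$pos[j], ".", vm$ref[j], vm$alt[j],
                       ".", "PASS", ".", "GT", gt), collapse = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Filter variants on MAF, missingness and mean depth
#'
#' Keeps variants with minor-allele frequency at least \code{maf_min}
#' (computed over non-missing genotypes), missing fraction at most
#' \code{miss_max}, and (when depth data are present and
#' \code{mean_depth_max} is given) mean depth not exceeding
#' \code{mean_depth_max}. Variant order is preserved; removing everything
#' yields an empty matrix with a warning.
#'
#' @param vm a [variant_matrix()].
#' @param maf_min minimum minor-allele frequency in [0, 1].
#' @param miss_max maximum missing fraction in [0, 1].
#' @param mean_depth_max optional maximum mean depth (the resequencing-era
#'   guard against collapsed repeats); ignored when no depth data exist.
#' @return the filtered [variant_matrix()].
#' @export
filter_variants <- function(vm, maf_min = 0.05, miss_max = 0.5,
                            mean_depth_max = NULL) {
  stopifnot(inherits(vm, "variant_matrix"),
            maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1)
  m <- maf(vm)
  missf <- colMeans(is.na(vm$dosage))
  keep <- !is.na(m) & m >= maf_min & missf <= miss_max
  if (!is.null(mean_depth_max) && !is.null(vm$mean_depth))
    keep <- keep & (is.na(vm$mean_depth) | vm$mean_depth <= mean_depth_max)
  if (!any(keep)) warning("all variants removed by filtering")
  vm[, keep]
}

#' Read / write the tidy phenotype table
#'
#' CSV schema: \code{genotype, environment, year, stress, replication,
#' block, trait, value} (one trial record per row).
#'
#' @param path CSV path.
#' @return \code{read_phenotypes}: a data frame with the schema above.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("genotype", "environment", "value")
  if (!all(need %in% names(df)))
    stop("phenotype table must contain at least: ",
         paste(need, collapse = ", "))
  df
}

#' @rdname read_phenotypes
#' @param pheno a phenotype data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
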