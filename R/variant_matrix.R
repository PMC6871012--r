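#' Construct a variant matrix
#'
#' The central genotype container: a samples x variants matrix of alt-allele
#' dosages (0, 1, 2 or \code{NA} for missing) together with variant
#' coordinates, alleles and optional per-sample population labels. Only
#' biallelic SNPs are represented; positions are 1-based and strictly
#' increasing within each chromosome.
#'
#' @param dosage numeric matrix, samples in rows, variants in columns; values
#'   in \{0, 1, 2, NA\}.
#' @param chrom character vector of chromosome names, one per variant.
#' @param pos integer vector of 1-based positions, one per variant.
#' @param ref,alt single-base reference / alternate alleles (recycled "A"/"T"
#'   placeholders if omitted — the dosage algebra never inspects them).
#' @param sample_ids character vector of sample names; defaults to rownames
#'   of \code{dosage} or \code{S1..Sn}.
#' @param population per-sample labels (e.g. "wild", "cultivated", "B", "R");
#'   optional.
#' @param mean_depth optional per-variant mean sequencing depth (used by the
#'   depth filter).
#' @param chrom_length optional named vector of chromosome lengths in bp;
#'   used by the window scan to tile complete chromosomes.
#' @return An object of class \code{variant_matrix}.
#' @export
variant_matrix <- function(dosage, chrom, pos, ref = NULL, alt = NULL,
                           sample_ids = NULL, population = NULL,
                           mean_depth = NULL, chrom_length = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  p <- ncol(dosage)
  n <- nrow(dosage)
  if (length(chrom) != p || length(pos) != p)
    stop("chrom/pos must have one entry per variant column")
  if (is.null(ref)) ref <- rep("A", p)
  if (is.null(alt)) alt <- rep("T", p)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosage)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(n))
  }
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    stop("dosage values must be 0, 1, 2 or NA")
  o <- order(chrom, pos)
  if (!identical(o, seq_len(p))) {
    dosage <- dosage[, o, drop = FALSE]
    chrom <- chrom[o]; pos <- pos[o]; ref <- ref[o]; alt <- alt[o]
    if (!is.null(mean_depth)) mean_depth <- mean_depth[o]
  }
  if (anyDuplicated(paste(chrom, pos)))
    warning("duplicated chrom:pos coordinates present")
  rownames(dosage) <- sample_ids
  structure(list(
    dosage = dosage,
    sample_ids = as.character(sample_ids),
    population = if (is.null(population)) NULL else as.character(population),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = as.character(ref),
    alt = as.character(alt),
    mean_depth = mean_depth,
    chrom_length = chrom_length
  ), class = "variant_matrix")
}

#' @export
print.variant_matrix <- function(x, ...) {
  cat(sprintf("variant_matrix: %d samples x %d variants\n",
              nrow(x$dosage), ncol(x$dosage)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$chrom), collapse = ", ")))
  if (!is.null(x$population))
    cat("  populations:",
        paste(sprintf("%s (%d)", names(table(x$population)),
                      table(x$population)), collapse = ", "), "\n")
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.variant_matrix <- function(x) dim(x$dosage)

#' Number of variants
#' @param vm a \code{variant_matrix}.
#' @return integer count of variant columns.
#' @export
n_variants <- function(vm) ncol(vm$dosage)

#' Number of samples
#' @param vm a \code{variant_matrix}.
#' @return integer count of samples.
#' @export
n_samples <- function(vm) nrow(vm$dosage)

#' Subset a variant matrix
#'
#' @param x a \code{variant_matrix}.
#' @param i sample index (logical, integer or sample id).
#' @param j variant index.
#' @param ... unused.
#' @return a \code{variant_matrix} restricted to the requested samples and
#'   variants (variant order preserved).
#' @export
`[.variant_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, x$sample_ids)
  variant_matrix(
    x$dosage[i, j, drop = FALSE],
    chrom = x$chrom[j], pos = x$pos[j], ref = x$ref[j], alt = x$alt[j],
    sample_ids = x$sample_ids[i],
    population = if (is.null(x$population)) NULL else x$population[i],
    mean_depth = if (is.null(x$mean_depth)) NULL else x$mean_depth[j],
    chrom_length = x$chrom_length
  )
}

#' Alternate-allele frequencies
#'
#' Per-variant alt-allele frequency computed over non-missing genotypes only.
#'
#' @param vm a \code{variant_matrix}.
#' @return numeric vector of frequencies in [0, 1] (NaN where all missing).
#' @export
allele_freq <- function(vm) {
  colMeans(vm$dosage, na.rm = TRUE) / 2
}

#' Minor-allele frequencies
#' @param vm a \code{variant_matrix}.
#' @return numeric vector, \code{pmin(p, 1 - p)} of [allele_freq()].
#' @export
maf <- function(vm) {
  p <- allele_freq(vm)
  pmin(p, 1 - p)
}

# internal: TRUE if every non-missing dosage is homozygous (0 or 2)
is_inbred <- function(vm) {
  d <- vm$dosage[!is.na(vm$dosage)]
  all(d %in% c(0, 2))
}
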