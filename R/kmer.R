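#' Canonical k-mer depth histogram from sequences
#'
#' Slides a window of width \code{k} by 1 bp over every sequence, collapses
#' each k-mer with its reverse complement (lexicographic minimum =
#' "canonical" form), drops any window containing a base outside A/C/G/T
#' (e.g. N), and tabulates how many distinct k-mers occur at each depth.
#'
#' @param sequences a \code{Biostrings::DNAStringSet}, a character vector of
#'   sequences, or the path to a FASTA file.
#' @param k k-mer length (>= 1; the paper-standard choice is 17).
#' @return an object of class \code{kmer_histogram} with fields \code{k},
#'   \code{counts} (named integer vector, names are depths) and
#'   \code{total_kmers} (= sum depth * count).
#' @export
kmer_histogram <- function(sequences, k = 17L) {
  stopifnot(k >= 1)
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- Biostrings::readDNAStringSet(sequences)
  if (inherits(sequences, "DNAStringSet"))
    sequences <- as.character(sequences)
  kmers <- unlist(lapply(sequences, canonical_kmers, k = k))
  if (!length(kmers))
    return(new_kmer_histogram(k = k, counts = integer(0)))
  tab <- table(table(kmers))
  counts <- as.integer(tab)
  names(counts) <- names(tab)
  new_kmer_histogram(k = k, counts = counts)
}

#' Estimate genome size from a k-mer histogram
#'
#' Applies the classic identity \emph{genome size = total k-mers / peak
#' depth}, where the peak depth is the mode of the depth histogram after
#' discarding the low-depth error shoulder (depths below
#' \code{error_depth_cutoff}).
#'
#' @param hist a \code{kmer_histogram}.
#' @param error_depth_cutoff smallest depth considered genuine (default 3).
#' @return estimated genome size in bp.
#' @export
estimate_genome_size <- function(hist, error_depth_cutoff = 3L) {
  stopifnot(inherits(hist, "kmer_histogram"))
  depths <- as.integer(names(hist$counts))
  keep <- depths >= error_depth_cutoff
  if (!any(keep)) stop("no k-mer depth at or above the error cutoff")
  d <- depths[keep]; n <- hist$counts[keep]
  peak_depth <- d[which.max(n)]
  hist$total_kmers / peak_depth
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("kmer_histogram: k = %d, %d depth classes, total k-mers %.0f\n",
              x$k, length(x$counts), x$total_kmers))
  invisible(x)
}

# internal ------------------------------------------------------------------

new_kmer_histogram <- function(k, counts) {
  counts <- counts[order(as.integer(names(counts)))]
  structure(list(
    k = as.integer(k),
    counts = counts,
    total_kmers = sum(as.numeric(names(counts)) * as.numeric(counts))
  ), class = "kmer_histogram")
}

# all canonical k-mers of one sequence; windows containing non-ACGT skipped
canonical_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  fw <- substring(seq, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", fw)
  fw <- fw[ok]
  if (!length(fw)) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(fw)))
  pmin(fw, rc)
}
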