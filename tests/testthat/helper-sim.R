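# shared fixtures and independent oracles, built in code at test time

# allele frequencies with a neutral-like site frequency spectrum
# (density proportional to 1/p), for equilibrium-style simulations
neutral_sfs_freqs <- function(n_loci, seed, lower = 0.001) {
  set.seed(seed)
  lower * ((1 - lower) / lower)^runif(n_loci)
}

# plain Hardy-Weinberg diploid panel at fixed frequencies
hwe_panel <- function(n, p, pos = NULL, seed = 1) {
  set.seed(seed)
  L <- length(p)
  D <- matrix(rbinom(n * L, 2, rep(p, each = n)), n)
  if (is.null(pos)) pos <- seq_len(L) * 100
  variant_matrix(D, chrom = rep("chr1", L), pos = pos)
}

# two-founder copying-model haplotypes: correlation between loci decays as
# exp(-2 d / decay_length), so mean r2 crosses 0.2 near decay_length*log(5)/4
copying_haplotypes <- function(n, n_loci, chrom_length, decay_length, seed) {
  set.seed(seed)
  pos <- sort(sample.int(chrom_length, n_loci))
  f1 <- rbinom(n_loci, 1, 0.5)
  f2 <- rbinom(n_loci, 1, 0.5)
  D <- matrix(0, n, n_loci)
  for (i in seq_len(n)) {
    st <- rbinom(1, 1, 0.5)
    for (j in seq_len(n_loci)) {
      if (j > 1) {
        q <- (1 - exp(-2 * (pos[j] - pos[j - 1]) / decay_length)) / 2
        if (runif(1) < q) st <- 1 - st
      }
      D[i, j] <- 2 * (if (st == 0) f1[j] else f2[j])
    }
  }
  variant_matrix(D, chrom = rep("chr1", n_loci), pos = pos)
}

# independently coded Tajima (1989) constants, kept separate from the
# package implementation on purpose
tajima_d_oracle <- function(S, pi_sum, n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (pi_sum - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# brute-force canonical k-mer counter (dictionary based)
kmer_count_oracle <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(table(character(0)))
  kms <- substring(seq, 1:(n - k + 1), k:n)
  kms <- kms[!grepl("[^ACGT]", kms)]
  rc <- vapply(kms, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1))
  table(pmin(kms, rc))
}

# brute-force BH step-up rejection set
bh_oracle_reject <- function(p, alpha) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= alpha * i / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[o[seq_len(k)]] <- TRUE
  rej
}

# write a VCF text fixture from explicit lines
write_vcf_fixture <- function(body, samples = c("s1", "s2"), path = tempfile(fileext = ".vcf")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000000>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body), path)
  path
}
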