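# In-code fixtures and independent brute-force oracles shared across tests.

# Build a variant_table from a compact spec: positions, and a genotype
# matrix given row-wise as a vector (0/1/2/NA).
toy_vt <- function(pos, geno, samples = NULL, chrom = "chr1",
                   ref = "A", alt = "G") {
  geno <- matrix(as.integer(geno), nrow = length(pos), byrow = TRUE)
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(geno)))
  variant_table(
    sites = data.frame(chrom = chrom, pos = as.integer(pos), ref = ref,
                       alt = alt, stringsAsFactors = FALSE),
    genotypes = geno, samples = samples)
}

# Write a small VCF as literal text (independent of write_vcf).
write_toy_vcf <- function(records, samples, path = tempfile(fileext = ".vcf")) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

# Exhaustive-scan ROH oracle: explicit loops over every window and run,
# implementing the same windowed semantics as detect_roh but with no
# shared code (cumulative sums, vectorization).
oracle_roh_chrom <- function(pos, g, p) {
  n <- length(pos)
  segs <- list()
  if (n >= p$window_snp) {
    nw <- n - p$window_snp + 1L
    hom_win <- logical(nw)
    for (j in seq_len(nw)) {
      idx <- j:(j + p$window_snp - 1L)
      n_het <- 0L; n_mis <- 0L
      for (i in idx) {
        if (is.na(g[i])) n_mis <- n_mis + 1L
        else if (g[i] == 1L) n_het <- n_het + 1L
      }
      hom_win[j] <- n_het <= p$window_het && n_mis <= p$window_missing
    }
    eligible <- logical(n)
    for (i in seq_len(n)) {
      n_cov <- 0L; n_hom <- 0L
      for (j in seq_len(nw)) {
        if (j <= i && i <= j + p$window_snp - 1L) {
          n_cov <- n_cov + 1L
          if (hom_win[j]) n_hom <- n_hom + 1L
        }
      }
      eligible[i] <- n_cov > 0L && n_hom / n_cov >= p$window_threshold
    }
    i <- 1L
    while (i <= n) {
      if (!eligible[i]) { i <- i + 1L; next }
      j <- i
      while (j < n && eligible[j + 1L]) j <- j + 1L
      # split run [i, j] at gaps, then test each piece
      a <- i
      for (k in i:j) {
        end_piece <- (k == j) || (pos[k + 1L] - pos[k] > p$max_gap_kb * 1000)
        if (end_piece) {
          len <- pos[k] - pos[a] + 1
          nsnp <- k - a + 1L
          if (len >= p$min_kb * 1000 && nsnp >= p$min_snp &&
              (len / 1000) / nsnp <= p$density_kb_per_snp)
            segs[[length(segs) + 1L]] <-
              data.frame(start = pos[a], end = pos[k], n_snps = nsnp,
                         length = len)
          a <- k + 1L
        }
      }
      i <- j + 1L
    }
  }
  if (!length(segs))
    return(data.frame(start = integer(0), end = integer(0),
                      n_snps = integer(0), length = numeric(0)))
  do.call(rbind, segs)
}

# Brute-force per-window pi: mean pairwise difference per bp across all
# ordered pairs of sample alleles (each diploid contributes 2 alleles).
oracle_pi_window <- function(geno, window_len) {
  # geno: sites x samples matrix for the population, one window
  total <- 0
  for (row in seq_len(nrow(geno))) {
    g <- geno[row, ]
    alleles <- unlist(lapply(g[!is.na(g)], function(x)
      c(as.integer(x >= 1), as.integer(x == 2))))
    n <- length(alleles)
    if (n < 2) next
    diffs <- 0L
    for (a in seq_len(n - 1)) for (b in (a + 1):n)
      if (alleles[a] != alleles[b]) diffs <- diffs + 1L
    total <- total + diffs / choose(n, 2)
  }
  total / window_len
}

# Random variant table for property tests.
random_vt <- function(n_snps, n_samples, chrom = "chr1", span = 1e6,
                      het_prob = 0.3, miss_prob = 0.05) {
  pos <- sort(sample.int(span, n_snps))
  g <- matrix(sample(c(0L, 1L, 2L, NA),
                     n_snps * n_samples, replace = TRUE,
                     prob = c((1 - het_prob - miss_prob) / 2, het_prob,
                              (1 - het_prob - miss_prob) / 2, miss_prob)),
              nrow = n_snps)
  variant_table(
    sites = data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                       stringsAsFactors = FALSE),
    genotypes = g, samples = paste0("s", seq_len(n_samples)))
}
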