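#' Windowed nucleotide diversity (vcftools --window-pi semantics)
#'
#' For each population and non-overlapping window of `window_bp` bp, per-bp
#' nucleotide diversity is the sum over sites of the unbiased per-site
#' heterozygosity `2 j (n - j) / (n (n - 1))`, divided by the window length,
#' where `j` is the alt-allele count among the population's called alleles
#' at the site and `n` the called allele count. Missing genotypes shrink `n`
#' per site. Windows with no variants report pi = 0. When a layout is
#' supplied, windows tile every autosome and a terminal window shorter than
#' `window_bp` uses its true length as denominator; without a layout,
#' windows extend to the last observed site and use `window_bp`.
#'
#' Genome-wide pi is reported two ways per population: `pi_weighted`, the
#' length-weighted mean over windows (equivalently total site contributions
#' over total covered length, the canonical value), and `pi_window_mean`,
#' the unweighted mean of window values.
#'
#' @param vt a filtered biallelic `variant_table`.
#' @param panel a [sample_panel()].
#' @param layout optional [genome_layout()] used to tile windows.
#' @param window_bp window size in bp (default 500,000).
#' @return list with `$windows` (population, chrom, bin_start, bin_end,
#'   n_variants, pi) and `$genome` (population, pi_weighted,
#'   pi_window_mean).
#' @export
windowed_pi <- function(vt, panel, layout = NULL, window_bp = 5e5) {
  if (window_bp <= 0) stop("window_bp must be positive", call. = FALSE)
  sites <- vt$sites
  win_rows <- list()
  genome_rows <- list()
  for (pop in names(panel$populations)) {
    members <- intersect(panel$populations[[pop]], vt$samples)
    g <- vt$genotypes[, members, drop = FALSE]
    called <- rowSums(!is.na(g))
    n_al <- 2 * called
    j <- rowSums(g, na.rm = TRUE)
    contrib <- ifelse(n_al >= 2, 2 * j * (n_al - j) /
                        (n_al * pmax(n_al - 1, 1)), 0)
    segregating <- n_al >= 2 & j > 0 & j < n_al
    chroms <- if (is.null(layout)) unique(sites$chrom)
    else names(layout$lengths)
    wl <- list()
    for (ch in chroms) {
      idx <- which(sites$chrom == ch)
      chrom_len <- if (!is.null(layout)) layout$lengths[[ch]]
      else if (length(idx)) max(sites$pos[idx]) else 0
      if (chrom_len <= 0) next
      n_win <- ceiling(chrom_len / window_bp)
      bin <- (sites$pos[idx] - 1) %/% window_bp + 1
      sums <- rep(0, n_win)
      nvar <- rep(0L, n_win)
      if (length(idx)) {
        t1 <- tapply(contrib[idx], bin, sum)
        sums[as.integer(names(t1))] <- t1
        t2 <- tapply(segregating[idx], bin, sum)
        nvar[as.integer(names(t2))] <- t2
      }
      start <- (seq_len(n_win) - 1) * window_bp + 1
      end <- pmin(seq_len(n_win) * window_bp, chrom_len)
      wlen <- if (!is.null(layout)) end - start + 1
      else rep(window_bp, n_win)
      wl[[ch]] <- data.frame(population = pop, chrom = ch,
                             bin_start = start, bin_end = end,
                             n_variants = nvar, pi = sums / wlen,
                             stringsAsFactors = FALSE)
    }
    wdf <- do.call(rbind, wl)
    rownames(wdf) <- NULL
    win_rows[[pop]] <- wdf
    wlen <- wdf$bin_end - wdf$bin_start + 1
    genome_rows[[pop]] <- data.frame(
      population = pop,
      pi_weighted = sum(wdf$pi * wlen) / sum(wlen),
      pi_window_mean = mean(wdf$pi),
      stringsAsFactors = FALSE
    )
  }
  list(windows = do.call(rbind, c(win_rows, make.row.names = FALSE)),
       genome = do.call(rbind, c(genome_rows, make.row.names = FALSE)))
}

#' Per-individual observed heterozygosity (vcftools --het style counts)
#'
#' Observed heterozygosity per sample is the number of heterozygous
#' genotypes over the number of non-missing genotypes. A sample with zero
#' called genotypes reports `NA` rather than erroring.
#'
#' @param vt a `variant_table`.
#' @return data.frame with columns `sample`, `n_het`, `n_hom`, `n_called`,
#'   `het_rate`.
#' @export
individual_heterozygosity <- function(vt) {
  g <- vt$genotypes
  n_het <- colSums(g == 1L, na.rm = TRUE)
  n_called <- colSums(!is.na(g))
  data.frame(
    sample = vt$samples,
    n_het = n_het,
    n_hom = n_called - n_het,
    n_called = n_called,
    het_rate = ifelse(n_called > 0, n_het / n_called, NA_real_),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}
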