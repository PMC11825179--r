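#' ROH detection parameters (PLINK --homozyg semantics)
#'
#' Defaults mirror PLINK v1.90: a scanning window of `window_snp` SNPs is
#' called homozygous when it contains at most `window_het` heterozygous and
#' at most `window_missing` missing calls; a SNP is run-eligible when the
#' fraction of homozygous windows among the windows spanning it is at least
#' `window_threshold`. Candidate runs of eligible SNPs are split at
#' inter-SNP gaps larger than `max_gap_kb` and must satisfy the minimum
#' length (`min_kb`), minimum SNP count (`min_snp`) and maximum sparseness
#' (`density_kb_per_snp`, kb of span per SNP) tests.
#'
#' @param window_snp SNPs per scanning window (PLINK `--homozyg-window-snp`).
#' @param min_kb minimum run length in kb (PLINK `--homozyg-kb`).
#' @param density_kb_per_snp maximum kb per SNP in a run
#'   (PLINK `--homozyg-density`).
#' @param window_het maximum heterozygous calls per homozygous window.
#' @param window_missing maximum missing calls per homozygous window.
#' @param window_threshold minimum homozygous-window fraction for a SNP.
#' @param min_snp minimum SNPs per run.
#' @param max_gap_kb maximum inter-SNP gap within a run, kb.
#' @param final_min_length_kb post-hoc length cutoff applied by
#'   [filter_roh_min_length()] (segments shorter than this are excluded from
#'   downstream inbreeding summaries).
#' @return An object of class `roh_params`.
#' @export
roh_params <- function(window_snp = 20L, min_kb = 10, density_kb_per_snp = 50,
                       window_het = 1L, window_missing = 5L,
                       window_threshold = 0.05, min_snp = 100L,
                       max_gap_kb = 1000, final_min_length_kb = 100) {
  p <- list(window_snp = as.integer(window_snp), min_kb = min_kb,
            density_kb_per_snp = density_kb_per_snp,
            window_het = as.integer(window_het),
            window_missing = as.integer(window_missing),
            window_threshold = window_threshold,
            min_snp = as.integer(min_snp), max_gap_kb = max_gap_kb,
            final_min_length_kb = final_min_length_kb)
  stopifnot(p$window_snp > 0, p$min_kb > 0, p$density_kb_per_snp > 0,
            p$window_het >= 0, p$window_missing >= 0,
            p$window_threshold > 0, p$window_threshold <= 1,
            p$min_snp > 0, p$max_gap_kb > 0, p$final_min_length_kb > 0)
  structure(p, class = "roh_params")
}

#' Detect runs of homozygosity
#'
#' Windowed scan with PLINK 1.9 semantics (see [roh_params()]). Windows are
#' truncated at chromosome ends: SNPs near an end are spanned by fewer
#' windows and their homozygous fraction uses the actual spanning-window
#' count as denominator. Chromosomes with fewer SNPs than `window_snp` yield
#' no windows and therefore no runs.
#'
#' @param vt a `variant_table` of sorted biallelic autosomal SNPs.
#' @param samples samples to scan (default: all samples in `vt`).
#' @param params an [roh_params()] object.
#' @return data.frame with columns `sample`, `chrom`, `start`, `end`
#'   (1-based, closed), `n_snps`, `length` (bp).
#' @export
detect_roh <- function(vt, samples = NULL, params = roh_params()) {
  validate_variant_table(vt)
  if (is.null(samples)) samples <- vt$samples
  unknown <- setdiff(samples, vt$samples)
  if (length(unknown))
    stop("unknown sample(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  chroms <- unique(vt$sites$chrom)
  out <- list()
  for (s in samples) {
    g_all <- vt$genotypes[, s]
    for (ch in chroms) {
      idx <- which(vt$sites$chrom == ch)
      segs <- .roh_scan_chrom(vt$sites$pos[idx], g_all[idx], params)
      if (nrow(segs)) {
        segs$sample <- s
        segs$chrom <- ch
        out[[length(out) + 1L]] <- segs
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(sample = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      n_snps = integer(0), length = numeric(0)))
  res <- do.call(rbind, out)
  res[, c("sample", "chrom", "start", "end", "n_snps", "length")]
}

# Core windowed scan on one sample x chromosome. pos sorted ascending.
.roh_scan_chrom <- function(pos, g, p) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_snps = integer(0), length = numeric(0))
  n <- length(pos)
  W <- p$window_snp
  if (n < W) return(empty)
  het <- as.integer(!is.na(g) & g == 1L)
  mis <- as.integer(is.na(g))
  ch <- c(0L, cumsum(het))
  cm <- c(0L, cumsum(mis))
  nw <- n - W + 1L
  j <- seq_len(nw)
  hom_win <- (ch[j + W] - ch[j]) <= p$window_het &
    (cm[j + W] - cm[j]) <= p$window_missing
  chom <- c(0L, cumsum(hom_win))
  i <- seq_len(n)
  lo <- pmax(1L, i - W + 1L)
  hi <- pmin(nw, i)
  frac <- (chom[hi + 1L] - chom[lo]) / (hi - lo + 1L)
  eligible <- frac >= p$window_threshold
  # maximal runs of eligible SNPs, split at large gaps, then filtered
  r <- rle(eligible)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  segs <- list()
  for (k in which(r$values)) {
    a <- starts[k]; b <- ends[k]
    cut <- which(diff(pos[a:b]) > p$max_gap_kb * 1000)
    piece_start <- c(a, a + cut)
    piece_end <- c(a + cut - 1L, b)
    for (q in seq_along(piece_start)) {
      i1 <- piece_start[q]; i2 <- piece_end[q]
      nsnp <- i2 - i1 + 1L
      len <- pos[i2] - pos[i1] + 1
      if (len >= p$min_kb * 1000 && nsnp >= p$min_snp &&
          (len / 1000) / nsnp <= p$density_kb_per_snp) {
        segs[[length(segs) + 1L]] <-
          data.frame(start = pos[i1], end = pos[i2], n_snps = nsnp,
                     length = len)
      }
    }
  }
  if (length(segs) == 0L) return(empty)
  do.call(rbind, segs)
}

#' Exclude ROH segments below a length cutoff
#'
#' Segments shorter than `min_length` (default 100 kb) are excluded from all
#' downstream inbreeding statistics; the threshold is inclusive (a segment
#' of exactly `min_length` bp is kept).
#'
#' @param segs segment data.frame from [detect_roh()].
#' @param min_length minimum segment length in bp (default 1e5).
#' @return filtered segment data.frame.
#' @export
filter_roh_min_length <- function(segs, min_length = 1e5) {
  segs[segs$length >= min_length, , drop = FALSE]
}

#' Inbreeding coefficient from ROH
#'
#' F_ROH = L_ROH / L_AUTOSOME: total length of (autosomal) ROH segments over
#' the total autosome length of the layout.
#'
#' @param segs segment data.frame for one sample.
#' @param layout a [genome_layout()].
#' @return numeric in \[0, 1\].
#' @export
compute_froh <- function(segs, layout) {
  if (nrow(segs)) {
    bad <- setdiff(unique(segs$chrom), names(layout$lengths))
    if (length(bad))
      stop("segment chromosome(s) absent from layout: ",
           paste(bad, collapse = ", "), call. = FALSE)
    segs <- segs[segs$chrom %in% layout$autosomes, , drop = FALSE]
  }
  sum(segs$length) / autosome_length(layout)
}

#' Per-sample and per-population inbreeding summary
#'
#' For each sample: F_ROH overall and restricted to segments of at least
#' 1 Mb and 5 Mb, counts and total lengths in the length classes
#' \[100 kb, 1 Mb), \[1 Mb, 5 Mb) and >= 5 Mb, and the fraction of segments
#' shorter than 1 Mb. For each population: mean and sample-sd (n - 1) of
#' F_ROH, plus the pooled fraction of segments shorter than 1 Mb.
#'
#' @param segs segment data.frame (multiple samples; typically after
#'   [filter_roh_min_length()]).
#' @param layout a [genome_layout()].
#' @param panel a [sample_panel()]; samples with no segments get F_ROH = 0.
#' @return list with data.frames `$samples` and `$populations`.
#' @export
summarize_inbreeding <- function(segs, layout, panel) {
  samples <- names(panel$assignments)
  L <- autosome_length(layout)
  per <- lapply(samples, function(s) {
    ss <- segs[segs$sample == s & segs$chrom %in% layout$autosomes, ,
               drop = FALSE]
    len <- ss$length
    cls <- cut(len, breaks = c(1e5, 1e6, 5e6, Inf), right = FALSE,
               labels = c("100kb_1mb", "1mb_5mb", "ge_5mb"))
    data.frame(
      sample = s,
      population = unname(panel$assignments[s]),
      n_segments = length(len),
      l_roh = sum(len),
      froh = sum(len) / L,
      froh_ge_1mb = sum(len[len >= 1e6]) / L,
      froh_ge_5mb = sum(len[len >= 5e6]) / L,
      n_100kb_1mb = sum(cls == "100kb_1mb", na.rm = TRUE),
      n_1mb_5mb = sum(cls == "1mb_5mb", na.rm = TRUE),
      n_ge_5mb = sum(cls == "ge_5mb", na.rm = TRUE),
      frac_lt_1mb = if (length(len)) mean(len < 1e6) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  per <- do.call(rbind, per)
  pops <- lapply(names(panel$populations), function(p) {
    rows <- per[per$population == p, ]
    pooled <- segs[segs$sample %in% panel$populations[[p]] &
                     segs$chrom %in% layout$autosomes, , drop = FALSE]
    data.frame(
      population = p,
      n_samples = nrow(rows),
      mean_froh = mean(rows$froh),
      sd_froh = stats::sd(rows$froh),
      mean_froh_ge_1mb = mean(rows$froh_ge_1mb),
      sd_froh_ge_1mb = stats::sd(rows$froh_ge_1mb),
      frac_lt_1mb = if (nrow(pooled)) mean(pooled$length < 1e6)
      else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  list(samples = per, populations = do.call(rbind, pops))
}

#' Write ROH segments as a PLINK .hom-style TSV
#' @param segs segment data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_roh_segments <- function(segs, path) {
  out <- data.frame(sample = segs$sample, chrom = segs$chrom,
                    start = segs$start, end = segs$end,
                    n_snps = segs$n_snps, length_kb = segs$length / 1000)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
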