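#' Deleterious-to-synonymous ratios inside and outside ROH
#'
#' For each individual and deleterious category, every site where the
#' individual carries at least one derived allele is assigned to the ROH or
#' non-ROH compartment according to whether its position falls inside any
#' of that individual's ROH segments (closed intervals). The statistic is
#'
#'   ROHf    = N_m(in ROH)  / S(in ROH)
#'   nonROHf = N_m(outside) / S(outside)
#'
#' where N_m counts derived-allele-carrying sites of the category and S
#' counts derived-allele-carrying synonymous sites in the same compartment.
#' Under genetic purging, deleterious derived alleles are depleted in the
#' (homozygosity-exposing) ROH compartment, so ROHf < nonROHf. Populations
#' are compared by a paired two-sided Wilcoxon signed-rank test of ROHf
#' versus nonROHf across individuals; individuals with an undefined ratio
#' (zero synonymous count in a compartment) are excluded from the test with
#' a message.
#'
#' @param vt a `variant_table`.
#' @param segs ROH segment data.frame from [detect_roh()] (after
#'   [filter_roh_min_length()]).
#' @param effects classified effects from [classify_effects()].
#' @param polar a `polarized_table` over the sites of `vt`.
#' @param panel a [sample_panel()].
#' @param categories deleterious categories (default LoF, dnsSNP,
#'   missense).
#' @return list with data.frames `$individual` (counts, rohf, nonrohf,
#'   ratio) and `$population` (means, sds, paired Wilcoxon p-value,
#'   n_excluded).
#' @export
rohf_statistics <- function(vt, segs, effects, polar, panel,
                            categories = c("LoF", "dnsSNP", "missense")) {
  dose <- derived_dose(vt, polar)
  masks <- category_site_masks(vt, effects,
                               c(categories, "synonymous"))
  rows <- list()
  for (smp in vt$samples) {
    in_roh <- sites_in_roh(vt$sites, segs[segs$sample == smp, ,
                                          drop = FALSE])
    carrier <- !is.na(dose[, smp]) & dose[, smp] >= 1L
    s_in <- sum(carrier & masks$synonymous & in_roh)
    s_out <- sum(carrier & masks$synonymous & !in_roh)
    for (cat in categories) {
      n_in <- sum(carrier & masks[[cat]] & in_roh)
      n_out <- sum(carrier & masks[[cat]] & !in_roh)
      rohf <- if (s_in > 0) n_in / s_in else NA_real_
      nonrohf <- if (s_out > 0) n_out / s_out else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        sample = smp, population = unname(panel$assignments[smp]),
        category = cat, n_in = n_in, s_in = s_in, n_out = n_out,
        s_out = s_out, rohf = rohf, nonrohf = nonrohf,
        ratio = if (!is.na(rohf) && !is.na(nonrohf) && nonrohf > 0)
          rohf / nonrohf else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  ind <- do.call(rbind, c(rows, make.row.names = FALSE))
  pops <- list()
  for (p in names(panel$populations)) {
    for (cat in categories) {
      d <- ind[ind$population == p & ind$category == cat, ]
      ok <- !is.na(d$rohf) & !is.na(d$nonrohf)
      if (any(!ok))
        message(sum(!ok), " individual(s) in ", p, "/", cat,
                " excluded from the paired test (undefined ratio)")
      pval <- if (sum(ok) >= 2 && any(d$rohf[ok] != d$nonrohf[ok]))
        suppressWarnings(stats::wilcox.test(d$rohf[ok], d$nonrohf[ok],
                                            paired = TRUE))$p.value
      else NA_real_
      pops[[length(pops) + 1L]] <- data.frame(
        population = p, category = cat,
        mean_rohf = mean(d$rohf, na.rm = TRUE),
        sd_rohf = stats::sd(d$rohf[ok]),
        mean_nonrohf = mean(d$nonrohf, na.rm = TRUE),
        sd_nonrohf = stats::sd(d$nonrohf[ok]),
        mean_ratio = mean(d$ratio, na.rm = TRUE),
        p_value = pval, n_excluded = sum(!ok),
        stringsAsFactors = FALSE)
    }
  }
  list(individual = ind,
       population = do.call(rbind, c(pops, make.row.names = FALSE)))
}

# logical vector: is each site of `sites` inside any segment of `segs`
# (one sample's segments; closed intervals)?
sites_in_roh <- function(sites, segs) {
  out <- rep(FALSE, nrow(sites))
  if (nrow(segs) == 0L) return(out)
  for (ch in unique(segs$chrom)) {
    ss <- segs[segs$chrom == ch, , drop = FALSE]
    idx <- which(sites$chrom == ch)
    if (!length(idx)) next
    pos <- sites$pos[idx]
    hit <- rep(FALSE, length(pos))
    for (k in seq_len(nrow(ss)))
      hit <- hit | (pos >= ss$start[k] & pos <= ss$end[k])
    out[idx] <- hit
  }
  out
}

#' Rxy relative derived-load statistic with block-jackknife errors
#'
#' Compares the derived-allele burden of a functional category in
#' population X against population Y, normalized by intergenic (neutral)
#' sites:
#'
#'   L_X = sum over category sites of (m_X/s_X)(1 - m_Y/s_Y) /
#'         sum over intergenic sites of (m_X/s_X)(1 - m_Y/s_Y)
#'
#' L_Y is the symmetric quantity with X and Y swapped, and
#' R_X/Y = L_X / L_Y. R = 1 means equal load; R < 1 means Y carries more
#' derived load than X; R > 1 the reverse. Sites with zero called alleles
#' in either population, and unresolved sites, are skipped in both sums.
#'
#' The standard error comes from a delete-one-block jackknife over
#' `n_blocks` contiguous equal-size blocks of the used sites (category and
#' intergenic partitioned jointly, in genomic order), using the
#' pseudo-value variance.
#'
#' @param polar a `polarized_table` (or counts built with
#'   [polarized_table()]).
#' @param pop_x,pop_y population column names in `polar`.
#' @param category_sites,intergenic_sites logical or integer index over the
#'   rows of `polar$sites` selecting the category (C) and neutral (I) site
#'   sets.
#' @param n_blocks jackknife block count (default 20).
#' @return An object of class `rxy_result`: list with `r`, `l_x`, `l_y`,
#'   `se`, `pseudo_values`, `n_blocks`, `n_category`, `n_intergenic`.
#' @export
rxy <- function(polar, pop_x, pop_y, category_sites, intergenic_sites,
                n_blocks = 20L) {
  stopifnot(pop_x %in% polar$populations, pop_y %in% polar$populations)
  nsite <- nrow(polar$sites)
  to_idx <- function(x) if (is.logical(x)) which(x) else as.integer(x)
  ci <- to_idx(category_sites)
  ii <- to_idx(intergenic_sites)
  if (!length(ci) || !length(ii))
    stop("category and intergenic site sets must be nonempty",
         call. = FALSE)
  mx <- polar$m[, pop_x]; sx <- polar$s[, pop_x]
  my <- polar$m[, pop_y]; sy <- polar$s[, pop_y]
  usable <- !is.na(mx) & !is.na(my) & sx > 0 & sy > 0
  ci <- ci[usable[ci]]
  ii <- ii[usable[ii]]
  fx <- mx / sx
  fy <- my / sy
  term_x <- fx * (1 - fy)   # contributions to L_X sums
  term_y <- fy * (1 - fx)   # contributions to L_Y sums
  est <- function(cc, io) {
    den_x <- sum(term_x[io]); den_y <- sum(term_y[io])
    if (den_x == 0 || den_y == 0)
      stop("zero intergenic denominator: Rxy undefined", call. = FALSE)
    (sum(term_x[cc]) / den_x) / (sum(term_y[cc]) / den_y)
  }
  r_hat <- est(ci, ii)
  # joint contiguous blocks over the used sites, genomic order
  used <- sort(unique(c(ci, ii)))
  B <- max(1L, min(as.integer(n_blocks), length(used)))
  block_of_used <- ceiling(seq_along(used) / (length(used) / B))
  block <- rep(NA_integer_, nsite)
  block[used] <- block_of_used
  loo <- vapply(seq_len(B), function(b) {
    tryCatch(est(ci[block[ci] != b], ii[block[ii] != b]),
             error = function(e) NA_real_)
  }, numeric(1))
  pseudo <- B * r_hat - (B - 1) * loo
  valid <- sum(!is.na(pseudo))
  se <- if (valid > 1) stats::sd(pseudo[!is.na(pseudo)]) / sqrt(valid)
  else NA_real_
  structure(list(r = r_hat,
                 l_x = sum(term_x[ci]) / sum(term_x[ii]),
                 l_y = sum(term_y[ci]) / sum(term_y[ii]),
                 se = se, pseudo_values = pseudo, n_blocks = B,
                 n_category = length(ci), n_intergenic = length(ii),
                 pop_x = pop_x, pop_y = pop_y),
            class = "rxy_result")
}

#' @export
print.rxy_result <- function(x, ...) {
  cat(sprintf("Rxy (%s / %s) = %.4f +/- %.4f (jackknife SE, %d blocks)\n",
              x$pop_x, x$pop_y, x$r, x$se, x$n_blocks))
  cat(sprintf("  L_X = %.4f, L_Y = %.4f; %d category, %d intergenic sites\n",
              x$l_x, x$l_y, x$n_category, x$n_intergenic))
  invisible(x)
}

#' Conservation track with top-quantile mask
#'
#' Attaches to a per-site conservation-score table the mask of the most
#' conserved fraction `top_q` of scored sites: the `ceiling(top_q * n)`
#' highest scores, ties broken by site order (deterministic).
#'
#' @param scores data.frame with columns `chrom`, `pos`, `score`.
#' @param top_q top quantile (default 0.001, i.e. top 0.1%).
#' @return data.frame with added logical column `top` and attribute
#'   `threshold` (lowest score inside the mask).
#' @export
conservation_track <- function(scores, top_q = 0.001) {
  sc <- as.data.frame(scores, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "score") %in% names(sc)))
  n <- sum(!is.na(sc$score))
  k <- max(1L, as.integer(ceiling(top_q * n)))
  ord <- order(-sc$score, seq_len(nrow(sc)), na.last = TRUE)
  top_idx <- ord[seq_len(min(k, n))]
  sc$top <- FALSE
  sc$top[top_idx] <- TRUE
  attr(sc, "threshold") <- min(sc$score[top_idx])
  attr(sc, "top_q") <- top_q
  sc
}

#' Read a conservation-score TSV (chrom, pos, score)
#' @param path file path (tab-separated, with header).
#' @param top_q top quantile passed to [conservation_track()].
#' @return a conservation track data.frame.
#' @export
read_conservation_track <- function(path, top_q = 0.001) {
  conservation_track(utils::read.table(path, header = TRUE, sep = "\t",
                                       stringsAsFactors = FALSE),
                     top_q = top_q)
}

#' Conservation-weighted relative mutational load
#'
#' Per individual: the sum, over sites in the top conservation quantile, of
#' derived-allele dose (heterozygote = 1, derived homozygote = 2) times the
#' site's conservation score, divided by the individual's total derived
#' allele count over all resolved polarized sites. A higher value means a
#' larger share of the individual's derived alleles falls in highly
#' conserved (putatively more deleterious) positions.
#'
#' @param vt a `variant_table`.
#' @param polar a `polarized_table` over the sites of `vt`.
#' @param track a [conservation_track()] (or raw scores data.frame, in
#'   which case the mask is derived here with `top_q`).
#' @param top_q top quantile used if `track` lacks a mask.
#' @return data.frame with `sample`, `weighted_sum`, `total_derived`,
#'   `relative_load`; attribute `threshold` carries the mask score cutoff.
#' @export
gerp_relative_load <- function(vt, polar, track, top_q = 0.001) {
  if (is.null(track$top)) track <- conservation_track(track, top_q)
  key_vt <- site_key(vt$sites$chrom, vt$sites$pos)
  key_tr <- site_key(track$chrom, track$pos)
  idx <- match(key_vt, key_tr)
  score <- track$score[idx]
  top <- track$top[idx]
  top[is.na(top)] <- FALSE
  dose <- derived_dose(vt, polar)
  w <- ifelse(top, score, 0)
  weighted <- colSums(dose * w, na.rm = TRUE)
  total <- colSums(dose, na.rm = TRUE)
  out <- data.frame(
    sample = vt$samples,
    weighted_sum = as.numeric(weighted),
    total_derived = as.numeric(total),
    relative_load = ifelse(total > 0, weighted / total, NA_real_),
    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "threshold") <- attr(track, "threshold")
  out
}

#' Derived site-frequency spectrum on a fixed subsample
#'
#' Projects each site's derived-allele count onto a fixed subsample of
#' `subsample_2n` alleles. At a site with `m` derived among `s` called
#' alleles, the contribution to frequency bin `k` (k = 0 .. subsample_2n)
#' is the hypergeometric probability of drawing `k` derived alleles in
#' `subsample_2n` draws without replacement — the deterministic expected
#' spectrum. A Monte-Carlo mode draws from the same hypergeometric instead
#' (a single draw per site by default). Bins 0 (absent) and `subsample_2n`
#' (fixed) are included. Sites with fewer than `subsample_2n` called
#' alleles are skipped.
#'
#' The damaging class pools LoF and missense sites; the neutral class is
#' intergenic sites.
#'
#' @param polar a `polarized_table`.
#' @param effects classified effects from [classify_effects()] over the
#'   same coordinates.
#' @param panel a [sample_panel()] (defines the population columns).
#' @param population population to compute the spectrum for.
#' @param subsample_2n even number of alleles to project onto.
#' @param mode `"expected"` (default) or `"montecarlo"`.
#' @param n_draws draws per site in Monte-Carlo mode (default 1).
#' @return An object of class `sfs_result`: list with `spectra` (matrix,
#'   classes x bins, proportions summing to 1 per class), `n_sites` per
#'   class, `population`, `subsample_2n`, `mode`.
#' @export
sfs <- function(polar, effects, panel, population, subsample_2n,
                mode = c("expected", "montecarlo"), n_draws = 1L) {
  mode <- match.arg(mode)
  if (subsample_2n %% 2 != 0 || subsample_2n <= 0)
    stop("subsample_2n must be a positive even allele count",
         call. = FALSE)
  stopifnot(population %in% polar$populations)
  key_pol <- site_key(polar$sites$chrom, polar$sites$pos)
  key_ef <- site_key(effects$chrom, effects$pos)
  cls <- effects$class[match(key_pol, key_ef)]
  m <- polar$m[, population]
  s <- polar$s[, population]
  ok <- !is.na(m) & s >= subsample_2n
  classes <- list(damaging = ok & !is.na(cls) & cls %in% c("LoF", "missense"),
                  neutral = ok & !is.na(cls) & cls == "intergenic")
  bins <- 0:subsample_2n
  spectra <- matrix(0, nrow = length(classes), ncol = length(bins),
                    dimnames = list(names(classes), as.character(bins)))
  n_sites_cls <- stats::setNames(integer(length(classes)), names(classes))
  for (cl in names(classes)) {
    idx <- which(classes[[cl]])
    n_sites_cls[cl] <- length(idx)
    if (!length(idx)) next
    if (mode == "expected") {
      acc <- numeric(length(bins))
      for (i in idx)
        acc <- acc + stats::dhyper(bins, m[i], s[i] - m[i], subsample_2n)
      spectra[cl, ] <- acc / length(idx)
    } else {
      counts <- numeric(length(bins))
      for (i in idx) {
        k <- stats::rhyper(n_draws, m[i], s[i] - m[i], subsample_2n)
        tab <- tabulate(k + 1L, nbins = length(bins))
        counts <- counts + tab
      }
      spectra[cl, ] <- counts / sum(counts)
    }
  }
  structure(list(spectra = spectra, n_sites = n_sites_cls,
                 population = population, subsample_2n = subsample_2n,
                 mode = mode),
            class = "sfs_result")
}

#' @export
print.sfs_result <- function(x, ...) {
  cat("sfs_result (", x$mode, "): population ", x$population,
      ", 2n' = ", x$subsample_2n, "\n", sep = "")
  print(round(x$spectra, 4))
  invisible(x)
}

#' Proportion of fixed derived alleles per mutation class
#'
#' The fraction of spectrum mass in the fixed bin (frequency 1) per class;
#' for a single-draw Monte-Carlo spectrum this is the fraction of sites
#' drawn fully derived.
#'
#' @param sfs_result an [sfs()] result.
#' @return named numeric vector, one value per class.
#' @export
proportion_fixed <- function(sfs_result) {
  spec <- sfs_result$spectra
  fixed_bin <- ncol(spec)
  out <- spec[, fixed_bin] / rowSums(spec)
  out[rowSums(spec) == 0] <- NA_real_
  out
}
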