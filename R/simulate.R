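#' Simulation configuration
#'
#' Defines a synthetic multi-population diploid dataset with the
#' statistical structure the analysis pipeline assumes: biallelic SNPs laid
#' down uniformly along a small set of autosomes, per-class derived-allele
#' frequency distributions per population, planted autozygous (ROH) tracts
#' with a controllable genome fraction and length range, an optional
#' purging effect, an outgroup allele per site, a heavy-tailed per-site
#' conservation score, and random missingness. There is no linkage model
#' beyond the shared ROH tracts: the statistics under study need ROH
#' structure and frequency spectra, not realistic LD.
#'
#' @param seed integer RNG seed; same seed, same config => bit-identical
#'   output.
#' @param n_chromosomes,chromosome_length synthetic autosome count and
#'   length in bp (default 2 x 20 Mb).
#' @param populations named list; each element a list with `n` (diploid
#'   individuals), `f` (target autozygous genome fraction in \[0, 1\]),
#'   `tract_min`, `tract_max` (ROH tract length range, bp; defaults
#'   0.2-3 Mb), and optionally `freq_beta`, a per-class override of the
#'   shared frequency distributions.
#' @param site_counts named integer vector of site counts per effect class
#'   (`LoF`, `missense`, `synonymous`, `intergenic`); the defaults give an
#'   average density of one SNP per 2 kb on the default genome.
#' @param freq_beta named list: per class, `c(shape1, shape2)` of the Beta
#'   distribution of derived-allele frequencies. Coding classes share one
#'   distribution by default so that deleterious and synonymous sites are
#'   exchangeable when no purging is applied; intergenic sites are
#'   uniform.
#' @param fixed_mass per-class probability that a site is fixed derived
#'   (frequency 1) in a population, emulating drift-driven fixation.
#' @param purging_rho probability in \[0, 1\] that a deleterious derived
#'   homozygote inside a planted ROH tract is purged, i.e. replaced by an
#'   ancestral homozygote (the tract stays homozygous; the derived allele
#'   is removed).
#' @param purging_classes classes subject to purging (default `"LoF"`).
#' @param roh_het_rate residual heterozygosity inside planted tracts.
#' @param missing_rate per-genotype missingness probability.
#' @param outgroup_error probability the outgroup allele is not the true
#'   ancestral allele.
#' @param conservation list: `df`, degrees of freedom of the Student-t
#'   score distribution (heavy-tailed), and `class_shift`, named additive
#'   shifts that associate higher scores with deleterious classes.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       chromosome_length = 20e6,
                       populations = list(
                         popA = list(n = 10L, f = 0.25),
                         popB = list(n = 10L, f = 0.05)
                       ),
                       site_counts = c(LoF = 400L, missense = 1600L,
                                       synonymous = 2000L,
                                       intergenic = 16000L),
                       freq_beta = list(LoF = c(0.8, 2.0),
                                        missense = c(0.8, 2.0),
                                        synonymous = c(0.8, 2.0),
                                        intergenic = c(1, 1)),
                       fixed_mass = c(LoF = 0.05, missense = 0.05,
                                      synonymous = 0.05,
                                      intergenic = 0.08),
                       purging_rho = 0,
                       purging_classes = "LoF",
                       roh_het_rate = 1e-4,
                       missing_rate = 0.02,
                       outgroup_error = 0.01,
                       conservation = list(df = 3,
                                           class_shift = c(LoF = 2,
                                                           missense = 1))) {
  for (p in names(populations)) {
    pp <- populations[[p]]
    if (is.null(pp$tract_min)) pp$tract_min <- 2e5
    if (is.null(pp$tract_max)) pp$tract_max <- 3e6
    stopifnot(pp$n >= 1, pp$f >= 0, pp$f <= 1,
              pp$tract_min <= pp$tract_max,
              pp$tract_max <= chromosome_length)
    populations[[p]] <- pp
  }
  stopifnot(all(site_counts >= 0), sum(site_counts) > 0,
            purging_rho >= 0, purging_rho <= 1,
            missing_rate >= 0, missing_rate < 1,
            all(fixed_mass >= 0 & fixed_mass <= 1))
  structure(list(seed = as.integer(seed), n_chromosomes = n_chromosomes,
                 chromosome_length = chromosome_length,
                 populations = populations, site_counts = site_counts,
                 freq_beta = freq_beta, fixed_mass = fixed_mass,
                 purging_rho = purging_rho,
                 purging_classes = purging_classes,
                 roh_het_rate = roh_het_rate, missing_rate = missing_rate,
                 outgroup_error = outgroup_error,
                 conservation = conservation),
            class = "sim_config")
}

#' Simulate a synthetic dataset
#'
#' Draws the full input bundle for the pipeline from a [sim_config()]:
#' diploid genotypes per site from population- and class-specific derived
#' frequencies, forced-homozygous planted ROH tracts (one allele draw per
#' tract site) with optional purging of deleterious derived homozygotes,
#' an outgroup allele per site (true ancestral with an error rate), and
#' heavy-tailed conservation scores shifted upward for deleterious
#' classes. Truth tables record the planted tracts, per-site ancestral
#' allele, class, score, and per-population frequencies.
#'
#' @param cfg a [sim_config()].
#' @return list with `vt` (`variant_table`), `panel`, `effects` (raw term
#'   table), `outgroup`, `track` (conservation scores), `layout`, and
#'   `truth` (list: `tracts`, per-site truth data.frame, per-population
#'   frequency matrix, `config`).
#' @export
simulate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  layout <- genome_layout(stats::setNames(
    rep(cfg$chromosome_length, cfg$n_chromosomes), chroms))

  n_total <- sum(cfg$site_counts)
  chrom_of <- sort(sample.int(cfg$n_chromosomes, n_total, replace = TRUE))
  pos <- integer(n_total)
  for (c_i in seq_len(cfg$n_chromosomes)) {
    idx <- which(chrom_of == c_i)
    pos[idx] <- sort(sample.int(cfg$chromosome_length, length(idx)))
  }
  classes <- sample(rep(names(cfg$site_counts), cfg$site_counts))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n_total, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  anc_is_ref <- stats::runif(n_total) < 0.5

  pops <- names(cfg$populations)
  freq <- matrix(NA_real_, n_total, length(pops),
                 dimnames = list(NULL, pops))
  for (p in pops) {
    fb <- cfg$populations[[p]]$freq_beta
    if (is.null(fb)) fb <- cfg$freq_beta
    for (cl in names(cfg$site_counts)) {
      idx <- which(classes == cl)
      sh <- fb[[cl]]
      pfr <- stats::rbeta(length(idx), sh[1], sh[2])
      fixed <- stats::runif(length(idx)) < cfg$fixed_mass[[cl]]
      pfr[fixed] <- 1
      freq[idx, p] <- pfr
    }
  }

  samples <- unlist(lapply(pops, function(p)
    paste0(p, "_", seq_len(cfg$populations[[p]]$n))))
  panel <- sample_panel(stats::setNames(
    rep(pops, vapply(pops, function(p) cfg$populations[[p]]$n, 1L)),
    samples))

  deleterious <- classes %in% cfg$purging_classes
  geno_derived <- matrix(NA_integer_, n_total, length(samples),
                         dimnames = list(NULL, samples))
  tracts <- list()
  for (p in pops) {
    pp <- cfg$populations[[p]]
    for (k in seq_len(pp$n)) {
      smp <- paste0(p, "_", k)
      tr <- .plant_tracts(pp$f, pp$tract_min, pp$tract_max, layout)
      if (nrow(tr)) {
        tr$sample <- smp
        tracts[[length(tracts) + 1L]] <- tr
      }
      in_tract <- sites_in_roh(
        data.frame(chrom = chroms[chrom_of], pos = pos,
                   stringsAsFactors = FALSE), tr)
      pfr <- freq[, p]
      d <- integer(n_total)
      out_i <- which(!in_tract)
      d[out_i] <- stats::rbinom(length(out_i), 2L, pfr[out_i])
      in_i <- which(in_tract)
      if (length(in_i)) {
        a <- stats::rbinom(length(in_i), 1L, pfr[in_i])
        d[in_i] <- 2L * a
        hetflip <- stats::runif(length(in_i)) < cfg$roh_het_rate
        d[in_i][hetflip] <- 1L
        if (cfg$purging_rho > 0) {
          tgt <- in_i[d[in_i] == 2L & deleterious[in_i]]
          purged <- tgt[stats::runif(length(tgt)) < cfg$purging_rho]
          d[purged] <- 0L
        }
      }
      geno_derived[, smp] <- d
    }
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(stats::runif(length(geno_derived)) < cfg$missing_rate,
                   nrow = n_total)
    geno_derived[miss] <- NA_integer_
  }
  # derived dose -> alt dose
  geno <- geno_derived
  flip <- which(!anc_is_ref)
  geno[flip, ] <- 2L - geno_derived[flip, , drop = FALSE]

  anc_base <- ifelse(anc_is_ref, ref, alt)
  der_base <- ifelse(anc_is_ref, alt, ref)
  og_err <- stats::runif(n_total) < cfg$outgroup_error
  og <- ifelse(og_err, der_base, anc_base)

  score <- stats::rt(n_total, df = cfg$conservation$df)
  shift <- cfg$conservation$class_shift
  for (cl in names(shift))
    score[classes == cl] <- score[classes == cl] + shift[[cl]]

  aa_ref <- aa_alt <- rep(NA_character_, n_total)
  mis <- which(classes == "missense")
  if (length(mis)) {
    radical <- stats::runif(length(mis)) < 0.3
    aa_ref[mis] <- ifelse(radical, "C", "L")
    aa_alt[mis] <- ifelse(radical, "W", "I")
  }
  term_of <- c(LoF = "stop_gained", missense = "missense_variant",
               synonymous = "synonymous_variant",
               intergenic = "intergenic_region")

  sites <- data.frame(chrom = chroms[chrom_of], pos = pos, ref = ref,
                      alt = alt, stringsAsFactors = FALSE)
  vt <- variant_table(sites, geno, samples)
  truth_tracts <- if (length(tracts)) do.call(rbind, tracts)
  else data.frame(sample = character(0), chrom = character(0),
                  start = numeric(0), end = numeric(0),
                  length = numeric(0))
  truth_froh <- vapply(samples, function(s) {
    tt <- truth_tracts[truth_tracts$sample == s, , drop = FALSE]
    sum(tt$length) / autosome_length(layout)
  }, numeric(1))
  list(
    vt = vt,
    panel = panel,
    effects = data.frame(chrom = sites$chrom, pos = sites$pos,
                         term = unname(term_of[classes]),
                         aa_ref = aa_ref, aa_alt = aa_alt,
                         stringsAsFactors = FALSE),
    outgroup = data.frame(chrom = sites$chrom, pos = sites$pos,
                          allele = og, stringsAsFactors = FALSE),
    track = data.frame(chrom = sites$chrom, pos = sites$pos,
                       score = score, stringsAsFactors = FALSE),
    layout = layout,
    truth = list(
      tracts = truth_tracts,
      froh = truth_froh,
      sites = data.frame(chrom = sites$chrom, pos = sites$pos,
                         class = classes, ancestral = anc_base,
                         score = score, stringsAsFactors = FALSE),
      freq = freq,
      config = cfg
    )
  )
}

# Place non-overlapping tracts covering fraction f of the genome; the last
# tract is trimmed so the planted fraction hits f exactly (subject to the
# tract minimum).
.plant_tracts <- function(f, tract_min, tract_max, layout) {
  empty <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), length = numeric(0),
                      stringsAsFactors = FALSE)
  L <- autosome_length(layout)
  target <- f * L
  if (target <= 0) return(empty)
  chroms <- layout$autosomes
  placed <- list()
  total <- 0
  guard <- 0L
  while (total < target && guard < 10000L) {
    guard <- guard + 1L
    len <- stats::runif(1, tract_min, tract_max)
    if (total + len > target)
      len <- max(tract_min, target - total)
    ch <- sample(chroms, 1L, prob = layout$lengths[chroms])
    chlen <- layout$lengths[[ch]]
    if (len >= chlen) next
    start <- floor(stats::runif(1, 1, chlen - len))
    end <- floor(start + len - 1)
    clash <- FALSE
    for (tr in placed) {
      if (tr$chrom == ch && start <= tr$end && end >= tr$start) {
        clash <- TRUE
        break
      }
    }
    if (clash) next
    placed[[length(placed) + 1L]] <- list(chrom = ch, start = start,
                                          end = end)
    total <- total + (end - start + 1)
  }
  if (!length(placed)) return(empty)
  out <- data.frame(
    chrom = vapply(placed, `[[`, "", "chrom"),
    start = vapply(placed, `[[`, 0, "start"),
    end = vapply(placed, `[[`, 0, "end"),
    stringsAsFactors = FALSE)
  out$length <- out$end - out$start + 1
  out[order(out$chrom, out$start), , drop = FALSE]
}

#' Write a simulated dataset in the pipeline's input formats
#'
#' Emits VCF (genotypes), sample panel TSV, genome layout TSV, effect
#' annotation TSV, outgroup allele TSV, conservation-score TSV and a truth
#' JSON into a directory.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    vcf = file.path(dir, "variants.vcf"),
    panel = file.path(dir, "panel.tsv"),
    layout = file.path(dir, "layout.tsv"),
    effects = file.path(dir, "effects.tsv"),
    outgroup = file.path(dir, "outgroup.tsv"),
    scores = file.path(dir, "scores.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_vcf(sim$vt, paths["vcf"])
  write_sample_panel(sim$panel, paths["panel"])
  write_genome_layout(sim$layout, paths["layout"])
  utils::write.table(sim$effects, paths["effects"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$outgroup, paths["outgroup"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$track, paths["scores"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tracts = sim$truth$tracts,
                            froh = as.list(sim$truth$froh)),
                       paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Hand-checkable worked fixtures
#'
#' A small bundle of fixtures whose expected outputs were evaluated by
#' hand, used in unit tests and examples:
#'
#' * `rxy_toy`: 2 category + 2 intergenic sites with printed m, s counts
#'   for two populations; the ratio-of-sums arithmetic gives
#'   L_X = 0.25/0.46875, L_Y = 0.75/0.46875, hence R = 1/3.
#' * `roh_toy`: one sample with 200 consecutive hom-alt SNPs spaced 750 bp
#'   (span 149,251 bp), no het or missing calls: one segment covering all
#'   200 SNPs.
#' * `sfs_toy`: one site with m = 2 derived of s = 4 called alleles;
#'   projection onto 2 alleles has bin probabilities (1/6, 2/3, 1/6).
#'
#' @return list with elements `rxy_toy` (polar, category, intergenic,
#'   expected_r), `roh_toy` (vt, params, expected segment bounds),
#'   `sfs_toy` (polar, effects, panel, expected spectrum).
#' @export
make_worked_toy <- function() {
  # Rxy: hand-evaluated 4-site fixture
  rxy_sites <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L, 400L),
                          ref = "A", alt = "G",
                          ancestral = "ref", stringsAsFactors = FALSE)
  m <- cbind(X = c(2, 4, 3, 5), Y = c(4, 6, 3, 5))
  s <- cbind(X = c(8, 8, 8, 8), Y = c(8, 8, 8, 8))
  rxy_toy <- list(
    polar = polarized_table(rxy_sites, m, s),
    category = c(TRUE, TRUE, FALSE, FALSE),
    intergenic = c(FALSE, FALSE, TRUE, TRUE),
    expected_r = (0.25 / 0.46875) / (0.75 / 0.46875)  # = 1/3
  )

  # ROH: 200 hom-alt SNPs at 750 bp spacing on a 1 Mb chromosome
  pos <- 10000L + 750L * (0:199)
  roh_vt <- variant_table(
    sites = data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                       stringsAsFactors = FALSE),
    genotypes = matrix(2L, nrow = 200, ncol = 1),
    samples = "ind1")
  roh_toy <- list(
    vt = roh_vt,
    params = roh_params(),
    expected = data.frame(start = pos[1], end = pos[200], n_snps = 200L,
                          length = pos[200] - pos[1] + 1)
  )

  # SFS: m = 2 of s = 4, projected to 2 alleles
  sfs_sites <- data.frame(chrom = "chr1", pos = 500L, ref = "A", alt = "G",
                          ancestral = "ref", stringsAsFactors = FALSE)
  sfs_toy <- list(
    polar = polarized_table(sfs_sites, cbind(pop1 = 2), cbind(pop1 = 4)),
    effects = data.frame(chrom = "chr1", pos = 500L, class = "intergenic",
                         dnssnp = FALSE, stringsAsFactors = FALSE),
    panel = sample_panel(c(a = "pop1", b = "pop1")),
    expected_spectrum = c(`0` = 1 / 6, `1` = 2 / 3, `2` = 1 / 6)
  )

  list(rxy_toy = rxy_toy, roh_toy = roh_toy, sfs_toy = sfs_toy)
}
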