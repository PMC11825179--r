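# purgekit

Population-genomic statistics for conservation genetics: runs of
homozygosity and inbreeding (F_ROH), windowed nucleotide diversity,
classified derived mutational load, and three complementary detectors of
**genetic purging** — the selective removal of recessive deleterious
alleles when inbreeding exposes them in homozygous state. The package is
aimed at analyses of resequenced cohorts from small or endangered
populations, where the practical questions are "how inbred is this
population", "how much deleterious variation does it carry", and "is
selection managing to remove any of it".

## What it computes

* **ROH and F_ROH** — a PLINK v1.9-style windowed scan (20-SNP windows,
  ≥ 10 kb, ≤ 50 kb/SNP, segments < 100 kb excluded) and
  F_ROH = L_ROH / L_AUTOSOME, with length-class summaries
  ([100 kb, 1 Mb), [1 Mb, 5 Mb), ≥ 5 Mb).
* **Diversity** — vcftools-style windowed π in 500 kb windows,
  π = Σ 2j(n−j)/(n(n−1)) per bp, and per-individual observed
  heterozygosity.
* **Load** — effect classes (LoF = stop-gained / splice acceptor /
  splice donor; missense; dnsSNP = missense with Grantham distance
  ≥ 150, recomputed from the published physicochemical properties;
  synonymous), outgroup + majority-rule polarization to derived alleles,
  per-individual het / derived-hom counts and the homozygous share
  2·hom/(2·hom + het).
* **Purging** —
  * ROHf vs non-ROHf: deleterious-to-synonymous carrier ratios inside
    and outside each individual's ROH, compared by paired Wilcoxon
    signed-rank test;
  * R_{X/Y} = L_X/L_Y with
    L_X = Σ_C (m_X/s_X)(1−m_Y/s_Y) / Σ_I (m_X/s_X)(1−m_Y/s_Y),
    with delete-one-block jackknife standard errors;
  * conservation-weighted relative load over the top 0.1% of GERP-like
    scores (het = 1 allele, hom = 2).
* **SFS** — derived site-frequency spectra for damaging (LoF+missense)
  vs neutral (intergenic) classes on a fixed hypergeometric subsample,
  fixed and absent bins included, with the fixed-proportion summary.
* **Synthetic data** — a seeded generator with planted ROH tracts,
  class-specific frequency distributions, a tunable purging effect,
  outgroup alleles and heavy-tailed conservation scores, plus truth
  tables, so the whole pipeline is testable offline.

## Worked example

Simulate two populations — one highly inbred (target F_ROH 0.40), one
mildly (0.10) — with a strong purging effect (ρ = 0.8) at LoF sites, and
run the stages:

```r
library(purgekit)

cfg <- sim_config(
  seed = 42,
  populations = list(MjavA = list(n = 8L, f = 0.40),
                     MjavB = list(n = 8L, f = 0.10)),
  purging_rho = 0.8
)
sim <- simulate_dataset(cfg)

vt   <- filter_missingness(filter_biallelic_snps(sim$vt), sim$panel)
segs <- filter_roh_min_length(detect_roh(vt), 1e5)
summarize_inbreeding(segs, sim$layout, sim$panel)$populations
#>   population n_samples mean_froh sd_froh mean_froh_ge_1mb sd_froh_ge_1mb frac_lt_1mb
#> 1      MjavA         8     0.406  0.0019           0.3514         0.0350       0.337
#> 2      MjavB         8     0.102  0.0016           0.0764         0.0199       0.517
```

The caller recovers the planted autozygosity (0.406 vs 0.40, 0.102 vs
0.10); most of the inbred population's ROH length sits in fragments
longer than 1 Mb, as expected when tracts of up to 3 Mb are planted.

```r
eff  <- classify_effects(sim$effects)
pol  <- polarize(vt, sim$outgroup, sim$panel)
rohf <- rohf_statistics(vt, segs, eff, pol, sim$panel, categories = "LoF")
rohf$population[, c("population", "mean_rohf", "mean_nonrohf", "mean_ratio", "p_value")]
#>   population mean_rohf mean_nonrohf mean_ratio p_value
#> 1      MjavA    0.0551        0.263      0.210 0.00781
#> 2      MjavB    0.0379        0.245      0.155 0.00781
```

Inside ROH, LoF carriers are depleted about fivefold relative to
synonymous carriers (ratio ≈ 0.2, paired Wilcoxon p ≈ 0.008 in both
populations) — the planted purging signal.

```r
masks <- category_site_masks(vt, eff)
rxy(pol, "MjavA", "MjavB", masks$LoF, masks$intergenic)
#> Rxy (MjavA / MjavB) = 0.7305 +/- 0.0837 (jackknife SE, 20 blocks)
#>   L_X = 0.0333, L_Y = 0.0456; 348 category, 6271 intergenic sites
```

R < 1 with an interval excluding 1: the more inbred population carries
relatively fewer derived LoF alleles, because its larger ROH fraction
exposed more of them to purging.

Or run everything at once — filters, ROH, diversity, load, purging, SFS,
TSV outputs, a JSON report and a parameter log:

```r
report <- run_all(list(simulate = list(seed = 42), purging = list(),
                       seed = 42),
                  out_dir = "purgekit_out")
```

A thin command-line wrapper over these functions ships at
`inst/cli/purgekit.R` (`Rscript purgekit.R run -c config.yaml -o out`).

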