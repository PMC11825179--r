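---
title: "Detecting inbreeding, mutational load and genetic purging with purgekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inbreeding, mutational load and genetic purging with purgekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(purgekit)
```

purgekit implements a conservation-genomics workflow for multi-sample SNP
data from small or endangered populations: how inbred are the individuals
(runs of homozygosity, F_ROH), how much deleterious variation do they carry
(classified derived mutational load), and is selection removing recessive
deleterious alleles where inbreeding exposes them as homozygotes (genetic
purging, measured three independent ways). This vignette explains the
models and the decisions behind each stage; the README shows the
end-to-end workflow.

## Input model and site filtering

All statistics operate on a `variant_table`: biallelic SNPs (sorted by
chromosome and position) by diploid samples, genotypes coded as unphased
alt-allele dose 0/1/2 with `NA` for missing. Phase is ignored — nothing
downstream needs it. Three filters precede analysis:

* `filter_biallelic_snps()` removes indels and multiallelic records.
* `apply_hard_filter()` removes a site iff any clause of the GATK-style
  expression fires: QD < 2, FS > 60, MQ < 40, MQRankSum < −12.5,
  ReadPosRankSum < −8. An *absent* annotation never removes a site
  (the GATK convention); removal on absence would silently empty
  annotation-poor inputs such as simulated data.
* `filter_missingness()` removes a site when missingness strictly exceeds
  20% *within any population*. The per-population reading keeps the
  criterion meaningful when cohort sizes are unbalanced; failing sites are
  dropped globally so every statistic sees one shared site matrix, which
  keeps cross-population comparisons on a common denominator.

Because each filter is a pure subset operation on independent per-site
predicates, the hard filter and the missingness filter commute — a
property the test suite checks on random inputs.

## Runs of homozygosity and F_ROH

`detect_roh()` reimplements the PLINK v1.9 `--homozyg` windowed scan. A
window of 20 consecutive SNPs is called homozygous when it has at most 1
heterozygous and at most 5 missing calls; each SNP receives the fraction
of the windows spanning it that are homozygous (windows truncate at
chromosome ends, so edge SNPs are spanned by fewer windows and the
fraction uses the actual spanning-window count); SNPs with fraction
≥ 0.05 are run-eligible. Maximal stretches of eligible SNPs are split
wherever adjacent SNPs are more than 1 Mb apart — gaps split runs
*before* any length test — and each piece must then span ≥ 10 kb, contain
≥ 100 SNPs and be no sparser than 50 kb per SNP. The three thresholds
stated as primary parameters (window of 20 SNPs, 10 kb, 50 kb/SNP) mirror
the published flags; every remaining knob is fixed to its PLINK default
and exposed in `roh_params()`.

Segments shorter than 100 kb are excluded afterwards
(`filter_roh_min_length()`, inclusive at the boundary), and the
inbreeding coefficient is

F_ROH = L_ROH / L_AUTOSOME,

total ROH length over total autosome length (`genome_layout` restricts
both to autosomes; sex chromosomes never enter the denominator, so they
are excluded from calling too). `summarize_inbreeding()` reports per
sample F_ROH overall and restricted to segments ≥ 1 Mb and ≥ 5 Mb, counts
in the classes [100 kb, 1 Mb), [1 Mb, 5 Mb) and ≥ 5 Mb, and the fraction
of fragments shorter than 1 Mb — the summaries used to distinguish
recent inbreeding (long ROH) from historical inbreeding (many short ROH).

The caller is validated two ways: exact equivalence with an independent
exhaustive-scan oracle on hundreds of randomized small inputs, and
parameter recovery — planted autozygous fractions of 0.1/0.25/0.5 are
recovered within ±0.05 (window-boundary effects extend called segments a
few SNPs beyond a planted tract, a known small upward bias of windowed
callers).

## Nucleotide diversity and heterozygosity

`windowed_pi()` follows the vcftools `--window-pi` computation: in each
non-overlapping 500 kb window, per-population π is the sum over sites of
the unbiased per-site heterozygosity 2j(n−j)/(n(n−1)) — j the alt count
among the population's called alleles, n the called allele count, so
missing genotypes shrink n per site — divided by the window length. A
terminal window shorter than 500 kb uses its true length. This equals the
mean per-bp pairwise difference over all allele pairs, which the tests
verify by brute force. Because the per-site term is symmetric in j and
n−j, π is invariant to ref/alt labelling.

The genome-wide summary is reported both ways one could aggregate
windows — the length-weighted mean (equivalently, total site
contributions over total length) and the unweighted mean of window
values — with the length-weighted version treated as canonical, since it
does not overweight short terminal windows. `individual_heterozygosity()`
reports per-sample het genotypes over non-missing genotypes (the
vcftools `--het` style observed heterozygosity); a sample with no called
genotypes yields `NA`, not an error.

## Effect classes, Grantham distances and polarization

`classify_effects()` maps annotation terms to load categories:
stop-gained and splice acceptor/donor variants are loss-of-function
(LoF); missense, synonymous and intergenic map from the standard
vocabulary; all other recognized terms (and, with a warning, unknown
terms) map to `other` and never silently disappear. When a site carries
several transcript annotations, the most severe class wins
(LoF > missense > synonymous > intergenic > other), matching how variant
annotators report one consequence per variant.

Missense changes are scored with the Grantham physicochemical distance,
recomputed from the published amino-acid composition, polarity and
volume values with the published weights and the scale factor that sets
the mean distance to 100. A distance ≥ 150 (inclusive) flags the variant
as a deleterious nonsynonymous SNP (dnsSNP) — reported as its own
category but always a subset of missense. The recomputed matrix agrees
with the published integer table within ±1 for all 190 pairs (rounding),
and is exactly symmetric with a zero diagonal.

`polarize()` infers the ancestral allele from a per-site outgroup allele
plus a majority rule: an allele is ancestral iff it equals the outgroup
base *and* its frequency in the focal population strictly exceeds 50%.
Sites failing either condition — outgroup missing or matching neither
allele, or frequency exactly 0.5 — stay unresolved and are excluded from
every derived-allele statistic. By default the "focal population" is the
pooled cohort (a species-level frequency); a single population can be
selected instead. The upstream alignment that would produce the outgroup
table for real data (mapping sister-species reads) is out of scope here:
the table is an input, and the synthetic generator produces it with a
controllable error rate.

One consequence of polarity-aware counting deserves emphasis: at sites
where the *reference* allele is derived, a hom-ref genotype is a derived
homozygote. `derived_dose()` handles this, and `tabulate_load()` counts,
per individual and category, heterozygous sites and derived-homozygous
sites. The homozygous share of an individual's load is
2·hom/(2·hom + het), undefined (NA) for empty categories. A conservation
identity ties the tabulation together: summing 2·hom + het over
individuals recovers the population derived-allele count at the
category's sites.

## Purging statistic 1: ROHf versus non-ROHf

For each individual, every site carrying at least one derived allele is
assigned to the ROH or non-ROH compartment by position (segments are
closed intervals of that individual's own ROH calls). The statistic
divides deleterious carriers by synonymous carriers in the same
compartment:

ROHf = N_m(in) / S(in),  nonROHf = N_m(out) / S(out).

Normalizing by synonymous sites inside the same compartment cancels the
overall reduction of diversity inside ROH; what remains is the *relative*
depletion of deleterious variants where homozygosity exposes them —
purging pushes ROHf below nonROHf. Populations are compared with a
paired two-sided Wilcoxon signed-rank test across individuals (a
conservative, distribution-free choice for small cohorts; the test is
configurable, and individuals with an undefined ratio — no synonymous
carriers in a compartment — are excluded with a message and counted in
the output).

Calibration: when deleterious and synonymous sites are placed with the
same frequency distribution and independently of ROH, the expected
ROHf/nonROHf ratio is 1; simulations with full purging at LoF sites
yield ratios far below 1 with significant paired tests. One caveat the
simulations make visible: all individuals of a population share one
realized set of site frequencies, so a single dataset's paired test can
be "significant" in either direction from site-sampling noise alone —
replication across datasets, not a smaller p-value, is what distinguishes
purging from luck.

## Purging statistic 2: Rxy with a block jackknife

Rxy compares the derived-allele burden of a category C between
populations X and Y, normalized by intergenic sites I:

L_X = Σ_{i∈C} (m_X/s_X)(1 − m_Y/s_Y) / Σ_{i∈I} (m_X/s_X)(1 − m_Y/s_Y),

L_Y symmetric with X and Y swapped, and R_{X/Y} = L_X/L_Y. R = 1 means
equal load; R < 1 means Y carries more; R > 1 means X carries more.
Sites with zero called alleles in either population are skipped in both
sums; an all-zero intergenic denominator is an error (the statistic is
undefined). Two exact identities hold by construction and are asserted
in tests: R(X, X) = 1, and R(X, Y)·R(Y, X) = 1 on a shared site set.

The standard error uses a delete-one-block jackknife: the used sites
(C and I jointly, in genomic order) are cut into 20 contiguous
equal-size blocks, each block is deleted in turn, and the SE comes from
the pseudo-value variance. Contiguous blocks were chosen because
physically linked sites are correlated — deleting scattered individual
sites would understate the error; 20 blocks is the conventional
compromise between bias and variance of the SE itself, and the count is
configurable. A leave-one-out replicate that becomes undefined (possible
only in degenerate tiny inputs) is dropped from the variance rather than
aborting. In power simulations, a twofold frequency difference at 1,000
category sites is detected (normal-theory 95% interval excluding 1) in
well over 90% of replicates.

## Purging statistic 3: conservation-weighted relative load

Sites are ranked by a per-site conservation score (a GERP-like rejected
substitutions score, supplied as a track; computing such scores from
multiple alignments is out of scope). The top 0.1% of scored sites —
exactly ceiling(q·n) sites, ties broken deterministically by site
order — form the highly constrained set. Per individual, the relative
mutational load is

Σ_{top sites} dose × score / total derived alleles,

with heterozygotes counted as 1 allele and derived homozygotes as 2. The
denominator is the individual's derived-allele dose over *all* resolved
polarized sites, not just the top quantile: the statistic then reads as
"what share of this individual's derived variation sits in the most
constrained part of the genome, weighted by constraint", which makes it
comparable across individuals with different overall loads. The measure
is linear in the scores (doubling all scores doubles it — only relative
comparisons are meaningful) and invariant to permuting scores below the
threshold.

## Site-frequency spectra

`sfs()` projects each site onto a fixed subsample of 2n′ alleles so that
populations with different sample sizes and missingness become
comparable. The default is the deterministic expected projection: a site
with m derived among s ≥ 2n′ called alleles contributes the
hypergeometric pmf over bins 0 … 2n′. A Monte-Carlo mode (single draw
per site by default, seeded) reproduces the resampling approach;
its mean converges to the expected projection, which the tests verify at
10,000 draws. Bins 0 (absent) and 2n′ (fixed) are retained — the fixed
bin is where drift-driven fixation of deleterious alleles shows up, and
`proportion_fixed()` reports its mass per class. Damaging sites are
LoF ∪ missense; neutral sites are intergenic. Sites with fewer than 2n′
called alleles are skipped rather than imputed.

## The synthetic generator

`simulate_dataset()` produces every input the pipeline consumes, plus
truth tables, so each stage can be calibrated without external data. It
emulates exactly the structure the statistics assume and no more:

* Sites are placed uniformly at random on 2 × 20 Mb autosomes at an
  average density of one SNP per 2 kb (the density at which the ROH
  caller's defaults are meaningful). There is **no linkage model**:
  allele frequencies are independent across sites. Planted ROH tracts
  are the only source of within-genome correlation.
* Derived-allele frequencies are Beta-distributed per class, with a
  point mass at 1 to emulate drift-driven fixation. Coding classes share
  one distribution by default so that deleterious and synonymous sites
  are exchangeable — the property the ROHf calibration rests on;
  real data, where purifying selection keeps deleterious alleles rarer,
  is emulated by overriding the class distributions.
* Autozygosity: each individual receives non-overlapping tracts with
  lengths uniform on 0.2–3 Mb until the configured genome fraction f is
  reached (the last tract is trimmed, so the planted fraction matches f
  to within 2%). Inside a tract one allele is drawn per site and
  doubled; residual heterozygosity inside tracts is 10⁻⁴.
* Purging is imposed, not evolved: with probability ρ, a deleterious
  derived *homozygote* inside a tract is replaced by an ancestral
  homozygote. Replacement by an ancestral homozygote (rather than a
  heterozygote) keeps the tract autozygous and actually removes the
  derived allele — which is what purging does and what the
  carrier-based ROHf statistic can see.
* The outgroup allele equals the true ancestral allele with a 1% error;
  conservation scores are Student-t with 3 df (heavy-tailed, as
  empirical constraint scores are) shifted upward for deleterious
  classes; genotypes go missing independently at 2%.

Passing calibration on these simulations therefore demonstrates
correctness of the *estimators* under the stated sampling models; it
does not demonstrate robustness to linkage disequilibrium, ascertainment
bias, annotation error or population structure, none of which the
generator produces.

## Numerical conventions and edge cases

* Coordinates are 1-based closed intervals everywhere (sites, ROH
  segments, windows).
* Strictness follows the definitions: missingness fails at > 0.20;
  ancestral frequency must exceed 0.5 (exactly 0.5 is unresolved); the
  Grantham cutoff and the 100 kb ROH cutoff are inclusive (≥).
* Undefined ratios (zero denominators) become `NA` and are excluded
  with a note, never silently converted to 0 — except the Rxy intergenic
  denominator, which is a hard error because the statistic itself is
  undefined.
* All randomness (simulation, Monte-Carlo SFS) flows from explicit
  seeds; `run_all()` derives per-stage seeds deterministically from one
  master seed, and identical configurations produce byte-identical
  reports.
* Validation problem sizes: oracle equivalence uses hundreds of ≤500-SNP
  inputs with shrunk window parameters (exhaustive scans scale
  quadratically); recovery and power checks use 50-replicate batches at
  2 × 20 Mb (ROH recovery) or 1,000 category sites (Rxy); these sizes
  give the binomial success criteria (≥ 45/50, ≥ 48/50) adequate
  resolution.

## Limitations

The pipeline starts from called genotypes: no variant calling, phasing,
annotation engine, or alignment. ROH detection is the genotype-based
windowed scan — likelihood-based HMM callers can outperform it at low
coverage. The Rxy jackknife's contiguous-block unit is a design choice,
not an inference from data; with strong long-range structure,
chromosome-level blocks may be preferable (the block count is the only
exposed knob). The SFS projection treats sites independently. And the
generator's known idealizations (above) bound what simulation-based
validation can claim about real data.
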