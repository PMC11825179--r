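test_that("Grantham matrix matches the frozen independent recomputation", {
  oracle <- read.table(test_path("grantham-oracle.tsv"), header = TRUE,
                       sep = "\t", stringsAsFactors = FALSE)
  m <- grantham_matrix()
  got <- m[cbind(oracle$aa1, oracle$aa2)]
  expect_equal(nrow(oracle), 190L)
  expect_true(all(abs(got - oracle$distance) <= 1))
  # symmetry and zero diagonal hold exactly
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(0, 20))
  # well-known published distances, to rounding
  expect_equal(round(m["L", "I"]), 5)
  expect_true(abs(m["C", "W"] - 215) <= 1)
  expect_true(abs(m["D", "E"] - 45) <= 1)
  expect_true(abs(m["F", "Y"] - 22) <= 1)
})

test_that("grantham() flags radical substitutions at the inclusive cutoff", {
  expect_equal(grantham("A", "A")$distance, 0)
  expect_false(grantham("A", "A")$dnssnp)
  li <- grantham("L", "I")
  expect_lt(li$distance, 150)
  expect_false(li$dnssnp)
  cw <- grantham("C", "W")
  expect_gte(cw$distance, 150)
  expect_true(cw$dnssnp)
  # three-letter codes accepted; nonstandard rejected
  expect_equal(grantham("Cys", "Trp")$distance, cw$distance)
  expect_error(grantham("X", "A"), "nonstandard")
})

test_that("effect classification maps terms and resolves multi-transcript sites", {
  ann <- data.frame(
    chrom = "chr1", pos = c(10, 20, 30, 40, 50),
    term = c("stop_gained", "synonymous_variant", "intron_variant",
             "splice_acceptor_variant", "intergenic_region"),
    stringsAsFactors = FALSE)
  eff <- classify_effects(ann)
  expect_equal(eff$class,
               c("LoF", "synonymous", "other", "LoF", "intergenic"))
  # most severe annotation wins at a multi-annotated site
  multi <- data.frame(chrom = "chr1", pos = c(10, 10, 10),
                      term = c("synonymous_variant", "stop_gained",
                               "intron_variant"), stringsAsFactors = FALSE)
  expect_equal(classify_effects(multi)$class, "LoF")
  # unknown terms warn and map to other
  expect_warning(out <- classify_effects(
    data.frame(chrom = "chr1", pos = 1, term = "made_up_term")),
    "unrecognized")
  expect_equal(out$class, "other")
  # dnsSNP flagged only for missense with a radical amino-acid change
  mis <- data.frame(chrom = "chr1", pos = c(1, 2),
                    term = "missense_variant",
                    aa_ref = c("C", "L"), aa_alt = c("W", "I"),
                    stringsAsFactors = FALSE)
  eff2 <- classify_effects(mis)
  expect_equal(eff2$dnssnp, c(TRUE, FALSE))
  expect_true(all(eff2$class == "missense"))
})

test_that("SnpEff ANN strings parse into per-transcript terms", {
  vt <- toy_vt(c(100, 200), c(0L, 0L))
  vt$info <- data.frame(ANN = c(
    "G|missense_variant|MODERATE|g1|g1|transcript|t1|Coding|1/2|c.1A>G|p.Cys10Trp|10|10|4|0|",
    "G|synonymous_variant&splice_region_variant|LOW|g2|g2|transcript|t2|Coding|1/2|c.2C>T|||||0|"),
    stringsAsFactors = FALSE)
  raw <- effects_from_ann(vt)
  expect_equal(raw$term[1], "missense_variant")
  expect_equal(raw$aa_ref[1], "Cys")
  expect_setequal(raw$term[raw$pos == 200],
                  c("synonymous_variant", "splice_region_variant"))
  eff <- classify_effects(raw)
  expect_true(eff$dnssnp[eff$pos == 100])
})

test_that("polarization applies the outgroup + majority rule strictly", {
  # 10 alleles in focal pop; site layout: (ref freq, outgroup)
  vt <- toy_vt(c(100, 200, 300, 400),
               c(0L, 0L, 0L, 1L, 0L,   # site1: ref freq 0.9
                 1L, 1L, 1L, 1L, 1L,   # site2: ref freq 0.5 exactly
                 0L, 0L, 2L, 2L, 1L,   # site3: outgroup matches neither
                 2L, 2L, 2L, 2L, 1L),  # site4: alt freq 0.9, outgroup alt
               ref = "A", alt = "G")
  outg <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                     allele = c("A", "A", "T", "G"),
                     stringsAsFactors = FALSE)
  panel <- sample_panel(setNames(rep("p", 5), vt$samples))
  pol <- polarize(vt, outg, panel)
  expect_equal(pol$sites$ancestral, c("ref", NA, NA, "alt"))
  # derived counts follow the ancestral call: site1 m = alt count = 1
  expect_equal(unname(pol$m[1, "p"]), 1)
  expect_equal(unname(pol$s[1, "p"]), 10)
  # site4 ancestral = alt, derived = ref: m = 10 - 9 = 1
  expect_equal(unname(pol$m[4, "p"]), 1)
  expect_true(all(is.na(pol$m[2:3, ])))
  expect_error(polarize(vt, transform(outg, allele = "N"), panel),
               "outgroup allele")
})

test_that("swapping ref/alt labels flips ancestral calls but not derived counts", {
  set.seed(12)
  vt <- random_vt(50, 6, span = 1e5, miss_prob = 0)
  panel <- sample_panel(setNames(rep("p", 6), vt$samples))
  anc <- sample(c("A", "G"), 50, replace = TRUE)
  outg <- data.frame(chrom = "chr1", pos = vt$sites$pos, allele = anc,
                     stringsAsFactors = FALSE)
  pol1 <- polarize(vt, outg, panel)
  sw <- vt
  sw$sites$ref <- vt$sites$alt
  sw$sites$alt <- vt$sites$ref
  sw$genotypes <- 2L - vt$genotypes
  pol2 <- polarize(sw, outg, panel)
  resolved <- !is.na(pol1$sites$ancestral)
  expect_equal(is.na(pol2$sites$ancestral), is.na(pol1$sites$ancestral))
  flip <- c(ref = "alt", alt = "ref")
  expect_equal(pol2$sites$ancestral[resolved],
               unname(flip[pol1$sites$ancestral[resolved]]))
  expect_equal(pol2$m, pol1$m)
  expect_equal(pol2$s, pol1$s)
  # idempotent: polarizing again yields the same table
  expect_equal(polarize(vt, outg, panel)$sites$ancestral,
               pol1$sites$ancestral)
})

test_that("load tabulation counts hets and derived homozygotes per category", {
  # 3 LoF sites for one individual: derived-hom, het, ancestral-hom,
  # plus 2 sites where derived = ref and genotype is hom-ref
  vt <- toy_vt(c(10, 20, 30, 40, 50),
               c(2L, 1L, 0L, 0L, 0L), ref = "A", alt = "G")
  effects <- data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50),
                        class = c("LoF", "LoF", "LoF", "missense",
                                  "synonymous"),
                        dnssnp = c(FALSE, FALSE, FALSE, TRUE, FALSE),
                        stringsAsFactors = FALSE)
  pol <- polarized_table(
    data.frame(chrom = "chr1", pos = c(10, 20, 30, 40, 50),
               ancestral = c("ref", "ref", "ref", "alt", "alt"),
               stringsAsFactors = FALSE),
    m = cbind(p = c(2, 1, 0, 2, 2)), s = cbind(p = rep(2, 5)))
  panel <- sample_panel(c(s1 = "p"))
  load <- tabulate_load(vt, effects, pol, panel)
  lof <- load$individual[load$individual$category == "LoF", ]
  expect_equal(lof$n_het, 1L)
  expect_equal(lof$n_hom, 1L)
  expect_equal(lof$n_total, 2L)
  # derived = ref sites: hom-ref counts as derived homozygote
  mis <- load$individual[load$individual$category == "missense", ]
  expect_equal(mis$n_hom, 1L)
  dns <- load$individual[load$individual$category == "dnsSNP", ]
  expect_equal(dns$n_hom, 1L)  # dnsSNP subset of missense
  # no polarized sites -> all zeros
  pol0 <- polarized_table(pol$sites[0, ],
                          matrix(numeric(0), 0, 1,
                                 dimnames = list(NULL, "p")),
                          matrix(numeric(0), 0, 1,
                                 dimnames = list(NULL, "p")))
  vt0 <- subset_sites(vt, integer(0))
  load0 <- tabulate_load(vt0, effects, pol0, panel)
  expect_true(all(load0$individual$n_total == 0L))
})

test_that("allele-dose totals are conserved between individuals and sites", {
  set.seed(77)
  vt <- random_vt(80, 10, span = 1e5, miss_prob = 0)
  panel <- sample_panel(setNames(rep("p", 10), vt$samples))
  outg <- data.frame(chrom = "chr1", pos = vt$sites$pos,
                     allele = sample(c("A", "G"), 80, replace = TRUE),
                     stringsAsFactors = FALSE)
  pol <- polarize(vt, outg, panel)
  effects <- data.frame(chrom = "chr1", pos = vt$sites$pos,
                        class = "synonymous", dnssnp = FALSE,
                        stringsAsFactors = FALSE)
  load <- tabulate_load(vt, effects, pol, panel,
                        categories = "synonymous")
  # sum over individuals of (2 n_hom + n_het) = sum of population m
  lhs <- sum(2 * load$individual$n_hom + load$individual$n_het)
  expect_equal(lhs, sum(pol$m[, "p"], na.rm = TRUE))
})

test_that("homozygous load ratio follows 2h/(2h + het) with NA on empty", {
  load <- list(individual = data.frame(
    sample = c("a", "b", "c", "d"), population = "p", category = "LoF",
    n_het = c(2L, 0L, 5L, 0L), n_hom = c(2L, 3L, 0L, 0L),
    n_total = c(4L, 3L, 5L, 0L), stringsAsFactors = FALSE))
  hr <- hom_load_ratio(load)
  expect_equal(hr$individual$ratio, c(4 / 6, 1, 0, NA))
  expect_equal(hr$population$mean_ratio, mean(c(4 / 6, 1, 0)))
})
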