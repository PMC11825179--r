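make_rohf_fixture <- function() {
  # one individual, one ROH [1e5, 2e5]; 3 LoF + 6 synonymous carriers
  # inside, 4 LoF + 4 synonymous carriers outside
  pos <- c(seq(100100, 100900, by = 100),   # 9 sites inside
           seq(300000, 300700, by = 100))   # 8 sites outside
  cls <- c(rep("LoF", 3), rep("synonymous", 6),
           rep("LoF", 4), rep("synonymous", 4))
  vt <- toy_vt(pos, rep(1L, length(pos)))   # het everywhere -> all carriers
  effects <- data.frame(chrom = "chr1", pos = pos, class = cls,
                        dnssnp = FALSE, stringsAsFactors = FALSE)
  pol <- polarized_table(
    data.frame(chrom = "chr1", pos = pos, ancestral = "ref",
               stringsAsFactors = FALSE),
    m = cbind(p = rep(1, length(pos))), s = cbind(p = rep(2, length(pos))))
  segs <- data.frame(sample = "s1", chrom = "chr1", start = 1e5, end = 2e5,
                     n_snps = 9L, length = 100001)
  panel <- sample_panel(c(s1 = "p"))
  list(vt = vt, effects = effects, pol = pol, segs = segs, panel = panel)
}

test_that("ROHf and non-ROHf are carrier-count ratios per compartment", {
  fx <- make_rohf_fixture()
  res <- rohf_statistics(fx$vt, fx$segs, fx$effects, fx$pol, fx$panel,
                         categories = "LoF")
  ind <- res$individual
  expect_equal(ind$n_in, 3L)
  expect_equal(ind$s_in, 6L)
  expect_equal(ind$rohf, 0.5)
  expect_equal(ind$nonrohf, 1)
  expect_equal(ind$ratio, 0.5)
})

test_that("identical composition inside and outside ROH gives ratio 1", {
  pos <- c(seq(110000, 119000, by = 1000),  # inside: 5 LoF, 5 syn
           seq(310000, 319000, by = 1000))  # outside: 5 LoF, 5 syn
  cls <- rep(c(rep("LoF", 5), rep("synonymous", 5)), 2)
  vt <- toy_vt(pos, rep(2L, length(pos)))
  effects <- data.frame(chrom = "chr1", pos = pos, class = cls,
                        dnssnp = FALSE, stringsAsFactors = FALSE)
  pol <- polarized_table(
    data.frame(chrom = "chr1", pos = pos, ancestral = "ref",
               stringsAsFactors = FALSE),
    m = cbind(p = rep(2, 20)), s = cbind(p = rep(2, 20)))
  segs <- data.frame(sample = "s1", chrom = "chr1", start = 1e5,
                     end = 2e5, n_snps = 10L, length = 100001)
  res <- rohf_statistics(vt, segs, effects, pol,
                         sample_panel(c(s1 = "p")), categories = "LoF")
  expect_equal(res$individual$ratio, 1)
})

test_that("individuals with no synonymous carriers in a compartment are excluded", {
  fx <- make_rohf_fixture()
  segs0 <- fx$segs[0, ]   # no ROH at all: s_in = 0 -> ROHf undefined
  expect_message(
    res <- rohf_statistics(fx$vt, segs0, fx$effects, fx$pol, fx$panel,
                           categories = "LoF"),
    "excluded")
  expect_true(is.na(res$individual$rohf))
  expect_true(is.na(res$population$p_value))
})

test_that("rxy reproduces the hand-evaluated 4-site fixture", {
  toy <- make_worked_toy()$rxy_toy
  res <- rxy(toy$polar, "X", "Y", toy$category, toy$intergenic,
             n_blocks = 2)
  expect_equal(res$r, toy$expected_r)
  expect_equal(res$r, 1 / 3)
  expect_equal(res$l_x, 0.25 / 0.46875)
  expect_equal(res$l_y, 0.75 / 0.46875)
})

test_that("rxy identity and reciprocity hold exactly", {
  set.seed(21)
  n <- 200
  sites <- data.frame(chrom = "chr1", pos = seq_len(n) * 100,
                      ancestral = "ref", stringsAsFactors = FALSE)
  s <- matrix(20, n, 2, dimnames = list(NULL, c("X", "Y")))
  m <- cbind(X = rbinom(n, 20, 0.3), Y = rbinom(n, 20, 0.35))
  pol <- polarized_table(sites, m, s)
  cat_idx <- seq_len(n) %% 2 == 0
  int_idx <- !cat_idx
  # identical counts in both populations -> R = 1 to machine precision
  pol_same <- polarized_table(sites, cbind(X = m[, "X"], Y = m[, "X"]), s)
  expect_equal(rxy(pol_same, "X", "Y", cat_idx, int_idx)$r, 1)
  # same population twice -> exactly 1
  expect_equal(rxy(pol, "X", "X", cat_idx, int_idx)$r, 1)
  # reciprocity on a shared site set
  rxy_xy <- rxy(pol, "X", "Y", cat_idx, int_idx)$r
  rxy_yx <- rxy(pol, "Y", "X", cat_idx, int_idx)$r
  expect_equal(rxy_xy * rxy_yx, 1)
})

test_that("rxy skips uncallable sites and rejects empty site sets", {
  sites <- data.frame(chrom = "chr1", pos = c(100, 200, 300, 400),
                      ancestral = "ref", stringsAsFactors = FALSE)
  m <- cbind(X = c(2, 0, 3, 5), Y = c(4, 6, 3, 5))
  s <- cbind(X = c(8, 0, 8, 8), Y = c(8, 8, 8, 8))  # site 2: s_X = 0
  pol <- polarized_table(sites, m, s)
  res <- rxy(pol, "X", "Y", c(TRUE, TRUE, FALSE, FALSE),
             c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(res$n_category, 1L)
  expect_error(rxy(pol, "X", "Y", rep(FALSE, 4), c(FALSE, FALSE, TRUE, TRUE)),
               "nonempty")
})

test_that("the jackknife interval covers a doubled-load signal", {
  set.seed(33)
  hits <- 0L
  n_rep <- 10L
  for (i in seq_len(n_rep)) {
    n_c <- 1000; n_i <- 1000; n2 <- 20
    p_x <- runif(n_c, 0.05, 0.45)
    p_n <- runif(n_i, 0.05, 0.95)
    sites <- data.frame(chrom = "chr1", pos = seq_len(n_c + n_i) * 50,
                        ancestral = "ref", stringsAsFactors = FALSE)
    m <- cbind(X = c(rbinom(n_c, n2, p_x), rbinom(n_i, n2, p_n)),
               Y = c(rbinom(n_c, n2, 2 * p_x), rbinom(n_i, n2, p_n)))
    s <- matrix(n2, n_c + n_i, 2, dimnames = list(NULL, c("X", "Y")))
    pol <- polarized_table(sites, m, s)
    res <- rxy(pol, "X", "Y", c(rep(TRUE, n_c), rep(FALSE, n_i)),
               c(rep(FALSE, n_c), rep(TRUE, n_i)))
    if (res$r < 1 && res$r + 1.96 * res$se < 1) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("conservation track masks exactly the top quantile", {
  set.seed(3)
  sc <- data.frame(chrom = "chr1", pos = 1:1000 * 10,
                   score = rnorm(1000), stringsAsFactors = FALSE)
  tr <- conservation_track(sc, top_q = 0.01)
  expect_equal(sum(tr$top), 10L)   # ceil(0.01 * 1000)
  expect_gte(min(tr$score[tr$top]), max(tr$score[!tr$top]))
  expect_equal(attr(tr, "threshold"), min(tr$score[tr$top]))
})

test_that("conservation-weighted load follows the dose x score formula", {
  # one top site (score 5) hom + total derived dose 10 -> 2*5/10 = 1
  pos <- 1:6 * 100
  vt <- toy_vt(pos, c(2L, 2L, 2L, 2L, 1L, 1L))
  pol <- polarized_table(
    data.frame(chrom = "chr1", pos = pos, ancestral = "ref",
               stringsAsFactors = FALSE),
    m = cbind(p = c(2, 2, 2, 2, 1, 1)), s = cbind(p = rep(2, 6)))
  track <- data.frame(chrom = "chr1", pos = pos,
                      score = c(5, 1, 1, 1, 1, 1), stringsAsFactors = FALSE)
  res <- gerp_relative_load(vt, pol, track, top_q = 1 / 6)
  expect_equal(res$total_derived, 10)
  expect_equal(res$relative_load, 1)
  # doubling scores doubles the relative load (scale equivariance)
  track2 <- transform(track, score = score * 2)
  expect_equal(gerp_relative_load(vt, pol, track2, 1 / 6)$relative_load, 2)
  # an individual with no derived alleles in the top quantile scores 0
  vt0 <- toy_vt(pos, c(0L, 2L, 2L, 2L, 1L, 1L))
  pol0 <- polarized_table(pol$sites, m = cbind(p = c(0, 2, 2, 2, 1, 1)),
                          s = cbind(p = rep(2, 6)))
  expect_equal(gerp_relative_load(vt0, pol0, track, 1 / 6)$relative_load, 0)
})

test_that("relative load ignores score permutations below the threshold", {
  set.seed(9)
  pos <- 1:50 * 100
  g <- sample(0:2, 50, replace = TRUE)
  vt <- toy_vt(pos, g)
  pol <- polarized_table(
    data.frame(chrom = "chr1", pos = pos, ancestral = "ref",
               stringsAsFactors = FALSE),
    m = cbind(p = g), s = cbind(p = rep(2, 50)))
  score <- c(rnorm(45), 10 + rnorm(5))
  track <- data.frame(chrom = "chr1", pos = pos, score = score,
                      stringsAsFactors = FALSE)
  r1 <- gerp_relative_load(vt, pol, track, top_q = 0.1)
  perm <- track
  perm$score[1:45] <- sample(perm$score[1:45])
  r2 <- gerp_relative_load(vt, pol, perm, top_q = 0.1)
  expect_equal(r1$relative_load, r2$relative_load)
})

test_that("expected SFS matches the enumeration pmf and handles edge bins", {
  toy <- make_worked_toy()$sfs_toy
  res <- sfs(toy$polar, toy$effects, toy$panel, "pop1", 2)
  expect_equal(unname(res$spectra["neutral", ]),
               unname(toy$expected_spectrum))
  # fixed derived -> all mass in the fixed bin; absent -> all in bin 0
  sites <- data.frame(chrom = "chr1", pos = c(10, 20), ancestral = "ref",
                      stringsAsFactors = FALSE)
  pol <- polarized_table(sites, m = cbind(p = c(4, 0)),
                         s = cbind(p = c(4, 4)))
  eff <- data.frame(chrom = "chr1", pos = c(10, 20),
                    class = c("intergenic", "intergenic"), dnssnp = FALSE,
                    stringsAsFactors = FALSE)
  panel <- sample_panel(c(a = "p"))
  res2 <- sfs(pol, eff, panel, "p", 2)
  expect_equal(unname(res2$spectra["neutral", ]), c(0.5, 0, 0.5))
  pf <- proportion_fixed(res2)
  expect_equal(unname(pf["neutral"]), 0.5)
  expect_true(is.na(pf["damaging"]))
  # odd subsample size rejected; undersampled sites skipped
  expect_error(sfs(pol, eff, panel, "p", 3), "even")
  pol_small <- polarized_table(sites, m = cbind(p = c(4, 0)),
                               s = cbind(p = c(4, 2)))
  expect_equal(sfs(pol_small, eff, panel, "p", 4)$n_sites[["neutral"]], 1L)
})

test_that("Monte-Carlo SFS converges to the expected spectrum", {
  toy <- make_worked_toy()$sfs_toy
  set.seed(101)
  n_draws <- 10000L
  mc <- sfs(toy$polar, toy$effects, toy$panel, "pop1", 2,
            mode = "montecarlo", n_draws = n_draws)
  p <- unname(toy$expected_spectrum)
  se <- sqrt(p * (1 - p) / n_draws)
  expect_true(all(abs(unname(mc$spectra["neutral", ]) - p) <= 3 * se))
})

test_that("proportion_fixed counts sites with fixed derived alleles", {
  sites <- data.frame(chrom = "chr1", pos = 1:25 * 10, ancestral = "ref",
                      stringsAsFactors = FALSE)
  m <- c(rep(4, 2), rep(1, 23))   # 2 fixed of 25
  pol <- polarized_table(sites, m = cbind(p = m), s = cbind(p = rep(4, 25)))
  eff <- data.frame(chrom = "chr1", pos = 1:25 * 10, class = "intergenic",
                    dnssnp = FALSE, stringsAsFactors = FALSE)
  res <- sfs(pol, eff, sample_panel(c(a = "p")), "p", 4)
  expect_equal(unname(proportion_fixed(res)["neutral"]), 2 / 25)
})
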