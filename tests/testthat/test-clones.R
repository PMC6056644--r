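test_that("translation follows the standard code with ambiguity and stop rules", {
  aa <- translate_clones(c(a = "ATGGCT", b = "TAA", c = "ATGNNN", d = "ATGGCTA"))
  expect_equal(as.character(aa), c(a = "MA", b = "*", c = "MX", d = "MA"))
  expect_false(any(attr(aa, "internal_stop")))

  stopin <- translate_clones(c(x = "ATGTAAGCT"))
  expect_equal(as.character(stopin), c(x = "M*A"))
  expect_true(attr(stopin, "internal_stop")[["x"]])

  expect_equal(as.character(translate_clones(c(y = "AATGGCT"), frame = 2)),
               c(y = "MA"))
  expect_error(translate_clones(c(z = "AT")), "shorter")
  expect_error(translate_clones(c(z = "ATGQQQ")), regexp = ".")
})

test_that("pairwise identity is column-wise on the trimmed global alignment", {
  expect_equal(pairwise_identity("MKLV", "MKLV"), 1.0)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("MKLVAAAAT", "MKLVT"), 5 / 9)  # internal gap run
  expect_equal(pairwise_identity("MKLV", "AMKLV"), 1.0)         # terminal gap trimmed
  expect_equal(pairwise_identity("PQRS", "QRSP"),
               pairwise_identity("QRSP", "PQRS"))
  expect_error(pairwise_identity("", "MKLV"), "empty")

  # unrelated random proteins sit far below any clustering cutoff
  set.seed(13)
  aas <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")
  mk <- function() paste(sample(aas, 200, TRUE), collapse = "")
  nulls <- unlist(lapply(1:4, function(i)
    gradsip:::.identity_vec(mk(), replicate(50, mk()))))
  expect_lt(max(nulls), 0.25)
})

test_that("greedy clustering is deterministic and respects planted structure", {
  ident <- setNames(rep("MKLVNPQRST", 4), paste0("c", 1:4))
  for (ct in c(0.83, 0.87, 0.95, 1.0)) {
    expect_equal(cluster_opfs(ident, ct)$S_obs, 1)
  }
  # any mismatching pair at cutoff 1.0 stays separate
  two <- c(a = "MKLVNPQRST", b = "MKLVNPQRSA", c = "MKLVNPQRST")
  expect_equal(cluster_opfs(two, 1.0)$S_obs, 2)

  set.seed(23)
  lib <- simulate_clone_library(3, c(10, 6, 2), within_divergence = 0.05,
                                between_divergence = 0.40)
  aa <- translate_clones(lib$dna)
  sweep_df <- cutoff_sweep(aa, c(0.83, 0.87, 0.90, 0.95))
  expect_equal(sweep_df$S_obs, rep(3L, 4))           # planted count at every cutoff
  expect_true(all(diff(sweep_df$S_obs) >= 0))        # monotone in cutoff
  # permuting input relabels families but keeps the partition
  perm <- sample(length(aa))
  cl1 <- cluster_opfs(aa, 0.87)
  cl2 <- cluster_opfs(aa[perm], 0.87)
  expect_equal(sort(cl1$sizes), sort(cl2$sizes))

  # clones with internal stops are excluded by default
  withstop <- setNames(c(as.character(aa), "MK*LVNPQRST"),
                       c(paste0("s", seq_along(aa)), "bad"))
  attr(withstop, "internal_stop") <- setNames(c(rep(FALSE, length(aa)), TRUE),
                                              names(withstop))
  cl3 <- cluster_opfs(withstop, 0.87)
  expect_equal(cl3$excluded, "bad")
  expect_equal(cl3$N, length(aa))
})

test_that("diversity estimators match brute force and the published formulas", {
  expect_equal(chao1(c(5, 3, 1, 1)), 5.0)
  expect_equal(chao1(c(66, 1, 1)), 4.0)
  expect_equal(chao1(c(4, 3, 2)), 3.0)                 # no singletons
  expect_equal(shannon_index(10), 0)
  expect_equal(shannon_index(rep(5, 4), base = 2), 2.0)
  expect_equal(round(shannon_index(c(35, 1), base = 2), 4), 0.1831)
  expect_equal(goods_coverage(c(4, 3, 2)), 1.0)
  expect_equal(goods_coverage(1), 0.0)
  expect_equal(round(goods_coverage(c(35, 1)), 2), 0.97)

  set.seed(31)
  for (i in 1:200) {
    sizes <- sample.int(50, sample.int(30, 1), replace = TRUE)
    expect_equal(chao1(sizes), oracle_chao1(sizes), tolerance = 1e-12)
    expect_equal(shannon_index(sizes, 2), oracle_shannon(sizes, 2),
                 tolerance = 1e-12)
    expect_equal(shannon_index(sizes, exp(1)), oracle_shannon(sizes, exp(1)),
                 tolerance = 1e-12)
    expect_equal(goods_coverage(sizes), oracle_coverage(sizes), tolerance = 1e-12)
  }
})

test_that("estimators agree with vegan's implementations", {
  skip_if_not_installed("vegan")
  set.seed(37)
  for (i in 1:20) {
    sizes <- sample.int(40, sample.int(15, 1) + 1, replace = TRUE)
    est <- suppressWarnings(vegan::estimateR(sizes))
    expect_equal(chao1(sizes), unname(est["S.chao1"]), tolerance = 1e-9)
    expect_equal(shannon_index(sizes, base = exp(1)),
                 unname(vegan::diversity(sizes)), tolerance = 1e-12)
    n <- sample.int(sum(sizes), 1)
    expect_equal(rarefaction_expected(sizes, n)$expected_richness,
                 unname(c(vegan::rarefy(sizes, n))), tolerance = 1e-9)
  }
})

test_that("analytic rarefaction matches exact limits and subsampling", {
  expect_equal(rarefaction_expected(c(3, 2, 1), 1)$expected_richness, 1.0)
  expect_equal(rarefaction_expected(c(3, 2, 1), 6)$expected_richness, 3.0)
  expect_equal(rarefaction_expected(c(2, 2), 2)$expected_richness, 5 / 3,
               tolerance = 1e-12)
  expect_error(rarefaction_expected(c(2, 2), 5), "between 1 and")

  set.seed(41)
  sizes <- c(8, 5, 3, 2, 1, 1)
  for (n in c(3, 7, 12)) {
    mc <- oracle_rarefaction_mc(sizes, n, reps = 4000)
    expect_equal(rarefaction_expected(sizes, n)$expected_richness, mc$mean,
                 tolerance = 3 * mc$se / mc$mean + 1e-12)
  }
})
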