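frs3 <- fractions(1:3, c(1.730, 1.722, 1.715))   # only fraction 1 is heavy (>1.723)

test_that("top-k filtering matches a brute-force abundance ranking", {
  set.seed(21)
  n <- 30
  m <- matrix(rpois(n * 3, 20), n, 3,
              dimnames = list(sprintf("OTU_%02d", 1:n),
                              sample_id("G", c("12C-BT", "12C-BT", "NB"),
                                        c(0, 6, 0), NA)))
  otu <- sip_otu(m)
  top5 <- top_k_otus(otu, 5)
  rel <- sweep(m, 2, colSums(m), "/")
  oracle <- rownames(m)[order(-rowSums(rel), rownames(m))][1:5]
  expect_equal(rownames(top5$counts), oracle)

  dom <- m; dom["OTU_07", ] <- 10000L
  expect_equal(rownames(top_k_otus(sip_otu(dom), 1)$counts), "OTU_07")
  expect_equal(dim(top_k_otus(otu, n)), dim(otu))
  expect_warning(all_back <- top_k_otus(otu, n + 10), "exceeds")
  expect_equal(nrow(all_back$counts), n)
})

test_that("density profiles are fraction-compositional and sorted by density", {
  c13 <- matrix(c(10L, 90L, 5L, 95L, 0L, 100L), 2, 3,
                dimnames = list(c("A", "B"), NULL))
  otu <- build_frac_otu(c13, c13, frs3)
  pr <- density_profile(otu, frs3, "A", "13C-BT", 12)
  expect_equal(pr$buoyant_density, sort(frs3$buoyant_density))
  expect_equal(pr$rel_abundance, c(0, 0.05, 0.10))
  # single-taxon table: profile of all ones
  solo <- build_frac_otu(matrix(c(3L, 8L, 2L), 1, 3, dimnames = list("A", NULL)),
                         matrix(c(1L, 1L, 1L), 1, 3, dimnames = list("A", NULL)),
                         frs3)
  expect_equal(density_profile(solo, frs3, "A", "13C-BT", 12)$rel_abundance,
               rep(1, 3))
  # absent everywhere: all-zero profile
  zero <- build_frac_otu(rbind(c13, Z = 0L), rbind(c13, Z = 0L), frs3)
  expect_equal(density_profile(zero, frs3, "Z", "13C-BT", 12)$rel_abundance,
               rep(0, 3))
  expect_error(density_profile(otu, frs3, "nope", "13C-BT", 12), "not in table")
  # zero-total fraction excluded with a warning
  c0 <- c13; c0[, 2] <- 0L
  gap <- build_frac_otu(c0, c13, frs3)
  expect_warning(pg <- density_profile(gap, frs3, "A", "13C-BT", 12), "zero total")
  expect_equal(nrow(pg), 2)
})

test_that("heavy share sums density-thresholded mass and ignores fraction depth", {
  pr <- data.frame(buoyant_density = c(1.73, 1.725, 1.72),
                   rel_abundance = c(0.2, 0.3, 0))
  expect_equal(heavy_share(pr, 1.723), 1)
  uni <- data.frame(buoyant_density = seq(1.737, 1.712, length.out = 9),
                    rel_abundance = rep(0.1, 9))
  expect_equal(heavy_share(uni, uni$buoyant_density[3] - 1e-9), 1 / 3)
  expect_equal(heavy_share(data.frame(buoyant_density = 1:2 / 1 + 0.7,
                                      rel_abundance = c(0, 0))), 0)
  # rescaling one fraction's sequencing depth leaves the share unchanged
  c13 <- matrix(c(10L, 90L, 5L, 95L, 0L, 100L), 2, 3,
                dimnames = list(c("A", "B"), NULL))
  deep <- c13; deep[, 1] <- deep[, 1] * 7L
  o1 <- build_frac_otu(c13, c13, frs3)
  o2 <- build_frac_otu(deep, c13, frs3)
  expect_equal(heavy_share(density_profile(o1, frs3, "A", "13C-BT", 12)),
               heavy_share(density_profile(o2, frs3, "A", "13C-BT", 12)),
               tolerance = 1e-12)
})

test_that("labeling calls require repeated heavy-share excess", {
  # identical treatments: E = 0 everywhere, nothing labeled
  c13 <- matrix(c(10L, 90L, 5L, 95L, 0L, 100L), 2, 3,
                dimnames = list(c("A", "B"), NULL))
  same <- build_frac_otu(c13, c13, frs3)
  calls <- classify_labeled(same, frs3, min_days = 1)
  expect_false(any(calls$labeled))
  expect_equal(attr(calls, "scores")$E, rep(0, 2))   # 2 taxa, 1 shared day

  # engineered H13 = 0.6 vs H12 = 0.2 for taxon A in the heavy fraction
  h13 <- matrix(c(60L, 40L, 20L, 80L, 20L, 80L), 2, 3,
                dimnames = list(c("A", "B"), NULL))
  h12 <- matrix(c(20L, 80L, 40L, 60L, 40L, 60L), 2, 3,
                dimnames = list(c("A", "B"), NULL))
  otu <- build_frac_otu(h13, h12, frs3)
  sc <- attr(classify_labeled(otu, frs3, min_days = 1), "scores")
  expect_equal(sc$E[sc$taxon_id == "A"], 0.4, tolerance = 1e-12)
  # one supporting day is not enough under the default two-day rule
  expect_false(any(classify_labeled(otu, frs3)$labeled))
  expect_true(classify_labeled(otu, frs3, min_days = 1)["A", "labeled"])

  only13 <- sip_otu(matrix(1L, 1, 3, dimnames = list("A",
    sample_id("G", "13C-BT", 12, 1:3))))
  expect_error(classify_labeled(only13, frs3), "no common")
})

test_that("one gasfield draw recovers exactly the planted responders", {
  sc <- sip_scenario("gasfield", seed = 11)
  calls <- classify_labeled(sc$otu, sc$fractions)
  expect_setequal(calls$taxon_id[calls$labeled],
                  sc$ground_truth$taxon_id[sc$ground_truth$responder])
  bg <- sip_scenario("background", seed = 11)
  bcalls <- classify_labeled(bg$otu, bg$fractions, soil = "NG")
  expect_false(any(bcalls$labeled))
})
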