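test_that("correspondence analysis matches the chi-square and eigen oracles", {
  set.seed(51)
  for (i in 1:10) {
    x <- random_count_table(10, 8)
    ca <- correspondence_analysis(x)
    chi <- suppressWarnings(chisq.test(x)$statistic)
    expect_equal(ca$total_inertia, unname(chi) / sum(x), tolerance = 1e-10)
    ev <- oracle_ca_eigenvalues(x)
    expect_equal(ca$eigenvalues, ev[seq_along(ca$eigenvalues)], tolerance = 1e-8)
    expect_equal(sum(ca$percent), 100, tolerance = 1e-8)
    expect_equal(ca$percent, 100 * ev[seq_along(ca$eigenvalues)] / sum(ev),
                 tolerance = 1e-6)
  }
})

test_that("degenerate tables behave: independence, perfect association, zero margins", {
  indep <- matrix(5, 2, 2)
  ca <- correspondence_analysis(indep)
  expect_equal(length(ca$eigenvalues), 0)
  expect_equal(ca$total_inertia, 0, tolerance = 1e-12)

  block <- matrix(c(10, 0, 0, 10), 2, 2)
  cb <- correspondence_analysis(block)
  expect_equal(cb$total_inertia, 1, tolerance = 1e-12)
  expect_equal(cb$percent, 100, tolerance = 1e-10)

  zr <- matrix(c(1, 0, 2, 0), 2, 2, dimnames = list(c("s1", "s2"), NULL))
  expect_error(correspondence_analysis(zr), "s2")
  expect_error(correspondence_analysis(matrix(c(1, 2, -1, 4), 2, 2)),
               "non-negative")
})

test_that("ordination is scale-invariant and row/column scores are dual", {
  set.seed(53)
  x <- random_count_table(7, 5)
  ca1 <- correspondence_analysis(x)
  ca2 <- correspondence_analysis(x * 13)
  expect_equal(ca1$eigenvalues, ca2$eigenvalues, tolerance = 1e-10)
  expect_equal(abs(ca1$sample_scores), abs(ca2$sample_scores), tolerance = 1e-8)

  # transition formula: taxon scores are the margin-weighted averages of
  # sample scores, scaled by the inverse singular value per axis
  P <- x / sum(x)
  cc <- colSums(P)
  d <- sqrt(ca1$eigenvalues)
  G_from_F <- sweep(t(P) %*% ca1$sample_scores, 1, cc, "/")
  G_from_F <- sweep(G_from_F, 2, d, "/")
  expect_equal(unname(G_from_F), unname(ca1$taxon_scores), tolerance = 1e-8)
})

test_that("segment detrending removes axis-1-explainable axis-2 structure", {
  set.seed(57)
  x <- random_count_table(12, 9)
  ca <- correspondence_analysis(x)
  flat <- ca
  flat$sample_scores[, 2] <- 0.7
  dt <- detrend_by_segments(flat, 5)
  expect_equal(unname(dt$sample_scores[, 2]), rep(0, nrow(x)), tolerance = 1e-12)
  expect_true(dt$detrended)
  expect_equal(dt$percent, ca$percent)   # percentages retained

  arch <- ca
  bins <- cut(arch$sample_scores[, 1], 4)
  arch$sample_scores[, 2] <- as.numeric(bins) * 2.5   # pure function of the bin
  da <- detrend_by_segments(arch, 4)
  expect_equal(unname(da$sample_scores[, 2]), rep(0, nrow(x)), tolerance = 1e-8)

  expect_error(detrend_by_segments(ca, 1), "n_segments")
  one_axis <- ca; one_axis$sample_scores <- ca$sample_scores[, 1, drop = FALSE]
  expect_error(detrend_by_segments(one_axis), "2 computed axes")
})

test_that("eigenvalues agree with vegan's correspondence analysis", {
  skip_if_not_installed("vegan")
  set.seed(59)
  x <- random_count_table(9, 6)
  ca <- correspondence_analysis(x)
  vg <- vegan::cca(x)
  expect_equal(ca$eigenvalues, unname(vg$CA$eig[seq_along(ca$eigenvalues)]),
               tolerance = 1e-8)
})

test_that("group aggregation sums relative abundances with an unassigned pool", {
  m <- matrix(c(10L, 10L, 5L, 15L), 2, 2,
              dimnames = list(c("t1", "t2"),
                              sample_id("G", c("12C-BT", "NB"), 0, NA)))
  otu <- sip_otu(m)
  one <- aggregate_groups(otu, data.frame(taxon_id = c("t1", "t2"),
                                          group = c("Proteo", "Proteo")))
  expect_equal(unname(one["Proteo", ]), c(1, 1))
  two <- aggregate_groups(otu, data.frame(taxon_id = c("t1", "t2"),
                                          group = c("A", "B")))
  expect_equal(unname(two[, 1]), c(0.5, 0.5))
  part <- aggregate_groups(otu, data.frame(taxon_id = "t1", group = "A"))
  expect_equal(unname(part["unassigned", 2]), 0.75)
  expect_error(aggregate_groups(otu, data.frame()), "empty")

  # oracle: group difference between samples equals brute-force recomputation
  set.seed(61)
  n <- 20
  mm <- matrix(rpois(n * 2, 30), n, 2,
               dimnames = list(sprintf("x%02d", 1:n),
                               sample_id("G", "12C-BT", c(0, 12), NA)))
  grp <- sample(c("g1", "g2", "g3"), n, TRUE)
  agg <- aggregate_groups(sip_otu(mm), data.frame(taxon_id = rownames(mm),
                                                  group = grp))
  rel <- sweep(mm, 2, colSums(mm), "/")
  for (g in c("g1", "g2", "g3")) {
    brute <- colSums(rel[grp == g, , drop = FALSE])
    expect_equal(unname(agg[g, 2] - agg[g, 1]), unname(brute[2] - brute[1]),
                 tolerance = 1e-12)
  }
})
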