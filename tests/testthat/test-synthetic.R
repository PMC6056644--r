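cfg0 <- sim_config()

test_that("taxon density follows the GC relation plus the labeling shift", {
  expect_equal(taxon_density(0.5, 0, cfg0), 1.709)
  expect_equal(taxon_density(0.5, 1, cfg0), 1.745)
  expect_equal(taxon_density(0, 0, cfg0), 1.660)
  expect_error(taxon_density(1.2, 0, cfg0), "lie in")
})

test_that("gas kinetics: abiotic decay only without responders, biotic loss with them", {
  set.seed(41)
  comm0 <- sim_community(cfg0, responders = 0)
  sim0 <- simulate_butane(cfg0, comm0)
  expect_equal(sim0$truth$R_live_true, sim0$truth$R_sterile_true, tolerance = 1e-12)
  expect_equal(sim0$truth$net_biodegradation, rep(0, 5), tolerance = 1e-12)
  # default abiotic rate reproduces ~86% sterile residual at day 14
  expect_equal(sim0$truth$R_sterile_true[sim0$truth$day == 14], 0.86,
               tolerance = 0.002)

  comm3 <- sim_community(cfg0, responders = 3)
  sim3 <- simulate_butane(cfg0, comm3)
  d14 <- sim3$truth$day == 14
  expect_lt(sim3$truth$R_live_true[d14], sim3$truth$R_sterile_true[d14])
  expect_gt(sim3$truth$biotic_consumed_frac[d14], 10)

  # zero growth rate shuts the biotic term off
  commflat <- comm3; commflat$growth_rate[] <- 0
  simflat <- simulate_butane(cfg0, commflat)
  expect_equal(simflat$truth$net_biodegradation, rep(0, 5), tolerance = 1e-12)

  expect_error(simulate_butane(cfg0, comm3, days = c(6, 9)), "start at 0")
})

test_that("gradient banding conserves mass and peaks at the taxon's density", {
  comm <- data.frame(id = c("t1", "t2"), gc = c(0.5, 0.55),
                     baseline_abundance = c(1, 2), responder = FALSE,
                     atom_fraction_excess = 0, growth_rate = 0,
                     carries_bmox = FALSE)
  wide <- sim_config(fraction_densities = seq(1.756, 1.700, length.out = 15),
                     fraction_indices = 1:15)
  g <- simulate_gradient(comm, cfg = wide)
  expect_equal(unname(rowSums(g$band)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(colSums(g$composition)), rep(1, 15), tolerance = 1e-12)
  # peak fraction holds the grid density nearest 1.709
  peak <- wide$fraction_densities[which.max(g$band["t1", ])]
  expect_equal(peak, wide$fraction_densities[which.min(abs(wide$fraction_densities - 1.709))])

  # degenerate kernel: all weight lands in the nearest fraction
  tiny <- sim_config(fraction_densities = wide$fraction_densities,
                     fraction_indices = 1:15, band_sigma = 1e-9,
                     delta_rho_max = 0.036)
  gt <- simulate_gradient(comm, cfg = tiny)
  expect_equal(max(gt$band["t1", ]), 1, tolerance = 1e-9)

  expect_error(simulate_gradient(comm, biomass = c(0, 0), cfg = wide), "all-zero")
})

test_that("full labeling moves the band by the configured density offset", {
  wide <- sim_config(fraction_densities = seq(1.756, 1.700, length.out = 15),
                     fraction_indices = 1:15)
  spacing <- abs(diff(wide$fraction_densities))[1]
  comm <- data.frame(id = "t1", gc = 0.49, baseline_abundance = 1,
                     responder = TRUE, atom_fraction_excess = 1,
                     growth_rate = 0, carries_bmox = TRUE)
  g0 <- simulate_gradient(comm, cfg = wide, atom_excess = 0)
  g1 <- simulate_gradient(comm, cfg = wide, atom_excess = 1)
  mean0 <- sum(wide$fraction_densities * g0$band[1, ])
  mean1 <- sum(wide$fraction_densities * g1$band[1, ])
  expect_equal(mean1 - mean0, wide$delta_rho_max, tolerance = spacing / 2)
  # heavy share is monotone in atom fraction excess
  shares <- vapply(seq(0, 1, by = 0.1), function(e) {
    g <- simulate_gradient(comm, cfg = wide, atom_excess = e)
    sum(g$band[1, wide$fraction_densities > 1.723]) / sum(g$band[1, ])
  }, numeric(1))
  expect_true(all(diff(shares) >= -1e-12))
})

test_that("amplicon counts are multinomial draws of the composition", {
  comp <- matrix(c(1, 0, 0, 0.2, 0.3, 0.5), 3, 2,
                 dimnames = list(paste0("t", 1:3), c("f01", "f02")))
  expect_error(simulate_amplicon(comp, 0), "positive")
  set.seed(5)
  cnt <- simulate_amplicon(comp, 100)
  expect_equal(unname(cnt[, 1]), c(100L, 0L, 0L))
  expect_equal(colSums(cnt), c(f01 = 100L, f02 = 100L))

  draws <- replicate(1000, simulate_amplicon(comp, 50)[, 2])
  p <- comp[, 2]
  se <- sqrt(p * (1 - p) / 50 / 1000)
  expect_true(all(abs(rowMeans(draws) / 50 - p) <= 3 * se + 1e-12))
})

test_that("qPCR simulation is exact at zero noise and inverts through the curve", {
  curve <- standard_curve(slope = -3.3219, intercept = 38)
  set.seed(1)
  q <- simulate_qpcr(c(a = 1e4, b = 1e5), curve, cq_noise_sd = 0, n_rep = 2)
  expect_equal(q$cq[q$sample_id == "a"], rep(38 - 3.3219 * 4, 2), tolerance = 1e-12)
  # one decade of dilution adds exactly one slope unit
  expect_equal(unique(q$cq[q$sample_id == "a"]) - unique(q$cq[q$sample_id == "b"]),
               3.3219, tolerance = 1e-12)
  back <- quantify_copies(q$cq, curve)
  expect_equal(back, rep(c(1e4, 1e5), each = 2), tolerance = 1e-6)
  expect_error(simulate_qpcr(c(a = 0), curve), "positive")
})

test_that("clone libraries plant recoverable protein-family structure", {
  set.seed(7)
  one <- simulate_clone_library(1, 5, within_divergence = 0)
  aa <- translate_clones(one$dna)
  expect_equal(length(unique(as.character(aa))), 1)

  expect_error(simulate_clone_library(2, c(3, 3), within_divergence = 0.3,
                                      between_divergence = 0.5), "infeasible")

  two <- simulate_clone_library(2, c(6, 4), within_divergence = 0.05,
                                between_divergence = 0.5)
  cl <- cluster_opfs(translate_clones(two$dna), 0.87)
  expect_equal(cl$S_obs, 2)
  expect_equal(unname(sort(cl$sizes)), c(4L, 6L))
  # recovered partition matches the planted one
  expect_equal(length(unique(paste(cl$assignments, two$truth$family))), 2)
})

test_that("scenarios expose ground truth and are seed-reproducible", {
  expect_error(sip_scenario("swamp"), "arg")
  sc1 <- sip_scenario("gasfield", seed = 31)
  expect_equal(sum(sc1$ground_truth$responder), 3)
  expect_true(all(sc1$ground_truth$atom_fraction_excess[sc1$ground_truth$responder] >= 0.5))
  sc1b <- sip_scenario("gasfield", seed = 31)
  expect_identical(sc1$otu$counts, sc1b$otu$counts)
  expect_identical(sc1$gas$butane_amount, sc1b$gas$butane_amount)
  sc2 <- sip_scenario("gasfield", seed = 32)
  expect_false(identical(sc1$otu$counts, sc2$otu$counts))
  expect_equal(dim(sc1$otu$counts), dim(sc2$otu$counts))

  bg <- sip_scenario("background", seed = 31)
  expect_equal(sum(bg$ground_truth$responder), 0)
  expect_true(any(bg$ground_truth$carries_bmox))
})
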