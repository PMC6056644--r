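#' Simulator configuration
#'
#' Parameters of the forward model of a DNA-SIP incubation: community size,
#' the GC-to-density relation, the full-labeling density shift, gradient
#' banding width, the fraction grid, sequencing depth, gas kinetics, and
#' observation noise. Defaults describe a gas-field soil microcosm fed
#' isotope-labeled butane: an abiotic loss rate giving ~86% sterile residual
#' at day 14, logistic growth of three rare responders whose yield-coupled
#' consumption removes a further ~21% of the butane by day 14, and a
#' 9-fraction analysis window spanning 1.712-1.737 g/ml (collection
#' fractions 4-12 of 15).
#'
#' @param n_taxa community size.
#' @param n_responders number of isotope-assimilating taxa planted.
#' @param schildkraut_intercept,schildkraut_slope linear GC-to-buoyant-density
#'   relation, g/ml and g/ml per GC unit: `rho = intercept + slope * GC`.
#' @param delta_rho_max g/ml density shift at full isotope labeling.
#' @param band_sigma g/ml standard deviation of a taxon's Gaussian band.
#' @param fraction_densities gradient fraction densities, strictly decreasing
#'   with collection index (heavy end first).
#' @param fraction_indices collection indices matching `fraction_densities`.
#' @param depth amplicon reads per fraction sample.
#' @param k_physical per-day abiotic gas loss rate.
#' @param growth_rate per-day logistic growth rate of responders.
#' @param carrying_capacity total responder biomass ceiling (relative units).
#' @param responder_baseline initial biomass of each responder.
#' @param yield gas consumed (initial-amount fraction) per unit responder growth.
#' @param initial_amount headspace gas amount at day 0 (arbitrary units).
#' @param gas_noise_sd sdlog of mean-one lognormal measurement noise on gas.
#' @param gas_replicates measurement replicates per treatment and day.
#' @param cq_noise_sd cycles; qPCR quantification-cycle noise.
#' @param qpcr_replicates qPCR replicates per sample.
#' @param gc_range GC content range for background taxa.
#' @param responder_gc_range GC content range for responders (mid-gradient,
#'   so labeled bands stay inside the analyzed window).
#' @param atom_fraction_excess isotope excess of responders at full labeling.
#' @param abundance_sdlog lognormal sdlog of baseline abundances; modest
#'   because only the dominant (top-k) community is modeled.
#' @param bmox_copies_per_biomass,ssu_copies_per_biomass copies contributed
#'   to the extract per biomass unit by the functional and the 16S gene.
#' @param incorporation named vector: fraction of the maximal atom excess
#'   attained per incubation day (labeling becomes detectable by day 12).
#' @param seed integer seed.
#' @return object of class `sim_config` (validated named list).
#' @export
sim_config <- function(n_taxa = 100L,
                       n_responders = 3L,
                       schildkraut_intercept = 1.660,
                       schildkraut_slope = 0.098,
                       delta_rho_max = 0.036,
                       band_sigma = 0.003,
                       fraction_densities = seq(1.737, 1.712, length.out = 9),
                       fraction_indices = 4:12,
                       depth = 20000L,
                       k_physical = -log(0.86) / 14,
                       growth_rate = 0.5,
                       carrying_capacity = 1,
                       responder_baseline = 0.01,
                       yield = 0.22,
                       initial_amount = 100,
                       gas_noise_sd = 0.02,
                       gas_replicates = 3L,
                       cq_noise_sd = 0.2,
                       qpcr_replicates = 3L,
                       gc_range = c(0.35, 0.58),
                       responder_gc_range = c(0.46, 0.56),
                       atom_fraction_excess = 0.8,
                       abundance_sdlog = 0.6,
                       bmox_copies_per_biomass = 1e7,
                       ssu_copies_per_biomass = 1e9,
                       incorporation = c("0" = 0, "6" = 0.1, "9" = 0.3,
                                         "12" = 1, "14" = 1),
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$n_taxa <- as.integer(n_taxa)
  cfg$n_responders <- as.integer(n_responders)
  cfg$depth <- as.integer(depth)
  rates <- c(k_physical, growth_rate, yield, band_sigma, delta_rho_max,
             gas_noise_sd, cq_noise_sd)
  if (any(rates < 0)) stop("rates and dispersions must be non-negative")
  if (any(diff(fraction_densities) >= 0))
    stop("fraction_densities must decrease strictly with fraction index")
  if (length(fraction_indices) != length(fraction_densities))
    stop("fraction_indices and fraction_densities lengths differ")
  if (!(delta_rho_max > band_sigma))
    stop("delta_rho_max must exceed band_sigma or labeling is undetectable")
  if (cfg$n_responders > cfg$n_taxa) stop("more responders than taxa")
  structure(cfg, class = "sim_config")
}

#' Buoyant density of a taxon's DNA
#'
#' Linear GC-to-density relation plus a labeling shift proportional to the
#' atom fraction excess:
#' `rho = intercept + slope * gc + excess * delta_rho_max`.
#'
#' @param gc GC content in `[0, 1]`.
#' @param atom_fraction_excess isotope excess in `[0, 1]`.
#' @param cfg a [sim_config()].
#' @return buoyant density in g/ml.
#' @export
taxon_density <- function(gc, atom_fraction_excess = 0, cfg = sim_config()) {
  if (any(gc < 0 | gc > 1) || any(atom_fraction_excess < 0 | atom_fraction_excess > 1))
    stop("gc and atom_fraction_excess must lie in [0, 1]")
  cfg$schildkraut_intercept + cfg$schildkraut_slope * gc +
    atom_fraction_excess * cfg$delta_rho_max
}

#' Draw a synthetic soil community
#'
#' Background taxa get GC contents and lognormal baseline abundances; the
#' first `n_responders` taxa are flagged as isotope assimilators carrying
#' the functional gene, starting rare and growing on the gas.
#'
#' @param cfg a [sim_config()].
#' @param responders number of responders (defaults to `cfg$n_responders`).
#' @return data.frame with columns `id`, `gc`, `baseline_abundance`,
#'   `responder`, `atom_fraction_excess`, `growth_rate`, `carries_bmox`.
#' @export
sim_community <- function(cfg = sim_config(), responders = cfg$n_responders) {
  n <- cfg$n_taxa
  responders <- as.integer(responders)
  gc <- runif(n, cfg$gc_range[1], cfg$gc_range[2])
  baseline <- rlnorm(n, meanlog = 0, sdlog = cfg$abundance_sdlog)
  baseline <- baseline / sum(baseline)
  resp <- rep(FALSE, n)
  carries <- rep(FALSE, n)
  afe <- rep(0, n)
  growth <- rep(0, n)
  if (responders > 0) {
    resp[seq_len(responders)] <- TRUE
    carries[seq_len(responders)] <- TRUE
    gc[seq_len(responders)] <- runif(responders, cfg$responder_gc_range[1],
                                     cfg$responder_gc_range[2])
    baseline[seq_len(responders)] <- cfg$responder_baseline
    afe[seq_len(responders)] <- cfg$atom_fraction_excess
    growth[seq_len(responders)] <- cfg$growth_rate
  } else {
    ## an unlabeled functional-gene pool still exists in background soils
    carries[seq_len(min(3L, n))] <- TRUE
  }
  data.frame(id = sprintf("OTU_%03d", seq_len(n)), gc = gc,
             baseline_abundance = baseline, responder = resp,
             atom_fraction_excess = afe, growth_rate = growth,
             carries_bmox = carries, stringsAsFactors = FALSE)
}

#' Simulate headspace gas depletion in live and sterile microcosms
#'
#' Forward-Euler integration (0.1 d step) of logistic responder growth with
#' yield-coupled substrate drawdown on top of first-order abiotic loss; the
#' sterile bottle sees abiotic loss only. Measurements carry multiplicative
#' mean-one lognormal noise per replicate.
#'
#' @param cfg a [sim_config()].
#' @param community a [sim_community()] data.frame.
#' @param days sorted measurement days starting at 0.
#' @return list with `gas` (data.frame `treatment`, `day`, `replicate`,
#'   `butane_amount`; treatments `12C-BT` live and `12C-ST` sterile),
#'   `biomass` (taxa x days matrix at the measurement days), and `truth`
#'   (deterministic residuals `R_live_true`, `R_sterile_true`, their
#'   difference `net_biodegradation` in percentage points, and the gross
#'   `biotic_consumed_frac` of the initial gas).
#' @export
simulate_butane <- function(cfg = sim_config(), community = sim_community(cfg),
                            days = c(0, 6, 9, 12, 14)) {
  if (is.unsorted(days, strictly = TRUE) || days[1] != 0)
    stop("days must be sorted and start at 0")
  dt <- 0.1
  t_end <- max(days)
  steps <- round(t_end / dt)
  ridx <- which(community$responder)
  b <- community$baseline_abundance[ridx]
  r <- community$growth_rate[ridx]
  A <- 1          # live, as fraction of initial amount
  A_st <- 1       # sterile
  consumed_bio <- 0
  K <- cfg$carrying_capacity
  day_grid <- round(days / dt)
  bio_at <- matrix(rep(community$baseline_abundance, length(days)),
                   ncol = length(days),
                   dimnames = list(community$id, paste0("d", days)))
  rec <- function(state, j) state
  snap <- function(step) which(day_grid == step)
  for (j in snap(0L)) {
    if (length(ridx)) bio_at[ridx, j] <- b
  }
  truth <- data.frame(day = days, R_live_true = NA_real_, R_sterile_true = NA_real_)
  truth$R_live_true[days == 0] <- 1
  truth$R_sterile_true[days == 0] <- 1
  consumed_at <- setNames(numeric(length(days)), paste0("d", days))
  for (s in seq_len(steps)) {
    db <- if (length(ridx) && A > 0) r * b * max(0, 1 - sum(b) / K) * dt else 0
    dbio <- if (length(db) > 1 || length(db) == 1) sum(db) else 0
    use <- cfg$yield * dbio
    A_next <- A - (cfg$k_physical * A * dt + use)
    if (A_next < 0) {             # gas exhausted within the step: cap uptake
      use <- max(0, A - cfg$k_physical * A * dt)
      scale <- if (cfg$yield * dbio > 0) use / (cfg$yield * dbio) else 0
      db <- db * scale
      A_next <- 0
    }
    b <- b + db
    consumed_bio <- consumed_bio + cfg$yield * sum(db)
    A <- A_next
    A_st <- A_st - cfg$k_physical * A_st * dt
    if (A < -1e-12 || A_st < -1e-12 || any(b < 0))
      stop("simulation state went negative; check kinetic parameters")
    for (j in snap(s)) {
      if (length(ridx)) bio_at[ridx, j] <- b
      truth$R_live_true[j] <- A
      truth$R_sterile_true[j] <- A_st
      consumed_at[j] <- consumed_bio
    }
  }
  truth$net_biodegradation <- 100 * (truth$R_sterile_true - truth$R_live_true)
  truth$biotic_consumed_frac <- 100 * consumed_at
  noise <- function(n) rlnorm(n, meanlog = -cfg$gas_noise_sd^2 / 2,
                              sdlog = cfg$gas_noise_sd)
  nrep <- cfg$gas_replicates
  gas <- do.call(rbind, lapply(seq_along(days), function(j) {
    data.frame(
      treatment = rep(c("12C-BT", "12C-ST"), each = nrep),
      day = days[j],
      replicate = rep(seq_len(nrep), 2),
      butane_amount = cfg$initial_amount *
        c(truth$R_live_true[j] * noise(nrep), truth$R_sterile_true[j] * noise(nrep)),
      stringsAsFactors = FALSE)
  }))
  list(gas = gas_series(gas), biomass = bio_at, truth = truth)
}

#' Distribute taxon DNA across gradient fractions
#'
#' Each taxon's DNA forms a Gaussian band centered at its buoyant density
#' (see [taxon_density()]); the band is evaluated on the fraction grid and
#' normalized per taxon. Per-fraction community composition follows by
#' weighting bands with biomass and renormalizing within each fraction.
#'
#' @param community a [sim_community()] data.frame.
#' @param biomass per-taxon biomass (non-negative, not all zero).
#' @param cfg a [sim_config()].
#' @param atom_excess per-taxon atom fraction excess (defaults to the
#'   community column, i.e. full labeling of responders).
#' @return list with matrices `band` (rows sum to 1), `mass`
#'   (biomass-weighted band), `composition` (columns sum to 1); columns are
#'   fractions in grid order (heavy first).
#' @export
simulate_gradient <- function(community, biomass = community$baseline_abundance,
                              cfg = sim_config(),
                              atom_excess = community$atom_fraction_excess) {
  if (any(biomass < 0)) stop("biomass must be non-negative")
  if (all(biomass == 0)) stop("all-zero biomass: no DNA to band")
  rho <- taxon_density(community$gc, atom_excess, cfg)
  grid <- cfg$fraction_densities
  d2 <- outer(rho, grid, function(a, b) (b - a)^2)
  band <- exp(-d2 / (2 * cfg$band_sigma^2))
  zero <- rowSums(band) == 0   # band far off-grid at tiny sigma: nearest fraction
  if (any(zero)) {
    nearest <- apply(abs(outer(rho[zero], grid, "-")), 1, which.min)
    band[zero, ] <- 0
    band[cbind(which(zero), nearest)] <- 1
  }
  band <- band / rowSums(band)
  mass <- band * biomass
  tot <- colSums(mass)
  comp <- sweep(mass, 2, ifelse(tot > 0, tot, 1), "/")
  dimnames(band) <- dimnames(mass) <- dimnames(comp) <-
    list(community$id, sprintf("f%02d", cfg$fraction_indices))
  list(band = band, mass = mass, composition = comp)
}

#' Draw multinomial amplicon counts per fraction
#'
#' @param composition taxa x fractions matrix of per-fraction compositions
#'   (columns sum to 1).
#' @param depth reads per fraction sample (positive integer).
#' @return integer matrix of counts with the dimnames of `composition`.
#' @export
simulate_amplicon <- function(composition, depth) {
  depth <- as.integer(depth)
  if (is.na(depth) || depth <= 0) stop("depth must be a positive integer")
  if (any(abs(colSums(composition) - 1) > 1e-8))
    stop("compositions must sum to 1 per fraction")
  counts <- apply(composition, 2, function(p) rmultinom(1, depth, p)[, 1])
  dimnames(counts) <- dimnames(composition)
  counts
}

#' Simulate qPCR quantification cycles for known copy numbers
#'
#' `Cq = intercept + slope * log10(copies) + Normal(0, cq_noise_sd)`,
#' replicated per sample.
#'
#' @param true_copies named vector of positive copy numbers (names become
#'   sample ids).
#' @param curve a [standard_curve()] (its slope and intercept generate).
#' @param cq_noise_sd cycle noise standard deviation.
#' @param gene gene label written into the rows.
#' @param n_rep replicates per sample.
#' @return data.frame `sample_id`, `gene`, `replicate`, `cq`.
#' @export
simulate_qpcr <- function(true_copies, curve, cq_noise_sd = 0.2,
                          gene = "bmoX", n_rep = 3L) {
  if (any(true_copies <= 0)) stop("true_copies must be positive")
  ids <- names(true_copies)
  if (is.null(ids)) ids <- sprintf("sample_%02d", seq_along(true_copies))
  mu <- curve$intercept + curve$slope * log10(true_copies)
  data.frame(
    sample_id = rep(ids, each = n_rep),
    gene = gene,
    replicate = rep(seq_len(n_rep), length(true_copies)),
    cq = rep(mu, each = n_rep) + rnorm(length(mu) * n_rep, 0, cq_noise_sd),
    stringsAsFactors = FALSE)
}

## Fixed reverse-translation table: lexicographically first codon per residue.
.codon_for_aa <- function() {
  gc <- Biostrings::GENETIC_CODE
  aa <- sort(unique(gc[gc != "*"]))
  vapply(aa, function(a) sort(names(gc)[gc == a])[1], character(1))
}

.AA20 <- c("A","C","D","E","F","G","H","I","K","L",
           "M","N","P","Q","R","S","T","V","W","Y")

.hamming_identity <- function(a, b) {
  ## equal-length character matrices of residues
  mean(a == b)
}

#' Simulate a clone library with planted protein-family structure
#'
#' Generates nucleotide clone sequences whose deduced proteins form
#' `n_families` clusters: mutually dissimilar random centroid proteins, and
#' members mutated from their centroid by at most `within_divergence` of the
#' residues. Sequences are reverse-translated with a fixed codon table, so
#' translation in frame 1 recovers the proteins exactly. Each family's first
#' emitted clone is its unmutated centroid.
#'
#' @param n_families number of planted families.
#' @param sizes integer family sizes (length `n_families`).
#' @param within_divergence maximum residue divergence of a member from its
#'   centroid.
#' @param between_divergence minimum divergence between centroids.
#' @param seq_length nucleotide sequence length (a multiple of 3).
#' @return list with `dna` (a [Biostrings::DNAStringSet] named
#'   `clone_001`...) and `truth` (data.frame `clone_id`, `family`).
#' @export
simulate_clone_library <- function(n_families, sizes,
                                   within_divergence = 0.05,
                                   between_divergence = 0.40,
                                   seq_length = 450L) {
  n_families <- as.integer(n_families)
  sizes <- as.integer(sizes)
  if (length(sizes) != n_families) stop("need one size per family")
  if (any(sizes < 1)) stop("family sizes must be positive")
  if (2 * within_divergence >= between_divergence)
    stop("infeasible divergences: need 2*within_divergence < between_divergence")
  L <- seq_length %/% 3L
  if (L < 10) stop("seq_length too short")
  gen_centroids <- function() {
    t(replicate(n_families, sample(.AA20, L, replace = TRUE)))
  }
  ok <- FALSE
  for (try in 1:25) {
    cent <- gen_centroids()
    ok <- TRUE
    if (n_families > 1) {
      for (i in seq_len(n_families - 1)) for (j in (i + 1):n_families) {
        if (.hamming_identity(cent[i, ], cent[j, ]) >= 1 - between_divergence)
          ok <- FALSE
      }
    }
    if (ok) break
  }
  if (!ok) stop("could not generate sufficiently divergent centroids")
  max_mut <- floor(within_divergence * L)
  prot <- list(); fam <- integer(0)
  for (f in seq_len(n_families)) {
    for (m in seq_len(sizes[f])) {
      p <- cent[f, ]
      if (m > 1 && max_mut > 0) {
        k <- sample.int(max_mut, 1)
        pos <- sample.int(L, k)
        p[pos] <- vapply(p[pos], function(a) sample(setdiff(.AA20, a), 1), "")
      }
      prot[[length(prot) + 1]] <- p
      fam <- c(fam, f)
    }
  }
  codons <- .codon_for_aa()
  dna <- vapply(prot, function(p) paste(codons[p], collapse = ""), character(1))
  ids <- sprintf("clone_%03d", seq_along(dna))
  dna <- Biostrings::DNAStringSet(setNames(dna, ids))
  list(dna = dna, truth = data.frame(clone_id = ids, family = fam,
                                     stringsAsFactors = FALSE))
}

#' Generate a full synthetic SIP study
#'
#' `"gasfield"` plants isotope-assimilating responders carrying the
#' functional gene in an active soil; `"background"` is the inactive control
#' with no responders (its functional-gene pool stays unlabeled). The bundle
#' holds everything the pipeline consumes -- OTU tables (fractionated days
#' 6/9/12/14 in both labeled and unlabeled treatments, plus unfractionated
#' time courses), fraction metadata, gas series, qPCR standards and
#' measurements, clone libraries -- together with the ground truth.
#'
#' @param name `"gasfield"` or `"background"`.
#' @param seed integer seed; one generator seeded once, stages drawing from
#'   it in a fixed order.
#' @param cfg a [sim_config()].
#' @return list bundle; see Details. `ground_truth` lists each taxon's
#'   responder flag, atom fraction excess, and functional-gene carriage.
#' @export
sip_scenario <- function(name = c("gasfield", "background"), seed = 1L,
                         cfg = sim_config()) {
  name <- match.arg(name)
  set.seed(as.integer(seed))
  soil <- if (name == "gasfield") "G" else "NG"
  n_resp <- if (name == "gasfield") cfg$n_responders else 0L
  community <- sim_community(cfg, responders = n_resp)
  days <- as.numeric(names(cfg$incorporation))
  frac_days <- days[days > 0]
  gas_sim <- simulate_butane(cfg, community, days)
  frs <- fractions(cfg$fraction_indices, cfg$fraction_densities)

  count_blocks <- list()
  ## fractionated samples, both butane treatments
  for (d in frac_days) {
    bio <- gas_sim$biomass[, paste0("d", d)]
    for (trt in c("13C-BT", "12C-BT")) {
      excess <- if (trt == "13C-BT")
        community$atom_fraction_excess * cfg$incorporation[[as.character(d)]]
      else rep(0, nrow(community))
      grad <- simulate_gradient(community, bio, cfg, atom_excess = excess)
      cnt <- simulate_amplicon(grad$composition, cfg$depth)
      colnames(cnt) <- sample_id(soil, trt, d, cfg$fraction_indices)
      count_blocks[[length(count_blocks) + 1]] <- cnt
    }
  }
  ## unfractionated time courses: butane-fed, labeled, and no-butane control
  for (d in days) {
    bio <- gas_sim$biomass[, paste0("d", d)]
    comp_bt <- bio / sum(bio)
    comp_nb <- community$baseline_abundance / sum(community$baseline_abundance)
    for (trt in c("12C-BT", "13C-BT", "NB")) {
      p <- if (trt == "NB") comp_nb else comp_bt
      cnt <- matrix(rmultinom(1, cfg$depth, p)[, 1], ncol = 1,
                    dimnames = list(community$id, sample_id(soil, trt, d, NA)))
      count_blocks[[length(count_blocks) + 1]] <- cnt
    }
  }
  otu <- sip_otu(do.call(cbind, count_blocks))

  ## qPCR: standards (decimal dilutions over five orders) + measurements
  curves <- list(bmoX = standard_curve(slope = -3.40, intercept = 38.5),
                 `16S` = standard_curve(slope = -3.3219, intercept = 36.0))
  std_levels <- 10^(3:7)
  standards <- do.call(rbind, lapply(names(curves), function(g) {
    df <- simulate_qpcr(setNames(std_levels, sprintf("std_1e%d", 3:7)),
                        curves[[g]], cfg$cq_noise_sd, gene = g,
                        n_rep = cfg$qpcr_replicates)
    df$log10_copies <- rep(3:7, each = cfg$qpcr_replicates)
    df
  }))

  meas <- list()
  carrier <- community$carries_bmox
  for (d in days) {   # unfractionated, butane-fed treatment
    bio <- gas_sim$biomass[, paste0("d", d)]
    copies <- c(bmoX = sum(bio[carrier]) * cfg$bmox_copies_per_biomass,
                `16S` = sum(bio) * cfg$ssu_copies_per_biomass)
    for (g in names(curves)) {
      meas[[length(meas) + 1]] <- simulate_qpcr(
        setNames(copies[[g]], sample_id(soil, "12C-BT", d, NA)),
        curves[[g]], cfg$cq_noise_sd, gene = g, n_rep = cfg$qpcr_replicates)
    }
  }
  for (d in frac_days) {  # per-fraction functional gene + 16S, both treatments
    bio <- gas_sim$biomass[, paste0("d", d)]
    for (trt in c("13C-BT", "12C-BT")) {
      excess <- if (trt == "13C-BT")
        community$atom_fraction_excess * cfg$incorporation[[as.character(d)]]
      else rep(0, nrow(community))
      grad <- simulate_gradient(community, bio, cfg, atom_excess = excess)
      ids <- sample_id(soil, trt, d, cfg$fraction_indices)
      bx <- colSums(grad$mass[carrier, , drop = FALSE]) * cfg$bmox_copies_per_biomass
      ss <- colSums(grad$mass) * cfg$ssu_copies_per_biomass
      bx <- pmax(bx, 1)  # qPCR cannot see zero template; floor at 1 copy
      meas[[length(meas) + 1]] <- simulate_qpcr(setNames(bx, ids), curves$bmoX,
        cfg$cq_noise_sd, gene = "bmoX", n_rep = cfg$qpcr_replicates)
      meas[[length(meas) + 1]] <- simulate_qpcr(setNames(ss, ids), curves$`16S`,
        cfg$cq_noise_sd, gene = "16S", n_rep = cfg$qpcr_replicates)
    }
  }
  measurements <- do.call(rbind, meas)

  ## clone libraries: diverse before incubation, collapsed after
  clones <- list(
    d0 = simulate_clone_library(8, c(14, 10, 8, 6, 5, 1, 1, 1)),
    d12 = simulate_clone_library(2, c(35, 1)))

  ground_truth <- data.frame(
    taxon_id = community$id,
    responder = community$responder,
    atom_fraction_excess = community$atom_fraction_excess,
    carries_bmox = community$carries_bmox,
    stringsAsFactors = FALSE)

  list(name = name, seed = as.integer(seed), soil = soil, config = cfg,
       community = community, fractions = frs, otu = otu,
       gas = gas_sim$gas, gas_truth = gas_sim$truth,
       qpcr_standards = standards, qpcr_measurements = measurements,
       true_curves = curves, clones = clones, ground_truth = ground_truth)
}

#' Write a scenario bundle to disk in the pipeline's input formats
#'
#' Emits `otu.tsv`, `fractions.tsv`, `gas.csv`, `qpcr_standards.csv`,
#' `qpcr_measurements.csv`, `clones_d0.fasta`, `clones_d12.fasta`, and
#' `ground_truth.tsv` under `dir`.
#'
#' @param sc a [sip_scenario()] bundle.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(sc, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(sc$otu, file.path(dir, "otu.tsv"))
  write_fraction_metadata(sc$fractions, file.path(dir, "fractions.tsv"))
  write_gas_csv(sc$gas, file.path(dir, "gas.csv"))
  write_qpcr_csv(sc$qpcr_standards, file.path(dir, "qpcr_standards.csv"))
  write_qpcr_csv(sc$qpcr_measurements, file.path(dir, "qpcr_measurements.csv"))
  for (nm in names(sc$clones))
    Biostrings::writeXStringSet(sc$clones[[nm]]$dna,
                                file.path(dir, sprintf("clones_%s.fasta", nm)))
  write.table(sc$ground_truth, file.path(dir, "ground_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
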