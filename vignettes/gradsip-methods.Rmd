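---
title: "Models and methods behind gradsip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gradsip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gradsip)
```

# The problem

DNA stable-isotope probing (DNA-SIP) identifies which members of a soil
community assimilate a particular substrate. Microcosms are fed an
isotope-labeled gas (here, ^13^C-butane); organisms that grow on it build
^13^C into their DNA, which raises the DNA's buoyant density. After CsCl
density-gradient ultracentrifugation and fractionation, taxa whose 16S
amplicons move into the *heavy* fractions of the labeled treatment -- but
not of the parallel unlabeled (^12^C) treatment -- are called substrate
assimilators. Around this core inference sit supporting measurements:
headspace gas chromatography (is the substrate actually being consumed
biologically?), qPCR of a functional marker gene (here, the butane
monooxygenase alpha subunit, *bmoX*) both in bulk DNA and per fraction,
clone libraries of that gene (what is its sequence diversity?), and
community ordination (how does the substrate reshape the community?).

`gradsip` implements the full analysis chain and a forward simulator of the
experiment, so every stage can be exercised at desk scale with known ground
truth.

# Gas depletion accounting

Sealed microcosms lose substrate both abiotically (leakage, dissolution)
and biotically. Sterile controls isolate the abiotic loss, so
biodegradation at day $t$ is estimated on *residual fractions*
$R(t) = \bar{A}(t)/\bar{A}(0)$:

$$B(t) = 100\,\big(R_\mathrm{sterile}(t) - R_\mathrm{live}(t)\big).$$

Working on residual fractions makes the estimate unit-free and independent
of initial loadings. Treatment differences are assessed with the classical
pooled-variance two-tailed Student's t-test on per-replicate residual
fractions (each measurement row is one observation); `alpha` defaults to
0.05. A noise-induced negative $B$ is clamped to zero for reporting, with
the raw value retained as an attribute, since "no detectable
biodegradation" is the scientifically meaningful statement.

One subtlety is worth recording. Under any kinetic model in which abiotic
loss acts proportionally on the remaining pool while biology removes
substrate in parallel, the residual-difference estimator targets the *net*
biologically attributable depletion, not the gross carbon consumed:
substrate consumed by biology early in the incubation escapes later
abiotic loss, so gross consumption exceeds the residual difference by a
factor bounded by the abiotic survival probability. The simulator
therefore records both quantities (`net_biodegradation` and
`biotic_consumed_frac`), and the estimator is validated for unbiasedness
against the net quantity, which is its estimand.

# The density model and enrichment classification

The simulator (and the interpretation of profiles) rests on two standard
pieces of SIP physics:

- **GC relation.** Unlabeled DNA bands at
  $\rho = 1.660 + 0.098 \cdot \mathrm{GC}$ g/ml (intercept and slope
  configurable).
- **Labeling shift.** Full ^13^C labeling adds `delta_rho_max` = 0.036
  g/ml, scaled linearly by the atom fraction excess.

A taxon's DNA spreads as a Gaussian band (`band_sigma` = 0.003 g/ml) over
the fraction grid; the default analysis window is 9 fractions spanning
1.737 to 1.712 g/ml, matching collection fractions 4--12 of a 15-fraction
gradient. Fractions are indexed from the heavy end in collection order, but
buoyant density is the authoritative axis everywhere; indices are labels.

Two zone conventions coexist and both are kept, because the amplicon and
qPCR analyses historically use different thresholds: the amplicon
convention calls fractions heavy above 1.723 g/ml (no mid zone); the qPCR
convention uses light below 1.7285 and heavy above 1.7319 g/ml.

For each taxon $o$, day, and treatment, the density profile is the
within-fraction relative abundance $p_{o,f}$ (compositional, so fraction
sequencing depth cancels), and the heavy share is

$$H = \frac{\sum_{f:\,\rho_f > 1.723} p_{o,f}}{\sum_f p_{o,f}}.$$

The labeling score is $E = H_{13C} - H_{12C}$ per day, and a taxon is
called **labeled** when $E > \delta$ on at least $K$ days. Enrichment
criteria in the SIP literature are usually stated qualitatively (a taxon's
heavy-fraction abundance "clearly" exceeding the control's); this package
formalizes the rule with defaults $\delta = 0.05$ and $K = 2$, chosen once as
the smallest rule that (a) never calls a taxon from a single day's
compositional noise and (b) reproduces the day-12/14 call pattern on
simulated data. Both are configurable, and an optional copy-weighted mode
multiplies $p_{o,f}$ by per-fraction 16S copies where those exist; the
unweighted compositional view is the default because that is what
per-fraction amplicon data directly support.

# qPCR quantification

Standard curves are ordinary least squares of Cq on $\log_{10}$ copies
over a decimal dilution series (at least 3 levels; 5 orders of magnitude
in the study design), with efficiency $10^{-1/b} - 1$ and an $r^2 \ge 0.9$
acceptance bound. Quantification inverts the curve exactly. Replicates are
averaged on the linear copy scale -- not the Cq scale -- after a mild
outlier rule (drop at most one replicate farther than 0.5 cycles from the
median, never below two replicates). Functional-gene abundance is
normalized to 16S copies per day and reported as fold change over day 0,
which cancels extraction-efficiency differences between samples. The
per-fraction labeling-shift test compares replicate heavy-zone copy shares
(qPCR convention, > 1.7319 g/ml) between treatments with the same pooled
t-test; without replicates it degrades to a descriptive difference with
the p-value marked unavailable. Copy-number peaks break density ties
toward the heavier fraction, so a genuinely flat heavy plateau is read as
labeled rather than not.

# Clone libraries and protein families

Clone nucleotide sequences are translated in frame 1 (primer-anchored
amplicons give a fixed frame); trailing partial codons are dropped,
ambiguous codons become `X`, and clones with internal stops are flagged
and excluded from clustering by default. Pairwise protein identity is
computed on a Needleman-Wunsch global alignment (+1 match, 0 mismatch,
affine gaps) as identical columns over alignment columns, excluding
terminal-gap columns -- the convention that treats truncated clones fairly.
Families are formed by deterministic greedy centroid clustering in input
order: a sequence joins the first-founded centroid at or above the cutoff,
else founds a new family. This is the standard identity-threshold grouping
(cf. CD-HIT/UCLUST-style greedy clustering); it is deterministic, fast,
and order-dependence is documented and fixed rather than hidden.

Diversity is summarized with the bias-corrected Chao1
$S_{obs} + F_1(F_1-1)/(2(F_2+1))$ (always the bias-corrected form: it is
defined when no doubletons exist, where the classic form is not), Shannon
$H'$, Good's coverage $1 - F_1/N$, and analytic rarefaction
$E[S_n] = \sum_i [1 - \binom{N-n_i}{n}/\binom{N}{n}]$ computed on log
binomial coefficients.

**Why base-2 Shannon?** The clone-library summaries this package
reproduces include $H' = 3.80$ for a library of 21 families of 66 clones;
the natural-log maximum for 21 categories is $\ln 21 \approx 3.04$, so
such values can only be base-2 logarithms. Base 2 is therefore the
default, and it remains configurable.

# Ordination

Community ordination is classical correspondence analysis: the
standardized residual matrix $(p_{ij} - r_i c_j)/\sqrt{r_i c_j}$ is
decomposed by singular values; eigenvalues are squared singular values,
total inertia equals Pearson's chi-square over the grand total, and
percent variability per axis is the eigenvalue share of total inertia --
the only definition under which axis percentages are well-defined for this
method. Scores are principal coordinates (weighted mean square per axis
equals the eigenvalue). Detrending is by segments only: axis-2 scores are
replaced by residuals from segment-wise means within 26 equal-width axis-1
bins. The nonlinear axis rescaling of canonical detrended correspondence
analysis is deliberately omitted: its use here is descriptive, and
variance percentages come from the underlying correspondence analysis in
any case. Published axis percentages obtained from other software are not
expected to be reproduced exactly by any detrended method, and the package
makes no such claim.

# The simulator: what it emulates, and what it does not

`sip_scenario()` generates a complete study: community, gas kinetics,
isotope incorporation, gradient banding, multinomial amplicon counts,
qPCR observations, and clone libraries, with a `ground_truth` table naming
the planted responders. Two scenarios are built in: `"gasfield"` (three
responders among 100 taxa) and `"background"` (none; its functional-gene
pool exists but stays unlabeled).

Defaults were chosen once, as study conditions, and are not tuned:

- **Gas kinetics.** Abiotic rate $k = -\ln(0.86)/14$ per day (86% sterile
  residual at day 14); responders grow logistically ($r = 0.5$/d from an
  initial 0.01 each toward capacity 1) with yield-coupled drawdown
  (`yield` = 0.22), integrated by forward Euler at 0.1 d. This is the
  simplest mechanism producing a sigmoidal depletion of realistic
  magnitude (~16%, ~20%, ~21% net biodegradation at days 9, 12, 14).
  Measurements carry mean-one lognormal noise (sdlog 0.02, triplicate).
- **Community.** Background GC contents uniform on 0.35--0.58, so
  unlabeled DNA bands in the light half of the analyzed window, as
  observed for unlabeled communities in this kind of gradient; responder
  GC on 0.46--0.56 keeps labeled bands inside the window. Baseline
  abundances are lognormal with sdlog 0.6 -- deliberately modest spread,
  because the table models only the dominant (top-100) community, not the
  full rare biosphere.
- **Labeling.** Responders reach atom fraction excess 0.8; incorporation
  follows the schedule 0, 0.1, 0.3, 1, 1 at days 0, 6, 9, 12, 14,
  emulating labeling that becomes detectable from day 12, the onset
  pattern reported for this system.
- **Observation layers.** 20 000 reads per fraction sample; Cq noise 0.2
  cycles, triplicate; with all noise parameters at zero every observation
  is an exact deterministic function of the latent state.

Features of real data the simulator does **not** emulate: PCR and primer
bias, chimeras, read-level errors (counts are drawn directly), gradient
diffusion asymmetries, co-migrating high-GC unlabeled taxa above the heavy
threshold, multi-copy 16S heterogeneity, and compositional coupling
between treatments. Passing the recovery tests therefore shows the
inference is correct *under the stated generative model*, not that real
soils cannot produce false positives -- in particular, real communities
contain high-GC organisms whose unlabeled DNA reaches heavy densities;
the paired ^12^C treatment controls for this in expectation, but shallow
sequencing of such taxa remains the main false-positive risk in practice.

# Numerical choices and degenerate inputs

- Zero-variance t-test samples: equal means give $p = 1$, different means
  $p = 0$ with a `degenerate` flag, so downstream logic never sees `NaN`.
- Zero-total fractions are excluded from profiles with a warning; a taxon
  absent everywhere has heavy share 0 by convention.
- Bands falling entirely off the fraction grid at tiny `band_sigma` are
  assigned to the nearest fraction rather than dividing by zero.
- Correspondence analysis drops numerically null axes
  ($\lambda \le 10^{-12}$); an exactly independent table yields zero axes
  and zero inertia rather than noise axes.
- Rarefaction uses `lchoose` differences, stable to $N$ in the thousands.
- Greedy clustering ties (a sequence matching several centroids) resolve
  to the first-founded centroid; input order is part of the contract.
- One random generator is seeded once per run; scenario stages draw from
  it in a fixed order, so a seed fully determines every output byte.

# Problem sizes used in validation

The shipped test suite validates at the sizes the estimators are meant for:
100-taxon communities at 20 000 reads per fraction over 20 simulation
seeds for responder recovery and null calibration; 1000 random abundance
vectors against brute-force estimator oracles; 200 simulated microcosm
pairs for the unbiasedness of the biodegradation estimator; 100 noisy
dilution-series fits for standard-curve recovery; clone libraries of 36-87
sequences for the diversity reconstructions. The whole suite runs in about
a minute on one CPU.

# Known limitations

- No quantitative-SIP estimation of atom fraction excess from the density
  shift; classification is binary by design.
- Clustering is $O(n \cdot k)$ alignments (sequences x centroids); fine
  for clone libraries (hundreds), not meant for amplicon-scale data.
- The detrended ordination is descriptive; no significance testing of
  sample separation is provided.
- The gas model assumes well-mixed headspace and first-order abiotic loss;
  rate-constant fitting to real kinetic data is out of scope.

# A short worked example

```{r example, eval = FALSE}
sc <- sip_scenario("gasfield", seed = 1)
calls <- classify_labeled(sc$otu, sc$fractions)
calls[calls$labeled, ]
degradation_table(sc$gas)
```
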