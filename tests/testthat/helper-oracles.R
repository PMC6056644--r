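# Independent brute-force oracles, kept deliberately naive and separate
# from the package implementations they check.

oracle_chao1 <- function(sizes) {
  s <- 0L; f1 <- 0L; f2 <- 0L
  for (n in sizes) {
    if (n > 0) s <- s + 1L
    if (n == 1) f1 <- f1 + 1L
    if (n == 2) f2 <- f2 + 1L
  }
  s + f1 * (f1 - 1) / (2 * (f2 + 1))
}

oracle_shannon <- function(sizes, base = 2) {
  sizes <- sizes[sizes > 0]
  total <- sum(sizes)
  h <- 0
  for (n in sizes) h <- h - (n / total) * (log(n / total) / log(base))
  h
}

oracle_coverage <- function(sizes) {
  sizes <- sizes[sizes > 0]
  f1 <- 0L
  for (n in sizes) if (n == 1) f1 <- f1 + 1L
  1 - f1 / sum(sizes)
}

# Expected richness by averaging over random subsamples without replacement.
oracle_rarefaction_mc <- function(sizes, n, reps = 10000) {
  pool <- rep(seq_along(sizes), sizes)
  draws <- replicate(reps, length(unique(sample(pool, n))))
  list(mean = mean(draws), se = sd(draws) / sqrt(reps))
}

# Correspondence-analysis eigenvalues via an explicit eigen-decomposition
# of the cross-product of the standardized residual matrix.
oracle_ca_eigenvalues <- function(x) {
  N <- sum(x)
  P <- x / N
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  ev <- eigen(crossprod(S), symmetric = TRUE)$values
  ev[ev > 1e-12]
}

# A random count table with no all-zero margin.
random_count_table <- function(nr = 10, nc = 8, lambda = 6) {
  repeat {
    x <- matrix(rpois(nr * nc, lambda), nr, nc)
    if (all(rowSums(x) > 0) && all(colSums(x) > 0)) return(x)
  }
}

# Small fractionated OTU table built directly from a count array:
# counts[taxon, fraction] per treatment/day.
build_frac_otu <- function(counts13, counts12, frs, day = 12, soil = "G") {
  stopifnot(ncol(counts13) == nrow(frs))
  ids13 <- sample_id(soil, "13C-BT", day, frs$fraction_index)
  ids12 <- sample_id(soil, "12C-BT", day, frs$fraction_index)
  m <- cbind(counts13, counts12)
  colnames(m) <- c(ids13, ids12)
  sip_otu(m)
}
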