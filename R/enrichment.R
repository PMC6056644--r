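#' Keep the most abundant taxa
#'
#' Ranks taxa by summed relative abundance across the unfractionated
#' samples (the community before density separation) and keeps the top `k`;
#' ties break by taxon id. If the table holds no unfractionated samples,
#' all samples are used with a warning.
#'
#' @param otu a [sip_otu()] table.
#' @param k number of taxa to keep (default 100).
#' @return a `sip_otu` restricted to the selected taxa, in rank order.
#' @export
top_k_otus <- function(otu, k = 100L) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  unf <- is.na(otu$samples$fraction)
  if (!any(unf)) {
    warning("no unfractionated samples; ranking over all samples")
    unf <- rep(TRUE, ncol(otu$counts))
  }
  cnt <- otu$counts[, unf, drop = FALSE]
  tot <- colSums(cnt)
  rel <- sweep(cnt, 2, ifelse(tot > 0, tot, 1), "/")
  score <- rowSums(rel)
  if (k >= nrow(cnt)) {
    if (k > nrow(cnt)) warning("k exceeds taxon count; returning all taxa")
    k <- nrow(cnt)
  }
  ord <- order(-score, rownames(cnt))
  keep <- ord[seq_len(k)]
  otu[keep, , drop = FALSE]
}

#' Buoyant-density profile of one taxon
#'
#' Relative abundance of the taxon within each gradient fraction of a given
#' treatment and day, plotted against buoyant density. Fractions with zero
#' total counts are excluded with a warning.
#'
#' @param otu a [sip_otu()] table containing fractionated samples.
#' @param frs fraction metadata from [fractions()].
#' @param taxon taxon id (must exist in the table).
#' @param treatment,day,soil the sample key to profile.
#' @return data.frame of class `density_profile`: `fraction_index`,
#'   `buoyant_density`, `rel_abundance`, sorted by ascending density, with
#'   `taxon`, `treatment`, `day` attributes.
#' @export
density_profile <- function(otu, frs, taxon, treatment, day, soil = "G") {
  if (!taxon %in% rownames(otu$counts)) stop("taxon not in table: ", taxon)
  s <- otu$samples
  sel <- which(s$soil == soil & s$treatment == treatment & s$day == day &
               !is.na(s$fraction))
  if (length(sel) == 0)
    stop("no fractionated samples for ", soil, "/", treatment, " day ", day)
  idx <- s$fraction[sel]
  bd <- frs$buoyant_density[match(idx, frs$fraction_index)]
  if (anyNA(bd)) stop("fraction index missing from metadata: ",
                      paste(idx[is.na(bd)], collapse = ", "))
  cnt <- otu$counts[, sel, drop = FALSE]
  tot <- colSums(cnt)
  if (any(tot == 0)) {
    warning("excluding fraction(s) with zero total counts: ",
            paste(idx[tot == 0], collapse = ", "))
    keep <- tot > 0
    cnt <- cnt[, keep, drop = FALSE]; idx <- idx[keep]; bd <- bd[keep]
    tot <- tot[keep]
  }
  p <- as.numeric(cnt[taxon, ]) / tot
  o <- order(bd)
  structure(data.frame(fraction_index = idx[o], buoyant_density = bd[o],
                       rel_abundance = p[o]),
            taxon = taxon, treatment = treatment, day = day,
            class = c("density_profile", "data.frame"))
}

#' Heavy-fraction share of a density profile
#'
#' Proportion of the taxon's summed fractional relative abundance lying in
#' fractions denser than `threshold`; 0 when the taxon is absent from every
#' fraction. Invariant to rescaling any fraction's counts by a common
#' factor, since profiles are compositional within fractions.
#'
#' @param profile a [density_profile()] (or data.frame with
#'   `buoyant_density` and `rel_abundance`).
#' @param threshold heavy threshold in g/ml (default 1.723, the amplicon
#'   convention).
#' @return share in `[0, 1]`.
#' @export
heavy_share <- function(profile, threshold = 1.723) {
  if (nrow(profile) == 0) stop("empty profile")
  tot <- sum(profile$rel_abundance)
  if (tot == 0) return(0)
  sum(profile$rel_abundance[profile$buoyant_density > threshold]) / tot
}

#' Classify isotopically labeled taxa by heavy-fraction enrichment
#'
#' For every taxon and incubation day, the heavy-fraction share is computed
#' in the labeled (13C) and unlabeled (12C) treatments and differenced:
#' `E = H13 - H12`. A taxon is called labeled when `E > delta` on at least
#' `min_days` days -- never from a single day under the defaults, which
#' guards against one-off compositional noise.
#'
#' @param otu a [sip_otu()] with fractionated samples for both treatments.
#' @param frs fraction metadata.
#' @param soil soil label to analyze.
#' @param label_treatment,ref_treatment treatments to compare (13C vs 12C).
#' @param threshold heavy density threshold in g/ml.
#' @param delta minimum heavy-share difference counting as enrichment.
#' @param min_days minimum number of supporting days.
#' @param taxa taxa to classify (default: all rows).
#' @return data.frame of class `enrichment_calls`, one row per taxon:
#'   `taxon_id`, `labeled`, `n_support`, `support_days` (comma-separated),
#'   `max_score`; per-day scores in the `scores` attribute (long data.frame
#'   `taxon_id`, `day`, `H13`, `H12`, `E`).
#' @export
classify_labeled <- function(otu, frs, soil = "G",
                             label_treatment = "13C-BT",
                             ref_treatment = "12C-BT",
                             threshold = 1.723, delta = 0.05,
                             min_days = 2L, taxa = rownames(otu$counts)) {
  s <- otu$samples
  d13 <- unique(s$day[s$soil == soil & s$treatment == label_treatment &
                      !is.na(s$fraction)])
  d12 <- unique(s$day[s$soil == soil & s$treatment == ref_treatment &
                      !is.na(s$fraction)])
  days <- sort(intersect(d13, d12))
  if (length(days) == 0)
    stop("no common fractionated days between ", label_treatment, " and ",
         ref_treatment)
  share_matrix <- function(trt) {
    out <- matrix(NA_real_, length(taxa), length(days),
                  dimnames = list(taxa, paste0("d", days)))
    for (j in seq_along(days)) {
      sel <- which(s$soil == soil & s$treatment == trt & s$day == days[j] &
                   !is.na(s$fraction))
      idx <- s$fraction[sel]
      bd <- frs$buoyant_density[match(idx, frs$fraction_index)]
      cnt <- otu$counts[taxa, sel, drop = FALSE]
      tot <- colSums(otu$counts[, sel, drop = FALSE])
      keep <- tot > 0
      p <- sweep(cnt[, keep, drop = FALSE], 2, tot[keep], "/")
      heavy <- bd[keep] > threshold
      rs <- rowSums(p)
      out[, j] <- ifelse(rs > 0, rowSums(p[, heavy, drop = FALSE]) / rs, 0)
    }
    out
  }
  H13 <- share_matrix(label_treatment)
  H12 <- share_matrix(ref_treatment)
  E <- H13 - H12
  support <- E > delta
  n_support <- rowSums(support)
  calls <- data.frame(
    taxon_id = taxa,
    labeled = n_support >= min_days,
    n_support = n_support,
    support_days = vapply(seq_along(taxa), function(i)
      paste(days[support[i, ]], collapse = ","), character(1)),
    max_score = apply(E, 1, max),
    stringsAsFactors = FALSE)
  scores <- data.frame(
    taxon_id = rep(taxa, times = length(days)),
    day = rep(days, each = length(taxa)),
    H13 = as.vector(H13), H12 = as.vector(H12), E = as.vector(E))
  structure(calls, scores = scores, delta = delta, min_days = min_days,
            class = c("enrichment_calls", "data.frame"))
}

#' @export
print.enrichment_calls <- function(x, ...) {
  lab <- x$taxon_id[x$labeled]
  cat(sprintf("enrichment_calls: %d taxa, %d labeled", nrow(x), length(lab)))
  if (length(lab)) cat(": ", paste(lab, collapse = ", "))
  cat("\n")
  NextMethod()
}
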