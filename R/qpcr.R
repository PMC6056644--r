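#' qPCR standard curve
#'
#' `Cq = intercept + slope * log10(copies)`; amplification efficiency
#' `E = 10^(-1/slope) - 1` (1.0 for perfect doubling, slope -3.3219).
#'
#' @param slope cycles per log10 copies (negative for a valid curve).
#' @param intercept cycles at 1 copy.
#' @param r_squared coefficient of determination of the fit, if known.
#' @return object of class `standard_curve`.
#' @export
standard_curve <- function(slope, intercept, r_squared = NA_real_) {
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared,
                 efficiency = 10^(-1 / slope) - 1),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve: Cq = %.4f %+.4f * log10(copies); E = %.3f",
              x$intercept, x$slope, x$efficiency))
  if (!is.na(x$r_squared)) cat(sprintf("; r^2 = %.4f", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Fit a qPCR standard curve by ordinary least squares
#'
#' Regresses quantification cycles on log10 template copies over a dilution
#' series (at least 3 distinct levels, typically a decimal series over five
#' orders of magnitude).
#'
#' @param log10_copies log10 template copy numbers.
#' @param cq observed quantification cycles.
#' @param min_r_squared curves below this r-squared are rejected.
#' @return a [standard_curve()].
#' @export
fit_standard_curve <- function(log10_copies, cq, min_r_squared = 0.9) {
  if (length(unique(log10_copies)) < 3)
    stop("need at least 3 distinct dilution levels")
  fit <- lm(cq ~ log10_copies)
  b <- unname(coef(fit)[2]); a <- unname(coef(fit)[1])
  if (b >= 0) stop("positive slope: dilution series appears inverted")
  ## summary.lm warns on exactly collinear (noise-free) dilution series
  r2 <- suppressWarnings(summary(fit)$r.squared)
  if (r2 < min_r_squared)
    stop(sprintf("standard curve r^2 = %.3f below the %.2f acceptance bound",
                 r2, min_r_squared))
  standard_curve(slope = b, intercept = a, r_squared = r2)
}

#' Absolute copy number from a quantification cycle
#'
#' Exact inverse of the curve: `copies = 10^((cq - intercept)/slope)`.
#'
#' @param cq quantification cycles.
#' @param curve a [standard_curve()].
#' @return copy numbers.
#' @export
quantify_copies <- function(cq, curve) {
  10^((cq - curve$intercept) / curve$slope)
}

#' Average replicate Cq measurements into per-sample copy numbers
#'
#' Replicates are converted to copies through the standard curve and
#' averaged on the linear (copies) scale. A mild outlier rule is applied
#' first: a single replicate lying more than `outlier_cycles` from the
#' replicate median Cq is dropped, never reducing a sample below 2
#' replicates.
#'
#' @param measurements data.frame with `sample_id`, `gene`, `replicate`,
#'   and `cq` (or `copies`, used as-is).
#' @param curve a [standard_curve()] for the gene.
#' @param gene gene to quantify.
#' @param outlier_cycles replicate rejection distance in cycles.
#' @return data.frame `sample_id`, `gene`, `copies` (mean), `cv`
#'   (coefficient of variation), `n_replicates`.
#' @export
gene_quant <- function(measurements, curve, gene, outlier_cycles = 0.5) {
  m <- measurements[measurements$gene == gene, , drop = FALSE]
  if (nrow(m) == 0) stop("no measurements for gene ", gene)
  out <- lapply(split(m, m$sample_id), function(g) {
    if ("cq" %in% names(g) && !all(is.na(g$cq))) {
      cqs <- g$cq
      if (length(cqs) > 2) {
        dist <- abs(cqs - median(cqs))
        worst <- which.max(dist)
        if (dist[worst] > outlier_cycles) cqs <- cqs[-worst]
      }
      copies <- quantify_copies(cqs, curve)
    } else {
      copies <- g$copies
    }
    if (length(copies) < 2)
      warning("fewer than 2 replicates for sample ", g$sample_id[1])
    data.frame(sample_id = g$sample_id[1], gene = gene,
               copies = mean(copies),
               cv = sd(copies) / mean(copies),
               n_replicates = length(copies),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Functional-gene to 16S ratio and fold change over incubation
#'
#' Normalizes the functional-gene copies to total 16S copies per day and
#' expresses each day's ratio as a fold change over day 0 (fold 1 at day 0
#' by definition). Invariant to any common extraction-efficiency factor.
#'
#' @param target data.frame `day`, `copies` for the functional gene
#'   (unfractionated extracts).
#' @param reference data.frame `day`, `copies` for the 16S gene.
#' @return data.frame `day`, `ratio`, `fold`.
#' @export
normalized_fold <- function(target, reference) {
  days <- sort(intersect(target$day, reference$day))
  if (!0 %in% days) stop("day 0 needed in both genes to define fold changes")
  ratio <- vapply(days, function(d)
    sum(target$copies[target$day == d]) / sum(reference$copies[reference$day == d]),
    numeric(1))
  if (!is.finite(ratio[days == 0]) || ratio[days == 0] == 0)
    stop("zero or undefined day-0 ratio")
  data.frame(day = days, ratio = ratio, fold = ratio / ratio[days == 0])
}

#' Buoyant density of the copy-number peak
#'
#' Density of the fraction with the maximal copy number; exact ties break
#' toward the heavier fraction.
#'
#' @param buoyant_density fraction densities (g/ml).
#' @param copies copy numbers per fraction (not all zero).
#' @return density of the peak fraction (g/ml).
#' @export
peak_density <- function(buoyant_density, copies) {
  if (length(buoyant_density) < 2) stop("need at least 2 fractions")
  if (all(copies == 0)) stop("all-zero copy numbers have no peak")
  top <- which(copies == max(copies))
  buoyant_density[top[which.max(buoyant_density[top])]]
}

#' Test for an isotope-labeling shift of a gene into heavy fractions
#'
#' Computes the heavy-zone copy share per replicate in the labeled and
#' unlabeled treatments and compares them with the pooled-variance
#' Student's t-test. Without replicate structure the difference is
#' reported descriptively with the p-value marked unavailable.
#'
#' @param profile13,profile12 data.frames `buoyant_density`, `copies`, and
#'   optionally `replicate`, for the labeled and unlabeled treatments.
#' @param heavy_min heavy-zone threshold in g/ml (qPCR convention, 1.7319).
#' @param alpha significance level.
#' @return list `share13`, `share12`, `difference`, `t`, `df`, `p`,
#'   `significant` (p and t are `NA` without replicates).
#' @export
labeling_shift_test <- function(profile13, profile12, heavy_min = 1.7319,
                                alpha = 0.05) {
  share <- function(df) {
    heavy <- df$buoyant_density > heavy_min
    if ("replicate" %in% names(df) && length(unique(df$replicate)) >= 2) {
      vapply(split(df, df$replicate),
             function(g) sum(g$copies[g$buoyant_density > heavy_min]) / sum(g$copies),
             numeric(1))
    } else {
      sum(df$copies[heavy]) / sum(df$copies)
    }
  }
  s13 <- share(profile13); s12 <- share(profile12)
  if (length(s13) >= 2 && length(s12) >= 2) {
    tt <- students_t_test(s13, s12)
    list(share13 = mean(s13), share12 = mean(s12),
         difference = mean(s13) - mean(s12),
         t = tt$t, df = tt$df, p = tt$p, significant = tt$p < alpha)
  } else {
    list(share13 = mean(s13), share12 = mean(s12),
         difference = mean(s13) - mean(s12),
         t = NA_real_, df = NA_real_, p = NA_real_, significant = NA)
  }
}
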