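#' Community matrix of unfractionated samples
#'
#' Extracts a samples x taxa count matrix from a [sip_otu()] table, by
#' default restricted to unfractionated (whole-community) samples, the
#' input ordination expects.
#'
#' @param otu a [sip_otu()].
#' @param unfractionated_only keep only unfractionated samples.
#' @return samples x taxa integer matrix.
#' @export
community_matrix <- function(otu, unfractionated_only = TRUE) {
  sel <- if (unfractionated_only) is.na(otu$samples$fraction)
         else rep(TRUE, ncol(otu$counts))
  if (!any(sel)) stop("no unfractionated samples in the table")
  t(otu$counts[, sel, drop = FALSE])
}

#' Correspondence analysis of a count table
#'
#' Chi-square-distance ordination: the standardized residual matrix
#' `(p_ij - r_i c_j) / sqrt(r_i c_j)` is decomposed by singular values.
#' Eigenvalues are squared singular values; total inertia equals the
#' Pearson chi-square statistic divided by the grand total; percent
#' variability per axis is the eigenvalue's share of total inertia. Scores
#' are in principal coordinates, scaled so the weighted mean square of each
#' axis equals its eigenvalue.
#'
#' @param x non-negative count matrix, samples as rows; no all-zero row or
#'   column.
#' @param n_axes number of axes to retain in the score matrices (default:
#'   all non-null axes).
#' @return object of class `sip_ca`: `eigenvalues` (all non-null, in
#'   descending order), `total_inertia`, `percent` (per axis, summing to
#'   100), `sample_scores`, `taxon_scores` (rows weighted by margins),
#'   `row_masses`, `col_masses`, `detrended = FALSE`.
#' @export
correspondence_analysis <- function(x, n_axes = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative")
  zr <- rowSums(x) == 0; zc <- colSums(x) == 0
  if (any(zr)) stop("all-zero row(s): ",
                    paste(rownames(x)[zr] %||% which(zr), collapse = ", "))
  if (any(zc)) stop("all-zero column(s): ",
                    paste(colnames(x)[zc] %||% which(zc), collapse = ", "))
  N <- sum(x)
  P <- x / N
  r <- rowSums(P); cc <- colSums(P)
  S <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  sv <- svd(S)
  tol <- max(dim(x)) * .Machine$double.eps * max(sv$d, 1)
  keep <- which(sv$d > sqrt(tol) & sv$d^2 > 1e-12)
  lambda <- sv$d[keep]^2
  inertia <- sum(S^2)
  if (length(keep) == 0) {
    return(structure(list(eigenvalues = numeric(0), total_inertia = inertia,
                          percent = numeric(0),
                          sample_scores = matrix(0, nrow(x), 0,
                                                 dimnames = list(rownames(x), NULL)),
                          taxon_scores = matrix(0, ncol(x), 0,
                                                dimnames = list(colnames(x), NULL)),
                          row_masses = r, col_masses = cc, detrended = FALSE),
                     class = "sip_ca"))
  }
  k_show <- if (is.null(n_axes)) length(keep) else min(n_axes, length(keep))
  F <- sweep(sv$u[, keep, drop = FALSE], 1, sqrt(r), "/") %*% diag(sv$d[keep],
                                                                   length(keep))
  G <- sweep(sv$v[, keep, drop = FALSE], 1, sqrt(cc), "/") %*% diag(sv$d[keep],
                                                                    length(keep))
  dimnames(F) <- list(rownames(x), paste0("CA", seq_along(keep)))
  dimnames(G) <- list(colnames(x), paste0("CA", seq_along(keep)))
  structure(list(eigenvalues = lambda, total_inertia = inertia,
                 percent = 100 * lambda / sum(lambda),
                 sample_scores = F[, seq_len(k_show), drop = FALSE],
                 taxon_scores = G[, seq_len(k_show), drop = FALSE],
                 row_masses = r, col_masses = cc, detrended = FALSE),
            class = "sip_ca")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sip_ca <- function(x, ...) {
  cat(sprintf("%scorrespondence analysis: %d axes, total inertia %.4f\n",
              if (x$detrended) "detrended " else "", length(x$eigenvalues),
              x$total_inertia))
  if (length(x$eigenvalues)) {
    k <- min(4, length(x$eigenvalues))
    cat(sprintf("  axis %d: lambda = %.4f (%.2f%%)\n",
                seq_len(k), x$eigenvalues[seq_len(k)], x$percent[seq_len(k)]))
  }
  invisible(x)
}

#' Detrend axis 2 by segment-wise means of axis 1
#'
#' Removes the arch artifact descriptively: axis-2 sample scores are
#' replaced by their residuals from segment means computed within
#' `n_segments` equal-width bins of axis 1. Eigenvalues and percent
#' variability of the underlying correspondence analysis are retained; no
#' nonlinear axis rescaling is applied.
#'
#' @param result a [correspondence_analysis()] result with >= 2 axes.
#' @param n_segments number of axis-1 bins (>= 2; 26 is the conventional
#'   default).
#' @return the result with detrended axis-2 sample scores and
#'   `detrended = TRUE`.
#' @export
detrend_by_segments <- function(result, n_segments = 26L) {
  n_segments <- as.integer(n_segments)
  if (n_segments < 2) stop("n_segments must be >= 2")
  if (ncol(result$sample_scores) < 2) stop("need at least 2 computed axes")
  if (nrow(result$sample_scores) < 2) stop("need at least 2 samples")
  ax1 <- result$sample_scores[, 1]
  ax2 <- result$sample_scores[, 2]
  rng <- range(ax1)
  breaks <- if (diff(rng) == 0) c(rng[1] - 0.5, rng[2] + 0.5)
            else seq(rng[1], rng[2], length.out = n_segments + 1)
  bin <- cut(ax1, breaks = breaks, include.lowest = TRUE)
  seg_mean <- tapply(ax2, bin, mean)
  result$sample_scores[, 2] <- ax2 - as.numeric(seg_mean[bin])
  result$detrended <- TRUE
  result
}

#' Aggregate taxon relative abundances into higher groups
#'
#' Sums per-sample relative abundances over a taxon-to-group mapping
#' (e.g. phylum or proteobacterial class); unmapped taxa pool into
#' `"unassigned"`. Optionally keeps only the `top_n` groups by mean
#' abundance, pooling the remainder into `"other"`.
#'
#' @param otu a [sip_otu()].
#' @param mapping data.frame with columns `taxon_id`, `group` (must cover
#'   at least one taxon of the table).
#' @param top_n optional number of groups to keep.
#' @return groups x samples matrix of relative abundances (columns sum to
#'   at most 1; exactly 1 when every taxon maps).
#' @export
aggregate_groups <- function(otu, mapping, top_n = NULL) {
  if (is.null(mapping) || nrow(mapping) == 0) stop("empty taxon-to-group mapping")
  if (!all(c("taxon_id", "group") %in% names(mapping)))
    stop("mapping needs columns taxon_id, group")
  grp <- mapping$group[match(rownames(otu$counts), mapping$taxon_id)]
  if (all(is.na(grp))) stop("mapping covers no taxon in the table")
  grp[is.na(grp)] <- "unassigned"
  tot <- colSums(otu$counts)
  rel <- sweep(otu$counts, 2, ifelse(tot > 0, tot, 1), "/")
  agg <- rowsum(rel, group = grp)
  if (!is.null(top_n) && top_n < nrow(agg)) {
    ord <- order(-rowMeans(agg))
    keep <- rownames(agg)[ord[seq_len(top_n)]]
    rest <- colSums(agg[!rownames(agg) %in% keep, , drop = FALSE])
    agg <- rbind(agg[keep, , drop = FALSE], other = rest)
  }
  agg
}
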