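#' Read clone nucleotide sequences from FASTA
#'
#' @param path FASTA file of nucleotide clone sequences.
#' @return a [Biostrings::DNAStringSet].
#' @export
read_clone_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("no sequences in ", path)
  if (anyDuplicated(names(x))) stop("duplicate clone ids in ", path)
  x
}

#' Deduce protein sequences from clone nucleotides
#'
#' Standard genetic code in the chosen frame; the trailing partial codon is
#' dropped; ambiguous codons translate to `X`; stops render as `*`. Clones
#' whose protein carries an internal stop are flagged (and excluded from
#' clustering by default downstream).
#'
#' @param dna a [Biostrings::DNAStringSet] (or character vector).
#' @param frame reading frame 1, 2, or 3.
#' @return a [Biostrings::AAStringSet] with a logical `internal_stop`
#'   attribute.
#' @export
translate_clones <- function(dna, frame = 1L) {
  if (!inherits(dna, "DNAStringSet")) dna <- Biostrings::DNAStringSet(dna)
  frame <- as.integer(frame)
  if (!frame %in% 1:3) stop("frame must be 1, 2, or 3")
  w <- Biostrings::width(dna)
  if (any(w - (frame - 1) < 3))
    stop("sequence(s) shorter than one codon in frame ", frame, ": ",
         paste(names(dna)[w - (frame - 1) < 3], collapse = ", "))
  end <- frame - 1 + ((w - (frame - 1)) %/% 3L) * 3L
  trimmed <- Biostrings::subseq(dna, start = frame, end = end)
  aa <- Biostrings::translate(trimmed, if.fuzzy.codon = "solve")
  ch <- as.character(aa)
  internal_stop <- grepl("\\*.", ch)  # a stop before the final residue
  attr(aa, "internal_stop") <- setNames(internal_stop, names(aa))
  aa
}

## Substitution matrix: +1 match, 0 mismatch over the amino-acid alphabet.
.aa_id_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      letters <- setdiff(Biostrings::AA_ALPHABET, c("-", "+", "."))
      m <- matrix(0, length(letters), length(letters),
                  dimnames = list(letters, letters))
      diag(m) <- 1
      cache <<- m
    }
    cache
  }
})

## Identity of one query against many targets in a single vectorized
## alignment call; identical pairs shortcut the alignment.
.identity_vec <- function(query, targets) {
  out <- numeric(length(targets))
  same <- targets == query
  out[same] <- 1
  todo <- which(!same)
  if (length(todo)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(targets[todo]), Biostrings::AAString(query),
      type = "global", substitutionMatrix = .aa_id_matrix(),
      gapOpening = 2, gapExtension = 0.5)
    a <- as.character(Biostrings::pattern(aln))
    b <- as.character(Biostrings::subject(aln))
    for (i in seq_along(todo)) {
      av <- strsplit(a[i], "")[[1]]; bv <- strsplit(b[i], "")[[1]]
      res <- av != "-" & bv != "-"
      cols <- min(which(res)):max(which(res))   # trim terminal gaps
      out[todo[i]] <- sum(av[cols] == bv[cols] & res[cols]) / length(cols)
    }
  }
  out
}

#' Pairwise protein identity from global alignment
#'
#' Needleman-Wunsch global alignment under +1 match / 0 mismatch scoring
#' with affine gaps, then identity = identical columns / alignment columns,
#' excluding terminal-gap columns. Symmetric by construction.
#'
#' @param p,q protein sequences (character or `AAString`).
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(p, q) {
  p <- as.character(p); q <- as.character(q)
  if (nchar(p) == 0 || nchar(q) == 0) stop("empty protein sequence")
  .identity_vec(q, p)
}

#' Cluster proteins into operational protein families (OPFs)
#'
#' Deterministic greedy centroid clustering: sequences are processed in
#' input order; each joins the first-founded centroid with identity at or
#' above the cutoff, otherwise founds a new family. Sequences flagged with
#' internal stops are excluded by default.
#'
#' @param proteins an `AAStringSet` (e.g. from [translate_clones()]) or
#'   named character vector.
#' @param cutoff identity cutoff in (0, 1] (the study standard is 0.87).
#' @param log_base Shannon log base for the diversity summary.
#' @param drop_internal_stops exclude flagged pseudogene-like clones.
#' @return object of class `opf_clustering`: `cutoff`, `assignments` (named
#'   integer family per clone), `sizes`, `excluded` (dropped clone ids),
#'   and the diversity summary fields `N`, `S_obs`, `F1`, `F2`, `chao1`,
#'   `shannon`, `coverage`.
#' @export
cluster_opfs <- function(proteins, cutoff = 0.87, log_base = 2,
                         drop_internal_stops = TRUE) {
  if (!(cutoff > 0 && cutoff <= 1)) stop("cutoff must lie in (0, 1]")
  seqs <- setNames(as.character(proteins), names(proteins))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
  excluded <- character(0)
  istop <- attr(proteins, "internal_stop")
  if (drop_internal_stops && !is.null(istop) && any(istop)) {
    excluded <- names(seqs)[istop]
    seqs <- seqs[!istop]
  }
  centroids <- character(0)
  assignment <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    hit <- 0L
    if (length(centroids)) {
      ids <- .identity_vec(seqs[i], centroids)
      ok <- which(ids >= cutoff)
      if (length(ok)) hit <- ok[1]   # first-founded centroid wins
    }
    if (hit == 0L) {
      centroids <- c(centroids, seqs[i])
      hit <- length(centroids)
    }
    assignment[i] <- hit
  }
  names(assignment) <- names(seqs)
  sizes <- as.integer(table(factor(assignment, levels = seq_along(centroids))))
  structure(c(list(cutoff = cutoff, assignments = assignment, sizes = sizes,
                   excluded = excluded, log_base = log_base),
              diversity_summary(sizes, base = log_base)),
            class = "opf_clustering")
}

#' @export
print.opf_clustering <- function(x, ...) {
  cat(sprintf(paste0("opf_clustering at %.0f%% identity: N = %d clones, ",
                     "%d families, Chao1 = %.1f, H' = %.2f, C = %.2f\n"),
              100 * x$cutoff, x$N, x$S_obs, x$chao1, x$shannon, x$coverage))
  invisible(x)
}

#' Alpha-diversity summary of a family-size vector
#'
#' @param sizes positive integer family sizes.
#' @param base Shannon log base.
#' @return list `N`, `S_obs`, `F1` (singletons), `F2` (doubletons),
#'   `chao1`, `shannon`, `coverage`.
#' @export
diversity_summary <- function(sizes, base = 2) {
  sizes <- as.integer(sizes)
  sizes <- sizes[sizes > 0]
  list(N = sum(sizes), S_obs = length(sizes),
       F1 = sum(sizes == 1L), F2 = sum(sizes == 2L),
       chao1 = chao1(sizes), shannon = shannon_index(sizes, base),
       coverage = goods_coverage(sizes))
}

#' Bias-corrected Chao1 richness estimator
#'
#' `S_obs + F1*(F1 - 1) / (2*(F2 + 1))`, defined even when no doubletons
#' are observed.
#'
#' @param sizes positive integer family sizes.
#' @return estimated richness.
#' @export
chao1 <- function(sizes) {
  sizes <- sizes[sizes > 0]
  if (length(sizes) == 0) stop("empty abundance vector")
  f1 <- sum(sizes == 1); f2 <- sum(sizes == 2)
  length(sizes) + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity index
#'
#' `H' = -sum (n_i/N) log_base(n_i/N)`. Base 2 is the package default (see
#' the methods vignette for why).
#'
#' @param sizes positive integer family sizes.
#' @param base logarithm base (> 1).
#' @return the index (0 for a single family).
#' @export
shannon_index <- function(sizes, base = 2) {
  sizes <- sizes[sizes > 0]
  if (length(sizes) == 0) stop("empty abundance vector")
  if (base <= 1) stop("base must exceed 1")
  p <- sizes / sum(sizes)
  -sum(p * log(p, base = base))
}

#' Good's coverage estimator
#'
#' `C = 1 - F1/N`: estimated probability that the next sampled clone
#' belongs to an already-observed family.
#'
#' @param sizes positive integer family sizes.
#' @return coverage in `[0, 1]`.
#' @export
goods_coverage <- function(sizes) {
  sizes <- sizes[sizes > 0]
  if (length(sizes) == 0) stop("empty abundance vector")
  1 - sum(sizes == 1) / sum(sizes)
}

#' Analytic rarefaction (expected richness in a subsample)
#'
#' `E[S_n] = sum_i [1 - C(N - n_i, n) / C(N, n)]` with the binomial
#' coefficient taken as 0 when `N - n_i < n`; computed on log binomials for
#' stability.
#'
#' @param sizes positive integer family sizes.
#' @param grid subsample sizes, each between 1 and `N = sum(sizes)`.
#' @return data.frame `n`, `expected_richness`.
#' @export
rarefaction_expected <- function(sizes, grid) {
  sizes <- sizes[sizes > 0]
  N <- sum(sizes)
  grid <- as.integer(grid)
  if (any(grid < 1) || any(grid > N))
    stop("subsample sizes must lie between 1 and N = ", N)
  es <- vapply(grid, function(n) {
    keep_absent <- (N - sizes) >= n
    absent <- numeric(length(sizes))
    absent[keep_absent] <- exp(lchoose(N - sizes[keep_absent], n) - lchoose(N, n))
    sum(1 - absent)
  }, numeric(1))
  data.frame(n = grid, expected_richness = es)
}

#' Cluster at several identity cutoffs and summarize each
#'
#' @param proteins as in [cluster_opfs()].
#' @param cutoffs identity cutoffs (default 0.83, 0.87, 0.90, 0.95).
#' @param log_base Shannon log base.
#' @return data.frame, one row per cutoff: `cutoff`, `N`, `S_obs`, `F1`,
#'   `F2`, `chao1`, `shannon`, `coverage`.
#' @export
cutoff_sweep <- function(proteins, cutoffs = c(0.83, 0.87, 0.90, 0.95),
                         log_base = 2) {
  if (length(cutoffs) == 0) stop("no cutoffs given")
  rows <- lapply(sort(cutoffs), function(ct) {
    cl <- cluster_opfs(proteins, cutoff = ct, log_base = log_base)
    data.frame(cutoff = ct, N = cl$N, S_obs = cl$S_obs, F1 = cl$F1,
               F2 = cl$F2, chao1 = cl$chao1, shannon = cl$shannon,
               coverage = cl$coverage)
  })
  do.call(rbind, rows)
}

#' Pairwise identity matrix for a protein set
#'
#' Square symmetric matrix of [pairwise_identity()] values; `1 - identity`
#' is the distance exported for external tree building.
#'
#' @param proteins `AAStringSet` or named character vector.
#' @return numeric matrix with clone ids as dimnames.
#' @export
identity_matrix <- function(proteins) {
  seqs <- setNames(as.character(proteins), names(proteins))
  if (is.null(names(seqs))) names(seqs) <- sprintf("seq_%03d", seq_along(seqs))
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      ids <- .identity_vec(seqs[i], seqs[(i + 1):n])
      m[i, (i + 1):n] <- ids
      m[(i + 1):n, i] <- ids
    }
  }
  m
}
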