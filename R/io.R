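#' @importFrom stats coef lm median pt qt rlnorm rmultinom rnorm runif sd setNames var
#' @importFrom utils read.delim read.csv write.csv write.table
NULL

## Closed vocabularies for the experimental design.
.SOILS      <- c("G", "NG")
.TREATMENTS <- c("12C-BT", "13C-BT", "NB", "12C-ST")

## Sanity window for CsCl buoyant densities (g/ml); DNA bands well inside it.
.BD_WINDOW <- c(1.60, 1.85)

#' Build a sample identifier from its experimental key
#'
#' Samples are keyed by soil, treatment, incubation day, and gradient
#' fraction (or unfractionated bulk DNA). The identifier is the four parts
#' joined by underscores, e.g. `"G_13C-BT_d12_f04"` or `"G_12C-BT_d0_unfrac"`.
#'
#' @param soil `"G"` (gas field) or `"NG"` (non-gas field background).
#' @param treatment one of `"12C-BT"`, `"13C-BT"`, `"NB"`, `"12C-ST"`.
#' @param day non-negative integer incubation day.
#' @param fraction integer fraction index 1-15, or `NA` for unfractionated.
#' @return character vector of sample identifiers.
#' @seealso [parse_sample_key()]
#' @export
sample_id <- function(soil, treatment, day, fraction = NA) {
  key <- validate_sample_key(soil, treatment, day, fraction)
  frac <- ifelse(is.na(key$fraction), "unfrac", sprintf("f%02d", key$fraction))
  paste(key$soil, key$treatment, paste0("d", key$day), frac, sep = "_")
}

validate_sample_key <- function(soil, treatment, day, fraction) {
  n <- max(length(soil), length(treatment), length(day), length(fraction))
  soil <- rep_len(as.character(soil), n)
  treatment <- rep_len(as.character(treatment), n)
  day <- rep_len(day, n)
  fraction <- rep_len(fraction, n)
  if (!all(soil %in% .SOILS))
    stop("unknown soil label(s): ", paste(unique(setdiff(soil, .SOILS)), collapse = ", "))
  if (!all(treatment %in% .TREATMENTS))
    stop("unknown treatment label(s): ",
         paste(unique(setdiff(treatment, .TREATMENTS)), collapse = ", "))
  day <- as.integer(day)
  if (anyNA(day) || any(day < 0)) stop("day must be a non-negative integer")
  fraction <- suppressWarnings(as.integer(fraction))
  bad <- !is.na(fraction) & (fraction < 1L | fraction > 15L)
  if (any(bad)) stop("fraction index must be in 1..15 or NA (unfractionated)")
  data.frame(soil = soil, treatment = treatment, day = day, fraction = fraction,
             stringsAsFactors = FALSE)
}

#' Parse sample identifiers back into their experimental key
#'
#' @param ids character vector of identifiers as produced by [sample_id()].
#' @return data.frame with columns `sample_id`, `soil`, `treatment`, `day`,
#'   `fraction` (`NA` for unfractionated samples).
#' @export
parse_sample_key <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 4L
  if (any(bad))
    stop("malformed sample id(s): ", paste(ids[bad], collapse = ", "),
         " (expected soil_treatment_dDAY_fNN|unfrac)")
  soil <- vapply(parts, `[`, "", 1L)
  treatment <- vapply(parts, `[`, "", 2L)
  dstr <- vapply(parts, `[`, "", 3L)
  fstr <- vapply(parts, `[`, "", 4L)
  if (!all(grepl("^d[0-9]+$", dstr)))
    stop("malformed day field in sample id(s): ",
         paste(ids[!grepl("^d[0-9]+$", dstr)], collapse = ", "))
  ok <- grepl("^f[0-9]{2}$", fstr) | fstr == "unfrac"
  if (!all(ok)) stop("malformed fraction field in sample id(s): ",
                     paste(ids[!ok], collapse = ", "))
  day <- as.integer(sub("^d", "", dstr))
  fraction <- rep(NA_integer_, length(fstr))
  fraction[fstr != "unfrac"] <- as.integer(sub("^f", "", fstr[fstr != "unfrac"]))
  key <- validate_sample_key(soil, treatment, day, fraction)
  cbind(data.frame(sample_id = ids, stringsAsFactors = FALSE), key)
}

#' Construct an OTU count table with sample metadata
#'
#' The central container for amplicon counts: an integer matrix of taxa
#' (rows) by samples (columns) whose column names encode the experimental
#' key (see [sample_id()]), plus the parsed per-sample metadata.
#'
#' @param counts non-negative integer matrix, rows = taxa (rownames are taxon
#'   ids), columns named by [sample_id()].
#' @return object of class `sip_otu`: list with elements `counts` (matrix)
#'   and `samples` (data.frame of parsed keys, one row per column).
#' @export
sip_otu <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) stop("counts must have taxon ids as rownames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon id(s): ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (is.null(colnames(counts))) stop("counts must have sample ids as colnames")
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid count at taxon '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  storage.mode(counts) <- "integer"
  samples <- parse_sample_key(colnames(counts))
  structure(list(counts = counts, samples = samples), class = "sip_otu")
}

#' @export
print.sip_otu <- function(x, ...) {
  cat(sprintf("sip_otu: %d taxa x %d samples (%d fractionated, %d unfractionated)\n",
              nrow(x$counts), ncol(x$counts),
              sum(!is.na(x$samples$fraction)), sum(is.na(x$samples$fraction))))
  invisible(x)
}

#' @export
dim.sip_otu <- function(x) dim(x$counts)

## Subset an OTU table by taxa and/or samples, keeping metadata in step.
#' @export
`[.sip_otu` <- function(x, i, j, ...) {
  cnt <- x$counts[i, j, drop = FALSE]
  sip_otu(cnt)
}

#' Read an OTU count table from TSV
#'
#' Tab-separated with a single header row; `#` prefixes comments. The first
#' column holds taxon identifiers; the remaining column names must parse as
#' sample keys (see [sample_id()]). Cells must be non-negative integers.
#'
#' @param path file path.
#' @return a [sip_otu()] object with column sums preserved exactly.
#' @export
read_otu_table <- function(path) {
  raw <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) stop("OTU table is empty: ", path)
  taxa <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(apply(mat, 2, as.numeric))
  num <- matrix(num, nrow = nrow(mat), dimnames = dimnames(mat))
  bad <- which(is.na(num) | num < 0 | num != round(num), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-count cell '%s' at taxon '%s', sample '%s' in %s",
                 mat[bad[1, 1], bad[1, 2]], taxa[bad[1, 1]],
                 colnames(mat)[bad[1, 2]], path))
  rownames(num) <- taxa
  sip_otu(num)
}

#' Write an OTU count table to TSV
#'
#' Inverse of [read_otu_table()]: integer counts round-trip exactly.
#'
#' @param x a `sip_otu` object.
#' @param path destination file.
#' @export
write_otu_table <- function(x, path) {
  stopifnot(inherits(x, "sip_otu"))
  df <- data.frame(taxon_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gradient-fraction metadata from TSV
#'
#' Columns `fraction_index` and `buoyant_density` (g/ml). Fractions are
#' numbered from the heavy end in collection order, so buoyant density
#' decreases with index; density is the authoritative axis, the index only
#' a label. Densities must fall in the (1.60, 1.85) g/ml sanity window.
#'
#' @param path file path.
#' @return data.frame sorted by `fraction_index` with columns
#'   `fraction_index`, `buoyant_density`.
#' @export
read_fraction_metadata <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop("fraction metadata is empty: ", path)
  need <- c("fraction_index", "buoyant_density")
  if (!all(need %in% names(df)))
    stop("fraction metadata must have columns ", paste(need, collapse = ", "))
  fractions(df$fraction_index, df$buoyant_density)
}

#' Construct validated gradient-fraction metadata
#'
#' @param fraction_index integer indices (1-based from the heavy end).
#' @param buoyant_density densities in g/ml, strictly decreasing with index.
#' @return data.frame sorted by index.
#' @export
fractions <- function(fraction_index, buoyant_density) {
  idx <- as.integer(fraction_index)
  bd <- as.numeric(buoyant_density)
  if (anyNA(idx) || anyDuplicated(idx)) stop("fraction indices must be unique integers")
  if (anyNA(bd) || any(!is.finite(bd))) stop("buoyant densities must be finite")
  if (any(bd <= .BD_WINDOW[1] | bd >= .BD_WINDOW[2]))
    stop(sprintf("buoyant density outside the (%.2f, %.2f) g/ml sanity window: %s",
                 .BD_WINDOW[1], .BD_WINDOW[2],
                 paste(bd[bd <= .BD_WINDOW[1] | bd >= .BD_WINDOW[2]], collapse = ", ")))
  o <- order(idx)
  idx <- idx[o]; bd <- bd[o]
  if (any(diff(bd) >= 0))
    stop("buoyant density must decrease strictly with fraction index ",
         "(fractions are collected heavy end first)")
  data.frame(fraction_index = idx, buoyant_density = bd)
}

#' @rdname read_fraction_metadata
#' @param frs fraction data.frame.
#' @param path destination file.
#' @export
write_fraction_metadata <- function(frs, path) {
  write.table(frs[, c("fraction_index", "buoyant_density")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign light/mid/heavy zones to gradient fractions
#'
#' Two conventions coexist in SIP work and both are supported. The qPCR
#' convention uses two thresholds (light below `light_max`, heavy above
#' `heavy_min`, a mid zone between); the amplicon convention uses a single
#' threshold (heavy above `amplicon_heavy_threshold`, no mid zone).
#'
#' @param frs fraction data.frame from [fractions()].
#' @param config a [run_config()]; its density thresholds are used.
#' @param convention `"qpcr"` (two thresholds) or `"amplicon"` (one).
#' @return factor of zones (`light`/`mid`/`heavy`), one per fraction.
#' @export
fraction_zones <- function(frs, config = run_config(), convention = c("qpcr", "amplicon")) {
  convention <- match.arg(convention)
  bd <- frs$buoyant_density
  if (convention == "qpcr") {
    z <- ifelse(bd < config$light_max_density, "light",
                ifelse(bd > config$heavy_min_density, "heavy", "mid"))
  } else {
    z <- ifelse(bd > config$amplicon_heavy_threshold, "heavy", "light")
  }
  factor(z, levels = c("light", "mid", "heavy"))
}

#' Read headspace gas measurements from CSV
#'
#' Columns `treatment`, `day`, `replicate`, `butane_amount` (any consistent
#' unit; residual fractions are scale-free). Each row is one measurement.
#'
#' @param path file path.
#' @return validated data.frame (see [gas_series()]).
#' @export
read_gas_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("treatment", "day", "replicate", "butane_amount")
  if (!all(need %in% names(df)))
    stop("gas CSV must have columns ", paste(need, collapse = ", "))
  gas_series(df)
}

#' @rdname read_gas_csv
#' @param gas gas data.frame.
#' @export
write_gas_csv <- function(gas, path) {
  write.csv(gas[, c("treatment", "day", "replicate", "butane_amount")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read qPCR measurements from CSV
#'
#' Columns `sample_id`, `gene`, `replicate`, and one of `cq` (quantification
#' cycles) or `copies` (absolute copy numbers).
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_qpcr_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "gene", "replicate")
  if (!all(need %in% names(df)))
    stop("qPCR CSV must have columns ", paste(need, collapse = ", "))
  if (!any(c("cq", "copies") %in% names(df)))
    stop("qPCR CSV must have a 'cq' or 'copies' column")
  df
}

#' @rdname read_qpcr_csv
#' @param q qPCR data.frame.
#' @export
write_qpcr_csv <- function(q, path) {
  write.csv(q, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Analysis run configuration
#'
#' Bundles the density thresholds and analysis constants used across the
#' pipeline. The qPCR zone convention calls fractions below 1.7285 g/ml
#' light and above 1.7319 g/ml heavy; the amplicon enrichment analysis uses
#' the single 1.723 g/ml threshold. The top-k filter keeps the 100 most
#' abundant taxa; protein-family cutoffs default to 83/87/90/95% identity.
#'
#' @param light_max_density g/ml; fractions below are light (qPCR convention).
#' @param heavy_min_density g/ml; fractions above are heavy (qPCR convention).
#' @param amplicon_heavy_threshold g/ml; single heavy threshold for the
#'   amplicon enrichment analysis.
#' @param top_k number of most-abundant taxa retained.
#' @param opf_cutoffs protein identity cutoffs in (0, 1].
#' @param alpha significance level for the two-tailed tests.
#' @param log_base base of the Shannon index logarithm.
#' @param enrich_delta minimum heavy-share difference calling a taxon labeled.
#' @param enrich_min_days minimum number of supporting days.
#' @param random_seed integer seed recorded with the run.
#' @return object of class `run_config` (a validated named list).
#' @export
run_config <- function(light_max_density = 1.7285,
                       heavy_min_density = 1.7319,
                       amplicon_heavy_threshold = 1.723,
                       top_k = 100L,
                       opf_cutoffs = c(0.83, 0.87, 0.90, 0.95),
                       alpha = 0.05,
                       log_base = 2,
                       enrich_delta = 0.05,
                       enrich_min_days = 2L,
                       random_seed = 1L) {
  cfg <- list(light_max_density = as.numeric(light_max_density),
              heavy_min_density = as.numeric(heavy_min_density),
              amplicon_heavy_threshold = as.numeric(amplicon_heavy_threshold),
              top_k = as.integer(top_k),
              opf_cutoffs = as.numeric(opf_cutoffs),
              alpha = as.numeric(alpha),
              log_base = as.numeric(log_base),
              enrich_delta = as.numeric(enrich_delta),
              enrich_min_days = as.integer(enrich_min_days),
              random_seed = as.integer(random_seed))
  if (!(cfg$light_max_density < cfg$heavy_min_density))
    stop("light_max_density must be below heavy_min_density")
  if (cfg$top_k < 1L) stop("top_k must be a positive integer")
  if (any(cfg$opf_cutoffs <= 0 | cfg$opf_cutoffs > 1))
    stop("every OPF cutoff must lie in (0, 1]")
  if (!(cfg$alpha > 0 && cfg$alpha < 1)) stop("alpha must lie in (0, 1)")
  if (!(cfg$log_base > 1)) stop("log_base must exceed 1")
  if (cfg$enrich_min_days < 1L) stop("enrich_min_days must be >= 1")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (k in names(x)) cat(sprintf("  %s = %s\n", k, paste(x[[k]], collapse = ",")))
  invisible(x)
}

#' Read a run configuration from a flat key/value file
#'
#' One `key = value` pair per line; `#` starts a comment; list values are
#' comma-separated. Unknown keys are rejected. Values given in the file
#' override the defaults of [run_config()].
#'
#' @param path file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  defaults <- run_config()
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(defaults)) stop("unknown config key: ", key)
    args[[key]] <- as.numeric(strsplit(val, ",", fixed = TRUE)[[1]])
  }
  do.call(run_config, args)
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    sprintf("%s = %s", k, paste(format(config[[k]], digits = 15), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}
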