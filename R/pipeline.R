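## Run a pipeline stage, aborting with the stage name on failure.
.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

.write_tsv <- function(df, path, rownames_as = NULL) {
  if (!is.null(rownames_as)) {
    df <- cbind(setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                         rownames_as),
                as.data.frame(df, check.names = FALSE))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Per-fraction copy-number profiles of a gene
#'
#' Quantifies each replicate through the standard curve and joins fraction
#' densities, yielding one profile row per fractionated sample and
#' replicate.
#'
#' @param measurements qPCR data.frame (`sample_id`, `gene`, `replicate`,
#'   `cq` or `copies`).
#' @param curve the gene's [standard_curve()].
#' @param frs fraction metadata.
#' @param gene gene name.
#' @return data.frame `sample_id`, `soil`, `treatment`, `day`, `fraction`,
#'   `buoyant_density`, `replicate`, `copies`.
#' @export
qpcr_fraction_profiles <- function(measurements, curve, frs, gene) {
  m <- measurements[measurements$gene == gene, , drop = FALSE]
  key <- parse_sample_key(m$sample_id)
  m <- m[!is.na(key$fraction), , drop = FALSE]
  key <- key[!is.na(key$fraction), , drop = FALSE]
  if (nrow(m) == 0) stop("no fractionated measurements for gene ", gene)
  copies <- if ("cq" %in% names(m) && !all(is.na(m$cq)))
    quantify_copies(m$cq, curve) else m$copies
  data.frame(sample_id = m$sample_id, soil = key$soil,
             treatment = key$treatment, day = key$day,
             fraction = key$fraction,
             buoyant_density = frs$buoyant_density[
               match(key$fraction, frs$fraction_index)],
             replicate = m$replicate, copies = copies,
             stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline over input files
#'
#' Chains the analysis stages over whichever inputs are supplied -- gas
#' depletion accounting, top-k filtering plus labeled-taxon classification,
#' qPCR standard curves, quantification, ratio normalization and
#' per-fraction labeling-shift tests, clone-library clustering and
#' diversity, and correspondence-analysis ordination -- and writes
#' machine-readable TSV result tables plus a run log (configuration, seed,
#' versions) under `out_dir`. Any stage failure aborts with the stage name.
#'
#' @param out_dir output directory (created if needed).
#' @param otu OTU table TSV path.
#' @param fraction_meta fraction metadata TSV path.
#' @param gas optional gas CSV path.
#' @param qpcr_standards,qpcr_measurements optional qPCR CSV paths; the
#'   standards file needs a `log10_copies` column.
#' @param clones optional named character vector of clone FASTA paths.
#' @param taxonomy optional TSV path with columns `taxon_id`, `group`.
#' @param config a [run_config()].
#' @return named list of written file paths, invisibly.
#' @export
run_pipeline <- function(out_dir, otu, fraction_meta, gas = NULL,
                         qpcr_standards = NULL, qpcr_measurements = NULL,
                         clones = NULL, taxonomy = NULL,
                         config = run_config()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$random_seed)
  outputs <- list()

  tab <- .stage("read_otu", read_otu_table(otu))
  frs <- .stage("read_fractions", read_fraction_metadata(fraction_meta))

  if (!is.null(gas)) {
    outputs$degradation <- .stage("gas", {
      series <- read_gas_csv(gas)
      .write_tsv(degradation_table(series, alpha = config$alpha),
                 file.path(out_dir, "degradation.tsv"))
    })
  }

  outputs$enrichment <- .stage("enrich", {
    top <- suppressWarnings(top_k_otus(tab, config$top_k))
    calls_all <- list()
    for (soil in unique(tab$samples$soil)) {
      has13 <- any(tab$samples$soil == soil & tab$samples$treatment == "13C-BT" &
                   !is.na(tab$samples$fraction))
      if (!has13) next
      calls <- classify_labeled(top, frs, soil = soil,
                                threshold = config$amplicon_heavy_threshold,
                                delta = config$enrich_delta,
                                min_days = config$enrich_min_days)
      calls$soil <- soil
      calls_all[[soil]] <- as.data.frame(calls)
      sc <- attr(calls, "scores"); sc$soil <- soil
      .write_tsv(sc, file.path(out_dir, sprintf("enrichment_scores_%s.tsv", soil)))
    }
    if (length(calls_all) == 0) stop("no fractionated 13C treatment found")
    .write_tsv(do.call(rbind, calls_all),
               file.path(out_dir, "enrichment_calls.tsv"))
  })

  if (!is.null(qpcr_standards) && !is.null(qpcr_measurements)) {
    outputs <- c(outputs, .stage("qpcr", {
      std <- read_qpcr_csv(qpcr_standards)
      if (!"log10_copies" %in% names(std))
        stop("standards file needs a log10_copies column")
      meas <- read_qpcr_csv(qpcr_measurements)
      genes <- unique(std$gene)
      curves <- lapply(setNames(genes, genes), function(g) {
        s <- std[std$gene == g, ]
        fit_standard_curve(s$log10_copies, s$cq)
      })
      curve_df <- do.call(rbind, lapply(genes, function(g)
        data.frame(gene = g, slope = curves[[g]]$slope,
                   intercept = curves[[g]]$intercept,
                   r_squared = curves[[g]]$r_squared,
                   efficiency = curves[[g]]$efficiency)))
      p_curves <- .write_tsv(curve_df, file.path(out_dir, "standard_curves.tsv"))

      quants <- do.call(rbind, lapply(genes, function(g)
        gene_quant(meas, curves[[g]], g)))
      p_quant <- .write_tsv(quants, file.path(out_dir, "gene_quant.tsv"))

      key <- parse_sample_key(quants$sample_id)
      unf <- is.na(key$fraction)
      p_folds <- NULL
      if (all(c("bmoX", "16S") %in% genes) && any(unf)) {
        bx <- data.frame(day = key$day[unf & quants$gene == "bmoX"],
                         copies = quants$copies[unf & quants$gene == "bmoX"])
        ss <- data.frame(day = key$day[unf & quants$gene == "16S"],
                         copies = quants$copies[unf & quants$gene == "16S"])
        if (0 %in% bx$day && 0 %in% ss$day) {
          p_folds <- .write_tsv(normalized_fold(bx, ss),
                                file.path(out_dir, "normalized_folds.tsv"))
        }
      }

      p_prof <- p_shift <- NULL
      kk <- parse_sample_key(meas$sample_id)
      if (any(!is.na(kk$fraction) & meas$gene == "bmoX")) {
        prof <- qpcr_fraction_profiles(meas, curves$bmoX, frs, "bmoX")
        p_prof <- .write_tsv(prof, file.path(out_dir, "bmox_fraction_profiles.tsv"))
        shifts <- list()
        for (soil in unique(prof$soil)) for (d in sort(unique(prof$day))) {
          p13 <- prof[prof$soil == soil & prof$treatment == "13C-BT" & prof$day == d, ]
          p12 <- prof[prof$soil == soil & prof$treatment == "12C-BT" & prof$day == d, ]
          if (nrow(p13) == 0 || nrow(p12) == 0) next
          st <- labeling_shift_test(p13, p12, heavy_min = config$heavy_min_density,
                                    alpha = config$alpha)
          shifts[[length(shifts) + 1]] <- data.frame(
            soil = soil, day = d, share13 = st$share13, share12 = st$share12,
            difference = st$difference, t_stat = st$t, df = st$df,
            p_value = st$p, significant = st$significant)
        }
        if (length(shifts))
          p_shift <- .write_tsv(do.call(rbind, shifts),
                                file.path(out_dir, "labeling_shift_tests.tsv"))
      }
      list(standard_curves = p_curves, gene_quant = p_quant,
           normalized_folds = p_folds, bmox_profiles = p_prof,
           labeling_shifts = p_shift)
    }))
  }

  if (!is.null(clones)) {
    outputs$clone_diversity <- .stage("clones", {
      rows <- list()
      for (nm in names(clones)) {
        aa <- translate_clones(read_clone_fasta(clones[[nm]]))
        sweep_df <- cutoff_sweep(aa, config$opf_cutoffs, config$log_base)
        sweep_df$library <- nm
        rows[[nm]] <- sweep_df
        main <- cluster_opfs(aa, 0.87, config$log_base)
        rar <- rarefaction_expected(main$sizes,
                                    unique(pmin(main$N, c(1, 2, 5, 10, 20, 50,
                                                          main$N))))
        .write_tsv(rar, file.path(out_dir, sprintf("rarefaction_%s.tsv", nm)))
        .write_tsv(1 - identity_matrix(aa),
                   file.path(out_dir, sprintf("protein_distances_%s.tsv", nm)),
                   rownames_as = "clone_id")
      }
      .write_tsv(do.call(rbind, rows), file.path(out_dir, "opf_summaries.tsv"))
    })
  }

  outputs$ordination <- .stage("ordinate", {
    cm <- community_matrix(tab)
    cm <- cm[rowSums(cm) > 0, colSums(cm) > 0, drop = FALSE]
    ca <- correspondence_analysis(cm)
    if (length(ca$eigenvalues) >= 2) ca <- detrend_by_segments(ca)
    .write_tsv(data.frame(axis = seq_along(ca$eigenvalues),
                          eigenvalue = ca$eigenvalues, percent = ca$percent),
               file.path(out_dir, "ordination_eigenvalues.tsv"))
    .write_tsv(as.data.frame(ca$sample_scores),
               file.path(out_dir, "ordination_scores.tsv"),
               rownames_as = "sample_id")
  })

  if (!is.null(taxonomy)) {
    outputs$groups <- .stage("groups", {
      mapping <- read.delim(taxonomy, stringsAsFactors = FALSE)
      agg <- aggregate_groups(tab, mapping, top_n = 10)
      .write_tsv(as.data.frame(agg), file.path(out_dir, "group_abundance.tsv"),
                 rownames_as = "group")
    })
  }

  log_lines <- c("gradsip run log",
                 sprintf("package_version: %s",
                         as.character(utils::packageVersion("gradsip"))),
                 sprintf("r_version: %s", R.version.string),
                 sprintf("seed: %d", config$random_seed),
                 "config:",
                 vapply(names(config), function(k)
                   sprintf("  %s = %s", k, paste(config[[k]], collapse = ",")),
                   character(1)))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  outputs$log <- file.path(out_dir, "run_log.txt")
  invisible(outputs)
}
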