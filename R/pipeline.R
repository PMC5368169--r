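# End-to-end runs: masks -> descriptors -> statistics -> report;
# expression -> candidates; Ct -> classifications; proteome -> RING sets.
# All tabular outputs are deterministic given inputs and seed, so an
# unchanged configuration re-run is byte-identical.

#' Read a run configuration
#'
#' YAML configuration with defaults: `mm_per_px` 0.25, analysis window days
#' 10-20, `alpha` 0.05, `control` "Col-0", `seed` 1, optional per-parameter
#' polynomial-order overrides and threshold overrides.
#'
#' @param path YAML file path, or a list to normalize directly.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  defaults <- list(mm_per_px = 0.25, days = 10:20, alpha = 0.05,
                   control = "Col-0", seed = 1L, orders = NULL,
                   log2fc_threshold = 1, perimeter_method = "contour",
                   block = NULL)
  for (k in names(defaults)) {
    if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  }
  if (!is.null(cfg$days) && length(cfg$days) == 2L) {
    cfg$days <- cfg$days[1L]:cfg$days[2L]
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1)
  cfg
}

log_line <- function(module, ...) {
  message(sprintf("[%s] %s", module, paste0(...)))
}

#' Phenotyping run: masks to descriptor statistics
#'
#' Reads the metadata CSV (columns `plant_id`, `genotype`, `day`, `path`,
#' `mm_per_px`, optionally `tray`), computes the nine descriptors per mask,
#' restricts to the analysis window, compares every mutant genotype against
#' the control per descriptor with the nested polynomial chi-square test,
#' and writes `descriptors.csv`, `model_comparisons.csv` (with significance
#' stars), a JSON summary, and (optionally) per-descriptor plots of daily
#' means with 95% confidence intervals and fitted curves. Per-plant QC
#' failures quarantine the plant, never the run.
#'
#' @param config list from [read_run_config()] with at least `metadata`
#'   (CSV path) and `out_dir`.
#' @param plots write PNG plots per descriptor.
#' @return Invisibly, a list with `descriptors` and `comparisons`.
#' @export
run_phenotype <- function(config, plots = FALSE) {
  config <- read_run_config(config)
  if (is.null(config$metadata)) stop("config$metadata (CSV path) is required")
  md <- utils::read.csv(config$metadata, stringsAsFactors = FALSE)
  if (nrow(md) == 0L) stop("empty metadata table: ", config$metadata)
  missing_files <- md$path[!file.exists(md$path)]
  if (length(missing_files)) {
    stop("missing mask files:\n", paste(missing_files, collapse = "\n"))
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_line("phenotype", "describing ", nrow(md), " masks")
  desc <- describe_series(md, perimeter_method = config$perimeter_method)
  desc <- desc[desc$day %in% config$days, , drop = FALSE]
  utils::write.csv(desc, file.path(out_dir, "descriptors.csv"), row.names = FALSE)
  n_quarantined <- length(unique(desc$plant_id[grepl("^failed|empty-mask", desc$qc_flags)]))
  if (n_quarantined > 0L) {
    log_line("phenotype", n_quarantined, " plant-days quarantined by QC")
  }
  ok <- desc[is.finite(desc$value), , drop = FALSE]
  cmp <- compare_genotypes(ok, control = config$control, orders = config$orders)
  utils::write.csv(cmp, file.path(out_dir, "model_comparisons.csv"), row.names = FALSE)
  if (plots) {
    for (p in unique(ok$parameter)) {
      gp <- plot_growth(ok, p, control = config$control)
      ggplot2::ggsave(file.path(out_dir, paste0("growth_", p, ".png")), gp,
                      width = 6, height = 4, dpi = 120)
    }
  }
  summary <- list(n_masks = nrow(md), n_quarantined = n_quarantined,
                  genotypes = sort(unique(md$genotype)),
                  alpha = config$alpha,
                  significant = cmp[!is.na(cmp$p_value) &
                                      cmp$p_value < config$alpha,
                                    c("genotype", "parameter", "p_value")])
  jsonlite::write_json(summary, file.path(out_dir, "phenotype_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(descriptors = desc, comparisons = cmp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Daily-mean growth plot with fitted polynomial curves
#'
#' Markers are daily means, error bars 95% confidence intervals of the mean,
#' curves the genotype-specific polynomial fit at [default_order()].
#'
#' @param data long descriptor table.
#' @param parameter descriptor to plot.
#' @param control control genotype (reference level).
#' @param order polynomial order; default per descriptor.
#' @return A ggplot object.
#' @export
plot_growth <- function(data, parameter, control = "Col-0",
                        order = default_order(parameter)) {
  d <- data[data$parameter == parameter & is.finite(data$value), , drop = FALSE]
  fit <- fit_growth_model(d, parameter, order = order,
                          with_genotype = length(unique(d$genotype)) > 1L,
                          control = control)
  newd <- expand.grid(day = seq(min(d$day), max(d$day), length.out = 80),
                      genotype = unique(d$genotype))
  newd$x <- scale_day(newd$day, range(d$day))
  if (fit$with_genotype) {
    newd$genotype <- stats::relevel(factor(newd$genotype), ref = control)
  }
  newd$value <- stats::predict(fit$fit, newdata = newd)
  ggplot2::ggplot(d, ggplot2::aes(x = day, y = value, colour = genotype)) +
    ggplot2::stat_summary(fun = mean, geom = "point") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_cl_normal, geom = "errorbar",
                          width = 0.25) +
    ggplot2::geom_line(data = newd) +
    ggplot2::labs(x = "days after stratification", y = parameter) +
    ggplot2::theme_bw()
}

#' Expression screen run
#'
#' Reads an expression CSV (first column `gene_id`, remaining columns
#' condition labels, linear scale), screens every category against the
#' reference column, and writes per-category gene lists, `union_genes.txt`
#' and `venn.json`.
#'
#' @param config list with `expression` (CSV path), `reference` (column
#'   name), optional `log2fc_threshold`, `out_dir`.
#' @return Invisibly, the [screen_expression()] result.
#' @export
run_screen <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$expression) || is.null(config$reference)) {
    stop("config needs $expression (CSV) and $reference (column name)")
  }
  mat <- utils::read.csv(config$expression, stringsAsFactors = FALSE)
  res <- screen_expression(mat, reference = config$reference,
                           threshold = config$log2fc_threshold)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (cat in names(res$up_sets)) {
    up <- res$up_sets[[cat]]
    utils::write.csv(data.frame(gene_id = up,
                                log2fc = unname(res$log2fc[[cat]][up])),
                     file.path(out_dir, paste0("up_", cat, ".csv")),
                     row.names = FALSE)
  }
  writeLines(res$union, file.path(out_dir, "union_genes.txt"))
  jsonlite::write_json(as.list(res$venn), file.path(out_dir, "venn.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' qPCR classification run
#'
#' Reads a Ct CSV (`sample`, `gene`, `role`, `replicate`, `ct`) and writes
#' `qpcr_classifications.csv` with the 2^-ddCt fold change and mutant
#' expression class per target.
#'
#' @param config list with `ct_table` (CSV path), optional `mutant`/`control`
#'   sample labels, `out_dir`.
#' @return Invisibly, the report data.frame.
#' @export
run_qpcr <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$ct_table)) stop("config$ct_table (CSV path) is required")
  ct <- utils::read.csv(config$ct_table, stringsAsFactors = FALSE)
  rep <- qpcr_report(ct, mutant = config$mutant %||% "mutant",
                     control = config$control_sample %||% "control")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(rep, file.path(out_dir, "qpcr_classifications.csv"),
                   row.names = FALSE)
  invisible(rep)
}

#' RING domain screen run
#'
#' Reads a proteome FASTA and an InterProScan-style TSV, locates and
#' classifies canonical RING domains, optionally reconciles the recovered
#' locus set against an older gene list, and writes `ring_hits.csv` and
#' `reconciliation.json`.
#'
#' @param config list with `proteome` (FASTA path), `domains` (TSV path),
#'   optional `old_ids` (text file, one locus per line), `evidence`
#'   (CSV `id`,`reason`), `out_dir`.
#' @return Invisibly, a list with `hits`, `signature_only`, `reconciliation`.
#' @export
run_ring <- function(config) {
  config <- read_run_config(config)
  if (is.null(config$proteome) || is.null(config$domains)) {
    stop("config needs $proteome (FASTA) and $domains (TSV)")
  }
  aa <- Biostrings::readAAStringSet(config$proteome)
  names(aa) <- sub("\\s.*$", "", names(aa))
  ann <- parse_domain_table(config$domains)
  res <- find_ring_domains(aa, ann)
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$hits)) {
    utils::write.csv(res$hits, file.path(out_dir, "ring_hits.csv"),
                     row.names = FALSE)
  }
  recon <- NULL
  if (!is.null(config$old_ids)) {
    old <- readLines(config$old_ids)
    ev <- if (!is.null(config$evidence)) {
      utils::read.csv(config$evidence, stringsAsFactors = FALSE)
    } else NULL
    new_loci <- collapse_isoforms(res$hits$protein_id)
    recon <- reconcile(new_loci, old, ev)
    jsonlite::write_json(list(matched = recon$matched,
                              newly_identified = recon$newly_identified,
                              dropped = recon$dropped,
                              counts = as.list(recon$counts)),
                         file.path(out_dir, "reconciliation.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(hits = res$hits, signature_only = res$signature_only,
                 reconciliation = recon))
}

#' Write a complete synthetic dataset bundle
#'
#' Materializes every input the analysis runs consume (mask series + metadata
#' CSV, expression CSV, Ct CSV, proteome FASTA + domain TSV) with their
#' ground-truth JSON files, in the exact formats the `run_*` functions read.
#'
#' @param out_dir output directory.
#' @param seed master seed; per-generator seeds are derived from it.
#' @param n_plants plants per genotype for the mask series.
#' @param genotypes named list of genotype effect settings for
#'   [rosette_model()]; names are genotype labels, first entry the control.
#' @param days days to render.
#' @param size_px,mm_per_px mask geometry.
#' @return Invisibly, a list of file paths.
#' @export
run_synth <- function(out_dir, seed = 1L, n_plants = 3L,
                      genotypes = list("Col-0" = list(),
                                       "mutant" = list(size_mult = 0.85)),
                      days = 10:20, size_px = 320L, mm_per_px = 0.25) {
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE, recursive = TRUE)
  md <- list()
  for (gi in seq_along(genotypes)) {
    g <- names(genotypes)[gi]
    for (p in seq_len(n_plants)) {
      pid <- sprintf("%s_%02d", g, p)
      args <- c(list(seed = seed + 1000L * gi + p), genotypes[[gi]])
      model <- do.call(rosette_model, args)
      ser <- render_rosette_series(model, days = days, size_px = size_px,
                                   mm_per_px = mm_per_px, plant_id = pid)
      for (k in seq_along(days)) {
        path <- file.path(out_dir, "masks", sprintf("%s_%02d.png", pid, days[k]))
        write_mask(ser$masks[[k]], path)
        md[[length(md) + 1L]] <- data.frame(
          plant_id = pid, genotype = g, tray = 1L, day = days[k],
          path = path, mm_per_px = mm_per_px, stringsAsFactors = FALSE)
      }
    }
  }
  md <- do.call(rbind, md)
  utils::write.csv(md, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  expr <- simulate_expression(seed = seed + 11L)
  expr_df <- data.frame(gene_id = rownames(expr$matrix), expr$matrix,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(expr_df, file.path(out_dir, "expression.csv"), row.names = FALSE)
  ct <- simulate_ct(targets = c(geneA = 0.05, geneB = 0.3, geneC = 1, geneD = 4),
                    replicate_sd = 0.2, seed = seed + 12L)
  utils::write.csv(ct$table, file.path(out_dir, "ct_table.csv"), row.names = FALSE)
  prot <- plant_ring_proteome(seed = seed + 13L)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(prot$proteins),
                              file.path(out_dir, "proteome.fasta"))
  if (!is.null(prot$annotations)) {
    ann <- prot$annotations
    tsv <- data.frame(ann$protein_id, "md5", nchar(prot$proteins[ann$protein_id]),
                      ann$signature_db, ann$signature_accession, "RING domain",
                      ann$start, ann$end, "1e-10", "T", "2026-01-01")
    utils::write.table(tsv, file.path(out_dir, "domains.tsv"), sep = "\t",
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(list(seed = seed,
                            expression = expr$truth,
                            ct = ct$truth,
                            ring = lapply(prot$truth$planted, function(x) {
                              list(class = x$class, positions = x$positions)
                            })),
                       file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(metadata = file.path(out_dir, "metadata.csv"),
                 expression = file.path(out_dir, "expression.csv"),
                 ct_table = file.path(out_dir, "ct_table.csv"),
                 proteome = file.path(out_dir, "proteome.fasta"),
                 domains = file.path(out_dir, "domains.tsv"),
                 truth = file.path(out_dir, "truth.json")))
}
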