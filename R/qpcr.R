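# Relative qPCR quantification by the 2^-ddCt method and classification of
# mutant expression levels.

#' Fold change by the 2^-ddCt method
#'
#' Technical replicates are averaged per sample and gene; each sample's
#' delta-Ct is the target mean Ct minus the arithmetic mean of the reference
#' genes' mean Cts; delta-delta-Ct is the mutant minus the control delta-Ct;
#' the fold change is `2^-ddCt`.
#'
#' @param table data.frame with columns `sample` (values `mutant`/`control`,
#'   configurable), `gene`, `role` (`target`/`reference`), `replicate`, `ct`.
#' @param target target gene name.
#' @param mutant,control sample labels.
#' @return List with `fold_change`, `ddct`, `dct_mutant`, `dct_control`, and
#'   `replicate_sd` (QC: per sample/gene technical SDs).
#' @examples
#' ct <- data.frame(sample = rep(c("control", "mutant"), each = 2),
#'                  gene = rep(c("G", "REF"), 2),
#'                  role = rep(c("target", "reference"), 2),
#'                  replicate = 1, ct = c(24, 20, 25, 20))
#' delta_delta_ct(ct, "G")$fold_change  # 0.5
#' @export
delta_delta_ct <- function(table, target, mutant = "mutant", control = "control") {
  need <- c("sample", "gene", "role", "replicate", "ct")
  if (!all(need %in% names(table))) {
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(table$ct <= 0, na.rm = TRUE)) stop("Ct values must be positive")
  refs <- unique(table$gene[table$role == "reference"])
  if (length(refs) == 0L) stop("no reference genes in Ct table")
  mean_ct <- function(samp, gene) {
    v <- table$ct[table$sample == samp & table$gene == gene]
    if (length(v) == 0L) {
      stop(sprintf("gene %s not measured in sample %s", gene, samp))
    }
    mean(v)
  }
  dct <- function(samp) {
    ref_means <- vapply(refs, function(g) mean_ct(samp, g), numeric(1))
    mean_ct(samp, target) - mean(ref_means)
  }
  dct_m <- dct(mutant)
  dct_c <- dct(control)
  ddct <- dct_m - dct_c
  sds <- stats::aggregate(ct ~ sample + gene, data = table,
                          FUN = function(v) stats::sd(v))
  names(sds)[names(sds) == "ct"] <- "replicate_sd"
  list(fold_change = 2^(-ddct), ddct = ddct,
       dct_mutant = dct_m, dct_control = dct_c, replicate_sd = sds)
}

#' Classify mutant expression from a fold change
#'
#' Thresholds: fold change below 0.1 is a knock-out; 0.1 to 0.5 (closed
#' interval) a knock-down; above 2 (strict) up-regulated; anything else
#' unchanged.
#'
#' @param fc positive fold change (vectorized).
#' @return Character vector over
#'   `{"knock-out", "knock-down", "unchanged", "up-regulated"}`.
#' @examples
#' classify_expression(c(0.05, 0.3, 1, 4))
#' @export
classify_expression <- function(fc) {
  if (any(!is.finite(fc) | fc <= 0)) stop("fold change must be positive")
  ifelse(fc < 0.1, "knock-out",
         ifelse(fc <= 0.5, "knock-down",
                ifelse(fc > 2, "up-regulated", "unchanged")))
}

#' Quantify and classify every target in a Ct table
#'
#' @param table Ct table (see [delta_delta_ct()]).
#' @param mutant,control sample labels.
#' @return data.frame with `target`, `fold_change`, `classification`, and
#'   `max_replicate_sd` as QC.
#' @export
qpcr_report <- function(table, mutant = "mutant", control = "control") {
  targets <- unique(table$gene[table$role == "target"])
  rows <- lapply(targets, function(tg) {
    res <- delta_delta_ct(table, tg, mutant = mutant, control = control)
    sdv <- res$replicate_sd$replicate_sd
    data.frame(target = tg, fold_change = res$fold_change,
               classification = classify_expression(res$fold_change),
               max_replicate_sd = if (all(is.na(sdv))) NA_real_ else max(sdv, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
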