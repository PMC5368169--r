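# Longitudinal genotype comparison: nested polynomial fits compared by a
# Gaussian likelihood-ratio chi-square test, flowering-time ANOVA with
# Dunnett many-to-one adjustment, and flower-defect contingency statistics.

#' Default polynomial order per descriptor
#'
#' The per-descriptor polynomial orders used for the growth-curve fits:
#' area 3, perimeter 3, compactness 4, roundness 5, roundness 2 5,
#' isotropy 6, eccentricity 6, RMS 6, SOL 3. Names are matched
#' case-insensitively and ignoring spaces ("Roundness 2" == "roundness2").
#'
#' @param parameter descriptor name.
#' @return Integer polynomial order.
#' @examples
#' default_order("Area")      # 3
#' default_order("Isotropy")  # 6
#' @export
default_order <- function(parameter) {
  key <- gsub("[ _]", "", tolower(parameter))
  orders <- c(area = 3L, perimeter = 3L, compactness = 4L, roundness = 5L,
              roundness1 = 5L, roundness2 = 5L, isotropy = 6L,
              eccentricity = 6L, rms = 6L, sol = 3L)
  if (!key %in% names(orders)) stop("unknown descriptor: ", parameter)
  unname(orders[key])
}

# Day axis centered and scaled to [-1, 1] to keep high-order polynomial
# bases well conditioned.
scale_day <- function(day, range_day = range(day)) {
  if (diff(range_day) == 0) return(day * 0)
  2 * (day - mean(range_day)) / diff(range_day)
}

#' Fit a polynomial growth model
#'
#' Ordinary least-squares fit of one descriptor against a polynomial in day
#' (day axis rescaled to [-1, 1]). With `with_genotype = TRUE` the model
#' gains a genotype main effect plus genotype-by-polynomial interactions,
#' i.e. `order + 1` extra coefficients per non-reference genotype, so the
#' full genotype curve may differ. The Gaussian log-likelihood is used for
#' nested model comparison.
#'
#' @param data long data.frame with columns `plant_id`, `genotype`, `day`,
#'   `parameter`, `value`.
#' @param parameter descriptor to model.
#' @param order polynomial order (>= 1); default from [default_order()].
#' @param with_genotype include genotype effects.
#' @param control reference genotype level.
#' @return Object of class `growth_fit`: the `lm` fit plus metadata.
#' @export
fit_growth_model <- function(data, parameter, order = default_order(parameter),
                             with_genotype = FALSE, control = "Col-0") {
  stopifnot(order >= 1)
  d <- data[data$parameter == parameter & is.finite(data$value), , drop = FALSE]
  if (nrow(d) == 0L) stop("no observations for parameter ", parameter)
  n_days <- length(unique(d$day))
  if (n_days < order + 2L) {
    stop(sprintf("parameter %s: %d distinct days cannot support order-%d fit",
                 parameter, n_days, order))
  }
  d$x <- scale_day(d$day)
  if (with_genotype) {
    if (length(unique(d$genotype)) < 2L) {
      stop("with_genotype requires at least two genotypes for ", parameter)
    }
    d$genotype <- stats::relevel(factor(d$genotype), ref = control)
    fit <- stats::lm(value ~ poly(x, degree = order) * genotype, data = d)
  } else {
    fit <- stats::lm(value ~ poly(x, degree = order), data = d)
  }
  structure(list(fit = fit, parameter = parameter, order = order,
                 with_genotype = with_genotype, n_obs = nrow(d),
                 genotypes = sort(unique(as.character(d$genotype))),
                 logLik = as.numeric(stats::logLik(fit)),
                 df = attr(stats::logLik(fit), "df"),
                 data = d, control = control),
            class = "growth_fit")
}

#' Likelihood-ratio comparison of nested growth models
#'
#' Chi-square test of whether the larger model (typically the one including
#' genotype) explains significantly more variance: the statistic
#' \eqn{2(\ell_{large} - \ell_{small})} is referred to a chi-square
#' distribution with df equal to the difference in parameter count.
#' Optionally a plant-level block bootstrap p-value is added as a
#' repeated-measures safeguard.
#'
#' @param model_small,model_large `growth_fit` objects fit to the same
#'   records; `model_small` must be nested in `model_large`.
#' @param boot number of plant-level bootstrap resamples (0 = none).
#' @param boot_seed RNG seed for the bootstrap.
#' @return Object of class `model_comparison`: a one-row data.frame with
#'   `parameter`, `polynomial_order`, `chisq_stat`, `df`, `p_value`, `n_obs`
#'   (plus `p_boot` when requested).
#' @export
compare_nested <- function(model_small, model_large, boot = 0L, boot_seed = 1L) {
  stopifnot(inherits(model_small, "growth_fit"), inherits(model_large, "growth_fit"))
  if (model_small$n_obs != model_large$n_obs ||
      model_small$parameter != model_large$parameter) {
    stop("models must be fit to identical records")
  }
  df <- model_large$df - model_small$df
  if (df < 0) stop("model_small is not nested in model_large")
  small_terms <- colnames(stats::model.matrix(model_small$fit))
  large_terms <- colnames(stats::model.matrix(model_large$fit))
  if (!all(small_terms %in% large_terms)) {
    stop("model_small terms are not a subset of model_large terms (non-nested)")
  }
  stat <- max(0, 2 * (model_large$logLik - model_small$logLik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  out <- data.frame(parameter = model_large$parameter,
                    polynomial_order = model_large$order,
                    chisq_stat = stat, df = df, p_value = p,
                    n_obs = model_large$n_obs, stringsAsFactors = FALSE)
  if (boot > 0L) out$p_boot <- bootstrap_lrt_p(model_small, model_large, boot, boot_seed)
  class(out) <- c("model_comparison", class(out))
  out
}

# Plant-level block bootstrap of the LRT statistic under the small model:
# whole-plant residual curves are resampled to respect within-plant
# correlation (falls back to iid rows when plants have unequal day sets).
bootstrap_lrt_p <- function(model_small, model_large, n_boot, seed) {
  d <- model_large$data
  order <- model_large$order
  fitted0 <- stats::fitted(model_small$fit)
  resid0 <- stats::resid(model_small$fit)
  blocks <- split(seq_len(nrow(d)), d$plant_id)
  balanced <- length(unique(lengths(blocks))) == 1L
  obs_stat <- max(0, 2 * (model_large$logLik - model_small$logLik))
  d$genotype <- stats::relevel(factor(d$genotype), ref = model_large$control)
  with_fixed_seed(seed, {
    stats_boot <- vapply(seq_len(n_boot), function(b) {
      idx <- if (balanced) {
        unlist(blocks[sample.int(length(blocks), replace = TRUE)], use.names = FALSE)
      } else {
        sample.int(nrow(d), replace = TRUE)
      }
      db <- d
      db$value <- fitted0 + resid0[idx]
      f0 <- stats::lm(value ~ poly(x, degree = order), data = db)
      f1 <- stats::lm(value ~ poly(x, degree = order) * genotype, data = db)
      max(0, 2 * (as.numeric(stats::logLik(f1)) - as.numeric(stats::logLik(f0))))
    }, numeric(1))
    (1 + sum(stats_boot >= obs_stat)) / (n_boot + 1)
  })
}

# Evaluate expr with a local, restored RNG state (keeps stochastic numerical
# integration reproducible without clobbering the caller's stream).
with_fixed_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Genotype-vs-control model comparisons for every descriptor
#'
#' For each mutant genotype and each requested descriptor, fits the pooled
#' and the genotype-augmented polynomial model on the control + mutant
#' records and reports the likelihood-ratio chi-square test, with
#' significance stars (*** p < 0.001, ** p < 0.01, * p < 0.05).
#'
#' @param data long descriptor table (`plant_id`, `genotype`, `day`,
#'   `parameter`, `value`).
#' @param control control genotype.
#' @param parameters descriptors to test (default: all present).
#' @param orders named integer overrides of [default_order()].
#' @return data.frame with one row per genotype x parameter.
#' @export
compare_genotypes <- function(data, control = "Col-0", parameters = NULL,
                              orders = NULL) {
  genos <- setdiff(unique(data$genotype), control)
  if (!control %in% data$genotype) stop("control genotype absent: ", control)
  if (is.null(parameters)) parameters <- unique(data$parameter)
  rows <- list()
  for (g in genos) {
    d <- data[data$genotype %in% c(control, g), , drop = FALSE]
    for (p in parameters) {
      ord <- if (!is.null(orders) && p %in% names(orders)) orders[[p]] else default_order(p)
      cmp <- tryCatch({
        m0 <- fit_growth_model(d, p, order = ord, with_genotype = FALSE, control = control)
        m1 <- fit_growth_model(d, p, order = ord, with_genotype = TRUE, control = control)
        compare_nested(m0, m1)
      }, error = function(e) {
        data.frame(parameter = p, polynomial_order = ord, chisq_stat = NA_real_,
                   df = NA_integer_, p_value = NA_real_, n_obs = NA_integer_,
                   stringsAsFactors = FALSE)
      })
      cmp$genotype <- g
      rows[[length(rows) + 1L]] <- as.data.frame(cmp)
    }
  }
  out <- do.call(rbind, rows)
  out$stars <- significance_stars(out$p_value)
  out[, c("genotype", "parameter", "polynomial_order", "chisq_stat", "df",
          "p_value", "stars", setdiff(names(out), c("genotype", "parameter",
          "polynomial_order", "chisq_stat", "df", "p_value", "stars")))]
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Flowering-time comparison with Dunnett adjustment
#'
#' One-way ANOVA of leaves at bolting (LAB) and days to bolting (DTB) with
#' many-to-one contrasts of every mutant against the control, adjusted with
#' the Dunnett procedure (multivariate-t critical points under the
#' equicorrelation implied by the shared control), family-wise alpha 0.05.
#'
#' @param table data.frame with columns `plant_id`, `genotype`, `LAB`, `DTB`.
#' @param control control genotype (must have >= 2 plants).
#' @param traits traits to analyse.
#' @param seed seed for the (quasi-random) multivariate-t integration.
#' @return data.frame with per genotype and trait: n, mean, sd, control mean
#'   and sd, Dunnett-adjusted p-value and significance mark.
#' @export
flowering_comparison <- function(table, control = "Col-0",
                                 traits = c("LAB", "DTB"), seed = 1L) {
  if (!control %in% table$genotype) stop("control genotype absent: ", control)
  if (sum(table$genotype == control) < 2L) stop("control needs >= 2 plants")
  if (length(unique(table$genotype)) < 2L) stop("need at least one mutant genotype")
  rows <- list()
  for (tr in traits) {
    d <- data.frame(genotype = stats::relevel(factor(table$genotype), ref = control),
                    y = table[[tr]])
    d <- d[is.finite(d$y), , drop = FALSE]
    fit <- stats::aov(y ~ genotype, data = d)
    gl <- with_fixed_seed(seed, {
      summary(multcomp::glht(fit, linfct = multcomp::mcp(genotype = "Dunnett")))
    })
    est <- gl$test$coefficients
    padj <- gl$test$pvalues
    genos <- sub(paste0(" - ", control, "$"), "", names(est))
    ctrl_y <- d$y[d$genotype == control]
    for (i in seq_along(genos)) {
      gy <- d$y[d$genotype == genos[i]]
      rows[[length(rows) + 1L]] <- data.frame(
        genotype = genos[i], trait = tr, n = length(gy),
        mean = mean(gy), sd = stats::sd(gy),
        control_mean = mean(ctrl_y), control_sd = stats::sd(ctrl_y),
        estimate = unname(est[i]), p_adj = unname(padj[i]),
        significant = unname(padj[i]) < 0.05, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Flower-defect proportions and two-proportion test
#'
#' Per-genotype percentage of affected flowers (displayed rounded half-up to
#' the nearest integer, raw fraction retained) and, for a two-genotype
#' table, Fisher's exact test with odds ratio.
#'
#' @param table data.frame with columns `genotype`, `n_affected`, `n_total`.
#' @return List with `proportions` (data.frame) and, for two genotypes,
#'   `fisher_p` and `odds_ratio`.
#' @examples
#' defect_proportions(data.frame(genotype = c("sinal7-2", "Col-0"),
#'                               n_affected = c(43, 6), n_total = c(80, 50)))
#' @export
defect_proportions <- function(table) {
  stopifnot(all(c("genotype", "n_affected", "n_total") %in% names(table)))
  if (any(table$n_total <= 0)) stop("n_total must be positive")
  if (any(table$n_affected < 0 | table$n_affected > table$n_total)) {
    stop("n_affected must lie in [0, n_total]")
  }
  frac <- table$n_affected / table$n_total
  props <- data.frame(genotype = table$genotype,
                      n_affected = table$n_affected, n_total = table$n_total,
                      fraction = frac,
                      percent = floor(100 * frac + 0.5),  # round half-up
                      stringsAsFactors = FALSE)
  out <- list(proportions = props)
  if (nrow(table) == 2L) {
    m <- rbind(c(table$n_affected[1L], table$n_total[1L] - table$n_affected[1L]),
               c(table$n_affected[2L], table$n_total[2L] - table$n_affected[2L]))
    ft <- stats::fisher.test(m)
    out$fisher_p <- ft$p.value
    out$odds_ratio <- unname(ft$estimate)
  }
  out
}
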