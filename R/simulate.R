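# Synthetic-data generators. Every generator is a pure function of its seed
# and parameters and emits a ground-truth record sufficient to score
# recovery exactly.

#' Parametric rosette model
#'
#' Describes a growing rosette: leaves emerge in opposite pairs (the first
#' two pairs decussate, 90 degrees apart), later leaves spiral at the
#' phyllotactic divergence angle (137.5 degrees by default). Each leaf
#' expands along a logistic curve from its emergence day; the blade is an
#' ellipse with optional margin serration carried on a petiole segment.
#' The oscillation of hull-based shape descriptors emerges from the paired
#' initiation cycle: each new pair makes the silhouette elliptical until the
#' pair expands and rounds it out again.
#'
#' @param seed RNG seed; the model (and all masks rendered from it) is a
#'   pure function of this seed.
#' @param first_pair_day day the first true-leaf pair emerges (cotyledons
#'   are modelled as pair 0 two days earlier).
#' @param leaf_interval days between successive leaf pairs.
#' @param divergence phyllotactic divergence angle, degrees.
#' @param blade_max0 asymptotic blade+petiole length of the first pair, mm.
#' @param blade_gain multiplicative length gain per successive pair.
#' @param blade_cap maximum asymptotic leaf length, mm.
#' @param expansion_rate logistic growth rate, 1/day.
#' @param expansion_lag days from emergence to half asymptotic size.
#' @param petiole_frac petiole length as a fraction of total leaf length.
#' @param blade_aspect blade width / blade length.
#' @param serration_depth relative amplitude of margin serration.
#' @param serration_freq serration bumps around the blade margin.
#' @param size_mult,timing_shift,serration_mult genotype effect multipliers:
#'   scale on leaf size, shift (days) of every emergence day, scale on
#'   serration depth.
#' @param n_pairs number of leaf pairs the plant can initiate.
#' @return Object of class `rosette_model` holding the per-leaf parameter
#'   table (emergence day, angle, asymptotic length).
#' @export
rosette_model <- function(seed = 1L, first_pair_day = 5, leaf_interval = 2,
                          divergence = 137.5, blade_max0 = 10,
                          blade_gain = 1.2, blade_cap = 24,
                          expansion_rate = 0.55, expansion_lag = 4.5,
                          petiole_frac = 0.3, blade_aspect = 0.7,
                          serration_depth = 0.05, serration_freq = 9,
                          size_mult = 1, timing_shift = 0,
                          serration_mult = 1, n_pairs = 6L) {
  leaves <- with_fixed_seed(seed, {
    theta0 <- stats::runif(1, 0, 360)
    rows <- list()
    angle_spiral <- theta0 + 90 + divergence
    for (k in 0:(n_pairs - 1L)) {
      emerge <- first_pair_day + k * leaf_interval + timing_shift
      lmax <- min(blade_max0 * blade_gain^k, blade_cap) * size_mult
      base_angle <- if (k == 0L) theta0 else if (k == 1L) theta0 + 90 else {
        angle_spiral <- angle_spiral + divergence
        angle_spiral
      }
      for (side in c(0, 180)) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair = k,
          emerge_day = emerge + stats::rnorm(1, 0, 0.15),
          angle = (base_angle + side + stats::rnorm(1, 0, 4)) %% 360,
          lmax = lmax * exp(stats::rnorm(1, 0, 0.06)))
      }
    }
    # cotyledon pair: small, round, early
    coty <- data.frame(pair = -1,
                       emerge_day = first_pair_day - 3 + timing_shift,
                       angle = (theta0 + 45 + c(0, 180)) %% 360,
                       lmax = 5.5 * size_mult)
    rbind(coty, do.call(rbind, rows))
  })
  structure(list(leaves = leaves, seed = seed,
                 expansion_rate = expansion_rate, expansion_lag = expansion_lag,
                 petiole_frac = petiole_frac, blade_aspect = blade_aspect,
                 serration_depth = serration_depth * serration_mult,
                 serration_freq = serration_freq,
                 params = list(first_pair_day = first_pair_day,
                               leaf_interval = leaf_interval,
                               divergence = divergence,
                               size_mult = size_mult,
                               timing_shift = timing_shift,
                               serration_mult = serration_mult)),
            class = "rosette_model")
}

leaf_length <- function(model, lmax, emerge_day, day) {
  ifelse(day < emerge_day, 0,
         lmax / (1 + exp(-model$expansion_rate * (day - emerge_day - model$expansion_lag))))
}

#' Render a rosette mask for one day
#'
#' Rasterizes every emerged leaf (petiole segment plus elliptical, optionally
#' serrated blade at its phyllotactic angle) into a hard-thresholded binary
#' mask with the plant centred in the frame. Masks are bit-reproducible for
#' a fixed model. If the rosette would overflow the frame the image is
#' enlarged automatically with a warning.
#'
#' @param model a [rosette_model()].
#' @param day days after stratification.
#' @param size_px image side length in pixels.
#' @param mm_per_px length scale.
#' @param plant_id identifier stored in the mask.
#' @return A [binary_mask()].
#' @export
render_rosette <- function(model, day, size_px = 400L, mm_per_px = 0.25,
                           plant_id = "synthetic") {
  lv <- model$leaves
  lens <- leaf_length(model, lv$lmax, lv$emerge_day, day)
  reach_mm <- max(lens) * (1 + model$serration_depth)
  half_mm <- size_px / 2 * mm_per_px
  if (reach_mm >= half_mm) {
    size_px <- as.integer(2 * ceiling(reach_mm / mm_per_px) + 10L)
    warning("rosette overflows frame; image resized to ", size_px, " px")
  }
  grid <- matrix(FALSE, size_px, size_px)
  c0 <- (size_px + 1) / 2
  for (i in seq_len(nrow(lv))) {
    if (lens[i] <= 0.3) next
    grid <- draw_leaf(grid, c0, c0, angle_deg = lv$angle[i],
                      total_mm = lens[i], mm_per_px = mm_per_px,
                      petiole_frac = model$petiole_frac,
                      aspect = model$blade_aspect,
                      ser_depth = model$serration_depth,
                      ser_freq = model$serration_freq)
  }
  binary_mask(grid, mm_per_px = mm_per_px, plant_id = plant_id, day = day)
}

draw_leaf <- function(grid, r0, c0, angle_deg, total_mm, mm_per_px,
                      petiole_frac, aspect, ser_depth, ser_freq) {
  phi <- angle_deg * pi / 180
  ux <- cos(phi); uy <- sin(phi)      # leaf axis direction in (r, c) plane
  total_px <- total_mm / mm_per_px
  pet_len <- petiole_frac * total_px
  blade_len <- total_px - pet_len
  a <- blade_len / 2
  b <- aspect * a
  bc_r <- r0 + (pet_len + a) * ux
  bc_c <- c0 + (pet_len + a) * uy
  pad <- max(a, b) * (1 + ser_depth) + 2
  rr <- max(1L, floor(min(bc_r - pad, r0))):min(nrow(grid), ceiling(max(bc_r + pad, r0)))
  cc <- max(1L, floor(min(bc_c - pad, c0))):min(ncol(grid), ceiling(max(bc_c + pad, c0)))
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  # blade: rotated ellipse with radial serration
  dr <- R - bc_r; dc <- C - bc_c
  u <- dr * ux + dc * uy
  v <- -dr * uy + dc * ux
  rho2 <- (u / a)^2 + (v / b)^2
  inside <- if (ser_depth > 0) {
    psi <- atan2(v / b, u / a)
    rho2 <= (1 + ser_depth * cos(ser_freq * psi))^2
  } else rho2 <= 1
  # petiole: capsule around the segment center -> blade base
  pw <- max(0.8 / mm_per_px, 1.5) / 2
  pr <- R - r0; pc <- C - c0
  t <- pmax(0, pmin(pet_len + 0.2 * a, pr * ux + pc * uy))
  dist2 <- (pr - t * ux)^2 + (pc - t * uy)^2
  inside <- inside | dist2 <= pw^2
  grid[rr, cc] <- grid[rr, cc] | inside
  grid
}

#' Render a daily mask series with ground truth
#'
#' @param model a [rosette_model()].
#' @param days vector of days to render.
#' @param size_px,mm_per_px,plant_id passed to [render_rosette()].
#' @return List with `masks` (list of [binary_mask()]) and `truth` (list:
#'   per-day true emerged leaf count, the leaf table, model parameters,
#'   seed).
#' @export
render_rosette_series <- function(model, days = 10:20, size_px = 400L,
                                  mm_per_px = 0.25, plant_id = "synthetic") {
  masks <- lapply(days, function(d) {
    render_rosette(model, d, size_px = size_px, mm_per_px = mm_per_px,
                   plant_id = plant_id)
  })
  leaf_count <- vapply(days, function(d) sum(model$leaves$emerge_day <= d), integer(1))
  list(masks = masks,
       truth = list(days = days, leaf_count = leaf_count,
                    leaves = model$leaves, params = model$params,
                    seed = model$seed))
}

#' Simulate a longitudinal descriptor dataset
#'
#' Plant-day values follow a genotype-specific quadratic mean curve plus iid
#' Gaussian noise: `baseline[1] + baseline[2]*(day - min(day)) +
#' baseline[3]*(day - min(day))^2`, shifted by the genotype's `intercept`
#' effect and tilted by its `slope` effect. The emitted truth records the
#' effects, so null and power simulations can be scored exactly.
#'
#' @param n_plants plants per genotype.
#' @param genotypes genotype labels; the first is the control.
#' @param effects named list (per non-control genotype) of
#'   `c(intercept =, slope =)` additive effects.
#' @param noise_sd Gaussian noise SD.
#' @param days measurement days.
#' @param parameter descriptor name stored in the table.
#' @param baseline quadratic mean-curve coefficients.
#' @param seed RNG seed.
#' @return List with `data` (long data.frame) and `truth`.
#' @export
simulate_longitudinal <- function(n_plants = 20L, genotypes = c("Col-0", "mutant"),
                                  effects = list(mutant = c(intercept = 0, slope = 0)),
                                  noise_sd = 1, days = 10:20,
                                  parameter = "area",
                                  baseline = c(5, 1.5, 0.35), seed = 1L) {
  stopifnot(n_plants >= 2L)
  control <- genotypes[1L]
  data <- with_fixed_seed(seed, {
    rows <- lapply(genotypes, function(g) {
      eff <- if (g == control) c(intercept = 0, slope = 0) else {
        e <- effects[[g]]
        c(intercept = unname(e["intercept"]), slope = unname(e["slope"]))
      }
      t0 <- days - min(days)
      mu <- baseline[1L] + baseline[2L] * t0 + baseline[3L] * t0^2 +
        eff[["intercept"]] + eff[["slope"]] * t0
      do.call(rbind, lapply(seq_len(n_plants), function(p) {
        data.frame(plant_id = sprintf("%s_%02d", g, p), genotype = g,
                   day = days, parameter = parameter,
                   value = mu + stats::rnorm(length(days), 0, noise_sd),
                   stringsAsFactors = FALSE)
      }))
    })
    do.call(rbind, rows)
  })
  rownames(data) <- NULL
  list(data = data,
       truth = list(effects = effects, noise_sd = noise_sd,
                    baseline = baseline, days = days,
                    n_plants = n_plants, seed = seed))
}

#' Simulate an expression matrix with planted up-regulated genes
#'
#' Reference-column expression is lognormal; in each category a planted
#' subset of genes is multiplied by a fold drawn strictly above 2, the rest
#' by a factor strictly below 2, so the 2-fold screen can recover the
#' planted sets exactly.
#'
#' @param n_genes number of genes.
#' @param categories category column names.
#' @param n_up planted up-regulated genes per category (recycled).
#' @param fold_range range of planted folds (must stay above 2).
#' @param reference reference column name.
#' @param seed RNG seed.
#' @return List with `matrix` (genes x (reference + categories)) and `truth`
#'   (planted gene ids per category).
#' @export
simulate_expression <- function(n_genes = 400L,
                                categories = c("bolting", "young_flower",
                                               "developed_flower", "flowers_siliques"),
                                n_up = 37L, fold_range = c(2.5, 8),
                                reference = "developed_rosette", seed = 1L) {
  stopifnot(all(n_up <= n_genes), fold_range[1L] > 2)
  n_up <- rep_len(n_up, length(categories))
  with_fixed_seed(seed, {
    genes <- sprintf("AT%dG%05d", sample(1:5, n_genes, TRUE),
                     sample.int(80000L, n_genes))
    genes <- make.unique(genes)
    ref <- stats::rlnorm(n_genes, meanlog = 6, sdlog = 1)
    mat <- matrix(0, n_genes, length(categories) + 1L,
                  dimnames = list(genes, c(reference, categories)))
    mat[, reference] <- ref
    planted <- list()
    for (i in seq_along(categories)) {
      up <- sample(genes, n_up[i])
      fold <- stats::runif(n_genes, 0.4, 1.9)
      fold[match(up, genes)] <- stats::runif(n_up[i], fold_range[1L], fold_range[2L])
      mat[, categories[i]] <- ref * fold
      planted[[categories[i]]] <- sort(up)
    }
    list(matrix = mat, truth = list(planted = planted, seed = seed))
  })
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Target Cts in the mutant sample are shifted by `-log2(fold)` relative to
#' the control; reference genes are equal in both samples. Technical
#' replicate noise is iid Gaussian on the cycle scale.
#'
#' @param targets named numeric vector of true fold changes per target gene.
#' @param references reference gene names.
#' @param replicate_sd technical replicate SD (cycles).
#' @param n_reps technical replicates.
#' @param base_ct baseline cycle number.
#' @param seed RNG seed.
#' @return List with `table` (Ct long table) and `truth`.
#' @export
simulate_ct <- function(targets = c(gene1 = 0.5),
                        references = c("TIP41-like", "AP2M", "PTB1"),
                        replicate_sd = 0, n_reps = 3L, base_ct = 24, seed = 1L) {
  stopifnot(all(targets > 0))
  with_fixed_seed(seed, {
    rows <- list()
    add <- function(sample, gene, role, mu) {
      rows[[length(rows) + 1L]] <<- data.frame(
        sample = sample, gene = gene, role = role, replicate = seq_len(n_reps),
        ct = mu + stats::rnorm(n_reps, 0, replicate_sd), stringsAsFactors = FALSE)
    }
    for (rg in references) {
      mu <- base_ct + stats::runif(1, -3, 3)
      add("control", rg, "reference", mu)
      add("mutant", rg, "reference", mu)
    }
    for (tg in names(targets)) {
      mu <- base_ct + stats::runif(1, -2, 4)
      add("control", tg, "target", mu)
      add("mutant", tg, "target", mu - log2(targets[[tg]]))
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    list(table = tab, truth = list(fold = targets, replicate_sd = replicate_sd,
                                   seed = seed))
  })
}

#' Plant canonical RING motifs into a toy proteome
#'
#' Generates background sequences over an alphabet free of the metal-ligand
#' residues (no C, H, D, S or T), so a planted motif is the only possible
#' canonical match and recovery can be scored exactly. Each planted domain
#' draws its gap lengths uniformly within the canonical spacing bounds and
#' sets metal positions 4/5 (and the full Cys set for C2) according to the
#' requested subtype. An InterProScan-style annotation table covering the
#' planted spans is emitted alongside.
#'
#' @param n_proteins number of proteins.
#' @param classes subtype labels to plant, recycled over the RING-bearing
#'   proteins; `NA` entries give motif-free background proteins.
#' @param frac_ring fraction of proteins that carry a motif (used when
#'   `classes` is NULL).
#' @param seq_len_range protein length range.
#' @param seed RNG seed.
#' @return List with `proteins` (named character vector),
#'   `annotations` (data.frame in parsed InterProScan layout) and `truth`
#'   (per-protein planted positions, residues and class).
#' @export
plant_ring_proteome <- function(n_proteins = 20L, classes = NULL,
                                frac_ring = 0.7,
                                seq_len_range = c(120L, 200L), seed = 1L) {
  background <- c("A", "E", "F", "G", "I", "K", "L", "M", "N", "P", "Q",
                  "R", "V", "W", "Y")
  class_residues <- list(
    "HC" = c("C", "C", "C", "H", "C", "C", "C", "C"),
    "H2" = c("C", "C", "C", "H", "H", "C", "C", "C"),
    "v" = c("C", "C", "C", "C", "H", "C", "C", "C"),
    "C2" = c("C", "C", "C", "C", "C", "C", "C", "C"),
    "D" = c("C", "C", "C", "D", "C", "C", "C", "C"),
    "S/T" = c("C", "C", "C", "S", "C", "C", "C", "C"))
  with_fixed_seed(seed, {
    if (is.null(classes)) {
      n_ring <- round(frac_ring * n_proteins)
      classes <- c(sample(names(class_residues), n_ring, TRUE),
                   rep(NA_character_, n_proteins - n_ring))
      classes <- sample(classes)
    } else {
      classes <- rep_len(classes, n_proteins)
    }
    gb <- ring_spacing()$gap_bounds
    proteins <- character(n_proteins)
    ids <- sprintf("AT%dG%05d.1", sample(1:5, n_proteins, TRUE),
                   sample.int(80000L, n_proteins))
    ids <- make.unique(ids, sep = "")
    truth <- list()
    ann <- list()
    for (i in seq_len(n_proteins)) {
      len <- sample(seq_len_range[1L]:seq_len_range[2L], 1L)
      seqv <- sample(background, len, TRUE)
      if (!is.na(classes[i])) {
        gaps <- vapply(seq_len(nrow(gb)), function(g) {
          gb[g, 1L] + sample.int(gb[g, 2L] - gb[g, 1L] + 1L, 1L) - 1L
        }, numeric(1))
        motif_len <- 8L + sum(gaps)
        start <- sample.int(max(1L, len - motif_len - 5L), 1L) + 2L
        pos <- start + c(0, cumsum(gaps + 1L))
        res <- class_residues[[classes[i]]]
        seqv[pos] <- res
        truth[[ids[i]]] <- list(class = classes[i], positions = pos,
                                residues = res)
        span_start <- max(1L, start - sample(0:5, 1L))
        span_end <- min(len, pos[8L] + sample(0:5, 1L))
        ann[[length(ann) + 1L]] <- data.frame(
          protein_id = ids[i],
          signature_db = sample(ring_signature_dbs(), 1L),
          signature_accession = "PF13639",
          start = span_start, end = span_end, known_db = TRUE,
          stringsAsFactors = FALSE)
      }
      proteins[i] <- paste(seqv, collapse = "")
    }
    names(proteins) <- ids
    list(proteins = proteins,
         annotations = if (length(ann)) do.call(rbind, ann) else NULL,
         truth = list(planted = truth, classes = classes, seed = seed))
  })
}
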