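# The nine rosette shape descriptors. Area and perimeter are in physical
# units (mm^2, mm); the remaining seven are dimensionless.

#' Descriptor formulas
#'
#' Scalar formulas for the shape descriptors:
#' * `roundness(A, P)` = \eqn{4\pi A / P^2}: area relative to a perfect
#'   circle of the same perimeter; 1 for a circle, clipped to (0, 1].
#' * `roundness2(hull_area, hull_perimeter)`: the same isoperimetric index
#'   evaluated on the convex hull.
#' * `compactness(A, hull_area)` = \eqn{A / A_h}: fraction of the hull the
#'   rosette fills; 1 for a convex silhouette.
#' * `sol(skeleton_length, A)` = \eqn{L^2 / A}: slenderness of leaves, the
#'   squared skeleton length over the area.
#' * `eccentricity_from_moments(mu20, mu02, mu11)`: eccentricity
#'   \eqn{\sqrt{1 - \lambda_2/\lambda_1}} of the ellipse with the same second
#'   central moments; 0 for a circle, approaching 1 for elongated shapes.
#'
#' Values of roundness and roundness2 marginally above 1 from raster
#' discretization are clipped to 1 (the `describe()` pipeline flags them).
#'
#' @param A region area.
#' @param P region perimeter.
#' @param clip clip results to a maximum of 1.
#' @return A single dimensionless value.
#' @export
roundness <- function(A, P, clip = TRUE) {
  if (!is.finite(A) || !is.finite(P) || A <= 0 || P <= 0) {
    stop("roundness needs positive finite area and perimeter")
  }
  v <- 4 * pi * A / P^2
  if (clip) min(v, 1) else v
}

#' @rdname roundness
#' @param hull_area,hull_perimeter convex hull area and perimeter.
#' @export
roundness2 <- function(hull_area, hull_perimeter, clip = TRUE) {
  roundness(hull_area, hull_perimeter, clip = clip)
}

#' @rdname roundness
#' @export
compactness <- function(A, hull_area) {
  if (!is.finite(hull_area) || hull_area <= 0) stop("hull area must be positive")
  if (!is.finite(A) || A <= 0) stop("area must be positive")
  min(A / hull_area, 1)
}

#' @rdname roundness
#' @param skeleton_length total skeleton length (same length unit as sqrt(A)).
#' @export
sol <- function(skeleton_length, A) {
  if (!is.finite(A) || A <= 0) stop("area must be positive")
  skeleton_length^2 / A
}

#' @rdname roundness
#' @param mu20,mu02,mu11 second central moments of the region.
#' @export
eccentricity_from_moments <- function(mu20, mu02, mu11) {
  tr <- mu20 + mu02
  if (tr <= 0) return(0)
  det <- mu20 * mu02 - mu11^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc
  l2 <- tr / 2 - disc
  if (l1 <= 0) return(0)
  sqrt(max(1 - l2 / l1, 0))
}

#' Eccentricity of a mask
#'
#' Moment-based eccentricity of the ellipse sharing the mask's second central
#' moments. A single-pixel (zero-variance) mask returns 0.
#'
#' @param mask a [binary_mask()].
#' @return Eccentricity in [0, 1).
#' @export
eccentricity <- function(mask) {
  mom <- mask_moments(mask)
  eccentricity_from_moments(mom$mu20, mom$mu02, mom$mu11)
}

#' Rotational mass symmetry (RMS)
#'
#' Ratio of the non-overlapping area between the convex hull and a disc of
#' equal area centered at the rosette centroid, to their overlapping area:
#' \eqn{\mathrm{area}(H \triangle D) / \mathrm{area}(H \cap D)}. 0 when the
#' hull is itself a centered disc; grows as the hull becomes asymmetric
#' around the centroid. Computed by exact polygon-disc clipping.
#'
#' @param hull_polygon n x 2 matrix of hull vertices.
#' @param centroid length-2 centroid in the same coordinates.
#' @return A non-negative number.
#' @export
rms <- function(hull_polygon, centroid) {
  a_h <- polygon_area(hull_polygon)
  if (!is.finite(a_h) || a_h <= 0) stop(degenerate_hull_error("zero-area hull"))
  r <- sqrt(a_h / pi)
  inter <- disc_polygon_intersection(hull_polygon, centroid, r)
  inter <- min(inter, a_h)
  if (inter <= 0) stop(degenerate_hull_error("hull and equal-area disc do not overlap"))
  2 * (a_h - inter) / inter
}

#' Isotropy of a leaf-tip polygon
#'
#' Circularity index \eqn{4\pi A / P^2} of the polygon connecting detected
#' leaf tips in angular order. With fewer than 3 detectable tips the convex
#' hull polygon is used instead and the result is flagged by `describe()`.
#'
#' @param tip_polygon n x 2 matrix of polygon vertices (n >= 3).
#' @return Isotropy value in (0, 1].
#' @export
isotropy <- function(tip_polygon) {
  if (is.null(tip_polygon) || nrow(tip_polygon) < 3L) {
    stop("isotropy needs a polygon with at least 3 vertices")
  }
  min(polygon_circularity(tip_polygon), 1)
}

#' All nine descriptors of one mask
#'
#' Computes the full descriptor set: area (mm^2), perimeter (mm), roundness,
#' roundness 2, isotropy, eccentricity, RMS, compactness and SOL, together
#' with QC flags. Smaller disconnected components are dropped before
#' measurement (flag `multi-component`); an empty mask yields all-NA values
#' with flag `empty-mask`; a degenerate hull (fewer than three non-collinear
#' pixels) yields NA for the hull-based descriptors.
#'
#' @param mask a [binary_mask()].
#' @param perimeter_method passed to [measure_area_perimeter()].
#' @return A one-row data.frame with columns `plant_id`, `day`, the nine
#'   descriptors, and `qc_flags` (comma-separated, empty when clean).
#' @examples
#' g <- matrix(FALSE, 60, 60)
#' xy <- expand.grid(r = 1:60, c = 1:60)
#' g[(xy$r - 30)^2 + (xy$c - 30)^2 <= 20^2] <- TRUE
#' describe(binary_mask(g, mm_per_px = 0.5))
#' @export
describe <- function(mask, perimeter_method = "contour") {
  stopifnot(inherits(mask, "binary_mask"))
  flags <- character(0)
  vals <- stats::setNames(rep(NA_real_, 9L),
                          c("area", "perimeter", "roundness", "roundness2",
                            "isotropy", "eccentricity", "rms", "compactness",
                            "sol"))
  if (mask_is_empty(mask)) {
    return(describe_row(mask, vals, c(flags, "empty-mask")))
  }
  lc <- largest_component(mask)
  if (lc$n_dropped > 0L) flags <- c(flags, "multi-component")
  m <- lc$mask
  ap <- measure_area_perimeter(m, method = perimeter_method)
  vals["area"] <- ap$area_mm2
  vals["perimeter"] <- ap$perimeter_mm
  rd <- roundness(ap$area_mm2, ap$perimeter_mm, clip = FALSE)
  if (rd > 1) flags <- c(flags, "clipped-roundness")
  vals["roundness"] <- min(rd, 1)
  mom <- mask_moments(m)
  vals["eccentricity"] <- eccentricity_from_moments(mom$mu20, mom$mu02, mom$mu11)
  skel_mm <- compute_skeleton_length(m)
  vals["sol"] <- sol(skel_mm, ap$area_mm2)
  hull <- tryCatch(compute_hull(m), phenoscreen_degenerate_hull = function(e) NULL)
  if (is.null(hull)) {
    flags <- c(flags, "degenerate-hull")
  } else {
    r2 <- roundness2(hull$hull_area, hull$hull_perimeter, clip = FALSE)
    if (r2 > 1) flags <- c(flags, "clipped-roundness2")
    vals["roundness2"] <- min(r2, 1)
    vals["compactness"] <- compactness(ap$area_mm2, hull$hull_area)
    centroid_mm <- mom$centroid * m$mm_per_px
    vals["rms"] <- rms(hull$hull_polygon, centroid_mm)
    tips <- detect_tips(m)
    if (is.null(tips)) {
      flags <- c(flags, "isotropy-hull-fallback")
      vals["isotropy"] <- isotropy(hull$hull_polygon)
    } else {
      vals["isotropy"] <- isotropy(tips * m$mm_per_px)
    }
  }
  describe_row(mask, vals, flags)
}

describe_row <- function(mask, vals, flags) {
  out <- data.frame(plant_id = mask$plant_id, day = mask$day,
                    t(vals), qc_flags = paste(flags, collapse = ","),
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Descriptors for a batch of masks
#'
#' Runs [describe()] over a metadata table and returns the long-format table
#' the growth statistics consume. Per-plant failures (missing file, empty
#' mask) quarantine that plant-day with a QC flag instead of aborting the
#' batch.
#'
#' @param metadata data.frame with columns `plant_id`, `genotype`, `day`,
#'   `path`, `mm_per_px` (and optionally `tray`).
#' @param perimeter_method passed to [describe()].
#' @return Long data.frame with columns `plant_id`, `genotype`, `day`,
#'   `parameter`, `value`, `qc_flags`.
#' @export
describe_series <- function(metadata, perimeter_method = "contour") {
  need <- c("plant_id", "genotype", "day", "path", "mm_per_px")
  if (!all(need %in% names(metadata))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(metadata)), function(i) {
    md <- metadata[i, ]
    ds <- tryCatch({
      mask <- read_mask(md$path, mm_per_px = md$mm_per_px,
                        plant_id = md$plant_id, day = md$day)
      describe(mask, perimeter_method = perimeter_method)
    }, error = function(e) {
      describe_row(binary_mask(matrix(FALSE, 1L, 1L), md$mm_per_px,
                               md$plant_id, md$day),
                   stats::setNames(rep(NA_real_, 9L), descriptor_names()),
                   paste0("failed:", conditionMessage(e)))
    })
    long <- data.frame(
      plant_id = md$plant_id, genotype = md$genotype, day = md$day,
      parameter = descriptor_names(),
      value = as.numeric(ds[1L, descriptor_names()]),
      qc_flags = ds$qc_flags, stringsAsFactors = FALSE
    )
    long
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

descriptor_names <- function() {
  c("area", "perimeter", "roundness", "roundness2", "isotropy",
    "eccentricity", "rms", "compactness", "sol")
}

#' Descriptors for an in-memory list of masks
#'
#' Like [describe_series()] but taking `binary_mask` objects directly,
#' e.g. from the synthetic renderer.
#'
#' @param masks list of [binary_mask()] objects.
#' @param genotype genotype label recycled over masks.
#' @param perimeter_method passed to [describe()].
#' @return Long data.frame as in [describe_series()].
#' @export
describe_masks <- function(masks, genotype = "Col-0", perimeter_method = "contour") {
  genotype <- rep_len(genotype, length(masks))
  rows <- lapply(seq_along(masks), function(i) {
    ds <- describe(masks[[i]], perimeter_method = perimeter_method)
    data.frame(plant_id = ds$plant_id, genotype = genotype[i], day = ds$day,
               parameter = descriptor_names(),
               value = as.numeric(ds[1L, descriptor_names()]),
               qc_flags = ds$qc_flags, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
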