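#' Binary rosette mask
#'
#' Container for one top-view binary silhouette of a single plant on a single
#' day. The grid is a logical matrix (rows x cols, origin top-left);
#' `mm_per_px` calibrates pixel units to millimetres. Foreground is treated as
#' 8-connected, background as 4-connected.
#'
#' @param grid logical (or 0/1 numeric) matrix; `TRUE`/nonzero is plant.
#' @param mm_per_px positive length scale, millimetres per pixel.
#' @param plant_id plant identifier (character).
#' @param day days after stratification (integer-ish scalar).
#' @return An object of class `binary_mask`.
#' @examples
#' m <- binary_mask(matrix(c(0, 1, 1, 0), 2, 2), mm_per_px = 0.5, plant_id = "p1", day = 10)
#' mask_is_empty(m)
#' @export
binary_mask <- function(grid, mm_per_px, plant_id = NA_character_, day = NA_integer_) {
  if (!is.matrix(grid)) stop("`grid` must be a matrix")
  if (!is.logical(grid)) {
    grid <- matrix(as.numeric(grid) > 0, nrow(grid), ncol(grid))
  }
  if (anyNA(grid)) stop("`grid` must not contain NA")
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1L || !is.finite(mm_per_px) ||
      mm_per_px <= 0) {
    stop("`mm_per_px` must be a single positive number")
  }
  structure(
    list(grid = grid, mm_per_px = as.numeric(mm_per_px),
         plant_id = as.character(plant_id), day = as.integer(day)),
    class = "binary_mask"
  )
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %.4g mm/px, plant %s, day %s, %d fg px\n",
              nrow(x$grid), ncol(x$grid), x$mm_per_px, x$plant_id,
              as.character(x$day), sum(x$grid)))
  invisible(x)
}

#' @rdname binary_mask
#' @param mask a `binary_mask`.
#' @export
mask_is_empty <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  !any(mask$grid)
}

# Structured condition for masks with no foreground: callers doing per-plant QC
# catch class "phenoscreen_empty_mask" instead of aborting a batch.
empty_mask_error <- function(mask) {
  structure(
    class = c("phenoscreen_empty_mask", "error", "condition"),
    list(message = sprintf("empty mask (no foreground pixels) for plant %s day %s",
                           mask$plant_id, as.character(mask$day)),
         call = sys.call(-1), plant_id = mask$plant_id, day = mask$day)
  )
}

degenerate_hull_error <- function(msg) {
  structure(class = c("phenoscreen_degenerate_hull", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}

stop_if_empty <- function(mask) {
  if (mask_is_empty(mask)) stop(empty_mask_error(mask))
  invisible(mask)
}

#' Read and write binary masks
#'
#' Masks are stored as single-channel PNG or TIFF with 0 = background and
#' 255 = foreground. On reading, any pixel above half intensity is foreground.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @param mm_per_px,plant_id,day passed to [binary_mask()].
#' @return `read_mask()` returns a `binary_mask`; `write_mask()` returns
#'   `path` invisibly.
#' @export
read_mask <- function(path, mm_per_px, plant_id = NA_character_, day = NA_integer_) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported mask format: ", ext)
  )
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  binary_mask(img > 0.5, mm_per_px = mm_per_px, plant_id = plant_id, day = day)
}

#' @rdname read_mask
#' @param mask a `binary_mask`.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- matrix(as.numeric(mask$grid), nrow(mask$grid), ncol(mask$grid))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path),
    stop("unsupported mask format: ", ext)
  )
  invisible(path)
}

#' Keep the largest 8-connected component
#'
#' The rosette is taken to be the largest 8-connected foreground component;
#' smaller components (soil specks, detached debris) are dropped and counted.
#'
#' @param mask a `binary_mask`.
#' @return A list with elements `mask` (cleaned `binary_mask`) and
#'   `n_dropped` (number of discarded components).
#' @export
largest_component <- function(mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask_is_empty(mask)) return(list(mask = mask, n_dropped = 0L))
  lab <- EBImage::bwlabel(matrix(as.numeric(mask$grid), nrow(mask$grid)))
  lab <- matrix(as.integer(lab), nrow(mask$grid))
  sizes <- tabulate(lab[lab > 0L])
  keep <- which.max(sizes)
  out <- mask
  out$grid <- lab == keep
  list(mask = out, n_dropped = length(sizes) - 1L)
}
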