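# Shared fixtures and independent oracles, built in code.

# --- raster shape builders -------------------------------------------------

raster_disc <- function(r, pad = 20, scale = 1) {
  n <- 2 * r + 2 * pad
  xy <- expand.grid(i = 1:n, j = 1:n)
  g <- matrix((xy$i - n / 2)^2 + (xy$j - n / 2)^2 <= r^2, n, n)
  binary_mask(g, scale)
}

raster_square <- function(s, pad = 10, scale = 1) {
  n <- s + 2 * pad
  g <- matrix(FALSE, n, n)
  g[(pad + 1):(pad + s), (pad + 1):(pad + s)] <- TRUE
  binary_mask(g, scale)
}

raster_ellipse <- function(a, b, pad = 20, scale = 1) {
  n <- 2 * max(a, b) + 2 * pad
  xy <- expand.grid(i = 1:n, j = 1:n)
  g <- matrix(((xy$j - n / 2) / a)^2 + ((xy$i - n / 2) / b)^2 <= 1, n, n)
  binary_mask(g, scale)
}

# union of k random discs around the image center; seeded and deterministic
random_blob <- function(seed, n = 96, k = 5) {
  set.seed(seed)
  g <- matrix(FALSE, n, n)
  xy <- expand.grid(i = 1:n, j = 1:n)
  for (b in seq_len(k)) {
    cx <- runif(1, n * 0.3, n * 0.7)
    cy <- runif(1, n * 0.3, n * 0.7)
    r <- runif(1, n * 0.06, n * 0.2)
    g <- g | matrix((xy$i - cy)^2 + (xy$j - cx)^2 <= r^2, n, n)
  }
  m <- binary_mask(g, 1)
  largest_component(m)$mask
}

# --- independent oracles ---------------------------------------------------

# boundary-walk perimeter: chain-code length of the ordered outer boundary
# (1 per orthogonal step, sqrt(2) per diagonal step)
chain_walk_perimeter <- function(mask) {
  pts <- phenoscreen:::mask_contour(mask$grid)
  d <- pts - pts[c(2:nrow(pts), 1), , drop = FALSE]
  sum(sqrt(rowSums(d^2)))
}

# grid-sampling oracle for the hull-vs-equal-area-disc overlap (RMS)
rms_grid_oracle <- function(poly, centroid, n_grid = 1500) {
  a_h <- polygon_area(poly)
  r <- sqrt(a_h / pi)
  lo <- pmin(apply(poly, 2, min), centroid - r)
  hi <- pmax(apply(poly, 2, max), centroid + r)
  xs <- seq(lo[1], hi[1], length.out = n_grid)
  ys <- seq(lo[2], hi[2], length.out = n_grid)
  cell <- diff(xs[1:2]) * diff(ys[1:2])
  X <- matrix(xs, n_grid, n_grid)
  Y <- matrix(ys, n_grid, n_grid, byrow = TRUE)
  in_disc <- (X - centroid[1])^2 + (Y - centroid[2])^2 <= r^2
  # convex polygon membership: consistently non-negative cross products
  if (phenoscreen:::polygon_signed_area(poly) < 0) poly <- poly[nrow(poly):1, ]
  in_poly <- matrix(TRUE, n_grid, n_grid)
  np <- nrow(poly)
  for (i in seq_len(np)) {
    a <- poly[i, ]; b <- poly[if (i == np) 1 else i + 1, ]
    in_poly <- in_poly & ((b[1] - a[1]) * (Y - a[2]) - (b[2] - a[2]) * (X - a[1]) >= 0)
  }
  inter <- sum(in_poly & in_disc) * cell
  2 * (a_h - inter) / inter
}

# brute-force enumeration oracle for the RING ligand pattern: enumerates all
# 8-tuples satisfying the spacing bounds, then applies the leftmost-longest
# tie-break (min start, max end, then left-to-right greedy interior)
ring_oracle <- function(seqc, spacing = ring_spacing()) {
  ch <- strsplit(toupper(seqc), "")[[1]]
  n <- length(ch)
  gb <- spacing$gap_bounds
  isC <- ch == "C"
  is45 <- ch %in% c("C", "H", "D", "S", "T")
  rng <- function(lo, hi) if (hi < lo) integer(0) else lo:hi
  for (p1 in which(isC)) {
    p2 <- p1 + gb[1, 1] + 1
    if (p2 > n || !isC[p2]) next
    tuples <- list()
    for (p3 in rng(p2 + gb[2, 1] + 1, min(p2 + gb[2, 2] + 1, n))) {
      if (!isC[p3]) next
      for (p4 in rng(p3 + gb[3, 1] + 1, min(p3 + gb[3, 2] + 1, n))) {
        if (!is45[p4]) next
        for (p5 in rng(p4 + gb[4, 1] + 1, min(p4 + gb[4, 2] + 1, n))) {
          if (!is45[p5]) next
          p6 <- p5 + gb[5, 1] + 1
          if (p6 > n || !isC[p6]) next
          for (p7 in rng(p6 + gb[6, 1] + 1, min(p6 + gb[6, 2] + 1, n))) {
            if (!isC[p7]) next
            p8 <- p7 + gb[7, 1] + 1
            if (p8 > n || !isC[p8]) next
            tuples[[length(tuples) + 1]] <- c(p1, p2, p3, p4, p5, p6, p7, p8)
          }
        }
      }
    }
    if (length(tuples)) {
      m <- do.call(rbind, tuples)
      m <- m[m[, 8] == max(m[, 8]), , drop = FALSE]
      for (col in 3:7) m <- m[m[, col] == max(m[, col]), , drop = FALSE]
      return(as.integer(m[1, ]))
    }
  }
  NULL
}

# independent rule-table oracle for RING subtype classification, hand-coded
# (does not read the package's CSV)
ring_class_oracle <- function(res) {
  if (res[4] == "H" && res[5] == "C") return("HC")
  if (res[4] == "H" && res[5] == "H") return("H2")
  if (res[4] == "C" && res[5] == "H") return("v")
  if (all(res == "C")) return("C2")
  if (any(res == "D")) return("D")
  if (any(res %in% c("S", "T"))) return("S/T")
  if (any(res == "G")) return("G")
  "non-canonical"
}

# random amino-acid sequence enriched in metal-ligand residues so that the
# spacing pattern has a realistic chance of matching
random_ringish_seq <- function(seed, len) {
  set.seed(seed)
  aa <- c("A", "C", "H", "D", "S", "T", "G", "L", "V", "E", "K", "R", "P")
  w <- c(2, 4, 1.5, 1, 1, 1, 1, 2, 2, 2, 2, 2, 1)
  paste(sample(aa, len, TRUE, prob = w), collapse = "")
}
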