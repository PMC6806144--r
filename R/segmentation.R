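#' Relative red-blue chromatic map
#'
#' Per-pixel (R - B) / max(B, 1). Lychee rind is strongly red-dominant while
#' foliage and sky have R approximately equal to B, so this ratio separates
#' fruit from background and, being a ratio, is largely invariant to global
#' illumination gain. The max(B, 1) guard keeps the map finite at B = 0.
#'
#' @param img RGB image array
#' @return numeric matrix, finite everywhere, negatives permitted
#' @export
chromatic_map <- function(img) {
  assert_rgb_image(img)
  (img[, , 1] - img[, , 3]) / pmax(img[, , 3], 1)
}

#' Otsu threshold of a real-valued map
#'
#' The map is quantized to 256 equal-width bins over its range; the threshold
#' maximizes the between-class variance of the quantized histogram. Ties take
#' the first (lowest) maximizing cut.
#'
#' @param map numeric matrix
#' @return list with `threshold` (value in map units, upper edge of the
#'   chosen bin), `mask` (logical matrix, `value > threshold`), and `bin`
#'   (0-based index of the chosen cut)
#' @export
otsu_threshold <- function(map) {
  v <- as.vector(map)
  if (anyNA(v) || any(!is.finite(v))) stop("map must be finite")
  mn <- min(v); mx <- max(v)
  if (mx == mn) stop("constant map: no threshold exists")
  q <- pmin(floor((v - mn) / (mx - mn) * 256), 255)
  h <- as.numeric(tabulate(q + 1L, nbins = 256))
  n <- length(v)
  w0 <- cumsum(h)
  mu <- cumsum(h * (0:255))
  mu_t <- mu[256]
  # between-class variance for cut after bin k (k = 0..254, 0-based)
  w0k <- w0[1:255]; muk <- mu[1:255]
  valid <- w0k > 0 & w0k < n
  bcv <- rep(-Inf, 255)
  bcv[valid] <- (mu_t * w0k[valid] / n - muk[valid])^2 /
    (w0k[valid] / n * (1 - w0k[valid] / n))
  k <- which.max(bcv) - 1L # 0-based bin index of the last "low" bin
  mask <- matrix(q > k, nrow(map), ncol(map))
  list(threshold = mn + (k + 1) * (mx - mn) / 256, mask = mask, bin = k)
}

# Disk structuring element offsets for radius r (r = 0 -> centre only).
disk_offsets <- function(r) {
  r <- as.integer(r)
  if (r <= 0) return(matrix(0L, 1, 2))
  d <- -r:r
  g <- expand.grid(dr = d, dc = d)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE])
}

#' Morphological cleanup of a binary mask
#'
#' Erosion then dilation with disk structuring elements (an opening when the
#' radii match), followed by hole filling: background is flood-filled
#' 4-connected from the border and unreachable background becomes foreground.
#' Every component of the result is simply connected.
#'
#' @param mask logical matrix
#' @param erode_r,dilate_r disk radii in px (>= 0)
#' @return cleaned logical matrix
#' @export
morph_clean <- function(mask, erode_r = 3, dilate_r = 3) {
  assert_mask(mask)
  if (erode_r < 0 || dilate_r < 0) stop("radii must be >= 0")
  out <- mask
  if (erode_r > 0) out <- cpp_binary_morph(out, disk_offsets(erode_r), TRUE)
  if (dilate_r > 0) out <- cpp_binary_morph(out, disk_offsets(dilate_r), FALSE)
  cpp_fill_holes(out)
}

#' Extract connected foreground regions
#'
#' 8-connected components of the mask, each reported with its pixel count,
#' first-moment centroid and outer boundary traced as an ordered closed
#' contour (Moore neighbour tracing). Components touching the image border
#' are retained.
#'
#' @param mask logical matrix (typically the output of [morph_clean()])
#' @return list of regions; each region is a list with `label`, `area`,
#'   `centroid` (x, y, 0-based sub-pixel), `bbox` (x0, y0, x1, y1 inclusive,
#'   0-based), `mask` (cropped to the bbox) and `boundary` (n x 2 matrix of
#'   x, y in full-image coordinates)
#' @export
extract_regions <- function(mask) {
  assert_mask(mask)
  lab <- cpp_label_components(mask, 8L)
  n <- max(lab)
  if (n == 0) return(list())
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  out <- vector("list", n)
  for (k in seq_len(n)) {
    pix <- idx[labs == k, , drop = FALSE] # (row, col) 1-based
    rows <- pix[, 1]; cols <- pix[, 2]
    r0 <- min(rows); r1 <- max(rows); c0 <- min(cols); c1 <- max(cols)
    sub <- lab[r0:r1, c0:c1, drop = FALSE] == k
    # topmost then leftmost pixel for the boundary trace start
    top <- min(rows)
    sc <- min(cols[rows == top])
    bnd <- cpp_trace_boundary(mask & (lab == k), top - 1L, sc - 1L)
    boundary <- cbind(x = bnd[, 2], y = bnd[, 1])
    out[[k]] <- structure(list(
      label = k,
      area = nrow(pix),
      centroid = c(x = mean(cols - 1), y = mean(rows - 1)),
      bbox = c(x0 = c0 - 1, y0 = r0 - 1, x1 = c1 - 1, y1 = r1 - 1),
      mask = sub,
      boundary = boundary
    ), class = "lychee_region")
  }
  out
}

#' One-call foreground segmentation
#'
#' Chromatic map, Otsu threshold, morphological cleanup and region
#' extraction in sequence; the standard entry into the detection pipeline.
#'
#' @inheritParams chromatic_map
#' @inheritParams morph_clean
#' @return list with `map`, `threshold`, `mask` (cleaned) and `regions`
#' @export
segment_foreground <- function(img, erode_r = 3, dilate_r = 3) {
  m <- chromatic_map(img)
  ot <- otsu_threshold(m)
  cleaned <- morph_clean(ot$mask, erode_r, dilate_r)
  list(map = m, threshold = ot$threshold, mask = cleaned,
       regions = extract_regions(cleaned))
}

# Build a full-size logical mask from a region's cropped bbox mask.
region_full_mask <- function(region, height = NULL, width = NULL) {
  bb <- region$bbox
  h <- if (is.null(height)) bb[["y1"]] + 1 else height
  w <- if (is.null(width)) bb[["x1"]] + 1 else width
  m <- matrix(FALSE, h, w)
  m[(bb[["y0"]] + 1):(bb[["y1"]] + 1), (bb[["x0"]] + 1):(bb[["x1"]] + 1)] <- region$mask
  m
}

# Construct a region object directly from a full-size mask containing a
# single connected component (used heavily by tests and the generators).
region_from_mask <- function(mask) {
  regs <- extract_regions(mask)
  if (length(regs) != 1) stop("mask does not contain exactly one component")
  regs[[1]]
}
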