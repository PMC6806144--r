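#' CLAHE parameters
#'
#' Contrast-limited adaptive histogram equalization is controlled by two
#' parameters: the tile grid dimension (`blocks` x `blocks`) and the clip
#' limit expressed as a fraction of the tile pixel count. The package
#' defaults, blocks = 10 and clip_limit = 0.015, are the combination that
#' maximizes the mean segmentation overlap rate in the grid search.
#'
#' @param blocks tiles per side (>= 1)
#' @param clip_limit clip limit as a fraction of tile pixel count, in (0, 1]
#' @return list of class `clahe_params`
#' @export
clahe_params <- function(blocks = 10, clip_limit = 0.015) {
  if (!is.numeric(blocks) || blocks < 1) stop("blocks must be >= 1")
  if (!is.numeric(clip_limit) || clip_limit <= 0 || clip_limit > 1)
    stop("clip_limit must lie in (0, 1]")
  structure(list(blocks = as.integer(blocks), clip_limit = clip_limit),
            class = "clahe_params")
}

# Clip a 256-bin histogram at clip_count and redistribute the excess evenly
# over all bins (single-pass redistribution; counts become fractional).
clip_histogram <- function(hist, clip_count) {
  excess <- sum(pmax(hist - clip_count, 0))
  pmin(hist, clip_count) + excess / length(hist)
}

# Per-tile equalization mapping from a (possibly clipped) histogram:
# m(v) = round(255 * cdf(v) / N).
tile_mapping <- function(hist) {
  round(255 * cumsum(hist) / sum(hist))
}

# CLAHE on one integer channel matrix (values 0..255). Pads by edge
# replication so the tile grid is exact, applies per-tile clipped
# equalization, and bilinearly interpolates between the four surrounding
# tile mappings for every pixel.
clahe_channel <- function(v, blocks, clip_limit) {
  H <- nrow(v); W <- ncol(v)
  b <- as.integer(blocks)
  th <- ceiling(H / b); tw <- ceiling(W / b)
  H2 <- th * b; W2 <- tw * b
  vp <- v[pmin(seq_len(H2), H), pmin(seq_len(W2), W), drop = FALSE]
  n_tile <- th * tw
  clip_count <- clip_limit * n_tile
  maps <- array(0, c(b, b, 256))
  for (ti in seq_len(b)) {
    rows <- ((ti - 1) * th + 1):(ti * th)
    for (tj in seq_len(b)) {
      cols <- ((tj - 1) * tw + 1):(tj * tw)
      hist <- tabulate(vp[rows, cols] + 1L, nbins = 256)
      maps[ti, tj, ] <- tile_mapping(clip_histogram(hist, clip_count))
    }
  }
  # bilinear interpolation between tile-centre mappings
  py <- (row(vp) - 0.5) / th + 0.5   # fractional tile coordinate, 1-based centres
  px <- (col(vp) - 0.5) / tw + 0.5
  i0 <- pmax(pmin(floor(py), b), 1); i1 <- pmin(i0 + 1, b)
  j0 <- pmax(pmin(floor(px), b), 1); j1 <- pmin(j0 + 1, b)
  wy <- pmax(pmin(py - i0, 1), 0)
  wx <- pmax(pmin(px - j0, 1), 0)
  look <- function(ti, tj) maps[cbind(as.vector(ti), as.vector(tj), as.vector(vp) + 1)]
  out <- (1 - wy) * (1 - wx) * look(i0, j0) + (1 - wy) * wx * look(i0, j1) +
    wy * (1 - wx) * look(i1, j0) + wy * wx * look(i1, j1)
  out <- matrix(out, H2, W2)
  pmax(pmin(round(out[seq_len(H), seq_len(W), drop = FALSE]), 255), 0)
}

#' Illumination compensation by CLAHE on the HSV value channel
#'
#' Converts the image to HSV, equalizes only the V channel with
#' contrast-limited adaptive histogram equalization, and converts back.
#' Hue and saturation are carried through untouched, so chromatic content is
#' preserved up to the integer round trip.
#'
#' @param img RGB image array (H x W x 3, intensities 0-255)
#' @param params a [clahe_params()] object
#' @return compensated RGB image of identical shape
#' @export
clahe_compensate <- function(img, params = clahe_params()) {
  assert_rgb_image(img)
  if (!inherits(params, "clahe_params")) params <- do.call(clahe_params, params)
  hsv <- rgb_to_hsv_img(img)
  v8 <- pmax(pmin(round(hsv$v * 255), 255), 0)
  v2 <- clahe_channel(v8, params$blocks, params$clip_limit)
  hsv_to_rgb_img(hsv$h, hsv$s, v2 / 255)
}

#' Relative overlap rate between two binary masks
#'
#' The Jaccard index |A n B| / |A u B| used to score CLAHE parameter
#' combinations against hand-segmented references.
#'
#' @param mask_a,mask_b logical matrices of identical shape
#' @return fraction in \[0, 1\]
#' @export
overlap_rate <- function(mask_a, mask_b) {
  assert_mask(mask_a); assert_mask(mask_b)
  if (!identical(dim(mask_a), dim(mask_b))) stop("mask shapes differ")
  u <- sum(mask_a | mask_b)
  if (u == 0) stop("overlap rate undefined: both masks are empty")
  sum(mask_a & mask_b) / u
}

#' Grid search of CLAHE parameters by mean segmentation overlap rate
#'
#' For every parameter combination, runs CLAHE compensation followed by the
#' chromatic segmentation pipeline on each image and scores the resulting
#' foreground mask against the paired reference mask with [overlap_rate()].
#' Ties on the mean rate are broken toward smaller `blocks`, then smaller
#' `clip_limit`.
#'
#' @param images list of RGB image arrays
#' @param refs list of reference logical masks, paired with `images`
#' @param grid list of [clahe_params()] objects
#' @param erode_r,dilate_r morphology radii forwarded to [morph_clean()]
#' @return list with `table` (data.frame blocks, clip_limit, mean_rate) and
#'   `best`, the winning `clahe_params`
#' @export
parameter_grid_search <- function(images, refs, grid, erode_r = 3, dilate_r = 3) {
  if (length(grid) == 0) stop("empty parameter grid")
  if (length(images) != length(refs)) stop("images and reference masks must be paired")
  rows <- lapply(grid, function(p) {
    if (!inherits(p, "clahe_params")) p <- do.call(clahe_params, p)
    rates <- vapply(seq_along(images), function(i) {
      seg <- segment_foreground(clahe_compensate(images[[i]], p),
                                erode_r = erode_r, dilate_r = dilate_r)
      overlap_rate(seg$mask, refs[[i]])
    }, numeric(1))
    data.frame(blocks = p$blocks, clip_limit = p$clip_limit, mean_rate = mean(rates))
  })
  tab <- do.call(rbind, rows)
  ord <- order(-tab$mean_rate, tab$blocks, tab$clip_limit)
  best <- tab[ord[1], ]
  list(table = tab, best = clahe_params(best$blocks, best$clip_limit))
}
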