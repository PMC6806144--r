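# Uniform LBP(8,1) lookup: codes whose circular 8-bit string has at most two
# 0/1 transitions get their own bin (58 of them); the rest pool into bin 59.
lbp_uniform_table <- local({
  tab <- NULL
  function() {
    if (is.null(tab)) {
      codes <- 0:255
      bits <- sapply(codes, function(v) as.integer(intToBits(v)[1:8]))
      trans <- colSums(bits != bits[c(2:8, 1), ])
      uniform <- codes[trans <= 2]
      map <- rep(59L, 256)
      map[uniform + 1] <- seq_along(uniform) # uniform codes ascending -> bins 1..58
      tab <<- list(map = map, uniform = uniform)
    }
    tab
  }
})

#' Uniform local binary pattern histogram
#'
#' 8-neighbour, radius-1 LBP codes over all interior pixels: bit k is set
#' when the k-th neighbour (circular order starting north-west, clockwise)
#' is greater than or equal to the centre. Codes whose circular bit string
#' has at most two transitions are uniform and map to 58 distinct bins; all
#' other codes pool into a 59th bin. The histogram is returned normalized.
#'
#' @param patch numeric grayscale matrix, at least 3 x 3
#' @param normalize return a probability histogram (default) or raw counts
#' @return numeric vector of length 59 with attribute `normalized`
#' @export
uniform_lbp <- function(patch, normalize = TRUE) {
  if (!is.matrix(patch) || nrow(patch) < 3 || ncol(patch) < 3)
    stop("patch must be a matrix of at least 3 x 3")
  h <- nrow(patch); w <- ncol(patch)
  ctr <- patch[2:(h - 1), 2:(w - 1)]
  off <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, 1),
              c(1, 1), c(1, 0), c(1, -1), c(0, -1)) # circular, clockwise
  code <- matrix(0L, h - 2, w - 2)
  for (k in seq_along(off)) {
    nb <- patch[2:(h - 1) + off[[k]][1], 2:(w - 1) + off[[k]][2]]
    code <- code + as.integer(nb >= ctr) * 2L^(k - 1)
  }
  map <- lbp_uniform_table()$map
  hist <- tabulate(map[code + 1L], nbins = 59)
  if (normalize) hist <- hist / sum(hist)
  structure(as.numeric(hist), normalized = normalize)
}

#' Histogram intersection kernel
#'
#' K(F1, F2) = sum over bins of min(F1, F2); a positive-definite kernel for
#' histogram features. Equals 1 exactly when two normalized histograms are
#' identical.
#'
#' @param f1,f2 numeric histograms of equal length
#' @return non-negative similarity
#' @export
hik <- function(f1, f2) {
  if (length(f1) != length(f2)) stop("histogram lengths differ")
  sum(pmin(f1, f2))
}

# HIK Gram matrix between rows of X (n x d) and rows of Y (m x d).
hik_gram <- function(X, Y = X) {
  n <- nrow(X); m <- nrow(Y)
  K <- matrix(0, n, m)
  for (l in seq_len(ncol(X))) K <- K + pmin(outer(X[, l], rep(1, m)),
                                            outer(rep(1, n), Y[, l]))
  K
}

#' Extract a grayscale patch for a detection circle
#'
#' Crops the circle's bounding square (clamped to the image), converts to
#' grayscale and resamples bilinearly to `out_size` x `out_size`.
#'
#' @param img RGB image array
#' @param circ a [circle()] or a one-row data.frame with cx, cy, r
#' @param out_size output side length in px
#' @return numeric matrix `out_size` x `out_size` in \[0, 255\]
#' @export
extract_patch <- function(img, circ, out_size = 32) {
  assert_rgb_image(img)
  cd <- as_circle_df(circ)
  cx <- cd$cx[1]; cy <- cd$cy[1]; r <- cd$r[1]
  h <- dim(img)[1]; w <- dim(img)[2]
  if (cx + r < 0 || cx - r > w - 1 || cy + r < 0 || cy - r > h - 1)
    stop("circle lies fully outside the image")
  x0 <- max(0, floor(cx - r)); x1 <- min(w - 1, ceiling(cx + r))
  y0 <- max(0, floor(cy - r)); y1 <- min(h - 1, ceiling(cy + r))
  g <- to_grayscale(img)[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  bilinear_resize(g, out_size, out_size)
}

# Bilinear resize of a numeric matrix to nh x nw.
bilinear_resize <- function(m, nh, nw) {
  h <- nrow(m); w <- ncol(m)
  if (h == nh && w == nw) return(m)
  ys <- (seq_len(nh) - 0.5) * h / nh + 0.5 # source coordinates, 1-based
  xs <- (seq_len(nw) - 0.5) * w / nw + 0.5
  y0 <- pmax(pmin(floor(ys), h), 1); y1 <- pmin(y0 + 1, h)
  x0 <- pmax(pmin(floor(xs), w), 1); x1 <- pmin(x0 + 1, w)
  wy <- pmax(pmin(ys - y0, 1), 0); wx <- pmax(pmin(xs - x0, 1), 0)
  m00 <- m[y0, x0, drop = FALSE]; m01 <- m[y0, x1, drop = FALSE]
  m10 <- m[y1, x0, drop = FALSE]; m11 <- m[y1, x1, drop = FALSE]
  WY <- matrix(wy, nh, nw); WX <- matrix(wx, nh, nw, byrow = TRUE)
  (1 - WY) * (1 - WX) * m00 + (1 - WY) * WX * m01 +
    WY * (1 - WX) * m10 + WY * WX * m11
}

#' Pixel-size gate for candidate regions
#'
#' Keeps regions whose pixel area lies in \[lo, hi\] (bounds inclusive);
#' the working gate is 800-1700 px at the imaging scale of the method.
#'
#' @param regions list of regions (anything with an `area` field)
#' @param lo,hi inclusive area bounds in px, `lo < hi`
#' @return the retained sub-list
#' @export
size_gate <- function(regions, lo = 800, hi = 1700) {
  if (lo >= hi) stop("lo must be below hi")
  Filter(function(r) r$area >= lo && r$area <= hi, regions)
}
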