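#' RGB image container and plain-text netpbm I/O
#'
#' Images are plain numeric arrays of dimension height x width x 3 with
#' integer intensities in \[0, 255\]. Masks are logical matrices of the same
#' height/width. Pixel coordinates are 0-based with x = column and y = row.
#'
#' @param pixels array H x W x 3 of intensities in \[0, 255\]
#' @return validated image array
#' @export
rgb_image <- function(pixels) {
  assert_rgb_image(pixels)
  pixels
}

assert_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3 || dim(img)[3] != 3)
    stop("image must be an H x W x 3 array")
  d <- dim(img)
  if (d[1] < 1 || d[2] < 1) stop("degenerate image: height and width must be >= 1")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("image intensities must lie in [0, 255]")
  invisible(img)
}

assert_mask <- function(mask) {
  if (!is.matrix(mask) || !is.logical(mask)) stop("mask must be a logical matrix")
  invisible(mask)
}

#' Convert RGB to HSV (hexcone model)
#'
#' V = max(R, G, B); all components returned in \[0, 1\]. Vectorized over the
#' whole image.
#'
#' @param img RGB image array (0-255)
#' @return list of matrices `h`, `s`, `v`
#' @export
rgb_to_hsv_img <- function(img) {
  assert_rgb_image(img)
  r <- img[, , 1] / 255; g <- img[, , 2] / 255; b <- img[, , 3] / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- matrix(0, nrow(r), ncol(r))
  nz <- d > 0
  # sector selection: which channel attains the max
  rmax <- nz & (mx == r)
  gmax <- nz & (mx == g) & !rmax
  bmax <- nz & !rmax & !gmax
  h[rmax] <- ((g[rmax] - b[rmax]) / d[rmax]) %% 6
  h[gmax] <- (b[gmax] - r[gmax]) / d[gmax] + 2
  h[bmax] <- (r[bmax] - g[bmax]) / d[bmax] + 4
  h <- h / 6
  s <- matrix(0, nrow(r), ncol(r))
  pos <- mx > 0
  s[pos] <- d[pos] / mx[pos]
  list(h = h, s = s, v = mx)
}

#' Convert HSV back to an RGB image
#'
#' @param h,s,v matrices in \[0, 1\]
#' @return RGB image array with intensities rounded to integers in \[0, 255\]
#' @export
hsv_to_rgb_img <- function(h, s, v) {
  hh <- (h %% 1) * 6
  i <- floor(hh)
  f <- hh - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  # sector table: (r, g, b) per i in 0..5
  r <- v; g <- v; b <- v
  sel <- function(k) i == k
  r[sel(1)] <- q[sel(1)]; r[sel(2)] <- p[sel(2)]
  r[sel(3)] <- p[sel(3)]; r[sel(4)] <- t[sel(4)] # i = 0, 5 keep r = v
  g[sel(0)] <- t[sel(0)]; g[sel(3)] <- q[sel(3)]
  g[sel(4)] <- p[sel(4)]; g[sel(5)] <- p[sel(5)] # i = 1, 2 keep g = v
  b[sel(0)] <- p[sel(0)]; b[sel(1)] <- p[sel(1)]
  b[sel(2)] <- t[sel(2)]; b[sel(5)] <- q[sel(5)] # i = 3, 4 keep b = v
  out <- array(0, c(nrow(r), ncol(r), 3))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  pmax(pmin(round(out * 255), 255), 0)
}

#' Convert an RGB image to grayscale
#'
#' Rec. 601 luma weights (0.299, 0.587, 0.114).
#'
#' @param img RGB image array
#' @return numeric matrix in \[0, 255\]
#' @export
to_grayscale <- function(img) {
  assert_rgb_image(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Read and write plain (ASCII) netpbm images
#'
#' Colour images use P3 (PPM), masks use P2 (PGM) with 0/255 levels. These
#' text formats keep every fixture and artifact human-readable; no binary
#' image codec is required at run time.
#'
#' @param path file path
#' @return `read_ppm`: an RGB image array; `read_mask_pgm`: a logical matrix
#' @export
read_ppm <- function(path) {
  tok <- scan_pnm_tokens(path, "P3")
  w <- tok[1]; h <- tok[2]; mx <- tok[3]
  px <- tok[-(1:3)]
  if (length(px) != 3 * w * h) stop("corrupt PPM: wrong pixel count")
  arr <- array(0, c(h, w, 3))
  m <- matrix(px, nrow = 3) # channels fastest, row-major pixel order
  for (ch in 1:3) arr[, , ch] <- matrix(m[ch, ], nrow = h, byrow = TRUE)
  if (mx != 255) arr <- round(arr / mx * 255)
  arr
}

#' @rdname read_ppm
#' @param img RGB image array to write
#' @export
write_ppm <- function(img, path) {
  assert_rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- as.integer(round(aperm(img, c(3, 2, 1)))) # channel, col, row -> row-major triples
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P3", paste(w, h), "255"), con)
  write(px, file = con, ncolumns = 15)
  invisible(path)
}

#' @rdname read_ppm
#' @export
read_mask_pgm <- function(path) {
  tok <- scan_pnm_tokens(path, "P2")
  w <- tok[1]; h <- tok[2]
  px <- tok[-(1:3)]
  if (length(px) != w * h) stop("corrupt PGM: wrong pixel count")
  matrix(px, nrow = h, byrow = TRUE) > 0
}

#' @rdname read_ppm
#' @param mask logical matrix to write (TRUE -> 255)
#' @export
write_mask_pgm <- function(mask, path) {
  assert_mask(mask)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(mask), nrow(mask)), "255"), con)
  write(as.integer(t(mask)) * 255L, file = con, ncolumns = 20)
  invisible(path)
}

scan_pnm_tokens <- function(path, magic) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  tok <- strsplit(paste(lines, collapse = " "), "[ \t]+")[[1]]
  tok <- tok[nzchar(tok)]
  if (length(tok) < 4 || tok[1] != magic)
    stop(sprintf("not a plain %s file: %s", magic, path))
  as.numeric(tok[-1])
}
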