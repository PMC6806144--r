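# Shared geometric fixtures, all built in code.

disc_on_grid <- function(h, w, cx, cy, r) {
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

two_disc_mask <- function(r = 20, spacing = 30, h = 160, w = 160,
                          cx = 65, cy = 80) {
  disc_on_grid(h, w, cx, cy, r) | disc_on_grid(h, w, cx + spacing, cy, r)
}

# A flat test image with all three channels constant.
flat_image <- function(h, w, rgb) {
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) img[, , ch] <- rgb[ch]
  img
}

random_image <- function(h, w, seed = 1) {
  lychee:::with_seed(seed, {
    img <- array(sample(0:255, h * w * 3, replace = TRUE), c(h, w, 3))
    img
  })
}
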