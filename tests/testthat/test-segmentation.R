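# Chromatic mapping, Otsu thresholding, morphology, region extraction.

test_that("chromatic_map computes (R - B) / max(B, 1)", {
  img <- flat_image(2, 2, c(255, 0, 0))
  expect_equal(chromatic_map(img)[1, 1], 255) # B = 0 guard
  img2 <- flat_image(2, 2, c(77, 77, 77))
  expect_equal(unique(as.vector(chromatic_map(img2))), 0)
  img3 <- flat_image(2, 2, c(200, 50, 100))
  expect_equal(chromatic_map(img3)[1, 1], 1.0)
  expect_true(all(is.finite(chromatic_map(random_image(20, 20, 5)))))
})

# independent oracle: exhaustive scan minimizing weighted intra-class variance
otsu_bruteforce <- function(q) {
  best <- -Inf; bestk <- NA
  n <- length(q)
  for (k in 0:254) {
    lo <- q[q <= k]; hi <- q[q > k]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / n; w1 <- 1 - w0
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; bestk <- k }
  }
  bestk
}

test_that("otsu_threshold maximizes between-class variance (oracle agreement)", {
  lychee:::with_seed(42, {
    for (i in 1:50) {
      m <- matrix(c(rnorm(150, 0, 1), rnorm(106, 5, 1.5)), 16, 16)
      ot <- otsu_threshold(m)
      q <- pmin(floor((as.vector(m) - min(m)) / (max(m) - min(m)) * 256), 255)
      expect_identical(as.integer(ot$bin), as.integer(otsu_bruteforce(q)))
      expect_identical(as.vector(ot$mask), q > ot$bin)
    }
  })
})

test_that("otsu_threshold handles bimodal, near-constant and constant maps", {
  m <- matrix(c(rep(0, 50), rep(10, 50)), 10, 10)
  ot <- otsu_threshold(m)
  expect_gt(ot$threshold, 0)
  expect_lt(ot$threshold, 10)
  expect_identical(sum(ot$mask), 50L)
  one <- matrix(0, 5, 5); one[3, 3] <- 9
  expect_identical(sum(otsu_threshold(one)$mask), 1L)
  expect_error(otsu_threshold(matrix(1, 4, 4)), "constant")
})

test_that("morph_clean removes specks, fills holes and breaks thin bridges", {
  # hole filling
  m <- disc_on_grid(60, 60, 30, 30, 20)
  m[28:30, 28:30] <- FALSE
  out <- morph_clean(m, 2, 2)
  expect_true(all(out[28:30, 28:30]))
  # isolated pixel removed by erosion
  sp <- matrix(FALSE, 20, 20); sp[10, 10] <- TRUE
  expect_false(any(morph_clean(sp, 2, 2)))
  # 1-px bridge between two discs broken: components 1 -> 2
  br <- disc_on_grid(60, 110, 25, 30, 12) | disc_on_grid(60, 110, 80, 30, 12)
  br[30 + 1, (25 + 1):(80 + 1)] <- TRUE
  expect_equal(max(lychee:::cpp_label_components(br, 8L)), 1)
  out2 <- morph_clean(br, 2, 2)
  expect_equal(max(lychee:::cpp_label_components(out2, 8L)), 2)
})

test_that("morph_clean erosion is anti-extensive and output components have no holes", {
  lychee:::with_seed(9, {
    m <- matrix(runif(80 * 80) < 0.5, 80, 80)
    m <- lychee:::cpp_binary_morph(m, lychee:::disk_offsets(2), FALSE)
    er <- lychee:::cpp_binary_morph(m, lychee:::disk_offsets(2), TRUE)
    expect_true(all(m[er])) # erosion subset of input
    out <- morph_clean(m, 2, 2)
    # no holes: background flood-filled from border reaches every bg pixel
    expect_identical(out, lychee:::cpp_fill_holes(out))
  })
})

test_that("extract_regions measures a disc and separates components", {
  m <- disc_on_grid(80, 80, 40, 40, 25)
  regs <- extract_regions(m)
  expect_length(regs, 1)
  expect_lt(abs(regs[[1]]$area - pi * 25^2) / (pi * 25^2), 0.01)
  expect_lt(max(abs(regs[[1]]$centroid - c(40, 40))), 0.5)
  expect_length(extract_regions(matrix(FALSE, 10, 10)), 0)
  m2 <- disc_on_grid(60, 120, 30, 30, 12) | disc_on_grid(60, 120, 90, 30, 12)
  regs2 <- extract_regions(m2)
  expect_length(regs2, 2)
  cents <- sapply(regs2, function(r) r$centroid[["x"]])
  expect_equal(sort(round(cents)), c(30, 90))
})

test_that("region areas partition the foreground and boundaries are closed contours on the region", {
  lychee:::with_seed(13, {
    m <- matrix(runif(70 * 70) < 0.3, 70, 70)
    m <- morph_clean(m, 1, 2)
    regs <- extract_regions(m)
    expect_identical(sum(vapply(regs, function(r) r$area, numeric(1))), as.numeric(sum(m)))
    for (r in regs) {
      b <- r$boundary
      expect_true(all(m[cbind(b[, "y"] + 1, b[, "x"] + 1)]))
      # consecutive boundary points are 8-neighbours (closed loop)
      if (nrow(b) > 1) {
        d <- pmax(abs(diff(b[, 1])), abs(diff(b[, 2])))
        wrap <- max(abs(b[1, ] - b[nrow(b), ]))
        expect_true(all(c(d, wrap) <= 1))
      }
    }
  })
})

test_that("segment_foreground isolates red-dominant discs from a green background", {
  sc <- generate_scene(scene_spec(seed = 5, n_fruits = 3, cluster_prob = 0,
                                  occluder_prob = 0, n_chaff = 0))
  seg <- segment_foreground(sc$image)
  expect_length(seg$regions, 3)
  got <- sort(vapply(seg$regions, function(r) r$centroid[["x"]], numeric(1)))
  want <- sort(sc$truth$fruits$cx)
  expect_lt(max(abs(got - want)), 2)
})
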