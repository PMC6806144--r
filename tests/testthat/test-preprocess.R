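# CLAHE illumination compensation and the overlap-rate grid search.

test_that("clahe_compensate preserves shape, range and near-identity on flat mid-gray", {
  img <- flat_image(40, 60, c(128, 128, 128))
  out <- clahe_compensate(img, clahe_params(4, 0.015))
  expect_identical(dim(out), dim(img))
  expect_true(min(out) >= 0 && max(out) <= 255)
  # equalizing a constant channel is identity up to clip redistribution
  expect_lte(max(abs(out - img)), 3)
})

test_that("clahe_compensate rejects invalid inputs and accepts the working defaults", {
  expect_error(clahe_compensate(array(0, c(0, 10, 3))), "degenerate|H x W")
  expect_error(clahe_params(0), "blocks")
  expect_error(clahe_params(10, 0), "clip_limit")
  expect_silent(p <- clahe_params()) # blocks = 10, clip_limit = 0.015
  expect_identical(p$blocks, 10L)
  expect_equal(p$clip_limit, 0.015)
})

test_that("clahe_compensate preserves hue and saturation up to rounding", {
  img <- random_image(48, 64, seed = 7)
  out <- clahe_compensate(img, clahe_params(8, 0.02))
  h1 <- rgb_to_hsv_img(img)
  h2 <- rgb_to_hsv_img(out)
  # restrict to pixels with well-conditioned hue: the integer round trip
  # perturbs channels by up to 0.5, which on chroma below ~20 levels moves
  # the hue angle more than any algorithm could avoid
  # equalization can darken a pixel, shrinking its output chroma, so the
  # conditioning bound applies to both ends of the round trip
  chroma <- pmin(h1$s * h1$v, h2$s * h2$v) * 255
  sel <- chroma > 48 & h1$v > 0.05
  dh <- abs(h1$h - h2$h)
  dh <- pmin(dh, 1 - dh) # hue is circular
  expect_lte(max(dh[sel]), 2 / 255 + 1e-9)
})

test_that("clahe_compensate stretches contrast inside a dark half", {
  img <- lychee:::with_seed(11, {
    v <- cbind(matrix(40 + sample(-6:6, 40 * 30, TRUE), 40, 30),
               matrix(220 + sample(-6:6, 40 * 30, TRUE), 40, 30))
    arr <- array(0, c(40, 60, 3))
    for (ch in 1:3) arr[, , ch] <- v
    pmax(pmin(arr, 255), 0)
  })
  out <- clahe_compensate(img, clahe_params(4, 0.05))
  vin <- rgb_to_hsv_img(img)$v[, 1:30]
  vout <- rgb_to_hsv_img(out)$v[, 1:30]
  expect_gt(var(as.vector(vout)), var(as.vector(vin)))
})

test_that("tile histogram clipping matches the direct definition", {
  # one 8x8 tile, values concentrated in few bins
  v <- matrix(rep(c(10, 10, 10, 200), 16), 8, 8)
  hist <- tabulate(as.vector(v) + 1L, nbins = 256)
  clip_count <- 0.05 * 64
  clipped <- lychee:::clip_histogram(hist, clip_count)
  excess <- sum(pmax(hist - clip_count, 0))
  # no bin exceeds the clip limit plus its equal share of the excess
  expect_lte(max(clipped), clip_count + excess / 256 + 1e-12)
  expect_equal(sum(clipped), sum(hist)) # mass conserved
})

test_that("overlap_rate follows the Jaccard definition", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE
  expect_equal(overlap_rate(a, a), 1)
  b <- matrix(FALSE, 20, 20); b[11:20, 11:20] <- TRUE
  expect_equal(overlap_rate(a, b), 0)
  # 100-px square against a shifted copy overlapping on 50 px
  s1 <- matrix(FALSE, 30, 30); s1[1:10, 1:10] <- TRUE
  s2 <- matrix(FALSE, 30, 30); s2[1:10, 6:15] <- TRUE
  expect_equal(overlap_rate(s1, s2), 50 / 150, tolerance = 1e-12)
  expect_error(overlap_rate(matrix(FALSE, 5, 5), matrix(FALSE, 5, 5)), "empty")
  expect_error(overlap_rate(a, matrix(TRUE, 5, 5)), "shape")
})

test_that("overlap_rate is symmetric and bounded by the size ratio", {
  lychee:::with_seed(3, {
    for (i in 1:20) {
      a <- matrix(runif(400) < 0.4, 20, 20)
      b <- matrix(runif(400) < 0.4, 20, 20)
      if (!any(a | b)) next
      expect_identical(overlap_rate(a, b), overlap_rate(b, a))
      if (any(a) && any(b))
        expect_lte(overlap_rate(a, b),
                   min(sum(a), sum(b)) / max(sum(a), sum(b)) + 1e-12)
    }
  })
})

test_that("parameter_grid_search scores a self-referential reference at 1 and breaks ties deterministically", {
  sc <- generate_scene(scene_spec(seed = 21, n_fruits = 3, cluster_prob = 0,
                                  occluder_prob = 0, n_chaff = 0))
  p_star <- clahe_params(5, 0.01)
  ref <- segment_foreground(clahe_compensate(sc$image, p_star))$mask
  grid <- list(p_star, clahe_params(5, 0.02), clahe_params(8, 0.01))
  res <- parameter_grid_search(list(sc$image), list(ref), grid)
  expect_equal(nrow(res$table), 3)
  expect_equal(max(res$table$mean_rate), 1)
  expect_identical(res$best$blocks, 5L)
  expect_equal(res$best$clip_limit, 0.01)
  expect_error(parameter_grid_search(list(sc$image), list(ref), list()), "empty")
  # tie-break: duplicate winning rate at larger blocks must not win
  grid2 <- list(clahe_params(8, 0.01), p_star, p_star)
  res2 <- parameter_grid_search(list(sc$image), list(ref), grid2)
  expect_identical(res2$best$blocks, 5L)
})
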