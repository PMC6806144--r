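# Polar profile, extrema, circumcircle and overlap splitting.

test_that("polar_profile of a centred disc is constant to rasterization accuracy", {
  reg <- lychee:::region_from_mask(disc_on_grid(90, 90, 45, 45, 20))
  pp <- polar_profile(reg)
  expect_length(pp$distances, 360)
  expect_lte(max(abs(pp$distances - 20)), 1)
  # distances equal direct Euclidean arithmetic on the sampled points
  d2 <- sqrt((pp$boundary_points[, 1] - pp$origin[["x"]])^2 +
               (pp$boundary_points[, 2] - pp$origin[["y"]])^2)
  expect_equal(pp$distances, d2, tolerance = 1e-9)
})

test_that("polar_profile of a square peaks at corners and dips at edge midpoints", {
  m <- matrix(FALSE, 80, 80)
  m[21:60, 21:60] <- TRUE # side 40, centred at (40.5, 40.5)
  pp <- polar_profile(lychee:::region_from_mask(m))
  ex <- find_extrema(pp, smooth_win = 5, min_prominence = 2)
  expect_identical(sum(ex$type == "max"), 4L)
  expect_identical(sum(ex$type == "min"), 4L)
  expect_equal(sort(ex$value[ex$type == "max"]), rep(20 * sqrt(2), 4), tolerance = 0.1)
  expect_equal(sort(ex$value[ex$type == "min"]), rep(20, 4), tolerance = 0.06 * 20)
})

test_that("polar_profile signals a centroid outside the region", {
  # L-shape: the centre of gravity falls in the concave corner, outside the
  # arms, and rays into the open quadrant never meet the region
  m <- matrix(FALSE, 70, 80)
  m[51:56, 11:71] <- TRUE # horizontal arm
  m[11:56, 11:16] <- TRUE # vertical arm
  reg <- extract_regions(m)[[1]]
  expect_error(polar_profile(reg), "centroid")
})

test_that("find_extrema resolves an analytic two-lobed profile", {
  prof <- structure(list(origin = c(x = 0, y = 0),
                         distances = 20 + 5 * cos(2 * (0:359) * pi / 180),
                         boundary_points = cbind(0:359, 0:359)),
                    class = "polar_profile")
  ex <- find_extrema(prof, smooth_win = 9, min_prominence = 2)
  expect_identical(sum(ex$type == "max"), 2L)
  expect_identical(sum(ex$type == "min"), 2L)
  expect_true(all(abs(sort(ex$degree[ex$type == "max"]) - c(0, 180)) <= 2))
  expect_true(all(abs(sort(ex$degree[ex$type == "min"]) - c(90, 270)) <= 2))
  # alternation around the circle
  expect_true(all(ex$type[seq(1, nrow(ex), 2)] == ex$type[1]))
  # constant profile: no extrema
  prof$distances <- rep(15, 360)
  expect_identical(nrow(find_extrema(prof)), 0L)
})

test_that("find_extrema validates the smoothing window", {
  prof <- structure(list(distances = rep(1, 360)), class = "polar_profile")
  expect_error(find_extrema(prof, smooth_win = 4), "odd")
})

test_that("circumcircle solves the three-point definite circle", {
  c1 <- circumcircle(c(0, 0), c(2, 0), c(1, 1))
  expect_equal(unname(c1[c("cx", "cy", "r")]), c(1, 0, 1), tolerance = 1e-12)
  c2 <- circumcircle(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(unname(c2[c("cx", "cy", "r")]), c(0.5, 0.5, sqrt(2) / 2),
               tolerance = 1e-12)
  expect_error(circumcircle(c(0, 0), c(4, 0), c(8, 0)), "collinear")
})

test_that("circumcircle is permutation invariant and equidistant (least-squares oracle)", {
  lychee:::with_seed(4, {
    for (i in 1:25) {
      pts <- matrix(runif(6, -50, 50), 3, 2)
      area2 <- abs((pts[2, 1] - pts[1, 1]) * (pts[3, 2] - pts[1, 2]) -
                     (pts[3, 1] - pts[1, 1]) * (pts[2, 2] - pts[1, 2]))
      if (area2 < 1) next
      cc <- circumcircle(pts[1, ], pts[2, ], pts[3, ])
      # brute-force circle fit through the same 3 points has zero residual
      d <- sqrt((pts[, 1] - cc[["cx"]])^2 + (pts[, 2] - cc[["cy"]])^2)
      expect_lt(max(abs(d - cc[["r"]])) / cc[["r"]], 1e-9)
      for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
        cc2 <- circumcircle(pts[perm[1], ], pts[perm[2], ], pts[perm[3], ])
        expect_equal(unname(cc2), unname(cc), tolerance = 1e-9)
      }
    }
  })
})

test_that("split_overlapped recovers two fused discs almost exactly", {
  reg <- lychee:::region_from_mask(two_disc_mask(r = 20, spacing = 30))
  sp <- split_overlapped(reg)
  expect_identical(nrow(sp), 2L)
  for (truth in list(c(65, 80, 20), c(95, 80, 20))) {
    d <- sqrt((sp$cx - truth[1])^2 + (sp$cy - truth[2])^2)
    j <- which.min(d)
    expect_lt(d[j], 3)
    expect_lt(abs(sp$r[j] - truth[3]) / truth[3], 0.15)
  }
})

test_that("split_overlapped recovers a three-disc row (jittered) and falls back on a lone disc", {
  discs <- lychee:::with_seed(6, lychee:::random_cluster_discs(3, r_range = c(17, 19)))
  m <- lychee:::rasterize_discs(discs)
  off <- attr(m, "offset")
  sp <- split_overlapped(lychee:::region_from_mask(m))
  expect_identical(nrow(sp), 3L)
  for (d in discs) {
    dd <- sqrt((sp$cx + off[["x"]] - d[1])^2 + (sp$cy + off[["y"]] - d[2])^2)
    j <- which.min(dd)
    expect_lt(abs(sp$r[j] - d[3]) / d[3], 0.2)
  }
  # isolated disc passed in by mistake: fallback to the area circle
  iso <- split_overlapped(lychee:::region_from_mask(disc_on_grid(80, 80, 40, 40, 20)))
  expect_identical(nrow(iso), 1L)
  expect_true(attr(iso, "fallback"))
  expect_lt(abs(iso$r[1] - 20) / 20, 0.02)
})

test_that("split_overlapped is 90-degree rotation equivariant", {
  m <- two_disc_mask(r = 18, spacing = 26, h = 150, w = 150, cx = 60, cy = 70)
  sp1 <- split_overlapped(lychee:::region_from_mask(m))
  mr <- t(m)[ncol(m):1, ] # 90 deg counter-clockwise in matrix terms
  sp2 <- split_overlapped(lychee:::region_from_mask(mr))
  expect_identical(nrow(sp1), nrow(sp2))
  h <- nrow(m)
  # (x, y) -> (y, H - 1 - x) under this rotation
  exp_cx <- sort(sp1$cy); got_cx <- sort(sp2$cx)
  expect_lt(max(abs(exp_cx - got_cx)), 1)
  exp_cy <- sort(h - 1 - sp1$cx); got_cy <- sort(sp2$cy)
  expect_lt(max(abs(exp_cy - got_cy)), 1)
})

test_that("cluster splitting succeeds on 85% of seeded 2-4 disc clusters", {
  bench <- pcevp_recovery_benchmark(n = 100, seed = 1)
  expect_gte(bench$success_rate, 0.85)
  expect_identical(nrow(bench$details), 100L)
})
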