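# Uniform LBP descriptor, histogram intersection kernel, SVM filter, gate.

test_that("exactly 58 uniform codes exist among all 256 patterns", {
  tab <- lychee:::lbp_uniform_table()
  expect_length(tab$uniform, 58)
  # independent enumeration: count circular bit transitions directly
  n_uniform <- sum(sapply(0:255, function(v) {
    b <- as.integer(intToBits(v)[1:8])
    sum(b != c(b[-1], b[1])) <= 2
  }))
  expect_identical(n_uniform, 58L)
  expect_identical(sort(unique(tab$map)), 1:59)
})

test_that("uniform_lbp maps canonical patches to the expected bins", {
  # constant patch: all-zero code (uniform), single bin holds mass 1
  f <- uniform_lbp(matrix(100, 8, 8))
  expect_length(f, 59)
  expect_equal(sum(f), 1)
  expect_equal(max(f), 1)
  expect_equal(f[lychee:::lbp_uniform_table()$map[0 + 1]], 0) # zero code maps with >= comparisons to code 255
  # checkerboard: high-centred pixels see alternating 10101010 codes
  # (non-uniform, pooled bin); low-centred pixels tie with their diagonals
  # and the >= convention gives the all-ones uniform code. Interior is 7x7.
  cb <- outer(1:9, 1:9, function(i, j) (i + j) %% 2) * 200
  fcb <- uniform_lbp(cb)
  n_high <- sum(outer(2:8, 2:8, function(i, j) (i + j) %% 2))
  expect_equal(fcb[59], n_high / 49)
  allones <- lychee:::lbp_uniform_table()$map[255 + 1]
  expect_equal(fcb[allones], 1 - n_high / 49)
  # vertical step edge: only uniform codes, nothing in the pooled bin
  step <- cbind(matrix(0, 9, 4), matrix(200, 9, 5))
  fs <- uniform_lbp(step)
  expect_equal(fs[59], 0)
  expect_error(uniform_lbp(matrix(1, 2, 5)), "3 x 3")
})

test_that("hik computes the min-sum and its kernel properties hold", {
  expect_equal(hik(c(0.5, 0.5, 0), c(0.25, 0.25, 0.5)), 0.5)
  expect_equal(hik(c(1, 0), c(0, 1)), 0)
  lychee:::with_seed(2, {
    X <- t(replicate(12, { v <- runif(59); v / sum(v) }))
    for (i in 1:5) {
      a <- X[sample(12, 1), ]; b <- X[sample(12, 1), ]
      expect_equal(hik(a, b), hik(b, a))
      expect_lte(hik(a, b), 1 + 1e-12)
    }
    expect_equal(hik(X[1, ], X[1, ]), 1) # K(F, F) = 1 for normalized features
    # Gram matrix positive semi-definite
    K <- lychee:::hik_gram(X)
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  })
  expect_error(hik(1:3, 1:4), "length")
})

test_that("size_gate keeps areas in [lo, hi] inclusive", {
  regs <- lapply(c(799, 800, 1700, 1701), function(a) list(area = a))
  kept <- size_gate(regs, 800, 1700)
  expect_identical(vapply(kept, function(r) r$area, numeric(1)), c(800, 1700))
  expect_length(size_gate(list(), 800, 1700), 0)
  all_in <- lapply(c(900, 1000), function(a) list(area = a))
  expect_identical(size_gate(all_in, 800, 1700), all_in)
  expect_error(size_gate(regs, 10, 5), "lo")
})

test_that("extract_patch crops, clamps and resamples", {
  img <- flat_image(40, 40, c(90, 120, 30))
  p <- extract_patch(img, circle(20, 20, 10), 32)
  expect_identical(dim(p), c(32L, 32L))
  expect_equal(sd(p), 0)
  # corner circle still yields a full-size patch
  p2 <- extract_patch(img, circle(1, 1, 10), 32)
  expect_identical(dim(p2), c(32L, 32L))
  expect_error(extract_patch(img, circle(500, 500, 5)), "outside")
  # patch mean tracks the source region mean
  sc <- generate_scene(scene_spec(seed = 9, n_fruits = 1, cluster_prob = 0,
                                  occluder_prob = 0, n_chaff = 0))
  fr <- sc$truth$fruits[1, ]
  patch <- extract_patch(sc$image, circle(fr$cx, fr$cy, fr$r))
  g <- to_grayscale(sc$image)
  sel <- disc_on_grid(dim(g)[1], dim(g)[2], fr$cx, fr$cy, fr$r)
  # bounding square includes background corners, so compare loosely
  expect_lt(abs(mean(patch) - mean(g[sel])) / mean(g[sel]), 0.35)
})

test_that("svm_train separates toy histograms and rejects degenerate input", {
  pos <- rbind(c(1, 0, 0), c(0.9, 0.1, 0), c(0.8, 0.2, 0))
  neg <- rbind(c(0, 0, 1), c(0, 0.1, 0.9), c(0.1, 0.1, 0.8))
  m <- svm_train(pos, neg)
  expect_true(all(svm_decision(m, pos) >= 0))
  expect_true(all(svm_decision(m, neg) < 0))
  expect_error(svm_train(pos, matrix(numeric(0), 0, 3)), "nonempty")
  # both classes identical: no useful separation (flagged degenerate)
  m2 <- svm_train(pos, pos)
  acc <- mean(c(svm_decision(m2, pos) >= 0, svm_decision(m2, pos) < 0))
  expect_lte(acc, 0.5 + 1e-9)
})

test_that("LBP-SVM separates synthetic fruit from background at 90% held out", {
  patches <- render_training_patches(scene_spec(seed = 77), 150, 150)
  feat <- function(ps) t(vapply(ps, function(p) as.numeric(uniform_lbp(p)), numeric(59)))
  Xp <- feat(patches$pos); Xn <- feat(patches$neg)
  model <- svm_train(Xp[1:100, ], Xn[1:100, ])
  acc <- mean(c(svm_decision(model, Xp[101:150, ]) >= 0,
                svm_decision(model, Xn[101:150, ]) < 0))
  expect_gte(acc, 0.9)
  # persistence: reloaded model gives bit-identical decisions
  path <- tempfile(fileext = ".json")
  svm_save(model, path)
  m2 <- svm_load(path)
  expect_identical(svm_decision(model, Xp[101:150, ]), svm_decision(m2, Xp[101:150, ]))
  # filter on detections: fruit circles survive, background circles do not
  sc <- generate_scene(scene_spec(seed = 901, n_fruits = 5, cluster_prob = 0,
                                  occluder_prob = 0, n_chaff = 0))
  fr <- sc$truth$fruits
  fl <- filter_detections(fr[, c("cx", "cy", "r")], sc$image, model)
  expect_lte(nrow(fl$rejected) / nrow(fr), 0.1)
  # detections placed on pure background texture: almost all rejected
  bgscene <- generate_scene(scene_spec(seed = 902, n_fruits = 0, n_chaff = 0))
  bg <- expand.grid(cx = c(40, 110, 180, 250, 290), cy = c(60, 180), r = 18)
  flb <- filter_detections(bg, bgscene$image, model)
  expect_lte(nrow(flb$accepted) / nrow(bg), 0.1)
  # empty detection list round-trips
  fle <- filter_detections(data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0)),
                           sc$image, model)
  expect_identical(nrow(fle$accepted) + nrow(fle$rejected), 0L)
})
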