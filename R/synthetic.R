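# Smooth band-limited noise field: coarse N(0,1) grid bilinearly upsampled.
# `scale` is the approximate correlation length in px.
smooth_field <- function(h, w, scale) {
  ch <- max(2, ceiling(h / scale) + 1)
  cw <- max(2, ceiling(w / scale) + 1)
  bilinear_resize(matrix(rnorm(ch * cw), ch, cw), h, w)
}

# Logical disc mask evaluated over the full image grid.
disc_mask <- function(h, w, cx, cy, r) {
  xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
  ys <- matrix(0:(h - 1), h, w)
  (xs - cx)^2 + (ys - cy)^2 <= r^2
}

#' Synthetic scene specification
#'
#' The stated world of the test fixtures: orchard-like frames with textured
#' near-circular fruits whose areas fall inside the 800-1700 px working
#' gate (radii about 16.5-23 px), rendered isolated, partially occluded by
#' elongated foliage strips, or overlapped in clusters of 2-4, under three
#' illumination regimes. `n_chaff` smooth reddish-brown non-fruit blobs
#' give the texture classifier false positives to remove. The seed fully
#' determines the output.
#'
#' @param width,height frame size in px
#' @param n_fruits number of fruits
#' @param radius_range fruit radius bounds in px
#' @param cluster_prob fraction of fruits placed in overlapping clusters
#' @param occluder_prob probability a non-clustered fruit is occluded
#' @param n_chaff number of background chaff blobs
#' @param illumination one of "well", "weak", "overexposed"
#' @param seed integer seed
#' @return list of class `scene_spec`
#' @export
scene_spec <- function(width = 320, height = 240, n_fruits = 6,
                       radius_range = c(16.5, 23), cluster_prob = 0.3,
                       occluder_prob = 0.2, n_chaff = 2,
                       illumination = c("well", "weak", "overexposed"),
                       seed = 1L) {
  illumination <- match.arg(illumination)
  stopifnot(width >= 64, height >= 64, n_fruits >= 0,
            radius_range[1] > 0, radius_range[1] <= radius_range[2],
            cluster_prob >= 0, cluster_prob <= 1,
            occluder_prob >= 0, occluder_prob <= 1, n_chaff >= 0)
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_fruits = as.integer(n_fruits),
                 radius_range = as.numeric(radius_range),
                 cluster_prob = cluster_prob, occluder_prob = occluder_prob,
                 n_chaff = as.integer(n_chaff), illumination = illumination,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

illumination_gain <- function(regime) {
  switch(regime, well = 1.0, weak = 0.4, overexposed = 1.8)
}

# A "bunch" of s overlapping fruits arranged around a common centre like a
# hanging cluster: members sit at jittered regular angles on a ring whose
# radius makes adjacent centre spacing fall in 1.2-1.6 of the mean radius,
# so every fruit keeps an exposed outer arc (the arrangement the polar
# splitting procedure is designed for; densely folded clusters are out of
# scope, as they are for the method itself). Returns centres about (0, 0).
cluster_bunch <- function(s, rr, cid) {
  r <- runif(s, rr[1], rr[2])
  f <- runif(1, 1.2, 1.6)
  if (s == 2) {
    d <- f * (r[1] + r[2]) / 2
    ang <- runif(1, 0, 2 * pi)
    cx <- c(-d / 2, d / 2) * cos(ang)
    cy <- c(-d / 2, d / 2) * sin(ang)
    rho <- rep(d / 2, 2)
  } else {
    base <- runif(1, 0, 2 * pi)
    th <- base + (seq_len(s) - 1) * 2 * pi / s + runif(s, -0.15, 0.15)
    pair_d <- f * (r + r[c(2:s, 1)]) / 2
    rho0 <- mean(pair_d) / (2 * sin(pi / s))
    rho <- rho0 * runif(s, 0.95, 1.05)
    cx <- rho * cos(th)
    cy <- rho * sin(th)
  }
  data.frame(cx = cx, cy = cy, r = r, cluster = cid, rho = rho + r)
}

# Partition n_clustered fruits into cluster sizes 2..4 (never a lone 1).
cluster_sizes <- function(n_clustered) {
  sizes <- integer(0)
  left <- n_clustered
  while (left >= 2) {
    s <- sample(2:4, 1)
    s <- min(s, left)
    if (left - s == 1) s <- s + 1 # avoid stranding a single
    s <- min(s, 4, left)
    sizes <- c(sizes, s)
    left <- left - s
  }
  sizes
}

place_fruits <- function(spec) {
  n <- spec$n_fruits
  if (n == 0) return(data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                                cluster = integer(0)))
  rr <- spec$radius_range
  n_clustered <- round(spec$cluster_prob * n)
  if (n_clustered == 1) n_clustered <- 0
  sizes <- cluster_sizes(n_clustered)
  placed <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                       cluster = integer(0))
  margin <- rr[2] + 4
  ok_new <- function(cx, cy, r, allow_cluster = NA) {
    if (cx < margin || cx > spec$width - margin ||
        cy < margin || cy > spec$height - margin) return(FALSE)
    if (nrow(placed) == 0) return(TRUE)
    d <- sqrt((placed$cx - cx)^2 + (placed$cy - cy)^2)
    lim <- placed$r + r + 4
    clash <- d < lim
    if (!is.na(allow_cluster)) clash <- clash & placed$cluster != allow_cluster
    !any(clash)
  }
  cid <- 0L
  for (s in sizes) {
    cid <- cid + 1L
    done <- FALSE
    for (try in 1:300) {
      members <- cluster_bunch(s, rr, cid)
      ox <- runif(1, margin + max(members$rho), spec$width - margin - max(members$rho))
      oy <- runif(1, margin + max(members$rho), spec$height - margin - max(members$rho))
      members$cx <- members$cx + ox
      members$cy <- members$cy + oy
      inb <- all(members$cx > margin & members$cx < spec$width - margin &
                   members$cy > margin & members$cy < spec$height - margin)
      sep_ok <- all(vapply(seq_len(s), function(k) {
        ok_new(members$cx[k], members$cy[k], members$r[k], allow_cluster = cid)
      }, logical(1)))
      if (inb && sep_ok) {
        placed <- rbind(placed, members[, c("cx", "cy", "r", "cluster")])
        done <- TRUE
        break
      }
    }
    if (!done) stop("infeasible placement: could not fit a fruit cluster within bounds")
  }
  n_single <- n - sum(sizes)
  for (k in seq_len(n_single)) {
    done <- FALSE
    for (try in 1:300) {
      r <- runif(1, rr[1], rr[2])
      cx <- runif(1, margin, spec$width - margin)
      cy <- runif(1, margin, spec$height - margin)
      if (ok_new(cx, cy, r)) {
        placed <- rbind(placed, data.frame(cx = cx, cy = cy, r = r, cluster = 0L))
        done <- TRUE
        break
      }
    }
    if (!done) stop("infeasible placement: could not fit an isolated fruit")
  }
  rownames(placed) <- NULL
  placed
}

#' Generate a synthetic orchard scene with exact ground truth
#'
#' Background is green/brown textured noise with low red-blue contrast;
#' fruits are red-dominant discs with high-frequency multiplicative rind
#' texture; occluders are elongated leaf-green strips (R roughly equal to
#' B) that remove foreground rather than adding red clutter; chaff blobs
#' are smooth and mildly red-dominant. The illumination regime applies a
#' global gain (weak 0.4, well 1.0, overexposed 1.8 with clipping).
#' Everything is a pure function of the spec, including its seed.
#'
#' @param spec a [scene_spec()]
#' @return list with `image` (RGB array) and `truth` (list with `fruits`
#'   data.frame cx, cy, r, status, coverage and `occluders`, a list of
#'   logical masks)
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    h <- spec$height; w <- spec$width
    fruits <- place_fruits(spec)
    img <- array(0, c(h, w, 3))
    img[, , 2] <- 95 + 18 * smooth_field(h, w, 24) + 6 * smooth_field(h, w, 4)
    # red-blue difference decorrelates at fine scale only: background
    # chromatic noise must not form fruit-sized coherent blobs
    base_rb <- 64 + 9 * smooth_field(h, w, 24)
    img[, , 1] <- base_rb + 4 * smooth_field(h, w, 4)
    img[, , 3] <- base_rb + 5 * smooth_field(h, w, 3)
    xs <- matrix(0:(w - 1), h, w, byrow = TRUE)
    ys <- matrix(0:(h - 1), h, w)
    # chaff: smooth, mildly red-dominant ellipses (non-fruit)
    chaff <- list()
    for (k in seq_len(spec$n_chaff)) {
      for (try in 1:200) {
        a <- runif(1, 18, 24); b <- runif(1, 14, 19)
        cx <- runif(1, a + 4, w - a - 4); cy <- runif(1, a + 4, h - a - 4)
        if (nrow(fruits) > 0) {
          d <- sqrt((fruits$cx - cx)^2 + (fruits$cy - cy)^2)
          if (any(d < fruits$r + a + 6)) next
        }
        if (length(chaff) > 0) {
          dc <- vapply(chaff, function(e) sqrt((e$cx - cx)^2 + (e$cy - cy)^2), numeric(1))
          if (any(dc < a + 26)) next
        }
        th <- runif(1, 0, pi)
        u <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
        v <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
        m <- (u / a)^2 + (v / b)^2 <= 1
        tex <- 1 + 0.05 * smooth_field(h, w, 8)
        img[, , 1][m] <- (runif(1, 150, 185) * tex)[m]
        img[, , 2][m] <- (runif(1, 84, 104) * tex)[m]
        img[, , 3][m] <- (runif(1, 55, 75) * tex)[m]
        chaff[[length(chaff) + 1]] <- list(cx = cx, cy = cy, a = a, b = b)
        break
      }
    }
    # fruits: red-dominant discs with bumpy rind texture and radial shading
    for (i in seq_len(nrow(fruits))) {
      cx <- fruits$cx[i]; cy <- fruits$cy[i]; r <- fruits$r[i]
      m <- (xs - cx)^2 + (ys - cy)^2 <= r^2
      bump <- pmax(pmin(smooth_field(h, w, 1.6), 2.2), -2.2)
      shade <- 1 - 0.22 * ((xs - cx)^2 + (ys - cy)^2) / r^2
      fac <- (1 + 0.16 * bump) * shade
      img[, , 1][m] <- (runif(1, 175, 215) * fac)[m]
      img[, , 2][m] <- (runif(1, 62, 100) * fac)[m]
      img[, , 3][m] <- (runif(1, 40, 66) * fac)[m]
    }
    # occluders: leaf-green strips across some non-clustered fruits
    occluders <- list()
    coverage <- numeric(nrow(fruits))
    if (nrow(fruits) > 0) {
      for (i in seq_len(nrow(fruits))) {
        if (fruits$cluster[i] != 0L || runif(1) >= spec$occluder_prob) next
        cx <- fruits$cx[i]; cy <- fruits$cy[i]; r <- fruits$r[i]
        phi <- runif(1, 0, 2 * pi)
        delta <- runif(1, -0.30, 0.35) * r
        widthb <- (r - delta) + runif(1, 3, 8)
        proj <- (xs - cx) * cos(phi) + (ys - cy) * sin(phi)
        perp <- -(xs - cx) * sin(phi) + (ys - cy) * cos(phi)
        strip <- proj >= delta & proj <= delta + widthb & abs(perp) <= 2.2 * r
        tex <- 1 + 0.07 * smooth_field(h, w, 6)
        img[, , 1][strip] <- (runif(1, 52, 70) * tex)[strip]
        img[, , 2][strip] <- (runif(1, 100, 140) * tex)[strip]
        img[, , 3][strip] <- (runif(1, 52, 70) * tex)[strip]
        occluders[[length(occluders) + 1]] <- strip
      }
    }
    # coverage measured against the union of all strips: a strip drawn for
    # one fruit may clip a neighbour, and the label must follow the pixels
    if (length(occluders) > 0 && nrow(fruits) > 0) {
      allstrips <- Reduce(`|`, occluders)
      for (i in seq_len(nrow(fruits))) {
        disc <- (xs - fruits$cx[i])^2 + (ys - fruits$cy[i])^2 <= fruits$r[i]^2
        coverage[i] <- sum(allstrips & disc) / sum(disc)
      }
    }
    # status from the rendered geometry
    status <- rep(ISOLATED, nrow(fruits))
    if (nrow(fruits) > 1) {
      for (i in seq_len(nrow(fruits))) {
        d <- sqrt((fruits$cx - fruits$cx[i])^2 + (fruits$cy - fruits$cy[i])^2)
        d[i] <- Inf
        if (any(d < fruits$r + fruits$r[i])) status[i] <- OVERLAPPED
      }
    }
    status[status == ISOLATED & coverage >= 0.2] <- OCCLUDED
    gain <- illumination_gain(spec$illumination)
    img <- pmax(pmin(round(img * gain), 255), 0)
    truth <- list(fruits = cbind(fruits[, c("cx", "cy", "r")],
                                 status = status, coverage = coverage,
                                 cluster = fruits$cluster),
                  occluders = occluders)
    list(image = img, truth = truth)
  })
}

#' Render labelled training patches from synthetic scenes
#'
#' Harvests `n_pos` fruit-centred grayscale patches and `n_neg` background
#' patches (guaranteed not to intersect any fruit disc; chaff blobs are
#' legitimate negatives) from a deterministic sequence of scenes derived
#' from the spec's seed.
#'
#' @param spec a [scene_spec()] (its seed anchors the scene sequence)
#' @param n_pos,n_neg patch counts (>= 1)
#' @param patch_size patch side length
#' @return list with `pos` and `neg`, each a list of grayscale matrices
#' @export
render_training_patches <- function(spec, n_pos, n_neg, patch_size = 32) {
  stopifnot(n_pos >= 1, n_neg >= 1)
  pos <- list(); neg <- list()
  k <- 0L
  while ((length(pos) < n_pos || length(neg) < n_neg) && k < 400L) {
    k <- k + 1L
    sp <- spec
    sp$seed <- derive_seed(spec$seed, k)
    sc <- generate_scene(sp)
    fr <- sc$truth$fruits
    for (i in seq_len(nrow(fr))) {
      if (length(pos) >= n_pos) break
      pos[[length(pos) + 1]] <- extract_patch(sc$image,
                                              circle(fr$cx[i], fr$cy[i], fr$r[i]),
                                              patch_size)
    }
    negs_here <- with_seed(derive_seed(spec$seed, 100000L + k), {
      out <- list()
      for (t in 1:80) {
        if (length(neg) + length(out) >= n_neg) break
        r <- runif(1, spec$radius_range[1], spec$radius_range[2])
        cx <- runif(1, r, spec$width - r - 1)
        cy <- runif(1, r, spec$height - r - 1)
        if (nrow(fr) > 0) {
          d <- sqrt((fr$cx - cx)^2 + (fr$cy - cy)^2)
          if (any(d < fr$r + r)) next # would intersect a fruit disc
        }
        out[[length(out) + 1]] <- extract_patch(sc$image, circle(cx, cy, r), patch_size)
      }
      out
    })
    neg <- c(neg, negs_here)
  }
  if (length(pos) < n_pos || length(neg) < n_neg)
    stop("insufficient scene area to harvest the requested patches")
  list(pos = pos[seq_len(n_pos)], neg = neg[seq_len(n_neg)])
}
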