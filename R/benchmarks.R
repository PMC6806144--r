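# Rasterized test geometries and seeded parameter-recovery experiments.
# These are the package's acceptance surface: every quantity is recomputed
# from scratch by running the detection primitives on freshly generated
# regions.

# Rasterize a set of discs (list of c(cx, cy, r)) on a canvas large enough
# to hold them with `pad` px of margin; returns a logical mask.
rasterize_discs <- function(discs, pad = 12) {
  xs <- vapply(discs, function(d) d[1], numeric(1))
  ys <- vapply(discs, function(d) d[2], numeric(1))
  rs <- vapply(discs, function(d) d[3], numeric(1))
  x0 <- floor(min(xs - rs)) - pad; y0 <- floor(min(ys - rs)) - pad
  w <- ceiling(max(xs + rs)) - x0 + pad; h <- ceiling(max(ys + rs)) - y0 + pad
  gx <- matrix(0:(w - 1), h, w, byrow = TRUE)
  gy <- matrix(0:(h - 1), h, w)
  m <- matrix(FALSE, h, w)
  for (i in seq_along(discs))
    m <- m | ((gx - (xs[i] - x0))^2 + (gy - (ys[i] - y0))^2 <= rs[i]^2)
  attr(m, "offset") <- c(x = x0, y = y0)
  m
}

# Crescent: a disc with the circular segment beyond the chord at signed
# offset `delta` (in units of r, along a random direction) removed.
rasterize_crescent <- function(cx, cy, r, delta_frac, phi, pad = 12) {
  m <- rasterize_discs(list(c(cx, cy, r)), pad)
  off <- attr(m, "offset")
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0:(w - 1), h, w, byrow = TRUE) + off[["x"]]
  gy <- matrix(0:(h - 1), h, w) + off[["y"]]
  proj <- (gx - cx) * cos(phi) + (gy - cy) * sin(phi)
  out <- m & (proj < delta_frac * r)
  attr(out, "offset") <- off
  out
}

# Random overlapping cluster of k discs in bunch arrangement; returns the
# disc parameters (centred near the origin).
random_cluster_discs <- function(k, r_range = c(15, 25), spacing = c(1.2, 1.6)) {
  r <- runif(k, r_range[1], r_range[2])
  f <- runif(1, spacing[1], spacing[2])
  if (k == 2) {
    d <- f * (r[1] + r[2]) / 2
    ang <- runif(1, 0, 2 * pi)
    cx <- c(-d / 2, d / 2) * cos(ang); cy <- c(-d / 2, d / 2) * sin(ang)
  } else {
    base <- runif(1, 0, 2 * pi)
    th <- base + (seq_len(k) - 1) * 2 * pi / k + runif(k, -0.15, 0.15)
    pair_d <- f * (r + r[c(2:k, 1)]) / 2
    rho <- mean(pair_d) / (2 * sin(pi / k)) * runif(k, 0.95, 1.05)
    cx <- rho * cos(th); cy <- rho * sin(th)
  }
  lapply(seq_len(k), function(i) c(cx[i] + 100, cy[i] + 100, r[i]))
}

#' Status-classification recovery on seeded synthetic regions
#'
#' Generates `n` regions cycling through isolated discs, occlusion
#' crescents (30-65% of the disc removed by a straight foliage edge) and
#' overlapping 2-3 disc clusters, runs the full per-region classification
#' (equivalent area circle, Hough circles, status decision) and scores the
#' predicted status against the construction's ground truth.
#'
#' @param n number of regions
#' @param seed RNG seed
#' @param thr an [achc_thresholds()]
#' @return list with `accuracy` and a per-case data.frame `details`
#' @export
achc_recovery_benchmark <- function(n = 50, seed = 1, thr = achc_thresholds()) {
  with_seed(seed, {
    kinds <- rep(c("isolated", "crescent", "cluster"), length.out = n)
    rows <- lapply(seq_len(n), function(i) {
      kind <- kinds[i]
      if (kind == "isolated") {
        r <- runif(1, 15, 25)
        m <- rasterize_discs(list(c(100, 100, r)))
        truth <- ISOLATED
      } else if (kind == "crescent") {
        r <- runif(1, 15, 25)
        m <- rasterize_crescent(100, 100, r, runif(1, -0.3, 0.2), runif(1, 0, 2 * pi))
        truth <- OCCLUDED
      } else {
        k <- sample(2:3, 1)
        m <- rasterize_discs(random_cluster_discs(k))
        truth <- OVERLAPPED
      }
      reg <- region_from_mask(m)
      cls <- classify_status(hough_circles(reg, thr), equivalent_area_circle(reg), thr)
      data.frame(kind = kind, truth = truth, predicted = as.integer(cls))
    })
    details <- do.call(rbind, rows)
    list(accuracy = mean(details$truth == details$predicted), details = details)
  })
}

#' Cluster-splitting recovery on seeded overlapping disc clusters
#'
#' Generates `n` clusters of k in 2-4 discs (radii 15-25 px, centre spacing
#' 1.2-1.6 of the mean radius), splits each rasterized union with
#' [split_overlapped()] and scores a trial as successful when the recovered
#' circle count equals k and every true disc is matched (nearest recovered
#' centre) with radius error at most `radius_tol`.
#'
#' @param n number of clusters
#' @param seed RNG seed
#' @param radius_tol relative radius error bound
#' @param smooth_win,min_prominence forwarded to [split_overlapped()]
#' @return list with `success_rate`, `count_rate`, `radius_rate` and
#'   per-trial `details`
#' @export
pcevp_recovery_benchmark <- function(n = 100, seed = 1, radius_tol = 0.2,
                                     smooth_win = 9, min_prominence = 2) {
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      k <- sample(2:4, 1)
      discs <- random_cluster_discs(k)
      m <- rasterize_discs(discs)
      off <- attr(m, "offset")
      reg <- region_from_mask(m)
      sp <- split_overlapped(reg, smooth_win, min_prominence)
      count_ok <- nrow(sp) == k
      rad_ok <- all(vapply(discs, function(d) {
        dd <- sqrt((sp$cx + off[["x"]] - d[1])^2 + (sp$cy + off[["y"]] - d[2])^2)
        j <- which.min(dd)
        abs(sp$r[j] - d[3]) / d[3] <= radius_tol
      }, logical(1)))
      data.frame(k = k, found = nrow(sp), count_ok = count_ok, radius_ok = rad_ok)
    })
    details <- do.call(rbind, rows)
    list(success_rate = mean(details$count_ok & details$radius_ok),
         count_rate = mean(details$count_ok),
         radius_rate = mean(details$radius_ok),
         details = details)
  })
}

#' Illumination / classifier ablation on seeded scenes
#'
#' Runs the full pipeline over `n_scenes` scenes per regime and reports the
#' pooled counts for each arm: preprocessing on/off (weak and overexposed
#' regimes) and LBP-SVM filter on/off (all regimes; requires `model`).
#'
#' @param n_scenes scenes per illumination regime
#' @param seed RNG seed anchor
#' @param model optional `hik_svm` for the filter arms
#' @param cfg base [pipeline_config()]
#' @return data.frame of pooled counts per (regime, arm)
#' @export
ablation_benchmark <- function(n_scenes = 20, seed = 1, model = NULL,
                               cfg = pipeline_config()) {
  regimes <- c("well", "weak", "overexposed")
  rows <- list()
  for (reg in regimes) {
    scenes <- lapply(seq_len(n_scenes), function(k) {
      generate_scene(scene_spec(seed = derive_seed(seed, k + 1000 * match(reg, regimes)),
                                n_fruits = 8, cluster_prob = 0.4,
                                occluder_prob = 0.25, n_chaff = 2,
                                illumination = reg))
    })
    arms <- list(
      base = {
        cfg2 <- cfg; cfg2$preprocess <- TRUE; cfg2$classifier <- FALSE; list(cfg2, NULL)
      },
      no_preprocess = {
        cfg2 <- cfg; cfg2$preprocess <- FALSE; cfg2$classifier <- FALSE; list(cfg2, NULL)
      },
      filtered = {
        cfg2 <- cfg; cfg2$preprocess <- TRUE; cfg2$classifier <- TRUE; list(cfg2, model)
      }
    )
    if (is.null(model)) arms$filtered <- NULL
    for (arm in names(arms)) {
      tot <- c(tp = 0, fn = 0, fp = 0)
      for (sc in scenes) {
        d <- detect(sc$image, arms[[arm]][[1]], arms[[arm]][[2]])
        m <- match_detections(d[d$accepted, , drop = FALSE], sc$truth$fruits,
                              cfg$eval$iou)
        tot <- tot + c(m$tp, m$fn, m$fp)
      }
      rows[[length(rows) + 1]] <- data.frame(regime = reg, arm = arm,
                                             tp = tot[1], fn = tot[2], fp = tot[3])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$precision <- 100 * out$tp / (out$tp + out$fp)
  out$recall <- 100 * out$tp / (out$tp + out$fn)
  out
}
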