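#' Polar distance profile of a region
#'
#' Takes the centre of gravity A as the origin of a polar coordinate system
#' and, for every integer degree counter-clockwise, finds the outermost
#' point of the region along the ray and records its Euclidean distance
#' |AE_d|. Rays are marched in 0.5-px steps; non-star-shaped regions keep
#' the outermost crossing so the profile stays single-valued.
#'
#' @param region a region from [extract_regions()]
#' @return list of class `polar_profile` with `origin` (x, y),
#'   `distances` (length-360 numeric, circular) and `boundary_points`
#'   (360 x 2 matrix of sampled E_d coordinates)
#' @export
polar_profile <- function(region) {
  mask <- region_full_mask(region)
  cx <- region$centroid[["x"]]; cy <- region$centroid[["y"]]
  bb <- region$bbox
  rmax <- sqrt((bb[["x1"]] - bb[["x0"]] + 1)^2 + (bb[["y1"]] - bb[["y0"]] + 1)^2)
  prof <- cpp_polar_profile(mask, cx, cy, 0.5, rmax)
  bad <- which(prof[, 1] < 0)
  if (length(bad) > 0) {
    stop(sprintf("centroid lies outside the region: no boundary crossing at degrees %s",
                 paste(bad - 1, collapse = ", ")))
  }
  structure(list(origin = c(x = cx, y = cy),
                 distances = prof[, 1],
                 boundary_points = prof[, 2:3, drop = FALSE]),
            class = "polar_profile")
}

# Circular moving average of odd width w.
circular_smooth <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  half <- (w - 1) / 2
  xx <- c(tail(x, half), x, head(x, half))
  as.numeric(stats::filter(xx, rep(1 / w, w), sides = 2))[(half + 1):(half + n)]
}

#' Alternating extrema of a polar profile
#'
#' Smooths the profile with a circular moving average, detects local maxima
#' and minima (plateaus contribute their midpoint) and prunes shallow
#' extremum pairs until every adjacent max-min difference reaches
#' `min_prominence`. The result strictly alternates minima and maxima
#' around the circle.
#'
#' @param profile a [polar_profile()] object
#' @param smooth_win odd moving-average window in degrees
#' @param min_prominence minimum |max - min| between circular neighbours, px
#' @return data.frame with columns `degree` (0-based), `value` (smoothed
#'   distance) and `type` ("min"/"max"), circularly ordered by degree;
#'   zero rows when the profile is flat
#' @export
find_extrema <- function(profile, smooth_win = 9, min_prominence = 2) {
  if (smooth_win < 1 || smooth_win %% 2 == 0) stop("smooth_win must be odd and >= 1")
  x <- circular_smooth(profile$distances, smooth_win)
  n <- length(x)
  # run-length encode so plateaus collapse to one node at their midpoint
  r <- rle(x)
  vals <- r$values
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mids <- floor((starts + ends) / 2)
  m <- length(vals)
  # circular rle: a plateau split across the 359 -> 0 wrap is one run whose
  # midpoint is taken circularly
  if (m >= 2 && vals[1] == vals[m]) {
    l1 <- r$lengths[1]; lm <- r$lengths[m]
    mid <- (starts[m] - 1 + (l1 + lm) %/% 2) %% n + 1
    vals <- vals[-m]; mids <- mids[-m]
    mids[1] <- mid
    m <- m - 1
  }
  if (m < 2) return(data.frame(degree = integer(0), value = numeric(0),
                               type = character(0), stringsAsFactors = FALSE))
  prv <- c(m, seq_len(m - 1)); nxt <- c(seq(2, m), 1)
  is_max <- vals > vals[prv] & vals > vals[nxt]
  is_min <- vals < vals[prv] & vals < vals[nxt]
  keep <- which(is_max | is_min)
  if (length(keep) < 2) return(data.frame(degree = integer(0), value = numeric(0),
                                          type = character(0), stringsAsFactors = FALSE))
  deg <- mids[keep] - 1L
  val <- vals[keep]
  typ <- ifelse(is_max[keep], "max", "min")
  # detection alternates by construction; prune shallow adjacent pairs
  repeat {
    k <- length(val)
    if (k < 2) break
    nx <- c(seq(2, k), 1)
    amp <- abs(val - val[nx])
    if (min(amp) >= min_prominence) break
    i <- which.min(amp) # remove this adjacent extremum pair, keep alternation
    drop <- c(i, if (i == k) 1 else i + 1)
    val <- val[-drop]; deg <- deg[-drop]; typ <- typ[-drop]
    if (length(val) < 2) { val <- numeric(0); deg <- integer(0); typ <- character(0); break }
    # merging can leave equal-type neighbours with non-extremal values; repair
    rep_idx <- repair_alternation(val, typ)
    val <- val[rep_idx]; deg <- deg[rep_idx]; typ <- typ[rep_idx]
  }
  data.frame(degree = as.integer(deg), value = val, type = typ,
             stringsAsFactors = FALSE)
}

# After removing a pair, two same-type neighbours may become adjacent; keep
# the more extreme of each same-type run (deterministic: first on ties).
repair_alternation <- function(val, typ) {
  k <- length(val)
  if (k < 2) return(seq_len(k))
  keep <- rep(TRUE, k)
  repeat {
    idx <- which(keep)
    kk <- length(idx)
    if (kk < 2) break
    changed <- FALSE
    for (a in seq_len(kk)) {
      b <- if (a == kk) 1 else a + 1
      i <- idx[a]; j <- idx[b]
      if (i == j) next
      if (typ[i] == typ[j]) {
        if (typ[i] == "max") {
          keep[if (val[i] >= val[j]) j else i] <- FALSE
        } else {
          keep[if (val[i] <= val[j]) j else i] <- FALSE
        }
        changed <- TRUE
        break
      }
    }
    if (!changed) break
  }
  which(keep)
}

#' Circle through three points
#'
#' The unique circle through three non-collinear points (the three-point
#' definite circle theorem), solved from the perpendicular-bisector linear
#' system.
#'
#' @param a,b,c numeric length-2 points (x, y)
#' @return a [circle()]
#' @export
circumcircle <- function(a, b, c) {
  ax <- a[1]; ay <- a[2]; bx <- b[1]; by <- b[2]; cx <- c[1]; cy <- c[2]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  scale2 <- max((bx - ax)^2 + (by - ay)^2, (cx - ax)^2 + (cy - ay)^2,
                (cx - bx)^2 + (cy - by)^2)
  if (abs(d) < 1e-12 * max(scale2, 1)) stop("collinear points: no circumcircle")
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  circle(ux, uy, sqrt((ux - ax)^2 + (uy - ay)^2))
}

#' Split an overlapped region into individual fruit circles
#'
#' The polar-coordinate extreme-value procedure: compute the polar distance
#' profile about the centre of gravity, find the alternating min/max
#' extremum sequence, and for every circular min-max-min triplet
#' q_i - p_j - q_(i+1) fit the circumcircle through the corresponding
#' boundary points. With m maxima, m circles are emitted; collinear
#' triplets are skipped. With fewer than two minima the region's
#' equivalent area circle is returned as a single detection.
#'
#' @param region a region (normally one classified OVERLAPPED)
#' @param smooth_win,min_prominence forwarded to [find_extrema()]
#' @return data.frame of circles (cx, cy, r) with attribute `extrema`
#' @export
split_overlapped <- function(region, smooth_win = 9, min_prominence = 2) {
  prof <- polar_profile(region)
  ex <- find_extrema(prof, smooth_win, min_prominence)
  fallback <- function() {
    ac <- equivalent_area_circle(region)
    structure(data.frame(cx = ac[["cx"]], cy = ac[["cy"]], r = ac[["r"]]),
              extrema = ex, fallback = TRUE)
  }
  if (nrow(ex) == 0 || sum(ex$type == "min") < 2) return(fallback())
  maxima <- which(ex$type == "max")
  k <- nrow(ex)
  circles <- list()
  for (j in maxima) {
    qa <- if (j == 1) k else j - 1
    qb <- if (j == k) 1 else j + 1
    pts <- prof$boundary_points[c(ex$degree[qa], ex$degree[j], ex$degree[qb]) + 1, ,
                                drop = FALSE]
    ci <- tryCatch(circumcircle(pts[1, ], pts[2, ], pts[3, ]),
                   error = function(e) NULL) # collinear triplet: skip, logged
    if (!is.null(ci)) circles[[length(circles) + 1]] <- ci
  }
  if (length(circles) == 0) return(fallback())
  structure(as_circle_df(circles), extrema = ex, fallback = FALSE)
}
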