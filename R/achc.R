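#' Region status codes
#'
#' Three-way label for a foreground region: `ISOLATED` (1) a single free
#' fruit, `OCCLUDED` (2) a fruit partially hidden by foliage or branches so
#' the foreground is truncated, `OVERLAPPED` (3) several fruits fused into
#' one foreground region.
#'
#' @format integer constants
#' @export
ISOLATED <- 1L
#' @rdname ISOLATED
#' @export
OCCLUDED <- 2L
#' @rdname ISOLATED
#' @export
OVERLAPPED <- 3L

#' @rdname ISOLATED
#' @param status integer status code
#' @return `status_name`: a character label
#' @export
status_name <- function(status) {
  c("ISOLATED", "OCCLUDED", "OVERLAPPED")[status]
}

#' Thresholds for the status classifier
#'
#' The status decision compares the largest Hough circle against the
#' region's equivalent area circle. The qualitative relations
#' "approximately equal" / "much greater" are made numeric here:
#' `approx_tol` is the relative tolerance applied on the circle-area scale
#' (two circles are comparable when their areas agree within a factor
#' 1 + approx_tol) and `dominance_ratio` is the radius ratio beyond which
#' one circle strictly dominates. The Hough search window and accumulator
#' acceptance are also collected here.
#'
#' @param approx_tol relative tolerance for approximate equality, in (0, 1)
#' @param dominance_ratio radius ratio for strict dominance, > 1
#' @param hough_vote_frac minimum supported fraction of a circle's perimeter
#' @param r_min_frac,r_max_frac Hough radius search bounds as fractions of
#'   the equivalent area radius
#' @param r_cap absolute upper radius bound in px; defaults to ~1.3 times
#'   the largest fruit radius the 1700 px area gate admits, so a large fused
#'   cluster is never explained away by one region-sized circle
#' @return list of class `achc_thresholds`
#' @export
achc_thresholds <- function(approx_tol = 0.2, dominance_ratio = 1.5,
                            hough_vote_frac = 0.3,
                            r_min_frac = 0.4, r_max_frac = 2.0,
                            r_cap = 30) {
  if (approx_tol <= 0 || approx_tol >= 1) stop("approx_tol must lie in (0, 1)")
  if (dominance_ratio <= 1) stop("dominance_ratio must exceed 1")
  structure(list(approx_tol = approx_tol, dominance_ratio = dominance_ratio,
                 hough_vote_frac = hough_vote_frac,
                 r_min_frac = r_min_frac, r_max_frac = r_max_frac,
                 r_cap = r_cap),
            class = "achc_thresholds")
}

#' Equivalent foreground area circle of a region
#'
#' The circle centred at the region's centre of gravity whose area equals
#' the region's pixel area: r = sqrt(area / pi).
#'
#' @param region a region from [extract_regions()]
#' @return a [circle()]
#' @export
equivalent_area_circle <- function(region) {
  if (is.null(region$area) || region$area <= 0) stop("region has zero area")
  circle(region$centroid[["x"]], region$centroid[["y"]], sqrt(region$area / pi))
}

#' Hough circle detection on a region boundary
#'
#' Accumulator voting over (cx, cy, r) at 1-px resolution with the radius
#' window tied to the region's equivalent area radius. Returns circles
#' sorted by vote score (supported perimeter fraction) with near-duplicates
#' merged; an empty data frame when the boundary carries no circular
#' evidence.
#'
#' @param region a region from [extract_regions()]
#' @param thr an [achc_thresholds()] object
#' @param max_circles cap on returned circles
#' @return data.frame with columns cx, cy, r, score
#' @export
hough_circles <- function(region, thr = achc_thresholds(), max_circles = 6) {
  pts <- unique(region$boundary)
  empty <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                      score = numeric(0))
  if (is.null(pts) || nrow(pts) < 3) return(empty)
  ra <- sqrt(region$area / pi)
  rmin <- max(5L, as.integer(floor(thr$r_min_frac * ra)))
  rmax <- min(as.integer(ceiling(thr$r_max_frac * ra)), as.integer(thr$r_cap))
  if (rmax < rmin) return(empty)
  margin <- min(rmax, 80L)
  bb <- region$bbox
  if ((bb[["x1"]] - bb[["x0"]] > 400) || (bb[["y1"]] - bb[["y0"]] > 400))
    return(empty) # degenerate mega-region: no per-fruit circle evidence
  if (nrow(pts) > 2000) pts <- pts[seq(1, nrow(pts), length.out = 2000), , drop = FALSE]
  res <- cpp_hough_circles(pts,
                           as.integer(bb[["x0"]] - margin), as.integer(bb[["x1"]] + margin),
                           as.integer(bb[["y0"]] - margin), as.integer(bb[["y1"]] + margin),
                           rmin, rmax, thr$hough_vote_frac,
                           0.5, thr$approx_tol, as.integer(max_circles))
  if (nrow(res) == 0) return(empty)
  out <- data.frame(cx = res[, 1], cy = res[, 2], r = res[, 3], score = res[, 4])
  # sub-pixel refinement: least-squares circle through the inlier boundary
  # points of each accumulator peak, then re-merge duplicates that the
  # refinement pulled together
  for (i in seq_len(nrow(out))) {
    ref <- kasa_refine(pts, out$cx[i], out$cy[i], out$r[i])
    out$cx[i] <- ref[1]; out$cy[i] <- ref[2]; out$r[i] <- ref[3]
  }
  merge_circles(out, 0.5, thr$approx_tol)
}

# Kasa algebraic circle fit on boundary points within `band` px of the
# accumulator circle; falls back to the input when the fit is degenerate or
# drifts implausibly far.
kasa_refine <- function(pts, cx, cy, r, band = 2) {
  d <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
  sel <- abs(d - r) <= band
  if (sum(sel) < 12) return(c(cx, cy, r))
  x <- pts[sel, 1]; y <- pts[sel, 2]
  A <- cbind(x, y, 1)
  sol <- tryCatch(qr.solve(A, -(x^2 + y^2)), error = function(e) NULL)
  if (is.null(sol)) return(c(cx, cy, r))
  cx2 <- -sol[1] / 2; cy2 <- -sol[2] / 2
  r2sq <- cx2^2 + cy2^2 - sol[3]
  if (!is.finite(r2sq) || r2sq <= 0) return(c(cx, cy, r))
  r2 <- sqrt(r2sq)
  moved <- sqrt((cx2 - cx)^2 + (cy2 - cy)^2)
  if (moved > r / 2 || r2 < 0.7 * r || r2 > 1.4 * r) return(c(cx, cy, r))
  c(cx2, cy2, r2)
}

# Greedy duplicate merging in score order: the spec rule (centre distance
# below dist_frac * min radius and relative radius difference below
# radius_tol) plus containment suppression of weaker circles centred inside
# a kept circle of larger radius.
merge_circles <- function(df, dist_frac, radius_tol) {
  df <- df[order(-df$score, df$r, df$cy, df$cx), , drop = FALSE]
  keep <- integer(0)
  for (i in seq_len(nrow(df))) {
    dup <- FALSE
    for (j in keep) {
      d <- sqrt((df$cx[i] - df$cx[j])^2 + (df$cy[i] - df$cy[j])^2)
      rm <- min(df$r[i], df$r[j])
      if ((d < dist_frac * rm && abs(df$r[i] - df$r[j]) / rm < radius_tol) ||
          (d < df$r[j] && df$r[i] <= df$r[j])) {
        dup <- TRUE
        break
      }
    }
    if (!dup) keep <- c(keep, i)
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify a region as isolated, occluded or overlapped
#'
#' Compares the largest Hough radius Rh* against the equivalent area radius
#' Ra on the circle-area scale. The region is OCCLUDED when the Hough circle
#' dominates (pi Rh*^2 > (1 + tol) pi Ra^2, or Rh* >= dominance_ratio Ra):
#' the boundary arc implies a fruit larger than the visible foreground.
#' It is OVERLAPPED in the reciprocal case (the foreground holds more area
#' than any single circle explains). Otherwise the circles agree and the
#' region is ISOLATED; with no Hough evidence at all the classifier falls
#' back to ISOLATED. The sum-of-circle-areas relation (T = sum pi Rh^2
#' versus pi Ra^2) is attached as audit metadata.
#'
#' @param houghs data.frame of Hough circles (possibly empty)
#' @param area_circle the region's [equivalent_area_circle()]
#' @param thr an [achc_thresholds()] object
#' @return integer status with attribute `evidence`
#' @export
classify_status <- function(houghs, area_circle, thr = achc_thresholds()) {
  ra <- area_circle[["r"]]
  n <- if (is.null(houghs)) 0L else nrow(houghs)
  if (n == 0) {
    return(structure(ISOLATED, evidence = list(n_hough = 0L, rh_max = 0,
                                               ra = ra, sum_area = 0)))
  }
  rh <- max(houghs$r)
  total <- sum(pi * houghs$r^2)
  ev <- list(n_hough = n, rh_max = rh, ra = ra, sum_area = total,
             area_ratio = (rh / ra)^2)
  status <- if (rh^2 > (1 + thr$approx_tol) * ra^2 || rh >= thr$dominance_ratio * ra) {
    OCCLUDED
  } else if (ra^2 > (1 + thr$approx_tol) * rh^2 || ra >= thr$dominance_ratio * rh) {
    OVERLAPPED
  } else if (n >= 3 && total > (1 + thr$approx_tol) * pi * ra^2) {
    # several distinct circles jointly exceeding the region's own circle
    # area: a rosette-like cluster whose envelope mimics one large circle
    OVERLAPPED
  } else {
    ISOLATED
  }
  structure(status, evidence = ev)
}

#' Full status classification of every region in a mask
#'
#' Runs [equivalent_area_circle()], [hough_circles()] and
#' [classify_status()] per region.
#'
#' @param regions list of regions
#' @param thr an [achc_thresholds()] object
#' @return list per region: `region`, `status`, `area_circle`, `houghs`
#' @export
classify_regions <- function(regions, thr = achc_thresholds()) {
  lapply(regions, function(reg) {
    ac <- equivalent_area_circle(reg)
    hc <- hough_circles(reg, thr)
    st <- classify_status(hc, ac, thr)
    list(region = reg, status = as.integer(st), area_circle = ac, houghs = hc,
         evidence = attr(st, "evidence"))
  })
}
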