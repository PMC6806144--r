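# Intersection area of two discs (closed-form lens area).
circle_intersection_area <- function(c1, c2) {
  d <- sqrt((c1["cx"] - c2["cx"])^2 + (c1["cy"] - c2["cy"])^2)
  r1 <- c1[["r"]]; r2 <- c2[["r"]]
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(pi * min(r1, r2)^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt(pmax((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2), 0))
  as.numeric(a1 + a2 - a3)
}

#' Intersection-over-union of two circles
#'
#' Closed form via the lens area; the matching criterion for detections
#' against ground-truth fruit circles.
#'
#' @param c1,c2 circles (named vectors or one-row data.frames with cx, cy, r)
#' @return fraction in \[0, 1\]
#' @export
circle_iou <- function(c1, c2) {
  c1 <- unlist(as_circle_df(c1)[1, ]); c2 <- unlist(as_circle_df(c2)[1, ])
  i <- circle_intersection_area(c1, c2)
  u <- pi * c1[["r"]]^2 + pi * c2[["r"]]^2 - i
  i / u
}

#' Match detections against ground truth
#'
#' Greedy one-to-one assignment by descending circle IoU: pairs at or above
#' `iou_thr` become true positives; unmatched truths are false negatives and
#' unmatched detections false positives. Ties are broken on coordinate
#' values so the result is invariant to input order.
#'
#' @param dets detections (data.frame cx, cy, r or list of circles)
#' @param truth ground-truth circles
#' @param iou_thr IoU threshold in (0, 1)
#' @return list with `tp`, `fn`, `fp` counts and `matches`, a data.frame of
#'   assigned (det, truth, iou) index pairs
#' @export
match_detections <- function(dets, truth, iou_thr = 0.4) {
  if (iou_thr <= 0 || iou_thr >= 1) stop("iou_thr must lie in (0, 1)")
  d <- as_circle_df(dets); g <- as_circle_df(truth)
  nd <- nrow(d); ng <- nrow(g)
  if (nd == 0 || ng == 0) {
    return(list(tp = 0L, fn = ng, fp = nd,
                matches = data.frame(det = integer(0), truth = integer(0),
                                     iou = numeric(0))))
  }
  pairs <- expand.grid(det = seq_len(nd), truth = seq_len(ng))
  pairs$iou <- vapply(seq_len(nrow(pairs)), function(k) {
    circle_iou(d[pairs$det[k], ], g[pairs$truth[k], ])
  }, numeric(1))
  pairs <- pairs[pairs$iou >= iou_thr, , drop = FALSE]
  # order-invariant tie-breaks: by IoU, then by coordinates of the pair
  ord <- order(-pairs$iou, g$cx[pairs$truth], g$cy[pairs$truth],
               d$cx[pairs$det], d$cy[pairs$det], d$r[pairs$det])
  pairs <- pairs[ord, , drop = FALSE]
  used_d <- logical(nd); used_g <- logical(ng)
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$det[k]; j <- pairs$truth[k]
    if (!used_d[i] && !used_g[j]) {
      keep[k] <- TRUE; used_d[i] <- TRUE; used_g[j] <- TRUE
    }
  }
  m <- pairs[keep, , drop = FALSE]
  rownames(m) <- NULL
  list(tp = nrow(m), fn = ng - nrow(m), fp = nd - nrow(m), matches = m)
}

#' Precision, recall and F1 from detection counts
#'
#' P = TP / (TP + FP), Rc = TP / (TP + FN), F1 = 2 P Rc / (P + Rc); reported
#' as percentages. When both P and Rc are zero the F1 0/0 limit is defined
#' as 0. Display values are rounded half-up to two decimals; unrounded
#' values are retained.
#'
#' @param tp,fn,fp non-negative counts
#' @return list of class `metrics_report` with `total`, the counts, exact
#'   `precision`, `recall`, `f1` (percent) and their 2-decimal display values
#' @export
compute_report <- function(tp, fn, fp) {
  if (any(c(tp, fn, fp) < 0)) stop("counts must be non-negative")
  if (tp + fp == 0) stop("precision undefined: no detections (tp + fp = 0)")
  if (tp + fn == 0) stop("recall undefined: no ground-truth fruits (tp + fn = 0)")
  p <- 100 * tp / (tp + fp)
  rc <- 100 * tp / (tp + fn)
  f1 <- if (p + rc == 0) 0 else 2 * p * rc / (p + rc)
  structure(list(total = tp + fn, tp = tp, fn = fn, fp = fp,
                 precision = p, recall = rc, f1 = f1,
                 display = c(precision = round_half_up(p, 2),
                             recall = round_half_up(rc, 2),
                             f1 = round_half_up(f1, 2))),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Total %d  TP %d  FN %d  FP %d  Precision %.2f%%  Recall %.2f%%  F1 %.2f%%\n",
              x$total, x$tp, x$fn, x$fp, x$display["precision"],
              x$display["recall"], x$display["f1"]))
  invisible(x)
}
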