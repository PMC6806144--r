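#' Pipeline configuration
#'
#' All module defaults in one nested list that round-trips through JSON.
#' The `preprocess` flag reproduces the with/without illumination
#' compensation ablation; `classifier` gates the LBP-SVM filter (a model
#' must also be supplied to [detect()]).
#'
#' @param preprocess apply CLAHE illumination compensation first
#' @param clahe list(blocks, clip_limit)
#' @param morph list(erode, dilate) disk radii
#' @param achc list(approx_tol, dominance_ratio, hough_vote_frac,
#'   r_min_frac, r_max_frac)
#' @param pcevp list(smooth_win, min_prominence)
#' @param lbp list(patch_size)
#' @param gate list(lo, hi) inclusive ROI pixel-area bounds
#' @param eval list(iou) matching threshold
#' @param classifier apply the LBP-SVM filter when a model is given
#' @return nested list of class `pipeline_config`
#' @export
pipeline_config <- function(preprocess = TRUE,
                            clahe = list(blocks = 10, clip_limit = 0.015),
                            morph = list(erode = 3, dilate = 3),
                            achc = list(approx_tol = 0.2, dominance_ratio = 1.5,
                                        hough_vote_frac = 0.3,
                                        r_min_frac = 0.4, r_max_frac = 2.0,
                                        r_cap = 30),
                            pcevp = list(smooth_win = 9, min_prominence = 2),
                            lbp = list(patch_size = 32),
                            gate = list(lo = 800, hi = 1700),
                            eval = list(iou = 0.4),
                            classifier = TRUE) {
  structure(list(preprocess = preprocess, clahe = clahe, morph = morph,
                 achc = achc, pcevp = pcevp, lbp = lbp, gate = gate,
                 eval = eval, classifier = classifier),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as JSON
#'
#' @param cfg a [pipeline_config()]
#' @param path JSON file path
#' @export
config_save <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname config_save
#' @export
config_load <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, j)
}

#' End-to-end fruit detection on one image
#'
#' The full flow: optional CLAHE compensation, chromatic segmentation,
#' per-region status classification, candidate circle generation (the
#' equivalent area circle for ISOLATED regions, the largest Hough circle
#' for OCCLUDED ones, the polar-profile split for OVERLAPPED clusters), the
#' ROI pixel-size gate on the candidate circle area, and the optional
#' LBP-SVM texture filter. Every region contributes at least one candidate
#' or a gating record, so nothing is silently dropped.
#'
#' @param img RGB image array
#' @param cfg a [pipeline_config()]
#' @param model optional trained `hik_svm`; filtered only when
#'   `cfg$classifier` is TRUE
#' @return data.frame of detections (cx, cy, r, status, score, accepted)
#'   with attribute `log`, one record per region per stage
#' @export
detect <- function(img, cfg = pipeline_config(), model = NULL) {
  assert_rgb_image(img)
  if (isTRUE(cfg$preprocess)) {
    img <- clahe_compensate(img, clahe_params(cfg$clahe$blocks, cfg$clahe$clip_limit))
  }
  seg <- tryCatch(segment_foreground(img, cfg$morph$erode, cfg$morph$dilate),
                  error = function(e) NULL) # constant map: no foreground at all
  empty <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                      status = integer(0), score = numeric(0),
                      accepted = logical(0))
  if (is.null(seg) || length(seg$regions) == 0) {
    return(structure(empty, log = list()))
  }
  thr <- do.call(achc_thresholds, cfg$achc)
  logrec <- list()
  cand <- list()
  for (cls in classify_regions(seg$regions, thr)) {
    reg <- cls$region
    circles <- if (cls$status == OVERLAPPED) {
      # strongly non-convex noise regions can put the centroid outside the
      # region; degrade to the single area circle rather than fail
      tryCatch(split_overlapped(reg, cfg$pcevp$smooth_win, cfg$pcevp$min_prominence),
               error = function(e) as_circle_df(cls$area_circle))
    } else if (cls$status == OCCLUDED && nrow(cls$houghs) > 0) {
      # the arc-completion circle localizes a truncated fruit
      as_circle_df(cls$houghs[which.max(cls$houghs$r), c("cx", "cy", "r")])
    } else {
      as_circle_df(cls$area_circle)
    }
    circles <- as_circle_df(circles)
    circles$status <- cls$status
    circles$label <- reg$label
    logrec[[length(logrec) + 1]] <- list(label = reg$label, stage = "classify",
                                         status = cls$status, area = reg$area,
                                         n_candidates = nrow(circles),
                                         evidence = cls$evidence)
    cand[[length(cand) + 1]] <- circles
  }
  cand <- do.call(rbind, cand)
  # ROI size gate on candidate circle areas (inclusive bounds)
  gated <- pi * cand$r^2 >= cfg$gate$lo & pi * cand$r^2 <= cfg$gate$hi
  for (i in which(!gated)) {
    logrec[[length(logrec) + 1]] <- list(label = cand$label[i], stage = "gate",
                                         area = pi * cand$r[i]^2,
                                         dropped = TRUE,
                                         status = cand$status[i])
  }
  cand <- cand[gated, , drop = FALSE]
  if (nrow(cand) == 0) return(structure(empty, log = logrec))
  if (isTRUE(cfg$classifier) && !is.null(model)) {
    feats <- t(vapply(seq_len(nrow(cand)), function(i) {
      as.numeric(uniform_lbp(extract_patch(img, cand[i, c("cx", "cy", "r")],
                                           cfg$lbp$patch_size)))
    }, numeric(59)))
    score <- svm_decision(model, feats)
    accepted <- score >= 0
  } else {
    score <- rep(NA_real_, nrow(cand))
    accepted <- rep(TRUE, nrow(cand))
  }
  out <- data.frame(cx = cand$cx, cy = cand$cy, r = cand$r,
                    status = cand$status, score = score, accepted = accepted)
  structure(out, log = logrec)
}

#' Write / read a scene (image + ground truth) to a directory
#'
#' Images as plain PPM, ground truth as JSON; the on-disk format consumed
#' by [batch_evaluate()] and the CLI.
#'
#' @param scene output of [generate_scene()]
#' @param dir directory
#' @param name basename without extension
#' @export
write_scene <- function(scene, dir, name) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_ppm(scene$image, file.path(dir, paste0(name, ".ppm")))
  fr <- scene$truth$fruits
  jsonlite::write_json(list(fruits = fr), file.path(dir, paste0(name, ".json")),
                       digits = NA, dataframe = "rows")
  invisible(file.path(dir, name))
}

#' @rdname write_scene
#' @param path JSON ground-truth path
#' @export
read_truth <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  fr <- as.data.frame(j$fruits)
  fr
}

#' Evaluate the detector over a directory of scenes
#'
#' Pairs every `<name>.ppm` with `<name>.json`, runs [detect()] on each
#' image, matches accepted detections against the ground-truth circles and
#' pools the counts (pooled counts are the sums of per-scene counts).
#'
#' @param scene_dir directory of paired `.ppm`/`.json` files
#' @param cfg a [pipeline_config()]
#' @param model optional `hik_svm`
#' @return list with `per_scene` (data.frame of counts per scene) and
#'   `pooled`, a [compute_report()] result
#' @export
batch_evaluate <- function(scene_dir, cfg = pipeline_config(), model = NULL) {
  ppm <- sort(list.files(scene_dir, pattern = "\\.ppm$", full.names = TRUE))
  if (length(ppm) == 0) stop("no scenes found in ", scene_dir)
  js <- sub("\\.ppm$", ".json", ppm)
  missing <- !file.exists(js)
  if (any(missing))
    stop("unpaired scene files (no ground truth): ",
         paste(basename(ppm[missing]), collapse = ", "))
  rows <- lapply(seq_along(ppm), function(i) {
    img <- read_ppm(ppm[i])
    truth <- read_truth(js[i])
    dets <- detect(img, cfg, model)
    dets <- dets[dets$accepted, , drop = FALSE]
    m <- match_detections(dets, truth, cfg$eval$iou)
    data.frame(scene = basename(ppm[i]), tp = m$tp, fn = m$fn, fp = m$fp)
  })
  per <- do.call(rbind, rows)
  pooled <- compute_report(sum(per$tp), sum(per$fn), sum(per$fp))
  list(per_scene = per, pooled = pooled)
}
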