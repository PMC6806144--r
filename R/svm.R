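#' Train a histogram-intersection-kernel SVM
#'
#' Soft-margin kernel SVM on the precomputed HIK Gram matrix, solved by a
#' deterministic sequential minimal optimization (SMO) loop: the first index
#' sweeps training points in order, the partner maximizes |E_i - E_j| with
#' ties to the smallest index, so identical inputs in identical order give
#' bit-identical models. Labels are fruit = +1, background = -1.
#'
#' @param pos matrix of positive-class feature histograms (rows)
#' @param neg matrix of negative-class feature histograms (rows)
#' @param C soft-margin regularization
#' @param tol KKT violation tolerance
#' @param max_epochs cap on full passes without progress check
#' @return list of class `hik_svm`: support vectors, dual coefficients
#'   (alpha * y), bias, and training metadata
#' @export
svm_train <- function(pos, neg, C = 1, tol = 1e-3, max_epochs = 200) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  if (nrow(pos) == 0 || nrow(neg) == 0) stop("both classes must be nonempty")
  if (ncol(pos) != ncol(neg)) stop("feature dimensions differ")
  X <- rbind(pos, neg)
  y <- c(rep(1, nrow(pos)), rep(-1, nrow(neg)))
  n <- nrow(X)
  K <- hik_gram(X)
  alpha <- numeric(n)
  b <- 0
  fcache <- function() as.numeric(K %*% (alpha * y)) + b
  epochs <- 0
  repeat {
    changed <- 0L
    f <- fcache()
    E <- f - y
    for (i in seq_len(n)) {
      Ei <- E[i]
      r <- Ei * y[i]
      if (!((r < -tol && alpha[i] < C) || (r > tol && alpha[i] > 0))) next
      j <- which.max(abs(E - Ei) + ifelse(seq_len(n) == i, -Inf, 0))
      if (j == i) next
      Ej <- E[j]
      ai_old <- alpha[i]; aj_old <- alpha[j]
      if (y[i] != y[j]) {
        L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
      } else {
        L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
      }
      if (L >= H) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= 0) next
      aj <- aj_old - y[j] * (Ei - Ej) / eta
      aj <- min(max(aj, L), H)
      if (abs(aj - aj_old) < 1e-7) next
      ai <- ai_old + y[i] * y[j] * (aj_old - aj)
      b_old <- b
      b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] - y[j] * (aj - aj_old) * K[i, j]
      b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] - y[j] * (aj - aj_old) * K[j, j]
      b <- if (ai > 0 && ai < C) b1 else if (aj > 0 && aj < C) b2 else (b1 + b2) / 2
      alpha[i] <- ai; alpha[j] <- aj
      # incremental error refresh for subsequent picks within this sweep
      E <- E + y[i] * (ai - ai_old) * K[, i] + y[j] * (aj - aj_old) * K[, j] +
        (b - b_old)
      changed <- changed + 1L
    }
    epochs <- epochs + 1
    if (changed == 0L || epochs >= max_epochs) break
  }
  sv <- which(alpha > 1e-8)
  structure(list(sv = X[sv, , drop = FALSE],
                 coef = alpha[sv] * y[sv],
                 bias = b,
                 kernel = "hik",
                 C = C,
                 n_pos = nrow(pos), n_neg = nrow(neg)),
            class = "hik_svm")
}

#' Decision values of a trained HIK-SVM
#'
#' f(x) = sum_i coef_i K(sv_i, x) + bias; the predicted class is fruit when
#' f(x) >= 0 (ties accepted).
#'
#' @param model a `hik_svm` from [svm_train()]
#' @param X matrix of feature histograms (rows)
#' @return numeric decision values
#' @export
svm_decision <- function(model, X) {
  X <- as.matrix(X)
  if (nrow(model$sv) == 0) return(rep(model$bias, nrow(X)))
  as.numeric(t(hik_gram(model$sv, X)) %*% model$coef) + model$bias
}

#' Save / load an HIK-SVM model as JSON
#'
#' Numbers are written at full IEEE round-trip precision so the reloaded
#' decision function is bit-identical.
#'
#' @param model a `hik_svm`
#' @param path JSON file path
#' @export
svm_save <- function(model, path) {
  # doubles stored as %.17g strings: JSON numeric emitters truncate to 15
  # significant digits, which breaks bit-identical reload
  full <- function(x) sprintf("%.17g", x)
  jsonlite::write_json(list(sv = matrix(full(model$sv), nrow(model$sv)),
                            coef = full(model$coef), bias = full(model$bias),
                            kernel = model$kernel, C = model$C,
                            n_pos = model$n_pos, n_neg = model$n_neg),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname svm_save
#' @export
svm_load <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(dim(j$sv))) j$sv <- matrix(j$sv, nrow = 1)
  structure(list(sv = matrix(as.numeric(j$sv), nrow = nrow(j$sv)),
                 coef = as.numeric(j$coef), bias = as.numeric(j$bias),
                 kernel = j$kernel, C = j$C,
                 n_pos = j$n_pos, n_neg = j$n_neg),
            class = "hik_svm")
}

#' Filter candidate detections with the LBP-SVM classifier
#'
#' Extracts a grayscale patch per detection circle, computes its uniform
#' LBP histogram and accepts the detection when the SVM decision value is
#' non-negative. Both accepted and rejected sets are returned with their
#' scores for auditability.
#'
#' @param dets data.frame of circles (cx, cy, r) or list of [circle()]s
#' @param img the RGB image the detections refer to
#' @param clf a trained `hik_svm`
#' @param patch_size patch side length for [extract_patch()]
#' @return list with data.frames `accepted` and `rejected`, each carrying a
#'   `score` column
#' @export
filter_detections <- function(dets, img, clf, patch_size = 32) {
  cd <- as_circle_df(dets)
  if (nrow(cd) == 0) {
    empty <- cbind(cd, score = numeric(0))
    return(list(accepted = empty, rejected = empty))
  }
  feats <- t(vapply(seq_len(nrow(cd)), function(i) {
    as.numeric(uniform_lbp(extract_patch(img, cd[i, ], patch_size)))
  }, numeric(59)))
  sc <- svm_decision(clf, feats)
  out <- cbind(cd, score = sc)
  list(accepted = out[sc >= 0, , drop = FALSE],
       rejected = out[sc < 0, , drop = FALSE])
}
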