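#' Round half away from zero
#'
#' Display rounding used for percentage tables; R's `round()` rounds half to
#' even, which does not reproduce conventional table formatting.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded generators are pure functions
#' of their spec and do not disturb the caller's RNG stream.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

# Derive a child seed from a base seed, staying inside 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + k * 104729) %% 2147483647)
}

#' Construct a circle
#'
#' The universal detection geometry: centre in pixel coordinates
#' (x = column, y = row, 0-based) and radius in pixels.
#'
#' @param cx,cy centre coordinates (sub-pixel allowed)
#' @param r radius in px, must be positive
#' @return a named numeric vector of class `lychee_circle`
#' @export
circle <- function(cx, cy, r) {
  if (!is.finite(r) || r <= 0) stop("circle radius must be positive")
  structure(c(cx = as.numeric(cx), cy = as.numeric(cy), r = as.numeric(r)),
            class = "lychee_circle")
}

# Normalize a collection of circles to a data.frame with cx, cy, r columns.
as_circle_df <- function(x) {
  if (is.null(x) || (is.list(x) && length(x) == 0))
    return(data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0)))
  if (inherits(x, "lychee_circle"))
    return(data.frame(cx = x[["cx"]], cy = x[["cy"]], r = x[["r"]]))
  if (is.data.frame(x)) {
    stopifnot(all(c("cx", "cy", "r") %in% names(x)))
    return(x[, c("cx", "cy", "r"), drop = FALSE][seq_len(nrow(x)), , drop = FALSE])
  }
  if (is.list(x)) {
    df <- do.call(rbind, lapply(x, function(ci) as_circle_df(ci)))
    rownames(df) <- NULL
    return(df)
  }
  stop("cannot interpret object as circles")
}
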