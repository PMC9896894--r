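#' Build a monotone depth-to-age model from dated anchors
#'
#' Sediment ages enter the pipeline as externally dated anchor points
#' (e.g. from excess Pb-210 and Cs-137 profiles published elsewhere); this
#' model only interpolates between them.  Anchors are sorted by depth and must
#' then be strictly increasing in both depth and age, giving a piecewise
#' constant sedimentation rate per segment.
#'
#' @param depth Anchor depths in cm below the sediment-water interface
#'   (layer midpoints).
#' @param age Anchor ages in years before sampling.
#' @param max_age Optional hard cap: [age_at_depth()] errors if an
#'   extrapolated age would exceed it (guards against absurd extrapolation).
#' @return Object of class `"age_model"` with the sorted anchors and
#'   per-segment sedimentation rates (cm/y).
#' @examples
#' m <- age_model(c(0, 10, 20), c(0, 50, 250))
#' m$rates_cm_y          # 0.2 and 0.05 cm/y
#' age_at_depth(m, 15)   # 150 y
#' @export
age_model <- function(depth, age, max_age = Inf) {
  stopifnot(length(depth) == length(age))
  if (length(depth) < 2L) stop("need at least 2 anchors")
  if (anyNA(depth) || anyNA(age)) stop("anchors must not contain NA")
  o <- order(depth)
  depth <- as.numeric(depth[o])
  age <- as.numeric(age[o])
  dd <- diff(depth)
  da <- diff(age)
  bad <- which(dd <= 0 | da <= 0)
  if (length(bad)) {
    i <- bad[1L]
    stop(sprintf(
      "anchors must be strictly increasing in depth and age; offending pair: (%g cm, %g y) -> (%g cm, %g y)",
      depth[i], age[i], depth[i + 1L], age[i + 1L]))
  }
  structure(
    list(depth_cm = depth, age_y = age, rates_cm_y = dd / da,
         max_age = max_age),
    class = "age_model"
  )
}

#' @rdname age_model
#' @param anchors For `build_age_model()`, a data frame with columns
#'   `depth_cm` and `age_y` (as returned by [read_anchors()]).
#' @param ... Passed on to `age_model()`.
#' @export
build_age_model <- function(anchors, ...) {
  age_model(anchors$depth_cm, anchors$age_y, ...)
}

#' Assign ages to sample depths
#'
#' Piecewise-linear interpolation between anchors; beyond the deepest anchor,
#' linear extrapolation continues the deepest segment's sedimentation rate
#' (and likewise the shallowest segment's rate above the shallowest anchor,
#' floored at age 0 for nonnegative depths above an age-0 surface anchor).
#'
#' @param model An [age_model()].
#' @param depth Depths in cm (`>= 0`).
#' @return Ages in years, same length as `depth`.
#' @export
age_at_depth <- function(model, depth) {
  stopifnot(inherits(model, "age_model"))
  depth <- as.numeric(depth)
  if (any(depth < 0, na.rm = TRUE)) stop("depth must be nonnegative")
  d <- model$depth_cm
  a <- model$age_y
  n <- length(d)
  out <- approx(d, a, xout = depth, rule = 1L)$y
  below <- !is.na(depth) & depth > d[n]
  out[below] <- a[n] + (depth[below] - d[n]) / model$rates_cm_y[n - 1L]
  above <- !is.na(depth) & depth < d[1L]
  out[above] <- pmax(0, a[1L] - (d[1L] - depth[above]) / model$rates_cm_y[1L])
  if (any(out > model$max_age, na.rm = TRUE)) {
    stop(sprintf("extrapolated age exceeds max_age = %g y", model$max_age))
  }
  out
}

#' @export
predict.age_model <- function(object, depth, ...) age_at_depth(object, depth)

#' @export
print.age_model <- function(x, ...) {
  cat(sprintf("<age_model> %d anchors, %g-%g cm, %g-%g y\n",
              length(x$depth_cm), min(x$depth_cm), max(x$depth_cm),
              min(x$age_y), max(x$age_y)))
  cat("  segment sedimentation rates (cm/y):",
      paste(signif(x$rates_cm_y, 4), collapse = ", "), "\n")
  invisible(x)
}
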