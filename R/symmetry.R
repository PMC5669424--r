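# Weighted four-axis mirror-symmetry measure.
#
# For each predefined axis, reflected pixel pairs are compared and matches
# are weighted linearly so that pairs adjacent to the axis count twice as
# much as pairs at the image border; the score is the weighted fraction of
# matching pairs. For the vertical axis with m rows, w columns and
# n = floor(w/2) pair columns this is
#
#   s = 2/(3 m n) * sum_i sum_j X_ij * (1 + (j - 1)/(n - 1)),
#
# where j runs from the border (weight 1) towards the axis (weight 2) and
# X_ij = 1 iff the pair matches; the constant 2/(3 m n) is exactly one over
# the total weight, so s ranges over [0, 1] and equals 1 iff the image is
# mirror-symmetric about the axis. A centre column/row (odd dimension) or
# the diagonal itself is ignored.

SYM_AXES <- c("vertical", "horizontal", "main_diagonal", "secondary_diagonal")

# Fixed axis order behind the exported per-axis column names MSA..MSD.
MS_AXIS_COLS <- c(MSA = "horizontal", MSB = "vertical",
                  MSC = "main_diagonal", MSD = "secondary_diagonal")

#' Mirror symmetry of a binary image about one axis
#'
#' Computes the weighted reflected-pair symmetry score for one of the four
#' predefined axes. Pixels close to the axis have more influence: the pair
#' weight rises linearly from 1 at the image border to 2 next to the axis.
#' The score is normalized to \[0, 1\] and equals 1 exactly when the image
#' is mirror-symmetric about the axis.
#'
#' @param img Binary numeric matrix (values 0/1).
#' @param axis One of `"vertical"`, `"horizontal"`, `"main_diagonal"`,
#'   `"secondary_diagonal"`. Diagonal axes require a square image.
#' @return A single number in \[0, 1\].
#' @examples
#' m <- matrix(c(1, 0, 0, 1,
#'               1, 1, 0, 0), nrow = 2, byrow = TRUE)
#' axis_symmetry(m, "vertical")  # 0.5
#' @export
axis_symmetry <- function(img, axis = SYM_AXES) {
  axis <- match.arg(axis)
  check_raster(img, binary = TRUE)
  switch(axis,
    vertical           = axis_symmetry_vertical(img),
    horizontal         = axis_symmetry_vertical(t(img)),
    main_diagonal      = axis_symmetry_diag(img),
    secondary_diagonal = axis_symmetry_diag(rot90(img))
  )
}

# Vertical-axis score: the closed-form weighted pair count.
axis_symmetry_vertical <- function(img) {
  m <- nrow(img); w <- ncol(img)
  n <- w %/% 2
  if (n == 0) stop("image width < 2: no reflected pairs", call. = FALSE)
  j <- seq_len(n)
  X <- img[, j, drop = FALSE] == img[, w + 1L - j, drop = FALSE]
  if (n == 1) return(sum(X) / m)  # single pair column: weight 1, normalizer m
  wt <- 1 + (j - 1) / (n - 1)
  2 / (3 * m * n) * sum(X %*% wt)
}

# Main-diagonal score: pairs (i, i+d) <-> (i+d, i) at offsets d = 1..w-1;
# the same linear border->axis weighting, normalized by the total weight.
axis_symmetry_diag <- function(img) {
  w <- ncol(img)
  if (nrow(img) != w)
    stop("diagonal symmetry requires a square image", call. = FALSE)
  if (w < 2) stop("image width < 2: no reflected pairs", call. = FALSE)
  nd <- w - 1L
  wt <- if (nd == 1) 1 else 1 + (nd - seq_len(nd)) / (nd - 1)
  num <- 0; den <- 0
  for (d in seq_len(nd)) {
    i <- seq_len(w - d)
    X <- img[cbind(i, i + d)] == img[cbind(i + d, i)]
    num <- num + wt[d] * sum(X)
    den <- den + wt[d] * (w - d)
  }
  num / den
}

#' Four-axis symmetry profile of a square binary image
#'
#' Scores all four predefined axes and aggregates them on a 0-100 scale:
#' `ms = 100 * (s1 + s2 + s3 + s4) / 4`. The per-axis scores map onto the
#' exported column names in the fixed order `MSA` (horizontal), `MSB`
#' (vertical), `MSC` (main diagonal), `MSD` (secondary diagonal).
#'
#' @param img Square binary numeric matrix.
#' @return An object of class `symmetry_profile`: list with `axes` (named
#'   per-axis scores), `ms` (aggregate, 0-100) and `image_shape`.
#' @export
mirror_symmetry <- function(img) {
  check_raster(img, binary = TRUE, square = TRUE)
  s <- vapply(SYM_AXES, function(a) axis_symmetry(img, a), numeric(1))
  structure(
    list(axes = s, ms = 100 * mean(s), image_shape = dim(img)),
    class = "symmetry_profile"
  )
}

#' @exportS3Method base::print
print.symmetry_profile <- function(x, ...) {
  cat("Mirror-symmetry profile (", paste(x$image_shape, collapse = " x "),
      " image)\n", sep = "")
  cat(sprintf("  %-18s %.4f\n", names(x$axes), x$axes), sep = "")
  cat(sprintf("  MS (0-100):        %.2f\n", x$ms))
  invisible(x)
}

#' Specify a non-linear transform of per-axis symmetry scores
#'
#' The transforms emphasize small deviations from perfect symmetry:
#' `power` maps s to s^a; `exponential` maps s to
#' (exp(a s) - 1)/(exp(a) - 1); `threshold_stretch` clamps scores below t
#' to 0 and linearly stretches \[t, 1\] onto \[0, 1\].
#'
#' @param family `"power"`, `"exponential"` or `"threshold_stretch"`.
#' @param a Exponent for the power/exponential families (a >= 1).
#' @param t Threshold in \[0, 1) for the stretch family.
#' @return An object of class `transform_spec`.
#' @export
transform_spec <- function(family = c("power", "exponential",
                                      "threshold_stretch"),
                           a = 1, t = 0.95) {
  family <- match.arg(family)
  if (family %in% c("power", "exponential")) {
    if (!is.numeric(a) || length(a) != 1 || a < 1)
      stop("exponent a must be a single number >= 1", call. = FALSE)
  } else if (!is.numeric(t) || length(t) != 1 || t < 0 || t >= 1) {
    stop("threshold t must lie in [0, 1)", call. = FALSE)
  }
  structure(list(family = family, a = a, t = t), class = "transform_spec")
}

# Apply a transform_spec to a vector of per-axis scores in [0, 1].
apply_transform <- function(s, spec) {
  switch(spec$family,
    power       = s^spec$a,
    exponential = if (spec$a == 1) s else expm1(spec$a * s) / expm1(spec$a),
    threshold_stretch = pmax(0, (s - spec$t) / (1 - spec$t))
  )
}

#' Transformed aggregate symmetry score
#'
#' Applies a non-linear transform to each per-axis score *before* averaging
#' and rescaling to 0-100. With the power family and exponent `a` this is
#' the MSA-a family, e.g. `MSA20 = 100 * (s1^20 + s2^20 + s3^20 + s4^20)/4`.
#' At `a = 1` it reduces to the untransformed aggregate.
#'
#' @param profile A `symmetry_profile` (or a numeric vector of 4 per-axis
#'   scores in \[0, 1\]).
#' @param spec A [transform_spec()].
#' @return Transformed aggregate score on the 0-100 scale.
#' @export
transform_profile <- function(profile, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  s <- if (inherits(profile, "symmetry_profile")) profile$axes else profile
  if (!is.numeric(s) || anyNA(s) || min(s) < 0 || max(s) > 1)
    stop("per-axis scores must lie in [0, 1]", call. = FALSE)
  100 * mean(apply_transform(s, spec))
}

#' Search a grid of symmetry transforms for the best two-predictor model
#'
#' For every transform in `grid`, the per-axis symmetry columns (`MSA`,
#' `MSB`, `MSC`, `MSD`) of `table` are transformed, aggregated to a 0-100
#' score, and an ordinary least-squares model
#' `rating ~ transformed symmetry + companion` is fitted; transforms are
#' ranked by model R^2 (descending, deterministic; ties broken by grid
#' position).
#'
#' @param table Data frame with per-axis symmetry columns `MSA`..`MSD`
#'   (unit scale) and the companion predictor column.
#' @param ratings Numeric vector of per-stimulus mean ratings, aligned with
#'   the rows of `table`.
#' @param companion Name of the companion predictor column (e.g.
#'   `"RMSGIF"`).
#' @param grid List of [transform_spec()] objects.
#' @return Data frame with one row per transform: family, parameter, and
#'   model `r_squared`, sorted by decreasing `r_squared`.
#' @export
transform_search <- function(table, ratings, companion, grid) {
  if (length(grid) == 0) stop("transform grid is empty", call. = FALSE)
  need <- c("MSA", "MSB", "MSC", "MSD", companion)
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table lacks columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(ratings) != nrow(table))
    stop("ratings and table are not aligned", call. = FALSE)
  S <- as.matrix(table[, c("MSA", "MSB", "MSC", "MSD")])
  res <- lapply(seq_along(grid), function(k) {
    spec <- grid[[k]]
    stopifnot(inherits(spec, "transform_spec"))
    sym <- 100 * rowMeans(apply_transform(S, spec))
    fit <- stats::lm.fit(cbind(1, sym, table[[companion]]), ratings)
    r2 <- 1 - sum(fit$residuals^2) / sum((ratings - mean(ratings))^2)
    data.frame(
      family = spec$family,
      parameter = if (spec$family == "threshold_stretch") spec$t else spec$a,
      r_squared = r2
    )
  })
  out <- do.call(rbind, res)
  out[order(-out$r_squared, seq_len(nrow(out))), , drop = FALSE]
}
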