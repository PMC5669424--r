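# Model-fitting harness: rating aggregation, z-standardization, OLS with
# full inference, exhaustive best-subset selection, performance metrics,
# and cross-validated random forests.

#' Aggregate a long rating table to per-stimulus means
#'
#' @param ratings Data frame with columns `participant`, `stimulus`,
#'   `rating` and optionally `exclude_from_mean` (logical); excluded rows
#'   (e.g. repeat presentations in a later session) do not enter the mean.
#' @return Data frame with columns `stimulus` and `mean_rating`; stimuli
#'   with no non-excluded ratings are absent.
#' @export
aggregate_ratings <- function(ratings) {
  stopifnot(is.data.frame(ratings), nrow(ratings) > 0,
            all(c("stimulus", "rating") %in% names(ratings)))
  keep <- if ("exclude_from_mean" %in% names(ratings))
    !ratings$exclude_from_mean else rep(TRUE, nrow(ratings))
  r <- ratings[keep, , drop = FALSE]
  mw <- tapply(r$rating, r$stimulus, mean)
  data.frame(stimulus = names(mw), mean_rating = as.numeric(mw),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' z-standardize predictor columns
#'
#' Centres each numeric column to mean 0 and scales to sample SD 1
#' (denominator n - 1). The centres and scales are attached as attributes
#' `center` and `scale` so the transform can be reused on new data.
#'
#' @param table Data frame of numeric predictor columns (non-numeric
#'   columns such as stimulus ids are passed through untouched).
#' @return The standardized data frame.
#' @export
zstandardize <- function(table) {
  num <- vapply(table, is.numeric, logical(1))
  ctr <- scl <- numeric(0)
  for (nm in names(table)[num]) {
    x <- table[[nm]]
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      stop("constant column cannot be standardized: ", nm, call. = FALSE)
    table[[nm]] <- (x - mean(x)) / s
    ctr[nm] <- mean(x); scl[nm] <- s
  }
  attr(table, "center") <- ctr
  attr(table, "scale") <- scl
  table
}

#' Ordinary least-squares fit with full inference
#'
#' @param X Data frame (or matrix) of predictor columns.
#' @param y Numeric response.
#' @return Object of class `linear_fit`: coefficient table (estimate, SE,
#'   t, p), F statistic with df, R^2 and adjusted R^2, plus the underlying
#'   `lm` fit.
#' @export
fit_ols <- function(X, y) {
  X <- as.data.frame(X)
  if (anyNA(X) || anyNA(y)) stop("missing values in X or y", call. = FALSE)
  if (nrow(X) <= ncol(X) + 1) stop("n must exceed p + 1", call. = FALSE)
  d <- cbind(X, .y = y)
  fit <- lm(.y ~ ., data = d)
  if (fit$rank < ncol(X) + 1) {
    bad <- names(which(is.na(coef(fit))))
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  structure(
    list(predictors = names(X),
         coefficients = sm$coefficients,
         r_squared = sm$r.squared,
         adj_r_squared = sm$adj.r.squared,
         f_statistic = unname(sm$fstatistic["value"]),
         f_df = unname(sm$fstatistic[c("numdf", "dendf")]),
         sigma = sm$sigma,
         n = nrow(X),
         lm = fit),
    class = "linear_fit"
  )
}

#' @exportS3Method base::print
print.linear_fit <- function(x, ...) {
  cat("Linear model:", paste(x$predictors, collapse = " + "), "\n")
  stats::printCoefmat(x$coefficients, digits = 4)
  cat(sprintf("F(%d, %d) = %.1f, R^2 = %.4f, adjusted R^2 = %.4f\n",
              x$f_df[1], x$f_df[2], x$f_statistic,
              x$r_squared, x$adj_r_squared))
  invisible(x)
}

# R^2 of every subset via cross-product algebra: with centred data,
# R^2(S) = b' Sxy / Syy where Sxx(S) b = Sxy(S). One pass computes the
# moments; each subset is a tiny solve.
subset_r2 <- function(Xc, yc, subsets) {
  Sxx <- crossprod(Xc)
  Sxy <- crossprod(Xc, yc)
  Syy <- sum(yc^2)
  vapply(subsets, function(s) {
    b <- tryCatch(solve(Sxx[s, s, drop = FALSE], Sxy[s, , drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(b)) return(NA_real_)
    sum(b * Sxy[s, ]) / Syy
  }, numeric(1))
}

#' Exhaustive best-subset linear model selection
#'
#' Fits all linear models with 1..`k_max` of the predictor columns and
#' ranks them by R^2 within each size. Ties are broken lexicographically
#' on the predictor names, so the ordering is deterministic.
#'
#' @param table Data frame of predictor columns (standardize first for
#'   comparable estimates).
#' @param y Numeric response (e.g. per-stimulus mean ratings).
#' @param k_max Maximum subset size (default 3).
#' @param top Number of models retained per size (default 5).
#' @return Object of class `best_subset`: list with `by_size` (one data
#'   frame per size: predictor names, R^2) and `best` (the top model per
#'   size refitted via [fit_ols()]).
#' @export
best_subset <- function(table, y, k_max = 3L, top = 5L) {
  table <- as.data.frame(table)
  num <- vapply(table, is.numeric, logical(1))
  table <- table[num]
  p <- ncol(table)
  if (p > 30) stop("more than 30 predictors: enumeration refused", call. = FALSE)
  if (length(y) != nrow(table)) stop("y and table are not aligned", call. = FALSE)
  X <- as.matrix(table)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  by_size <- list()
  best <- list()
  for (k in seq_len(min(k_max, p))) {
    subs <- combn(p, k, simplify = FALSE)
    r2 <- subset_r2(Xc, yc, subs)
    nm <- vapply(subs, function(s)
      paste(sort(colnames(X)[s]), collapse = " + "), character(1))
    ord <- order(-r2, nm, na.last = TRUE)
    keep <- head(ord, top)
    by_size[[k]] <- data.frame(
      model = nm[keep], r_squared = r2[keep],
      stringsAsFactors = FALSE, row.names = NULL)
    best_vars <- colnames(X)[subs[[ord[1]]]]
    best[[k]] <- fit_ols(table[best_vars], y)
  }
  structure(list(by_size = by_size, best = best, k_max = k_max),
            class = "best_subset")
}

#' @exportS3Method base::print
print.best_subset <- function(x, ...) {
  for (k in seq_along(x$by_size)) {
    cat(k, "predictor(s):\n")
    df <- x$by_size[[k]]
    for (i in seq_len(nrow(df)))
      cat(sprintf("  %-40s R^2 = %.4f\n", df$model[i], df$r_squared[i]))
  }
  invisible(x)
}

#' Prediction performance metrics
#'
#' @param pred,obs Numeric vectors.
#' @return Named vector: Pearson `r`, Spearman `r_s` (average ranks for
#'   ties), `RMSE`, `MAE`.
#' @export
metrics <- function(pred, obs) {
  if (length(pred) != length(obs)) stop("length mismatch", call. = FALSE)
  if (stats::sd(pred) == 0 || stats::sd(obs) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  c(r = cor(pred, obs),
    r_s = cor(pred, obs, method = "spearman"),
    RMSE = sqrt(mean((pred - obs)^2)),
    MAE = mean(abs(pred - obs)))
}

#' Cross-validated random-forest prediction
#'
#' Regression random forest (500 trees, `max(1, floor(p/3))` candidate
#' predictors per split) evaluated by k-fold cross-validation: fold
#' membership is a seeded permutation, and metrics are computed on the
#' pooled out-of-fold predictions. R^2 is reported as the squared Pearson
#' correlation of out-of-fold predictions with the observed values.
#'
#' @param table Data frame containing the predictor columns.
#' @param predictor_subset Character vector of column names to use.
#' @param y Numeric response.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed controlling fold assignment and forest
#'   randomness.
#' @param ntree Trees per forest (default 500).
#' @return Object of class `cv_result`: out-of-fold `predictions`, fold
#'   assignment, `metrics`, `r_squared`, and the forest settings.
#' @export
rf_cv <- function(table, predictor_subset, y, folds = 10L, seed = 1L,
                  ntree = 500L) {
  if (length(predictor_subset) == 0)
    stop("empty predictor subset", call. = FALSE)
  miss <- setdiff(predictor_subset, names(table))
  if (length(miss))
    stop("unknown predictors: ", paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(table)
  if (folds > n) stop("more folds than observations", call. = FALSE)
  X <- as.data.frame(table[predictor_subset])
  p <- ncol(X)
  with_seed(seed, {
    fold <- sample(rep(seq_len(folds), length.out = n))
    pred <- numeric(n)
    for (f in seq_len(folds)) {
      te <- fold == f
      rf <- randomForest::randomForest(
        x = X[!te, , drop = FALSE], y = y[!te],
        ntree = ntree, mtry = max(1L, floor(p / 3)))
      pred[te] <- predict(rf, X[te, , drop = FALSE])
    }
    mt <- metrics(pred, y)
    structure(
      list(predictions = pred, fold = fold, metrics = mt,
           r_squared = unname(mt["r"]^2),
           settings = list(ntree = ntree, mtry = max(1L, floor(p / 3)),
                           folds = folds, seed = seed,
                           predictors = predictor_subset)),
      class = "cv_result"
    )
  })
}

#' @exportS3Method base::print
print.cv_result <- function(x, ...) {
  s <- x$settings
  cat(sprintf("Random forest (%d trees, mtry %d), %d-fold CV on %s\n",
              s$ntree, s$mtry, s$folds, paste(s$predictors, collapse = " + ")))
  cat(sprintf("  CV R^2 = %.3f  r = %.3f  r_s = %.3f  RMSE = %.3f  MAE = %.3f\n",
              x$r_squared, x$metrics["r"], x$metrics["r_s"],
              x$metrics["RMSE"], x$metrics["MAE"]))
  invisible(x)
}
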