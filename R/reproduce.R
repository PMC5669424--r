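# Reproduction of the published model table from supplementary data.
#
# Published rating studies of this stimulus format distribute their
# stimulus-property and rating tables as supplementary downloads. When those tab-separated files are available
# locally, this routine re-runs the analysis pipeline on them: predictor
# standardization, the reference OLS models (RMSGIF alone; MS + RMSGIF;
# MSA20 + RMSGIF), best-subset selection and the cross-validated random
# forests, returning the explained-variance table for comparison with the
# printed values.

#' Re-run the reference analyses on supplementary data files
#'
#' @param predictor_file Tab-separated stimulus-property table (24
#'   predictors plus MSA..MSD, possibly as H/V orientation pairs).
#' @param rating_file Tab-separated long rating table.
#' @param folds,seed Cross-validation settings for the forest models.
#' @return List with the three reference `linear_fit`s, the `best_subset`
#'   result, forest `cv_result`s, and a compact `summary` data frame of
#'   R^2 values.
#' @export
reproduce_published_models <- function(predictor_file, rating_file,
                                       folds = 10L, seed = 1L) {
  tab <- read_predictor_table(predictor_file)
  ratings <- read_rating_table(rating_file)
  mean_r <- aggregate_ratings(ratings)
  tab <- tab[match(mean_r$stimulus, as.character(tab$stimulus)), , drop = FALSE]
  if (anyNA(tab$stimulus))
    stop("rating stimuli missing from predictor table", call. = FALSE)
  y <- mean_r$mean_rating

  # MSA20 from the per-axis scores, then standardize all predictors
  if (!all(c("MSA", "MSB", "MSC", "MSD") %in% names(tab)))
    stop("per-axis symmetry columns MSA..MSD required", call. = FALSE)
  tab$MSA20 <- 100 * rowMeans(as.matrix(tab[, c("MSA", "MSB", "MSC", "MSD")])^20)
  keep <- c(PREDICTOR_NAMES, "MSA20")
  z <- zstandardize(tab[keep])
  z$stimulus <- as.character(tab$stimulus)

  fit1 <- fit_ols(z["RMSGIF"], y)
  fit2 <- fit_ols(z[c("MS", "RMSGIF")], y)
  fit3 <- fit_ols(z[c("MSA20", "RMSGIF")], y)
  bs <- best_subset(z[PREDICTOR_NAMES], y, k_max = 3L)
  rf2 <- rf_cv(z, c("MS", "RMSGIF"), y, folds = folds, seed = seed)
  rf3 <- rf_cv(z, c("MSA20", "RMSGIF"), y, folds = folds, seed = seed)

  summary <- data.frame(
    model = c("OLS RMSGIF", "OLS MS + RMSGIF", "OLS MSA20 + RMSGIF",
              "RF MS + RMSGIF", "RF MSA20 + RMSGIF"),
    r_squared = c(fit1$r_squared, fit2$r_squared, fit3$r_squared,
                  rf2$r_squared, rf3$r_squared))
  list(ols_rmsgif = fit1, ols_ms_rmsgif = fit2, ols_msa20_rmsgif = fit3,
       best_subset = bs, rf_ms_rmsgif = rf2, rf_msa20_rmsgif = rf3,
       summary = summary)
}

#' Locate bundled supplementary data, if present
#'
#' The package does not redistribute externally published supplementary
#' tables;
#' users who have downloaded them can drop the files into
#' `inst/extdata/supplementary/` (source) or the installed
#' `extdata/supplementary/` directory to enable the reproduction path.
#'
#' @param set 1 or 2 (the two stimulus sets).
#' @return Named character vector with `predictors` and `ratings` paths,
#'   or `NULL` when the files are absent.
#' @export
supplementary_paths <- function(set = 1L) {
  dir <- system.file("extdata", "supplementary", package = "symcomp")
  if (dir == "") return(NULL)
  pred <- file.path(dir, sprintf("S%dDataset_predictors.tsv", 2L * set - 1L))
  rat <- file.path(dir, sprintf("S%dDataset_ratings.tsv", 2L * set))
  if (!file.exists(pred) || !file.exists(rat)) return(NULL)
  c(predictors = pred, ratings = rat)
}
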