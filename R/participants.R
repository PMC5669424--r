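# Individual-differences analyses: per-participant best two-predictor
# models, and random-slope mixed-effects model comparison.

#' Best two-predictor model for every participant
#'
#' For each participant, all two-predictor linear models of that
#' participant's own ratings are enumerated and the winner by R^2 is
#' compared with the reference model (default symmetry + RMSGIF). Also
#' returns corpus-level frequency counts of winning predictors and models.
#'
#' @param ratings Long rating table (`participant`, `stimulus`, `rating`,
#'   optional `exclude_from_mean`).
#' @param table Standardized predictor table with a `stimulus` id column.
#' @param reference Character vector of the two reference predictor names
#'   (default `c("MS", "RMSGIF")`).
#' @param min_stimuli Participants who rated fewer stimuli are skipped.
#' @return Object of class `participant_models`: data frame `per_participant`
#'   (winner, its R^2, reference R^2, delta), `predictor_counts`,
#'   `model_counts`, and the ids of skipped or constant-rating
#'   participants.
#' @export
per_participant_models <- function(ratings, table,
                                   reference = c("MS", "RMSGIF"),
                                   min_stimuli = 20L) {
  stopifnot(all(c("participant", "stimulus", "rating") %in% names(ratings)))
  if (!"stimulus" %in% names(table))
    stop("predictor table needs a stimulus id column", call. = FALSE)
  miss <- setdiff(reference, names(table))
  if (length(miss))
    stop("reference predictors absent: ", paste(miss, collapse = ", "),
         call. = FALSE)
  num <- intersect(PREDICTOR_NAMES, names(table))
  if (length(num) < 2)  # non-standard battery: use all numeric columns
    num <- setdiff(names(table)[vapply(table, is.numeric, logical(1))],
                   c("MSA", "MSB", "MSC", "MSD"))
  X_all <- as.matrix(table[num])
  rownames(X_all) <- as.character(table$stimulus)

  keep <- if ("exclude_from_mean" %in% names(ratings))
    !ratings$exclude_from_mean else rep(TRUE, nrow(ratings))
  ratings <- ratings[keep, , drop = FALSE]

  participants <- unique(ratings$participant)
  pairs <- combn(length(num), 2L, simplify = FALSE)
  pair_names <- vapply(pairs, function(s)
    paste(sort(num[s]), collapse = " + "), character(1))
  ref_name <- paste(sort(reference), collapse = " + ")

  rows <- list(); constant <- c(); skipped <- c()
  for (p in participants) {
    rp <- ratings[ratings$participant == p, , drop = FALSE]
    rp <- rp[as.character(rp$stimulus) %in% rownames(X_all), , drop = FALSE]
    if (nrow(rp) < min_stimuli) { skipped <- c(skipped, p); next }
    y <- rp$rating
    if (stats::sd(y) == 0) { constant <- c(constant, p); next }
    X <- X_all[as.character(rp$stimulus), , drop = FALSE]
    Xc <- scale(X, center = TRUE, scale = FALSE)
    yc <- y - mean(y)
    r2 <- subset_r2(Xc, yc, pairs)
    ord <- order(-r2, pair_names, na.last = TRUE)
    best_idx <- ord[1]
    ref_r2 <- subset_r2(Xc, yc, list(match(reference, colnames(X))))
    rows[[length(rows) + 1L]] <- data.frame(
      participant = p,
      n_rated = nrow(rp),
      best_model = pair_names[best_idx],
      best_r2 = r2[best_idx],
      reference_r2 = ref_r2,
      delta_r2 = r2[best_idx] - ref_r2,
      stringsAsFactors = FALSE)
  }
  pp <- do.call(rbind, rows)
  winners <- strsplit(pp$best_model, " \\+ ")
  structure(
    list(per_participant = pp,
         predictor_counts = sort(table(unlist(winners)), decreasing = TRUE),
         model_counts = sort(table(pp$best_model), decreasing = TRUE),
         reference = reference,
         reference_model = ref_name,
         constant_participants = constant,
         skipped_participants = skipped),
    class = "participant_models"
  )
}

#' @exportS3Method base::print
print.participant_models <- function(x, ...) {
  cat("Per-participant two-predictor models (n =", nrow(x$per_participant), ")\n")
  cat("Most frequent winning predictors:\n")
  print(utils::head(x$predictor_counts, 5))
  cat("Reference model", x$reference_model, ": median delta R^2 =",
      signif(stats::median(x$per_participant$delta_r2), 3), "\n")
  invisible(x)
}

#' Compare random-effects structures for the two-factor rating model
#'
#' Fits four linear mixed models of individual ratings on the two fixed
#' predictors (default MS and RMSGIF) by maximum likelihood:
#' M1 random intercepts for participant and stimulus; M2 adds an
#' (uncorrelated) participant slope on the first predictor; M3 adds a
#' participant slope on the second predictor instead; M4 has both slopes.
#' Each slope is tested by a likelihood-ratio test against the nested
#' model; because a variance is on the boundary under the null, the
#' chi-square p-value is halved.
#'
#' @param ratings Long rating table (`participant`, `stimulus`, `rating`).
#' @param table Standardized predictor table with `stimulus` id column and
#'   the two predictor columns.
#' @param predictors Character vector of the two fixed-effect predictor
#'   names (default `c("MS", "RMSGIF")`).
#' @return Object of class `lmm_comparison`: per-model fits (fixed
#'   effects, variance components, logLik, AIC, BIC, convergence), an
#'   `anova_table`, slope LRT results with halved p-values, and the
#'   AIC/BIC ranking.
#' @export
lmm_compare <- function(ratings, table, predictors = c("MS", "RMSGIF")) {
  stopifnot(length(predictors) == 2)
  miss <- setdiff(c("stimulus", predictors), names(table))
  if (length(miss))
    stop("predictor table lacks: ", paste(miss, collapse = ", "), call. = FALSE)
  d <- merge(ratings, table[c("stimulus", predictors)], by = "stimulus")
  d$participant <- factor(d$participant)
  d$stimulus <- factor(d$stimulus)
  p1 <- predictors[1]; p2 <- predictors[2]
  forms <- list(
    M1 = sprintf("rating ~ %s + %s + (1 | participant) + (1 | stimulus)", p1, p2),
    M2 = sprintf("rating ~ %s + %s + (1 | participant) + (0 + %s | participant) + (1 | stimulus)", p1, p2, p1),
    M3 = sprintf("rating ~ %s + %s + (1 | participant) + (0 + %s | participant) + (1 | stimulus)", p1, p2, p2),
    M4 = sprintf("rating ~ %s + %s + (1 | participant) + (0 + %s | participant) + (0 + %s | participant) + (1 | stimulus)", p1, p2, p1, p2)
  )
  fits <- lapply(names(forms), function(nm) {
    tryCatch({
      fit <- lme4::lmer(stats::as.formula(forms[[nm]]), data = d, REML = FALSE)
      vc <- as.data.frame(lme4::VarCorr(fit))
      list(model = nm, fit = fit, formula = forms[[nm]],
           fixef = lme4::fixef(fit),
           varcorr = vc,
           logLik = as.numeric(stats::logLik(fit)),
           AIC = stats::AIC(fit), BIC = stats::BIC(fit),
           converged = length(fit@optinfo$conv$lme4) == 0,
           messages = unlist(fit@optinfo$conv$lme4$messages))
    }, error = function(e) list(model = nm, fit = NULL, error = conditionMessage(e)))
  })
  names(fits) <- names(forms)

  lrt <- function(full, nested, label) {
    if (is.null(fits[[full]]$fit) || is.null(fits[[nested]]$fit)) return(NULL)
    stat <- 2 * (fits[[full]]$logLik - fits[[nested]]$logLik)
    stat <- max(stat, 0)
    data.frame(slope = label, comparison = paste(full, "vs", nested),
               chisq = stat, df = 1,
               p_halved = pchisq(stat, df = 1, lower.tail = FALSE) / 2,
               stringsAsFactors = FALSE)
  }
  slope_tests <- rbind(
    lrt("M2", "M1", p1), lrt("M3", "M1", p2),
    lrt("M4", "M3", p1), lrt("M4", "M2", p2))

  ok <- !vapply(fits, function(f) is.null(f$fit), logical(1))
  tab <- data.frame(
    model = names(fits)[ok],
    logLik = vapply(fits[ok], `[[`, numeric(1), "logLik"),
    AIC = vapply(fits[ok], `[[`, numeric(1), "AIC"),
    BIC = vapply(fits[ok], `[[`, numeric(1), "BIC"),
    converged = vapply(fits[ok], `[[`, logical(1), "converged"),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(fits = fits, anova_table = tab, slope_tests = slope_tests,
         best_aic = tab$model[which.min(tab$AIC)],
         best_bic = tab$model[which.min(tab$BIC)],
         predictors = predictors),
    class = "lmm_comparison"
  )
}

#' @exportS3Method base::print
print.lmm_comparison <- function(x, ...) {
  cat("Random-effects structure comparison (ML fits)\n")
  print(x$anova_table, row.names = FALSE)
  cat("Best by AIC:", x$best_aic, "| best by BIC:", x$best_bic, "\n")
  if (!is.null(x$slope_tests)) {
    cat("Slope likelihood-ratio tests (boundary-corrected p):\n")
    print(x$slope_tests, row.names = FALSE)
  }
  invisible(x)
}
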