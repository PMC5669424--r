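# Rating aggregation, standardization, OLS, best-subset selection,
# metrics, and cross-validated random forests.

test_that("rating aggregation averages only non-excluded ratings", {
  r <- data.frame(
    participant = c("a", "b", "a", "b", "c"),
    stimulus = c("s1", "s1", "s2", "s2", "s1"),
    rating = c(1L, 5L, 4L, 4L, 2L),
    exclude_from_mean = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  agg <- aggregate_ratings(r)
  expect_equal(agg$mean_rating[agg$stimulus == "s1"], 3)   # {1,5}, 2 excluded
  expect_equal(agg$mean_rating[agg$stimulus == "s2"], 4)
  one <- aggregate_ratings(data.frame(stimulus = "x", rating = 4L))
  expect_equal(one$mean_rating, 4)
  # a stimulus with only excluded ratings is absent
  r2 <- rbind(r, data.frame(participant = "d", stimulus = "s3", rating = 5L,
                            exclude_from_mean = TRUE))
  expect_false("s3" %in% aggregate_ratings(r2)$stimulus)
})

test_that("z-standardization is exact, idempotent, and rejects constants", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 30, 20))
  z <- zstandardize(d)
  expect_equal(z$a, c(-1, 0, 1))
  expect_lt(abs(mean(z$b)), 1e-12)
  expect_lt(abs(sd(z$b) - 1), 1e-12)
  z2 <- zstandardize(z)
  expect_equal(z2$a, z$a, tolerance = 1e-12)
  expect_error(zstandardize(data.frame(ok = 1:3, flat = rep(2, 3))), "flat")
  expect_equal(unname(attr(z, "center")["a"]), 2)
})

test_that("fit_ols matches the normal-equations oracle", {
  set.seed(20)
  for (rep in 1:100) {
    n <- sample(30:80, 1)
    X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
    beta <- rnorm(4)
    y <- beta[1] + as.matrix(X) %*% beta[-1] + rnorm(n, 0, 0.5)
    fit <- fit_ols(X, as.numeric(y))
    expect_equal(unname(fit$coefficients[, "Estimate"]),
                 unname(brute_ols_coef(X, y)), tolerance = 1e-10)
  }
  # exact linear response -> R^2 = 1
  X <- data.frame(x = 1:20)
  fit <- fit_ols(X, 2 + 3 * X$x)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$adj_r_squared <= fit$r_squared)
  # rank deficiency is named
  X2 <- data.frame(u = rnorm(20))
  X2$v <- 2 * X2$u
  expect_error(fit_ols(X2, rnorm(20)), "collinear.*v")
})

test_that("best_subset is exhaustive, monotone and deterministic", {
  set.seed(21)
  n <- 120
  tab <- as.data.frame(matrix(rnorm(n * 8), n,
                              dimnames = list(NULL, paste0("p", 1:8))))
  # response equal to one predictor: its singleton model wins exactly
  bs <- best_subset(tab, tab$p3, k_max = 3)
  expect_equal(bs$by_size[[1]]$model[1], "p3")
  expect_equal(bs$by_size[[1]]$r_squared[1], 1)
  # monotone: best R^2 non-decreasing in subset size
  y <- 0.8 * tab$p1 - 0.5 * tab$p4 + rnorm(n, 0, 0.4)
  bs2 <- best_subset(tab, y, k_max = 3)
  r2 <- vapply(bs2$by_size, function(df) df$r_squared[1], numeric(1))
  expect_true(all(diff(r2) >= -1e-12))
  expect_equal(bs2$by_size[[2]]$model[1], "p1 + p4")
  # determinism
  bs3 <- best_subset(tab, y, k_max = 3)
  expect_identical(bs2$by_size, bs3$by_size)
  # enumerated R^2 agrees with a direct lm fit
  direct <- summary(lm(y ~ p1 + p4, data = tab))$r.squared
  expect_equal(bs2$by_size[[2]]$r_squared[1], direct, tolerance = 1e-12)
})

test_that("metrics match hand-computed values and reject constants", {
  expect_equal(metrics(1:5, 1:5), c(r = 1, r_s = 1, RMSE = 0, MAE = 0))
  expect_equal(unname(metrics(-(1:5), 1:5)["r"]), -1)
  pred <- c(1, 2, 3); obs <- c(1, 2, 4)
  m <- metrics(pred, obs)
  expect_equal(unname(m["r"]), cov(pred, obs) / (sd(pred) * sd(obs)))
  expect_equal(unname(m["r_s"]), 1)  # both strictly increasing
  expect_equal(unname(m["RMSE"]), sqrt(1 / 3))
  expect_equal(unname(m["MAE"]), 1 / 3)
  expect_error(metrics(rep(1, 5), 1:5), "constant")
})

test_that("rf_cv partitions out-of-fold predictions and is seeded", {
  set.seed(22)
  n <- 200
  tab <- data.frame(x = runif(n), z = runif(n))
  y <- sin(3 * tab$x)  # noiseless monotone-ish function of one predictor
  cv <- rf_cv(tab, c("x"), y, folds = 10, seed = 5, ntree = 150)
  expect_equal(sort(unique(cv$fold)), 1:10)
  expect_equal(tabulate(cv$fold), rep(20, 10))
  expect_gt(cv$r_squared, 0.9)
  cv2 <- rf_cv(tab, c("x"), y, folds = 10, seed = 5, ntree = 150)
  expect_identical(cv$predictions, cv2$predictions)
  cv3 <- rf_cv(tab, c("x"), y, folds = 10, seed = 6, ntree = 150)
  expect_false(identical(cv$predictions, cv3$predictions))
  expect_error(rf_cv(tab, character(), y), "empty")
  expect_error(rf_cv(tab, "nope", y), "unknown")
  expect_error(rf_cv(tab, "x", y, folds = n + 1), "folds")
})

test_that("per-participant selection recovers heterogeneous weights", {
  set.seed(23)
  ns <- 150
  tab <- data.frame(
    stimulus = sprintf("s%03d", 1:ns),
    MS = rnorm(ns), RMSGIF = rnorm(ns),
    GIF = rnorm(ns), APB = rnorm(ns))
  # participants weight the structural and quantitative factors differently
  rows <- list()
  for (p in 1:12) {
    bq <- 0.6 + 0.3 * runif(1); bs <- -0.3 - 0.3 * runif(1)
    lat <- 3 + bq * tab$RMSGIF + bs * tab$MS + rnorm(ns, 0, 0.3)
    rows[[p]] <- data.frame(
      participant = sprintf("P%02d", p), stimulus = tab$stimulus,
      rating = pmin(5L, pmax(1L, as.integer(round(lat)))))
  }
  ratings <- do.call(rbind, rows)
  res <- per_participant_models(ratings, tab, reference = c("MS", "RMSGIF"))
  expect_equal(nrow(res$per_participant), 12)
  # frequency counts concentrate on the generating pair
  top2 <- names(sort(res$predictor_counts, decreasing = TRUE))[1:2]
  expect_setequal(top2, c("MS", "RMSGIF"))
  # the winner never trails the reference model
  expect_true(all(res$per_participant$delta_r2 >= -1e-12))
  # constant raters are flagged and excluded
  ratings2 <- rbind(ratings, data.frame(
    participant = "Pflat", stimulus = tab$stimulus, rating = 3L))
  res2 <- per_participant_models(ratings2, tab)
  expect_true("Pflat" %in% res2$constant_participants)
  expect_false("Pflat" %in% res2$per_participant$participant)
})

test_that("identical raters all select the group-level best model", {
  set.seed(24)
  ns <- 120
  tab <- data.frame(stimulus = sprintf("s%03d", 1:ns),
                    MS = rnorm(ns), RMSGIF = rnorm(ns), GIF = rnorm(ns))
  lat <- 3 + 0.7 * tab$RMSGIF - 0.5 * tab$MS + rnorm(ns, 0, 0.2)
  shared <- pmin(5L, pmax(1L, as.integer(round(lat))))
  ratings <- do.call(rbind, lapply(1:5, function(p)
    data.frame(participant = paste0("P", p), stimulus = tab$stimulus,
               rating = shared)))
  res <- per_participant_models(ratings, tab)
  expect_equal(unique(res$per_participant$best_model), "MS + RMSGIF")
})

test_that("lmm_compare nests deviances and ranks structures sanely", {
  fix <- study_corpus()
  z <- standardized_table(fix)
  idx <- seq_len(150)
  zz <- z[idx, c("stimulus", "MS", "RMSGIF")]
  spec <- rating_sim_spec(n_participants = 20L, sym_col = "MS",
                          slope_sd_quant = 0.25, slope_sd_sym = 0.25,
                          seed = 99L)
  sim <- simulate_ratings(zz, spec)
  res <- lmm_compare(sim$ratings, zz)
  tab <- res$anova_table
  expect_equal(nrow(tab), 4)
  # nesting: adding a slope can only improve the ML deviance
  ll <- setNames(tab$logLik, tab$model)
  expect_true(ll["M2"] >= ll["M1"] - 1e-6)
  expect_true(ll["M3"] >= ll["M1"] - 1e-6)
  expect_true(ll["M4"] >= ll["M2"] - 1e-6)
  expect_true(ll["M4"] >= ll["M3"] - 1e-6)
  expect_true(all(c("chisq", "p_halved") %in% names(res$slope_tests)))
  expect_true(all(res$slope_tests$chisq >= 0))
  # with generous true slope variances the full model wins by AIC
  expect_equal(res$best_aic, "M4")
})
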