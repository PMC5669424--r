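# Synthetic rating generator embodying the two-factor account of
# perceived visual complexity: a quantitative factor (amount of content,
# positive weight) and a structural factor (symmetry, negative weight),
# with per-participant random weights, crossed random intercepts, and
# 5-point discretization.

#' Specify a rating simulation
#'
#' Latent score of participant p for stimulus s:
#' `beta0 + (beta_quant + b_q[p]) * quant + (beta_sym + b_s[p]) * sym +
#'  u[p] + v[s] + eps`, discretized to the 1..5 scale by rounding and
#' clipping. The structural predictor defaults to the power-20 transformed
#' symmetry (`MSA20`), reflecting that perceived structure reacts sharply
#' to small deviations from perfect symmetry.
#'
#' @param beta0 Grand intercept on the rating scale (default 3).
#' @param beta_quant Slope on the standardized quantitative predictor
#'   (default 0.5).
#' @param beta_sym Slope on the standardized symmetry predictor (default
#'   -0.4; negative: symmetry reduces complexity).
#' @param slope_sd_quant,slope_sd_sym SDs of per-participant slope
#'   deviations (defaults 0.1).
#' @param intercept_sd_participant,intercept_sd_stimulus Random-intercept
#'   SDs (defaults 0.2).
#' @param noise_sd Residual SD (default 0.5).
#' @param n_participants Number of simulated raters (default 50).
#' @param quant_col,sym_col Names of the predictor columns to use
#'   (defaults `"RMSGIF"` and `"MSA20"`).
#' @param seed Integer seed.
#' @return Object of class `rating_sim_spec`.
#' @export
rating_sim_spec <- function(beta0 = 3, beta_quant = 0.5, beta_sym = -0.4,
                            slope_sd_quant = 0.1, slope_sd_sym = 0.1,
                            intercept_sd_participant = 0.2,
                            intercept_sd_stimulus = 0.2,
                            noise_sd = 0.5, n_participants = 50L,
                            quant_col = "RMSGIF", sym_col = "MSA20",
                            seed = 1L) {
  sds <- c(slope_sd_quant, slope_sd_sym, intercept_sd_participant,
           intercept_sd_stimulus, noise_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0", call. = FALSE)
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  structure(
    list(beta0 = beta0, beta_quant = beta_quant, beta_sym = beta_sym,
         slope_sd_quant = slope_sd_quant, slope_sd_sym = slope_sd_sym,
         intercept_sd_participant = intercept_sd_participant,
         intercept_sd_stimulus = intercept_sd_stimulus,
         noise_sd = noise_sd, n_participants = as.integer(n_participants),
         quant_col = quant_col, sym_col = sym_col, seed = as.integer(seed)),
    class = "rating_sim_spec"
  )
}

#' Simulate a long rating table from a predictor table
#'
#' Every simulated participant rates every stimulus once. The latent
#' parameters (per-participant slopes and intercepts, stimulus intercepts)
#' are returned alongside the ratings for parameter-recovery tests.
#'
#' @param table Predictor table containing a `stimulus` id column and the
#'   standardized columns named in `spec`.
#' @param spec A [rating_sim_spec()].
#' @return List with `ratings` (data frame `participant`, `stimulus`,
#'   `rating`, `exclude_from_mean`), `latent` (the un-discretized scores)
#'   and `truth` (spec plus the drawn random effects).
#' @export
simulate_ratings <- function(table, spec) {
  stopifnot(inherits(spec, "rating_sim_spec"))
  miss <- setdiff(c("stimulus", spec$quant_col, spec$sym_col), names(table))
  if (length(miss))
    stop("predictor table lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  q <- table[[spec$quant_col]]
  s <- table[[spec$sym_col]]
  ns <- nrow(table); np <- spec$n_participants
  with_seed(spec$seed, {
    b_q <- rnorm(np, 0, spec$slope_sd_quant)
    b_s <- rnorm(np, 0, spec$slope_sd_sym)
    u_p <- rnorm(np, 0, spec$intercept_sd_participant)
    v_s <- rnorm(ns, 0, spec$intercept_sd_stimulus)
    eps <- matrix(rnorm(np * ns, 0, spec$noise_sd), ns, np)
    latent <- outer(q, spec$beta_quant + b_q) + outer(s, spec$beta_sym + b_s) +
      matrix(u_p, ns, np, byrow = TRUE) + v_s + spec$beta0 + eps
    rating <- pmin(5L, pmax(1L, as.integer(round(latent))))
    ratings <- data.frame(
      participant = rep(sprintf("P%03d", seq_len(np)), each = ns),
      stimulus = rep(as.character(table$stimulus), np),
      rating = as.integer(rating),
      exclude_from_mean = FALSE,
      stringsAsFactors = FALSE)
    list(ratings = ratings,
         latent = latent,
         truth = list(spec = spec, b_q = b_q, b_s = b_s,
                      u_p = u_p, v_s = v_s))
  })
}
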