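# Tab-separated table adapters and run configuration.
#
# Predictor tables follow the supplementary-data layout: header row,
# tab-separated, one row per stimulus, the 24 predictor columns plus the
# per-axis symmetry columns MSA..MSD; orientation-specific predictors may
# appear as paired H.../V... columns whose mean is used for analysis.

#' Write a predictor table
#'
#' @param table Data frame with a `stimulus` column and predictor columns.
#' @param path Output path (tab-separated, header row).
#' @return `path`, invisibly.
#' @export
write_predictor_table <- function(table, path) {
  write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a predictor table
#'
#' Validates the header against the 24-predictor registry (plus the
#' per-axis symmetry columns). When a predictor is present only as an
#' orientation pair `H<name>`/`V<name>`, the two columns are averaged into
#' `<name>`.
#'
#' @param path Tab-separated file with header row.
#' @param require_all Error if any of the 24 predictors is missing
#'   (default TRUE).
#' @return Data frame with a `stimulus` column and numeric predictors.
#' @export
read_predictor_table <- function(path, require_all = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  # merge orientation pairs
  for (nm in PREDICTOR_NAMES) {
    h <- paste0("H", nm); v <- paste0("V", nm)
    if (!nm %in% names(df) && all(c(h, v) %in% names(df)))
      df[[nm]] <- (df[[h]] + df[[v]]) / 2
  }
  if (!"stimulus" %in% names(df)) {
    id_col <- intersect(c("id", "Stimulus", "stim", "pattern"), names(df))
    if (length(id_col)) names(df)[names(df) == id_col[1]] <- "stimulus"
    else df$stimulus <- as.character(seq_len(nrow(df)))
  }
  if (require_all) {
    miss <- setdiff(PREDICTOR_NAMES, names(df))
    if (length(miss))
      stop("predictor table schema error; missing columns: ",
           paste(miss, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a long rating table
#'
#' @param ratings Data frame (`participant`, `stimulus`, `rating`, ...).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rating_table <- function(ratings, path) {
  write.table(ratings, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a long rating table
#'
#' Requires `participant`, `stimulus` and `rating` columns; ratings must
#' be integers 1..5 (violations are reported with their line number). An
#' optional `session` column marked with `exclude_from_mean`, or an
#' explicit `exclude_from_mean` logical column, flags repeat
#' presentations excluded from mean complexity.
#'
#' @param path Tab-separated file with header row.
#' @return Data frame with validated columns.
#' @export
read_rating_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("participant", "stimulus", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("rating table schema error; missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!(df$rating %in% 1:5))
  if (length(bad))
    stop("rating out of range 1..5 on line ", bad[1] + 1L,
         " (value ", df$rating[bad[1]], ")", call. = FALSE)
  if (!"exclude_from_mean" %in% names(df)) df$exclude_from_mean <- FALSE
  df$exclude_from_mean <- as.logical(df$exclude_from_mean)
  df$stimulus <- as.character(df$stimulus)
  df$participant <- as.character(df$participant)
  df
}

#' Default run configuration
#'
#' All tunable parameters of the pipeline in one serializable list:
#' encoder choices, edge-operator parameters, annealing schedule, and
#' modeling options.
#'
#' @param ... Named overrides of the defaults (nested lists are merged).
#' @return Object of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    codecs = list(gif = "internal-gif87a-lzw",
                  png = paste("png", utils::packageVersion("png")),
                  tiff = paste("tiff-lzw", utils::packageVersion("tiff")),
                  jpeg = paste("jpeg-q90", utils::packageVersion("jpeg"))),
    edges = list(rms_window = 5L, canny_sigma = 1, canny_low_frac = 0.4,
                 phc = PHC_DEFAULTS),
    annealing = list(initial_temperature = 1.0, cooling_factor = 0.95,
                     steps_per_temperature = 200L, min_temperature = 1e-3,
                     asym_threshold = 0.98, eval_px = 4L),
    modeling = list(k_max = 3L, folds = 10L, ntree = 500L),
    render = list(px_per_cell = 75L)
  )
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  structure(cfg, class = "run_config")
}

#' Write / read a run configuration as YAML
#'
#' @param cfg A `run_config`.
#' @param path File path.
#' @return `read_config` returns a `run_config`; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  structure(yaml::read_yaml(path), class = "run_config")
}

#' Generate a pattern corpus with ground-truth sidecar table
#'
#' Generates `n_per_class` patterns for each requested symmetry class
#' (annealed to their target axes), optionally a broken variant of every
#' symmetric pattern, renders them, and writes PNGs plus a tab-separated
#' ground-truth table (id, class, element count, seed, per-axis scores).
#'
#' @param n_per_class Patterns per symmetry class.
#' @param classes Character vector of class labels (default all five
#'   symmetric classes plus `"asymmetric"`).
#' @param broken Also create one broken variant per symmetric pattern.
#' @param px_per_cell Rendering resolution.
#' @param seed Base seed; pattern k of class c uses a distinct derived
#'   seed.
#' @param out_dir Directory for PNGs and `patterns.tsv`; `NULL` (default)
#'   renders in memory only.
#' @return List with `patterns` (grid_pattern list), `images` (list of
#'   matrices) and `meta` (the ground-truth data frame).
#' @export
generate_corpus <- function(n_per_class = 10L,
                            classes = c("asymmetric", "1-orthogonal",
                                        "2-orthogonal", "1-diagonal",
                                        "2-diagonal", "4-axes"),
                            broken = TRUE, px_per_cell = 16L, seed = 1L,
                            out_dir = NULL) {
  if (n_per_class >= 50000L)
    stop("n_per_class too large for the seed-derivation scheme", call. = FALSE)
  base <- (as.integer(seed) %% 2000L) * 1000000L  # keeps derived seeds < 2^31
  patterns <- list(); images <- list(); meta <- list()
  k <- 0L
  for (ci in seq_along(classes)) {
    cls <- classes[ci]
    axes <- class_axes(cls)
    for (i in seq_len(n_per_class)) {
      k <- k + 1L
      sd_i <- base + ci * 100000L + i
      pat <- generate_pattern(sim_spec(target_axes = axes, seed = sd_i))
      img <- render(pat, px_per_cell)
      prof <- mirror_symmetry(img)
      id <- sprintf("%s_%03d", gsub("-", "", cls), i)
      patterns[[id]] <- pat
      images[[id]] <- img
      ax <- setNames(as.list(prof$axes[MS_AXIS_COLS]), names(MS_AXIS_COLS))
      meta[[id]] <- data.frame(
        stimulus = id, symmetry_class = cls, n_elements = pat$n_elements,
        seed = sd_i, ax, MS = prof$ms, stringsAsFactors = FALSE)
      if (broken && length(axes)) {
        k <- k + 1L
        origin <- with_seed(sd_i + 70000L,
                            c(sample.int(6, 1), sample.int(6, 1)))
        bp <- tryCatch(
          break_symmetry(pat, origin, seed = sd_i + 50000L),
          error = function(e) NULL)
        if (is.null(bp)) next
        bimg <- render(bp, px_per_cell)
        bprof <- mirror_symmetry(bimg)
        bid <- paste0(id, "_broken")
        patterns[[bid]] <- bp
        images[[bid]] <- bimg
        bax <- setNames(as.list(bprof$axes[MS_AXIS_COLS]), names(MS_AXIS_COLS))
        meta[[bid]] <- data.frame(
          stimulus = bid, symmetry_class = "broken",
          n_elements = bp$n_elements, seed = sd_i + 50000L,
          bax, MS = bprof$ms, stringsAsFactors = FALSE)
      }
    }
  }
  meta <- do.call(rbind, c(meta, list(make.row.names = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(images))
      write_image_png(images[[id]], file.path(out_dir, paste0(id, ".png")))
    write.table(meta, file.path(out_dir, "patterns.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  list(patterns = patterns, images = images, meta = meta)
}
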