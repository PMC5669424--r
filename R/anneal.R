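# Simulated-annealing pattern generation.
#
# Target symmetry is maintained *by construction*: moves resample the whole
# orbit of a cell under the reflection group generated by the target axes,
# so every declared axis scores exactly 1 at all times. Annealing only has
# to drive the element count into [36, 44] and push non-target axes below
# the asymmetry threshold; acceptance requires zero energy.

#' Specify a pattern-generation run
#'
#' @param target_axes Character vector, subset of `"vertical"`,
#'   `"horizontal"`, `"main_diagonal"`, `"secondary_diagonal"`; empty for an
#'   asymmetric target.
#' @param n_elements_range Inclusive element-count range, default `c(36, 44)`.
#' @param seed Integer seed; identical specs give identical patterns.
#' @param initial_temperature,cooling_factor,steps_per_temperature,min_temperature
#'   Geometric annealing schedule (defaults 1.0, 0.95, 200, 1e-3).
#' @param asym_threshold Non-target axes must score strictly below this
#'   (default 0.98).
#' @param eval_px Cell size (pixels) of the rendering on which non-target
#'   axis scores are evaluated during annealing; exact-symmetry guarantees
#'   are resolution-invariant.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(target_axes = character(),
                     n_elements_range = c(36L, 44L),
                     seed = 1L,
                     initial_temperature = 1.0,
                     cooling_factor = 0.95,
                     steps_per_temperature = 200L,
                     min_temperature = 1e-3,
                     asym_threshold = 0.98,
                     eval_px = 4L) {
  target_axes <- unique(as.character(target_axes))
  if (length(target_axes) && !all(target_axes %in% SYM_AXES))
    stop("unknown target axes: ",
         paste(setdiff(target_axes, SYM_AXES), collapse = ", "), call. = FALSE)
  if (cooling_factor <= 0 || cooling_factor >= 1)
    stop("cooling_factor must lie in (0, 1)", call. = FALSE)
  if (steps_per_temperature < 1 || initial_temperature <= 0 ||
      min_temperature <= 0)
    stop("annealing schedule counts must be positive", call. = FALSE)
  if (length(n_elements_range) != 2 || n_elements_range[1] > n_elements_range[2])
    stop("n_elements_range must be an ordered pair", call. = FALSE)
  structure(
    list(target_axes = target_axes,
         n_elements_range = as.integer(n_elements_range),
         seed = as.integer(seed),
         annealing = list(initial_temperature = initial_temperature,
                          cooling_factor = cooling_factor,
                          steps_per_temperature = as.integer(steps_per_temperature),
                          min_temperature = min_temperature),
         asym_threshold = asym_threshold,
         eval_px = as.integer(eval_px)),
    class = "sim_spec"
  )
}

# The reflection group generated by the target axes. Each element is a
# pair (perm, smap): applying element T to a grid C gives
#   apply_T(C)[i] = smap[C[perm[i]] + 1],
# i.e. perm says where cell i's content comes from and smap re-orients the
# triangle state. A grid is symmetric under T iff apply_T(C) == C.
axis_group <- function(target_axes) {
  ncell <- GRID_N * GRID_N
  idx <- matrix(seq_len(ncell), GRID_N, GRID_N)
  gen_perm <- function(axis) {
    as.integer(switch(axis,
      vertical           = idx[, GRID_N:1],
      horizontal         = idx[GRID_N:1, ],
      main_diagonal      = t(idx),
      secondary_diagonal = t(idx)[GRID_N:1, GRID_N:1]
    ))
  }
  gens <- lapply(target_axes, function(a)
    list(perm = gen_perm(a), smap = STATE_MAP[[a]]))
  ident <- list(perm = seq_len(ncell), smap = CELL_STATES)
  key <- function(e) paste(c(e$perm, e$smap), collapse = ",")
  elems <- list(ident)
  seen <- key(ident)
  queue <- list(ident)
  while (length(queue)) {
    f <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      # h = g o f (apply f first, then g)
      h <- list(perm = f$perm[g$perm], smap = g$smap[f$smap + 1L])
      k <- key(h)
      if (!k %in% seen) {
        seen <- c(seen, k)
        elems <- c(elems, list(h))
        queue <- c(queue, list(h))
      }
    }
  }
  elems
}

group_apply <- function(e, cells) {
  matrix(e$smap[cells[e$perm] + 1L], GRID_N, GRID_N)
}

# Orbit partition of the 64 cells under the group, with, per orbit, the
# states admissible for its representative: stabilizer elements of the
# representative (e.g. the transpose fixing a diagonal cell) constrain
# which triangle orientations it may hold.
orbit_structure <- function(group) {
  ncell <- GRID_N * GRID_N
  orbit_id <- integer(ncell)
  orbits <- list(); reps <- integer(0); adm <- list()
  for (r in seq_len(ncell)) {
    if (orbit_id[r] != 0L) next
    members <- sort(unique(vapply(group, function(e) match(r, e$perm), integer(1))))
    oid <- length(orbits) + 1L
    orbit_id[members] <- oid
    orbits[[oid]] <- members
    reps[oid] <- r
    # admissible states: each group element writes smap[s+1] into the cell
    # j = match(r, perm); distinct elements targeting the same cell must agree
    targets <- vapply(group, function(e) match(r, e$perm), integer(1))
    adm[[oid]] <- Filter(function(s) {
      vals <- vapply(group, function(e) e$smap[s + 1L], integer(1))
      all(tapply(vals, targets, function(v) length(unique(v)) == 1L))
    }, CELL_STATES)
  }
  list(orbit_id = orbit_id, orbits = orbits, reps = reps, admissible = adm)
}

# Write state s (admissible) into the whole orbit of representative r.
set_orbit <- function(cells, group, r, s) {
  for (e in group) cells[match(r, e$perm)] <- e$smap[s + 1L]
  cells
}

# Energy of a grid w.r.t. the spec: element-count distance plus a penalty
# for every non-target axis at or above the asymmetry threshold.
pattern_energy <- function(cells, spec) {
  n <- n_elements(cells)
  lo <- spec$n_elements_range[1]; hi <- spec$n_elements_range[2]
  e <- max(0L, lo - n) + max(0L, n - hi)
  free_axes <- setdiff(SYM_AXES, spec$target_axes)
  if (length(free_axes)) {
    img <- render(cells, spec$eval_px)
    for (a in free_axes) {
      s <- axis_symmetry(img, a)
      if (s >= spec$asym_threshold) e <- e + (s - spec$asym_threshold) + 0.01
    }
  }
  e
}

#' Generate a pattern by simulated annealing
#'
#' Draws an initial grid that is exactly symmetric under the target axes
#' (orbit-wise random fill), then anneals single-orbit state-resampling
#' moves under a geometric cooling schedule until the energy — element
#' count outside the range plus any non-target axis at or above the
#' asymmetry threshold — reaches zero.
#'
#' @param spec A [sim_spec()].
#' @return A [grid_pattern()] whose declared axes score exactly 1 under
#'   [axis_symmetry()] and whose element count lies in the requested range.
#' @export
generate_pattern <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    group <- axis_group(spec$target_axes)
    os <- orbit_structure(group)
    reps <- os$reps
    adm <- os$admissible

    cells <- matrix(0L, GRID_N, GRID_N)
    for (k in seq_along(reps))
      cells <- set_orbit(cells, group, reps[k], resample1(adm[[k]]))

    e <- pattern_energy(cells, spec)
    ann <- spec$annealing
    temp <- ann$initial_temperature
    best <- cells; best_e <- e
    while (temp > ann$min_temperature && best_e > 0) {
      for (step in seq_len(ann$steps_per_temperature)) {
        k <- sample.int(length(reps), 1)
        s_new <- resample1(adm[[k]])
        cand <- set_orbit(cells, group, reps[k], s_new)
        e_new <- pattern_energy(cand, spec)
        if (e_new <= e || runif(1) < exp((e - e_new) / temp)) {
          cells <- cand; e <- e_new
          if (e < best_e) { best <- cells; best_e <- e }
          if (best_e == 0) break
        }
      }
      temp <- temp * ann$cooling_factor
    }
    if (best_e > 0)
      stop(sprintf("annealing failed to converge: residual energy %.4f",
                   best_e), call. = FALSE)

    cls <- symmetry_class_name(spec$target_axes)
    grid_pattern(best, cls, spec$seed, target_axes = spec$target_axes)
  })
}

# Canonical class label for a set of target axes.
symmetry_class_name <- function(target_axes) {
  orth <- sum(target_axes %in% c("vertical", "horizontal"))
  diag <- sum(target_axes %in% c("main_diagonal", "secondary_diagonal"))
  if (orth + diag == 0) "asymmetric"
  else if (orth + diag == 4) "4-axes"
  else if (diag == 0) paste0(orth, "-orthogonal")
  else if (orth == 0) paste0(diag, "-diagonal")
  else paste0(orth + diag, "-mixed")
}

# Axes a symmetry class declares as perfect.
class_axes <- function(symmetry_class) {
  switch(symmetry_class,
    "asymmetric"   = character(),
    "broken"       = character(),
    "1-orthogonal" = "vertical",
    "2-orthogonal" = c("vertical", "horizontal"),
    "1-diagonal"   = "main_diagonal",
    "2-diagonal"   = c("main_diagonal", "secondary_diagonal"),
    "4-axes"       = SYM_AXES,
    stop("unknown symmetry class: ", symmetry_class, call. = FALSE)
  )
}

#' Break the symmetry of a pattern inside a 3 x 3 window
#'
#' Resamples the nine cells of the window uniformly until a candidate is
#' found that (a) changes the image, (b) keeps the element count within
#' range, and (c) makes every previously perfect axis score strictly below
#' 1 — producing a "just-not-symmetric" version of a symmetric pattern.
#'
#' @param p A symmetric `grid_pattern`.
#' @param window_origin Length-2 integer (row, col) of the window's
#'   top-left cell; the 3 x 3 window must lie inside the 8 x 8 grid.
#' @param seed Integer seed.
#' @param n_elements_range Inclusive element-count range to preserve.
#' @param max_tries Attempts before giving up with an error.
#' @return A `grid_pattern` with `symmetry_class = "broken"`.
#' @export
break_symmetry <- function(p, window_origin = c(3L, 3L), seed = 1L,
                           n_elements_range = c(36L, 44L), max_tries = 100L) {
  stopifnot(inherits(p, "grid_pattern"))
  if (p$symmetry_class %in% c("asymmetric", "broken"))
    stop("pattern has no symmetric class to break", call. = FALSE)
  wo <- as.integer(window_origin)
  if (length(wo) != 2 || any(wo < 1L) || any(wo > GRID_N - 2L))
    stop("window_origin must place a 3x3 window inside the grid", call. = FALSE)
  axes <- if (length(p$target_axes)) p$target_axes else class_axes(p$symmetry_class)
  rows <- wo[1]:(wo[1] + 2L); cols <- wo[2]:(wo[2] + 2L)
  w9 <- p$cells[rows, cols]
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      # count-preserving shuffle: permute the window's states and
      # re-orient its triangles, with an occasional single-cell jitter
      # (uniform resampling of the whole window almost never stays inside
      # the element-count range when the window is sparse or dense)
      new9 <- sample(w9)
      tri <- new9 %in% 1:4
      new9[tri] <- sample(1:4, sum(tri), replace = TRUE)
      if (runif(1) < 0.5) new9[sample.int(9L, 1L)] <- sample(CELL_STATES, 1L)
      cand <- p$cells
      cand[rows, cols] <- new9
      if (identical(cand, p$cells)) next
      n <- n_elements(cand)
      if (n < n_elements_range[1] || n > n_elements_range[2]) next
      img <- render(cand, 4L)
      broken_all <- all(vapply(axes, function(a) axis_symmetry(img, a) < 1,
                               logical(1)))
      if (!broken_all) next
      out <- grid_pattern(cand, "broken", seed)
      attr(out, "parent_class") <- p$symmetry_class
      return(out)
    }
    stop("no admissible perturbation found in the 3x3 window after ",
         max_tries, " tries", call. = FALSE)
  })
}
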