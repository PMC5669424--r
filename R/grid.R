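# Triangle-grid patterns: an 8 x 8 grid of cells, each empty, one of four
# half-square triangles, or full. Cell states are coded
#   0 empty, 1 NE, 2 NW, 3 SE, 4 SW, 5 full,
# where the triangle name is the black half-square: NE/SW lie across the
# cell's main diagonal, NW/SE across its anti-diagonal. A triangle counts
# as one black element, a full cell as two.

GRID_N <- 8L
CELL_STATES <- 0:5
STATE_ELEMENTS <- c(0L, 1L, 1L, 1L, 1L, 2L)  # indexed by state + 1

# State images under the four reflections (indexed by state + 1).
# Derived from the rasterized masks below; verified by tests that
# render(reflect(grid)) == reflect(render(grid)).
STATE_MAP <- list(
  vertical           = c(0L, 2L, 1L, 4L, 3L, 5L),  # NE<->NW, SE<->SW
  horizontal         = c(0L, 3L, 4L, 1L, 2L, 5L),  # NE<->SE, NW<->SW
  main_diagonal      = c(0L, 4L, 2L, 3L, 1L, 5L),  # NE<->SW
  secondary_diagonal = c(0L, 1L, 3L, 2L, 4L, 5L)   # NW<->SE
)

# Pixel mask of a cell state at even resolution p (TRUE = black).
# Triangles include their diagonal pixels, so that each reflection maps
# state masks exactly onto state masks.
state_mask <- function(state, p) {
  r <- matrix(seq_len(p), p, p)
  c_ <- t(r)
  switch(state + 1L,
    matrix(FALSE, p, p),   # empty
    c_ >= r,               # NE
    r + c_ <= p + 1,       # NW
    r + c_ >= p + 1,       # SE
    c_ <= r,               # SW
    matrix(TRUE, p, p)     # full
  )
}

#' Construct a triangle-grid pattern
#'
#' @param cells Integer 8 x 8 matrix of cell states (0 empty, 1-4 the four
#'   half-square triangles NE/NW/SE/SW, 5 full).
#' @param symmetry_class One of `"asymmetric"`, `"1-orthogonal"`,
#'   `"2-orthogonal"`, `"1-diagonal"`, `"2-diagonal"`, `"4-axes"`,
#'   `"broken"`.
#' @param seed Integer seed recorded for provenance.
#' @param target_axes Axes the pattern is declared symmetric about.
#' @return Object of class `grid_pattern` with fields `cells`,
#'   `symmetry_class`, `n_elements`, `target_axes`, `seed`.
#' @export
grid_pattern <- function(cells, symmetry_class = "asymmetric",
                         seed = NA_integer_, target_axes = character()) {
  cells <- matrix(as.integer(cells), GRID_N, GRID_N)
  if (!all(cells %in% CELL_STATES))
    stop("invalid cell state codes", call. = FALSE)
  structure(
    list(cells = cells,
         symmetry_class = symmetry_class,
         n_elements = n_elements(cells),
         target_axes = target_axes,
         seed = as.integer(seed)),
    class = "grid_pattern"
  )
}

#' Number of black elements in a pattern
#'
#' Triangles count as one element, full cells as two.
#'
#' @param x A `grid_pattern` or a cell-state matrix.
#' @return Integer element count.
#' @export
n_elements <- function(x) {
  cells <- if (inherits(x, "grid_pattern")) x$cells else x
  sum(STATE_ELEMENTS[cells + 1L])
}

#' @exportS3Method base::print
print.grid_pattern <- function(x, ...) {
  glyph <- c(".", "◥", "◤", "◢", "◣", "#")
  cat("grid_pattern:", x$symmetry_class, "|", x$n_elements, "elements\n")
  for (i in seq_len(GRID_N))
    cat(" ", glyph[x$cells[i, ] + 1L], "\n")
  invisible(x)
}

# Reflect a cell-state matrix across one of the four axes of the grid.
reflect_cells <- function(cells, axis) {
  sm <- STATE_MAP[[axis]]
  moved <- switch(axis,
    vertical           = cells[, GRID_N:1],
    horizontal         = cells[GRID_N:1, ],
    main_diagonal      = t(cells),
    secondary_diagonal = t(cells)[GRID_N:1, GRID_N:1]
  )
  matrix(sm[moved + 1L], GRID_N, GRID_N)
}

# Is the grid exactly symmetric about the given axis?
cells_symmetric <- function(cells, axis) {
  identical(reflect_cells(cells, axis), matrix(as.integer(cells), GRID_N, GRID_N))
}

#' Render a grid pattern to a binary raster image
#'
#' Each cell becomes a `px_per_cell` x `px_per_cell` block; triangles fill
#' the half-square on their side of the cell diagonal (diagonal pixels
#' included). Black elements are 0, background is 1. The default 75 px per
#' cell gives the 600 x 600 stimulus format.
#'
#' Because triangle masks include their diagonal pixels, every reflection
#' maps cell masks exactly onto cell masks at any resolution, so rendered
#' images of symmetric grids are exactly mirror-symmetric regardless of the
#' parity of `px_per_cell`.
#'
#' @param p A `grid_pattern` (or a cell-state matrix).
#' @param px_per_cell Integer >= 2, pixels per grid cell.
#' @return Binary matrix of size `(8 * px_per_cell)^2`.
#' @export
render <- function(p, px_per_cell = 75L) {
  cells <- if (inherits(p, "grid_pattern")) p$cells else p
  px <- as.integer(px_per_cell)
  if (is.na(px) || px < 2L)
    stop("px_per_cell must be an integer >= 2", call. = FALSE)
  masks <- lapply(CELL_STATES, state_mask, p = px)
  img <- matrix(1, GRID_N * px, GRID_N * px)
  for (i in seq_len(GRID_N)) for (j in seq_len(GRID_N)) {
    s <- cells[i, j]
    if (s == 0L) next
    rows <- ((i - 1L) * px + 1L):(i * px)
    cols <- ((j - 1L) * px + 1L):(j * px)
    blk <- img[rows, cols]
    blk[masks[[s + 1L]]] <- 0
    img[rows, cols] <- blk
  }
  img
}
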