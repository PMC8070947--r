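#' Raster grid geometry
#'
#' A lightweight description of a regular raster grid: dimensions, cell size
#' in meters, and the map coordinate of the outer (top-left) corner of cell
#' (1,1). Rows run north to south, columns west to east, and all distance
#' computations use cell centers. Every multi-raster operation in the package
#' requires its inputs to share an identical grid (see [grids_aligned()]);
#' nothing is ever resampled implicitly.
#'
#' @param n_rows,n_cols Grid dimensions (positive integers).
#' @param cell_size Edge length of a square cell, in meters (> 0).
#' @param origin Numeric length-2, the (x, y) map coordinate of the top-left
#'   corner of the top-left cell.
#' @param crs_label Free-text spatial-reference tag; may be empty. Carried
#'   through I/O but never interpreted.
#' @return An object of class `iev_grid`.
#' @examples
#' g <- iev_grid(10, 10, cell_size = 30)
#' g
#' @export
iev_grid <- function(n_rows, n_cols, cell_size, origin = c(0, 0), crs_label = "") {
  if (!is_scalar_number(n_rows) || !is_scalar_number(n_cols) ||
      n_rows < 1 || n_cols < 1) {
    stop_config("n_rows and n_cols must be positive integers")
  }
  if (!is_scalar_number(cell_size) || cell_size <= 0) {
    stop_config("cell_size must be a positive number (meters)")
  }
  if (!is.numeric(origin) || length(origin) != 2L || any(!is.finite(origin))) {
    stop_config("origin must be a finite (x, y) pair")
  }
  structure(
    list(
      n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
      cell_size = as.numeric(cell_size), origin = as.numeric(origin),
      crs_label = as.character(crs_label)[1]
    ),
    class = "iev_grid"
  )
}

#' @export
print.iev_grid <- function(x, ...) {
  cat(sprintf("<iev_grid> %d x %d cells, %g m resolution, origin (%g, %g)%s\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin[1], x$origin[2],
              if (nzchar(x$crs_label)) paste0(", crs: ", x$crs_label) else ""))
  invisible(x)
}

#' Test whether two grids are aligned
#'
#' Grids are aligned iff dimensions, cell size, origin and CRS label are all
#' equal. Aligned grids are a precondition of every cross-raster operation.
#'
#' @param a,b `iev_grid` objects (or objects carrying a `$grid`).
#' @return `TRUE` or `FALSE`.
#' @export
grids_aligned <- function(a, b) {
  a <- as_grid(a); b <- as_grid(b)
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    a$cell_size == b$cell_size &&
    all(a$origin == b$origin) && a$crs_label == b$crs_label
}

#' @noRd
as_grid <- function(x) {
  if (inherits(x, "iev_grid")) return(x)
  if (is.list(x) && inherits(x$grid, "iev_grid")) return(x$grid)
  stop_config("not a grid-bearing object")
}

#' @noRd
check_aligned <- function(...) {
  objs <- list(...)
  g0 <- as_grid(objs[[1]])
  for (o in objs[-1]) {
    if (!grids_aligned(g0, o)) stop_data("unaligned grids: all layers must share an identical grid")
  }
  invisible(g0)
}

#' Continuous-valued raster layer
#'
#' A georeferenced grid of real values with an explicit validity mask. Cells
#' with `valid = FALSE` are nodata: they are excluded from every statistic,
#' probability table and area count downstream, and any cell invalid in one
#' input of a multi-layer operation is invalid in its output.
#'
#' @param values Numeric matrix (`n_rows` x `n_cols`) or vector of that length,
#'   row-major from the top row.
#' @param grid An [iev_grid()].
#' @param valid Optional logical matrix of the same shape; defaults to
#'   `is.finite(values)`.
#' @return An object of class `iev_raster` with fields `grid`, `values`,
#'   `valid`. Invalid cells hold `NA` in `values`.
#' @export
iev_raster <- function(values, grid, valid = NULL) {
  stopifnot(inherits(grid, "iev_grid"))
  values <- shape_matrix(values, grid, "values", "double")
  if (is.null(valid)) valid <- is.finite(values)
  valid <- shape_matrix(valid, grid, "valid", "logical")
  valid[!is.finite(values)] <- FALSE
  values[!valid] <- NA_real_
  structure(list(grid = grid, values = values, valid = valid),
            class = "iev_raster")
}

# coerce to a grid-shaped matrix of the requested mode; matrices keep their
# orientation (mode changed in place), bare vectors are filled row-major
#' @noRd
shape_matrix <- function(x, grid, what, mode = "double") {
  if (is.matrix(x)) {
    if (nrow(x) != grid$n_rows || ncol(x) != grid$n_cols) {
      stop_data(what, " matrix does not match the grid dimensions")
    }
    storage.mode(x) <- mode
    return(x)
  }
  if (length(x) != grid$n_rows * grid$n_cols) {
    stop_data(what, " must have n_rows * n_cols entries")
  }
  storage.mode(x) <- mode
  matrix(x, nrow = grid$n_rows, ncol = grid$n_cols, byrow = TRUE)
}

#' @export
print.iev_raster <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<iev_raster> %d x %d, %d valid cells, range [%s, %s]\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$valid),
              if (length(v)) signif(min(v), 4) else "-",
              if (length(v)) signif(max(v), 4) else "-"))
  invisible(x)
}

#' Constant raster over a grid
#'
#' Materializes a spatially uniform layer (used for adaptability-type
#' indicators whose value is island-wide constant) as an ordinary raster so
#' it can enter the same aggregation pipeline as heterogeneous layers.
#'
#' @param value Single finite number.
#' @param grid An [iev_grid()].
#' @param domain Optional [region_mask()]; cells outside it become invalid.
#' @return An `iev_raster`.
#' @export
constant_raster <- function(value, grid, domain = NULL) {
  if (!is_scalar_number(value)) stop_config("value must be a single finite number")
  valid <- matrix(TRUE, grid$n_rows, grid$n_cols)
  if (!is.null(domain)) {
    check_aligned(grid, domain)
    valid <- domain$member
  }
  iev_raster(matrix(value, grid$n_rows, grid$n_cols), grid, valid)
}

#' Categorical (state-level) raster layer
#'
#' A grid of integer states in `1..n_states` with a validity mask, as produced
#' by [discretize()] or [classify_ievi()]. States are ordinal: level 1 is the
#' lowest interval of the underlying continuous variable.
#'
#' @param levels Integer matrix/vector of states.
#' @param n_states Number of states `m` (>= 2).
#' @param grid An [iev_grid()].
#' @param valid Optional logical mask; defaults to non-`NA` levels.
#' @param id Optional variable identifier carried into probability tables.
#' @param labels Optional character vector of length `n_states`.
#' @return An object of class `iev_categorical`.
#' @export
categorical_raster <- function(levels, n_states, grid, valid = NULL,
                               id = NULL, labels = NULL) {
  stopifnot(inherits(grid, "iev_grid"))
  if (!is_scalar_number(n_states) || n_states < 2) {
    stop_config("n_states must be an integer >= 2")
  }
  n_states <- as.integer(n_states)
  levels <- shape_matrix(levels, grid, "levels", "integer")
  if (is.null(valid)) valid <- !is.na(levels)
  valid <- shape_matrix(valid, grid, "valid", "logical")
  valid[is.na(levels)] <- FALSE
  levels[!valid] <- NA_integer_
  lv <- levels[valid]
  if (length(lv) && (min(lv) < 1L || max(lv) > n_states)) {
    stop_data("every valid cell's level must lie in 1..n_states")
  }
  if (!is.null(labels) && length(labels) != n_states) {
    stop_config("labels must have one entry per state")
  }
  structure(list(grid = grid, levels = levels, n_states = n_states,
                 valid = valid, id = id, labels = labels),
            class = "iev_categorical")
}

#' @export
print.iev_categorical <- function(x, ...) {
  cat(sprintf("<iev_categorical>%s %d x %d, %d states, %d valid cells\n",
              if (!is.null(x$id)) paste0(" ", x$id) else "",
              x$grid$n_rows, x$grid$n_cols, x$n_states, sum(x$valid)))
  tab <- tabulate(x$levels[x$valid], x$n_states)
  names(tab) <- x$labels %||% paste0("state ", seq_len(x$n_states))
  print(tab)
  invisible(x)
}

#' Convert an integer-valued raster to a categorical raster
#'
#' @param r An `iev_raster` holding whole numbers at valid cells.
#' @param n_states Number of states.
#' @param id,labels Passed to [categorical_raster()].
#' @return An `iev_categorical`.
#' @export
as_categorical <- function(r, n_states, id = NULL, labels = NULL) {
  stopifnot(inherits(r, "iev_raster"))
  v <- r$values
  if (any(r$valid & (v != round(v)))) {
    stop_data("raster holds non-integer values; cannot interpret as states")
  }
  lv <- matrix(NA_integer_, r$grid$n_rows, r$grid$n_cols)
  lv[r$valid] <- as.integer(round(v[r$valid]))
  categorical_raster(lv, n_states, r$grid, r$valid, id = id, labels = labels)
}

#' Boolean region mask
#'
#' Marks the cells belonging to a region (island land, the 1-km-buffered
#' study area, a matched state subset, a promotion tier). A mask used as an
#' analysis domain must be non-empty.
#'
#' @param member Logical matrix/vector of membership.
#' @param grid An [iev_grid()].
#' @return An object of class `iev_mask`.
#' @export
region_mask <- function(member, grid) {
  stopifnot(inherits(grid, "iev_grid"))
  member <- shape_matrix(member, grid, "member", "logical")
  member[is.na(member)] <- FALSE
  structure(list(grid = grid, member = member), class = "iev_mask")
}

#' @export
print.iev_mask <- function(x, ...) {
  cat(sprintf("<iev_mask> %d x %d, %d member cells (%.1f ha)\n",
              x$grid$n_rows, x$grid$n_cols, sum(x$member),
              sum(x$member) * x$grid$cell_size^2 / 1e4))
  invisible(x)
}

#' @noRd
domain_member <- function(domain, grid) {
  if (is.null(domain)) return(matrix(TRUE, grid$n_rows, grid$n_cols))
  check_aligned(grid, domain)
  domain$member
}

#' Buffer a region mask outward by a metric distance
#'
#' Grows a land mask by Euclidean distance on cell centers: the result
#' contains every cell whose center lies within `distance` of the center of
#' some member cell, including the members themselves. With
#' `distance = 1000` this implements the assessment-scope convention of a
#' 1-km seaward extension of the island land.
#'
#' The operation is monotone in `distance` and `distance = 0` is the
#' identity.
#'
#' @param land A non-empty [region_mask()].
#' @param distance Buffer distance in meters (>= 0).
#' @return A [region_mask()] on the same grid.
#' @export
buffer_mask <- function(land, distance) {
  stopifnot(inherits(land, "iev_mask"))
  if (!is_scalar_number(distance) || distance < 0) {
    stop_config("distance must be a nonnegative number of meters")
  }
  if (!any(land$member)) stop_data("land mask is empty")
  g <- land$grid
  r <- floor(distance / g$cell_size)
  nr <- g$n_rows; nc <- g$n_cols
  out <- matrix(FALSE, nr, nc)
  mem <- land$member
  d2max <- (distance / g$cell_size)^2
  for (di in -r:r) {
    if (max(1L, 1L - di) > min(nr, nr - di)) next
    sr <- max(1L, 1L - di):min(nr, nr - di)
    tr <- sr + di
    for (dj in -r:r) {
      if (di * di + dj * dj > d2max) next
      if (max(1L, 1L - dj) > min(nc, nc - dj)) next
      sc <- max(1L, 1L - dj):min(nc, nc - dj)
      tc <- sc + dj
      out[tr, tc] <- out[tr, tc] | mem[sr, sc]
    }
  }
  region_mask(out, g)
}

#' @noRd
raster_values_on <- function(r, member) {
  r$values[r$valid & member]
}
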