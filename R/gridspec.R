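#' Grid specification for a regular lon/lat lattice
#'
#' A `grid_spec` describes a rectangular lattice of square cells anchored at
#' its top-left (north-west) corner. Coordinates are geographic degrees
#' treated as planar; row 1 is the northernmost row. Cell `(r, c)` covers the
#' half-open box `[origin_lon + (c-1)*s, origin_lon + c*s)` in longitude and
#' `(origin_lat - r*s, origin_lat - (r-1)*s]` in latitude, so points on shared
#' edges belong to exactly one cell.
#'
#' @param origin_lon,origin_lat Top-left corner, degrees.
#' @param cell_size Cell edge length, degrees (> 0).
#' @param n_rows,n_cols Lattice dimensions (>= 1).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_lon, origin_lat, cell_size, n_rows, n_cols) {
  stopifnot(is.numeric(cell_size), length(cell_size) == 1L, cell_size > 0)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L) stop("n_rows and n_cols must be >= 1")
  structure(
    list(origin_lon = as.numeric(origin_lon),
         origin_lat = as.numeric(origin_lat),
         cell_size = as.numeric(cell_size),
         n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %g deg, top-left (%g, %g)\n",
              x$n_rows, x$n_cols, x$cell_size, x$origin_lon, x$origin_lat))
  invisible(x)
}

n_cells <- function(spec) spec$n_rows * spec$n_cols

#' Nesting factor between a coarse and a fine grid
#'
#' Two grids are nested when the coarse cell size is an integer multiple
#' `k >= 2` of the fine cell size and the extents coincide, so the k^2 fine
#' children of any coarse cell tile it exactly.
#'
#' @param coarse,fine `grid_spec` objects.
#' @return The integer nesting factor `k`.
#' @export
nesting_factor <- function(coarse, fine) {
  k <- coarse$cell_size / fine$cell_size
  tol <- 1e-9 * fine$cell_size
  if (abs(k - round(k)) > 1e-9 || round(k) < 2)
    stop("grids are not nested: coarse cell size must be an integer multiple (k >= 2) of the fine size")
  k <- as.integer(round(k))
  same <- abs(coarse$origin_lon - fine$origin_lon) < tol &&
    abs(coarse$origin_lat - fine$origin_lat) < tol &&
    coarse$n_rows * k == fine$n_rows && coarse$n_cols * k == fine$n_cols
  if (!same) stop("grids are not nested: extents do not coincide")
  k
}

#' Derive the coarse grid nested above a fine grid
#' @param fine A `grid_spec` whose dimensions are divisible by `k`.
#' @param k Integer nesting factor (>= 2).
#' @return The coarse `grid_spec`.
#' @export
coarsen_spec <- function(fine, k) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (fine$n_rows %% k != 0L || fine$n_cols %% k != 0L)
    stop("fine grid dimensions must be divisible by k")
  grid_spec(fine$origin_lon, fine$origin_lat, fine$cell_size * k,
            fine$n_rows %/% k, fine$n_cols %/% k)
}

#' Map points to cell ids
#'
#' Cell ids are row-major: `id = (row - 1) * n_cols + col`. Points outside the
#' grid extent get `NA`.
#'
#' @param spec A `grid_spec`.
#' @param lon,lat Point coordinates, degrees.
#' @return Integer cell ids.
#' @export
point_to_cell <- function(spec, lon, lat) {
  s <- spec$cell_size
  u <- (spec$origin_lat - lat) / s   # row offset; top edge closed
  v <- (lon - spec$origin_lon) / s   # col offset; left edge closed
  r <- floor(u) + 1L
  cc <- floor(v) + 1L
  # the northernmost edge (u == 0) belongs to row 1
  r[u == 0] <- 1L
  ok <- r >= 1L & r <= spec$n_rows & cc >= 1L & cc <= spec$n_cols
  id <- (r - 1L) * spec$n_cols + cc
  id[!ok] <- NA_integer_
  as.integer(id)
}

cell_to_rc <- function(spec, id) {
  id <- as.integer(id)
  r <- (id - 1L) %/% spec$n_cols + 1L
  cc <- (id - 1L) %% spec$n_cols + 1L
  cbind(row = r, col = cc)
}

#' Cell-centre coordinates
#' @param spec A `grid_spec`.
#' @param id Integer cell ids (default: all cells).
#' @return A two-column matrix (lon, lat) of cell centres.
#' @export
cell_centres <- function(spec, id = seq_len(n_cells(spec))) {
  rc <- cell_to_rc(spec, id)
  cbind(lon = spec$origin_lon + (rc[, "col"] - 0.5) * spec$cell_size,
        lat = spec$origin_lat - (rc[, "row"] - 0.5) * spec$cell_size)
}

#' Parent map from fine to coarse cells
#'
#' @param fine,coarse Nested `grid_spec` objects.
#' @return An integer vector of length `n_fine_cells`; entry `i` is the coarse
#'   cell id containing fine cell `i`.
#' @export
parent_map <- function(fine, coarse) {
  k <- nesting_factor(coarse, fine)
  rc <- cell_to_rc(fine, seq_len(n_cells(fine)))
  pr <- (rc[, "row"] - 1L) %/% k + 1L
  pc <- (rc[, "col"] - 1L) %/% k + 1L
  as.integer((pr - 1L) * coarse$n_cols + pc)
}

# matrix layer helpers -------------------------------------------------------

#' Constant layer on a grid
#' @param spec A `grid_spec`.
#' @param fill Fill value.
#' @return Matrix of dimension `n_rows x n_cols`.
#' @export
empty_layer <- function(spec, fill = 0) {
  matrix(fill, nrow = spec$n_rows, ncol = spec$n_cols)
}

check_layer <- function(layer, spec) {
  if (!is.matrix(layer) || nrow(layer) != spec$n_rows || ncol(layer) != spec$n_cols)
    stop("layer dimensions do not match the grid spec")
  invisible(TRUE)
}

# cell ids (row-major) <-> matrix positions; R matrices are column-major so
# translate explicitly rather than indexing by id.

#' Read layer values at row-major cell ids
#' @param layer A layer matrix.
#' @param id Integer cell ids (`(row - 1) * n_cols + col`).
#' @return Values at those cells.
#' @export
layer_values <- function(layer, id) {
  nc <- ncol(layer)
  r <- (id - 1L) %/% nc + 1L
  cc <- (id - 1L) %% nc + 1L
  layer[cbind(r, cc)]
}

`layer_values<-` <- function(layer, id, value) {
  nc <- ncol(layer)
  r <- (id - 1L) %/% nc + 1L
  cc <- (id - 1L) %% nc + 1L
  layer[cbind(r, cc)] <- value
  layer
}

#' Row-major cell ids where a mask is TRUE
#' @param layer A layer matrix (defines the dimensions).
#' @param mask Logical matrix of the same shape.
#' @return Sorted integer cell ids.
#' @export
layer_which <- function(layer, mask) {
  # cell ids (row-major) where logical matrix `mask` is TRUE
  pos <- which(mask)                     # column-major positions
  r <- (pos - 1L) %% nrow(layer) + 1L
  cc <- (pos - 1L) %/% nrow(layer) + 1L
  sort(as.integer((r - 1L) * ncol(layer) + cc))
}

# evaluate an expression with a temporary RNG seed, restoring global state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# deterministic fan-out of a master seed into per-stage seeds (< 2^31)
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 10007 + counter * 7919 + 1) %% 2147483629)
}
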