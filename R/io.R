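#' Write a layer as an ESRI ASCII grid
#'
#' @param layer Numeric matrix (row 1 = north).
#' @param spec The layer's `grid_spec`.
#' @param path Output path (conventionally `.asc`).
#' @param nodata NODATA value written for `NA` cells.
#' @export
write_ascii_grid <- function(layer, spec, path, nodata = -9999) {
  check_layer(layer, spec)
  hdr <- c(sprintf("ncols %d", spec$n_cols),
           sprintf("nrows %d", spec$n_rows),
           sprintf("xllcorner %.10g", spec$origin_lon),
           sprintf("yllcorner %.10g", spec$origin_lat - spec$n_rows * spec$cell_size),
           sprintf("cellsize %.10g", spec$cell_size),
           sprintf("NODATA_value %g", nodata))
  vals <- layer
  vals[is.na(vals)] <- nodata
  body <- apply(vals, 1L, function(row) paste(format(row, trim = TRUE, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to an `.asc` file.
#' @return A list with elements `spec` (a `grid_spec`) and `values` (matrix,
#'   row 1 = north, `NA` for NODATA cells).
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"), quiet = TRUE)
  if (length(vals) != nr * nc) stop("ESRI ASCII body has wrong length in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  spec <- grid_spec(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize, hdr$cellsize, nr, nc)
  list(spec = spec, values = m)
}

#' Write occurrence records as CSV
#' @param records Data frame with columns `species`, `lon`, `lat`.
#' @param path Output CSV path.
#' @export
write_records_csv <- function(records, path) {
  stopifnot(all(c("species", "lon", "lat") %in% names(records)))
  utils::write.csv(records[, c("species", "lon", "lat")], path, row.names = FALSE)
  invisible(path)
}

#' Read occurrence records from CSV
#' @param path CSV path with columns `species`, `lon`, `lat`.
#' @return Data frame of records.
#' @export
read_records_csv <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "lon", "lat") %in% names(rec)))
    stop("records CSV must have columns species, lon, lat")
  rec
}

# reserves are lists of simple polygons: each a two-column (lon, lat) matrix,
# open ring (first vertex not repeated), vertices in any consistent order

#' Axis-aligned rectangular reserve polygon
#' @param lon0,lat0 One corner (degrees).
#' @param lon1,lat1 Opposite corner (degrees).
#' @return A 4 x 2 vertex matrix (counter-clockwise, open ring).
#' @export
rect_reserve <- function(lon0, lat0, lon1, lat1) {
  xs <- sort(c(lon0, lon1)); ys <- sort(c(lat0, lat1))
  cbind(lon = c(xs[1], xs[2], xs[2], xs[1]),
        lat = c(ys[1], ys[1], ys[2], ys[2]))
}

#' Area-matched polygon for a point reserve
#'
#' Protected areas known only as point locations are represented as circles of
#' the reported surface; here a regular 64-gon whose polygon area equals
#' `area` exactly.
#'
#' @param lon,lat Centre (degrees).
#' @param area Reported surface (square degrees).
#' @param n Number of vertices.
#' @return Vertex matrix.
#' @export
point_reserve <- function(lon, lat, area, n = 64L) {
  r <- sqrt(2 * area / (n * sin(2 * pi / n)))
  th <- 2 * pi * (seq_len(n) - 1L) / n
  cbind(lon = lon + r * cos(th), lat = lat + r * sin(th))
}

#' Polygon area by the shoelace formula
#' @param poly Two-column vertex matrix (open ring).
#' @return Absolute area.
#' @export
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(seq_len(nrow(poly))[-1], 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Write reserves as a GeoJSON FeatureCollection
#' @param reserves List of polygon vertex matrices.
#' @param path Output path.
#' @export
write_reserves_geojson <- function(reserves, path) {
  feats <- lapply(seq_along(reserves), function(i) {
    p <- reserves[[i]]
    ring <- rbind(p, p[1, , drop = FALSE])     # GeoJSON rings are closed
    list(type = "Feature",
         properties = list(id = i),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(j) as.numeric(ring[j, ])))))
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read reserves from a GeoJSON FeatureCollection of Polygons
#' @param path GeoJSON path.
#' @return List of polygon vertex matrices (open rings, outer ring only).
#' @export
read_reserves_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (is.null(fc$type) || fc$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  lapply(fc$features, function(f) {
    g <- f$geometry
    if (g$type != "Polygon") stop("only Polygon features are supported")
    ring <- do.call(rbind, lapply(g$coordinates[[1]], function(v) as.numeric(v[1:2])))
    # drop the closing vertex
    if (nrow(ring) > 1 && all(ring[1, ] == ring[nrow(ring), ]))
      ring <- ring[-nrow(ring), , drop = FALSE]
    colnames(ring) <- c("lon", "lat")
    ring
  })
}
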