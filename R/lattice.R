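#' Generate a unit-square toy lattice with Queen contiguity
#'
#' Builds a `rows` x `cols` grid of unit-square polygons as a stand-in map
#' for small-area analysis, keeping the first `n_areas` cells in row-major
#' order (dropping trailing cells keeps the map connected, which allows maps
#' whose area count is not a product of two integers, e.g. 79 areas from an
#' 8 x 10 grid).
#'
#' @param rows,cols positive integers, grid dimensions.
#' @param n_areas number of cells to keep (default all `rows * cols`).
#' @return an object of class `hrr_lattice`: list with `polygons` (closed
#'   rings, integer coordinates), `adjacency` (Queen-1 [adjacency]), `ids`,
#'   `rows`, `cols`.
#' @examples
#' lat <- generate_lattice(3, 3)
#' lat$adjacency$counts[5] # centre cell has 8 Queen neighbours
#' @export
generate_lattice <- function(rows, cols, n_areas = rows * cols) {
  if (!(rows >= 1 && cols >= 1)) stop("lattice dimensions must be positive")
  rows <- as.integer(rows)
  cols <- as.integer(cols)
  n_areas <- as.integer(n_areas)
  if (n_areas < 1L || n_areas > rows * cols) {
    stop("`n_areas` must be between 1 and rows * cols")
  }
  polygons <- vector("list", n_areas)
  for (i in seq_len(n_areas)) {
    r <- (i - 1L) %/% cols
    c0 <- (i - 1L) %% cols
    polygons[[i]] <- rbind(
      c(c0, r), c(c0 + 1L, r), c(c0 + 1L, r + 1L), c(c0, r + 1L), c(c0, r)
    )
  }
  structure(
    list(
      polygons = polygons,
      adjacency = build_adjacency_from_polygons(polygons),
      ids = seq_len(n_areas),
      rows = rows,
      cols = cols
    ),
    class = "hrr_lattice"
  )
}

#' @export
print.hrr_lattice <- function(x, ...) {
  cat(sprintf(
    "Toy lattice: %d areas on a %d x %d grid\n",
    length(x$ids), x$rows, x$cols
  ))
  invisible(x)
}

#' Write polygons (plus optional per-area properties) as GeoJSON
#'
#' Coordinates are written as-is (unit grid coordinates, no CRS assumed).
#'
#' @param polygons list of closed-ring coordinate matrices.
#' @param file output path.
#' @param properties optional data frame, one row per polygon.
#' @return `file`, invisibly.
#' @export
write_geojson <- function(polygons, file, properties = NULL) {
  J <- length(polygons)
  if (!is.null(properties) && nrow(properties) != J) {
    stop("`properties` must have one row per polygon")
  }
  features <- lapply(seq_len(J), function(i) {
    p <- polygons[[i]]
    props <- if (is.null(properties)) {
      list(area_id = i)
    } else {
      c(list(area_id = i), as.list(properties[i, , drop = FALSE]))
    }
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        # one ring; GeoJSON wants an array of [x, y] positions
        coordinates = list(lapply(seq_len(nrow(p)), function(r) c(p[r, 1L], p[r, 2L])))
      )
    )
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features),
    file,
    auto_unbox = TRUE, digits = NA
  )
  invisible(file)
}

#' Read polygons and properties back from GeoJSON
#'
#' @param file path to a GeoJSON FeatureCollection of Polygon features.
#' @return list with `polygons` (closed rings) and `properties` (data frame).
#' @export
read_geojson <- function(file) {
  gj <- jsonlite::read_json(file)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  polygons <- lapply(feats, function(f) {
    ring <- f$geometry$coordinates[[1L]]
    do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
  })
  props <- lapply(feats, function(f) {
    lapply(f$properties, function(v) if (is.null(v)) NA else unlist(v))
  })
  properties <- do.call(rbind, lapply(props, function(p) as.data.frame(p)))
  list(polygons = polygons, properties = properties)
}
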