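#' Construct an adjacency structure from neighbor lists
#'
#' An `adjacency` object stores the symmetric Queen-1 neighbor graph used by
#' the ICAR prior: per-area sorted neighbor index lists, binary weights
#' (every neighbor contributes equally, weight 1), neighbor counts
#' \eqn{n_i = \sum_j w_{ij}}, and connected-component labels.
#'
#' @param neighbors list of integer vectors; `neighbors[[i]]` are the 1-based
#'   indices of the areas adjacent to area `i`. Must be symmetric and free of
#'   self-loops.
#' @return an object of class `adjacency` with elements `n_areas`,
#'   `neighbors`, `counts`, `components` (1-based component labels).
#' @export
adjacency <- function(neighbors) {
  if (!is.list(neighbors)) stop("`neighbors` must be a list of integer vectors")
  neighbors <- lapply(neighbors, function(x) sort(unique(as.integer(x))))
  J <- length(neighbors)
  for (i in seq_len(J)) {
    nb <- neighbors[[i]]
    if (length(nb) == 0L) next
    if (any(nb < 1L | nb > J)) {
      stop(sprintf("neighbor index out of range for area %d", i))
    }
    if (any(nb == i)) stop(sprintf("self-loop at area %d", i))
    for (j in nb) {
      if (!(i %in% neighbors[[j]])) {
        stop(sprintf("asymmetric adjacency: %d lists %d but not conversely", i, j))
      }
    }
  }
  structure(
    list(
      n_areas = J,
      neighbors = neighbors,
      counts = vapply(neighbors, length, integer(1)),
      components = graph_components(neighbors)
    ),
    class = "adjacency"
  )
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf(
    "Queen-1 adjacency: %d areas, %d edges, %d connected component(s)\n",
    x$n_areas, sum(x$counts) / 2L, max(x$components)
  ))
  invisible(x)
}

# Connected components by breadth-first search over the neighbor lists.
graph_components <- function(neighbors) {
  J <- length(neighbors)
  comp <- integer(J)
  current <- 0L
  for (s in seq_len(J)) {
    if (comp[s] > 0L) next
    current <- current + 1L
    queue <- s
    comp[s] <- current
    while (length(queue)) {
      i <- queue[[1L]]
      queue <- queue[-1L]
      for (j in neighbors[[i]]) {
        if (comp[j] == 0L) {
          comp[j] <- current
          queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

#' Binary adjacency matrix
#'
#' @param adj an [adjacency] object.
#' @return a symmetric 0/1 matrix with zero diagonal.
#' @export
adjacency_matrix <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  J <- adj$n_areas
  W <- matrix(0, J, J)
  for (i in seq_len(J)) W[i, adj$neighbors[[i]]] <- 1
  W
}

#' Graph Laplacian of an adjacency structure
#'
#' `L = diag(n_i) - W`; the ICAR prior has (improper) precision `L / tau_u2`.
#'
#' @inheritParams adjacency_matrix
#' @return a J x J matrix.
#' @export
graph_laplacian <- function(adj) {
  W <- adjacency_matrix(adj)
  diag(rowSums(W)) - W
}

#' Build Queen-1 adjacency from polygons
#'
#' Two areas are adjacent iff their boundaries share at least one point; on
#' the unit-grid toy maps produced by [generate_lattice()] every boundary
#' contact includes a shared vertex, so the predicate compares vertex
#' coordinates exactly (tolerance zero, coordinates are integers there).
#' A shared corner suffices (Queen contiguity).
#'
#' @param polygons list of closed rings: numeric matrices with two columns
#'   (x, y) whose last row repeats the first.
#' @return an [adjacency] object.
#' @export
build_adjacency_from_polygons <- function(polygons) {
  J <- length(polygons)
  if (J == 0L) stop("no polygons supplied")
  for (i in seq_len(J)) {
    p <- polygons[[i]]
    ok <- is.matrix(p) && ncol(p) == 2L && nrow(p) >= 4L &&
      all(is.finite(p)) && all(p[1L, ] == p[nrow(p), ])
    if (!ok) stop(sprintf("invalid geometry: polygon %d is not a closed finite ring", i))
  }
  # vertex -> polygons incidence using exact coordinate keys
  vert <- new.env(parent = emptyenv())
  for (i in seq_len(J)) {
    p <- polygons[[i]]
    keys <- unique(paste(p[-nrow(p), 1L], p[-nrow(p), 2L], sep = "|"))
    for (k in keys) {
      assign(k, c(vert[[k]], i), envir = vert)
    }
  }
  neighbors <- vector("list", J)
  for (k in ls(vert)) {
    ids <- unique(vert[[k]])
    if (length(ids) < 2L) next
    for (i in ids) neighbors[[i]] <- c(neighbors[[i]], setdiff(ids, i))
  }
  neighbors <- lapply(neighbors, function(x) sort(unique(x)))
  adjacency(neighbors)
}

#' Write / read a neighbor list in GAL-style text format
#'
#' Plain-text exchange format: a header line with the number of areas, then
#' for each area a line `id count` followed by a line of neighbor ids.
#'
#' @param adj an [adjacency] object.
#' @param file path to write to / read from.
#' @return `write_gal` returns `file` invisibly; `read_gal` an [adjacency].
#' @export
write_gal <- function(adj, file) {
  stopifnot(inherits(adj, "adjacency"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(as.character(adj$n_areas), con)
  for (i in seq_len(adj$n_areas)) {
    writeLines(paste(i, adj$counts[i]), con)
    writeLines(paste(adj$neighbors[[i]], collapse = " "), con)
  }
  invisible(file)
}

#' @rdname write_gal
#' @export
read_gal <- function(file) {
  lines <- readLines(file)
  J <- as.integer(lines[[1L]])
  neighbors <- vector("list", J)
  pos <- 2L
  for (i in seq_len(J)) {
    hd <- as.integer(strsplit(trimws(lines[[pos]]), "\\s+")[[1L]])
    if (hd[1L] != i) stop("GAL file areas out of order")
    nb <- if (hd[2L] > 0L) {
      as.integer(strsplit(trimws(lines[[pos + 1L]]), "\\s+")[[1L]])
    } else {
      integer(0)
    }
    if (length(nb) != hd[2L]) stop(sprintf("GAL neighbor count mismatch at area %d", i))
    neighbors[[i]] <- nb
    pos <- pos + 2L
  }
  adjacency(neighbors)
}

#' Write a neighbor list as JSON
#'
#' @inheritParams write_gal
#' @export
write_neighbors_json <- function(adj, file) {
  stopifnot(inherits(adj, "adjacency"))
  jsonlite::write_json(
    list(n_areas = adj$n_areas, neighbors = adj$neighbors),
    file,
    auto_unbox = TRUE
  )
  invisible(file)
}
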