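#' Construct a surface mesh
#'
#' Builds the common "surface" all vertex maps live on: either a regular
#' 2-D grid (the default working surface; topology plus millimetre
#' distances are all the downstream analyses need) or a geodesic icosphere
#' obtained by repeated triangle subdivision of an icosahedron.
#'
#' @param kind `"grid"` or `"icosphere"`.
#' @param size_param For `"grid"`, the number of vertices per side (the
#'   mesh has `size_param^2` vertices). For `"icosphere"`, the subdivision
#'   level `k` (the mesh has `10 * 4^k + 2` vertices).
#' @param spacing Grid spacing in mm (grid meshes only).
#' @param radius Sphere radius in mm (icosphere meshes only).
#'
#' @return An object of class `votc_mesh`: a list with `kind`,
#'   `n_vertices`, `coords` (n x 2 or n x 3 matrix, mm), `edges`
#'   (two-column integer matrix of undirected neighbor pairs), and
#'   `spacing`.
#'
#' @examples
#' m <- make_mesh("grid", 8)
#' m$n_vertices  # 64
#' @export
make_mesh <- function(kind = c("grid", "icosphere"), size_param,
                      spacing = 1, radius = 50) {
  kind <- match.arg(kind)
  if (!is.numeric(size_param) || length(size_param) != 1L ||
      size_param < 2 || size_param != round(size_param)) {
    stop("`size_param` must be a single integer >= 2", call. = FALSE)
  }
  size_param <- as.integer(size_param)
  if (kind == "grid") {
    mesh_grid(size_param, spacing)
  } else {
    mesh_icosphere(size_param, radius)
  }
}

# Column-major grid: vertex v has col = (v-1) %/% s + 1, row = (v-1) %% s + 1,
# coords x = (col-1)*spacing, y = (row-1)*spacing. A +x shift of one spacing
# therefore moves a value by exactly s indices.
mesh_grid <- function(s, spacing) {
  n <- s * s
  col <- rep(seq_len(s), each = s)
  row <- rep(seq_len(s), times = s)
  coords <- cbind(x = (col - 1) * spacing, y = (row - 1) * spacing)
  v <- seq_len(n)
  vert <- cbind(v[row < s], v[row < s] + 1L)          # within-column neighbors
  horiz <- cbind(v[col < s], v[col < s] + s)          # across-column neighbors
  structure(
    list(kind = "grid", n_vertices = n, side = s, coords = coords,
         edges = rbind(vert, horiz), spacing = spacing),
    class = "votc_mesh"
  )
}

mesh_icosphere <- function(level, radius) {
  phi <- (1 + sqrt(5)) / 2
  verts <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  verts <- verts / sqrt(rowSums(verts^2))
  faces <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (i in seq_len(level)) {
    res <- subdivide_once(verts, faces)
    verts <- res$verts
    faces <- res$faces
  }
  edges <- unique(t(apply(
    rbind(faces[, 1:2], faces[, 2:3], faces[, c(1, 3)]), 1L, sort
  )))
  structure(
    list(kind = "icosphere", n_vertices = nrow(verts),
         coords = verts * radius, edges = edges,
         spacing = radius * mean(sqrt(rowSums(
           (verts[edges[, 1], , drop = FALSE] -
              verts[edges[, 2], , drop = FALSE])^2)))),
    class = "votc_mesh"
  )
}

# One midpoint-subdivision pass: each triangle becomes 4, new vertices are
# edge midpoints projected back to the unit sphere.
subdivide_once <- function(verts, faces) {
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  mid_env <- new.env(parent = emptyenv())
  n <- nrow(verts)
  new_verts <- list()
  midpoint <- function(a, b) {
    k <- key(a, b)
    if (!is.null(mid_env[[k]])) return(mid_env[[k]])
    p <- (verts[a, ] + verts[b, ]) / 2
    p <- p / sqrt(sum(p^2))
    n <<- n + 1L
    new_verts[[length(new_verts) + 1L]] <<- p
    mid_env[[k]] <- n
    n
  }
  out <- matrix(0L, nrow = 4L * nrow(faces), ncol = 3L)
  r <- 0L
  for (f in seq_len(nrow(faces))) {
    a <- faces[f, 1]; b <- faces[f, 2]; c <- faces[f, 3]
    ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
    out[r + 1L, ] <- c(a, ab, ca)
    out[r + 2L, ] <- c(b, bc, ab)
    out[r + 3L, ] <- c(c, ca, bc)
    out[r + 4L, ] <- c(ab, bc, ca)
    r <- r + 4L
  }
  list(verts = rbind(verts, do.call(rbind, new_verts)), faces = out)
}

#' @export
print.votc_mesh <- function(x, ...) {
  cat(sprintf("<votc_mesh: %s, %d vertices, %d edges, spacing %.3g mm>\n",
              x$kind, x$n_vertices, nrow(x$edges), x$spacing))
  invisible(x)
}

#' Euclidean distance from every mesh vertex to a point
#'
#' @param mesh A `votc_mesh`.
#' @param point Numeric coordinates (length = mesh dimensionality), mm.
#' @return Numeric vector of length `n_vertices`.
#' @export
vertex_distances <- function(mesh, point) {
  stopifnot(inherits(mesh, "votc_mesh"), length(point) == ncol(mesh$coords))
  sqrt(colSums((t(mesh$coords) - point)^2))
}

#' Nearest mesh vertex to a point
#'
#' For grid meshes this is index arithmetic (with `NA` returned for points
#' outside the grid when `clamp = FALSE`); for other meshes a linear scan.
#'
#' @param mesh A `votc_mesh`.
#' @param point Numeric coordinates, mm.
#' @param clamp If `TRUE`, points outside a grid are clamped to its
#'   boundary instead of returning `NA`.
#' @return Integer vertex index (or `NA_integer_`).
#' @export
nearest_vertex <- function(mesh, point, clamp = TRUE) {
  if (mesh$kind == "grid") {
    s <- mesh$side
    ij <- round(point / mesh$spacing) + 1
    if (!clamp && (any(ij < 1) || any(ij > s))) return(NA_integer_)
    ij <- pmin(pmax(ij, 1), s)
    as.integer((ij[1] - 1) * s + ij[2])
  } else {
    which.min(vertex_distances(mesh, point))
  }
}

# Per-vertex tessellation area: grid cells are spacing^2; icosphere vertices
# get an equal share of the sphere surface (a barycentric-area surrogate
# adequate for size summaries).
vertex_area <- function(mesh) {
  if (mesh$kind == "grid") {
    rep(mesh$spacing^2, mesh$n_vertices)
  } else {
    r <- sqrt(sum(mesh$coords[1, ]^2))
    rep(4 * pi * r^2 / mesh$n_vertices, mesh$n_vertices)
  }
}

# Connected components of a vertex subset, via igraph on the induced subgraph.
# Returns a list of integer vectors (each one component, original indices).
vertex_components <- function(mesh, vertices) {
  vertices <- sort(unique(as.integer(vertices)))
  if (length(vertices) == 0L) return(list())
  keep <- mesh$edges[, 1] %in% vertices & mesh$edges[, 2] %in% vertices
  idx <- match(mesh$edges[keep, , drop = FALSE], vertices)
  g <- igraph::graph_from_edgelist(
    matrix(idx, ncol = 2L), directed = FALSE
  )
  g <- igraph::add_vertices(g, max(0L, length(vertices) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  unname(split(vertices, comp))
}
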