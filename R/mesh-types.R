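#' Construct a triangulated surface mesh
#'
#' A light container for a triangle soup after vertex merging: a matrix of
#' 3D vertex coordinates (mm) and an integer matrix of vertex index triples.
#'
#' @param vertices numeric matrix, n x 3, vertex coordinates in mm.
#' @param triangles integer matrix, m x 3, 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @examples
#' tri <- surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
#'                     rbind(c(1L, 2L, 3L)))
#' surface_area(tri)
#' @export
surface_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  triangles <- as.matrix(triangles)
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix")
  if (ncol(triangles) != 3L) stop("triangles must be an m x 3 matrix")
  if (nrow(triangles) > 0L &&
      (min(triangles) < 1L || max(triangles) > nrow(vertices)))
    stop("triangle indices out of range [1, ", nrow(vertices), "]")
  structure(list(vertices = vertices, triangles = triangles),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("<surface_mesh> ", nrow(x$vertices), " vertices, ",
      nrow(x$triangles), " triangles, area ",
      format(surface_area(x), digits = 6), " mm^2\n", sep = "")
  invisible(x)
}

#' Construct a four-node tetrahedral mesh with named node sets
#'
#' Elements with negative signed volume are repaired by swapping their last
#' two node indices so every tetrahedron ends up positively oriented; a
#' zero-volume element is an error.
#'
#' @param nodes numeric matrix, n x 3, node coordinates in mm.
#' @param tets integer matrix, m x 4, 1-based node indices per tetrahedron.
#' @param node_sets named list of integer vectors of node indices (e.g.
#'   `bite`, `joint`, muscle insertion patches).
#' @param fix_orientation logical; repair negatively oriented elements
#'   (default `TRUE`).
#' @return An object of class `tet_mesh`.
#' @export
tet_mesh <- function(nodes, tets, node_sets = list(), fix_orientation = TRUE) {
  nodes <- as.matrix(nodes)
  storage.mode(nodes) <- "double"
  dimnames(nodes) <- NULL
  tets <- as.matrix(tets)
  storage.mode(tets) <- "integer"
  dimnames(tets) <- NULL
  if (ncol(nodes) != 3L) stop("nodes must be an n x 3 matrix")
  if (ncol(tets) != 4L) stop("tets must be an m x 4 matrix")
  if (nrow(tets) == 0L) stop("mesh has no elements")
  if (min(tets) < 1L || max(tets) > nrow(nodes))
    stop("tet node indices out of range [1, ", nrow(nodes), "]")
  v <- tet_signed_volumes(nodes, tets)
  if (fix_orientation && any(v < 0)) {
    neg <- which(v < 0)
    tets[neg, c(3L, 4L)] <- tets[neg, c(4L, 3L)]
    v <- abs(v)
  }
  if (any(v <= 0))
    stop("zero-volume tetrahedra at element(s): ",
         paste(utils::head(which(v <= 0), 10L), collapse = ", "))
  if (length(node_sets)) {
    if (is.null(names(node_sets)) || any(!nzchar(names(node_sets))))
      stop("node_sets must be a named list")
    for (nm in names(node_sets)) {
      ids <- as.integer(node_sets[[nm]])
      if (any(ids < 1L | ids > nrow(nodes)))
        stop("node set '", nm, "' references invalid nodes")
      node_sets[[nm]] <- ids
    }
  }
  structure(list(nodes = nodes, tets = tets, node_sets = node_sets),
            class = "tet_mesh")
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat("<tet_mesh> ", nrow(x$nodes), " nodes, ", nrow(x$tets), " tets",
      sep = "")
  if (length(x$node_sets))
    cat(", sets: ", paste0(names(x$node_sets), "[",
                           lengths(x$node_sets), "]", collapse = ", "),
        sep = "")
  cat("\n")
  invisible(x)
}

## signed volumes det([b-a, c-a, d-a]) / 6, vectorized over elements
tet_signed_volumes <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - a
  e2 <- nodes[tets[, 3L], , drop = FALSE] - a
  e3 <- nodes[tets[, 4L], , drop = FALSE] - a
  (e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
   e2[, 1L] * (e1[, 2L] * e3[, 3L] - e1[, 3L] * e3[, 2L]) +
   e3[, 1L] * (e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L])) / 6
}

#' Per-element volumes and geometric totals of a tetrahedral mesh
#'
#' @param mesh a `tet_mesh`.
#' @return A `mesh_summary`: `surface_area` (mm^2, of the extracted boundary),
#'   `total_volume` (mm^3), `element_volumes` (mm^3 per tet) and
#'   `element_count`.
#' @export
element_volumes <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  v <- tet_signed_volumes(mesh$nodes, mesh$tets)
  if (any(v <= 0))
    stop("non-positive volume at element(s): ",
         paste(utils::head(which(v <= 0), 10L), collapse = ", "),
         " (orientation not fixed?)")
  bt <- boundary_triangles(mesh)
  structure(list(surface_area = triangle_area_sum(mesh$nodes, bt),
                 total_volume = sum(v),
                 element_volumes = v,
                 element_count = nrow(mesh$tets)),
            class = "mesh_summary")
}

#' @export
print.mesh_summary <- function(x, ...) {
  cat("<mesh_summary> ", x$element_count, " tets, volume ",
      format(x$total_volume, digits = 6), " mm^3, boundary area ",
      format(x$surface_area, digits = 6), " mm^2\n", sep = "")
  invisible(x)
}

#' Extract the boundary triangles of a tetrahedral mesh
#'
#' Faces shared by exactly one tetrahedron form the boundary; for a
#' watertight volume mesh this surface is closed.
#'
#' @param mesh a `tet_mesh`.
#' @return Integer matrix, k x 3, of node index triples.
#' @export
boundary_triangles <- function(mesh) {
  stopifnot(inherits(mesh, "tet_mesh"))
  tt <- mesh$tets
  ## four faces per tet, outward orientation for positive tets
  faces <- rbind(tt[, c(1L, 3L, 2L), drop = FALSE],
                 tt[, c(1L, 2L, 4L), drop = FALSE],
                 tt[, c(2L, 3L, 4L), drop = FALSE],
                 tt[, c(1L, 4L, 3L), drop = FALSE])
  key <- apply(faces, 1L, function(f) paste(sort(f), collapse = "-"))
  faces[key %in% names(which(table(key) == 1L)), , drop = FALSE]
}

triangle_area_sum <- function(vertices, triangles) {
  if (nrow(triangles) == 0L) return(0)
  a <- vertices[triangles[, 1L], , drop = FALSE]
  u <- vertices[triangles[, 2L], , drop = FALSE] - a
  v <- vertices[triangles[, 3L], , drop = FALSE] - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  sum(0.5 * sqrt(cx^2 + cy^2 + cz^2))
}

#' Total surface area of a mesh
#'
#' Sum of triangle areas (half cross-product magnitude per triangle);
#' degenerate triangles contribute zero. For a `tet_mesh` the area of the
#' extracted boundary surface is returned.
#'
#' @param mesh a `surface_mesh` or `tet_mesh`.
#' @return Area in mm^2.
#' @export
surface_area <- function(mesh) {
  if (inherits(mesh, "surface_mesh"))
    return(triangle_area_sum(mesh$vertices, mesh$triangles))
  if (inherits(mesh, "tet_mesh"))
    return(triangle_area_sum(mesh$nodes, boundary_triangles(mesh)))
  stop("surface_area: unsupported object of class ",
       paste(class(mesh), collapse = "/"))
}
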