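#' Read an STL surface mesh (ASCII or binary)
#'
#' The format is auto-detected. Duplicate vertices (STL stores one copy per
#' facet) are merged within `tolerance`.
#'
#' @param path path to an `.stl` file.
#' @param tolerance vertex merge tolerance in mm (default 1e-6).
#' @return A [surface_mesh()].
#' @export
read_stl <- function(path, tolerance = 1e-6) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (stl_is_ascii(path)) {
    verts <- read_stl_ascii(path)
  } else {
    verts <- read_stl_binary(path)
  }
  merge_vertices(verts, tolerance)
}

## an STL is ASCII when it starts with "solid" AND contains facet keywords
## near the top; binary files may also start with "solid" in the header.
stl_is_ascii <- function(path) {
  head_raw <- readBin(path, "raw", n = 512L)
  ## keep printable ASCII only: binary STL headers/floats are arbitrary bytes
  printable <- head_raw >= as.raw(32L) & head_raw <= as.raw(126L) |
    head_raw == as.raw(10L) | head_raw == as.raw(13L)
  head_txt <- rawToChar(head_raw[printable])
  startsWith(trimws(head_txt), "solid") &&
    grepl("facet", head_txt, fixed = TRUE)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) == 0L || length(vlines) %% 3L != 0L)
    stop("malformed ASCII STL '", path, "': found ", length(vlines),
         " vertex lines (expected a positive multiple of 3)")
  nums <- lapply(strsplit(trimws(vlines), "\\s+"), function(x) {
    v <- suppressWarnings(as.numeric(x[-1L]))
    if (length(v) != 3L || anyNA(v))
      stop("malformed ASCII STL vertex line: ", paste(x, collapse = " "))
    v
  })
  do.call(rbind, nums)
}

read_stl_binary <- function(path) {
  sz <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", n = 80L)                    # header
  ntri <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  expected <- 84 + 50 * as.numeric(ntri)
  if (is.na(ntri) || ntri < 0L || sz < expected)
    stop("malformed binary STL '", path, "': header at byte 80 declares ",
         ntri, " facets (needs ", expected, " bytes, file has ", sz, ")")
  verts <- matrix(0, 3L * ntri, 3L)
  for (t in seq_len(ntri)) {
    rec <- readBin(con, "numeric", n = 12L, size = 4L, endian = "little")
    if (length(rec) < 12L)
      stop("malformed binary STL '", path, "': truncated facet ", t,
           " at byte ", 84 + 50 * (t - 1))
    verts[3L * t - 2L:0, ] <- matrix(rec[4:12], 3L, 3L, byrow = TRUE)
    readBin(con, "raw", n = 2L)                   # attribute byte count
  }
  verts
}

## merge per-facet duplicated vertices within tolerance; drops degenerate
## (zero-area) triangles produced by the merge
merge_vertices <- function(verts, tolerance) {
  ntri <- nrow(verts) / 3L
  key <- apply(round(verts / tolerance), 1L, paste, collapse = ",")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  vertices <- verts[first, , drop = FALSE]
  tris <- matrix(idx, ncol = 3L, byrow = TRUE)
  degen <- tris[, 1L] == tris[, 2L] | tris[, 2L] == tris[, 3L] |
    tris[, 1L] == tris[, 3L]
  surface_mesh(vertices, tris[!degen, , drop = FALSE])
}

#' Write a surface mesh as ASCII STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  tr <- mesh$triangles
  a <- v[tr[, 1L], , drop = FALSE]
  u <- v[tr[, 2L], , drop = FALSE] - a
  w <- v[tr[, 3L], , drop = FALSE] - a
  n <- cbind(u[, 2L] * w[, 3L] - u[, 3L] * w[, 2L],
             u[, 3L] * w[, 1L] - u[, 1L] * w[, 3L],
             u[, 1L] * w[, 2L] - u[, 2L] * w[, 1L])
  len <- sqrt(rowSums(n^2))
  n <- n / ifelse(len > 0, len, 1)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("solid skullfea", con)
  for (t in seq_len(nrow(tr))) {
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g",
                         n[t, 1L], n[t, 2L], n[t, 3L]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g",
                         v[tr[t, ], 1L], v[tr[t, ], 2L], v[tr[t, ], 3L]),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines("endsolid skullfea", con)
  invisible(path)
}

#' Read a tetrahedral mesh from the plain-text tet-mesh format
#'
#' The format holds a `NODES n` block of `id x y z` rows, a `TETS m` block
#' of `id n1 n2 n3 n4` rows and any number of `SET name` blocks listing node
#' ids (whitespace separated, possibly over several lines). Ids are 1-based
#' in the file.
#'
#' @param path path to a tet-mesh text file.
#' @return A [tet_mesh()] with its named node sets.
#' @export
read_tet_mesh <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  i <- 1L
  expect_kw <- function(kw) {
    tok <- strsplit(lines[i], "\\s+")[[1L]]
    if (toupper(tok[1L]) != kw)
      stop("tet-mesh parse error at line ", i, ": expected ", kw)
    tok
  }
  tok <- expect_kw("NODES")
  n <- as.integer(tok[2L])
  nodes <- matrix(NA_real_, n, 3L)
  for (r in seq_len(n)) {
    x <- as.numeric(strsplit(lines[i + r], "\\s+")[[1L]])
    nodes[x[1L], ] <- x[2:4]
  }
  i <- i + n + 1L
  tok <- expect_kw("TETS")
  m <- as.integer(tok[2L])
  tets <- matrix(NA_integer_, m, 4L)
  for (r in seq_len(m)) {
    x <- as.integer(strsplit(lines[i + r], "\\s+")[[1L]])
    tets[x[1L], ] <- x[2:5]
  }
  i <- i + m + 1L
  sets <- list()
  while (i <= length(lines)) {
    tok <- expect_kw("SET")
    nm <- tok[2L]
    ids <- integer(0)
    i <- i + 1L
    while (i <= length(lines) &&
           toupper(strsplit(lines[i], "\\s+")[[1L]][1L]) != "SET") {
      ids <- c(ids, as.integer(strsplit(lines[i], "\\s+")[[1L]]))
      i <- i + 1L
    }
    sets[[nm]] <- ids
  }
  tet_mesh(nodes, tets, node_sets = sets)
}

#' Write a tetrahedral mesh in the plain-text tet-mesh format
#'
#' @param mesh a [tet_mesh()].
#' @param path output path.
#' @return `path`, invisibly.
#' @seealso [read_tet_mesh()] for the format.
#' @export
write_tet_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "tet_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  n <- nrow(mesh$nodes)
  writeLines(sprintf("NODES %d", n), con)
  writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(n),
                     mesh$nodes[, 1L], mesh$nodes[, 2L], mesh$nodes[, 3L]),
             con)
  m <- nrow(mesh$tets)
  writeLines(sprintf("TETS %d", m), con)
  writeLines(sprintf("%d %d %d %d %d", seq_len(m), mesh$tets[, 1L],
                     mesh$tets[, 2L], mesh$tets[, 3L], mesh$tets[, 4L]), con)
  for (nm in names(mesh$node_sets)) {
    writeLines(sprintf("SET %s", nm), con)
    writeLines(paste(mesh$node_sets[[nm]], collapse = " "), con)
  }
  invisible(path)
}

#' Export a solved model as a legacy VTK unstructured grid
#'
#' Writes an ASCII legacy VTK file carrying the mesh, nodal displacement
#' vectors and per-element von Mises stress (MPa) and maximum principal
#' strain, for inspection in ParaView or similar viewers.
#'
#' @param mesh a [tet_mesh()].
#' @param field a `solution_field` from [solve_fe()], or `NULL` to export
#'   geometry only.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_vtk <- function(mesh, field, path) {
  stopifnot(inherits(mesh, "tet_mesh"))
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  if (!is.null(field)) {
    stopifnot(inherits(field, "solution_field"))
    if (nrow(field$displacements) != n || length(field$von_mises) != m)
      stop("field dimensions (", nrow(field$displacements), " nodes, ",
           length(field$von_mises), " cells) do not match mesh (",
           n, ", ", m, ")")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "skullfea results", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  writeLines(sprintf("%.9g %.9g %.9g", mesh$nodes[, 1L], mesh$nodes[, 2L],
                     mesh$nodes[, 3L]), con)
  writeLines(sprintf("CELLS %d %d", m, 5L * m), con)
  writeLines(sprintf("4 %d %d %d %d", mesh$tets[, 1L] - 1L,
                     mesh$tets[, 2L] - 1L, mesh$tets[, 3L] - 1L,
                     mesh$tets[, 4L] - 1L), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("10", m), con)
  if (!is.null(field)) {
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS displacement double"), con)
    writeLines(sprintf("%.9g %.9g %.9g", field$displacements[, 1L],
                       field$displacements[, 2L], field$displacements[, 3L]),
               con)
    writeLines(c(sprintf("CELL_DATA %d", m),
                 "SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", field$von_mises), con)
    writeLines(c("SCALARS max_principal_strain double 1",
                 "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", field$max_principal_strain), con)
  }
  invisible(path)
}

#' Read back a legacy VTK unstructured grid written by this package
#'
#' A minimal reader for round-trip checks and downstream tooling: returns
#' points, cells and any cell scalar arrays.
#'
#' @param path path to a legacy ASCII VTK file.
#' @return List with `points` (n x 3), `cells` (m x 4, 1-based) and
#'   `cell_data` (named list of numeric vectors).
#' @export
read_vtk_ugrid <- function(path) {
  lines <- readLines(path, warn = FALSE)
  pts_at <- grep("^POINTS ", lines)[1L]
  n <- as.integer(strsplit(lines[pts_at], "\\s+")[[1L]][2L])
  pts <- matrix(scan(text = lines[(pts_at + 1L):(pts_at + n)],
                     quiet = TRUE), ncol = 3L, byrow = TRUE)
  cel_at <- grep("^CELLS ", lines)[1L]
  m <- as.integer(strsplit(lines[cel_at], "\\s+")[[1L]][2L])
  cel <- matrix(as.integer(scan(text = lines[(cel_at + 1L):(cel_at + m)],
                                quiet = TRUE)), ncol = 5L, byrow = TRUE)
  cells <- cel[, 2:5, drop = FALSE] + 1L
  cell_data <- list()
  for (at in grep("^SCALARS ", lines)) {
    nm <- strsplit(lines[at], "\\s+")[[1L]][2L]
    cell_data[[nm]] <- scan(text = lines[(at + 2L):(at + 1L + m)],
                            quiet = TRUE)
  }
  list(points = pts, cells = cells, cell_data = cell_data)
}
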