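# Fixtures are built in code: unit shapes, an icosphere, STL writers and
# a box proxy wrapper around the parametric generator.

# unit right tetrahedron (volume 1/6)
unit_tet_coords <- function() {
  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
}

# unit cube split into 6 tets (Freudenthal split, positive volumes)
unit_cube_tets <- function() {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
                 c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  splits <- rbind(c(1, 2, 3, 7), c(1, 3, 4, 7), c(1, 4, 8, 7),
                  c(1, 8, 5, 7), c(1, 5, 6, 7), c(1, 6, 2, 7))
  tet_mesh(nodes, splits)
}

# the 12 facets of the unit cube as a surface_mesh (24 outward triangles
# would be 12; vertices duplicated per facet as STL would store them)
unit_cube_surface <- function() {
  m <- unit_cube_tets()
  bt <- boundary_triangles(m)
  surface_mesh(m$nodes, bt)
}

# icosphere: icosahedron refined by midpoint subdivision, projected to the
# unit sphere
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    env <- new.env()
    nv <- nrow(v)
    mid <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(env[[key]])) return(env[[key]])
      p <- v[a, ] + v[b, ]
      p <- p / sqrt(sum(p^2))
      v <<- rbind(v, p)
      env[[key]] <- nrow(v)
      nrow(v)
    }
    f <- do.call(rbind, lapply(seq_len(nrow(f)), function(t) {
      a <- f[t, 1]; b <- f[t, 2]; c_ <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c_); ca <- mid(c_, a)
      rbind(c(a, ab, ca), c(b, bc, ab), c(c_, ca, bc), c(ab, bc, ca))
    }))
  }
  surface_mesh(v, f)
}

# write a surface_mesh as binary STL (little-endian, 50-byte records)
write_stl_binary <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(rep(0L, 80L)), con)
  tr <- mesh$triangles
  writeBin(as.integer(nrow(tr)), con, size = 4L, endian = "little")
  for (t in seq_len(nrow(tr))) {
    writeBin(c(0, 0, 0, t(mesh$vertices[tr[t, ], ])), con, size = 4L,
             endian = "little")
    writeBin(as.raw(c(0L, 0L)), con)
  }
  invisible(path)
}

# rectangular box proxy (taper 1 collapses the wedge to a prism)
box_proxy <- function(L, W, H, nx, ny, nz, preset = "cranium") {
  generate_proxy(proxy_params(preset, length = L, posterior_width = W,
                              posterior_depth = H, anterior_taper = 1,
                              resolution = nx,
                              cross_resolution = c(ny, nz)))
}

# shift a box proxy so the section is [0,W]x[0,H]? not needed: boxes are
# centered on the x-axis; selectors below work in centered coordinates.

# nodes of a box-proxy mesh on the plane x = x0
plane_nodes <- function(mesh, axis, value, tol = 1e-9) {
  which(abs(mesh$nodes[, axis] - value) < tol)
}

# 3D rotation matrix from an axis (unit) and angle
rotation_matrix <- function(axis, theta) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * K %*% K
}

# uniaxial patch test case on a box proxy: traction on the x = L face,
# minimal compatible constraints on the x = 0 face
patch_case <- function(L = 10, W = 2, H = 2, nx = 5, ny = 2, nz = 2,
                       force = 100) {
  model <- box_proxy(L, W, H, nx, ny, nz)
  mesh <- model$mesh
  endn <- plane_nodes(mesh, 1, L)
  loads <- traction_loads(mesh, endn, c(force / (W * H), 0, 0))
  backn <- plane_nodes(mesh, 1, 0)
  cons <- data.frame(node = backn, dir = 1L)
  # one node pinned in y and z, one more in z: removes the remaining
  # rigid-body modes without constraining Poisson contraction
  corner1 <- backn[which.min(mesh$nodes[backn, 2] + mesh$nodes[backn, 3])]
  corner2 <- backn[which.max(mesh$nodes[backn, 2] - mesh$nodes[backn, 3])]
  cons <- rbind(cons,
                data.frame(node = corner1, dir = c(2L, 3L)),
                data.frame(node = corner2, dir = 3L))
  list(model = model,
       loads = load_case(cons, bite_loads = loads),
       sigma = force / (W * H))
}

# cantilever bending case on a box proxy: clamped at x = 0, transverse
# tip load at x = L; returns the FE tip deflection and the Timoshenko
# closed form P L^3 / (3 E I) + P L / (kappa G A)
cantilever_deflection <- function(nx, ny, nz, L = 40, W = 4, H = 4,
                                  P = 100, material = material_properties()) {
  model <- box_proxy(L, W, H, nx, ny, nz)
  mesh <- model$mesh
  backn <- plane_nodes(mesh, 1, 0)
  cons <- data.frame(node = rep(backn, each = 3), dir = rep(1:3, length(backn)))
  tipn <- plane_nodes(mesh, 1, L)
  loads <- load_case(cons,
                     bite_loads = distribute_over_nodes(c(0, 0, P), tipn))
  field <- solve_fe(mesh, material, loads)
  E <- material$youngs_modulus
  nu <- material$poisson_ratio
  G <- E / (2 * (1 + nu))
  I <- W * H^3 / 12
  kap <- 10 * (1 + nu) / (12 + 11 * nu)
  list(w = mean(field$displacements[tipn, 3]),
       w_ref = P * L^3 / (3 * E * I) + P * L / (kap * G * W * H))
}

# muscle-only load case for a proxy model (no bite load)
muscle_only_case <- function(model, policy = scaling_policy("actual_size"))
  build_load_case(model, muscles = muscle_spec(model$adductor_area),
                  bite = bite_config("load", 0), policy = policy)

# printed worked examples of the muscle sensitivity tables: baseline and
# perturbed mesh-weighted mean von Mises stresses with their published
# percent differences
sensitivity_worked_examples <- function() {
  rbind(
    data.frame(part = "cranium", taxon = "raptorex",
               base = 7.111209, up = 7.729046, down = 7.748312,
               pct_up = 8.3265, pct_down = 8.57501),
    data.frame(part = "cranium", taxon = "albertosaurus",
               base = 1.988823, up = 1.905102, down = 2.183277,
               pct_up = 4.30008, pct_down = 9.32164),
    data.frame(part = "cranium", taxon = "tyrannosaurus",
               base = 9.201477, up = 9.790244, down = 9.110124,
               pct_up = 6.20025, pct_down = 0.997761),
    data.frame(part = "mandible", taxon = "raptorex",
               base = 9.720271, up = 9.920344, down = 9.901121,
               pct_up = 2.03734, pct_down = 1.8434),
    data.frame(part = "mandible", taxon = "albertosaurus",
               base = 14.21646, up = 17.31926, down = 17.92455,
               pct_up = 19.678, pct_down = 23.0739),
    data.frame(part = "mandible", taxon = "tyrannosaurus",
               base = 11.9148, up = 12.3112, down = 13.2155,
               pct_up = 3.27252, pct_down = 10.3516))
}
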