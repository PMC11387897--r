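#' Isotropic linear-elastic material properties
#'
#' Defaults are cortical bone values measured on sub-adult *Alligator
#' mississippiensis* skull bone, the standard stand-in for archosaur cranial
#' bone: Young's modulus 15,000 MPa and Poisson's ratio 0.29. Units follow
#' the N-mm-MPa system used throughout the package.
#'
#' @param youngs_modulus Young's modulus E in MPa (> 0).
#' @param poisson_ratio Poisson's ratio (in (-1, 0.5)).
#' @return An object of class `material_properties`.
#' @export
material_properties <- function(youngs_modulus = 15000,
                                poisson_ratio = 0.29) {
  if (!is.numeric(youngs_modulus) || youngs_modulus <= 0)
    stop("youngs_modulus must be > 0")
  if (poisson_ratio <= -1 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (-1, 0.5)")
  structure(list(youngs_modulus = youngs_modulus,
                 poisson_ratio = poisson_ratio),
            class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat("<material_properties> E =", x$youngs_modulus, "MPa, nu =",
      x$poisson_ratio, "\n")
  invisible(x)
}

## 6x6 isotropic elasticity matrix, Voigt order (xx,yy,zz,xy,yz,zx),
## engineering shear strains
elastic_matrix <- function(material) {
  E <- material$youngs_modulus
  nu <- material$poisson_ratio
  la <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(0, 3), rep(mu, 3)))
  D[1:3, 1:3] <- la
  diag(D)[1:3] <- la + 2 * mu
  D
}

## shape-function gradients and volume of one tet: 4 x 3 gradient matrix
tet_gradients <- function(coords) {
  M <- cbind(coords[2L, ] - coords[1L, ],
             coords[3L, ] - coords[1L, ],
             coords[4L, ] - coords[1L, ])
  V <- det(M) / 6
  if (V <= 0) stop("degenerate or negatively oriented tetrahedron (V = ",
                   format(V), ")")
  Minv <- solve(M)
  g <- rbind(-colSums(Minv), Minv)
  list(V = V, g = g)
}

## 6 x 12 constant strain-displacement matrix from 4 x 3 gradients
strain_matrix <- function(g) {
  B <- matrix(0, 6L, 12L)
  for (i in 1:4) {
    c0 <- 3L * (i - 1L)
    gx <- g[i, 1L]; gy <- g[i, 2L]; gz <- g[i, 3L]
    B[1L, c0 + 1L] <- gx
    B[2L, c0 + 2L] <- gy
    B[3L, c0 + 3L] <- gz
    B[4L, c0 + 1L] <- gy; B[4L, c0 + 2L] <- gx
    B[5L, c0 + 2L] <- gz; B[5L, c0 + 3L] <- gy
    B[6L, c0 + 1L] <- gz; B[6L, c0 + 3L] <- gx
  }
  B
}

#' Element stiffness matrix of a constant-strain tetrahedron
#'
#' Computes `K_e = V_e * t(B) %*% D %*% B` with the constant
#' strain-displacement matrix B of the four-node tetrahedron and the
#' isotropic elasticity matrix D. The 12 x 12 result is symmetric positive
#' semidefinite with exactly six zero eigenvalues (the rigid-body modes).
#'
#' @param coords numeric 4 x 3 matrix of node coordinates (mm).
#' @param material a [material_properties()].
#' @return 12 x 12 stiffness matrix (N/mm); DOFs ordered
#'   (x1,y1,z1,...,x4,y4,z4).
#' @export
element_stiffness <- function(coords, material) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == 4L, ncol(coords) == 3L)
  ge <- tet_gradients(coords)
  B <- strain_matrix(ge$g)
  ge$V * crossprod(B, elastic_matrix(material) %*% B)
}

## vectorized per-element geometry: volumes and shape gradients for all tets
## g is an ne x 4 x 3 array
mesh_tet_geometry <- function(nodes, tets) {
  a <- nodes[tets[, 1L], , drop = FALSE]
  e1 <- nodes[tets[, 2L], , drop = FALSE] - a
  e2 <- nodes[tets[, 3L], , drop = FALSE] - a
  e3 <- nodes[tets[, 4L], , drop = FALSE] - a
  detM <- e1[, 1L] * (e2[, 2L] * e3[, 3L] - e2[, 3L] * e3[, 2L]) -
    e2[, 1L] * (e1[, 2L] * e3[, 3L] - e1[, 3L] * e3[, 2L]) +
    e3[, 1L] * (e1[, 2L] * e2[, 3L] - e1[, 3L] * e2[, 2L])
  if (any(detM <= 0))
    stop("degenerate or negatively oriented tetrahedra at element(s): ",
         paste(utils::head(which(detM <= 0), 10L), collapse = ", "))
  cross_rows <- function(u, v)
    cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
          u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
          u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
  r1 <- cross_rows(e2, e3) / detM
  r2 <- cross_rows(e3, e1) / detM
  r3 <- cross_rows(e1, e2) / detM
  g <- array(0, c(nrow(tets), 4L, 3L))
  g[, 2L, ] <- r1
  g[, 3L, ] <- r2
  g[, 4L, ] <- r3
  g[, 1L, ] <- -(r1 + r2 + r3)
  list(V = detM / 6, g = g)
}

## global sparse stiffness via the closed-form isotropic CST node blocks
##   K_ij[a,b] = V (la g_i[a] g_j[b] + mu g_i[b] g_j[a] + mu (g_i.g_j) d_ab)
## (equals element_stiffness assembled per element; asserted in tests)
assemble_stiffness <- function(nodes, tets, material) {
  E <- material$youngs_modulus
  nu <- material$poisson_ratio
  la <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  ge <- mesh_tet_geometry(nodes, tets)
  V <- ge$V
  g <- ge$g
  ne <- nrow(tets)
  dot <- array(0, c(ne, 4L, 4L))
  for (i in 1:4) for (j in 1:4)
    dot[, i, j] <- rowSums(g[, i, ] * g[, j, ])
  ii <- jj <- integer(144L * ne)
  xx <- numeric(144L * ne)
  p <- 0L
  for (i in 1:4) for (j in 1:4) for (a in 1:3) for (b in 1:3) {
    idx <- p * ne + seq_len(ne)
    ii[idx] <- 3L * (tets[, i] - 1L) + a
    jj[idx] <- 3L * (tets[, j] - 1L) + b
    xx[idx] <- V * (la * g[, i, a] * g[, j, b] +
                    mu * g[, i, b] * g[, j, a] +
                    (a == b) * mu * dot[, i, j])
    p <- p + 1L
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = rep(3L * nrow(nodes), 2L))
}

#' Assemble and solve the linear elastostatic system
#'
#' Solves `K u = f` on a four-node tetrahedral mesh under a static load
#' case: Dirichlet constraints are applied by row/column elimination (the
#' reduced system), so constrained displacements are exactly zero, and
#' reactions are recovered as `K u - f` on the eliminated rows. Per-element
#' constant strain and stress are recovered from the displacement field,
#' along with von Mises stress and the maximum principal strain.
#'
#' @param mesh a [tet_mesh()].
#' @param material a [material_properties()].
#' @param loads a [load_case()].
#' @param method `"direct"` (sparse Cholesky), `"cg"` (Jacobi-preconditioned
#'   conjugate gradients) or `"auto"` (direct below `cg_threshold` DOFs).
#' @param cg_threshold DOF count above which `"auto"` switches to CG.
#' @param cg_tol relative residual tolerance for CG.
#' @return A `solution_field` with `displacements` (n x 3, mm),
#'   `element_strain` and `element_stress` (ne x 6, Voigt order
#'   xx,yy,zz,xy,yz,zx; engineering shear strains; MPa stresses),
#'   `von_mises` (MPa), `max_principal_strain`, `reactions` (data frame of
#'   constrained nodes, N) and `element_volumes` (mm^3).
#' @export
solve_fe <- function(mesh, material, loads, method = c("auto", "direct", "cg"),
                     cg_threshold = 200000L, cg_tol = 1e-10) {
  stopifnot(inherits(mesh, "tet_mesh"),
            inherits(material, "material_properties"),
            inherits(loads, "load_case"))
  method <- match.arg(method)
  n <- nrow(mesh$nodes)
  ndof <- 3L * n
  cons <- load_case_constraints(loads)
  if (nrow(cons) == 0L)
    stop("no constraints: the system retains all six rigid-body modes")
  fixed <- sort(unique(3L * (cons$node - 1L) + cons$dir))
  if (length(fixed) < 6L)
    stop("insufficient constraints (", length(fixed),
         " constrained DOFs < 6): rigid-body modes remain")
  f <- load_vector(loads, n)
  K <- assemble_stiffness(mesh$nodes, mesh$tets, material)
  free <- setdiff(seq_len(ndof), fixed)
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  if (method == "auto")
    method <- if (length(free) > cg_threshold) "cg" else "direct"
  uf <- if (method == "direct") {
    ch <- tryCatch(Matrix::Cholesky(Kff, perm = TRUE),
                   error = function(e)
                     stop("stiffness matrix is singular after applying ",
                          "constraints - the constraint set leaves an ",
                          "unconstrained mode (", conditionMessage(e), ")",
                          call. = FALSE))
    as.vector(Matrix::solve(ch, f[free]))
  } else {
    cg_solve(Kff, f[free], tol = cg_tol)
  }
  u <- numeric(ndof)
  u[free] <- uf
  resid <- as.vector(K %*% u) - f
  cnodes <- sort(unique(cons$node))
  reactions <- data.frame(node = cnodes,
                          rx = resid[3L * (cnodes - 1L) + 1L],
                          ry = resid[3L * (cnodes - 1L) + 2L],
                          rz = resid[3L * (cnodes - 1L) + 3L])
  recover_field(mesh, material, u, reactions)
}

## Jacobi-preconditioned conjugate gradients on a sparse SPD system
cg_solve <- function(A, b, tol = 1e-10, maxit = 50000L) {
  d <- Matrix::diag(A)
  if (any(d <= 0)) stop("CG: non-positive diagonal, system not SPD")
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  bnorm <- sqrt(sum(b^2))
  if (bnorm == 0) return(x)
  for (it in seq_len(maxit)) {
    Ap <- as.vector(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * bnorm) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("CG did not converge in ", maxit, " iterations (relative residual ",
       format(sqrt(sum(r^2)) / bnorm, digits = 3), ")")
}

## per-element strain/stress recovery from the nodal displacement vector
recover_field <- function(mesh, material, u, reactions) {
  ge <- mesh_tet_geometry(mesh$nodes, mesh$tets)
  g <- ge$g
  tets <- mesh$tets
  ne <- nrow(tets)
  ## displacement components per element node: ne x 4 each
  ux <- matrix(u[3L * (tets - 1L) + 1L], ne, 4L)
  uy <- matrix(u[3L * (tets - 1L) + 2L], ne, 4L)
  uz <- matrix(u[3L * (tets - 1L) + 3L], ne, 4L)
  exx <- rowSums(g[, , 1L] * ux)
  eyy <- rowSums(g[, , 2L] * uy)
  ezz <- rowSums(g[, , 3L] * uz)
  gxy <- rowSums(g[, , 2L] * ux + g[, , 1L] * uy)
  gyz <- rowSums(g[, , 3L] * uy + g[, , 2L] * uz)
  gzx <- rowSums(g[, , 1L] * uz + g[, , 3L] * ux)
  strain <- cbind(xx = exx, yy = eyy, zz = ezz,
                  xy = gxy, yz = gyz, zx = gzx)
  stress <- strain %*% t(elastic_matrix(material))
  colnames(stress) <- colnames(strain)
  vm <- sqrt(0.5 * ((stress[, 1L] - stress[, 2L])^2 +
                    (stress[, 2L] - stress[, 3L])^2 +
                    (stress[, 3L] - stress[, 1L])^2) +
             3 * (stress[, 4L]^2 + stress[, 5L]^2 + stress[, 6L]^2))
  mps <- max_eig_sym_voigt(strain, shear = "engineering")
  structure(list(displacements = matrix(u, ncol = 3L, byrow = TRUE),
                 element_strain = strain,
                 element_stress = stress,
                 von_mises = vm,
                 max_principal_strain = mps,
                 reactions = reactions,
                 element_volumes = ge$V),
            class = "solution_field")
}

#' @export
print.solution_field <- function(x, ...) {
  cat("<solution_field> ", nrow(x$displacements), " nodes, ",
      length(x$von_mises), " elements\n", sep = "")
  cat("  |u|max = ", format(max(sqrt(rowSums(x$displacements^2))),
                            digits = 6),
      " mm, von Mises range [",
      format(min(x$von_mises), digits = 6), ", ",
      format(max(x$von_mises), digits = 6), "] MPa\n", sep = "")
  invisible(x)
}

## vectorized largest eigenvalue of symmetric 3x3 tensors in Voigt rows,
## via the trigonometric closed form for the characteristic cubic
max_eig_sym_voigt <- function(v, shear = c("engineering", "tensor")) {
  shear <- match.arg(shear)
  s <- if (shear == "engineering") 0.5 else 1
  a11 <- v[, 1L]; a22 <- v[, 2L]; a33 <- v[, 3L]
  a12 <- s * v[, 4L]; a23 <- s * v[, 5L]; a13 <- s * v[, 6L]
  q <- (a11 + a22 + a33) / 3
  p2 <- (a11 - q)^2 + (a22 - q)^2 + (a33 - q)^2 +
    2 * (a12^2 + a23^2 + a13^2)
  p <- sqrt(p2 / 6)
  out <- q                      # isotropic tensors: all eigenvalues = q
  nz <- p > 0
  if (any(nz)) {
    b11 <- (a11[nz] - q[nz]) / p[nz]
    b22 <- (a22[nz] - q[nz]) / p[nz]
    b33 <- (a33[nz] - q[nz]) / p[nz]
    b12 <- a12[nz] / p[nz]
    b23 <- a23[nz] / p[nz]
    b13 <- a13[nz] / p[nz]
    detB <- b11 * (b22 * b33 - b23^2) - b12 * (b12 * b33 - b23 * b13) +
      b13 * (b12 * b23 - b22 * b13)
    r <- pmin(pmax(detB / 2, -1), 1)
    phi <- acos(r) / 3
    out[nz] <- q[nz] + 2 * p[nz] * cos(phi)
  }
  out
}

#' Von Mises equivalent stress of a stress tensor
#'
#' The rotation-invariant scalar
#' `sqrt(0.5 * ((s1-s2)^2 + (s2-s3)^2 + (s3-s1)^2))` of the principal
#' stresses, used as a proxy for how close bone is to failure.
#'
#' @param stress a symmetric 3 x 3 stress tensor (MPa), or a length-6 Voigt
#'   vector (xx, yy, zz, xy, yz, zx) of stress components.
#' @return Von Mises stress in MPa (non-negative).
#' @examples
#' von_mises_from_tensor(diag(c(10, 0, 0)))  # uniaxial: 10
#' von_mises_from_tensor(diag(c(5, 5, 5)))   # hydrostatic: 0
#' @export
von_mises_from_tensor <- function(stress) {
  if (is.matrix(stress)) {
    stopifnot(nrow(stress) == 3L, ncol(stress) == 3L)
    if (max(abs(stress - t(stress))) > 1e-8 * max(1, max(abs(stress))))
      stop("stress tensor must be symmetric")
    s <- c(stress[1L, 1L], stress[2L, 2L], stress[3L, 3L],
           stress[1L, 2L], stress[2L, 3L], stress[1L, 3L])
  } else {
    stopifnot(length(stress) == 6L)
    s <- as.numeric(stress)
  }
  sqrt(0.5 * ((s[1L] - s[2L])^2 + (s[2L] - s[3L])^2 + (s[3L] - s[1L])^2) +
       3 * (s[4L]^2 + s[5L]^2 + s[6L]^2))
}

#' Principal strains of a symmetric strain tensor
#'
#' @param strain a symmetric 3 x 3 strain tensor, or a length-6 Voigt vector
#'   (xx, yy, zz, xy, yz, zx) with engineering shear strains.
#' @return Numeric vector of the three eigenvalues in descending order; the
#'   first is the maximum principal strain.
#' @export
principal_strains <- function(strain) {
  if (!is.matrix(strain)) {
    stopifnot(length(strain) == 6L)
    e <- as.numeric(strain)
    strain <- matrix(c(e[1L], e[4L] / 2, e[6L] / 2,
                       e[4L] / 2, e[2L], e[5L] / 2,
                       e[6L] / 2, e[5L] / 2, e[3L]), 3L, 3L)
  }
  stopifnot(nrow(strain) == 3L, ncol(strain) == 3L)
  sort(eigen(strain, symmetric = TRUE, only.values = TRUE)$values,
       decreasing = TRUE)
}
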