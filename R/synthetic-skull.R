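#' Parameters of a parametric skull-proxy mesh
#'
#' A skull proxy is a tapered-wedge solid: rectangular cross-sections
#' lofted along the length axis, shrinking anteriorly to `anterior_taper`
#' times the posterior section. The `cranium` preset is a deep, wide box
#' (bite points ventral, as for premaxillary teeth); the `mandible` preset
#' is shallower (bite points dorsal). `robusticity` multiplies the
#' posterior depth, moving a shape along the gracile-robust axis.
#'
#' @param preset `"cranium"` or `"mandible"`; sets defaults for the
#'   unspecified dimensions and the bite-row side.
#' @param length proxy length in mm (posterior to anterior).
#' @param posterior_width,posterior_depth posterior cross-section in mm.
#' @param anterior_taper anterior/posterior section ratio, in (0, 1].
#' @param robusticity dimensionless multiplier on posterior depth.
#' @param fenestra optional window cut through the solid along the width
#'   axis: `list(x = c(x0, x1), z = c(z0, z1))` in mm.
#' @param resolution number of element layers along the length (>= 4).
#' @param cross_resolution optional integer pair `c(ny, nz)` of element
#'   layers across width and depth; derived from the aspect ratio when
#'   `NULL`.
#' @param adductor_area adductor chamber cross-sectional area in cm^2.
#' @param jitter relative magnitude of deterministic interior-node
#'   perturbation (default 0: purely analytic geometry).
#' @param seed integer seed used only when `jitter > 0`.
#' @return An object of class `proxy_params`.
#' @export
proxy_params <- function(preset = c("cranium", "mandible"),
                         length = NULL, posterior_width = NULL,
                         posterior_depth = NULL, anterior_taper = NULL,
                         robusticity = 1, fenestra = NULL,
                         resolution = 10L, cross_resolution = NULL,
                         adductor_area = 25, jitter = 0, seed = 1L) {
  preset <- match.arg(preset)
  def <- switch(preset,
    cranium  = list(length = 300, posterior_width = 140,
                    posterior_depth = 100, anterior_taper = 0.35),
    mandible = list(length = 300, posterior_width = 110,
                    posterior_depth = 45, anterior_taper = 0.3))
  p <- list(preset = preset,
            length = length %||% def$length,
            posterior_width = posterior_width %||% def$posterior_width,
            posterior_depth = posterior_depth %||% def$posterior_depth,
            anterior_taper = anterior_taper %||% def$anterior_taper,
            robusticity = robusticity, fenestra = fenestra,
            resolution = as.integer(resolution),
            cross_resolution = cross_resolution,
            adductor_area = adductor_area, jitter = jitter,
            seed = as.integer(seed))
  if (p$length <= 0 || p$posterior_width <= 0 || p$posterior_depth <= 0)
    stop("length, posterior_width and posterior_depth must be > 0")
  if (p$anterior_taper <= 0 || p$anterior_taper > 1)
    stop("anterior_taper must lie in (0, 1]")
  if (p$robusticity <= 0) stop("robusticity must be > 0")
  if (p$resolution < 4L) stop("resolution must be >= 4")
  if (p$adductor_area <= 0) stop("adductor_area must be > 0 (cm^2)")
  structure(p, class = "proxy_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Analytic volume of the (unfenestrated) tapered-wedge solid
#'
#' `V = L * W * D * r * (1 + t + t^2) / 3` for taper ratio `t`: the loft of
#' a rectangle whose both dimensions shrink linearly to `t` times their
#' posterior values.
#'
#' @param params a [proxy_params()].
#' @return Volume in mm^3.
#' @export
proxy_analytic_volume <- function(params) {
  t <- params$anterior_taper
  params$length * params$posterior_width *
    params$posterior_depth * params$robusticity * (1 + t + t^2) / 3
}

## greedy nearest-node picks: one distinct node per anchor row
nearest_distinct_nodes <- function(nodes, anchors) {
  picked <- integer(nrow(anchors))
  for (r in seq_len(nrow(anchors))) {
    d2 <- (nodes[, 1L] - anchors[r, 1L])^2 +
          (nodes[, 2L] - anchors[r, 2L])^2 +
          (nodes[, 3L] - anchors[r, 3L])^2
    d2[picked] <- Inf
    picked[r] <- which.min(d2)
  }
  picked
}

#' Generate a labeled skull-proxy tetrahedral mesh
#'
#' Builds the tapered-wedge solid on a structured hexahedral grid, splits
#' every cell into six tetrahedra (the Freudenthal decomposition, which is
#' conforming and uniformly oriented), and labels the loading topology:
#' ten bite nodes (five per side in two anterior tooth rows), six jaw-joint
#' nodes (three per posterior lateral hinge) and posterolateral adductor
#' muscle insertion patches. Node-set selection is purely geometric
#' (nearest nodes to analytic anchor points). The result is deterministic
#' for fixed parameters.
#'
#' @param params a [proxy_params()].
#' @return A `labeled_model`: list with `mesh` (a [tet_mesh()] whose
#'   `node_sets` hold `bite`, `joint`, `adductor`, `adductor_left`,
#'   `adductor_right`), `summary` (a `mesh_summary`), `adductor_area`
#'   (cm^2), `muscle_target` (the point adductor tractions pull toward),
#'   `part` and `params`.
#' @export
generate_proxy <- function(params) {
  stopifnot(inherits(params, "proxy_params"))
  L <- params$length
  W <- params$posterior_width
  D <- params$posterior_depth * params$robusticity
  taper <- params$anterior_taper
  nx <- params$resolution
  if (!is.null(params$cross_resolution)) {
    ny <- as.integer(params$cross_resolution[1L])
    nz <- as.integer(params$cross_resolution[2L])
  } else {
    ny <- max(2L, as.integer(round(nx * W / L)))
    nz <- max(2L, as.integer(round(nx * D / L)))
  }
  shrink <- function(x) 1 - (1 - taper) * x / L

  nid <- function(i, j, k) (k * (ny + 1L) + j) * (nx + 1L) + i + 1L
  gg <- expand.grid(i = 0:nx, j = 0:ny, k = 0:nz)
  x <- gg$i / nx * L
  s <- shrink(x)
  nodes <- cbind(x, (gg$j / ny - 0.5) * W * s, (gg$k / nz - 0.5) * D * s)
  colnames(nodes) <- NULL

  if (params$jitter > 0) {
    interior <- gg$i > 0 & gg$i < nx & gg$j > 0 & gg$j < ny &
      gg$k > 0 & gg$k < nz
    h <- min(L / nx, W / ny, D / nz) * taper
    set.seed(params$seed)
    nodes[interior, ] <- nodes[interior, ] +
      matrix(stats::runif(3L * sum(interior), -1, 1), ncol = 3L) *
        (params$jitter * h)
  }

  cg <- expand.grid(i = 0:(nx - 1L), j = 0:(ny - 1L), k = 0:(nz - 1L))
  if (!is.null(params$fenestra)) {
    fen <- params$fenestra
    if (fen$x[1L] < 0 || fen$x[2L] > L || fen$x[1L] >= fen$x[2L])
      stop("fenestra x-window outside solid bounds [0, ", L, "]")
    dmin <- D * shrink(fen$x[2L])
    if (fen$z[1L] >= fen$z[2L] || fen$z[1L] < -dmin / 2 ||
        fen$z[2L] > dmin / 2)
      stop("fenestra z-window outside solid depth at its anterior edge (+-",
           dmin / 2, ")")
    xc <- (cg$i + 0.5) / nx * L
    zc <- ((cg$k + 0.5) / nz - 0.5) * D * shrink(xc)
    keep <- !(xc > fen$x[1L] & xc < fen$x[2L] &
              zc > fen$z[1L] & zc < fen$z[2L])
    cg <- cg[keep, , drop = FALSE]
    if (nrow(cg) == 0L) stop("fenestra removes the whole solid")
  }
  splits <- rbind(c(0L, 1L, 2L, 6L), c(0L, 2L, 3L, 6L), c(0L, 3L, 7L, 6L),
                  c(0L, 7L, 4L, 6L), c(0L, 4L, 5L, 6L), c(0L, 5L, 1L, 6L))
  corner <- function(di, dj, dk) nid(cg$i + di, cg$j + dj, cg$k + dk)
  v <- cbind(corner(0L, 0L, 0L), corner(1L, 0L, 0L), corner(1L, 1L, 0L),
             corner(0L, 1L, 0L), corner(0L, 0L, 1L), corner(1L, 0L, 1L),
             corner(1L, 1L, 1L), corner(0L, 1L, 1L))
  tets <- do.call(rbind, lapply(1:6, function(sx)
    v[, splits[sx, ] + 1L, drop = FALSE]))

  ## drop nodes orphaned by a fenestra, remap connectivity
  used <- sort(unique(as.vector(tets)))
  if (length(used) < nrow(nodes)) {
    remap <- integer(nrow(nodes))
    remap[used] <- seq_along(used)
    nodes <- nodes[used, , drop = FALSE]
    tets <- matrix(remap[tets], ncol = 4L)
  }

  ## loading topology: anchors are analytic points on the ideal solid
  zsign <- if (params$preset == "cranium") -1 else 1
  bite_x <- L * (1 - 0.05 * (0:4))
  bite_anchors <- do.call(rbind, lapply(c(-1, 1), function(side)
    cbind(bite_x, side * W * shrink(bite_x) / 4,
          zsign * D * shrink(bite_x) / 2)))
  joint_anchors <- do.call(rbind, lapply(c(-1, 1), function(side)
    cbind(0, side * W / 2, c(-0.25, 0, 0.25) * D)))
  bite_nodes <- nearest_distinct_nodes(nodes, bite_anchors)
  joint_nodes <- nearest_distinct_nodes(nodes, joint_anchors)

  ## posterolateral insertion patches: boundary nodes on the lateral walls
  on_wall <- abs(abs(nodes[, 2L]) - W * shrink(nodes[, 1L]) / 2) <
    1e-9 * W
  in_band <- nodes[, 1L] > 0.02 * L & nodes[, 1L] < 0.45 * L
  patch <- which(on_wall & in_band)
  patch <- setdiff(patch, joint_nodes)
  left <- patch[nodes[patch, 2L] < 0]
  right <- patch[nodes[patch, 2L] > 0]
  if (!length(left) || !length(right))
    stop("resolution too coarse to form lateral muscle insertion patches")

  mesh <- tet_mesh(nodes, tets,
                   node_sets = list(bite = bite_nodes, joint = joint_nodes,
                                    adductor = c(left, right),
                                    adductor_left = left,
                                    adductor_right = right))
  structure(list(mesh = mesh,
                 summary = element_volumes(mesh),
                 adductor_area = params$adductor_area,
                 muscle_target = c(0.3 * L, 0, zsign * 1.2 * D),
                 part = params$preset,
                 label = NULL,
                 params = params),
            class = "labeled_model")
}

#' @export
print.labeled_model <- function(x, ...) {
  cat("<labeled_model> ", x$part,
      if (!is.null(x$label)) paste0(" '", x$label, "'"), ": ",
      nrow(x$mesh$nodes), " nodes, ", nrow(x$mesh$tets),
      " tets, SA ", format(x$summary$surface_area, digits = 6),
      " mm^2, adductor ", x$adductor_area, " cm^2\n", sep = "")
  invisible(x)
}

#' Isometrically scaled copy of a labeled model
#'
#' Multiplies all coordinates by `scale`, keeping connectivity and node
#' sets; the adductor area scales by `scale^2`, as any area does under
#' isometry.
#'
#' @param model a `labeled_model`.
#' @param scale positive scale factor.
#' @return A `labeled_model`.
#' @export
isometric_copy <- function(model, scale) {
  stopifnot(inherits(model, "labeled_model"), scale > 0)
  mesh <- tet_mesh(model$mesh$nodes * scale, model$mesh$tets,
                   node_sets = model$mesh$node_sets,
                   fix_orientation = FALSE)
  out <- model
  out$mesh <- mesh
  out$summary <- element_volumes(mesh)
  out$adductor_area <- model$adductor_area * scale^2
  out$muscle_target <- model$muscle_target * scale
  out
}

#' Packaged deterministic example family of skull proxies
#'
#' Three morphotypes spanning the gracile-robust and small-large axes, each
#' as a cranium and a mandible: `gracile-small`, `gracile-large` (an exact
#' isometric double of `gracile-small`) and `robust-large` (same length as
#' `gracile-large` but 1.5x deeper posteriorly). Adductor areas are sized
#' so actual-size muscle forces fall in the range estimated for small to
#' mid-sized tyrannosauroids (approximately 0.8 to 4 kN).
#'
#' @param resolution element layers along the length (default 10).
#' @return Named list of six `labeled_model`s; names are
#'   `<label>.<part>`.
#' @export
example_family <- function(resolution = 10L) {
  specs <- list(
    list(label = "gracile-small", scale = 1, robusticity = 1,
         adductor_area = 25),
    list(label = "gracile-large", scale = 2, robusticity = 1,
         adductor_area = 25),            # area rescales with the copy
    list(label = "robust-large", scale = 2, robusticity = 1.5,
         adductor_area = 120))
  out <- list()
  for (sp in specs) {
    for (part in c("cranium", "mandible")) {
      if (sp$label == "gracile-large") {
        base <- generate_proxy(proxy_params(part, resolution = resolution,
                                            adductor_area = sp$adductor_area))
        m <- isometric_copy(base, sp$scale)
      } else {
        pp <- proxy_params(part, resolution = resolution,
                           robusticity = sp$robusticity,
                           adductor_area = sp$adductor_area)
        if (sp$scale != 1) {
          pp$length <- pp$length * sp$scale
          pp$posterior_width <- pp$posterior_width * sp$scale
          pp$posterior_depth <- pp$posterior_depth * sp$scale
        }
        m <- generate_proxy(pp)
      }
      m$label <- sp$label
      out[[paste(sp$label, part, sep = ".")]] <- m
    }
  }
  out
}
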