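#' Assemble a static load case
#'
#' A load case holds the Dirichlet constraints (jaw-joint anchoring), the
#' bite-point loads and the muscle loads, with muscle loads kept per group
#' so that sensitivity perturbations can rescale one group at a time.
#'
#' @param constraints data frame with columns `node` and `dir` (1 = x,
#'   2 = y, 3 = z); one row per constrained degree of freedom.
#' @param bite_loads `NULL` or data frame with columns `node`, `fx`, `fy`,
#'   `fz` (N).
#' @param muscle_loads named list of data frames in the same shape as
#'   `bite_loads`, one per muscle group.
#' @return An object of class `load_case`.
#' @export
load_case <- function(constraints, bite_loads = NULL, muscle_loads = list()) {
  constraints <- as.data.frame(constraints)
  if (!all(c("node", "dir") %in% names(constraints)))
    stop("constraints needs columns node, dir")
  if (nrow(constraints) && !all(constraints$dir %in% 1:3))
    stop("constraint dir must be 1 (x), 2 (y) or 3 (z)")
  check_loads <- function(df, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!all(c("node", "fx", "fy", "fz") %in% names(df)))
      stop(what, " needs columns node, fx, fy, fz")
    df
  }
  bite_loads <- check_loads(bite_loads, "bite_loads")
  if (length(muscle_loads)) {
    if (is.null(names(muscle_loads)) || any(!nzchar(names(muscle_loads))))
      stop("muscle_loads must be a named list")
    muscle_loads <- lapply(muscle_loads, check_loads, what = "muscle_loads")
  }
  lc <- structure(list(constraints = constraints, bite_loads = bite_loads,
                       muscle_loads = muscle_loads),
                  class = "load_case")
  cdof <- paste(constraints$node, constraints$dir)
  for (df in c(list(bite_loads), muscle_loads)) {
    if (is.null(df)) next
    comp <- cbind(df$fx, df$fy, df$fz)
    for (d in 1:3) {
      hot <- df$node[comp[, d] != 0]
      clash <- hot[paste(hot, d) %in% cdof]
      if (length(clash))
        warning("load applied along a constrained direction at node(s) ",
                paste(utils::head(clash, 5L), collapse = ", "),
                "; it will be absorbed by the reaction")
    }
  }
  lc
}

#' @export
print.load_case <- function(x, ...) {
  tot <- total_applied_force(x)
  cat("<load_case> ", nrow(x$constraints), " constrained DOFs, ",
      if (is.null(x$bite_loads)) 0L else nrow(x$bite_loads),
      " bite-loaded nodes, ", length(x$muscle_loads),
      " muscle group(s)\n  total applied force (N): [",
      paste(format(tot, digits = 6), collapse = ", "), "]\n", sep = "")
  invisible(x)
}

load_case_constraints <- function(loads) loads$constraints

## dense global force vector (3n) from bite + muscle loads
load_vector <- function(loads, n_nodes) {
  f <- numeric(3L * n_nodes)
  add <- function(df) {
    if (is.null(df) || nrow(df) == 0L) return()
    idx <- 3L * (df$node - 1L)
    ## accumulate: a node may appear in several groups
    for (d in 1:3) {
      comp <- df[[c("fx", "fy", "fz")[d]]]
      tapply_add <- rowsum(comp, idx + d)
      f[as.integer(rownames(tapply_add))] <<-
        f[as.integer(rownames(tapply_add))] + tapply_add[, 1L]
    }
  }
  add(loads$bite_loads)
  for (df in loads$muscle_loads) add(df)
  f
}

## component sums of all applied loads
total_applied_force <- function(loads) {
  tot <- c(0, 0, 0)
  for (df in c(list(loads$bite_loads), loads$muscle_loads)) {
    if (is.null(df) || nrow(df) == 0L) next
    tot <- tot + c(sum(df$fx), sum(df$fy), sum(df$fz))
  }
  tot
}

#' Muscle specification from adductor chamber cross-sectional area
#'
#' Total jaw-adductor force is estimated with the subtemporal-fenestra
#' method: the adductor chamber cross-sectional area multiplied by the
#' isometric muscle specific tension, 31.5 N/cm^2 by default, then split
#' across named muscle groups by fixed fractions.
#'
#' @param adductor_area adductor chamber cross-sectional area in cm^2.
#' @param specific_tension isometric specific muscle tension in N/cm^2.
#' @param group_fractions named numeric vector of per-group fractions
#'   summing to 1; default one pooled `adductor` group.
#' @return An object of class `muscle_spec`.
#' @examples
#' muscle_force_from_area(muscle_spec(100))  # 3150 N
#' @export
muscle_spec <- function(adductor_area, specific_tension = 31.5,
                        group_fractions = c(adductor = 1)) {
  if (!is.numeric(adductor_area) || adductor_area <= 0)
    stop("adductor_area must be > 0 (cm^2)")
  if (specific_tension <= 0) stop("specific_tension must be > 0 (N/cm^2)")
  if (is.null(names(group_fractions)) || any(!nzchar(names(group_fractions))))
    stop("group_fractions must be named")
  if (abs(sum(group_fractions) - 1) > 1e-9)
    stop("group_fractions must sum to 1 (got ",
         format(sum(group_fractions)), ")")
  structure(list(adductor_area = adductor_area,
                 specific_tension = specific_tension,
                 group_fractions = group_fractions),
            class = "muscle_spec")
}

#' Per-group muscle force magnitudes from adductor area
#'
#' @param spec a [muscle_spec()].
#' @return Named numeric vector of group force magnitudes in N; the sum is
#'   `adductor_area * specific_tension`.
#' @export
muscle_force_from_area <- function(spec) {
  stopifnot(inherits(spec, "muscle_spec"))
  spec$adductor_area * spec$specific_tension * spec$group_fractions
}

#' Distribute a force vector evenly over a node set
#'
#' Each node receives `total / n` of every component, so the per-node loads
#' sum back to the input vector exactly.
#'
#' @param force numeric length-3 total force vector (N).
#' @param nodes integer vector of node indices.
#' @return Data frame with columns `node`, `fx`, `fy`, `fz`.
#' @export
distribute_over_nodes <- function(force, nodes) {
  stopifnot(length(force) == 3L)
  nodes <- as.integer(nodes)
  if (length(nodes) == 0L) stop("cannot distribute a force over 0 nodes")
  data.frame(node = nodes,
             fx = force[1L] / length(nodes),
             fy = force[2L] / length(nodes),
             fz = force[3L] / length(nodes))
}

#' Scaling policy for size-vs-shape comparisons
#'
#' In `sa_equalized` mode every model is loaded at the reference model's
#' force-to-surface-area ratio, so residual stress differences between
#' models reflect shape rather than size; `actual_size` mode leaves each
#' model's own forces untouched.
#'
#' @param mode `"actual_size"` or `"sa_equalized"`.
#' @param reference_surface_area reference model surface area (mm^2),
#'   required for `sa_equalized`.
#' @param reference_forces named per-group reference force magnitudes (N),
#'   required for `sa_equalized`.
#' @return An object of class `scaling_policy`.
#' @export
scaling_policy <- function(mode = c("actual_size", "sa_equalized"),
                           reference_surface_area = NULL,
                           reference_forces = NULL) {
  mode <- match.arg(mode)
  if (mode == "sa_equalized") {
    if (is.null(reference_surface_area) || reference_surface_area <= 0)
      stop("sa_equalized mode needs reference_surface_area > 0")
    if (is.null(reference_forces) || any(reference_forces <= 0))
      stop("sa_equalized mode needs positive reference_forces")
  }
  structure(list(mode = mode,
                 reference_surface_area = reference_surface_area,
                 reference_forces = reference_forces),
            class = "scaling_policy")
}

#' Scale muscle forces to a reference force-to-surface-area ratio
#'
#' Under `sa_equalized`, group forces become
#' `F_ref_g * (model_sa / reference_sa)`: every model carries the same
#' force per unit surface area as the reference. Under `actual_size` the
#' input forces are returned unchanged.
#'
#' @param forces named per-group force magnitudes of the model (N).
#' @param model_sa the model's surface area (mm^2).
#' @param policy a [scaling_policy()].
#' @return Named per-group force magnitudes (N).
#' @export
scale_to_reference <- function(forces, model_sa, policy) {
  stopifnot(inherits(policy, "scaling_policy"))
  if (policy$mode == "actual_size") return(forces)
  ref <- policy$reference_forces
  if (!is.null(names(forces))) {
    missing <- setdiff(names(forces), names(ref))
    if (length(missing))
      stop("reference_forces missing group(s): ",
           paste(missing, collapse = ", "))
    ref <- ref[names(forces)]
  }
  ref * (model_sa / policy$reference_surface_area)
}

#' Bite treatment configuration
#'
#' `mode = "load"` applies an external point-load at each bite node (the
#' total split evenly over the ten nodes); `mode = "constrain"` instead
#' fixes the bite nodes along the bite direction axis so the bite force is
#' recovered as a reaction.
#'
#' @param mode `"load"` or `"constrain"`.
#' @param magnitude total bite force magnitude (N) for `"load"` mode.
#' @param direction length-3 direction of the applied bite load; normalized
#'   internally. Default `(0, 0, -1)`.
#' @return An object of class `bite_config`.
#' @export
bite_config <- function(mode = c("load", "constrain"), magnitude = 0,
                        direction = c(0, 0, -1)) {
  mode <- match.arg(mode)
  stopifnot(length(direction) == 3L)
  nrm <- sqrt(sum(direction^2))
  if (nrm == 0) stop("bite direction must be non-zero")
  structure(list(mode = mode, magnitude = magnitude,
                 direction = direction / nrm),
            class = "bite_config")
}

## resolve a muscle group direction: unit vectors from each insertion node
## toward the target point, averaged over the group, re-normalized
toward_point_direction <- function(nodes_xyz, target) {
  d <- matrix(rep(target, each = nrow(nodes_xyz)), ncol = 3L) - nodes_xyz
  len <- sqrt(rowSums(d^2))
  if (any(len == 0)) stop("muscle target coincides with an insertion node")
  mean_dir <- colMeans(d / len)
  nrm <- sqrt(sum(mean_dir^2))
  if (nrm == 0) stop("degenerate muscle direction (vectors cancel)")
  mean_dir / nrm
}

#' Build the load case of a labeled skull-proxy model
#'
#' Fully constrains the six jaw-joint nodes (three translational directions
#' each, 18 DOFs), applies the bite treatment at the ten bite nodes, and
#' resolves, scales and distributes the muscle loads over their insertion
#' patches. Muscle force magnitudes come from the model's adductor area via
#' [muscle_force_from_area()] (or explicit `forces`), optionally rescaled
#' by a [scaling_policy()], and each group's total is divided evenly over
#' the nodes of its insertion set.
#'
#' @param model a `labeled_model` from [generate_proxy()].
#' @param muscles a [muscle_spec()] (the default builds one from the
#'   model's adductor area), `NULL` for no muscle loads, or a named
#'   numeric vector of explicit per-group force magnitudes (N).
#' @param bite a [bite_config()]; default applies no bite load.
#' @param policy a [scaling_policy()]; default `actual_size`.
#' @param muscle_target length-3 point toward which insertion-node force
#'   vectors point; default the model's `muscle_target` anchor.
#' @param insertion_sets named character vector mapping group name to node
#'   set name; default every group maps to the `"adductor"` set.
#' @return A [load_case()].
#' @export
build_load_case <- function(model, muscles = default_muscles(model),
                            bite = bite_config(),
                            policy = scaling_policy("actual_size"),
                            muscle_target = NULL, insertion_sets = NULL) {
  stopifnot(inherits(model, "labeled_model"))
  sets <- model$mesh$node_sets
  need_set <- function(nm) {
    if (!nm %in% names(sets))
      stop("model has no node set '", nm, "'; available: ",
           paste(names(sets), collapse = ", "))
    sets[[nm]]
  }
  joint <- need_set("joint")
  bite_nodes <- need_set("bite")
  constraints <- data.frame(node = rep(joint, each = 3L),
                            dir = rep(1:3, times = length(joint)))
  bite_loads <- NULL
  if (bite$mode == "constrain") {
    ax <- which.max(abs(bite$direction))
    constraints <- rbind(constraints,
                         data.frame(node = bite_nodes, dir = ax))
  } else if (bite$magnitude != 0) {
    bite_loads <- distribute_over_nodes(bite$magnitude * bite$direction,
                                        bite_nodes)
  }
  muscle_loads <- list()
  if (!is.null(muscles)) {
    forces <- if (inherits(muscles, "muscle_spec"))
      muscle_force_from_area(muscles) else muscles
    if (is.null(names(forces)) || any(!nzchar(names(forces))))
      stop("muscle forces must be named by group")
    forces <- scale_to_reference(forces, model$summary$surface_area, policy)
    if (is.null(muscle_target)) muscle_target <- model$muscle_target
    if (is.null(muscle_target))
      stop("no muscle_target given and the model carries none")
    for (gname in names(forces)) {
      set_name <- if (!is.null(insertion_sets) && gname %in%
                      names(insertion_sets)) insertion_sets[[gname]]
                  else if (gname %in% names(sets)) gname
                  else "adductor"
      ins <- need_set(set_name)
      dir <- toward_point_direction(model$mesh$nodes[ins, , drop = FALSE],
                                    muscle_target)
      muscle_loads[[gname]] <-
        distribute_over_nodes(forces[[gname]] * dir, ins)
    }
  }
  load_case(constraints, bite_loads, muscle_loads)
}

#' Consistent nodal loads for a uniform surface traction
#'
#' Distributes a uniform traction (force per mm^2) over the boundary
#' triangles whose three vertices all belong to `nodes`, assigning each
#' triangle's `area / 3` share of the traction to each of its vertices -
#' the consistent load vector for linear triangles. Useful for patch tests
#' and for spreading prey-contact loads over a facial region.
#'
#' @param mesh a [tet_mesh()].
#' @param nodes node indices delimiting the loaded boundary region.
#' @param traction length-3 traction vector in N/mm^2 (MPa).
#' @return Data frame with columns `node`, `fx`, `fy`, `fz`; the component
#'   sums equal traction times the loaded area.
#' @export
traction_loads <- function(mesh, nodes, traction) {
  stopifnot(inherits(mesh, "tet_mesh"), length(traction) == 3L)
  bt <- boundary_triangles(mesh)
  sel <- bt[, 1L] %in% nodes & bt[, 2L] %in% nodes & bt[, 3L] %in% nodes
  bt <- bt[sel, , drop = FALSE]
  if (nrow(bt) == 0L)
    stop("no boundary triangle lies entirely within the given nodes")
  a <- mesh$nodes[bt[, 1L], , drop = FALSE]
  u <- mesh$nodes[bt[, 2L], , drop = FALSE] - a
  v <- mesh$nodes[bt[, 3L], , drop = FALSE] - a
  area <- 0.5 * sqrt((u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L])^2 +
                     (u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L])^2 +
                     (u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])^2)
  node <- as.vector(bt)
  w <- rep(area / 3, times = 3L)
  agg <- rowsum(cbind(w * traction[1L], w * traction[2L], w * traction[3L]),
                node)
  data.frame(node = as.integer(rownames(agg)), fx = agg[, 1L],
             fy = agg[, 2L], fz = agg[, 3L])
}

## lazy default for build_load_case: a pooled adductor spec from the
## model's area, or no muscles when the model carries no area
default_muscles <- function(model) {
  if (is.null(model$adductor_area)) NULL
  else muscle_spec(model$adductor_area)
}
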