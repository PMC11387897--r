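#' Symmetric percent difference
#'
#' `|a - b| / ((a + b) / 2) * 100`: the percent-difference statistic used
#' to compare baseline and perturbed mesh-weighted mean stresses. It is
#' symmetric in its arguments and zero iff they are equal.
#'
#' @param a,b positive scalars (or equal-length vectors) with `a + b > 0`.
#' @return Percent difference(s) in the 0-200 range.
#' @examples
#' percent_difference(7.111209, 7.729046)  # 8.3265
#' @export
percent_difference <- function(a, b) {
  if (any(a + b <= 0))
    stop("percent_difference needs a positive mean (a + b > 0)")
  abs(a - b) / ((a + b) / 2) * 100
}

#' Scale muscle loads of a load case
#'
#' Multiplies muscle-group loads by `factor`, either for all groups
#' (`mode = "global"`) or for a single `target_group` (`mode =
#' "per_muscle"`). Bite loads and constraints are untouched.
#'
#' @param loads a [load_case()].
#' @param factor positive multiplier (1.1 and 0.9 for the +/-10% study).
#' @param mode `"global"` or `"per_muscle"`.
#' @param target_group group name, required for `"per_muscle"`.
#' @return A [load_case()].
#' @export
perturb_loads <- function(loads, factor, mode = c("global", "per_muscle"),
                          target_group = NULL) {
  stopifnot(inherits(loads, "load_case"))
  mode <- match.arg(mode)
  if (factor <= 0) stop("factor must be > 0")
  groups <- names(loads$muscle_loads)
  targets <- if (mode == "global") groups else {
    if (is.null(target_group) || !target_group %in% groups)
      stop("unknown muscle group '", target_group, "'; available: ",
           paste(groups, collapse = ", "))
    target_group
  }
  for (g in targets) {
    df <- loads$muscle_loads[[g]]
    df[c("fx", "fy", "fz")] <- df[c("fx", "fy", "fz")] * factor
    loads$muscle_loads[[g]] <- df
  }
  loads
}

#' Muscle-force sensitivity analysis of one model
#'
#' Solves the baseline case and re-solves with every muscle force scaled
#' 10% up and 10% down (by default). In `"global"` mode all groups are
#' perturbed together (one run per direction); in `"per_muscle"` mode each
#' group is perturbed in turn while the others stay at baseline, and the
#' per-group perturbed MWAMs are averaged per direction. The reported
#' statistic is the symmetric percent difference between baseline and
#' perturbed MWAM von Mises stress.
#'
#' For a purely muscle-loaded linear model in global mode the solution
#' scales exactly with the load, so the percent differences are the
#' closed-form constants `100 * 0.1 / 1.05 = 9.5238` (up) and
#' `100 * 0.1 / 0.95 = 10.5263` (down) - a useful verification oracle.
#'
#' @param model a `labeled_model` (used for the mesh).
#' @param material a [material_properties()].
#' @param loads the baseline [load_case()].
#' @param mode `"per_muscle"` (default) or `"global"`.
#' @param delta relative perturbation (default 0.1).
#' @param ... passed to [solve_fe()].
#' @return A `sensitivity_result`: `baseline_mwam`, `mwam_up`,
#'   `mwam_down` (MPa), `pct_diff_up`, `pct_diff_down` (%), `mode`,
#'   and in per-muscle mode a `per_muscle` data frame of group-wise runs.
#' @export
run_sensitivity <- function(model, material, loads,
                            mode = c("per_muscle", "global"), delta = 0.1,
                            ...) {
  stopifnot(inherits(model, "labeled_model"))
  mode <- match.arg(mode)
  mesh <- model$mesh
  base_field <- solve_fe(mesh, material, loads, ...)
  base <- mwam(base_field$von_mises, base_field$element_volumes)
  solve_mwam <- function(lc) {
    f <- solve_fe(mesh, material, lc, ...)
    mwam(f$von_mises, f$element_volumes)
  }
  per_muscle <- NULL
  if (mode == "global") {
    up <- solve_mwam(perturb_loads(loads, 1 + delta, "global"))
    down <- solve_mwam(perturb_loads(loads, 1 - delta, "global"))
  } else {
    groups <- names(loads$muscle_loads)
    if (length(groups) == 0L) {
      up <- down <- base
    } else {
      ups <- vapply(groups, function(g)
        solve_mwam(perturb_loads(loads, 1 + delta, "per_muscle", g)),
        numeric(1L))
      downs <- vapply(groups, function(g)
        solve_mwam(perturb_loads(loads, 1 - delta, "per_muscle", g)),
        numeric(1L))
      up <- mean(ups)
      down <- mean(downs)
      per_muscle <- data.frame(group = groups, mwam_up = ups,
                               mwam_down = downs,
                               pct_diff_up = percent_difference(base, ups),
                               pct_diff_down =
                                 percent_difference(base, downs),
                               row.names = NULL)
    }
  }
  structure(list(label = model$label, part = model$part,
                 baseline_mwam = base, mwam_up = up, mwam_down = down,
                 pct_diff_up = percent_difference(base, up),
                 pct_diff_down = percent_difference(base, down),
                 mode = mode, delta = delta, per_muscle = per_muscle),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> ", x$part,
      if (!is.null(x$label)) paste0(" '", x$label, "'"),
      " (", x$mode, ", +/-", 100 * x$delta, "%)\n",
      "  baseline MWAM ", format(x$baseline_mwam, digits = 7),
      " MPa; up ", format(x$mwam_up, digits = 7),
      " (", format(x$pct_diff_up, digits = 6), "%); down ",
      format(x$mwam_down, digits = 7),
      " (", format(x$pct_diff_down, digits = 6), "%)\n", sep = "")
  invisible(x)
}

#' Tabulate sensitivity results
#'
#' One row per model, mirroring the columns of a muscle-sensitivity
#' results table: baseline, perturbed means and symmetric percent
#' differences in both directions.
#'
#' @param results list of `sensitivity_result` objects.
#' @return A data frame with columns `label`, `part`, `baseline`, `up`,
#'   `down`, `pct_up`, `pct_down`, `mode`.
#' @export
sensitivity_table <- function(results) {
  do.call(rbind, lapply(results, function(r)
    data.frame(label = r$label %||% NA_character_, part = r$part,
               baseline = r$baseline_mwam, up = r$mwam_up,
               down = r$mwam_down, pct_up = r$pct_diff_up,
               pct_down = r$pct_diff_down, mode = r$mode)))
}
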