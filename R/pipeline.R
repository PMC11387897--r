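#' Read a study configuration from YAML
#'
#' The configuration describes the full comparative study: the models
#' (parametric proxies or tet-mesh files with labeled node sets), material
#' properties, bite treatment, muscle constants, the surface-area scaling
#' reference, sensitivity settings, and output location. See
#' `vignette("skull-proxy-fea")` for the schema and a worked example.
#'
#' @param path path to a YAML file.
#' @return The configuration as a nested list, class `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "study_config")
}

#' Validate a study configuration
#'
#' Collects fatal problems (missing/duplicate labels, unresolved scaling
#' reference, nonpositive areas, missing files or node sets) and warnings
#' (e.g. a bite load of zero magnitude) without running anything.
#'
#' @param config a `study_config` (or plain list in the same shape).
#' @return Data frame with columns `level` (`"fatal"`/`"warning"`) and
#'   `message`; zero rows when the configuration is clean. Attribute
#'   `fatal` is `TRUE` when any fatal finding is present.
#' @export
validate_config <- function(config) {
  probs <- list()
  add <- function(level, msg)
    probs[[length(probs) + 1L]] <<- data.frame(level = level, message = msg)
  models <- config$models
  if (is.null(models) || length(models) == 0L) {
    add("fatal", "no models defined")
  } else {
    labels <- vapply(models, function(m) m$label %||% "", character(1L))
    if (any(!nzchar(labels))) add("fatal", "model without a label")
    if (anyDuplicated(labels))
      add("fatal", paste("duplicate model labels:",
                         paste(unique(labels[duplicated(labels)]),
                               collapse = ", ")))
    for (m in models) {
      lab <- m$label %||% "<unlabeled>"
      if (!isTRUE((m$part %||% "cranium") %in% c("cranium", "mandible")))
        add("fatal", paste0(lab, ": part must be cranium or mandible"))
      src <- m$source %||% list(type = "proxy")
      if (identical(src$type, "file")) {
        if (is.null(src$path) || !file.exists(src$path))
          add("fatal", paste0(lab, ": mesh file not found: ",
                              src$path %||% "<missing>"))
        if (is.null(m$adductor_area))
          add("fatal", paste0(lab, ": file models need adductor_area"))
      }
      area <- m$adductor_area %||% src$adductor_area
      if (!is.null(area) && area <= 0)
        add("fatal", paste0(lab, ": adductor_area must be > 0 cm^2"))
    }
    modes <- config$modes %||% c("actual_size", "sa_equalized")
    if ("sa_equalized" %in% modes) {
      ref <- config$scaling$reference
      if (is.null(ref)) {
        add("fatal", "sa_equalized mode needs scaling$reference")
      } else if (!ref %in% labels) {
        add("fatal", paste0("scaling reference '", ref,
                            "' is not a model label"))
      }
    }
  }
  bite <- config$bite
  if (!is.null(bite)) {
    if (identical(bite$mode %||% "load", "load") &&
        (bite$magnitude %||% 0) == 0)
      add("warning", "bite mode 'load' with zero magnitude: no bite load")
    if (!is.null(bite$mode) && !bite$mode %in% c("load", "constrain"))
      add("fatal", paste0("unknown bite mode '", bite$mode, "'"))
  }
  mat <- config$material
  if (!is.null(mat)) {
    ok <- tryCatch({
      material_properties(mat$youngs_modulus %||% 15000,
                          mat$poisson_ratio %||% 0.29)
      TRUE
    }, error = function(e) {
      add("fatal", paste("material:", conditionMessage(e)))
      FALSE
    })
  }
  out <- if (length(probs)) do.call(rbind, probs) else
    data.frame(level = character(0), message = character(0))
  attr(out, "fatal") <- any(out$level == "fatal")
  out
}

## materialize one config model entry into a labeled_model
build_model <- function(entry) {
  part <- entry$part %||% "cranium"
  src <- entry$source %||% list(type = "proxy")
  if (identical(src$type, "file")) {
    mesh <- read_tet_mesh(src$path)
    need <- setdiff(c("bite", "joint", "adductor"), names(mesh$node_sets))
    if (length(need))
      stop("mesh file ", src$path, " lacks node set(s): ",
           paste(need, collapse = ", "))
    bb <- apply(mesh$nodes, 2L, range)
    zsign <- if (part == "cranium") -1 else 1
    target <- entry$muscle_target %||%
      c(bb[1L, 1L] + 0.3 * diff(bb[, 1L]), mean(bb[, 2L]),
        mean(bb[, 3L]) + zsign * 1.2 * diff(bb[, 3L]))
    model <- structure(list(mesh = mesh, summary = element_volumes(mesh),
                            adductor_area = entry$adductor_area,
                            muscle_target = as.numeric(target),
                            part = part, label = entry$label,
                            params = NULL),
                       class = "labeled_model")
  } else {
    args <- src
    args$type <- NULL
    args$preset <- part
    if (!is.null(entry$adductor_area)) args$adductor_area <- entry$adductor_area
    model <- generate_proxy(do.call(proxy_params, args))
    model$label <- entry$label
  }
  model
}

config_bite <- function(config) {
  b <- config$bite
  if (is.null(b)) return(bite_config())
  bite_config(mode = b$mode %||% "load", magnitude = b$magnitude %||% 0,
              direction = as.numeric(b$direction %||% c(0, 0, -1)))
}

config_muscles <- function(config, area) {
  mu <- config$muscles
  fr <- mu$group_fractions %||% c(adductor = 1)
  muscle_spec(adductor_area = area,
              specific_tension = mu$specific_tension %||% 31.5,
              group_fractions = unlist(fr))
}

## short deterministic hash of the configuration for output provenance
config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA, force = TRUE), f)
  substr(unname(tools::md5sum(f)), 1L, 12L)
}

#' Run the full comparative feeding-biomechanics study
#'
#' For every configured model: build or load the mesh, assemble the
#' actual-size load case (joint constraints, bite treatment, adductor
#' muscle loads from area x specific tension), solve, and summarize; then
#' repeat with muscle forces surface-area-equalized to the reference model
#' so the comparison isolates shape from size; optionally run the
#' muscle-force sensitivity analysis. Writes per-mode comparison CSVs,
#' per-model VTK result files, a sensitivity CSV and a JSON run manifest.
#' A failing model is logged and skipped; the remaining models continue.
#'
#' @param config a `study_config` (see [read_study_config()]).
#' @param output_dir output directory (default `config$output_dir`, or
#'   `"skullfea-out"`).
#' @param write_vtk write per-model VTK files (default `TRUE`).
#' @return Invisibly, a list with `tables` (per-mode comparison data
#'   frames), `sensitivity` (data frame or `NULL`), `fields` (per
#'   model x mode `solution_field`s) and `manifest`.
#' @export
run_study <- function(config, output_dir = NULL, write_vtk = TRUE) {
  t0 <- Sys.time()
  findings <- validate_config(config)
  if (isTRUE(attr(findings, "fatal")))
    stop("invalid study config:\n  ",
         paste(findings$message[findings$level == "fatal"],
               collapse = "\n  "))
  for (w in findings$message[findings$level == "warning"])
    warning(w, call. = FALSE)
  output_dir <- output_dir %||% config$output_dir %||% "skullfea-out"
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)
  hash <- config_hash(config)
  logf <- file.path(output_dir, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    message(msg)
    cat(msg, "\n", file = logf, append = TRUE)
  }
  log_line("study start, config hash ", hash)

  material <- material_properties(
    config$material$youngs_modulus %||% 15000,
    config$material$poisson_ratio %||% 0.29)
  bite <- config_bite(config)
  modes <- config$modes %||% c("actual_size", "sa_equalized")

  models <- list()
  failures <- character(0)
  for (entry in config$models) {
    m <- tryCatch(build_model(entry), error = function(e) {
      log_line("FAILED to build '", entry$label, "': ",
               conditionMessage(e))
      failures <<- c(failures, entry$label)
      NULL
    })
    if (!is.null(m)) models[[entry$label]] <- m
  }

  ref_label <- config$scaling$reference
  policy_sa <- NULL
  if ("sa_equalized" %in% modes) {
    if (!ref_label %in% names(models))
      stop("scaling reference '", ref_label, "' failed to build")
    refm <- models[[ref_label]]
    policy_sa <- scaling_policy(
      "sa_equalized",
      reference_surface_area = refm$summary$surface_area,
      reference_forces =
        muscle_force_from_area(config_muscles(config, refm$adductor_area)))
  }

  fields <- list()
  stats <- stats::setNames(vector("list", length(modes)), modes)
  for (mode in modes) stats[[mode]] <- list()
  for (lab in names(models)) {
    model <- models[[lab]]
    spec <- config_muscles(config, model$adductor_area)
    for (mode in modes) {
      res <- tryCatch({
        policy <- if (mode == "actual_size")
          scaling_policy("actual_size") else policy_sa
        lc <- build_load_case(model, muscles = spec, bite = bite,
                              policy = policy)
        field <- solve_fe(model$mesh, material, lc)
        list(lc = lc, field = field, stats = summarize_field(field))
      }, error = function(e) {
        log_line("FAILED '", lab, "' [", mode, "]: ", conditionMessage(e))
        failures <<- c(failures, paste0(lab, ":", mode))
        NULL
      })
      if (is.null(res)) next
      fields[[paste(lab, mode, sep = ".")]] <- res$field
      stats[[mode]][[lab]] <- list(part = model$part, mode = mode,
                                   stats = res$stats)
      if (write_vtk)
        write_results_vtk(model$mesh, res$field,
                          file.path(output_dir,
                                    paste0(lab, "_", mode, ".vtk")))
      log_line(lab, " [", mode, "]: MWAM vM = ",
               format(res$stats$mwam_von_mises, digits = 7), " MPa")
    }
  }

  tables <- list()
  for (mode in modes) {
    if (length(stats[[mode]]) == 0L) next
    tab <- comparison_table(stats[[mode]])
    tab$config_hash <- hash
    tables[[mode]] <- tab
    utils::write.csv(tab,
                     file.path(output_dir,
                               paste0("comparison_", mode, ".csv")),
                     row.names = FALSE)
  }

  sens_tab <- NULL
  scfg <- config$sensitivity
  if (isTRUE(scfg$enabled %||% FALSE)) {
    sens_labels <- unlist(scfg$models) %||% names(models)
    sens <- list()
    for (lab in intersect(sens_labels, names(models))) {
      model <- models[[lab]]
      spec <- config_muscles(config, model$adductor_area)
      r <- tryCatch({
        lc <- build_load_case(model, muscles = spec, bite = bite,
                              policy = scaling_policy("actual_size"))
        run_sensitivity(model, material, lc,
                        mode = scfg$mode %||% "per_muscle",
                        delta = scfg$delta %||% 0.1)
      }, error = function(e) {
        log_line("FAILED sensitivity '", lab, "': ", conditionMessage(e))
        failures <<- c(failures, paste0(lab, ":sensitivity"))
        NULL
      })
      if (!is.null(r)) sens[[lab]] <- r
    }
    if (length(sens)) {
      sens_tab <- sensitivity_table(sens)
      sens_tab$config_hash <- hash
      utils::write.csv(sens_tab, file.path(output_dir, "sensitivity.csv"),
                       row.names = FALSE)
    }
  }

  manifest <- list(
    package = "skullfea",
    version = as.character(utils::packageVersion("skullfea")),
    r_version = R.version.string,
    config_hash = hash,
    seed = config$seed %||% NA,
    models = names(models),
    modes = modes,
    failures = failures,
    started = format(t0, "%Y-%m-%dT%H:%M:%S"),
    elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log_line("study done (", manifest$elapsed_s, " s)")
  invisible(list(tables = tables, sensitivity = sens_tab, fields = fields,
                 manifest = manifest))
}
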