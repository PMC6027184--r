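# YAML model configuration: everything needed to rebuild an elbow_model
# (bodies, ligaments, muscles, contact parameters, analytic surfaces, and
# references to cartilage meshes that are re-discretized on load).

attach_to_list <- function(a) list(body = a$body, point = as.numeric(a$point))

#' Serialize an elbow model to a YAML configuration
#'
#' @param model an `elbow_model`.
#' @param path output YAML path.
#' @param mesh_files named character vector mapping element-grid contact
#'   pair names to mesh file paths (relative to the config); the grids are
#'   re-discretized from these meshes when the config is loaded.
#' @return the path, invisibly.
#' @export
write_model_config <- function(model, path, mesh_files = character()) {
  cfg <- list(
    units = list(length = "mm", mass = "kg", force = "N", pressure = "MPa"),
    gravity = model$gravity,
    free_bodies = model$free_bodies,
    bodies = lapply(model$bodies, function(b)
      list(name = b$name, mass = b$mass,
           inertia = as.numeric(b$inertia), com = b$com)),
    contact = list(kc = model$contact$kc, n = model$contact$n,
                   c_max = model$contact$c_max, d_max = model$contact$d_max),
    dampers = model$dampers,
    contact_pairs = lapply(model$contact_pairs, function(cp) {
      if (identical(cp$type, "point_sphere_cup")) {
        list(name = cp$name, type = "point_sphere_cup",
             sphere = list(body = cp$sphere$body,
                           center = as.numeric(cp$sphere$center),
                           radius = cp$sphere$radius),
             cup = unclass_surface(cp$cup), area = cp$area)
      } else {
        list(name = cp$name, type = "element_grid",
             mesh = if (cp$name %in% names(mesh_files))
               unname(mesh_files[[cp$name]]) else NULL,
             parent_body = cp$grid$parent_body,
             element_size = cp$grid$target_size,
             thickness = cp$grid$elements$thickness[1L],
             opposing = unclass_surface(cp$opposing))
      }
    }),
    ligaments = lapply(unname(model$ligaments$bundles), function(b)
      list(name = b$name, origin = attach_to_list(b$origin),
           insertion = attach_to_list(b$insertion),
           via_points = lapply(b$via_points, attach_to_list),
           wrap_obstacles = lapply(b$wrap_obstacles, function(o)
             list(type = o$type, body = o$body,
                  center = as.numeric(o$center), radius = o$radius,
                  axis = if (!is.null(o$axis)) as.numeric(o$axis) else NULL)),
           k = b$k, eps_l = b$eps_l,
           l0 = if (is.na(b$l0)) NULL else b$l0)),
    muscles = lapply(unname(model$muscles), function(m)
      list(name = m$name, origin = attach_to_list(m$origin),
           insertion = attach_to_list(m$insertion),
           via_points = lapply(m$via_points, attach_to_list),
           PCSA_mm2 = m$PCSA, Fmax_N = m$F_max)),
    frames = lapply(model$frames, function(fr)
      list(origin = as.numeric(fr$origin), axes = as.numeric(fr$axes))))
  yaml::write_yaml(cfg, path, precision = 15L)
  invisible(path)
}

unclass_surface <- function(s) {
  out <- unclass(s)
  out[!vapply(out, is.null, TRUE)]
}

#' Load an elbow model from a YAML configuration
#'
#' Cartilage meshes referenced by element-grid contact pairs are loaded
#' relative to the config file and re-discretized at the configured element
#' size.
#'
#' @param path YAML path written by [write_model_config()].
#' @return an `elbow_model`.
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  dir <- dirname(path)
  bodies <- lapply(cfg$bodies, function(b)
    rigid_body(b$name, b$mass, matrix(as.numeric(b$inertia), 3L, 3L),
               com = as.numeric(b$com)))
  names(bodies) <- vapply(bodies, `[[`, "", "name")
  mk_surface <- function(s) {
    args <- s[setdiff(names(s), c("type", "body"))]
    args <- lapply(args, function(x) if (is.list(x)) unlist(x) else x)
    do.call(contact_surface, c(list(type = s$type, body = s$body), args))
  }
  contact_pairs <- lapply(cfg$contact_pairs, function(cp) {
    if (identical(cp$type, "point_sphere_cup")) {
      list(name = cp$name, type = "point_sphere_cup",
           sphere = list(body = cp$sphere$body,
                         center = as.numeric(cp$sphere$center),
                         radius = cp$sphere$radius),
           cup = mk_surface(cp$cup), area = cp$area)
    } else {
      if (is.null(cp$mesh))
        stop("contact pair '", cp$name, "' has no mesh reference")
      mesh <- load_mesh(file.path(dir, cp$mesh), body_name = cp$parent_body)
      list(name = cp$name,
           grid = discretize_cartilage(mesh, cp$element_size,
                                       thickness = cp$thickness %||% 2,
                                       parent_body = cp$parent_body),
           opposing = mk_surface(cp$opposing))
    }
  })
  mk_attach <- function(a) list(body = a$body, point = as.numeric(a$point))
  ligaments <- ligament_complex(lapply(cfg$ligaments, function(b)
    ligament_bundle(b$name, mk_attach(b$origin), mk_attach(b$insertion),
                    k = b$k, eps_l = b$eps_l,
                    l0 = if (is.null(b$l0)) NA_real_ else b$l0,
                    via_points = lapply(b$via_points, mk_attach),
                    wrap_obstacles = lapply(b$wrap_obstacles, function(o)
                      list(type = o$type, body = o$body,
                           center = as.numeric(o$center), radius = o$radius,
                           axis = if (!is.null(o$axis)) as.numeric(o$axis)
                           else NULL)))))
  muscles <- lapply(cfg$muscles, function(m)
    muscle_actuator(m$name, mk_attach(m$origin), mk_attach(m$insertion),
                    PCSA = m$PCSA_mm2, F_max = m$Fmax_N,
                    via_points = lapply(m$via_points, mk_attach)))
  frames <- lapply(cfg$frames, function(fr)
    structure(list(origin = as.numeric(fr$origin),
                   axes = matrix(as.numeric(fr$axes), 3L, 3L,
                                 dimnames = list(NULL, c("ML", "AP", "SI")))),
              class = "anatomical_frame"))
  elbow_model(bodies,
              ligaments = ligaments, muscles = muscles,
              contact = contact_params(cfg$contact$kc, cfg$contact$n,
                                       cfg$contact$c_max, cfg$contact$d_max),
              contact_pairs = contact_pairs, frames = frames,
              gravity = as.numeric(cfg$gravity),
              dampers = if (is.null(cfg$dampers)) list() else cfg$dampers,
              free_bodies = unlist(cfg$free_bodies))
}

#' Write the per-signal CSV outputs of a simulation result
#'
#' Writes `poses.csv` (trial format), `muscles.csv` (force, length and
#' target per muscle), `tensions.csv`, and one `contact_<pair>.csv` summary
#' per contact pair, plus `element_peak_force_<pair>.csv` for element
#' grids.
#'
#' @param result a `simulation_result`.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_result_csv <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_trial_csv(motion_trial(result$label, result$time, result$poses),
                  file.path(dir, "poses.csv"))
  mf <- data.frame(time_s = result$time)
  for (m in colnames(result$muscle_forces)) {
    mf[[paste0(m, "_force_N")]] <- result$muscle_forces[, m]
    mf[[paste0(m, "_length_mm")]] <- result$muscle_lengths[, m]
    mf[[paste0(m, "_target_mm")]] <- result$muscle_targets[, m]
  }
  utils::write.csv(mf, file.path(dir, "muscles.csv"), row.names = FALSE)
  if (!is.null(result$ligament_tensions))
    utils::write.csv(data.frame(time_s = result$time,
                                result$ligament_tensions,
                                check.names = FALSE),
                     file.path(dir, "tensions.csv"), row.names = FALSE)
  for (nm in result$contact_pairs) {
    utils::write.csv(result$contact[[nm]],
                     file.path(dir, paste0("contact_",
                                           gsub("[^A-Za-z0-9]", "_", nm),
                                           ".csv")), row.names = FALSE)
    utils::write.csv(data.frame(element_id = seq_along(result$element_peak_force[[nm]]),
                                peak_force_N = result$element_peak_force[[nm]]),
                     file.path(dir, paste0("element_peak_force_",
                                           gsub("[^A-Za-z0-9]", "_", nm),
                                           ".csv")), row.names = FALSE)
  }
  invisible(dir)
}
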