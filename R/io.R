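# Artifact export: legacy VTK unstructured grids, node-set JSON, YAML
# run configuration.

#' Write a mesh (with optional fields) as a legacy VTK unstructured grid
#'
#' ASCII VTK 2.0, triangle cells. Cell data always includes
#' `domain_code`, `organ_label` and `quality`; any named entries of
#' `point_data` are written as nodal scalar fields.
#'
#' @param mesh a `domain_mesh`.
#' @param path output `.vtk` path.
#' @param point_data named list of per-node numeric vectors (NA allowed;
#'   written as -1).
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, point_data = list()) {
  stopifnot(inherits(mesh, "domain_mesh"))
  n <- nrow(mesh$nodes); m <- nrow(mesh$elements)
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(c(...), con)
  wl("# vtk DataFile Version 2.0", "vascox multi-domain mesh", "ASCII",
     "DATASET UNSTRUCTURED_GRID")
  wl(sprintf("POINTS %d float", n))
  writeLines(sprintf("%.8g %.8g 0", mesh$nodes[, 1L], mesh$nodes[, 2L]), con)
  wl(sprintf("CELLS %d %d", m, 4L * m))
  writeLines(sprintf("3 %d %d %d", mesh$elements[, 1L] - 1L,
                     mesh$elements[, 2L] - 1L, mesh$elements[, 3L] - 1L), con)
  wl(sprintf("CELL_TYPES %d", m))
  writeLines(rep("5", m), con)
  wl(sprintf("CELL_DATA %d", m))
  cell_scalar <- function(name, v) {
    wl(sprintf("SCALARS %s float 1", name), "LOOKUP_TABLE default")
    writeLines(sprintf("%.8g", v), con)
  }
  cell_scalar("domain_code", mesh$code)
  cell_scalar("organ_label", mesh$organ)
  cell_scalar("quality", element_quality(mesh))
  if (length(point_data)) {
    wl(sprintf("POINT_DATA %d", n))
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      v[is.na(v)] <- -1
      wl(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default")
      writeLines(sprintf("%.8g", v), con)
    }
  }
  invisible(path)
}

#' Read back the node/cell structure of a legacy VTK file
#'
#' Minimal reader for round-trip checks: returns counts and the names of
#' data arrays.
#'
#' @param path a `.vtk` file written by [write_mesh_vtk()].
#' @return list with `n_points`, `n_cells`, `arrays`.
#' @export
read_vtk_info <- function(path) {
  ln <- readLines(path)
  np <- as.integer(sub("POINTS (\\d+).*", "\\1", grep("^POINTS", ln, value = TRUE)[1]))
  nc <- as.integer(sub("CELLS (\\d+).*", "\\1", grep("^CELLS ", ln, value = TRUE)[1]))
  arrays <- sub("^SCALARS (\\S+).*", "\\1", grep("^SCALARS", ln, value = TRUE))
  list(n_points = np, n_cells = nc, arrays = arrays)
}

#' Export boundary node sets as JSON
#'
#' @param bsets a `boundary_sets`.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_node_sets <- function(bsets, path) {
  jsonlite::write_json(
    list(inlet_nodes = bsets$inlet_nodes, edge_nodes = bsets$edge_nodes,
         inlet_sides = bsets$inlet_sides),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' Default run configuration
#'
#' The fully-resolved configuration of a pipeline run: imaging thresholds,
#' mesh options and transport parameters (reference defaults).
#'
#' @return nested named list (YAML-serializable).
#' @export
default_config <- function() {
  p <- transport_params()
  list(
    pixel_size = 5,
    binarize_threshold = 0.2,
    inlet_sides = c("left", "right"),
    min_component_px = 10,
    connectivity = 8,
    mesh = list(grad_limit = 0.2, max_area_px = 25, simplify_tol_px = 0.5,
                boundary_spacing_px = 2, smooth_iters = 4),
    transport = list(D_vessel = p$D_vessel, D_tissue = p$D_tissue,
                     P_wall = p$P_wall, C_inlet = p$C_inlet,
                     kinetics_mode = p$kinetics_mode, R0 = p$R0,
                     R_max = p$R_max, K_M = p$K_M,
                     picard_tol = p$picard_tol,
                     picard_max_iter = p$picard_max_iter),
    organs = list())
}

#' Load a YAML run configuration over the defaults
#'
#' Keys present in the file override [default_config()]; everything else
#' keeps its default, and the fully-resolved configuration is echoed next
#' to the outputs of every run.
#'
#' @param path YAML file (NULL = pure defaults).
#' @return resolved configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  merge_into <- function(base, over) {
    for (nm in names(over)) {
      if (is.list(over[[nm]]) && is.list(base[[nm]]))
        base[[nm]] <- merge_into(base[[nm]], over[[nm]])
      else base[[nm]] <- over[[nm]]
    }
    base
  }
  merge_into(cfg, user)
}

# configuration -> constructor arguments
.config_params <- function(cfg) {
  tr <- cfg$transport
  organs <- cfg$organs
  if (length(organs)) names(organs) <- as.character(names(organs))
  transport_params(D_vessel = tr$D_vessel, D_tissue = tr$D_tissue,
                   P_wall = tr$P_wall, C_inlet = tr$C_inlet,
                   kinetics_mode = tr$kinetics_mode, R0 = tr$R0,
                   R_max = tr$R_max, K_M = tr$K_M, organs = organs,
                   picard_tol = tr$picard_tol,
                   picard_max_iter = tr$picard_max_iter)
}

.config_mesh_options <- function(cfg) {
  ps <- cfg$pixel_size
  m <- cfg$mesh
  list(grad_limit = m$grad_limit, max_area = m$max_area_px * ps^2,
       simplify_tol = m$simplify_tol_px * ps,
       boundary_spacing = m$boundary_spacing_px * ps,
       smooth_iters = m$smooth_iters)
}
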