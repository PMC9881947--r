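# Network-performance transport metrics.
#
# All concentration metrics are reported normalized to the inlet
# concentration; flux metrics are in model units (amount per second per
# unit thickness, with lengths in um).

#' Per-element concentration flux vectors
#'
#' `-D * grad(C)` on each element, exact for the P1 interpolant (constant
#' per element). Also reports the outward normal flux on vessel-tissue
#' interface edges when boundary sets are supplied.
#'
#' @param mesh a `domain_mesh`.
#' @param field a `conc_field`.
#' @param diffusivity scalar or per-element diffusivity.
#' @param bsets optional `boundary_sets`; adds `interface_normal_flux`.
#' @return list with `flux` (m x 2 matrix, NA rows where the field is not
#'   defined) and optionally `interface_normal_flux` (per interface edge).
#' @export
element_flux <- function(mesh, field, diffusivity = 1, bsets = NULL) {
  tri <- mesh$elements
  A <- mesh$areas
  vals <- field$values
  x <- matrix(mesh$nodes[tri, 1L], ncol = 3L)
  y <- matrix(mesh$nodes[tri, 2L], ncol = 3L)
  b <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L]) / (2 * A)
  cc <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L]) / (2 * A)
  cv <- matrix(vals[tri], ncol = 3L)
  D <- rep_len(diffusivity, nrow(tri))
  gx <- rowSums(cv * b)
  gy <- rowSums(cv * cc)
  flux <- cbind(-D * gx, -D * gy)
  out <- list(flux = flux)
  if (!is.null(bsets) && nrow(bsets$interface_edges)) {
    # owning vessel element of each interface edge
    ee <- .element_edges(mesh)
    ekey <- paste(pmin(bsets$interface_edges[, 1L], bsets$interface_edges[, 2L]),
                  pmax(bsets$interface_edges[, 1L], bsets$interface_edges[, 2L]))
    vess <- mesh$code[ee$elem] == 1
    pos <- match(ekey, ee$key[vess])
    own <- ee$elem[vess][pos]
    out$interface_normal_flux <-
      flux[own, 1L] * bsets$interface_normals[, 1L] +
      flux[own, 2L] * bsets$interface_normals[, 2L]
  }
  out
}

#' Net inlet oxygen influx (residual method)
#'
#' Total flux entering the domain through the Dirichlet (inlet) nodes,
#' computed from the reaction forces of the unconstrained operator:
#' `sum over inlet nodes of (K0 %*% C - F0)`. At steady state this equals
#' the interface outflux plus total consumption, so it measures the rate
#' of oxygen delivery of the network.
#'
#' @param field a `conc_field` whose system carries Dirichlet constraints.
#' @return scalar net influx (positive into the domain).
#' @export
total_flux <- function(field) {
  sys <- field$system
  if (is.null(sys) || is.null(sys$K0)) stop("field carries no constrained system")
  loc <- sys$map[sys$dirichlet_nodes]
  vals <- field$values[sys$nodes]
  r <- as.numeric(sys$K0 %*% vals - sys$F0)
  sum(r[loc])
}

#' Area-averaged normalized vessel oxygenation
#'
#' Element-area-weighted mean of the normalized concentration over
#' connected-vessel elements (element value = mean of its three nodes).
#'
#' @param mesh a `domain_mesh`.
#' @param vessel_field vessel-phase `conc_field`.
#' @return dimensionless scalar in (0, 1] for consumption-only kinetics.
#' @export
vascular_oxygen <- function(mesh, vessel_field) {
  sel <- mesh$code == 1
  if (!any(sel)) return(NA_real_)
  em <- rowMeans(matrix(vessel_field$normalized[mesh$elements[sel, , drop = FALSE]],
                        ncol = 3L))
  sum(em * mesh$areas[sel]) / sum(mesh$areas[sel])
}

#' Area-averaged normalized tissue oxygenation ("oxygen delivery")
#'
#' Same area weighting over tissue plus disconnected-vessel elements.
#' Undefined (NA) for an all-vessel image.
#'
#' @param mesh a `domain_mesh`.
#' @param tissue_field tissue-phase `conc_field`.
#' @return dimensionless scalar.
#' @export
oxygen_delivery <- function(mesh, tissue_field) {
  sel <- mesh$code != 1
  if (!any(sel) || isTRUE(tissue_field$empty)) return(NA_real_)
  em <- rowMeans(matrix(tissue_field$normalized[mesh$elements[sel, , drop = FALSE]],
                        ncol = 3L))
  sum(em * mesh$areas[sel]) / sum(mesh$areas[sel])
}

#' End-to-end network connectivity
#'
#' Re-classifies the image with the left edge as the only inlet, solves
#' the vessel phase, and returns the length-weighted mean normalized
#' concentration over vessel boundary edges on the right image edge: the
#' directional end-to-end oxygen transport capacity. Zero when no vessel
#' fed from the left reaches the right edge.
#'
#' @param dom a `domain_image`.
#' @param params a [transport_params()].
#' @param mesh_options named list passed to [build_mesh()].
#' @param min_component_px,connectivity_conn forwarded to
#'   [classify_domains()] for the single-inlet reclassification.
#' @return dimensionless scalar in `[0, 1]`.
#' @export
connectivity <- function(dom, params = transport_params(),
                         mesh_options = list(), min_component_px = 10,
                         connectivity_conn = 8) {
  stopifnot(inherits(dom, "domain_image"))
  bin <- binary_image((dom$codes > 0) * 1.0, dom$pixel_size)
  if (!any(bin$pixels > 0)) {
    warning("no vessel pixels; connectivity = 0")
    return(0)
  }
  dom1 <- suppressWarnings(
    classify_domains(bin, inlet_sides = "left",
                     min_component_px = min_component_px,
                     connectivity = connectivity_conn))
  if (!any(dom1$codes == 1)) {
    warning("no vessel touches the left inlet; connectivity = 0")
    return(0)
  }
  mesh <- do.call(build_mesh, c(list(dom1), mesh_options))
  bsets <- classify_nodes(mesh, "left")
  if (!length(bsets$inlet_nodes)) return(0)
  fld <- solve_vessel_phase(mesh, bsets, params)
  # vessel boundary edges on the right image edge
  ps <- mesh$pixel_size
  xr <- mesh$img_width * ps - 0.5 * ps
  ee <- .element_edges(mesh)
  vess <- mesh$code[ee$elem] == 1
  tab <- table(ee$key[vess])
  bkeys <- names(tab)[tab == 1L]
  bidx <- which(vess & ee$key %in% bkeys)
  u <- ee$u[bidx]; v <- ee$v[bidx]
  onr <- mesh$nodes[u, 1L] > xr & mesh$nodes[v, 1L] > xr
  if (!any(onr)) return(0)
  u <- u[onr]; v <- v[onr]
  len <- sqrt(rowSums((mesh$nodes[u, , drop = FALSE] -
                       mesh$nodes[v, , drop = FALSE])^2))
  ev <- (fld$normalized[u] + fld$normalized[v]) / 2
  if (anyNA(ev)) { len <- len[!is.na(ev)]; ev <- ev[!is.na(ev)] }
  if (!length(ev)) return(0)
  sum(ev * len) / sum(len)
}

#' Vessel coverage
#'
#' Percentage of image pixels occupied by vessel (connected or
#' disconnected).
#'
#' @param dom a `domain_image`.
#' @return percentage in `[0, 100]`.
#' @export
vessel_coverage <- function(dom) {
  stopifnot(inherits(dom, "domain_image"))
  100 * mean(dom$codes > 0)
}

#' All transport metrics for one image
#'
#' Runs the full two-phase solve plus the single-inlet connectivity solve
#' and collects the per-image network performance metrics.
#'
#' @param dom a `domain_image`.
#' @param params a [transport_params()].
#' @param inlet_sides inlet sides for the main solve.
#' @param mesh_options named list passed to [build_mesh()].
#' @param image_id identifier recorded in the output row.
#' @return one-row `data.frame`: `image_id`, `vessel_coverage`,
#'   `total_flux`, `interface_outflux`, `vascular_oxygen`,
#'   `oxygen_delivery`, `connectivity`, `mesh_mean_quality`, `n_elements`,
#'   `n_nodes`, `convergence_iters`.
#' @export
transport_metrics <- function(dom, params = transport_params(),
                              inlet_sides = c("left", "right"),
                              mesh_options = list(), image_id = "image") {
  sol <- solve_full(dom, params, inlet_sides, mesh_options)
  q <- element_quality(sol$mesh)
  conn <- connectivity(dom, params, mesh_options)
  outflux <- params$P_wall * sum(sol$boundary$interface_lengths)
  data.frame(
    image_id = image_id,
    vessel_coverage = vessel_coverage(dom),
    total_flux = total_flux(sol$vessel),
    interface_outflux = outflux,
    vascular_oxygen = vascular_oxygen(sol$mesh, sol$vessel),
    oxygen_delivery = oxygen_delivery(sol$mesh, sol$tissue),
    connectivity = conn,
    mesh_mean_quality = mean(q),
    n_elements = nrow(sol$mesh$elements),
    n_nodes = nrow(sol$mesh$nodes),
    convergence_iters = length(sol$tissue$convergence_trace),
    stringsAsFactors = FALSE)
}
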