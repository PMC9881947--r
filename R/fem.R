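# Galerkin P1 finite-element solution of the stationary two-phase oxygen
# transport problem.
#
# Phase 1 (connected vessels): pure diffusion with inlet Dirichlet
# concentration and a constant outward wall flux (Neumann) on the
# vessel-tissue interface. Phase 2 (tissue + disconnected vessels):
# diffusion with consumption, Dirichlet-coupled to the vessel solution at
# the interface nodes; the exterior image border is natural zero-flux.
# Michaelis-Menten consumption is linearized semi-implicitly and solved by
# Picard iteration.

#' Transport parameters
#'
#' Physical constants of the transport model. The defaults are the
#' reference parameter set for oxygen in microvascular networks:
#' `D_vessel = 3e-9`, `D_tissue = 2e-9` (diffusivities), `P_wall =
#' 2.75e-14` (constant outward trans-wall oxygen flux), `R_max = 0.06e-12`
#' and `K_M = 1e-3` (Michaelis-Menten consumption), with the inlet
#' concentration normalized to 1. These magnitudes are applied over the
#' mesh's micrometre coordinate system (see the methods vignette for the
#' unit convention and its rationale).
#'
#' @param D_vessel vessel oxygen diffusivity.
#' @param D_tissue tissue oxygen diffusivity.
#' @param P_wall constant outward oxygen flux across the vessel wall,
#'   applied per unit interface length.
#' @param C_inlet inlet oxygen concentration (default 1: normalized).
#' @param kinetics_mode tissue consumption model: `"michaelis_menten"`
#'   (rate `R_max * C / (K_M + C)`, the default since the reference
#'   constants are Michaelis-Menten constants), `"zero_order"` (constant
#'   rate `R0`) or `"none"`.
#' @param R0 zero-order consumption rate (defaults to `R_max`).
#' @param R_max maximum Michaelis-Menten consumption rate.
#' @param K_M Michaelis-Menten constant.
#' @param organs optional named list of per-organ-label overrides; each
#'   entry (name = label) may set `kinetics_mode`, `R0`, `R_max`, `K_M`,
#'   `D`.
#' @param picard_tol relative convergence tolerance of Picard iteration.
#' @param picard_max_iter iteration cap.
#' @return a `transport_params` list.
#' @export
transport_params <- function(D_vessel = 3e-9, D_tissue = 2e-9,
                             P_wall = 2.75e-14, C_inlet = 1.0,
                             kinetics_mode = c("michaelis_menten",
                                               "zero_order", "none"),
                             R0 = R_max, R_max = 0.06e-12, K_M = 1e-3,
                             organs = list(),
                             picard_tol = 1e-6, picard_max_iter = 100) {
  kinetics_mode <- match.arg(kinetics_mode)
  stopifnot(D_vessel > 0, D_tissue > 0, K_M > 0, R0 >= 0, R_max >= 0,
            P_wall >= 0, C_inlet > 0)
  structure(list(D_vessel = D_vessel, D_tissue = D_tissue, P_wall = P_wall,
                 C_inlet = C_inlet, kinetics_mode = kinetics_mode,
                 R0 = R0, R_max = R_max, K_M = K_M, organs = organs,
                 picard_tol = picard_tol, picard_max_iter = picard_max_iter),
            class = "transport_params")
}

# scatter-add: sum w into an n-vector at positions idx
.acc <- function(idx, w, n) {
  out <- numeric(n)
  tmp <- rowsum(w, idx)
  out[as.integer(rownames(tmp))] <- tmp[, 1L]
  out
}

# per-element kinetic/diffusive properties with organ overrides applied
.element_props <- function(mesh, elements, params, base_D) {
  n <- length(elements)
  out <- list(D = rep(base_D, n),
              mode = rep(params$kinetics_mode, n),
              R0 = rep(params$R0, n),
              R_max = rep(params$R_max, n),
              K_M = rep(params$K_M, n))
  labs <- mesh$organ[elements]
  for (lab in names(params$organs)) {
    sel <- labs == as.integer(lab)
    if (!any(sel)) next
    ov <- params$organs[[lab]]
    if (!is.null(ov$D)) out$D[sel] <- ov$D
    if (!is.null(ov$kinetics_mode)) out$mode[sel] <- ov$kinetics_mode
    if (!is.null(ov$R0)) out$R0[sel] <- ov$R0
    if (!is.null(ov$R_max)) out$R_max[sel] <- ov$R_max
    if (!is.null(ov$K_M)) out$K_M[sel] <- ov$K_M
  }
  bad <- setdiff(unique(out$mode), c("none", "zero_order", "michaelis_menten"))
  if (length(bad)) stop("unknown kinetics_mode: ", paste(bad, collapse = ", "))
  out
}

#' Assemble the P1 stiffness matrix and load vector
#'
#' Linear-triangle Galerkin assembly of the diffusion operator over a
#' subset of mesh elements, with an optional constant source per element
#' (lumped as `s * A / 3` onto each of its three nodes). Node numbering is
#' local to the subset; `nodes` maps local to global ids.
#'
#' @param mesh a `domain_mesh`.
#' @param elements element indices to assemble over.
#' @param diffusivity scalar or per-element diffusion coefficient.
#' @param source scalar or per-element constant volumetric source
#'   (negative = sink).
#' @return an `assembled_system`: `K` (sparse, local), `F`, `nodes`
#'   (global node ids), plus bookkeeping used by the solvers.
#' @export
fem_assemble <- function(mesh, elements = seq_len(nrow(mesh$elements)),
                         diffusivity = 1, source = 0) {
  stopifnot(inherits(mesh, "domain_mesh"), length(elements) >= 1L)
  tri <- mesh$elements[elements, , drop = FALSE]
  A <- mesh$areas[elements]
  if (any(A <= 0)) stop("zero-area element in assembly: ",
                        paste(elements[A <= 0][1:min(3, sum(A <= 0))],
                              collapse = ", "))
  nodes <- sort(unique(as.vector(tri)))
  map <- integer(nrow(mesh$nodes))
  map[nodes] <- seq_along(nodes)
  lt <- matrix(map[tri], ncol = 3L)
  n <- length(nodes)
  D <- rep_len(diffusivity, nrow(tri))
  s <- rep_len(source, nrow(tri))
  x <- matrix(mesh$nodes[tri, 1L], ncol = 3L)
  y <- matrix(mesh$nodes[tri, 2L], ncol = 3L)
  # P1 gradient coefficients: grad(phi_i) = (b_i, c_i)
  b <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L]) / (2 * A)
  cc <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L]) / (2 * A)
  ii <- jj <- xx <- vector("list", 9L)
  k <- 0L
  for (i in 1:3) for (j in 1:3) {
    k <- k + 1L
    ii[[k]] <- lt[, i]
    jj[[k]] <- lt[, j]
    xx[[k]] <- D * A * (b[, i] * b[, j] + cc[, i] * cc[, j])
  }
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(n, n))
  FF <- numeric(n)
  for (i in 1:3) FF <- FF + .acc(lt[, i], s * A / 3, n)
  structure(list(K = K, F = FF, nodes = nodes, map = map,
                 elements = elements, K0 = NULL, F0 = NULL,
                 dirichlet_nodes = integer(0), dirichlet_values = numeric(0)),
            class = "assembled_system")
}

#' Impose Dirichlet values by row replacement
#'
#' Constrained rows are replaced by identity rows with the prescribed
#' value on the right-hand side, so the solution attains the values
#' exactly. The unconstrained operator is kept (`K0`, `F0`) for residual
#' (reaction-force) flux computation.
#'
#' @param sys an `assembled_system`.
#' @param nodes global node ids.
#' @param values prescribed concentrations (recycled).
#' @return the modified `assembled_system`.
#' @export
apply_dirichlet <- function(sys, nodes, values) {
  stopifnot(inherits(sys, "assembled_system"))
  values <- rep_len(values, length(nodes))
  loc <- sys$map[nodes]
  if (any(loc == 0L)) stop("Dirichlet node not in the assembled system")
  dup <- duplicated(nodes)
  if (any(dup)) {
    first <- match(nodes[dup], nodes)
    if (any(values[dup] != values[first]))
      stop("conflicting duplicate Dirichlet prescriptions")
    loc <- loc[!dup]; values <- values[!dup]; nodes <- nodes[!dup]
  }
  if (is.null(sys$K0)) { sys$K0 <- sys$K; sys$F0 <- sys$F }
  K <- sys$K
  K[loc, ] <- 0
  K[cbind(loc, loc)] <- 1
  sys$K <- K
  sys$F[loc] <- values
  sys$dirichlet_nodes <- c(sys$dirichlet_nodes, nodes)
  sys$dirichlet_values <- c(sys$dirichlet_values, values)
  sys
}

#' Apply a constant outward Neumann flux on boundary edges
#'
#' Each edge of length `L` contributes `-flux * L / 2` to the load vector
#' at both end nodes (the consistent boundary integral of a constant
#' outward normal flux in the P1 weak form).
#'
#' @param sys an `assembled_system`.
#' @param edges e x 2 matrix of global node ids.
#' @param flux outward flux magnitude (positive = leaving the domain).
#' @param lengths optional edge lengths (um); computed from `mesh` node
#'   coordinates if `coords` given.
#' @param coords node coordinate matrix used to compute lengths when
#'   `lengths` is NULL.
#' @return the modified `assembled_system`.
#' @export
apply_neumann <- function(sys, edges, flux, lengths = NULL, coords = NULL) {
  stopifnot(inherits(sys, "assembled_system"))
  if (is.null(dim(edges))) edges <- matrix(edges, ncol = 2L)
  if (nrow(edges) == 0L || flux == 0) return(sys)
  lu <- sys$map[edges[, 1L]]
  lv <- sys$map[edges[, 2L]]
  if (any(lu == 0L) || any(lv == 0L))
    stop("Neumann edge endpoint not in the assembled system")
  if (is.null(lengths)) {
    if (is.null(coords)) stop("either lengths or coords must be supplied")
    lengths <- sqrt(rowSums((coords[edges[, 2L], , drop = FALSE] -
                             coords[edges[, 1L], , drop = FALSE])^2))
  }
  half <- flux * lengths / 2
  dF <- .acc(c(lu, lv), c(half, half), length(sys$F))
  sys$F <- sys$F - dF
  if (!is.null(sys$F0)) sys$F0 <- sys$F0 - dF
  sys
}

# direct sparse solve with an informative error on singular systems
.fem_solve <- function(K, FF, context) {
  out <- tryCatch(Matrix::solve(K, FF),
                  error = function(e) stop("linear solve failed (", context,
                                           "): ", conditionMessage(e),
                                           call. = FALSE))
  as.numeric(out)
}

.conc_field <- function(mesh, sys, local_values, phase, params,
                        trace = numeric(0)) {
  v <- rep(NA_real_, nrow(mesh$nodes))
  v[sys$nodes] <- local_values
  structure(list(values = v, normalized = v / params$C_inlet, phase = phase,
                 convergence_trace = trace, system = sys),
            class = "conc_field")
}

#' @export
print.conc_field <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("conc_field (%s phase): %d nodes, range [%.4g, %.4g]",
              x$phase, length(v), min(v), max(v)))
  if (length(x$convergence_trace))
    cat(sprintf(", Picard %d iters (last residual %.2e)",
                length(x$convergence_trace),
                x$convergence_trace[length(x$convergence_trace)]))
  cat("\n")
  invisible(x)
}

#' Solve the vessel (connected-network) phase
#'
#' Pure diffusion over connected-vessel elements with the inlet Dirichlet
#' concentration and a constant outward wall flux on vessel-tissue
#' interface edges. No bulk reaction occurs in the vessel phase.
#'
#' @param mesh a `domain_mesh`.
#' @param bsets a `boundary_sets` from [classify_nodes()].
#' @param params a [transport_params()].
#' @return a `conc_field` over the vessel nodes (NA elsewhere).
#' @export
solve_vessel_phase <- function(mesh, bsets, params = transport_params()) {
  elems <- which(mesh$code == 1)
  if (!length(elems) || !length(bsets$inlet_nodes))
    stop("no vessel reaches an inlet face")
  sys <- fem_assemble(mesh, elems, diffusivity = params$D_vessel)
  sys <- apply_neumann(sys, bsets$interface_edges, params$P_wall,
                       lengths = bsets$interface_lengths)
  sys <- apply_dirichlet(sys, bsets$inlet_nodes, params$C_inlet)
  vals <- .fem_solve(sys$K, sys$F, "vessel phase")
  .conc_field(mesh, sys, vals, "vessel", params)
}

#' Picard iteration for Michaelis-Menten consumption
#'
#' Semi-implicit lagged linearization: iteration k+1 solves the linear
#' system in which the reaction term `R_max * C / (K_M + C)` is replaced by
#' `[R_max / (K_M + C_k)] * C`, the bracketed coefficient evaluated at the
#' previous iterate and lumped onto the diagonal as `A/3` nodal masses.
#' This keeps the operator an M-matrix (solutions stay positive) and
#' converges linearly. The initial guess is the mean Dirichlet value.
#'
#' @param mesh a `domain_mesh`.
#' @param sys an `assembled_system` over the reacting (plus passive)
#'   elements, diffusion only, before Dirichlet imposition.
#' @param dirichlet_nodes,dirichlet_values interface Dirichlet data
#'   (global ids).
#' @param mm_elements indices (into `sys$elements`) of elements carrying
#'   Michaelis-Menten kinetics.
#' @param R_max,K_M per-`mm_elements` kinetic constants.
#' @param tol relative convergence tolerance on the max nodal change.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   residual trace.
#' @param extra_sink optional fixed per-node sink vector (local numbering),
#'   e.g. from zero-order elements solved alongside.
#' @return list `values` (local), `trace` (per-iteration residuals).
#' @export
picard_iterate <- function(mesh, sys, dirichlet_nodes, dirichlet_values,
                           mm_elements, R_max, K_M, tol = 1e-6,
                           max_iter = 100, extra_sink = NULL) {
  n <- length(sys$nodes)
  tri_mm <- matrix(sys$map[mesh$elements[sys$elements[mm_elements], ,
                                         drop = FALSE]], ncol = 3L)
  A_mm <- mesh$areas[sys$elements[mm_elements]]
  loc_dir <- sys$map[dirichlet_nodes]
  C <- rep(mean(dirichlet_values), n)
  trace <- numeric(0)
  F_base <- sys$F
  if (!is.null(extra_sink)) F_base <- F_base + extra_sink
  for (it in seq_len(max_iter)) {
    # lumped reaction coefficient on the diagonal, lagged at C^(k)
    coefs <- numeric(n)
    for (i in 1:3) {
      idx <- tri_mm[, i]
      coefs <- coefs + .acc(idx, (A_mm / 3) * R_max / (K_M + pmax(C[idx], 0)), n)
    }
    K <- sys$K + Matrix::Diagonal(n, coefs)
    FF <- F_base
    K[loc_dir, ] <- 0
    K[cbind(loc_dir, loc_dir)] <- 1
    FF[loc_dir] <- dirichlet_values
    Cn <- .fem_solve(K, FF, "Picard iteration")
    res <- max(abs(Cn - C)) / max(max(abs(Cn)), 1e-300)
    trace <- c(trace, res)
    C <- Cn
    if (res < tol) break
  }
  if (trace[length(trace)] >= tol) {
    err <- simpleError(sprintf(
      "Picard iteration did not converge in %d iterations (last residual %.3e)",
      max_iter, trace[length(trace)]))
    err$trace <- trace
    stop(err)
  }
  list(values = C, trace = trace)
}

#' Solve the tissue (+ disconnected vessel) phase
#'
#' Diffusion-consumption over the union of tissue elements (tissue
#' diffusivity, reaction active) and disconnected-vessel elements (vessel
#' diffusivity, no reaction), with Dirichlet values at the vessel-tissue
#' interface taken from the vessel-phase solution and natural zero-flux on
#' the exterior image border. Organ-labelled elements use their per-organ
#' parameter overrides.
#'
#' After a zero-order solve, elements whose three nodal values are all
#' non-positive have their sink disabled and the system is re-solved (at
#' most 20 passes): a constant sink has no intrinsic positivity and would
#' otherwise drive far-from-vessel tissue to nonphysical negative
#' plateaus.
#'
#' @inheritParams solve_vessel_phase
#' @param vessel_field `conc_field` from [solve_vessel_phase()].
#' @return a `conc_field` over tissue + disconnected-vessel nodes.
#' @export
solve_tissue_phase <- function(mesh, vessel_field, bsets,
                               params = transport_params()) {
  elems <- which(mesh$code != 1)
  if (!length(elems)) {
    return(structure(list(values = rep(NA_real_, nrow(mesh$nodes)),
                          normalized = rep(NA_real_, nrow(mesh$nodes)),
                          phase = "tissue", convergence_trace = numeric(0),
                          system = NULL, empty = TRUE),
                     class = "conc_field"))
  }
  if (!length(bsets$edge_nodes))
    stop("tissue phase has no vessel interface to take Dirichlet values from")
  dir_vals <- vessel_field$values[bsets$edge_nodes]
  if (anyNA(dir_vals))
    stop("vessel field does not cover all interface nodes")
  is_disc <- mesh$code[elems] == 0.5
  props <- .element_props(mesh, elems, params, base_D = params$D_tissue)
  props$D[is_disc] <- params$D_vessel
  props$mode[is_disc] <- "none"   # no consumption inside vessel lumina
  sys <- fem_assemble(mesh, elems, diffusivity = props$D)
  A <- mesh$areas[elems]
  n <- length(sys$nodes)
  lt <- matrix(sys$map[mesh$elements[elems, , drop = FALSE]], ncol = 3L)

  zo <- which(props$mode == "zero_order")
  mm <- which(props$mode == "michaelis_menten")
  zo_active <- rep(TRUE, length(zo))
  trace <- numeric(0)

  zo_sink <- function(active) {
    s <- numeric(n)
    if (!length(zo)) return(s)
    az <- zo[active]
    if (!length(az)) return(s)
    for (i in 1:3) s <- s - .acc(lt[az, i], props$R0[az] * A[az] / 3, n)
    s
  }

  for (pass in 1:20) {
    if (length(mm)) {
      out <- picard_iterate(mesh, sys, bsets$edge_nodes, dir_vals,
                            mm_elements = mm, R_max = props$R_max[mm],
                            K_M = props$K_M[mm], tol = params$picard_tol,
                            max_iter = params$picard_max_iter,
                            extra_sink = zo_sink(zo_active))
      vals <- out$values
      trace <- out$trace
    } else {
      s2 <- sys
      s2$F <- s2$F + zo_sink(zo_active)
      s2 <- apply_dirichlet(s2, bsets$edge_nodes, dir_vals)
      vals <- .fem_solve(s2$K, s2$F, "tissue phase")
    }
    if (!length(zo)) break
    allneg <- vals[lt[zo, 1L]] <= 0 & vals[lt[zo, 2L]] <= 0 &
              vals[lt[zo, 3L]] <= 0
    newly <- zo_active & allneg
    if (!any(newly)) break
    zo_active <- zo_active & !allneg
  }

  sysd <- sys
  sysd$F <- sysd$F + zo_sink(zo_active)
  sysd <- apply_dirichlet(sysd, bsets$edge_nodes, dir_vals)
  fld <- .conc_field(mesh, sysd, vals, "tissue", params, trace = trace)
  fld$zero_order_disabled <- if (length(zo)) sum(!zo_active) else 0L
  fld
}

#' Run the full image-to-physics pipeline on a domain image
#'
#' Meshes the domain image, classifies boundary nodes, solves the vessel
#' phase and then the tissue phase. Deterministic given identical inputs
#' and options.
#'
#' @param dom a `domain_image`.
#' @param params a [transport_params()].
#' @param inlet_sides inlet image sides, subset of `c("left", "right")`.
#' @param mesh_options named list passed to [build_mesh()].
#' @return a `transport_solution`: list with `mesh`, `boundary`, `vessel`
#'   and `tissue` fields, plus the parameters used.
#' @export
solve_full <- function(dom, params = transport_params(),
                       inlet_sides = c("left", "right"),
                       mesh_options = list()) {
  stopifnot(inherits(dom, "domain_image"))
  mesh <- tryCatch(do.call(build_mesh, c(list(dom), mesh_options)),
                   error = function(e) stop("meshgen: ", conditionMessage(e),
                                            call. = FALSE))
  if (!any(mesh$code == 1)) stop("fem: no vessel reaches an inlet face")
  bsets <- classify_nodes(mesh, inlet_sides)
  vessel <- tryCatch(solve_vessel_phase(mesh, bsets, params),
                     error = function(e) stop("fem (vessel): ",
                                              conditionMessage(e),
                                              call. = FALSE))
  tissue <- tryCatch(solve_tissue_phase(mesh, vessel, bsets, params),
                     error = function(e) stop("fem (tissue): ",
                                              conditionMessage(e),
                                              call. = FALSE))
  structure(list(mesh = mesh, boundary = bsets, vessel = vessel,
                 tissue = tissue, params = params,
                 inlet_sides = inlet_sides),
            class = "transport_solution")
}

#' @export
print.transport_solution <- function(x, ...) {
  cat("transport_solution\n")
  print(x$mesh)
  print(x$vessel)
  if (!isTRUE(x$tissue$empty)) print(x$tissue)
  invisible(x)
}
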