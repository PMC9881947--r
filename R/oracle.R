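# Independent verification oracles: a 5-point finite-difference solver on
# the pixel grid and closed-form 1D solutions. These never touch the FEM
# path; they exist so the finite-element solution can be checked against
# an independent discretization of the same boundary-value problem.

#' Closed-form 1D slab solution with zero-order consumption
#'
#' Steady diffusion across a slab of width `L` with both faces held at
#' `C0` and constant consumption `R0`:
#' `C(x) = C0 - (R0 / (2 D)) * x * (L - x)`.
#'
#' @param x position(s) in `[0, L]`.
#' @param C0 face concentration.
#' @param R0 zero-order consumption rate.
#' @param D diffusivity.
#' @param L slab width.
#' @return concentration at `x`.
#' @export
closed_form_slab <- function(x, C0, R0, D, L) {
  stopifnot(all(x >= -1e-9), all(x <= L + 1e-9))
  C0 - (R0 / (2 * D)) * x * (L - x)
}

#' Finite-difference oracle for the two-phase transport problem
#'
#' 5-point finite-difference discretization of the same boundary-value
#' problem the FEM solves, on the pixel grid (unknowns at pixel centers,
#' spacing = pixel size): inlet vessel pixels are Dirichlet, vessel pixels
#' facing non-vessel pixels lose the wall flux through that face, the
#' tissue phase takes Dirichlet values from vessel pixels adjacent to the
#' interface, heterogeneous diffusivities are face-harmonic-averaged, and
#' Michaelis-Menten consumption uses the same lagged-coefficient Picard
#' linearization. Intended for small images (<= 256 x 256).
#'
#' @param dom a `domain_image`.
#' @param params a [transport_params()].
#' @param phase `"vessel"` or `"tissue"`.
#' @param inlet_sides inlet sides for the vessel phase.
#' @param vessel_grid optional vessel-phase oracle output (matrix) reused
#'   for the tissue Dirichlet values; computed on the fly if missing.
#' @return H x W matrix of concentrations (NA outside the phase).
#' @export
fd_oracle <- function(dom, params = transport_params(),
                      phase = c("vessel", "tissue"),
                      inlet_sides = c("left", "right"), vessel_grid = NULL) {
  stopifnot(inherits(dom, "domain_image"))
  phase <- match.arg(phase)
  inlet_sides <- match.arg(inlet_sides, c("left", "right"), several.ok = TRUE)
  H <- dom$height; W <- dom$width
  h <- dom$pixel_size
  codes <- dom$codes

  if (phase == "vessel") {
    unk <- which(codes == 1)
    if (!length(unk)) stop("no connected-vessel pixels")
    dir_mask <- matrix(FALSE, H, W)
    if ("left" %in% inlet_sides) dir_mask[, 1L] <- TRUE
    if ("right" %in% inlet_sides) dir_mask[, W] <- TRUE
    dir_mask <- dir_mask & codes == 1
    Dpix <- matrix(params$D_vessel, H, W)
    sol <- .fd_solve(codes == 1, dir_mask, matrix(params$C_inlet, H, W),
                     Dpix, h, wall_flux = params$P_wall,
                     wall_against = codes != 1,
                     react_mode = matrix("none", H, W),
                     R0 = matrix(0, H, W), R_max = matrix(0, H, W),
                     K_M = matrix(1, H, W), params = params)
    return(sol)
  }

  # tissue phase
  if (is.null(vessel_grid))
    vessel_grid <- fd_oracle(dom, params, "vessel", inlet_sides)
  in_phase <- codes != 1
  if (!any(in_phase)) stop("no tissue pixels")
  # Dirichlet at phase pixels 4-adjacent to a connected-vessel pixel
  nb_vessel_val <- matrix(NA_real_, H, W)
  nb_count <- matrix(0, H, W)
  shift <- function(m, dr, dc) {
    out <- matrix(NA, nrow(m), ncol(m))
    rs <- seq_len(H) + dr; cs <- seq_len(W) + dc
    ok_r <- rs >= 1 & rs <= H; ok_c <- cs >= 1 & cs <= W
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    vv <- shift(vessel_grid, d[1], d[2])
    isv <- !is.na(vv) & shift(codes, d[1], d[2]) == 1
    isv[is.na(isv)] <- FALSE
    add <- ifelse(isv, vv, 0)
    nb_vessel_val[is.na(nb_vessel_val) & isv] <- 0
    nb_vessel_val[isv] <- nb_vessel_val[isv] + add[isv]
    nb_count <- nb_count + isv
  }
  dir_mask <- in_phase & nb_count > 0
  dir_vals <- matrix(0, H, W)
  dir_vals[dir_mask] <- nb_vessel_val[dir_mask] / nb_count[dir_mask]

  Dpix <- matrix(params$D_tissue, H, W)
  Dpix[codes == 0.5] <- params$D_vessel
  mode <- matrix(params$kinetics_mode, H, W)
  mode[codes == 0.5] <- "none"
  R0m <- matrix(params$R0, H, W)
  Rmm <- matrix(params$R_max, H, W)
  KMm <- matrix(params$K_M, H, W)
  for (lab in names(params$organs)) {
    sel <- dom$organ == as.integer(lab) & codes == 0
    ov <- params$organs[[lab]]
    if (!is.null(ov$D)) Dpix[sel] <- ov$D
    if (!is.null(ov$kinetics_mode)) mode[sel] <- ov$kinetics_mode
    if (!is.null(ov$R0)) R0m[sel] <- ov$R0
    if (!is.null(ov$R_max)) Rmm[sel] <- ov$R_max
    if (!is.null(ov$K_M)) KMm[sel] <- ov$K_M
  }
  .fd_solve(in_phase, dir_mask, dir_vals, Dpix, h, wall_flux = 0,
            wall_against = matrix(FALSE, H, W), react_mode = mode,
            R0 = R0m, R_max = Rmm, K_M = KMm, params = params)
}

# Core 5-point solver. in_phase: logical grid of unknowns; dir_mask pixels
# are held at dir_vals; faces against wall_against pixels carry an outward
# wall flux; faces against anything else outside the phase (or the image
# border) are zero-flux. Reaction active where react_mode != "none" and
# the pixel is not Dirichlet.
.fd_solve <- function(in_phase, dir_mask, dir_vals, Dpix, h, wall_flux,
                      wall_against, react_mode, R0, R_max, K_M, params) {
  H <- nrow(in_phase); W <- ncol(in_phase)
  idx <- which(in_phase)
  n <- length(idx)
  gidx <- matrix(0L, H, W)
  gidx[idx] <- seq_len(n)
  rr <- (idx - 1L) %% H + 1L
  cc <- (idx - 1L) %/% H + 1L
  ii <- list(); jj <- list(); xx <- list()
  diag_add <- numeric(n)
  rhs <- numeric(n)
  wall_loss <- numeric(n)
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    nr <- rr + d[1L]; nc <- cc + d[2L]
    inside <- nr >= 1L & nr <= H & nc >= 1L & nc <= W
    nidx <- ifelse(inside, (pmax(nc, 1L) - 1L) * H + pmax(nr, 1L), NA_integer_)
    nb_in <- inside & in_phase[ifelse(is.na(nidx), 1L, nidx)]
    # conduction across shared faces (harmonic-mean diffusivity)
    sel <- which(nb_in)
    if (length(sel)) {
      Dh <- 2 / (1 / Dpix[idx[sel]] + 1 / Dpix[nidx[sel]])
      w <- Dh / h^2
      ii[[length(ii) + 1L]] <- seq_len(n)[sel]
      jj[[length(jj) + 1L]] <- gidx[nidx[sel]]
      xx[[length(xx) + 1L]] <- -w
      diag_add[sel] <- diag_add[sel] + w
    }
    # wall flux through faces against the opposing phase
    wsel <- which(inside & !nb_in &
                    wall_against[ifelse(is.na(nidx), 1L, nidx)])
    if (length(wsel) && wall_flux != 0)
      wall_loss[wsel] <- wall_loss[wsel] + wall_flux / h
  }
  rhs <- rhs - wall_loss
  dl <- gidx[which(dir_mask & in_phase)]
  is_dir <- logical(n); is_dir[dl] <- TRUE
  mode_v <- react_mode[idx]
  react <- mode_v != "none" & !is_dir
  zo <- which(react & mode_v == "zero_order")
  mm <- which(react & mode_v == "michaelis_menten")

  Kbase <- Matrix::sparseMatrix(i = c(unlist(ii), seq_len(n)),
                                j = c(unlist(jj), seq_len(n)),
                                x = c(unlist(xx), diag_add),
                                dims = c(n, n))
  solve_once <- function(extra_diag, extra_rhs) {
    K <- Kbase + Matrix::Diagonal(n, extra_diag)
    FF <- rhs + extra_rhs
    K[dl, ] <- 0
    K[cbind(dl, dl)] <- 1
    FF[dl] <- dir_vals[idx[dl]]
    as.numeric(Matrix::solve(K, FF))
  }

  zo_active <- rep(TRUE, length(zo))
  C <- NULL
  for (pass in 1:20) {
    er <- numeric(n)
    if (length(zo)) er[zo[zo_active]] <- -R0[idx[zo[zo_active]]]
    if (length(mm)) {
      Ck <- if (is.null(C)) rep(mean(dir_vals[idx[dl]]), n) else C
      for (it in seq_len(params$picard_max_iter)) {
        ed <- numeric(n)
        ed[mm] <- R_max[idx[mm]] / (K_M[idx[mm]] + pmax(Ck[mm], 0))
        Cn <- solve_once(ed, er)
        res <- max(abs(Cn - Ck)) / max(max(abs(Cn)), 1e-300)
        Ck <- Cn
        if (res < params$picard_tol) break
      }
      C <- Ck
    } else {
      C <- solve_once(numeric(n), er)
    }
    if (!length(zo)) break
    neg <- C[zo] <= 0
    newly <- zo_active & neg
    if (!any(newly)) break
    zo_active <- zo_active & !neg
  }
  out <- matrix(NA_real_, H, W)
  out[idx] <- C
  out
}

#' Sample a nodal FEM field at the pixel containing each node
#'
#' Nearest-pixel sampling used to compare FEM nodal values against the
#' finite-difference oracle grid.
#'
#' @param mesh a `domain_mesh`.
#' @param grid H x W oracle matrix.
#' @param nodes node ids to sample (default: all with a defined pixel).
#' @return numeric vector of oracle values at the nodes' pixels.
#' @export
sample_grid_at_nodes <- function(mesh, grid, nodes = seq_len(nrow(mesh$nodes))) {
  ps <- mesh$pixel_size
  H <- mesh$img_height; W <- mesh$img_width
  x <- mesh$nodes[nodes, 1L] / ps
  y <- mesh$nodes[nodes, 2L] / ps
  col <- pmin(pmax(ceiling(x), 1L), W)
  row <- pmin(pmax(ceiling(H - y + 1e-9), 1L), H)
  grid[cbind(row, col)]
}
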