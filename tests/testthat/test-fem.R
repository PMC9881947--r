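test_that("P1 assembly reproduces hand-integrated element matrices", {
  msh <- structure(list(
    nodes = rbind(c(0, 0), c(1, 0), c(0, 1)),
    elements = matrix(c(1L, 2L, 3L), 1), code = 1, organ = 0L,
    areas = 0.5, pixel_size = 1, img_height = 1, img_width = 1),
    class = "domain_mesh")
  K <- as.matrix(fem_assemble(msh, 1L, diffusivity = 1)$K)
  expect_equal(K, 0.5 * rbind(c(2, -1, -1), c(-1, 1, 0), c(-1, 0, 1)),
               tolerance = 1e-12)
  # constant source s = 3 on a unit-area element: each node receives 1
  msh$nodes <- rbind(c(0, 0), c(2, 0), c(0, 1))
  msh$areas <- 1
  FF <- fem_assemble(msh, 1L, diffusivity = 1, source = 3)$F
  expect_equal(FF, c(1, 1, 1))
})

test_that("unconstrained stiffness annihilates constants", {
  dom <- fix_channel(60, 40, 12)
  m <- build_mesh(dom)
  sys <- fem_assemble(m, diffusivity = 2)
  ones <- rep(1, length(sys$nodes))
  expect_lt(max(abs(sys$K %*% ones)), 1e-9)
  # symmetric to machine tolerance
  expect_lt(max(abs(sys$K - Matrix::t(sys$K))), 1e-9)
})

test_that("Dirichlet rows are imposed exactly", {
  m <- build_mesh(fix_channel(60, 40, 12))
  b <- classify_nodes(m)
  sys <- fem_assemble(m, which(m$code == 1), diffusivity = 1)
  # prescribing every node returns exactly the prescribed vector
  sys_all <- apply_dirichlet(sys, sys$nodes, 0.7)
  expect_equal(as.numeric(Matrix::solve(sys_all$K, sys_all$F)),
               rep(0.7, length(sys$nodes)))
  # conflicting duplicates are an error
  expect_error(apply_dirichlet(sys, c(b$inlet_nodes[1], b$inlet_nodes[1]),
                               c(1, 0.5)), "conflicting")
  # two inlet values: solution bounded by them (maximum principle)
  x <- m$nodes[, 1]
  left <- intersect(b$inlet_nodes, which(x < 0.5))
  right <- intersect(b$inlet_nodes, which(x > 59.5))
  s2 <- apply_dirichlet(sys, left, 1.0)
  s2 <- apply_dirichlet(s2, right, 0.5)
  v <- as.numeric(Matrix::solve(s2$K, s2$F))
  expect_gte(min(v), 0.5 - 1e-9)
  expect_lte(max(v), 1.0 + 1e-9)
  # and the profile is the exact 1D linear interpolant; midpoint 0.75
  expect_equal(v, 1 - 0.5 * m$nodes[sys$nodes, 1] / 60, tolerance = 1e-9)
})

test_that("Neumann edges subtract flux * L / 2 per end node", {
  m <- fix_square_mesh()
  sys <- fem_assemble(m, diffusivity = 1)
  s0 <- apply_neumann(sys, rbind(c(1L, 2L)), flux = 0, coords = m$nodes)
  expect_equal(s0$F, sys$F)
  # edge (1,2) has length 1 -> each endpoint loses flux * 0.5
  s1 <- apply_neumann(sys, rbind(c(1L, 2L)), flux = 2, coords = m$nodes)
  expect_equal(s1$F - sys$F, c(-1, -1, 0, 0))
  expect_error(apply_neumann(sys, rbind(c(1L, 99L)), 1, coords = m$nodes))
})

test_that("vessel phase: uniform and wall-flux solutions match theory", {
  dom <- fix_channel()
  b0 <- transport_params(P_wall = 0, kinetics_mode = "none")
  sol <- solve_full(dom, b0)
  v <- sol$vessel$values[!is.na(sol$vessel$values)]
  expect_lt(max(abs(v - 1)), 1e-10)

  # monotonicity in P_wall: larger wall flux lowers every nodal value
  m <- sol$mesh; bs <- sol$boundary
  p1 <- transport_params(P_wall = 5e-13, kinetics_mode = "none")
  p2 <- transport_params(P_wall = 1e-12, kinetics_mode = "none")
  f1 <- solve_vessel_phase(m, bs, p1)
  f2 <- solve_vessel_phase(m, bs, p2)
  d <- f2$values - f1$values
  expect_lte(max(d, na.rm = TRUE), 1e-12)
  expect_lt(min(d, na.rm = TRUE), 0)
})

test_that("tissue phase reproduces the zero-order slab parabola", {
  s <- fix_slab()
  p <- transport_params(P_wall = 0, kinetics_mode = "zero_order",
                        R0 = s$R0, D_tissue = s$D)
  sol <- solve_full(s$dom, p)
  tn <- sol$tissue$system$nodes
  tx <- sol$mesh$nodes[tn, 1]
  sel <- tx >= s$x0 & tx <= s$x0 + s$L
  expected <- closed_form_slab(tx[sel] - s$x0, 1, s$R0, s$D, s$L)
  expect_lt(max(abs(sol$tissue$values[tn][sel] - expected)), 0.01)
  centre <- which.min(abs(tx - (s$x0 + s$L / 2)))
  expect_equal(sol$tissue$values[tn][centre], 0.5, tolerance = 0.01)
  # zero reaction, uniform interface Dirichlet 1 -> identically 1
  p0 <- transport_params(P_wall = 0, kinetics_mode = "none")
  sol0 <- solve_full(s$dom, p0)
  tv <- sol0$tissue$values[!is.na(sol0$tissue$values)]
  expect_lt(max(abs(tv - 1)), 1e-10)
})

test_that("zero-order sink positivity guard activates on sparse networks", {
  # strong sink: far tissue would go negative without the guard
  dom <- fix_network(seed = 5, coverage = 25, size = 64)
  D <- 2e-9
  # decay length sqrt(2 D / R0) = 50 um (10 px at 5 um/px): far tissue
  # would sit on a negative plateau without the guard
  p <- transport_params(P_wall = 0, kinetics_mode = "zero_order",
                        R0 = 8e-4 * D, D_tissue = D)
  sol <- solve_full(dom, p)
  tv <- sol$tissue$values[sol$tissue$system$nodes]
  expect_gt(sol$tissue$zero_order_disabled, 0)
  expect_gt(min(tv), -0.05)  # no deep negative plateaus remain
})

test_that("Michaelis-Menten Picard iteration converges and orders correctly", {
  s <- fix_slab()
  # R_max = 0 converges immediately to the linear solution
  pr0 <- transport_params(P_wall = 0, kinetics_mode = "michaelis_menten",
                          R_max = 0, D_tissue = s$D)
  sol0 <- solve_full(s$dom, pr0)
  expect_equal(length(sol0$tissue$convergence_trace), 1L)
  tv0 <- sol0$tissue$values[!is.na(sol0$tissue$values)]
  expect_lt(max(abs(tv0 - 1)), 1e-9)

  # C >> K_M: MM approaches the zero-order solution with rate R_max
  pz <- transport_params(P_wall = 0, kinetics_mode = "zero_order",
                         R0 = s$R0, D_tissue = s$D)
  solz <- solve_full(s$dom, pz)
  pm <- transport_params(P_wall = 0, kinetics_mode = "michaelis_menten",
                         R_max = s$R0, K_M = 1e-6, D_tissue = s$D)
  solm <- solve_full(s$dom, pm)
  tn <- solz$tissue$system$nodes
  expect_lt(max(abs(solm$tissue$values[tn] - solz$tissue$values[tn])), 0.01)

  # at a physiological K_M the MM field dominates zero-order nodewise
  pm2 <- transport_params(P_wall = 0, kinetics_mode = "michaelis_menten",
                          R_max = s$R0, K_M = 0.3, D_tissue = s$D)
  solm2 <- solve_full(s$dom, pm2)
  expect_true(all(solm2$tissue$values[tn] - solz$tissue$values[tn] >= -1e-9))
  # residual trace decreases monotonically
  tr <- solm2$tissue$convergence_trace
  expect_true(all(diff(tr) <= 0))
  expect_lt(tr[length(tr)], 1e-6)
})

test_that("solve_full propagates stage errors and handles edge images", {
  expect_warning(dom0 <- classify_domains(binary_image(matrix(0, 16, 16), 1)))
  expect_error(solve_full(dom0), "no vessel reaches an inlet face")
  # all-white image: vessel field only, tissue empty
  solw <- solve_full(domain_image(matrix(1, 16, 16), pixel_size = 1),
                     transport_params(P_wall = 0, kinetics_mode = "none"))
  expect_true(isTRUE(solw$tissue$empty))
  expect_false(anyNA(solw$vessel$values))
})

test_that("an organ label with tissue kinetics leaves the solution unchanged", {
  dom <- fix_network(seed = 5, coverage = 25, size = 64)
  mask <- matrix(0L, 64, 64); mask[40:52, 20:34] <- 1L
  domi <- apply_region_labels(dom, mask)
  p <- transport_params(P_wall = 0, kinetics_mode = "zero_order",
                        R0 = 2e-4 * 2e-9, D_tissue = 2e-9)
  p_same <- p; p_same$organs <- list(`1` = list())  # label, no overrides
  sol_a <- solve_full(dom, p)
  sol_b <- solve_full(domi, p_same)
  # the organ boundary is meshed conformingly, so node sets differ; with
  # identical kinetics the transport result must nevertheless agree to
  # discretization accuracy
  expect_equal(oxygen_delivery(sol_b$mesh, sol_b$tissue),
               oxygen_delivery(sol_a$mesh, sol_a$tissue), tolerance = 2e-3)
  expect_equal(vascular_oxygen(sol_b$mesh, sol_b$vessel),
               vascular_oxygen(sol_a$mesh, sol_a$vessel), tolerance = 2e-3)
  # a metabolically more active organ lowers tissue oxygenation
  p_hot <- p
  p_hot$organs <- list(`1` = list(R0 = 10 * p$R0))
  sol_c <- solve_full(domi, p_hot)
  expect_lt(oxygen_delivery(sol_c$mesh, sol_c$tissue),
            oxygen_delivery(sol_b$mesh, sol_b$tissue))
})

test_that("mirror-symmetric images give mirror-consistent oxygenation", {
  dom <- fix_network(seed = 7, coverage = 30, size = 64)
  p <- transport_params(kinetics_mode = "michaelis_menten")
  sol_a <- solve_full(dom, p)
  sol_b <- solve_full(mirror_dom(dom), p)
  expect_equal(vascular_oxygen(sol_b$mesh, sol_b$vessel),
               vascular_oxygen(sol_a$mesh, sol_a$vessel), tolerance = 5e-3)
  expect_equal(oxygen_delivery(sol_b$mesh, sol_b$tissue),
               oxygen_delivery(sol_a$mesh, sol_a$tissue), tolerance = 5e-3)
})
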