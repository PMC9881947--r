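test_that("element flux is exact for P1 fields", {
  m <- build_mesh(fix_channel(60, 40, 12))
  # uniform field -> zero flux
  f_uniform <- list(values = rep(1, nrow(m$nodes)),
                    normalized = rep(1, nrow(m$nodes)))
  fl <- element_flux(m, f_uniform, diffusivity = 1)
  expect_lt(max(abs(fl$flux)), 1e-10)
  # linear field C = x with D = 1 -> flux (-1, 0) in every element
  f_lin <- list(values = m$nodes[, 1], normalized = m$nodes[, 1])
  fl2 <- element_flux(m, f_lin, diffusivity = 1)
  expect_equal(fl2$flux[, 1], rep(-1, nrow(m$elements)), tolerance = 1e-9)
  expect_lt(max(abs(fl2$flux[, 2])), 1e-9)
})

test_that("total inlet flux balances wall outflux and scales linearly", {
  dom <- fix_channel()
  # no sink, equal Dirichlet both ends: zero net flux
  sol0 <- solve_full(dom, transport_params(P_wall = 0, kinetics_mode = "none"))
  expect_lt(abs(total_flux(sol0$vessel)), 1e-12)
  # with wall flux: influx = P_wall * interface perimeter within 1%
  p <- transport_params(P_wall = 1e-12, kinetics_mode = "none")
  sol <- solve_full(dom, p)
  S <- sum(sol$boundary$interface_lengths)
  expect_equal(total_flux(sol$vessel), p$P_wall * S, tolerance = 0.01)
  # doubling P_wall doubles the influx (linearity)
  p2 <- transport_params(P_wall = 2e-12, kinetics_mode = "none")
  sol2 <- solve_full(dom, p2)
  expect_equal(total_flux(sol2$vessel) / total_flux(sol$vessel), 2,
               tolerance = 0.01)
})

test_that("tissue consumption balances interface influx (conservation)", {
  s <- fix_slab()
  p <- transport_params(P_wall = 0, kinetics_mode = "zero_order",
                        R0 = s$R0, D_tissue = s$D)
  sol <- solve_full(s$dom, p)
  influx <- total_flux(sol$tissue)
  consumed <- s$R0 * sum(sol$mesh$areas[sol$mesh$code == 0])
  expect_equal(influx, consumed, tolerance = 0.01)
})

test_that("area-averaged oxygenation metrics match closed forms", {
  dom <- fix_channel(60, 40, 12)
  sol <- solve_full(dom, transport_params(P_wall = 0, kinetics_mode = "none"))
  expect_equal(vascular_oxygen(sol$mesh, sol$vessel), 1, tolerance = 1e-9)
  expect_equal(oxygen_delivery(sol$mesh, sol$tissue), 1, tolerance = 1e-9)

  # linear strip profile (left 1, right 0): average 0.5
  m <- sol$mesh
  b <- classify_nodes(m)
  sys <- fem_assemble(m, which(m$code == 1), diffusivity = 1)
  x <- m$nodes[, 1]
  sys <- apply_dirichlet(sys, intersect(b$inlet_nodes, which(x < 0.5)), 1)
  sys <- apply_dirichlet(sys, intersect(b$inlet_nodes, which(x > 59.5)), 0)
  v <- rep(NA_real_, nrow(m$nodes))
  v[sys$nodes] <- as.numeric(Matrix::solve(sys$K, sys$F))
  expect_equal(vascular_oxygen(m, list(values = v, normalized = v)), 0.5,
               tolerance = 1e-6)

  # slab: mean of the parabola = 1 - (2/3) * 0.5
  s <- fix_slab()
  ps <- transport_params(P_wall = 0, kinetics_mode = "zero_order",
                         R0 = s$R0, D_tissue = s$D)
  sols <- solve_full(s$dom, ps)
  expect_equal(oxygen_delivery(sols$mesh, sols$tissue), 1 - 2 / 3 * 0.5,
               tolerance = 0.01)
  # increasing the sink strictly decreases delivery
  ps2 <- transport_params(P_wall = 0, kinetics_mode = "zero_order",
                          R0 = 1.5 * s$R0, D_tissue = s$D)
  sols2 <- solve_full(s$dom, ps2)
  expect_lt(oxygen_delivery(sols2$mesh, sols2$tissue),
            oxygen_delivery(sols$mesh, sols$tissue))
})

test_that("connectivity measures end-to-end transport under a left inlet", {
  # unobstructed channel: connectivity 1
  dom <- fix_channel(80, 60, 16)
  expect_equal(connectivity(dom, transport_params(P_wall = 0,
                                                  kinetics_mode = "none")),
               1, tolerance = 1e-9)
  # right-edge vessel disconnected from the left inlet: connectivity 0
  codes <- matrix(0, 60, 80)
  codes[20:30, 1:30] <- 1    # left stub, does not reach the right
  codes[40:50, 60:80] <- 1   # right blob, unreachable from the left
  domd <- domain_image(codes, pixel_size = 1)
  expect_equal(connectivity(domd, transport_params(P_wall = 0,
                                                   kinetics_mode = "none")), 0)
  # connectivity never exceeds 1 under consumption-only kinetics
  domn <- fix_network(seed = 3, coverage = 30, size = 128)
  cn <- connectivity(domn, transport_params())
  expect_gte(cn, 0)
  expect_lte(cn, 1 + 1e-9)
})

test_that("vessel coverage counts both vessel domains", {
  expect_equal(vessel_coverage(domain_image(matrix(1, 10, 10))), 100)
  expect_equal(vessel_coverage(domain_image(matrix(0, 10, 10))), 0)
  half <- matrix(0, 10, 10); half[, 1:5] <- 1
  expect_equal(vessel_coverage(domain_image(half)), 50)
  mix <- matrix(0, 10, 10); mix[1:2, ] <- 1; mix[5:6, 3:7] <- 0.5
  expect_equal(vessel_coverage(domain_image(mix)), 30)
})

test_that("transport_metrics returns one coherent row", {
  dom <- fix_network(seed = 3, coverage = 30, size = 128)
  row <- transport_metrics(dom, transport_params(), image_id = "net")
  expect_s3_class(row, "data.frame")
  expect_equal(nrow(row), 1L)
  expect_true(row$vascular_oxygen > 0 && row$vascular_oxygen <= 1)
  expect_true(row$oxygen_delivery > 0 && row$oxygen_delivery <= 1)
  expect_true(row$mesh_mean_quality > 0.85)
  expect_equal(row$interface_outflux, row$total_flux, tolerance = 0.05)
})
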