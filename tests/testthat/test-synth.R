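test_that("network generation is seeded and deterministic", {
  i1 <- generate_network(network_spec(seed = 7, target_coverage = 30,
                                      width = 128, height = 128))
  i2 <- generate_network(network_spec(seed = 7, target_coverage = 30,
                                      width = 128, height = 128))
  expect_identical(i1$pixels, i2$pixels)
  i3 <- generate_network(network_spec(seed = 8, target_coverage = 30,
                                      width = 128, height = 128))
  expect_false(identical(i1$pixels, i3$pixels))
  # generation does not disturb the global RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_network(network_spec(seed = 1,
                                                         width = 64,
                                                         height = 64)))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("degenerate specs produce empty images", {
  img <- generate_network(network_spec(seed = 1, n_trunks = 0,
                                       n_disconnected = 0,
                                       width = 64, height = 64))
  expect_true(all(img$pixels == 0))
})

test_that("coverage control hits the target within 5 points", {
  for (tc in c(15, 30, 55)) {
    img <- generate_network(network_spec(seed = tc, target_coverage = tc,
                                         n_trunks = max(2, round(tc / 8)),
                                         width = 128, height = 128))
    expect_lte(abs(attr(img, "achieved_coverage") - tc), 5)
  }
})

test_that("generated networks always reach an inlet when trunks exist", {
  for (s in 1:5) {
    img <- generate_network(network_spec(seed = s, target_coverage = 20,
                                         width = 96, height = 96))
    dom <- classify_domains(img)
    expect_true(any(dom$codes == 1))
  }
})

test_that("the channel fixture has the stated geometry", {
  dom <- generate_channel(100, 100, 20, pixel_size = 1)
  expect_equal(vessel_coverage(dom), 20)
  expect_equal(sort(unique(as.vector(dom$codes))), c(0, 1))
  lab <- label_components(binary_image((dom$codes == 1) * 1, 1))
  expect_equal(max(lab), 1L)   # one connected component, no 0.5 domain
  # equal-end Dirichlet, no wall flux: uniform field
  sol <- solve_full(dom, transport_params(P_wall = 0, kinetics_mode = "none"))
  v <- sol$vessel$values[!is.na(sol$vessel$values)]
  expect_lt(max(abs(v - 1)), 1e-10)
})

test_that("band presets cover the five coverage bands", {
  specs <- synth_preset_bands(n_per_band = 2, size = 128)
  expect_length(specs, 10L)
  tc <- vapply(specs, function(s) s$target_coverage, numeric(1))
  expect_equal(sort(unique(tc)), c(10, 25, 40, 60, 75))
  # distinct seeds throughout
  sd <- vapply(specs, function(s) s$seed, numeric(1))
  expect_equal(anyDuplicated(sd), 0L)
})
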