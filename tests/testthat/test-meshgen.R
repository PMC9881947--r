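test_that("boundary extraction of simple shapes gives the expected polygons", {
  # all-white 10x10: boundary is just the image border rectangle
  dom <- domain_image(matrix(1, 10, 10), pixel_size = 1)
  ps <- extract_boundaries(dom, simplify_tol = 0.5)
  expect_equal(nrow(ps$vertices), 4L)   # 4 corners after simplification
  expect_equal(nrow(ps$segments), 4L)
  expect_equal(range(ps$vertices[, 1]), c(0, 10))
  expect_equal(range(ps$vertices[, 2]), c(0, 10))

  # single interior white pixel: its unit square appears as an inner loop
  codes <- matrix(0, 10, 10); codes[5, 5] <- 0.5
  dom1 <- domain_image(codes, pixel_size = 1)
  ps1 <- extract_boundaries(dom1, simplify_tol = 0.5)
  inner <- ps1$vertices[ps1$vertices[, 1] > 0 & ps1$vertices[, 1] < 10, ,
                        drop = FALSE]
  expect_equal(nrow(inner), 4L)
  expect_equal(diff(range(inner[, 1])), 1)
  expect_equal(diff(range(inner[, 2])), 1)
})

test_that("meshing conserves per-domain area (L-shape and network)", {
  # L-shaped 3-pixel region: mesh area must equal 3 * pixel_size^2
  codes <- matrix(0, 10, 10)
  codes[5, 2:3] <- 0.5; codes[6, 2] <- 0.5
  dom <- domain_image(codes, pixel_size = 2)
  m <- build_mesh(dom)
  expect_equal(sum(m$areas[m$code == 0.5]), 3 * 4, tolerance = 1e-9)
  expect_equal(sum(m$areas), 100 * 4, tolerance = 1e-9)

  dom2 <- fix_network(seed = 3, coverage = 30, size = 128)
  m2 <- build_mesh(dom2)
  for (cd in c(0, 0.5, 1)) {
    pa <- sum(dom2$codes == cd) * dom2$pixel_size^2
    if (pa == 0) next
    expect_lt(abs(sum(m2$areas[m2$code == cd]) - pa) / pa, 0.02)
  }
})

test_that("element quality matches its closed form and is scale invariant", {
  eq <- rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  expect_equal(element_quality(eq), 1, tolerance = 1e-12)
  expect_equal(element_quality(rbind(c(0, 0), c(1, 0), c(2, 0))), 0)
  rt <- rbind(c(0, 0), c(1, 0), c(0, 1))
  expect_equal(element_quality(rt), sqrt(3) / 2, tolerance = 1e-12)
  for (s in c(0.01, 3, 1000))
    expect_equal(element_quality(rt * s), sqrt(3) / 2, tolerance = 1e-12)
})

test_that("mesh quality report summarizes per-element scores", {
  m <- fix_square_mesh()
  qr <- mesh_quality(m)
  expect_equal(qr$mean, sqrt(3) / 2, tolerance = 1e-12)
  expect_true(qr$min >= 0 && qr$mean <= 1)
  expect_true(qr$flag_low_quality)  # sqrt(3)/2 < 0.9
  expect_equal(sum(qr$hist), 2L)
})

test_that("interior edges satisfy the Delaunay empty-circumcircle property", {
  skip_if_not_installed("deldir")
  set.seed(99)
  pts <- cbind(runif(400, 2, 98), runif(400, 2, 98))
  res <- vascox:::cpp_triangulate(matrix(numeric(0), 0, 2),
                                  matrix(integer(0), 0, 2), pts,
                                  matrix(1L, 100, 100), 0L, 0, 0)
  tri <- res$triangles
  mine <- unique(t(apply(rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)]),
                         1, sort)))
  dd <- deldir::deldir(pts[, 1], pts[, 2])
  ref <- unique(t(apply(cbind(dd$delsgs$ind1, dd$delsgs$ind2), 1, sort)))
  k1 <- paste(mine[, 1], mine[, 2]); k2 <- paste(ref[, 1], ref[, 2])
  # every edge produced must be a Delaunay edge of the independent oracle
  expect_equal(sum(!(k1 %in% k2)), 0L)
})

test_that("multi-domain meshes conform at interfaces", {
  dom <- fix_network(seed = 3, coverage = 30, size = 128)
  m <- build_mesh(dom)
  b <- classify_nodes(m)
  # every interface edge is referenced by exactly one vessel and one
  # non-vessel element, with identical node ids
  ee <- vascox:::.element_edges(m)
  vess <- m$code[ee$elem] == 1
  ikeys <- paste(pmin(b$interface_edges[, 1], b$interface_edges[, 2]),
                 pmax(b$interface_edges[, 1], b$interface_edges[, 2]))
  expect_true(all(ikeys %in% ee$key[vess]))
  expect_true(all(ikeys %in% ee$key[!vess]))
  # no hanging nodes: used node ids are exactly 1..n
  used <- sort(unique(as.vector(m$elements)))
  expect_equal(used, seq_len(nrow(m$nodes)))
  # all elements positively oriented
  expect_true(all(m$areas > 0))
})

test_that("node classification finds inlet and interface sets", {
  dom <- fix_channel(100, 60, 20)
  m <- build_mesh(dom)
  b <- classify_nodes(m)
  x <- m$nodes[b$inlet_nodes, 1]
  expect_true(any(x < 0.5) && any(x > 99.5))   # both vertical sides
  ys <- sort(unique(round(m$nodes[b$edge_nodes, 2], 6)))
  expect_equal(ys, c(20, 40))                  # both long strip sides
  # outward normals from the vessel strip point away from it (|ny| = 1)
  expect_true(all(abs(abs(b$interface_normals[, 2]) - 1) < 1e-9))

  # all-white image: no interface exists
  mw <- build_mesh(domain_image(matrix(1, 20, 20), pixel_size = 1))
  bw <- classify_nodes(mw)
  expect_length(bw$edge_nodes, 0)
  expect_gt(length(bw$inlet_nodes), 0)

  # network: inlet and edge sets non-empty, largely disjoint
  dn <- fix_network(seed = 3, coverage = 30, size = 128)
  bn <- classify_nodes(build_mesh(dn))
  expect_gt(length(bn$inlet_nodes), 0)
  expect_gt(length(bn$edge_nodes), 0)
})

test_that("meshing is deterministic", {
  dom <- fix_network(seed = 5, coverage = 25, size = 64)
  m1 <- build_mesh(dom)
  m2 <- build_mesh(dom)
  expect_identical(m1$nodes, m2$nodes)
  expect_identical(m1$elements, m2$elements)
  expect_identical(m1$code, m2$code)
})
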