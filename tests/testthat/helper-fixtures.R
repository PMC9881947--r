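# Shared fixtures (built in code) and comparison helpers.

rel_l2 <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  sqrt(sum((a[ok] - b[ok])^2) / sum(b[ok]^2))
}

# channel: full-width horizontal vessel strip
fix_channel <- function(width = 120, height = 80, strip = 24, ps = 1) {
  generate_channel(width, height, strip, pixel_size = ps)
}

# slab: tissue between two full-height vessel walls; R0 tuned so the
# centre of the closed-form parabola sits at C = 0.5
fix_slab <- function(width = 120, height = 60, wall = 10, ps = 1,
                     D = 2e-9, drop = 0.5) {
  dom <- generate_slab(width, height, wall, pixel_size = ps)
  L <- attr(dom, "slab_L_um")
  list(dom = dom, L = L, x0 = attr(dom, "slab_x0_um"), D = D,
       R0 = drop * 8 * D / L^2)
}

# small synthetic network (cached per session: meshing is the slow part)
fix_network <- function(seed = 3, coverage = 30, size = 128) {
  key <- sprintf("net_%d_%d_%d", seed, coverage, size)
  cache <- getOption("vascox.test.cache", new.env(parent = emptyenv()))
  options(vascox.test.cache = cache)
  if (is.null(cache[[key]])) {
    img <- generate_network(network_spec(seed = seed,
                                         target_coverage = coverage,
                                         width = size, height = size))
    cache[[key]] <- classify_domains(img)
  }
  cache[[key]]
}

# hand-built unit-square mesh of two right triangles (vessel domain)
fix_square_mesh <- function() {
  structure(list(
    nodes = rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
    elements = rbind(c(1L, 2L, 3L), c(1L, 3L, 4L)),
    code = c(1, 1), organ = c(0L, 0L), areas = c(0.5, 0.5),
    constrained = matrix(integer(0), 0, 2), fixed = rep(TRUE, 4),
    pixel_size = 1, img_height = 1, img_width = 1),
    class = "domain_mesh")
}

mirror_dom <- function(dom) {
  domain_image(dom$codes[, ncol(dom$codes):1],
               dom$organ[, ncol(dom$organ):1],
               dom$pixel_size, dom$empty)
}
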