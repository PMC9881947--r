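test_that("image loading rescales by the dtype maximum", {
  td <- withr::local_tempdir()
  # 8-bit PNG with a pixel at 51/255 = 0.2
  m8 <- matrix(c(0, 51, 255, 128), 2, 2) / 255
  p8 <- file.path(td, "img8.png")
  png::writePNG(m8, p8)
  g <- load_image(p8, pixel_size = 2)
  expect_equal(sort(unique(as.vector(g$pixels))),
               c(0, 51 / 255, 128 / 255, 1), tolerance = 1e-9)
  expect_equal(g$pixel_size, 2)

  # 16-bit TIFF extremes
  m16 <- matrix(c(0, 65535, 32768, 65535) / 65535, 2, 2)
  p16 <- file.path(td, "img16.tif")
  tiff::writeTIFF(m16, p16, bits.per.sample = 16L)
  g16 <- load_image(p16, pixel_size = 1)
  expect_equal(max(g16$pixels), 1)
  expect_equal(min(g16$pixels), 0)

  expect_error(load_image(file.path(td, "absent.png"), 1), "cannot read")

  # multi-channel reduced to first channel with a warning
  rgb <- array(runif(12), dim = c(2, 2, 3))
  prgb <- file.path(td, "rgb.png")
  png::writePNG(rgb, prgb)
  expect_warning(grgb <- load_image(prgb, 1), "first channel")
  expect_equal(dim(grgb$pixels), c(2L, 2L))
})

test_that("binarization uses a strict threshold and is idempotent", {
  g <- gray_image(matrix(c(0.25, 0.2, 0, 0.9), 2, 2), 1)
  b <- binarize(g, 0.2)
  expect_equal(as.vector(b$pixels), c(1, 0, 0, 1))
  # exactly at threshold -> background; all-zero image stays zero
  expect_equal(binarize(gray_image(matrix(0, 3, 3), 1))$pixels,
               matrix(0, 3, 3))
  # idempotence for any threshold < 1
  for (thr in c(0.1, 0.2, 0.7)) {
    once <- binarize(g, thr)
    twice <- binarize(once, thr)
    expect_identical(once$pixels, twice$pixels)
  }
  expect_error(binarize(g, 1.2), "threshold")
})

test_that("component labeling connectivity matches the requested mode", {
  m <- matrix(0, 5, 5)
  m[1, 1] <- 1; m[2, 2] <- 1  # touch only diagonally
  expect_equal(max(label_components(m, 8)), 1L)
  expect_equal(max(label_components(m, 4)), 2L)
  # 4-connected labeling agrees with the independent EBImage routine
  set.seed(11)
  r <- matrix(rbinom(400, 1, 0.35), 20, 20)
  mine <- label_components(r, 4)
  ref <- EBImage::bwlabel(r)
  expect_equal(max(mine), max(ref))
  expect_equal(sort(tabulate(mine)), sort(tabulate(as.integer(ref))))
})

test_that("domain classification separates connected and disconnected vessels", {
  px <- matrix(0, 40, 60)
  px[10:20, 1:25] <- 1      # touches left edge -> connected
  px[28:32, 30:39] <- 1     # interior 50 px -> disconnected
  px[5:6, 45:46] <- 1       # 4 px speck -> filtered to tissue
  dom <- classify_domains(binary_image(px, 1), min_component_px = 10)
  expect_equal(sort(unique(as.vector(dom$codes))), c(0, 0.5, 1))
  expect_true(all(dom$codes[10:20, 1:25] == 1))
  expect_true(all(dom$codes[28:32, 30:39] == 0.5))
  expect_true(all(dom$codes[5:6, 45:46] == 0))
  # partition: counts sum to the pixel count
  expect_equal(sum(dom$codes == 0) + sum(dom$codes == 0.5) + sum(dom$codes == 1),
               40L * 60L)
  # no disconnected component touches an inlet column; all connected do
  expect_true(all(dom$codes[, 1] != 0.5) && all(dom$codes[, 60] != 0.5))
  lab <- label_components(binary_image((dom$codes == 1) * 1, 1))
  for (l in setdiff(unique(as.vector(lab)), 0L))
    expect_true(any(lab[, 1] == l) || any(lab[, 60] == l))

  expect_true(all(classify_domains(binary_image(matrix(1, 8, 8), 1))$codes == 1))
  tiny <- matrix(0, 12, 12); tiny[5:6, 5:6] <- 1
  expect_true(all(classify_domains(binary_image(tiny, 1))$codes == 0))
  expect_warning(e <- classify_domains(binary_image(matrix(0, 8, 8), 1)),
                 "no vessel")
  expect_true(e$empty)
})

test_that("classification is invariant to image mirroring", {
  dom <- fix_network(seed = 5, coverage = 25, size = 64)
  img <- binary_image((dom$codes > 0) * 1, 1)
  rev_img <- binary_image(img$pixels[, 64:1], 1)
  dom_rev <- classify_domains(rev_img)
  expect_equal(dom_rev$codes, dom$codes[, 64:1])
})

test_that("organ labels overlay tissue only and report vessel overlap", {
  dom <- fix_channel(40, 40, 10)
  mask <- matrix(0L, 40, 40)
  mask[3:8, 3:8] <- 1L            # tissue region
  out <- apply_region_labels(dom, mask)
  expect_equal(sum(out$organ == 1L), 36L)
  expect_equal(attr(out, "overlap_px"), 0L)
  # all-zero mask: no labels
  out0 <- apply_region_labels(dom, matrix(0L, 40, 40))
  expect_true(all(out0$organ == 0L))
  # mask entirely inside the vessel strip: ignored, overlap counted
  mv <- matrix(0L, 40, 40); mv[18:22, 10:14] <- 1L
  outv <- apply_region_labels(dom, mv)
  expect_true(all(outv$organ == 0L))
  expect_equal(attr(outv, "overlap_px"), 25L)
  expect_error(apply_region_labels(dom, matrix(0L, 10, 10)), "dimensions")
})

test_that("domain image PNG round trip preserves codes and pixel size", {
  td <- withr::local_tempdir()
  dom <- fix_network(seed = 5, coverage = 25, size = 64)
  p <- file.path(td, "dom.png")
  write_domain_image(dom, p)
  back <- read_domain_image(p)
  expect_equal(back$codes, dom$codes)
  expect_equal(back$pixel_size, dom$pixel_size)
})
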