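# Image loading, binarization and domain classification.
#
# Domain codes follow the three-level grayscale convention used throughout
# the package: 1 = vessel connected to an inlet face, 0.5 = disconnected
# vessel, 0 = tissue.

#' Grayscale image container
#'
#' Stores a 2D intensity raster normalized to `[0, 1]` together with the
#' physical pixel size.
#'
#' @param pixels numeric matrix of intensities in `[0, 1]`; rows are image
#'   rows (row 1 = top).
#' @param pixel_size physical length of one pixel (um/pixel), > 0.
#' @return an object of class `gray_image` with fields `pixels`, `height`,
#'   `width`, `pixel_size`.
#' @export
gray_image <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 2L || ncol(pixels) < 2L)
    stop("image must be at least 2 x 2 pixels")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1)
    stop("intensities must lie in [0, 1]")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0)
    stop("pixel_size must be a single positive number (um/pixel)")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         pixel_size = pixel_size),
    class = "gray_image")
}

#' Binary image container
#'
#' @param pixels matrix with values exactly 0 or 1.
#' @inheritParams gray_image
#' @return an object of class `binary_image`.
#' @export
binary_image <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels) * 1.0
  if (!all(pixels %in% c(0, 1)))
    stop("binary image values must be exactly 0 or 1")
  structure(
    list(pixels = pixels, height = nrow(pixels), width = ncol(pixels),
         pixel_size = pixel_size),
    class = "binary_image")
}

#' Load a grayscale image from TIFF or PNG
#'
#' Reads an 8- or 16-bit single-channel image and rescales intensities to
#' `[0, 1]` by the dtype maximum (255 or 65535). Multi-channel inputs are
#' reduced to their first channel with a warning.
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size physical pixel size in um/pixel.
#' @return a [gray_image()].
#' @export
load_image <- function(path, pixel_size) {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format '", ext, "' (use TIFF or PNG)"))
  if (length(dim(px)) == 3L) {
    warning("multi-channel image: using first channel only")
    px <- px[, , 1L]
  }
  if (length(px) == 0L) stop("zero-sized image: ", path)
  # readTIFF/readPNG already divide by the dtype maximum
  gray_image(pmin(pmax(px, 0), 1), pixel_size)
}

#' Binarize a grayscale image
#'
#' Pixels with intensity strictly greater than `threshold` become vessel
#' (1), all others background (0). The default threshold of 0.2 is the
#' value used for fluorescence images of microvascular networks.
#'
#' @param img a [gray_image()] (a `binary_image` passes through unchanged
#'   up to thresholding, making the operation idempotent).
#' @param threshold intensity threshold in (0, 1).
#' @return a [binary_image()].
#' @export
binarize <- function(img, threshold = 0.2) {
  stopifnot(inherits(img, c("gray_image", "binary_image")))
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  binary_image((img$pixels > threshold) * 1.0, img$pixel_size)
}

#' Label connected components of a binary image
#'
#' 8-connected by default (diagonal pixels join); 4-connected available.
#'
#' @param img a [binary_image()] or 0/1 matrix.
#' @param connectivity 8 (default) or 4.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(img, connectivity = 8) {
  px <- if (inherits(img, "binary_image")) img$pixels else img
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  cpp_label_components(matrix(as.integer(px != 0), nrow(px), ncol(px)),
                       as.integer(connectivity))
}

#' Classify vessel pixels into transport domains
#'
#' Vessel components touching an inlet side of the image become the
#' connected-vessel domain (code 1); remaining components of at least
#' `min_component_px` pixels become the disconnected-vessel domain
#' (code 0.5); everything else is tissue (code 0). Components smaller than
#' `min_component_px` are speckle and are reassigned to tissue, since they
#' produce degenerate mesh regions.
#'
#' @param img a [binary_image()].
#' @param inlet_sides character vector, subset of `c("left", "right")`.
#' @param min_component_px minimum component area (pixels) kept as a
#'   disconnected vessel.
#' @param connectivity component connectivity, 8 (default) or 4.
#' @return a `domain_image`: list with `codes` (matrix of 0/0.5/1),
#'   `organ` (integer matrix of region labels, 0 = plain tissue),
#'   `pixel_size`, and `empty` flag (TRUE when the image had no vessel
#'   pixels at all).
#' @export
classify_domains <- function(img, inlet_sides = c("left", "right"),
                             min_component_px = 10, connectivity = 8) {
  stopifnot(inherits(img, "binary_image"))
  inlet_sides <- match.arg(inlet_sides, c("left", "right"), several.ok = TRUE)
  px <- img$pixels
  H <- nrow(px); W <- ncol(px)
  codes <- matrix(0, H, W)
  empty <- !any(px != 0)
  if (empty) {
    warning("image contains no vessel pixels; returning all-tissue domains")
  } else {
    lab <- label_components(img, connectivity)
    touching <- integer(0)
    if ("left" %in% inlet_sides) touching <- c(touching, lab[, 1L])
    if ("right" %in% inlet_sides) touching <- c(touching, lab[, W])
    touching <- setdiff(unique(touching), 0L)
    sizes <- tabulate(lab, nbins = max(lab))
    keep <- which(sizes >= min_component_px)
    codes[lab %in% touching] <- 1
    disc <- setdiff(keep, touching)
    codes[lab %in% disc] <- 0.5
  }
  domain_image(codes, pixel_size = img$pixel_size, empty = empty)
}

#' Domain image container
#'
#' @param codes matrix of domain codes, restricted to `{0, 0.5, 1}`.
#' @param organ optional integer matrix of organ/region labels (0 = plain
#'   tissue); non-zero labels may only overlay tissue pixels.
#' @param pixel_size um/pixel.
#' @param empty flag: image had no vessel pixels.
#' @return object of class `domain_image`.
#' @export
domain_image <- function(codes, organ = NULL, pixel_size = 1, empty = FALSE) {
  codes <- as.matrix(codes)
  if (!all(codes %in% c(0, 0.5, 1))) stop("domain codes must be 0, 0.5 or 1")
  if (is.null(organ)) organ <- matrix(0L, nrow(codes), ncol(codes))
  organ <- matrix(as.integer(organ), nrow(codes), ncol(codes))
  if (any(organ < 0L)) stop("organ labels must be non-negative")
  if (any(organ != 0L & codes != 0))
    stop("organ labels may only overlay tissue pixels")
  structure(
    list(codes = codes, organ = organ, pixel_size = pixel_size,
         height = nrow(codes), width = ncol(codes), empty = empty),
    class = "domain_image")
}

#' Overlay organ/region labels onto the tissue domain
#'
#' Non-zero mask pixels label tissue sub-regions (e.g. an islet) that may
#' carry their own kinetic parameters. Mask pixels that fall on vessel
#' pixels are ignored; their count is reported in the `overlap_px`
#' attribute so silent misregistration is visible.
#'
#' @param dom a `domain_image`.
#' @param mask a [binary_image()] (label 1) or an integer label matrix of
#'   the same dimensions.
#' @return a `domain_image` with `organ` labels set; attribute
#'   `overlap_px` counts mask pixels that overlapped vessels.
#' @export
apply_region_labels <- function(dom, mask) {
  stopifnot(inherits(dom, "domain_image"))
  m <- if (inherits(mask, "binary_image")) mask$pixels else as.matrix(mask)
  if (!all(dim(m) == dim(dom$codes)))
    stop("mask dimensions must equal domain image dimensions")
  m <- matrix(as.integer(m), nrow(m), ncol(m))
  overlap <- sum(m != 0L & dom$codes != 0)
  organ <- matrix(0L, nrow(m), ncol(m))
  sel <- m != 0L & dom$codes == 0
  organ[sel] <- m[sel]
  out <- domain_image(dom$codes, organ, dom$pixel_size, dom$empty)
  attr(out, "overlap_px") <- overlap
  out
}

#' Write a domain image as an 8-bit PNG plus sidecar JSON
#'
#' Codes `{0, 0.5, 1}` map to gray values `{0, 128, 255}`. The sidecar
#' `<path>.json` stores pixel size and the organ label table.
#'
#' @param dom a `domain_image`.
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_domain_image <- function(dom, path) {
  stopifnot(inherits(dom, "domain_image"))
  g <- matrix(0, dom$height, dom$width)
  g[dom$codes == 0.5] <- 128 / 255
  g[dom$codes == 1] <- 1
  png::writePNG(g, path)
  side <- list(pixel_size = dom$pixel_size,
               organ_labels = sort(unique(as.integer(dom$organ))))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a domain image written by [write_domain_image()]
#'
#' @param path PNG path (sidecar `<path>.json` supplies the pixel size).
#' @return a `domain_image`.
#' @export
read_domain_image <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3L) g <- g[, , 1L]
  codes <- matrix(0, nrow(g), ncol(g))
  codes[abs(g - 128 / 255) < 0.1] <- 0.5
  codes[g > 0.9] <- 1
  ps <- 1
  side <- paste0(path, ".json")
  if (file.exists(side)) ps <- jsonlite::read_json(side)$pixel_size
  domain_image(codes, pixel_size = ps)
}

#' @export
print.domain_image <- function(x, ...) {
  cov <- 100 * mean(x$codes > 0)
  cat(sprintf(
    "domain_image %d x %d px (%.3g um/px): %.1f%% vessel (%.1f%% connected, %.1f%% disconnected)\n",
    x$height, x$width, x$pixel_size, cov,
    100 * mean(x$codes == 1), 100 * mean(x$codes == 0.5)))
  norg <- setdiff(unique(as.integer(x$organ)), 0L)
  if (length(norg)) cat("organ labels:", paste(norg, collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("gray_image %d x %d px (%.3g um/px), intensity [%.3f, %.3f]\n",
              x$height, x$width, x$pixel_size, min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("binary_image %d x %d px (%.3g um/px), %.1f%% foreground\n",
              x$height, x$width, x$pixel_size, 100 * mean(x$pixels)))
  invisible(x)
}
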