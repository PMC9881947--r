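# Single-image and batch orchestration.

#' Run the full pipeline on one image and write artifacts
#'
#' Stages: load -> binarize -> classify domains -> (optional organ mask)
#' -> mesh -> solve both phases -> metrics. Writes into `out_dir`:
#' `<id>_mesh.vtk` (mesh + nodal fields `C_vessel`, `C_tissue`,
#' `C_normalized`), `<id>_quality.csv` (quality histogram),
#' `<id>_metrics.csv` (one metrics row), `<id>_nodesets.json`,
#' `<id>_convergence.csv` (Picard residual trace) and
#' `<id>_config.json` (fully resolved configuration echo).
#'
#' @param input path to a TIFF/PNG image, or a `domain_image` directly.
#' @param out_dir output directory (created if missing).
#' @param config resolved configuration list (see [load_config()]).
#' @param organ_mask optional path to a PNG label mask (or a matrix).
#' @param image_id identifier used in file names and the metrics row
#'   (default: input file base name).
#' @return the metrics row (invisibly: list of artifact paths as
#'   attribute `artifacts`).
#' @export
run_single <- function(input, out_dir, config = load_config(),
                       organ_mask = NULL, image_id = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(input, "domain_image")) {
    dom <- input
    if (is.null(image_id)) image_id <- "image"
  } else {
    if (is.null(image_id))
      image_id <- tools::file_path_sans_ext(basename(input))
    img <- load_image(input, pixel_size = config$pixel_size)
    bin <- binarize(img, threshold = config$binarize_threshold)
    dom <- classify_domains(bin, inlet_sides = config$inlet_sides,
                            min_component_px = config$min_component_px,
                            connectivity = config$connectivity)
  }
  if (!is.null(organ_mask)) {
    m <- if (is.character(organ_mask)) {
      g <- png::readPNG(organ_mask)
      if (length(dim(g)) == 3L) g <- g[, , 1L]
      round(g * 255)
    } else organ_mask
    dom <- apply_region_labels(dom, m)
  }
  params <- .config_params(config)
  mesh_options <- .config_mesh_options(config)

  sol <- solve_full(dom, params, inlet_sides = config$inlet_sides,
                    mesh_options = mesh_options)
  metrics <- transport_metrics(dom, params, inlet_sides = config$inlet_sides,
                               mesh_options = mesh_options,
                               image_id = image_id)

  pre <- file.path(out_dir, image_id)
  qr <- mesh_quality(sol$mesh)
  paths <- c(
    mesh = write_mesh_vtk(sol$mesh, paste0(pre, "_mesh.vtk"),
                          point_data = list(
                            C_vessel = sol$vessel$values,
                            C_tissue = sol$tissue$values,
                            C_normalized = ifelse(
                              is.na(sol$vessel$normalized),
                              sol$tissue$normalized,
                              sol$vessel$normalized))),
    nodesets = write_node_sets(sol$boundary, paste0(pre, "_nodesets.json")))
  qdf <- data.frame(bin_low = qr$breaks[-length(qr$breaks)],
                    bin_high = qr$breaks[-1L], count = qr$hist)
  write.csv(qdf, paste0(pre, "_quality.csv"), row.names = FALSE)
  write.csv(metrics, paste0(pre, "_metrics.csv"), row.names = FALSE)
  tr <- sol$tissue$convergence_trace
  write.csv(data.frame(iteration = seq_along(tr), residual = tr),
            paste0(pre, "_convergence.csv"), row.names = FALSE)
  jsonlite::write_json(config, paste0(pre, "_config.json"), auto_unbox = TRUE,
                       digits = NA)
  attr(metrics, "artifacts") <- c(paths,
                                  quality = paste0(pre, "_quality.csv"),
                                  metrics = paste0(pre, "_metrics.csv"),
                                  convergence = paste0(pre, "_convergence.csv"),
                                  config = paste0(pre, "_config.json"))
  invisible(metrics)
}

#' Run the pipeline over a directory (or list) of images
#'
#' Per-image failures are caught, logged in the `failure` column and
#' skipped; summary statistics over the successful rows are written as a
#' footer file.
#'
#' @param inputs directory containing TIFF/PNG images, or a character
#'   vector of paths, or a named list of `domain_image` objects.
#' @param out_dir output directory.
#' @param config resolved configuration list.
#' @return data frame of per-image metrics rows (failures carry NA metrics
#'   and a message), sorted by `image_id`; also written to
#'   `metrics_batch.csv` with `metrics_summary.csv` alongside.
#' @export
run_batch <- function(inputs, out_dir, config = load_config()) {
  if (is.character(inputs) && length(inputs) == 1L && dir.exists(inputs)) {
    inputs <- list.files(inputs, pattern = "\\.(tif|tiff|png)$",
                         ignore.case = TRUE, full.names = TRUE)
  }
  if (!length(inputs)) stop("no input images found")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- if (!is.null(names(inputs)) && all(nzchar(names(inputs))))
    names(inputs) else
      vapply(inputs, function(p)
        if (is.character(p)) tools::file_path_sans_ext(basename(p)) else "image",
        character(1))
  rows <- vector("list", length(inputs))
  for (i in seq_along(inputs)) {
    rows[[i]] <- tryCatch({
      r <- run_single(inputs[[i]], out_dir, config, image_id = ids[i])
      r$failure <- ""
      r
    }, error = function(e) {
      data.frame(image_id = ids[i], vessel_coverage = NA_real_,
                 total_flux = NA_real_, interface_outflux = NA_real_,
                 vascular_oxygen = NA_real_, oxygen_delivery = NA_real_,
                 connectivity = NA_real_, mesh_mean_quality = NA_real_,
                 n_elements = NA_integer_, n_nodes = NA_integer_,
                 convergence_iters = NA_integer_,
                 failure = conditionMessage(e), stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$image_id), , drop = FALSE]
  rownames(out) <- NULL
  write.csv(out, file.path(out_dir, "metrics_batch.csv"), row.names = FALSE)
  ok <- out[out$failure == "", , drop = FALSE]
  numcols <- c("vessel_coverage", "total_flux", "vascular_oxygen",
               "oxygen_delivery", "connectivity", "mesh_mean_quality")
  summ <- do.call(rbind, lapply(numcols, function(cn) {
    v <- ok[[cn]]
    data.frame(metric = cn, mean = mean(v, na.rm = TRUE),
               median = median(v, na.rm = TRUE),
               q25 = unname(quantile(v, 0.25, na.rm = TRUE)),
               q75 = unname(quantile(v, 0.75, na.rm = TRUE)))
  }))
  write.csv(summ, file.path(out_dir, "metrics_summary.csv"), row.names = FALSE)
  out
}

#' Generate a synthetic batch to disk
#'
#' Writes the images of a [synth_preset_bands()] preset as PNGs plus a
#' manifest CSV (seed, band, achieved coverage).
#'
#' @param out_dir output directory.
#' @param n_per_band images per coverage band.
#' @param seed_offset batch seed offset.
#' @param size image side (px).
#' @return manifest data frame, invisibly.
#' @export
write_synth_batch <- function(out_dir, n_per_band = 10, seed_offset = 0,
                              size = 256) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  specs <- synth_preset_bands(n_per_band, seed_offset, size)
  man <- do.call(rbind, lapply(names(specs), function(nm) {
    sp <- specs[[nm]]
    img <- generate_network(sp)
    png::writePNG(img$pixels, file.path(out_dir, paste0(nm, ".png")))
    data.frame(image = paste0(nm, ".png"), seed = sp$seed,
               target_coverage = sp$target_coverage,
               achieved_coverage = attr(img, "achieved_coverage"),
               pixel_size = sp$pixel_size)
  }))
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}
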