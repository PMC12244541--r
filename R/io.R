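# Image and table I/O. Maps and masks travel as 8-bit PNG or TIFF; masks use
# the convention pore = 255 (white), cell = 0 (black). Metrics go to CSV,
# structured summaries and run manifests to JSON.

read_image_array <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  if (length(dim(img)) == 3 && dim(img)[3] == 4) {
    img <- img[, , 1:3, drop = FALSE]  # drop alpha
  }
  round(img * 255)
}

write_image_array <- function(pixels, path) {
  ext <- tolower(tools::file_ext(path))
  img <- pixels / 255
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext, " (use PNG or TIFF)"))
  invisible(path)
}

#' Read a grayscale map from a PNG or TIFF image
#'
#' RGB images are collapsed to brightness with the NTSC weights via
#' [to_grayscale()]; grayscale images pass through.
#'
#' @param path Image file (8-bit PNG or TIFF).
#' @inheritParams grayscale_map
#' @return A [grayscale_map].
#' @export
read_grayscale_map <- function(path, pixel_size_nm = 8, source_kind = "raw") {
  to_grayscale(read_image_array(path), pixel_size_nm, source_kind)
}

#' Write a grayscale map as an image
#'
#' @param map A [grayscale_map].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_grayscale_map <- function(map, path) {
  stopifnot(inherits(map, "grayscale_map"))
  write_image_array(map$pixels, path)
}

#' Read a binary mask image as a domain
#'
#' Pixels at or above `cutoff` are pore (white), pixels below are cell. Use
#' this for manually labelled ground-truth masks stored with the
#' pore = 255 / cell = 0 convention.
#'
#' @param path Image file (8-bit PNG or TIFF).
#' @param lattice_spacing_nm Site edge in nm.
#' @param provenance Provenance tag, default `"manual_label"`.
#' @param cutoff Brightness at which a mask pixel counts as pore
#'   (default 128, i.e. mid-scale).
#' @return A [binary_domain].
#' @export
read_mask <- function(path, lattice_spacing_nm = 8,
                      provenance = "manual_label", cutoff = 128) {
  px <- read_image_array(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  binary_domain(px >= cutoff, lattice_spacing_nm = lattice_spacing_nm,
                provenance = provenance)
}

#' Write a binary domain as a mask image (pore = white)
#'
#' @param domain A [binary_domain].
#' @param path Output path ending in `.png`, `.tif` or `.tiff`.
#' @export
write_mask <- function(domain, path) {
  stopifnot(inherits(domain, "binary_domain"))
  write_image_array(ifelse(domain$sites, 255, 0), path)
}

#' Write an MSD series to CSV
#'
#' One row per sample time with columns `time_s`, `msd_cm2`, `n_particles`.
#'
#' @param series An [msd_series].
#' @param path Output CSV path.
#' @export
write_msd_csv <- function(series, path) {
  stopifnot(inherits(series, "msd_series"))
  write.csv(data.frame(time_s = series$times_s, msd_cm2 = series$msd_cm2,
                       n_particles = series$n_particles),
            path, row.names = FALSE)
  invisible(path)
}

#' Read an MSD series from CSV
#'
#' @param path CSV written by [write_msd_csv()].
#' @return An [msd_series].
#' @export
read_msd_csv <- function(path) {
  df <- read.csv(path)
  msd_series(df$time_s, df$msd_cm2, df$n_particles[1])
}

#' Build a run manifest for reproducibility
#'
#' Records the command, resolved configuration, seeds, input digests and
#' package version so a run can be reproduced from its output directory.
#'
#' @param command Name of the pipeline stage or subcommand.
#' @param config Resolved configuration (a list).
#' @param seed RNG seed(s) used.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @return A list suitable for [jsonlite::write_json()].
#' @export
run_manifest <- function(command, config, seed, inputs = character()) {
  digests <- if (length(inputs)) {
    as.list(tools::md5sum(inputs))
  } else {
    NULL
  }
  list(command = command,
       config = config,
       seed = seed,
       input_md5 = digests,
       package_version = as.character(packageVersion("lkmcpore")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_manifest <- function(manifest, dir) {
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(file.path(dir, "manifest.json"))
}
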