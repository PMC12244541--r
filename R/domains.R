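#' Grayscale segmentation map
#'
#' Container for an 8-bit brightness field, typically a rendered segmentation
#' output (cell-probability or gradient-flow map) awaiting binarization into
#' a pore/cell simulation domain.
#'
#' @param pixels Integer matrix of brightness values in \[0, 255\]. Rows index
#'   the vertical image axis (origin top-left), columns the horizontal axis.
#' @param pixel_size_nm Physical edge length of one pixel in nanometres
#'   (default 8, the in-plane resolution of serial block-face SEM imaging of
#'   platelet masses).
#' @param source_kind One of `"cell_probability"`, `"gradient_flow"`,
#'   `"raw"`, `"synthetic"`.
#' @return An object of class `grayscale_map`.
#' @export
grayscale_map <- function(pixels, pixel_size_nm = 8,
                          source_kind = c("raw", "cell_probability",
                                          "gradient_flow", "synthetic")) {
  source_kind <- match.arg(source_kind)
  if (!is.matrix(pixels)) stop("pixels must be a 2D matrix")
  if (nrow(pixels) < 1 || ncol(pixels) < 1) stop("pixels must be non-empty")
  if (anyNA(pixels)) stop("pixels must not contain NA")
  if (any(pixels < 0 | pixels > 255)) stop("brightness must lie in [0, 255]")
  if (!is.numeric(pixel_size_nm) || length(pixel_size_nm) != 1 ||
      pixel_size_nm <= 0) {
    stop("pixel_size_nm must be a single positive number")
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, pixel_size_nm = pixel_size_nm,
                 source_kind = source_kind),
            class = "grayscale_map")
}

#' @export
print.grayscale_map <- function(x, ...) {
  cat(sprintf("<grayscale_map> %d x %d px, %.3g nm/px, source: %s\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size_nm, x$source_kind))
  cat(sprintf("  brightness range [%d, %d]\n",
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary pore/cell lattice domain
#'
#' The simulation arena: each lattice site is either `pore` (accessible to
#' diffusing tracers, plasma-filled space) or `cell` (excluded, platelet or
#' red-blood-cell material). Site `(i, j)` (0-based) has its physical centre
#' at `(i + 0.5, j + 0.5) * lattice_spacing_nm`.
#'
#' @param sites Logical matrix, `TRUE` for pore sites and `FALSE` for cell.
#' @param lattice_spacing_nm Physical site edge length `h` in nm (default 8).
#' @param provenance One of `"manual_label"`, `"thresholded"`, `"synthetic"`,
#'   `"fixture"`.
#' @param btv_used Optional integer brightness threshold applied to produce
#'   this domain.
#' @return An object of class `binary_domain`.
#' @export
binary_domain <- function(sites, lattice_spacing_nm = 8,
                          provenance = c("fixture", "manual_label",
                                         "thresholded", "synthetic"),
                          btv_used = NULL) {
  provenance <- match.arg(provenance)
  if (!is.matrix(sites)) stop("sites must be a 2D matrix")
  if (nrow(sites) < 1 || ncol(sites) < 1) stop("sites must be non-empty")
  if (is.numeric(sites)) {
    if (!all(sites %in% c(0, 1))) stop("numeric sites must be 0/1")
    sites <- sites == 1
  }
  if (!is.logical(sites) || anyNA(sites)) {
    stop("sites must be logical (TRUE = pore) without NA")
  }
  if (!is.numeric(lattice_spacing_nm) || length(lattice_spacing_nm) != 1 ||
      lattice_spacing_nm <= 0) {
    stop("lattice_spacing_nm must be a single positive number")
  }
  if (!is.null(btv_used)) {
    btv_used <- as.integer(btv_used)
    if (btv_used < 0 || btv_used > 255) stop("btv_used must lie in [0, 255]")
  }
  structure(list(sites = sites, lattice_spacing_nm = lattice_spacing_nm,
                 provenance = provenance, btv_used = btv_used),
            class = "binary_domain")
}

#' @export
print.binary_domain <- function(x, ...) {
  cat(sprintf(
    "<binary_domain> %d x %d sites, h = %.3g nm, porosity %.3f, from %s%s\n",
    nrow(x$sites), ncol(x$sites), x$lattice_spacing_nm, porosity(x),
    x$provenance,
    if (is.null(x$btv_used)) "" else sprintf(" (btv %d)", x$btv_used)))
  invisible(x)
}

#' Convert an RGB (or already-grayscale) image to a brightness map
#'
#' Collapses colour channels with the NTSC luma weights
#' `0.299 R + 0.587 G + 0.114 B`, rounding half to even, so that rendered
#' colour segmentation maps become scalar 0-255 brightness fields.
#' Single-channel input passes through unchanged.
#'
#' @param image Either a matrix (grayscale, values in \[0, 255\]) or a
#'   3-dimensional array `height x width x 3` of RGB values in \[0, 255\].
#' @inheritParams grayscale_map
#' @return A [grayscale_map].
#' @examples
#' img <- array(c(255, 0, 0), dim = c(1, 1, 3))  # pure red
#' to_grayscale(img)$pixels  # 76
#' @export
to_grayscale <- function(image, pixel_size_nm = 8, source_kind = "raw") {
  if (is.matrix(image)) {
    if (any(image < 0 | image > 255)) stop("channel values must lie in [0, 255]")
    return(grayscale_map(round(image), pixel_size_nm, source_kind))
  }
  if (!is.array(image) || length(dim(image)) != 3) {
    stop("image must be a 2D matrix or a height x width x channels array")
  }
  nch <- dim(image)[3]
  if (!nch %in% c(1, 3)) {
    stop("channel count must be 1 (grayscale) or 3 (RGB), got ", nch)
  }
  if (any(image < 0 | image > 255)) stop("channel values must lie in [0, 255]")
  if (nch == 1) {
    gray <- round(image[, , 1, drop = TRUE])
  } else {
    gray <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    gray <- round(gray)  # round() halves go to even
  }
  gray <- matrix(pmin(pmax(gray, 0), 255), dim(image)[1], dim(image)[2])
  grayscale_map(gray, pixel_size_nm, source_kind)
}

#' Binarize a grayscale map at a brightness threshold
#'
#' Applies a brightness threshold value (BTV) to split a map into pore and
#' cell sites. Two polarities are supported:
#' \describe{
#'   \item{`dark_pore` (default)}{brightness `< btv` becomes pore; raising
#'     the threshold makes the domain more porous. This is the natural
#'     polarity for renderings where cell material is bright (e.g.
#'     cell-probability maps, where high probability means cell).}
#'   \item{`dark_cell`}{brightness `< btv` becomes cell; raising the
#'     threshold makes the domain less porous.}
#' }
#'
#' @param map A [grayscale_map].
#' @param btv Integer threshold in \[0, 255\].
#' @param polarity `"dark_pore"` or `"dark_cell"` (see Details).
#' @return A [binary_domain] with `provenance = "thresholded"` and matching
#'   dimensions.
#' @export
binarize <- function(map, btv, polarity = c("dark_pore", "dark_cell")) {
  stopifnot(inherits(map, "grayscale_map"))
  polarity <- match.arg(polarity)
  if (length(btv) != 1 || is.na(btv) || btv < 0 || btv > 255) {
    stop("btv must be a single value in [0, 255]")
  }
  dark <- map$pixels < btv
  pore <- if (polarity == "dark_pore") dark else !dark
  binary_domain(pore, lattice_spacing_nm = map$pixel_size_nm,
                provenance = "thresholded", btv_used = btv)
}

#' Pore fraction of a binary domain
#'
#' @param domain A [binary_domain].
#' @return Fraction of sites classified as pore, in \[0, 1\].
#' @export
porosity <- function(domain) {
  stopifnot(inherits(domain, "binary_domain"))
  mean(domain$sites)
}

#' Intersection-over-union of the cell phase
#'
#' Pixel-wise overlap score between the cell sets of two same-sized binary
#' domains. When both domains contain no cell sites the cell sets are
#' identical (both empty) and the score is defined as 1.
#'
#' @param predicted,truth [binary_domain] objects of identical dimensions.
#' @return IoU in \[0, 1\].
#' @export
iou <- function(predicted, truth) {
  stopifnot(inherits(predicted, "binary_domain"),
            inherits(truth, "binary_domain"))
  if (!identical(dim(predicted$sites), dim(truth$sites))) {
    stop("domains must have identical dimensions")
  }
  cell_p <- !predicted$sites
  cell_t <- !truth$sites
  union_n <- sum(cell_p | cell_t)
  if (union_n == 0) return(1)
  sum(cell_p & cell_t) / union_n
}

#' Summarise a batch of IoU values
#'
#' Mean and spread of per-image IoU scores. The default spread is the sample
#' standard deviation divided by `n` (`sd_over_n`); the conventional standard
#' error of the mean (`sd_over_sqrt_n`) is available as an alternative.
#'
#' @param values Numeric vector of IoU values, length >= 1.
#' @param se_formula `"sd_over_n"` (default) or `"sd_over_sqrt_n"`.
#' @return List with `mean`, `se`, `n`, `se_formula`.
#' @export
iou_summary <- function(values, se_formula = c("sd_over_n", "sd_over_sqrt_n")) {
  se_formula <- match.arg(se_formula)
  if (length(values) < 1) stop("values must contain at least one IoU")
  if (any(values < 0 | values > 1)) stop("IoU values must lie in [0, 1]")
  s <- if (length(values) == 1) 0 else sd(values)
  se <- switch(se_formula,
               sd_over_n = s / length(values),
               sd_over_sqrt_n = s / sqrt(length(values)))
  list(mean = mean(values), se = se, n = length(values),
       se_formula = se_formula)
}

# Inscribed-disc radius field in site units: Euclidean distance from each
# pore site centre to the nearest cell site centre (image border counts as
# cell), minus half a site so a 1-site channel has radius 0.5. Cell sites
# get 0.
pore_radius_field <- function(domain) {
  sites <- domain$sites
  padded <- matrix(FALSE, nrow(sites) + 2, ncol(sites) + 2)
  padded[2:(nrow(sites) + 1), 2:(ncol(sites) + 1)] <- sites
  # EBImage::distmap: Euclidean distance to the nearest zero (cell) pixel
  dt <- EBImage::imageData(EBImage::distmap(EBImage::Image(padded * 1)))
  dt <- dt[2:(nrow(sites) + 1), 2:(ncol(sites) + 1), drop = FALSE]
  r <- dt - 0.5
  r[!sites] <- 0
  r
}

#' Pore width distribution by local thickness
#'
#' Assigns every pore site a local width equal to twice the radius of the
#' largest disc that both fits in the pore space and covers the site (the
#' local-thickness measure standard in porous-media image analysis), then
#' histograms the widths in nanometres. The image border is treated as
#' solid, so an unconfined pore is bounded by the field of view.
#'
#' @param domain A [binary_domain] with at least one pore site.
#' @param bin_width_nm Histogram bin width in nm (default: one lattice
#'   spacing).
#' @return An object of class `pore_width_distribution`: `bin_edges_nm`,
#'   `counts`, `widths_nm` (per pore site), and `summary` (mean and
#'   quartiles).
#' @export
pore_width_distribution <- function(domain, bin_width_nm = NULL) {
  stopifnot(inherits(domain, "binary_domain"))
  if (!any(domain$sites)) stop("domain has no pore sites")
  bin_width_nm <- bin_width_nm %||% domain$lattice_spacing_nm
  if (bin_width_nm <= 0) stop("bin_width_nm must be positive")
  r <- pore_radius_field(domain)
  lt <- local_thickness_cpp(r)
  widths <- lt[domain$sites] * domain$lattice_spacing_nm
  hi <- max(widths, bin_width_nm)
  edges <- seq(0, ceiling(hi / bin_width_nm) * bin_width_nm, by = bin_width_nm)
  counts <- as.integer(table(cut(widths, breaks = edges, right = TRUE,
                                 include.lowest = TRUE)))
  structure(list(
    bin_edges_nm = edges,
    counts = counts,
    widths_nm = widths,
    summary = c(mean = mean(widths),
                quantile(widths, c(0.25, 0.5, 0.75)))),
    class = "pore_width_distribution")
}

#' @export
print.pore_width_distribution <- function(x, ...) {
  cat(sprintf("<pore_width_distribution> %d pore sites, mean %.1f nm, median %.1f nm\n",
              sum(x$counts), x$summary[["mean"]], x$summary[["50%"]]))
  invisible(x)
}
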