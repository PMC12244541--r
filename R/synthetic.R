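# Synthetic domain generation. Platelet packings are emulated as Voronoi
# tessellations whose convex cells are shrunk back from their boundaries,
# leaving connected plasma channels between platelets: uniform thin
# channels for dense cores (narrow pore-width distribution around the
# minimum gap), variable wide channels for sparse shell-like regions
# (long-tailed distribution). An ellipse-union mode with morphological
# closing of the cell phase provides explicitly controlled geometries.

#' Specification for a synthetic platelet-mass domain
#'
#' @param class_label Packing class: `"sparse"` (loosely packed shell-like
#'   regions, default target porosity 0.33), `"dense"` (core-like packing,
#'   default target porosity 0.11), `"dense_rbc"` (dense packing plus one
#'   large red-blood-cell inclusion), or `"hybrid"` (a sparse and a dense
#'   field side by side).
#' @param grid_shape Sites per dimension, `c(rows, cols)` (default 250 x 250,
#'   i.e. 2 x 2 um at 8 nm spacing).
#' @param lattice_spacing_nm Physical site edge in nm (default 8).
#' @param target_porosity Desired pore fraction in (0, 1); ellipses are added
#'   until the porosity first crosses this value. Defaults by class (see
#'   `class_label`). Ignored when `ellipse_count` is given.
#' @param ellipse_count Optional fixed number of ellipses instead of a
#'   porosity target; `0` yields an all-pore domain.
#' @param semi_axis_range_nm Range `c(min, max)` each ellipse semi-axis is
#'   drawn from, in nm. Default 150-400 nm (platelet cross-sections of
#'   0.3-0.8 um).
#' @param min_gap_nm Minimum pore-channel width in nm (default 40, five
#'   sites at 8 nm — the modal pore width of densely packed platelet
#'   regions). Porosity-targeted packings never carve a channel narrower
#'   than this; in ellipse mode it is the diameter of the closing disc.
#' @param channel_width_range_nm Range of inter-platelet channel widths for
#'   porosity-targeted packings. Defaults by class: `c(40, 40)` for dense
#'   classes (narrow, uniform pores) and `c(40, 300)` for sparse (wide,
#'   long-tailed pore-width distribution).
#' @param seal_fraction Fraction of platelet-platelet interfaces in full
#'   contact, i.e. channels sealed shut. Sealed contacts create dead ends
#'   and tortuous detours, which is what couples diffusivity to porosity.
#'   Defaults by class: 0.3 for dense classes (pressed into contact), 0.1
#'   for sparse.
#' @param rbc_semi_axes_nm Semi-axes of the red-blood-cell inclusion for
#'   `dense_rbc`, in nm (default 800 x 500).
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(class_label = c("sparse", "dense", "dense_rbc",
                                           "hybrid"),
                           grid_shape = c(250, 250),
                           lattice_spacing_nm = 8,
                           target_porosity = NULL,
                           ellipse_count = NULL,
                           semi_axis_range_nm = c(150, 400),
                           min_gap_nm = 40,
                           channel_width_range_nm = NULL,
                           seal_fraction = NULL,
                           rbc_semi_axes_nm = c(800, 500),
                           seed = 1) {
  class_label <- match.arg(class_label)
  if (is.null(channel_width_range_nm)) {
    channel_width_range_nm <- switch(class_label,
      sparse = c(min_gap_nm, 300),
      c(min_gap_nm, min_gap_nm))
  }
  if (length(channel_width_range_nm) != 2 ||
      any(channel_width_range_nm < min_gap_nm) ||
      channel_width_range_nm[1] > channel_width_range_nm[2]) {
    stop("channel_width_range_nm must be ordered and >= min_gap_nm")
  }
  if (is.null(seal_fraction)) {
    seal_fraction <- switch(class_label, sparse = 0.1, 0.3)
  }
  if (seal_fraction < 0 || seal_fraction >= 1) {
    stop("seal_fraction must lie in [0, 1)")
  }
  if (is.null(target_porosity) && is.null(ellipse_count)) {
    target_porosity <- switch(class_label, sparse = 0.33, dense = 0.11,
                              dense_rbc = 0.11, hybrid = NA_real_)
  }
  if (!is.null(target_porosity) && !is.na(target_porosity) &&
      (target_porosity <= 0 || target_porosity >= 1)) {
    stop("target_porosity must lie in (0, 1)")
  }
  if (length(grid_shape) != 2 || any(grid_shape < 1)) {
    stop("grid_shape must be two positive site counts")
  }
  if (min_gap_nm < 0) stop("min_gap_nm must be >= 0")
  if (any(semi_axis_range_nm <= 0) ||
      semi_axis_range_nm[1] > semi_axis_range_nm[2]) {
    stop("semi_axis_range_nm must be positive and ordered")
  }
  structure(list(class_label = class_label,
                 grid_shape = as.integer(grid_shape),
                 lattice_spacing_nm = lattice_spacing_nm,
                 target_porosity = target_porosity,
                 ellipse_count = ellipse_count,
                 semi_axis_range_nm = semi_axis_range_nm,
                 min_gap_nm = min_gap_nm,
                 channel_width_range_nm = channel_width_range_nm,
                 seal_fraction = seal_fraction,
                 rbc_semi_axes_nm = rbc_semi_axes_nm,
                 seed = seed),
            class = "synthetic_spec")
}

# Mark sites inside a rotated ellipse as cell (FALSE) in a pore matrix.
stamp_ellipse <- function(pore, ci, cj, a, b, theta) {
  nr <- nrow(pore); nc <- ncol(pore)
  ext <- ceiling(max(a, b))
  i0 <- max(1, floor(ci - ext)); i1 <- min(nr, ceiling(ci + ext))
  j0 <- max(1, floor(cj - ext)); j1 <- min(nc, ceiling(cj + ext))
  if (i0 > i1 || j0 > j1) return(pore)
  di <- (i0:i1) - ci
  dj <- (j0:j1) - cj
  ct <- cos(theta); st <- sin(theta)
  u <- outer(di * ct, dj * st, "+") / a
  v <- outer(-di * st, dj * ct, "+") / b
  inside <- u * u + v * v <= 1
  pore[i0:i1, j0:j1][inside] <- FALSE
  pore
}

# Packing as a gap-separated Voronoi tessellation: each generator point
# grows a convex platelet-like cell, shrunk back from its Voronoi boundary
# by a per-generator margin, so neighbouring platelets are separated by a
# plasma channel whose width is the sum of the two margins. Uniform margins
# (dense) give the narrow ~min-gap pore-width distribution of tightly
# packed cores; variable margins (sparse) give wide, long-tailed channels.
# Every channel follows a Voronoi edge, so the pore network is connected —
# which is what lets sparse regions out-diffuse dense ones at equal seed
# counts. Generators are proposed at random positions; a proposal is
# rejected when it would overshoot the target porosity (sparse generator
# configurations have wide near-equidistant bands, so porosity is not
# monotone in the generator count and unconstrained additions can jump far
# past the target). Generation stops as soon as the porosity lands in
# [target, target + 0.045].
gap_voronoi_pack <- function(nr, nc, margin_range_sites, target,
                             max_proposals, seal_fraction = 0) {
  ii <- matrix(rep(seq_len(nr), nc), nr, nc)
  jj <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  si <- numeric(0); sj <- numeric(0)  # generator coordinates
  sm <- numeric(0)                    # per-generator shrink margins
  d1 <- matrix(Inf, nr, nc); i1 <- matrix(NA_integer_, nr, nc)
  d2 <- matrix(Inf, nr, nc); i2 <- matrix(NA_integer_, nr, nc)

  # Distance from a site to the Voronoi edge between its two nearest
  # generators is (d2 - d1) / (2 sin(theta/2)) with theta the angle the two
  # generators subtend at the site; without the normalization the band
  # |d2 - d1| < width balloons where the generators are seen nearly
  # collinearly, producing spuriously wide pores. A site is pore when it is
  # closer to the edge than the mean of the two adjoining margins.
  # A fraction of platelet-platelet interfaces is in full contact: those
  # channels are sealed. The seal decision is a deterministic hash of the
  # (unordered) generator pair so it is stable as generators accumulate.
  sealed_pair <- function(a, b) {
    lo <- pmin(a, b); hi <- pmax(a, b)
    x <- sin(lo * 12.9898 + hi * 78.233) * 43758.5453
    (x - floor(x)) < seal_fraction
  }

  pore_mask <- function(d1, d2, i1, i2, si, sj, sm) {
    dot <- (si[i1] - ii) * (si[i2] - ii) + (sj[i1] - jj) * (sj[i2] - jj)
    cost <- pmin(pmax(dot / pmax(d1 * d2, 1e-9), -1), 1)
    sin_half <- sqrt((1 - cost) / 2)
    edge_dist <- (d2 - d1) / (2 * pmax(sin_half, 1e-9))
    open_channel <- edge_dist < (sm[i1] + sm[i2]) / 2
    open_channel & !sealed_pair(i1, i2)
  }

  slack <- 0.045
  phi <- 1
  for (prop in seq_len(max_proposals)) {
    ci <- runif(1, 1, nr); cj <- runif(1, 1, nc)
    cm <- runif(1, margin_range_sites[1], margin_range_sites[2])
    k_new <- length(si) + 1L
    d_new <- sqrt((ii - ci)^2 + (jj - cj)^2)
    closer <- d_new < d1
    mid <- !closer & d_new < d2
    d2c <- d2; i2c <- i2
    d2c[closer] <- d1[closer]; i2c[closer] <- i1[closer]
    d2c[mid] <- d_new[mid];    i2c[mid] <- k_new
    d1c <- d1; i1c <- i1
    d1c[closer] <- d_new[closer]; i1c[closer] <- k_new
    if (k_new <= 2) {  # porosity undefined until two generators exist
      si <- c(si, ci); sj <- c(sj, cj); sm <- c(sm, cm)
      d1 <- d1c; d2 <- d2c; i1 <- i1c; i2 <- i2c
      next
    }
    si_c <- c(si, ci); sj_c <- c(sj, cj); sm_c <- c(sm, cm)
    phi_cand <- mean(pore_mask(d1c, d2c, i1c, i2c, si_c, sj_c, sm_c))
    if (phi_cand <= target + slack || phi_cand < phi) {
      si <- si_c; sj <- sj_c; sm <- sm_c
      d1 <- d1c; d2 <- d2c; i1 <- i1c; i2 <- i2c
      phi <- phi_cand
      if (phi >= target && phi <= target + slack) {
        return(pore_mask(d1, d2, i1, i2, si, sj, sm))
      }
    }
  }
  stop(sprintf(
    "target porosity %.3f unattainable: %.3f after %d proposals",
    target, phi, max_proposals))
}

# Morphological closing of the cell phase with a disc of diameter gap_sites:
# pore channels narrower than the minimum gap are sealed (become cell), so
# every surviving pore is at least about gap_sites wide.
close_cell_phase <- function(pore, gap_sites) {
  if (gap_sites < 2) return(pore)
  size <- 2 * floor(gap_sites / 2) + 1
  brush <- EBImage::makeBrush(size, shape = "disc")
  cell <- EBImage::closing(EBImage::Image((!pore) * 1), brush)
  !(EBImage::imageData(cell) > 0.5)
}

#' Generate a synthetic binary platelet-mass domain
#'
#' Porosity-targeted packings are built as a gap-separated Voronoi
#' tessellation: each generator point grows a convex platelet-like cell
#' shrunk back from its Voronoi boundary, so neighbouring platelets are
#' separated by plasma channels drawn from `channel_width_range_nm`.
#' Dense classes use uniform channels one minimum gap wide (narrow
#' pore-width distribution, tightly packed polygonal platelets); sparse
#' uses variable wide channels (long-tailed distribution of loosely packed
#' cells). The channel network follows the Voronoi edges, so pore space
#' stays connected. Generators are added under porosity-overshoot
#' rejection until the achieved porosity lands within the target band.
#' With `ellipse_count` set, the domain is instead a union of that many
#' random rotated ellipses with the cell phase morphologically closed at
#' the minimum gap. `dense_rbc` additionally stamps one large elliptical
#' inclusion separated from the packing by a pore rim one gap wide;
#' `hybrid` concatenates a sparse and a dense field along the column axis.
#'
#' @param spec A [synthetic_spec].
#' @param max_ellipses Safety cap on ellipse placements before declaring the
#'   target porosity unattainable.
#' @return A [binary_domain] (`provenance = "synthetic"`) with a `meta` field
#'   holding the spec and the achieved porosity.
#' @export
generate_domain <- function(spec, max_ellipses = 10000) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$lattice_spacing_nm

  if (spec$class_label == "hybrid") {
    nc_half <- spec$grid_shape[2] %/% 2
    sub <- function(lbl, seed_off) {
      s <- spec
      s$class_label <- lbl
      s$grid_shape <- c(spec$grid_shape[1], nc_half)
      s$target_porosity <- switch(lbl, sparse = 0.33, dense = 0.11)
      s$seed <- spec$seed + seed_off
      generate_domain(s, max_ellipses)
    }
    left <- sub("sparse", 0)
    right <- sub("dense", 1)
    out <- binary_domain(cbind(left$sites, right$sites),
                         lattice_spacing_nm = h, provenance = "synthetic")
    out$meta <- list(spec = spec, achieved_porosity = porosity(out))
    return(out)
  }

  gap_sites <- spec$min_gap_nm / h
  ax_range <- spec$semi_axis_range_nm / h
  margin_range <- spec$channel_width_range_nm / (2 * h)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]

  domain <- with_seed(spec$seed, {
    pore <- matrix(TRUE, nr, nc)
    if (!is.null(spec$ellipse_count)) {
      n <- spec$ellipse_count
      if (n > 0) {
        for (k in seq_len(n)) {
          pore <- stamp_ellipse(pore,
                                runif(1, 1, nr), runif(1, 1, nc),
                                runif(1, ax_range[1], ax_range[2]),
                                runif(1, ax_range[1], ax_range[2]),
                                runif(1, 0, pi))
        }
        pore <- close_cell_phase(pore, gap_sites)
      }
    } else {
      pore <- gap_voronoi_pack(nr, nc, margin_range, spec$target_porosity,
                               max_ellipses, spec$seal_fraction)
    }
    if (spec$class_label == "dense_rbc") {
      rbc_ax <- spec$rbc_semi_axes_nm / h
      ci <- runif(1, nr * 0.25, nr * 0.75)
      cj <- runif(1, nc * 0.25, nc * 0.75)
      theta <- runif(1, 0, pi)
      # pore rim one gap wide around the inclusion, then the inclusion
      rim <- gap_sites
      ring <- matrix(TRUE, nr, nc)
      ring <- stamp_ellipse(ring, ci, cj, rbc_ax[1] + rim, rbc_ax[2] + rim,
                            theta)
      pore[!ring] <- TRUE
      pore <- stamp_ellipse(pore, ci, cj, rbc_ax[1], rbc_ax[2], theta)
    }
    pore
  })

  out <- binary_domain(domain, lattice_spacing_nm = h,
                       provenance = "synthetic")
  out$meta <- list(spec = spec, achieved_porosity = porosity(out))
  out
}

#' Analytic fixture domains
#'
#' Small exactly-known geometries used as oracles for the simulation engine.
#'
#' @param kind One of `"empty"` (all pore), `"full"` (all cell), `"channel"`
#'   (a straight all-pore band of `width_sites` rows crossing an all-cell
#'   field), `"isolated_trap"` (a single pore site surrounded by cell), or
#'   `"checkerboard"` (alternating classes).
#' @param grid_shape Sites per dimension, `c(rows, cols)`.
#' @param width_sites Channel width in sites (channel only).
#' @param lattice_spacing_nm Site edge in nm.
#' @return A [binary_domain] with `provenance = "fixture"`.
#' @export
generate_fixture <- function(kind = c("empty", "full", "channel",
                                      "isolated_trap", "checkerboard"),
                             grid_shape = c(100, 100), width_sites = 1,
                             lattice_spacing_nm = 8) {
  kind <- match.arg(kind)
  nr <- grid_shape[1]; nc <- grid_shape[2]
  sites <- switch(kind,
    empty = matrix(TRUE, nr, nc),
    full = matrix(FALSE, nr, nc),
    channel = {
      if (width_sites < 1) stop("width_sites must be >= 1")
      if (width_sites > nr) stop("channel wider than grid")
      s <- matrix(FALSE, nr, nc)
      r0 <- (nr - width_sites) %/% 2 + 1
      s[r0:(r0 + width_sites - 1), ] <- TRUE
      s
    },
    isolated_trap = {
      s <- matrix(FALSE, nr, nc)
      s[(nr + 1) %/% 2, (nc + 1) %/% 2] <- TRUE
      s
    },
    checkerboard = outer(seq_len(nr), seq_len(nc),
                         function(i, j) (i + j) %% 2 == 0))
  binary_domain(sites, lattice_spacing_nm = lattice_spacing_nm,
                provenance = "fixture")
}

#' Specification for emulating a grayscale segmentation rendering
#'
#' Describes how a known binary domain is rendered into an 8-bit brightness
#' field standing in for a segmentation-model output: cell sites bright
#' (high cell probability), pore sites dark, with optional per-site Gaussian
#' noise and Gaussian blur.
#'
#' @param cell_brightness_mean,cell_brightness_sd Brightness distribution of
#'   cell sites (defaults 200 and 15).
#' @param pore_brightness_mean,pore_brightness_sd Brightness distribution of
#'   pore sites (defaults 20 and 15).
#' @param blur_sigma_px Gaussian blur width in pixels (default 1).
#' @param seed RNG seed.
#' @return An object of class `grayscale_emulation_spec`.
#' @export
grayscale_emulation_spec <- function(cell_brightness_mean = 200,
                                     cell_brightness_sd = 15,
                                     pore_brightness_mean = 20,
                                     pore_brightness_sd = 15,
                                     blur_sigma_px = 1,
                                     seed = 1) {
  means <- c(cell_brightness_mean, pore_brightness_mean)
  if (any(means < 0 | means > 255)) stop("brightness means must lie in [0, 255]")
  if (cell_brightness_sd < 0 || pore_brightness_sd < 0) {
    stop("brightness sds must be >= 0")
  }
  if (blur_sigma_px < 0) stop("blur_sigma_px must be >= 0")
  structure(list(cell_brightness_mean = cell_brightness_mean,
                 cell_brightness_sd = cell_brightness_sd,
                 pore_brightness_mean = pore_brightness_mean,
                 pore_brightness_sd = pore_brightness_sd,
                 blur_sigma_px = blur_sigma_px,
                 seed = seed),
            class = "grayscale_emulation_spec")
}

#' Render a binary domain as an emulated grayscale segmentation map
#'
#' @param domain A [binary_domain].
#' @param spec A [grayscale_emulation_spec].
#' @return A [grayscale_map] with `source_kind = "synthetic"`.
#' @export
emulate_grayscale <- function(domain, spec = grayscale_emulation_spec()) {
  stopifnot(inherits(domain, "binary_domain"),
            inherits(spec, "grayscale_emulation_spec"))
  sites <- domain$sites
  img <- with_seed(spec$seed, {
    x <- matrix(0, nrow(sites), ncol(sites))
    n_pore <- sum(sites)
    x[sites] <- rnorm(n_pore, spec$pore_brightness_mean,
                      spec$pore_brightness_sd)
    x[!sites] <- rnorm(length(sites) - n_pore, spec$cell_brightness_mean,
                       spec$cell_brightness_sd)
    if (spec$blur_sigma_px > 0) {
      x <- EBImage::imageData(EBImage::gblur(EBImage::Image(x),
                                             sigma = spec$blur_sigma_px,
                                             boundary = "replicate"))
    }
    x
  })
  grayscale_map(pmin(pmax(round(img), 0), 255),
                pixel_size_nm = domain$lattice_spacing_nm,
                source_kind = "synthetic")
}
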