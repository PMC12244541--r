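# Spatially resolved diffusivity: staggered-subdomain decomposition,
# per-subdomain LKMC runs, and overlap-averaged heatmaps.

#' Staggered subdomain decomposition grid
#'
#' Defaults follow the 2 x 2 um subdomain staggered by 1 um at 8 nm spacing:
#' 250-site windows every 125 sites, so a 1250 x 1250-site (10 x 10 um)
#' parent yields 9 x 9 = 81 subdomains and a 10 x 10 = 100-cell output grid.
#'
#' @param subdomain_size_sites Window edge in sites (default 250).
#' @param stagger_sites Offset between window origins in sites (default
#'   125); must divide `subdomain_size_sites`.
#' @param output_cell_size_sites Edge of one output heatmap cell (defaults
#'   to the stagger).
#' @return An object of class `subdomain_grid`.
#' @export
subdomain_grid <- function(subdomain_size_sites = 250, stagger_sites = 125,
                           output_cell_size_sites = stagger_sites) {
  if (subdomain_size_sites < 1 || stagger_sites < 1) {
    stop("sizes must be positive")
  }
  if (subdomain_size_sites %% stagger_sites != 0) {
    stop("stagger_sites must divide subdomain_size_sites")
  }
  structure(list(subdomain_size_sites = as.integer(subdomain_size_sites),
                 stagger_sites = as.integer(stagger_sites),
                 output_cell_size_sites = as.integer(output_cell_size_sites)),
            class = "subdomain_grid")
}

# Crop a site matrix to whole multiples of the stagger (bottom/right),
# returning the matrix unchanged when it already fits.
crop_to_stagger <- function(sites, stagger) {
  nr <- nrow(sites) %/% stagger * stagger
  nc <- ncol(sites) %/% stagger * stagger
  if (nr != nrow(sites) || nc != ncol(sites)) {
    message(sprintf("cropping domain from %d x %d to %d x %d sites",
                    nrow(sites), ncol(sites), nr, nc))
  }
  sites[seq_len(nr), seq_len(nc), drop = FALSE]
}

subdomain_origins <- function(extent, size, stagger) {
  if (extent < size) stop("domain smaller than one subdomain")
  seq(0L, extent - size, by = stagger)
}

#' Decompose a domain into staggered subdomains
#'
#' All axis-aligned windows of the grid's subdomain size whose origins are
#' spaced by the stagger and that lie fully inside the (cropped) parent.
#'
#' @param domain A [binary_domain] at least one subdomain large.
#' @param grid A [subdomain_grid].
#' @return A list of [binary_domain] windows; the attribute `origins` holds
#'   the 0-based `(row, col)` site origin of each window.
#' @export
decompose <- function(domain, grid = subdomain_grid()) {
  stopifnot(inherits(domain, "binary_domain"),
            inherits(grid, "subdomain_grid"))
  s <- grid$subdomain_size_sites
  st <- grid$stagger_sites
  if (nrow(domain$sites) < s || ncol(domain$sites) < s) {
    stop("domain smaller than one subdomain")
  }
  sites <- crop_to_stagger(domain$sites, st)
  oi <- subdomain_origins(nrow(sites), s, st)
  oj <- subdomain_origins(ncol(sites), s, st)
  origins <- expand.grid(row = oi, col = oj)
  subs <- lapply(seq_len(nrow(origins)), function(k) {
    i0 <- origins$row[k]; j0 <- origins$col[k]
    binary_domain(sites[(i0 + 1):(i0 + s), (j0 + 1):(j0 + s), drop = FALSE],
                  lattice_spacing_nm = domain$lattice_spacing_nm,
                  provenance = domain$provenance)
  })
  attr(subs, "origins") <- origins
  attr(subs, "cropped_shape") <- dim(sites)
  subs
}

#' Spatially resolved diffusivity and porosity heatmap
#'
#' Runs an independent LKMC simulation in every staggered subdomain (mirror
#' boundaries at the subdomain edge, so each window sees only its local
#' geometry), estimates the local normalized diffusivity `D/Dp`, and
#' attributes each subdomain's value to the output cells its footprint
#' covers; a cell's value is the unweighted mean over the subdomains
#' covering it. Subdomains with no pore sites contribute `D = 0`.
#' Per-subdomain seeds are derived from `config$seed` so the map is
#' reproducible.
#'
#' @param domain Parent [binary_domain].
#' @param grid A [subdomain_grid].
#' @param config A [simulation_config]; `n_particles` applies per subdomain.
#' @param t_min_s Burn-in passed to [estimate_diffusivity()].
#' @return An object of class `heatmap_result`: `d_normalized_grid`,
#'   `porosity_grid`, `coverage_counts` (same dimensions), and `records`,
#'   a data frame with one row per subdomain (origin, porosity,
#'   d_normalized, n_pore_sites).
#' @export
local_diffusivity_map <- function(domain, grid = subdomain_grid(),
                                  config = simulation_config(),
                                  t_min_s = 0.001) {
  subs <- decompose(domain, grid)
  origins <- attr(subs, "origins")
  shape <- attr(subs, "cropped_shape")
  st <- grid$stagger_sites
  f <- grid$subdomain_size_sites %/% st  # output cells per subdomain edge
  n_ci <- shape[1] %/% st
  n_cj <- shape[2] %/% st

  acc_d <- matrix(0, n_ci, n_cj)
  acc_p <- matrix(0, n_ci, n_cj)
  cover <- matrix(0L, n_ci, n_cj)
  records <- data.frame(origin_row = origins$row, origin_col = origins$col,
                        porosity = NA_real_, d_normalized = NA_real_,
                        n_pore_sites = NA_integer_)

  for (k in seq_along(subs)) {
    sub <- subs[[k]]
    phi <- porosity(sub)
    if (any(sub$sites)) {
      cfg_k <- config
      cfg_k$seed <- config$seed + k - 1
      est <- estimate_diffusivity(run_simulation(sub, cfg_k),
                                  t_min_s = t_min_s,
                                  dp = config$diffusivity_dp)
      dnorm_k <- est$d_normalized
    } else {
      dnorm_k <- 0  # fully blocked window, kept so the grid stays complete
    }
    records$porosity[k] <- phi
    records$d_normalized[k] <- dnorm_k
    records$n_pore_sites[k] <- sum(sub$sites)
    ci <- origins$row[k] %/% st + seq_len(f)
    cj <- origins$col[k] %/% st + seq_len(f)
    acc_d[ci, cj] <- acc_d[ci, cj] + dnorm_k
    acc_p[ci, cj] <- acc_p[ci, cj] + phi
    cover[ci, cj] <- cover[ci, cj] + 1L
  }

  structure(list(d_normalized_grid = acc_d / cover,
                 porosity_grid = acc_p / cover,
                 coverage_counts = cover,
                 records = records,
                 grid = grid),
            class = "heatmap_result")
}

#' @export
print.heatmap_result <- function(x, ...) {
  cat(sprintf("<heatmap_result> %d x %d output cells from %d subdomains; D/Dp in [%.3f, %.3f]\n",
              nrow(x$d_normalized_grid), ncol(x$d_normalized_grid),
              nrow(x$records), min(x$d_normalized_grid),
              max(x$d_normalized_grid)))
  invisible(x)
}

#' Porosity-diffusivity records for scatter analysis
#'
#' Pools per-subdomain records from one or more heatmap results (or raw
#' record data frames) into one table of local porosity versus local
#' normalized diffusivity, suitable for scatter plotting and trend tests.
#'
#' @param results A `heatmap_result`, a list of them, or a list of data
#'   frames with `porosity` and `d_normalized` columns.
#' @param class_labels Optional class label per element of `results`
#'   (recycled if length 1).
#' @param provenance Optional provenance per element (recycled).
#' @return Data frame with columns `porosity`, `d_normalized`,
#'   `class_label`, `provenance`.
#' @export
porosity_diffusivity_table <- function(results, class_labels = NA,
                                       provenance = NA) {
  if (inherits(results, "heatmap_result") || is.data.frame(results)) {
    results <- list(results)
  }
  if (length(results) < 1) stop("need at least one record set")
  class_labels <- rep_len(class_labels, length(results))
  provenance <- rep_len(provenance, length(results))
  out <- lapply(seq_along(results), function(k) {
    r <- results[[k]]
    rec <- if (inherits(r, "heatmap_result")) r$records else r
    data.frame(porosity = rec$porosity, d_normalized = rec$d_normalized,
               class_label = class_labels[k], provenance = provenance[k])
  })
  do.call(rbind, out)
}

#' Write a heatmap result to disk
#'
#' Writes the `D/Dp` grid and the porosity grid as CSV, the per-subdomain
#' records as CSV, and a grayscale PNG rendering of the diffusivity map
#' (linear ramp, black = 0 to white = `D/Dp` = 1).
#'
#' @param result A [local_diffusivity_map()] result.
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_heatmap <- function(result, dir) {
  stopifnot(inherits(result, "heatmap_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(result$d_normalized_grid,
            file.path(dir, "d_normalized_grid.csv"), row.names = FALSE)
  write.csv(result$porosity_grid,
            file.path(dir, "porosity_grid.csv"), row.names = FALSE)
  write.csv(result$records, file.path(dir, "subdomain_records.csv"),
            row.names = FALSE)
  png::writePNG(pmin(pmax(result$d_normalized_grid, 0), 1),
                file.path(dir, "d_normalized_heatmap.png"))
  invisible(dir)
}
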