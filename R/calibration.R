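# Functional calibration of the binarization threshold: the right BTV is
# the one whose thresholded domain reproduces the ground-truth diffusivity,
# not the one with the best pixel overlap.

#' Ground-truth diffusivity of a labelled domain
#'
#' Simulates tracer diffusion on a manually labelled (or otherwise trusted)
#' binary domain and estimates its long-time diffusivity, the reference
#' `D_GT` against which thresholded domains are judged.
#'
#' @param gt_domain A [binary_domain] with at least one pore site.
#' @param config A [simulation_config].
#' @param t_min_s Burn-in passed to [estimate_diffusivity()].
#' @return A [estimate_diffusivity()] result.
#' @export
ground_truth_diffusivity <- function(gt_domain, config = simulation_config(),
                                     t_min_s = 0.001) {
  estimate_diffusivity(run_simulation(gt_domain, config), t_min_s = t_min_s,
                       dp = config$diffusivity_dp)
}

#' Sweep the binarization threshold against a ground-truth domain
#'
#' For each BTV in the grid: binarize the map, simulate, estimate `D`, and
#' form the ratio `D / D_GT`. The same simulation seed is used at every BTV
#' (common random numbers), so the curve reflects geometry rather than
#' sampling noise.
#'
#' @param map A [grayscale_map], same dimensions as `gt_domain`.
#' @param gt_domain Ground-truth [binary_domain].
#' @param btv_grid Integer thresholds to evaluate (sorted internally).
#' @param config A [simulation_config].
#' @param polarity Binarization polarity, see [binarize()].
#' @param t_min_s Burn-in for the diffusivity fit.
#' @param d_gt Optional precomputed ground-truth estimate (saves one
#'   simulation when sweeping several maps of the same labelled domain).
#' @return Data frame with columns `btv`, `porosity`, `d_normalized`,
#'   `ratio` (= D / D_GT); the attribute `d_gt` carries the ground-truth
#'   estimate.
#' @export
sweep_btv <- function(map, gt_domain, btv_grid = seq(0, 255, by = 5),
                      config = simulation_config(),
                      polarity = "dark_pore", t_min_s = 0.001,
                      d_gt = NULL) {
  stopifnot(inherits(map, "grayscale_map"),
            inherits(gt_domain, "binary_domain"))
  if (!identical(dim(map$pixels), dim(gt_domain$sites))) {
    stop("map and ground-truth domain must have identical dimensions")
  }
  if (length(btv_grid) < 1) stop("btv_grid must be non-empty")
  btv_grid <- sort(unique(as.integer(btv_grid)))
  d_gt <- d_gt %||% ground_truth_diffusivity(gt_domain, config, t_min_s)
  if (d_gt$d_cm2_s <= 0) {
    stop("ground-truth diffusivity is 0; the ratio D/D_GT is undefined")
  }
  res <- data.frame(btv = btv_grid, porosity = NA_real_,
                    d_normalized = NA_real_, ratio = NA_real_)
  for (k in seq_along(btv_grid)) {
    dom <- binarize(map, btv_grid[k], polarity)
    res$porosity[k] <- porosity(dom)
    if (any(dom$sites)) {
      est <- estimate_diffusivity(run_simulation(dom, config),
                                  t_min_s = t_min_s,
                                  dp = config$diffusivity_dp)
      res$d_normalized[k] <- est$d_normalized
    } else {
      res$d_normalized[k] <- 0  # fully blocked domain
    }
    res$ratio[k] <- res$d_normalized[k] * config$diffusivity_dp / d_gt$d_cm2_s
  }
  attr(res, "d_gt") <- d_gt
  res
}

#' Locate the optimal binarization threshold from sweep curves
#'
#' Averages `D / D_GT` over images at each threshold, then takes the optimal
#' BTV as the linear interpolation of the first upward crossing of ratio 1.
#' The tolerance band is the contiguous BTV interval over which the mean
#' ratio stays within \[0.9, 1.1\] (the interval containing the crossing
#' when one exists, otherwise the first such interval). A missing crossing
#' is reported as `NA`, never fabricated.
#'
#' @param curves A single sweep data frame or a list of them (as returned by
#'   [sweep_btv()]); all must share the same `btv` grid.
#' @param class_label Optional packing-class annotation.
#' @return An object of class `calibration_curve`: `btv_values`,
#'   `ratio_mean`, `ratio_spread` (sd across images, 0 for one image),
#'   `optimal_btv`, `tolerance_band` (`c(lo, hi)` or `NULL`),
#'   `class_label`.
#' @export
find_optimal_btv <- function(curves, class_label = NA) {
  if (is.data.frame(curves)) curves <- list(curves)
  if (length(curves) < 1) stop("need at least one sweep curve")
  btv <- curves[[1]]$btv
  for (cv in curves) {
    if (!identical(cv$btv, btv)) stop("curves must share a common btv grid")
  }
  ratios <- vapply(curves, function(cv) cv$ratio, numeric(length(btv)))
  ratios <- matrix(ratios, nrow = length(btv))
  ratio_mean <- rowMeans(ratios)
  ratio_spread <- if (ncol(ratios) > 1) apply(ratios, 1, sd) else
    rep(0, length(btv))

  optimal <- NA_real_
  cross_idx <- NA_integer_
  if (ratio_mean[1] >= 1) {
    optimal <- btv[1]
    cross_idx <- 1L
  } else {
    for (k in seq_len(length(btv) - 1)) {
      if (ratio_mean[k] < 1 && ratio_mean[k + 1] >= 1) {
        frac <- (1 - ratio_mean[k]) / (ratio_mean[k + 1] - ratio_mean[k])
        optimal <- btv[k] + frac * (btv[k + 1] - btv[k])
        cross_idx <- k + 1L
        break
      }
    }
  }

  in_band <- ratio_mean >= 0.9 & ratio_mean <= 1.1
  band <- NULL
  if (any(in_band)) {
    runs <- rle(in_band)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    true_runs <- which(runs$values)
    pick <- true_runs[1]
    if (!is.na(cross_idx)) {
      covering <- true_runs[starts[true_runs] <= cross_idx &
                            ends[true_runs] >= cross_idx - 1L]
      if (length(covering)) pick <- covering[1]
    }
    band <- c(btv[starts[pick]], btv[ends[pick]])
  }

  structure(list(btv_values = btv, ratio_mean = ratio_mean,
                 ratio_spread = ratio_spread, optimal_btv = optimal,
                 tolerance_band = band, class_label = class_label),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d thresholds, optimal BTV %s, band %s\n",
              length(x$btv_values),
              if (is.na(x$optimal_btv)) "absent" else
                sprintf("%.1f", x$optimal_btv),
              if (is.null(x$tolerance_band)) "empty" else
                sprintf("[%d, %d]", x$tolerance_band[1],
                        x$tolerance_band[2])))
  invisible(x)
}

#' Calibrate the binarization threshold over a set of images
#'
#' Sweeps every map against its ground truth on a coarse threshold grid,
#' and optionally refines with step-1 thresholds around the crossing of
#' the mean curve, matching the precision at which optimal thresholds are
#' usefully reported.
#'
#' @param maps List of [grayscale_map] objects.
#' @param gt_domains List of matching ground-truth [binary_domain]s.
#' @param btv_grid Coarse threshold grid (default 0-255 step 5).
#' @param config A [simulation_config].
#' @param polarity Binarization polarity.
#' @param refine If `TRUE` (default), re-sweep with step 1 within one coarse
#'   step either side of the crossing.
#' @param class_label Annotation passed through to the curve.
#' @param t_min_s Burn-in for diffusivity fits.
#' @return A [find_optimal_btv()] result on the (possibly refined) grid.
#' @export
calibrate_btv <- function(maps, gt_domains, btv_grid = seq(0, 255, by = 5),
                          config = simulation_config(),
                          polarity = "dark_pore", refine = TRUE,
                          class_label = NA, t_min_s = 0.001) {
  if (length(maps) != length(gt_domains)) {
    stop("maps and gt_domains must pair up")
  }
  d_gts <- lapply(gt_domains, ground_truth_diffusivity, config = config,
                  t_min_s = t_min_s)
  run_grid <- function(grid) {
    curves <- lapply(seq_along(maps), function(k) {
      sweep_btv(maps[[k]], gt_domains[[k]], grid, config, polarity,
                t_min_s, d_gt = d_gts[[k]])
    })
    find_optimal_btv(curves, class_label = class_label)
  }
  coarse <- run_grid(btv_grid)
  if (!refine || is.na(coarse$optimal_btv)) return(coarse)
  step <- if (length(btv_grid) > 1) min(diff(sort(btv_grid))) else 0
  if (step <= 1) return(coarse)
  lo <- max(0, floor(coarse$optimal_btv) - step)
  hi <- min(255, ceiling(coarse$optimal_btv) + step)
  run_grid(sort(unique(c(btv_grid, seq(lo, hi, by = 1)))))
}

#' Coarsen a binary domain to a larger lattice spacing
#'
#' Blocks of `factor x factor` fine sites collapse to one coarse site that
#' is pore only if every fine site is pore: a tracer occupying one coarse
#' site must fit entirely through the pore, so coarsening tightens the
#' effective molecular radius tied to the lattice spacing. The domain is
#' cropped (bottom/right) to whole blocks.
#'
#' @param domain A [binary_domain].
#' @param factor Integer coarsening factor >= 1.
#' @return A [binary_domain] with `lattice_spacing_nm` scaled by `factor`.
#' @export
coarsen_domain <- function(domain, factor) {
  stopifnot(inherits(domain, "binary_domain"))
  factor <- as.integer(factor)
  if (factor < 1) stop("factor must be >= 1")
  if (factor == 1) return(domain)
  sites <- domain$sites
  nr <- nrow(sites) %/% factor
  nc <- ncol(sites) %/% factor
  if (nr < 1 || nc < 1) stop("domain smaller than one coarse site")
  sites <- sites[seq_len(nr * factor), seq_len(nc * factor), drop = FALSE]
  coarse <- matrix(TRUE, nr, nc)
  for (a in seq_len(factor)) {
    for (b in seq_len(factor)) {
      coarse <- coarse & sites[seq(a, by = factor, length.out = nr),
                               seq(b, by = factor, length.out = nc)]
    }
  }
  binary_domain(coarse,
                lattice_spacing_nm = domain$lattice_spacing_nm * factor,
                provenance = domain$provenance, btv_used = domain$btv_used)
}

#' Sensitivity of the optimal threshold to lattice spacing
#'
#' Repeats the threshold sweep at coarsened lattice spacings (the spacing
#' sets an upper bound on the effective tracer radius) and reports the
#' optimal BTV and tolerance band per spacing.
#'
#' @param map A [grayscale_map].
#' @param gt_domain Matching ground-truth [binary_domain].
#' @param btv_grid Thresholds to evaluate.
#' @param config A [simulation_config]; its `lattice_spacing_nm` is scaled
#'   per factor.
#' @param factors Integer coarsening factors (default 1:4, i.e. 8, 16, 24,
#'   32 nm at the default spacing).
#' @param polarity Binarization polarity.
#' @param t_min_s Burn-in for diffusivity fits.
#' @return Data frame with one row per spacing: `factor`, `spacing_nm`,
#'   `optimal_btv`, `band_lo`, `band_hi`.
#' @export
btv_spacing_sensitivity <- function(map, gt_domain,
                                    btv_grid = seq(0, 255, by = 5),
                                    config = simulation_config(),
                                    factors = 1:4,
                                    polarity = "dark_pore",
                                    t_min_s = 0.001) {
  out <- data.frame(factor = as.integer(factors),
                    spacing_nm = map$pixel_size_nm * factors,
                    optimal_btv = NA_real_, band_lo = NA_real_,
                    band_hi = NA_real_)
  for (k in seq_along(factors)) {
    f <- factors[k]
    gt_k <- coarsen_domain(gt_domain, f)
    cfg_k <- config
    cfg_k$lattice_spacing_nm <- config$lattice_spacing_nm * f
    d_gt <- ground_truth_diffusivity(gt_k, cfg_k, t_min_s)
    res <- data.frame(btv = sort(unique(as.integer(btv_grid))))
    res$ratio <- NA_real_
    for (m in seq_len(nrow(res))) {
      dom <- coarsen_domain(binarize(map, res$btv[m], polarity), f)
      if (any(dom$sites) && d_gt$d_cm2_s > 0) {
        est <- estimate_diffusivity(run_simulation(dom, cfg_k),
                                    t_min_s = t_min_s,
                                    dp = cfg_k$diffusivity_dp)
        res$ratio[m] <- est$d_cm2_s / d_gt$d_cm2_s
      } else {
        res$ratio[m] <- 0
      }
    }
    curve <- find_optimal_btv(res)
    out$optimal_btv[k] <- curve$optimal_btv
    if (!is.null(curve$tolerance_band)) {
      out$band_lo[k] <- curve$tolerance_band[1]
      out$band_hi[k] <- curve$tolerance_band[2]
    }
  }
  out
}
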