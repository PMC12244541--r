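# Next-reaction lattice kinetic Monte Carlo engine (R surface; the event
# loop itself is compiled, see src/lkmc.cpp).

#' Configuration for an LKMC diffusion simulation
#'
#' @param diffusivity_dp Free (unhindered) tracer diffusivity `Dp` in cm^2/s.
#'   Default `1e-6`, typical of protein diffusion in water.
#' @param lattice_spacing_nm Lattice spacing `h` in nm (default 8, the
#'   in-plane SEM pixel resolution). Each of the four directional hops is an
#'   independent event with rate `Dp / h^2`.
#' @param n_particles Number of tracer particles (default 1000).
#' @param t_end_s Total simulated time in seconds (default 0.003, long
#'   enough for a diffusion length of about 1.1 um at the default `Dp`).
#' @param sample_times_s Strictly increasing times at which the ensemble MSD
#'   is recorded; default 31 uniformly spaced times over `[0, t_end_s]`.
#' @param seed RNG seed; runs are bit-reproducible given the seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(diffusivity_dp = 1e-6, lattice_spacing_nm = 8,
                              n_particles = 1000, t_end_s = 0.003,
                              sample_times_s = NULL, seed = 1) {
  if (diffusivity_dp <= 0) stop("diffusivity_dp must be positive")
  if (lattice_spacing_nm <= 0) stop("lattice_spacing_nm must be positive")
  if (n_particles < 1) stop("n_particles must be >= 1")
  if (t_end_s <= 0) stop("t_end_s must be positive")
  if (is.null(sample_times_s)) {
    sample_times_s <- seq(0, t_end_s, length.out = 31)
  }
  if (is.unsorted(sample_times_s, strictly = TRUE)) {
    stop("sample_times_s must be strictly increasing")
  }
  if (any(sample_times_s < 0) || max(sample_times_s) > t_end_s) {
    stop("sample_times_s must lie in [0, t_end_s]")
  }
  structure(list(diffusivity_dp = diffusivity_dp,
                 lattice_spacing_nm = lattice_spacing_nm,
                 n_particles = as.integer(n_particles),
                 t_end_s = t_end_s,
                 sample_times_s = sample_times_s,
                 seed = seed),
            class = "simulation_config")
}

#' Fold an unbounded lattice coordinate into a mirrored domain
#'
#' Mirror boundary conditions tile the plane with reflected copies of the
#' domain, so trajectories continue without discontinuity past its edges.
#' The fold is the symmetric (repeated-edge) reflection with period
#' `2 * extent`: `m = x mod 2*extent`, result `m` if `m < extent`, else
#' `2*extent - 1 - m`.
#'
#' @param x Integer coordinate(s) on the unbounded axis.
#' @param extent Number of sites along the axis.
#' @return Folded coordinate(s) in `[0, extent)` (0-based).
#' @examples
#' fold_coordinate(c(3, 10, -1), 10)  # 3, 9, 0
#' @export
fold_coordinate <- function(x, extent) {
  if (length(extent) != 1 || extent < 1) stop("extent must be >= 1")
  fold_coordinate_cpp(as.numeric(x), as.integer(extent))
}

#' Tentative event time of the next-reaction scheme
#'
#' A diffusive hop pending at system time `t_sys` fires at
#' `t_event = t_sys - h^2 log(r) / Dp` with `r` uniform on (0, 1], i.e. the
#' waiting time is exponential with rate `Dp / h^2`.
#'
#' @param t_sys_s Current system time in seconds.
#' @param h_cm Lattice spacing in cm.
#' @param dp_cm2_s Free diffusivity in cm^2/s.
#' @param r Uniform random draw(s) in (0, 1].
#' @return Event time(s) in seconds.
#' @export
draw_event_time <- function(t_sys_s, h_cm, dp_cm2_s, r) {
  if (h_cm <= 0 || dp_cm2_s <= 0) stop("h_cm and dp_cm2_s must be positive")
  if (any(r <= 0) || any(r > 1)) {
    stop("r must lie in (0, 1]; r = 0 would give an infinite event time")
  }
  t_sys_s - h_cm^2 * log(r) / dp_cm2_s
}

#' Ensemble mean-squared-displacement series
#'
#' @param times_s Strictly increasing sample times (s).
#' @param msd_cm2 Ensemble MSD at each time (cm^2),
#'   `MSD(t) = mean_i |r_i(t) - r_i(0)|^2` over tracers, computed from
#'   unfolded displacements.
#' @param n_particles Ensemble size.
#' @param n_events Number of executed hop events (diagnostic, optional).
#' @param config The [simulation_config] used (optional).
#' @return An object of class `msd_series`.
#' @export
msd_series <- function(times_s, msd_cm2, n_particles, n_events = NA,
                       config = NULL) {
  if (length(times_s) != length(msd_cm2)) {
    stop("times_s and msd_cm2 must have equal length")
  }
  if (is.unsorted(times_s, strictly = TRUE)) {
    stop("times_s must be strictly increasing")
  }
  if (any(msd_cm2 < 0)) stop("msd must be non-negative")
  if (any(times_s == 0) && msd_cm2[times_s == 0] != 0) {
    stop("msd at t = 0 must be 0")
  }
  structure(list(times_s = times_s, msd_cm2 = msd_cm2,
                 n_particles = n_particles, n_events = n_events,
                 config = config),
            class = "msd_series")
}

#' @export
print.msd_series <- function(x, ...) {
  cat(sprintf("<msd_series> %d samples to t = %.4g s, %d particles\n",
              length(x$times_s), max(x$times_s), x$n_particles))
  invisible(x)
}

#' Simulate hindered tracer diffusion on a binary domain
#'
#' Runs the next-reaction LKMC: each tracer carries one tentative event per
#' lattice direction drawn via [draw_event_time()]; the globally earliest
#' event executes, the clock advances to it, and the moved particle's four
#' events are redrawn. Hops into cell sites are made inaccessible by a
#' sentinel-infinite time. Particles start uniformly at random over pore
#' sites (tracers do not interact, so sites may be shared) and move on
#' unfolded coordinates; legality is checked on coordinates folded by the
#' mirror boundary, so trajectories tile an infinite reflected plane. The
#' ensemble MSD is recorded from unfolded displacements at each sample time.
#'
#' @param domain A [binary_domain] with at least one pore site.
#' @param config A [simulation_config].
#' @param check_legality If `TRUE`, assert at every sample that every folded
#'   position is a pore site (debug aid; slows long runs only marginally).
#' @return An [msd_series].
#' @export
run_simulation <- function(domain, config = simulation_config(),
                           check_legality = FALSE) {
  stopifnot(inherits(domain, "binary_domain"),
            inherits(config, "simulation_config"))
  if (!any(domain$sites)) stop("domain has no pore sites")
  h_cm <- config$lattice_spacing_nm * 1e-7  # nm -> cm, converted once
  res <- with_seed(config$seed,
    run_lkmc_cpp(domain$sites, h_cm, config$diffusivity_dp,
                 config$n_particles, config$t_end_s, config$sample_times_s,
                 check_legality))
  msd_series(config$sample_times_s, res$msd_cm2, config$n_particles,
             n_events = res$n_events, config = config)
}
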