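fake_curve <- function(btv, ratio) data.frame(btv = btv, ratio = ratio)

test_that("the optimal threshold interpolates the first upward crossing", {
  cv <- fake_curve(c(5, 15), c(0.5, 1.5))
  res <- find_optimal_btv(cv)
  expect_equal(res$optimal_btv, 10)

  # averaging across images happens before the crossing search
  res2 <- find_optimal_btv(list(fake_curve(c(5, 15), c(0.4, 1.4)),
                                fake_curve(c(5, 15), c(0.6, 1.6))))
  expect_equal(res2$optimal_btv, 10)
  expect_equal(res2$ratio_mean, c(0.5, 1.5))
  expect_equal(res2$ratio_spread, c(sd(c(0.4, 0.6)), sd(c(1.4, 1.6))))
})

test_that("an absent crossing is reported, not fabricated", {
  res <- find_optimal_btv(fake_curve(c(0, 10, 20), c(0.2, 0.5, 0.8)))
  expect_true(is.na(res$optimal_btv))
  expect_null(res$tolerance_band)
})

test_that("a curve identically 1 is optimal everywhere", {
  res <- find_optimal_btv(fake_curve(c(0, 10, 20), c(1, 1, 1)))
  expect_equal(res$optimal_btv, 0)
  expect_equal(res$tolerance_band, c(0, 20))
})

test_that("the tolerance band brackets the crossing", {
  cv <- fake_curve(seq(0, 60, by = 10),
                   c(0.2, 0.85, 0.95, 1.05, 1.15, 1.5, 2.0))
  res <- find_optimal_btv(cv)
  expect_equal(res$tolerance_band, c(20, 30))  # 1.15 at 40 is outside
  expect_gte(res$optimal_btv, 20)
  expect_lte(res$optimal_btv, 30)
})

test_that("sweeping a noiseless rendering gives ratio 1 between the levels", {
  dom <- generate_domain(synthetic_spec("dense", grid_shape = c(80, 80),
                                        seed = 4))
  map <- emulate_grayscale(dom, noiseless_emulation())
  cfg <- quick_config(n_particles = 60, t_end_s = 0.0015, seed = 2)
  sw <- sweep_btv(map, dom, btv_grid = c(10, 60, 150, 200, 210), cfg,
                  t_min_s = 0.0005)
  # btv below both levels: everything cell, fully blocked
  expect_equal(sw$ratio[sw$btv == 10], 0)
  # btv between the levels: identical domain, identical seed, exact ratio 1
  expect_equal(sw$ratio[sw$btv %in% c(60, 150, 200)], rep(1, 3))
  # btv above both levels: all pore, free diffusion beats the packed truth
  expect_gt(sw$ratio[sw$btv == 210], 1)
})

test_that("sweeps demand matching dimensions and a nonzero ground truth", {
  dom <- generate_fixture("empty", c(20, 20))
  map <- emulate_grayscale(generate_fixture("empty", c(10, 10)),
                           noiseless_emulation())
  expect_error(sweep_btv(map, dom, c(100), quick_config()), "dimensions")

  trap <- generate_fixture("isolated_trap", c(21, 21))
  map2 <- emulate_grayscale(trap, noiseless_emulation())
  expect_error(sweep_btv(map2, trap, c(100),
                         quick_config(n_particles = 10)),
               "undefined")
})

test_that("coarsening keeps a coarse site pore only if every fine site is", {
  s <- matrix(TRUE, 4, 4)
  s[1, 2] <- FALSE          # poisons the top-left 2x2 block
  dom <- binary_domain(s, lattice_spacing_nm = 8)
  co <- coarsen_domain(dom, 2)
  expect_equal(dim(co$sites), c(2L, 2L))
  expect_identical(co$sites, matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  expect_equal(co$lattice_spacing_nm, 16)

  # a checkerboard has no all-pore block at any even coarsening
  cb <- generate_fixture("checkerboard", c(8, 8))
  expect_equal(porosity(coarsen_domain(cb, 2)), 0)

  expect_identical(coarsen_domain(dom, 1), dom)
})

test_that("lattice-spacing sensitivity reports one optimum per spacing", {
  dom <- generate_domain(synthetic_spec("sparse", grid_shape = c(80, 80),
                                        seed = 5))
  map <- emulate_grayscale(dom, noiseless_emulation())
  cfg <- quick_config(n_particles = 40, t_end_s = 0.001)
  sens <- btv_spacing_sensitivity(map, dom, btv_grid = c(10, 110, 210),
                                  config = cfg, factors = 1:2,
                                  t_min_s = 0.00025)
  expect_equal(sens$spacing_nm, c(8, 16))
  # noiseless rendering: the between-levels threshold is optimal at both
  # spacings because coarsened prediction and truth coincide
  expect_equal(sens$optimal_btv, c(110, 110), tolerance = 25)
})

test_that("calibration over noisy images lands between the class means", {
  dom <- generate_domain(synthetic_spec("dense", grid_shape = c(80, 80),
                                        seed = 7))
  map <- emulate_grayscale(dom, grayscale_emulation_spec(seed = 3))
  cfg <- quick_config(n_particles = 60, t_end_s = 0.0015, seed = 4)
  curve <- calibrate_btv(list(map), list(dom),
                         btv_grid = seq(0, 250, by = 25), config = cfg,
                         refine = FALSE, t_min_s = 0.0005)
  expect_gt(curve$optimal_btv, 20)
  expect_lt(curve$optimal_btv, 200)
})
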