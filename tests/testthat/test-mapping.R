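test_that("staggered decomposition counts follow the window arithmetic", {
  big <- binary_domain(matrix(FALSE, 1250, 1250))
  subs <- decompose(big, subdomain_grid(250, 125))
  expect_length(subs, 81)

  one <- binary_domain(matrix(TRUE, 250, 250))
  expect_length(decompose(one, subdomain_grid(250, 125)), 1)

  expect_length(decompose(big, subdomain_grid(250, 250)), 25)  # no overlap

  small <- binary_domain(matrix(TRUE, 100, 100))
  expect_error(decompose(small, subdomain_grid(250, 125)), "smaller")
  expect_error(subdomain_grid(250, 120), "divide")

  # (N - s)/stagger + 1 windows per axis for assorted shapes
  for (case in list(c(500, 100, 50), c(300, 60, 20), c(240, 120, 40))) {
    N <- case[1]; s <- case[2]; st <- case[3]
    dom <- binary_domain(matrix(TRUE, N, N))
    expect_length(decompose(dom, subdomain_grid(s, st)),
                  ((N - s) / st + 1)^2)
  }
})

test_that("windows carry the parent geometry", {
  set.seed(3)
  dom <- binary_domain(matrix(runif(200 * 200) > 0.5, 200, 200),
                       lattice_spacing_nm = 16)
  subs <- decompose(dom, subdomain_grid(100, 50))
  origins <- attr(subs, "origins")
  k <- 5
  i0 <- origins$row[k]; j0 <- origins$col[k]
  expect_identical(subs[[k]]$sites,
                   dom$sites[(i0 + 1):(i0 + 100), (j0 + 1):(j0 + 100)])
  expect_equal(subs[[k]]$lattice_spacing_nm, 16)
})

test_that("an all-cell parent maps to zero diffusivity everywhere", {
  dom <- binary_domain(matrix(FALSE, 1250, 1250))
  hm <- local_diffusivity_map(dom, subdomain_grid(250, 125), quick_config())
  expect_equal(dim(hm$d_normalized_grid), c(10L, 10L))  # 100 output cells
  expect_equal(nrow(hm$records), 81)
  expect_true(all(hm$d_normalized_grid == 0))
  expect_true(all(hm$porosity_grid == 0))
  expect_true(all(hm$coverage_counts %in% c(1L, 2L, 4L)))
})

test_that("a uniform empty parent recovers free diffusion per cell", {
  dom <- generate_fixture("empty", c(100, 100))
  cfg <- quick_config(n_particles = 100, t_end_s = 0.002, seed = 2)
  hm <- local_diffusivity_map(dom, subdomain_grid(50, 25), cfg,
                              t_min_s = 0.0005)
  expect_equal(dim(hm$d_normalized_grid), c(4L, 4L))
  expect_true(all(hm$porosity_grid == 1))
  # per-cell values carry per-subdomain Monte-Carlo error; the grid mean
  # averages it down
  expect_true(all(abs(hm$d_normalized_grid - 1) < 0.5))
  expect_lt(abs(mean(hm$d_normalized_grid) - 1), 0.15)
})

test_that("overlap averaging stays within the covering subdomain range", {
  set.seed(9)
  dom <- binary_domain(matrix(runif(150 * 150) > 0.35, 150, 150))
  grid <- subdomain_grid(50, 25)
  hm <- local_diffusivity_map(dom, grid,
                              quick_config(n_particles = 40, t_end_s = 0.001),
                              t_min_s = 0.00025)
  recs <- hm$records
  f <- grid$subdomain_size_sites / grid$stagger_sites
  for (ci in seq_len(nrow(hm$d_normalized_grid))) {
    for (cj in seq_len(ncol(hm$d_normalized_grid))) {
      covering <- recs$d_normalized[
        recs$origin_row / 25 + 1 <= ci & ci <= recs$origin_row / 25 + f &
        recs$origin_col / 25 + 1 <= cj & cj <= recs$origin_col / 25 + f]
      expect_equal(length(covering), hm$coverage_counts[ci, cj])
      expect_equal(hm$d_normalized_grid[ci, cj], mean(covering))
      expect_gte(hm$d_normalized_grid[ci, cj], min(covering))
      expect_lte(hm$d_normalized_grid[ci, cj], max(covering))
    }
  }
})

test_that("odd-sized parents are cropped to the stagger", {
  dom <- binary_domain(matrix(TRUE, 130, 140))
  expect_message(subs <- decompose(dom, subdomain_grid(50, 25)),
                 "cropping")
  expect_equal(attr(subs, "cropped_shape"), c(125L, 125L))
})

test_that("porosity-diffusivity records pool across heatmaps", {
  r1 <- data.frame(porosity = c(1, 0.5), d_normalized = c(0.99, 0.4))
  r2 <- data.frame(porosity = 0.1, d_normalized = 0.05)
  tab <- porosity_diffusivity_table(list(r1, r2),
                                    class_labels = c("sparse", "dense"),
                                    provenance = "synthetic")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$class_label, c("sparse", "sparse", "dense"))

  # single empty-domain record: porosity 1, D/Dp about 1
  dom <- generate_fixture("empty", c(60, 60))
  hm <- local_diffusivity_map(dom, subdomain_grid(60, 60),
                              quick_config(n_particles = 80, t_end_s = 0.002),
                              t_min_s = 0.0005)
  tab1 <- porosity_diffusivity_table(hm)
  expect_equal(tab1$porosity, 1)
  expect_equal(tab1$d_normalized, 1, tolerance = 0.25)
})
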