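test_that("analytic fixtures have exactly-known porosities", {
  expect_equal(porosity(generate_fixture("empty", c(100, 100))), 1)
  expect_equal(porosity(generate_fixture("channel", c(100, 100), 1)), 0.01)
  expect_equal(porosity(generate_fixture("isolated_trap", c(9, 11))), 1 / 99)
  expect_equal(porosity(generate_fixture("checkerboard", c(10, 10))), 0.5)
  expect_error(generate_fixture("channel", c(10, 10), 11), "wider than")
})

test_that("generated domains are deterministic and hit their porosity band", {
  spec <- synthetic_spec("dense", seed = 5)
  d1 <- generate_domain(spec)
  d2 <- generate_domain(spec)
  expect_identical(d1$sites, d2$sites)

  for (seed in 1:3) {
    dn <- generate_domain(synthetic_spec("dense", seed = seed))
    expect_gte(porosity(dn), 0.06)
    expect_lte(porosity(dn), 0.16)
    sp <- generate_domain(synthetic_spec("sparse", seed = seed))
    expect_gte(porosity(sp), 0.28)
    expect_lte(porosity(sp), 0.38)
  }
})

test_that("ellipse_count = 0 yields an all-pore domain", {
  d <- generate_domain(synthetic_spec("sparse", grid_shape = c(30, 30),
                                      ellipse_count = 0))
  expect_equal(porosity(d), 1)
})

test_that("an unattainable porosity target errors with the attained value", {
  spec <- synthetic_spec("dense", grid_shape = c(60, 60),
                         target_porosity = 0.9)  # needs far more generators
  expect_error(generate_domain(spec, max_ellipses = 15), "unattainable")
})

test_that("hybrid concatenates a sparse and a dense half", {
  hy <- generate_domain(synthetic_spec("hybrid", grid_shape = c(120, 240),
                                       seed = 2))
  expect_equal(dim(hy$sites), c(120L, 240L))
  left <- mean(hy$sites[, 1:120])
  right <- mean(hy$sites[, 121:240])
  expect_gt(left, right)  # sparse half more porous than dense half
})

test_that("dense_rbc contains one large blocked inclusion", {
  # same seed: the packing is identical, the inclusion is the difference;
  # its interior swallows pore channels and its rim carves new pore
  dr <- generate_domain(synthetic_spec("dense_rbc", seed = 3))
  dn <- generate_domain(synthetic_spec("dense", seed = 3))
  expect_gt(sum(!dr$sites & dn$sites), 1000)  # channels sealed by the body
  expect_gt(sum(dr$sites & !dn$sites), 1000)  # pore rim around the body
})

test_that("noiseless emulation round-trips exactly through binarization", {
  dom <- generate_domain(synthetic_spec("dense", grid_shape = c(80, 80),
                                        seed = 4))
  map <- emulate_grayscale(dom, noiseless_emulation())
  expect_setequal(unique(as.vector(map$pixels)), c(20L, 200L))
  for (btv in c(21, 110, 200)) {
    expect_equal(iou(binarize(map, btv, "dark_pore"), dom), 1)
    expect_identical(binarize(map, btv, "dark_pore")$sites, dom$sites)
  }
  # the literal dark-is-cell rule recovers a pore-bright rendering instead
  map_inv <- emulate_grayscale(dom, noiseless_emulation(pore_level = 200,
                                                        cell_level = 20))
  expect_equal(iou(binarize(map_inv, 110, "dark_cell"), dom), 1)
})

test_that("blurred noisy emulation still recovers the domain at midpoint", {
  dom <- generate_domain(synthetic_spec("dense", grid_shape = c(100, 100),
                                        seed = 6))
  map <- emulate_grayscale(dom, grayscale_emulation_spec(seed = 9))
  expect_gt(iou(binarize(map, 110, "dark_pore"), dom), 0.9)
  # bimodal brightness histogram: mass near both class means
  expect_gt(mean(map$pixels < 60), 0.05)
  expect_gt(mean(map$pixels > 160), 0.05)
})

test_that("an all-pore domain renders at the pore brightness only", {
  dom <- generate_fixture("empty", c(10, 10))
  map <- emulate_grayscale(dom, noiseless_emulation())
  expect_true(all(map$pixels == 20))
})

test_that("emulation is deterministic under a fixed seed", {
  dom <- generate_domain(synthetic_spec("sparse", grid_shape = c(60, 60),
                                        seed = 8))
  spec <- grayscale_emulation_spec(seed = 3)
  expect_identical(emulate_grayscale(dom, spec)$pixels,
                   emulate_grayscale(dom, spec)$pixels)
})

test_that("dense packings have narrower pores than sparse packings", {
  for (seed in 1:3) {
    md <- pore_width_distribution(
      generate_domain(synthetic_spec("dense", seed = seed)))$summary[["50%"]]
    ms <- pore_width_distribution(
      generate_domain(synthetic_spec("sparse", seed = seed)))$summary[["50%"]]
    expect_lt(md, ms)
  }
})
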