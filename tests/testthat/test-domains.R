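test_that("NTSC grayscale conversion matches the scalar formula", {
  white <- array(255, dim = c(2, 3, 3))
  expect_true(all(to_grayscale(white)$pixels == 255))
  black <- array(0, dim = c(2, 3, 3))
  expect_true(all(to_grayscale(black)$pixels == 0))

  # independent scalar oracle for a few colours (round half to even)
  oracle <- function(rgb) round(0.299 * rgb[1] + 0.587 * rgb[2] + 0.114 * rgb[3])
  for (rgb in list(c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
                   c(12, 200, 77), c(128, 128, 128))) {
    img <- array(rep(rgb, each = 4), dim = c(2, 2, 3))
    expect_equal(to_grayscale(img)$pixels[1, 1], oracle(rgb))
  }
  expect_equal(to_grayscale(array(c(255, 0, 0), dim = c(1, 1, 3)))$pixels[1, 1],
               76)
})

test_that("already-grayscale input passes through unchanged", {
  m <- matrix(c(0, 100, 200, 255), 2, 2)
  expect_equal(to_grayscale(m)$pixels, matrix(as.integer(m), 2, 2))
})

test_that("grayscale conversion rejects malformed input", {
  expect_error(to_grayscale(array(0, dim = c(2, 2, 2))), "channel count")
  expect_error(to_grayscale(array(300, dim = c(2, 2, 3))), "\\[0, 255\\]")
  expect_error(to_grayscale(1:5), "2D")
})

test_that("binarization applies the threshold with both polarities", {
  px <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  map <- grayscale_map(px)

  # dark pixels become cell under dark_cell: the literal threshold rule
  dc <- binarize(map, 100, "dark_cell")
  expect_equal(porosity(dc), 0.5)
  expect_true(all(dc$sites[px == 200]))
  expect_false(any(dc$sites[px == 10]))

  # mirrored under the default polarity
  dp <- binarize(map, 100, "dark_pore")
  expect_equal(porosity(dp), 0.5)
  expect_true(all(dp$sites[px == 10]))

  # degenerate threshold: uniform map collapses to a single class
  u <- grayscale_map(matrix(0L, 4, 4))
  expect_true(porosity(binarize(u, 0, "dark_pore")) %in% c(0, 1))
  expect_true(porosity(binarize(u, 0, "dark_cell")) %in% c(0, 1))

  expect_error(binarize(map, 300), "\\[0, 255\\]")
  expect_error(binarize(map, -1), "\\[0, 255\\]")
})

test_that("re-binarizing a rendered two-level domain reproduces it", {
  dom <- generate_fixture("checkerboard", c(12, 12))
  map <- emulate_grayscale(dom, noiseless_emulation())
  for (btv in c(21, 60, 128, 199)) {
    expect_equal(binarize(map, btv, "dark_pore")$sites, dom$sites)
  }
})

test_that("porosity is monotone in the threshold across a full sweep", {
  for (seed in 1:3) {
    map <- random_map(15, 15, seed)
    sweep_p <- sapply(0:255, function(b) porosity(binarize(map, b, "dark_pore")))
    expect_true(all(diff(sweep_p) >= 0))
    sweep_c <- sapply(0:255, function(b) porosity(binarize(map, b, "dark_cell")))
    expect_true(all(diff(sweep_c) <= 0))
  }
})

test_that("porosity counts pore sites", {
  expect_equal(porosity(generate_fixture("empty", c(10, 10))), 1)
  expect_equal(porosity(generate_fixture("full", c(10, 10))), 0)
  s <- matrix(FALSE, 10, 10)
  s[seq_len(33)] <- TRUE
  expect_equal(porosity(binary_domain(s)), 0.33)
})

test_that("iou matches hand counts and handles the empty union", {
  blk <- matrix(TRUE, 4, 6)
  a <- blk; a[2:3, 2:3] <- FALSE          # 2x2 cell block
  b <- blk; b[2:3, 3:4] <- FALSE          # shifted one column
  expect_equal(iou(binary_domain(a), binary_domain(b)), 1 / 3)

  expect_equal(iou(binary_domain(a), binary_domain(a)), 1)
  d <- blk; d[1, 6] <- FALSE              # disjoint from a
  expect_equal(iou(binary_domain(a), binary_domain(d)), 0)

  empty <- binary_domain(matrix(TRUE, 3, 3))
  expect_equal(iou(empty, empty), 1)

  expect_error(iou(binary_domain(blk), binary_domain(matrix(TRUE, 3, 3))),
               "dimensions")
})

test_that("iou is symmetric, bounded, and 1 only for identical cell sets", {
  set.seed(42)
  for (k in 1:10) {
    a <- binary_domain(matrix(runif(64) > 0.5, 8, 8))
    b <- binary_domain(matrix(runif(64) > 0.5, 8, 8))
    v <- iou(a, b)
    expect_equal(v, iou(b, a))
    expect_gte(v, 0)
    expect_lte(v, 1)
    if (v == 1) expect_identical(a$sites, b$sites)
  }
})

test_that("iou summary implements the printed SE formula and its variant", {
  expect_equal(iou_summary(0.5), list(mean = 0.5, se = 0, n = 1,
                                      se_formula = "sd_over_n"))
  expect_equal(iou_summary(c(0.8, 0.8, 0.8))$se, 0)
  s <- iou_summary(c(0.2, 0.4))
  expect_equal(s$mean, 0.3)
  expect_equal(s$se, sd(c(0.2, 0.4)) / 2)
  s2 <- iou_summary(c(0.2, 0.4), "sd_over_sqrt_n")
  expect_equal(s2$se, sd(c(0.2, 0.4)) / sqrt(2))
  expect_error(iou_summary(numeric(0)), "at least one")
})

test_that("channel fixtures give a point mass at the channel width", {
  for (w in c(1, 3, 5, 7)) {
    ch <- generate_fixture("channel", c(41, 30), width_sites = w)
    pw <- pore_width_distribution(ch)
    expect_equal(unname(pw$summary[["50%"]]), w * 8)
    # modal bin contains the channel width
    modal <- which.max(pw$counts)
    expect_true(pw$bin_edges_nm[modal] < w * 8 &&
                pw$bin_edges_nm[modal + 1] >= w * 8)
    expect_equal(sum(pw$counts), sum(ch$sites))
  }
})

test_that("an unconfined pore is bounded by the field of view", {
  W <- 21
  pw <- pore_width_distribution(generate_fixture("empty", c(W, W)))
  expect_equal(max(pw$widths_nm), W * 8)      # largest inscribable disc
  modal <- which.max(pw$counts)
  expect_gte(pw$bin_edges_nm[modal + 1], W * 8)
  expect_error(pore_width_distribution(generate_fixture("full", c(5, 5))),
               "no pore sites")
})
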