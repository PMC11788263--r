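test_that("phantom configuration validates its invariants", {
  expect_error(phantom_config(shape = c(32, 64)), "shape")
  expect_error(phantom_config(bone_peak = 0), "bone_peak")
  expect_error(phantom_config(bone_peak = 1.5), "bone_peak")
  expect_error(phantom_config(n_anterior = -1), "counts")
})

test_that("background is deterministic, smooth, and bounded", {
  cfg <- phantom_config(seed = 5)
  b1 <- generate_background(cfg)
  b2 <- generate_background(cfg)
  expect_identical(b1, b2)
  expect_true(all(b1$background >= 0 & b1$background <= 0.8))
  expect_true(all(b1$lung_mask %in% c(0, 1)))

  # infinite-smoothness limit: the stochastic field becomes spatially
  # constant (differencing two seeds cancels the deterministic lung
  # depression, whose soft walls extend slightly beyond the ellipses)
  bf1 <- generate_background(phantom_config(seed = 5, background_scale = 1e9))
  bf2 <- generate_background(phantom_config(seed = 6, background_scale = 1e9))
  expect_lt(diff(range(bf1$background - bf2$background)), 1e-9)
  corner <- bf1$background[1:10, 1:10]   # far from both lung ellipses
  expect_lt(diff(range(corner)), 1e-3)
})

test_that("background spectrum is concentrated below the cutoff", {
  # DERIVED oracle: discrete Fourier transform of one seeded output, with
  # the deterministic lung depression removed by differencing two seeds'
  # fields (the depression is seed-independent)
  scale <- 32
  f1 <- generate_background(phantom_config(seed = 1, background_scale = scale))
  f2 <- generate_background(phantom_config(seed = 2, background_scale = scale))
  noise_part <- f1$background - f2$background
  spec <- Mod(stats::fft(noise_part))^2
  nr <- nrow(noise_part); nc <- ncol(noise_part)
  fr <- c(0:(nr %/% 2), -((ceiling(nr / 2) - 1):1)) / nr
  fc <- c(0:(nc %/% 2), -((ceiling(nc / 2) - 1):1)) / nc
  rad <- sqrt(outer(fr^2, fc^2, `+`))
  below <- sum(spec[rad <= 1 / scale + 1e-9])
  expect_gt(below / sum(spec), 0.99)
})

test_that("generate_bone has exact flat geometry and cross-section integral", {
  nr <- 96; nc <- 96; hw <- 6; peak <- 0.4; row <- 40
  b <- generate_bone(cbind(c(row, row, row), c(5, 48, 90)), hw, peak,
                     c(nr, nc), taper = 0)
  # straight horizontal centerline: upper at row - hw, lower at row + hw
  expect_equal(unname(b$upper$points[, 1]), rep(row - hw, nrow(b$upper$points)))
  expect_equal(unname(b$lower$points[, 1]), rep(row + hw, nrow(b$lower$points)))
  expect_equal(unname(b$centerline$points[, 1]),
               rep(row, nrow(b$centerline$points)))

  # DERIVED: continuous line integral of the raised cosine
  # integral of peak * 0.5 * (1 + cos(pi d / hw)) over d in (-hw, hw)
  # = peak * hw  (mean 1/2 times width 2 hw)
  expected <- peak * hw
  col <- 48
  f <- function(d) peak * 0.5 * (1 + cos(pi * abs(d) / hw)) * (abs(d) < hw)
  oracle <- integrate(f, -hw, hw)$value
  expect_equal(oracle, expected, tolerance = 1e-6)
  got <- sum(b$bone[, col])   # unit-spaced discrete transect
  expect_equal(got, expected, tolerance = 0.02)

  # peak = 0: zero image, edges still returned
  b0 <- generate_bone(cbind(c(row, row), c(5, 90)), hw, 0, c(nr, nc))
  expect_equal(max(b0$bone), 0)
  expect_gt(nrow(b0$upper$points), 2)

  expect_error(generate_bone(cbind(c(-3, 40), c(5, 90)), hw, 0.3, c(nr, nc)),
               "inside")
  expect_warning(
    generate_bone(cbind(c(3, 90), c(5, 90)), 6, 0.1, c(96, 96)),
    NA)  # interior curve: no clipping warning
})

test_that("generate_phantom satisfies the scene invariants", {
  # property check over seeds: exact additivity, edge-list bookkeeping,
  # bone support between the edges, determinism
  for (seed in c(1, 9, 23)) {
    sc <- generate_phantom(phantom_config(seed = seed, noise_sd = 0.02))
    expect_identical(sc$cxr, sc$soft + sc$bone)
    expect_length(sc$edge_lists, 5)  # 2 + 2 + 1 by default
    expect_identical(sort(names(sc$edge_masks)),
                     c("anterior", "clavicle", "posterior"))
    for (b in sc$edge_lists) {
      pts <- rbind(b$upper$points, b$lower$points, b$centerline$points)
      expect_true(all(pts[, 1] >= 1 & pts[, 1] <= nrow(sc$cxr)))
      expect_true(all(pts[, 2] >= 1 & pts[, 2] <= ncol(sc$cxr)))
    }
  }
  sc1 <- generate_phantom(phantom_config(seed = 4))
  sc2 <- generate_phantom(phantom_config(seed = 4))
  expect_identical(sc1, sc2)
})

test_that("bone-free noise-free phantom reduces to its background", {
  sc <- generate_phantom(phantom_config(n_anterior = 0, n_posterior = 0,
                                        n_clavicle = 0, n_corruptors = 0,
                                        noise_sd = 0))
  expect_identical(sc$cxr, sc$soft)
  expect_equal(max(sc$bone), 0)
  expect_length(sc$edge_lists, 0)
})

test_that("bone intensity is confined between paired edge polylines", {
  sc <- generate_phantom(phantom_config(seed = 2, n_anterior = 0,
                                        n_corruptors = 0))
  # rasterize the filled regions of all bones; bone > 0 must lie inside
  mask <- make_bone_region_mask(
    lapply(sc$edge_lists, function(e) {
      structure(list(upper = e$upper, lower = e$lower,
                     centerline = e$centerline, category = e$category),
                class = "bone_pair")
    }), dim(sc$cxr))
  expect_equal(max(sc$bone[mask == 0]), 0, tolerance = 1e-12)
})
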