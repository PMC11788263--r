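test_that("tangent and normal are exact on straight edges", {
  h <- edge_list(cbind(rep(10, 30), 1:30))
  tn <- tangent_normal(h, 15)
  expect_equal(abs(tn$tangent), c(0, 1))
  expect_equal(abs(tn$normal), c(1, 0))

  # 45-degree edge: finite difference of an exact line is exact
  d45 <- edge_list(cbind(1:30, 1:30))
  tn45 <- tangent_normal(d45, 15)
  expect_equal(tn45$tangent, c(sqrt(2) / 2, sqrt(2) / 2), tolerance = 1e-12)

  # endpoint: one-sided difference, still unit norm
  tne <- tangent_normal(d45, 1)
  expect_equal(sqrt(sum(tne$tangent^2)), 1, tolerance = 1e-12)

  # orientation towards a target point
  tno <- tangent_normal(h, 15, toward = c(20, 15))
  expect_gt(tno$normal[1], 0)
  expect_error(tangent_normal(edge_list(cbind(1, 1)), 1), "2 points")
})

test_that("find_opposite_point minimizes the parallelogram height", {
  lower <- edge_list(cbind(rep(20, 100), 1:100))
  res <- find_opposite_point(c(10, 50), c(1, 0), lower)
  expect_equal(unname(res$point), c(20, 50))
  expect_equal(res$h, 0)

  # DERIVED: exhaustive-scan oracle on random geometries
  set.seed(7)
  for (i in 1:50) {
    pts <- cbind(runif(40, 10, 60), sort(runif(40, 1, 90)))
    lo <- edge_list(pts)
    u <- c(runif(1, 1, 30), runif(1, 20, 70))
    ang <- runif(1, 0, 2 * pi)
    e <- c(cos(ang), sin(ang))
    v_r <- pts[, 1] - u[1]; v_c <- pts[, 2] - u[2]
    dist <- sqrt(v_r^2 + v_c^2)
    h <- abs(e[1] * v_c - e[2] * v_r)
    h[dist >= 100] <- Inf
    if (all(is.infinite(h))) next
    best <- which(h == min(h))
    if (length(best) > 1) best <- best[which.min(dist[best])]
    got <- find_opposite_point(u, e, lo, max_dist = 100)
    expect_equal(got$index, best)
  }

  far <- edge_list(cbind(rep(500, 10), 1:10))
  expect_error(find_opposite_point(c(10, 5), c(1, 0), far, max_dist = 100),
               "max_dist")
})

test_that("sample_profiles straightens bones with fixed edge rows", {
  sc <- flat_bone_scene()
  sp <- sample_profiles(sc$cxr, sc$pair, n_outer = 10, n_inner = 40,
                        max_dist = 40)
  expect_equal(dim(sp$profile$values), c(50, nrow(sc$pair$upper$points)))
  expect_equal(sp$profile$row_of_upper_edge, 11)
  expect_equal(sp$profile$row_of_lower_edge, 50)

  # constant image -> constant profile
  spc <- sample_profiles(matrix(0.42, 96, 96), sc$pair, max_dist = 40)
  expect_equal(max(abs(spc$profile$values - 0.42)), 0, tolerance = 1e-12)

  # flat-geometry phantom: identical cross-sections -> identical columns
  inner <- sp$profile$values[, 10:80]
  dev <- max(abs(inner - rowMeans(inner)))
  expect_lt(dev, 1e-6)

  # straightening: both edges land on their fixed rows (bone edge = 0 there,
  # peak midway)
  peak_rows <- apply(sp$profile$values[, 10:80], 2, which.max)
  expect_true(all(abs(peak_rows - 30.5) <= 1))

  expect_error(
    sample_profiles(sc$cxr, structure(list(
      upper = edge_list(cbind(rep(10, 4), 1:4)),
      lower = edge_list(cbind(rep(500, 4), 1:4))), class = "bone_pair"),
      max_dist = 5),
    "too short|5 valid")
})

test_that("reverse sampling inverts the map and fills holes by nearest value", {
  sc <- flat_bone_scene()
  sp <- sample_profiles(sc$cxr, sc$pair, max_dist = 40)

  # round trip: mean absolute error over the sampled footprint is within
  # the bilinear + scatter bound
  img <- reverse_sample(sp$profile, sp$map, dim(sc$cxr))
  touched <- img != 0
  expect_gt(sum(touched), 100)
  expect_lt(mean(abs(img - sc$cxr)[touched]), 2e-2)

  # all-ones profile -> ones on the footprint, zero elsewhere
  ones <- sp$profile; ones$values[] <- 1
  oimg <- reverse_sample(ones, sp$map, dim(sc$cxr))
  expect_true(all(oimg %in% c(0, 1)))
  expect_gt(sum(oimg), 0)

  # empty profile -> zero image
  empty <- ribsep:::new_profile_image(matrix(numeric(0), 0, 0), NA, NA)
  expect_equal(max(reverse_sample(empty,
                                  structure(list(r = matrix(numeric(0), 0, 0),
                                                 c = matrix(numeric(0), 0, 0)),
                                            class = "sampling_map"),
                                  c(20, 20))), 0)

  # DERIVED: constructed 1-px hole takes the value of its nearest assigned
  # pixel (exhaustive nearest search oracle)
  vals <- matrix(seq(0, 1, length.out = 25), 5, 5)
  mr <- matrix(rep(1:5, each = 5), 5, 5, byrow = TRUE)
  mc <- matrix(rep(1:5, 5), 5, 5, byrow = TRUE)
  # drop the sample that would land on (3, 3): its column offset makes
  # (3, 4)'s value the unique nearest assignment
  mr[2, 3] <- 3; mc[2, 3] <- 4  # duplicate onto (3,4); (3,3) never assigned
  map <- structure(list(r = mr, c = mc), class = "sampling_map")
  out <- reverse_sample(vals, map, c(5, 5))
  assigned <- matrix(FALSE, 5, 5)
  acc <- matrix(0, 5, 5); cnt <- matrix(0, 5, 5)
  for (i in seq_along(vals)) {
    acc[mr[i], mc[i]] <- acc[mr[i], mc[i]] + vals[i]
    cnt[mr[i], mc[i]] <- cnt[mr[i], mc[i]] + 1
  }
  assigned <- cnt > 0
  pos <- which(assigned, arr.ind = TRUE)
  d2 <- (pos[, 1] - 3)^2 + (pos[, 2] - 3)^2
  nn <- pos[which.min(d2), ]
  expect_equal(out[3, 3], acc[nn[1], nn[2]] / cnt[nn[1], nn[2]])
})

test_that("centerline profiles are centered with tagged bands", {
  img <- matrix(0.2, 64, 64)
  img[30, ] <- 0.9   # thin bright line on the centerline
  cl <- edge_list(cbind(rep(30, 40), 10:49))
  sp <- sample_centerline_profiles(img, cl, each_side = 10)
  expect_equal(dim(sp$profile$values), c(21, 40))
  # horizontal centerline at row 30: column samples rows 20..40
  expect_equal(sp$map$r[, 5], 20:40)
  expect_equal(sp$profile$edge_rows, 6:16)
  expect_equal(sp$profile$background_rows, c(1:5, 17:21))
  # profile max at the central row
  expect_true(all(apply(sp$profile$values, 2, which.max) == 11))

  spc <- sample_centerline_profiles(matrix(0.3, 64, 64), cl)
  expect_equal(max(abs(spc$profile$values - 0.3)), 0, tolerance = 1e-12)

  expect_error(sample_centerline_profiles(img, edge_list(cbind(1:3, 1:3))),
               "short")
})
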