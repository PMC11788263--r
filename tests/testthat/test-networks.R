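test_that("input assembly stacks intensity, Sobel gradients, and the mask", {
  I <- matrix(0.5, 32, 32)
  mask <- matrix(0, 32, 32); mask[16, ] <- 1
  x <- assemble_input(I, mask)
  expect_equal(dim(x), c(32, 32, 4))
  expect_equal(max(abs(x[, , 2])), 0)   # constant image: zero gradients
  expect_equal(max(abs(x[, , 3])), 0)
  expect_identical(x[, , 4], mask)

  # DERIVED: column-index ramp -> constant d/dx in the interior, zero d/dy
  ramp <- matrix(seq(0, 1, length.out = 32), 32, 32, byrow = TRUE)
  xr <- assemble_input(ramp, mask, standardize = FALSE)
  interior <- xr[2:31, 2:31, 2]
  expect_lt(diff(range(interior)), 1e-12)
  expect_equal(interior[1, 1], 8 * (1 / 31), tolerance = 1e-12)  # Sobel gain 8
  expect_equal(max(abs(xr[2:31, 2:31, 3])), 0)

  expect_error(assemble_input(I, matrix(0, 16, 16)), "shapes differ")
})

test_that("backpropagation matches numeric gradients", {
  set.seed(2)
  w <- ribsep:::init_weights(2, 3)
  x <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  tgt <- matrix(runif(64), 8)
  for (loss in c("mse", "bce")) {
    cache <- ribsep:::net_forward(w, x, cache = TRUE)
    lg <- ribsep:::loss_grad(cache$out, tgt, loss)
    g <- ribsep:::net_backward(w, cache, lg$grad)
    for (nm in names(w)) {
      i <- sample(length(w[[nm]]), 1)
      eps <- 1e-6
      wp <- w; wp[[nm]][i] <- wp[[nm]][i] + eps
      wm <- w; wm[[nm]][i] <- wm[[nm]][i] - eps
      num <- (ribsep:::loss_grad(ribsep:::net_forward(wp, x), tgt, loss)$loss -
              ribsep:::loss_grad(ribsep:::net_forward(wm, x), tgt, loss)$loss) /
        (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-5)
    }
  }
})

test_that("cosine annealing warm restarts hit lr0 at every restart", {
  lr0 <- 1e-4
  # periods 10, 20, 40: restarts at epochs 0, 10, 30, 70
  expect_equal(cosine_annealing_lr(c(0, 10, 30, 70), lr0), rep(lr0, 4))
  # decays within a cycle
  lrs <- cosine_annealing_lr(0:9, lr0)
  expect_true(all(diff(lrs) < 0))
  expect_equal(cosine_annealing_lr(5, lr0), lr0 * 0.5 * (1 + cos(pi * 0.5)))
})

test_that("training is seeded-deterministic and records history", {
  set.seed(99)
  ds <- lapply(1:3, function(i) {
    list(input = matrix(runif(32 * 32), 32),
         target = matrix(runif(32 * 32), 32))
  })
  cfg <- train_config(image_size = 32, epochs = 6, batch_size = 2,
                      lr0 = 1e-3, n_filters = 2, seed = 4)
  m1 <- train_edge_model(ds, cfg)
  m2 <- train_edge_model(ds, cfg)
  expect_identical(m1$history$loss, m2$history$loss)
  expect_equal(nrow(m1$history), 6)
  expect_equal(m1$history$lr, cosine_annealing_lr(0:5, 1e-3))
  # predictions deterministic and clipped
  p1 <- predict_edge_map(m1, ds[[1]]$input)
  expect_identical(p1, predict_edge_map(m2, ds[[1]]$input))
  expect_true(all(p1 >= 0 & p1 <= 1))
})

test_that("bundles round-trip through JSON with identical predictions", {
  set.seed(100)
  ds <- list(list(input = matrix(runif(32 * 32), 32),
                  target = matrix(runif(32 * 32), 32)))
  cfg <- train_config(image_size = 32, epochs = 3, batch_size = 1,
                      lr0 = 1e-3, n_filters = 2, seed = 1)
  m <- train_edge_model(ds, cfg)
  path <- tempfile(fileext = ".json")
  save_model_bundle(m, path)
  m2 <- load_model_bundle(path)
  expect_identical(predict_edge_map(m, ds[[1]]$input),
                   predict_edge_map(m2, ds[[1]]$input))
  expect_equal(m2$arch$in_channels, 1)
})

test_that("suppressor predicts an exactly additive decomposition", {
  sc <- generate_phantom(phantom_config(shape = c(64, 64), seed = 3,
                                        n_anterior = 1, n_posterior = 1,
                                        n_clavicle = 0))
  mask <- combine_category_masks(sc$edge_masks)
  cfg <- train_config(image_size = 64, epochs = 10, batch_size = 1,
                      lr0 = 2e-3, n_filters = 2, seed = 2)
  m <- train_suppressor(list(list(input = assemble_input(sc$cxr, mask),
                                  target = sc$bone)), cfg)
  out <- predict_decomposition(m, sc$cxr, mask)
  expect_identical(out$soft, sc$cxr - out$bone)
  expect_true(all(out$bone >= 0))
  out2 <- predict_decomposition(m, sc$cxr, mask)
  expect_identical(out$bone, out2$bone)
  expect_error(predict_decomposition(m, sc$cxr), "edge mask")
})

test_that("zero-bone targets drive predictions towards zero", {
  set.seed(12)
  ds <- lapply(1:4, function(i) {
    sc <- generate_phantom(phantom_config(shape = c(64, 64), seed = i,
                                          n_anterior = 0, n_posterior = 0,
                                          n_clavicle = 0))
    list(input = assemble_input(sc$cxr, matrix(0, 64, 64)),
         target = sc$bone)
  })
  cfg <- train_config(image_size = 64, epochs = 40, batch_size = 2,
                      lr0 = 5e-3, n_filters = 2, seed = 3)
  m <- train_suppressor(ds, cfg)
  pred <- ribsep:::net_forward(m$weights, ds[[1]]$input)
  expect_lt(mean(abs(pred)), 0.05)
})

test_that("fine-tuning starts from the pretrained weights", {
  set.seed(55)
  ds <- list(list(input = matrix(runif(32 * 32), 32),
                  target = matrix(runif(32 * 32), 32) * 0.1))
  cfg <- train_config(image_size = 32, epochs = 5, batch_size = 1,
                      lr0 = 2e-3, n_filters = 2, seed = 9)
  pre <- train_suppressor(ds, cfg)
  ft <- train_suppressor(ds, cfg, init = pre)
  expect_match(ft$provenance, "finetuned")
  # fine-tuned run starts near the pretrained loss, far below scratch init
  scratch0 <- evaluate_loss(untrained_model(1, cfg), ds)
  pre_end <- tail(pre$history$loss, 1)
  expect_lte(ft$history$loss[1], scratch0)
  expect_lt(abs(ft$history$loss[1] - pre_end), pre_end + 1e-3)
})
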