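# Desk-scale training scaffolding for the edge-regression and
# bone-suppression networks.  The architecture is a deliberately small
# two-scale convolutional encoder-decoder (conv -> pool -> conv -> upsample
# -> skip concat -> conv) trained with Adam and cosine annealing warm
# restarts; it stands in for the full-scale dense encoder-decoder used on
# clinical data, which is out of desk-scale reach.

#' Training configuration
#'
#' @param image_size working image size in pixels (must be even); clinical
#'   scale is 512, desk-scale tests use 64
#' @param batch_size samples per gradient step
#' @param epochs training epochs
#' @param lr0 initial learning rate of each warm restart
#' @param t0 epochs in the first cosine annealing cycle
#' @param t_mult cycle-length multiplier at each restart
#' @param loss `"mse"` (distance-transform regression, bone prediction) or
#'   `"bce"` (binary segmentation baseline)
#' @param n_filters filters per convolution
#' @param seed integer seed fixing initialization and batch order
#' @param augment list of logical flags: `rotation`, `translation`, `flip`,
#'   `normalization`
#' @return object of class `train_config`
#' @export
train_config <- function(image_size = 512, batch_size = 6, epochs = 300,
                         lr0 = 1e-4, t0 = 10, t_mult = 2,
                         loss = c("mse", "bce"), n_filters = 8, seed = 1,
                         augment = list(rotation = FALSE, translation = FALSE,
                                        flip = FALSE, normalization = FALSE)) {
  loss <- match.arg(loss)
  stopifnot(image_size > 0, image_size %% 2 == 0, batch_size > 0,
            epochs > 0, lr0 > 0, t0 > 0, t_mult >= 1, n_filters > 0)
  structure(list(image_size = image_size, batch_size = batch_size,
                 epochs = epochs, lr0 = lr0, t0 = t0, t_mult = t_mult,
                 loss = loss, n_filters = n_filters, seed = as.integer(seed),
                 augment = augment),
            class = "train_config")
}

#' Learning rate under cosine annealing with warm restarts
#'
#' Cycle lengths are `t0, t0*t_mult, t0*t_mult^2, ...` epochs; within a
#' cycle the rate decays from `lr0` (at the restart) towards 0 on a cosine.
#'
#' @param epoch 0-based epoch index
#' @param lr0 initial learning rate
#' @param t0 first cycle length (epochs)
#' @param t_mult cycle multiplier
#' @return learning rate
#' @export
cosine_annealing_lr <- function(epoch, lr0 = 1e-4, t0 = 10, t_mult = 2) {
  vapply(epoch, function(e) {
    Ti <- t0
    while (e >= Ti) {
      e <- e - Ti
      Ti <- Ti * t_mult
    }
    lr0 * 0.5 * (1 + cos(pi * e / Ti))
  }, numeric(1))
}

#' Assemble the 4-channel input stack for the suppression network
#'
#' Channels are `[intensity, d/dx (Sobel), d/dy (Sobel), edge mask]`.  The
#' gradients are computed on the raw intensity image (replicated-border
#' 3x3 Sobel) and then standardized to zero mean and unit variance
#' (constant channels become all-zero).
#'
#' @param I image matrix
#' @param edge_mask binary matrix of the same shape
#' @param standardize standardize the gradient channels (default TRUE)
#' @return array `(rows, cols, 4)`
#' @export
assemble_input <- function(I, edge_mask, standardize = TRUE) {
  assert_image(I)
  if (!identical(dim(I), dim(edge_mask))) {
    stop("image and edge mask shapes differ", call. = FALSE)
  }
  gx <- sobel(I, "x")
  gy <- sobel(I, "y")
  if (standardize) {
    gx <- standardize_channel(gx)
    gy <- standardize_channel(gy)
  }
  out <- array(0, c(dim(I), 4))
  out[, , 1] <- I
  out[, , 2] <- gx
  out[, , 3] <- gy
  out[, , 4] <- edge_mask
  out
}

standardize_channel <- function(x) {
  s <- stats::sd(as.vector(x))
  if (s < 1e-12) return(x * 0)
  (x - mean(x)) / s
}

# 3x3 Sobel with replicated borders; "x" = column direction, "y" = rows.
sobel <- function(I, dir = c("x", "y")) {
  dir <- match.arg(dir)
  pad <- function(m, dr, dc) {
    nr <- nrow(m); nc <- ncol(m)
    rs <- pmin(pmax(seq_len(nr) - dr, 1), nr)
    cs <- pmin(pmax(seq_len(nc) - dc, 1), nc)
    m[rs, cs, drop = FALSE]
  }
  if (dir == "x") {
    (pad(I, 0, -1) - pad(I, 0, 1)) * 2 +
      (pad(I, -1, -1) - pad(I, -1, 1)) +
      (pad(I, 1, -1) - pad(I, 1, 1))
  } else {
    (pad(I, -1, 0) - pad(I, 1, 0)) * 2 +
      (pad(I, -1, -1) - pad(I, 1, -1)) +
      (pad(I, -1, 1) - pad(I, 1, 1))
  }
}

# ---- tiny conv net ----------------------------------------------------------

shift_ch <- function(m, dr, dc) shift_mat(m, dr, dc, fill = 0)

conv_fwd <- function(x, W, b) {
  # x: (H, W, Cin); W: (3, 3, Cin, Cout); out[r,c,co] uses x[r+dr, c+dc, ci]
  H <- dim(x)[1]; Wd <- dim(x)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  out <- array(0, c(H, Wd, cout))
  for (co in seq_len(cout)) {
    acc <- matrix(b[co], H, Wd)
    for (ci in seq_len(cin)) {
      xc <- x[, , ci]
      for (dr in -1:1) for (dc in -1:1) {
        w <- W[dr + 2, dc + 2, ci, co]
        if (w != 0) acc <- acc + w * shift_ch(xc, -dr, -dc)
      }
    }
    out[, , co] <- acc
  }
  out
}

conv_bwd <- function(x, W, dout) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  cin <- dim(W)[3]; cout <- dim(W)[4]
  dW <- array(0, dim(W))
  db <- numeric(cout)
  dx <- array(0, dim(x))
  for (co in seq_len(cout)) {
    dc_out <- dout[, , co]
    db[co] <- sum(dc_out)
    for (ci in seq_len(cin)) {
      xc <- x[, , ci]
      dxc <- dx[, , ci]
      for (dr in -1:1) for (dc in -1:1) {
        dW[dr + 2, dc + 2, ci, co] <- sum(dc_out * shift_ch(xc, -dr, -dc))
        dxc <- dxc + W[dr + 2, dc + 2, ci, co] * shift_ch(dc_out, dr, dc)
      }
      dx[, , ci] <- dxc
    }
  }
  list(dW = dW, db = db, dx = dx)
}

pool2_fwd <- function(x) {
  H <- dim(x)[1]; Wd <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(H / 2, Wd / 2, C))
  for (c in seq_len(C)) {
    m <- x[, , c]
    out[, , c] <- (m[seq(1, H, 2), seq(1, Wd, 2)] +
                   m[seq(2, H, 2), seq(1, Wd, 2)] +
                   m[seq(1, H, 2), seq(2, Wd, 2)] +
                   m[seq(2, H, 2), seq(2, Wd, 2)]) / 4
  }
  out
}

pool2_bwd <- function(dout) {
  H2 <- dim(dout)[1]; W2 <- dim(dout)[2]; C <- dim(dout)[3]
  dx <- array(0, c(H2 * 2, W2 * 2, C))
  one <- matrix(1, 2, 2)
  for (c in seq_len(C)) dx[, , c] <- kronecker(dout[, , c], one) / 4
  dx
}

up2_fwd <- function(x) {
  C <- dim(x)[3]
  out <- array(0, c(dim(x)[1] * 2, dim(x)[2] * 2, C))
  one <- matrix(1, 2, 2)
  for (c in seq_len(C)) out[, , c] <- kronecker(x[, , c], one)
  out
}

up2_bwd <- function(dout) {
  H <- dim(dout)[1]; Wd <- dim(dout)[2]; C <- dim(dout)[3]
  dx <- array(0, c(H / 2, Wd / 2, C))
  for (c in seq_len(C)) {
    m <- dout[, , c]
    dx[, , c] <- m[seq(1, H, 2), seq(1, Wd, 2)] +
      m[seq(2, H, 2), seq(1, Wd, 2)] +
      m[seq(1, H, 2), seq(2, Wd, 2)] +
      m[seq(2, H, 2), seq(2, Wd, 2)]
  }
  dx
}

init_weights <- function(in_channels, n_filters) {
  he <- function(d) array(stats::rnorm(prod(d), sd = sqrt(2 / (9 * d[3]))), d)
  list(
    W1 = he(c(3, 3, in_channels, n_filters)), b1 = numeric(n_filters),
    W2 = he(c(3, 3, n_filters, n_filters)), b2 = numeric(n_filters),
    W3 = he(c(3, 3, 2 * n_filters, 1)), b3 = numeric(1)
  )
}

net_forward <- function(weights, x, cache = FALSE) {
  z1 <- conv_fwd(x, weights$W1, weights$b1)
  a1 <- pmax(z1, 0)
  p <- pool2_fwd(a1)
  z2 <- conv_fwd(p, weights$W2, weights$b2)
  a2 <- pmax(z2, 0)
  u <- up2_fwd(a2)
  cat2 <- array(0, c(dim(a1)[1], dim(a1)[2], dim(a1)[3] + dim(u)[3]))
  cat2[, , seq_len(dim(a1)[3])] <- a1
  cat2[, , dim(a1)[3] + seq_len(dim(u)[3])] <- u
  z3 <- conv_fwd(cat2, weights$W3, weights$b3)
  out <- z3[, , 1]
  if (!cache) return(out)
  list(out = out, x = x, z1 = z1, a1 = a1, p = p, z2 = z2, a2 = a2, u = u,
       cat2 = cat2)
}

net_backward <- function(weights, cache, dout) {
  dz3 <- array(dout, c(dim(dout), 1))
  g3 <- conv_bwd(cache$cat2, weights$W3, dz3)
  F <- dim(cache$a1)[3]
  da1 <- g3$dx[, , seq_len(F), drop = FALSE]
  du <- g3$dx[, , F + seq_len(F), drop = FALSE]
  da2 <- up2_bwd(du)
  dz2 <- da2 * (cache$z2 > 0)
  g2 <- conv_bwd(cache$p, weights$W2, dz2)
  dp <- g2$dx
  da1 <- da1 + pool2_bwd(dp)
  dz1 <- da1 * (cache$z1 > 0)
  g1 <- conv_bwd(cache$x, weights$W1, dz1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db)
}

loss_grad <- function(pred, target, loss) {
  n <- length(target)
  if (loss == "mse") {
    diff <- pred - target
    list(loss = mean(diff^2), grad = 2 * diff / n)
  } else {
    # bce with logits
    z <- pred
    l <- mean(pmax(z, 0) - z * target + log1p(exp(-abs(z))))
    list(loss = l, grad = (1 / (1 + exp(-z)) - target) / n)
  }
}

adam_state <- function(weights) {
  list(m = lapply(weights, function(w) w * 0),
       v = lapply(weights, function(w) w * 0), t = 0L)
}

adam_update <- function(weights, grads, state, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(weights)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    weights[[nm]] <- weights[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(weights = weights, state = state)
}

as_input_array <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1)) else x
}

# Core training loop shared by both networks.
train_network <- function(dataset, config, init = NULL, provenance = "scratch") {
  stopifnot(length(dataset) >= 1)
  x0 <- as_input_array(dataset[[1]]$input)
  cin <- dim(x0)[3]
  fit <- with_seed(config$seed, {
    weights <- if (is.null(init)) init_weights(cin, config$n_filters)
               else init$weights
    state <- adam_state(weights)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          lr = numeric(0))
    n <- length(dataset)
    for (epoch in seq_len(config$epochs) - 1L) {
      lr <- cosine_annealing_lr(epoch, config$lr0, config$t0, config$t_mult)
      ord <- sample.int(n)
      ep_loss <- 0; nb <- 0L
      for (bstart in seq(1, n, by = config$batch_size)) {
        bidx <- ord[bstart:min(bstart + config$batch_size - 1L, n)]
        grads <- NULL
        bloss <- 0
        for (si in bidx) {
          smp <- dataset[[si]]
          x <- as_input_array(smp$input)
          if (isTRUE(config$augment$flip) || isTRUE(config$augment$rotation) ||
              isTRUE(config$augment$translation)) {
            aug <- augment_pair(x, smp$target, config$augment)
            x <- aug$input; smp <- list(target = aug$target)
          }
          cache <- net_forward(weights, x, cache = TRUE)
          lg <- loss_grad(cache$out, smp$target, config$loss)
          if (!is.finite(lg$loss)) {
            stop(sprintf(
              "NaN/Inf loss at epoch %d (lr %.2g): try a smaller lr0",
              epoch, lr), call. = FALSE)
          }
          bloss <- bloss + lg$loss
          g <- net_backward(weights, cache, lg$grad)
          grads <- if (is.null(grads)) g
                   else Map(`+`, grads, g)
        }
        grads <- lapply(grads, function(g) g / length(bidx))
        upd <- adam_update(weights, grads, state, lr)
        weights <- upd$weights
        state <- upd$state
        ep_loss <- ep_loss + bloss / length(bidx)
        nb <- nb + 1L
      }
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss / nb, lr)
    }
    list(weights = weights, history = history)
  })
  structure(list(
    arch = list(id = "tiny-unet2", in_channels = cin,
                n_filters = config$n_filters, loss = config$loss),
    weights = fit$weights, history = fit$history, provenance = provenance,
    config = config
  ), class = "model_bundle")
}

# Shared geometric augmentation of an input stack and its target.
augment_pair <- function(x, target, flags) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  ang <- if (isTRUE(flags$rotation)) stats::runif(1, -10, 10) * pi / 180 else 0
  tr <- if (isTRUE(flags$translation)) {
    round(stats::runif(2, -0.05, 0.05) * c(H, Wd))
  } else c(0, 0)
  flip <- isTRUE(flags$flip) && stats::runif(1) < 0.5
  cy <- (H + 1) / 2; cx <- (Wd + 1) / 2
  rows <- matrix(seq_len(H), H, Wd)
  cols <- matrix(seq_len(Wd), H, Wd, byrow = TRUE)
  if (flip) cols <- Wd + 1 - cols
  rr <- cy + cos(ang) * (rows - cy) - sin(ang) * (cols - cx) - tr[1]
  cc <- cx + sin(ang) * (rows - cy) + cos(ang) * (cols - cx) - tr[2]
  warp <- function(m) matrix(bilinear(m, as.vector(rr), as.vector(cc)), H, Wd)
  for (c in seq_len(dim(x)[3])) x[, , c] <- warp(x[, , c])
  list(input = x, target = warp(target))
}

#' Train the distance-transform edge-regression network (or BCE baseline)
#'
#' Targets are distance-transform encodings ([distance_transform_encode()])
#' for the `"mse"` loss, or binary edge masks for the `"bce"` segmentation
#' baseline.  One network is trained per bone category in practice; the
#' category is recorded in the provenance tag.
#'
#' @param dataset list of samples: `list(input = matrix or 3-channel array,
#'   target = matrix)`
#' @param config a [train_config()]
#' @param category optional category tag (`"anterior"`, ...)
#' @return a `model_bundle`
#' @export
train_edge_model <- function(dataset, config, category = NA_character_) {
  bundle <- train_network(dataset, config,
                          provenance = paste0("edge:", config$loss,
                                              ":", category))
  bundle
}

#' Predict a soft edge map (clipped to `[0, 1]`) from a trained edge model
#'
#' @param model a `model_bundle` from [train_edge_model()]
#' @param I input image matrix
#' @return matrix in `[0, 1]` (decode with [edges_from_logits()])
#' @export
predict_edge_map <- function(model, I) {
  x <- as_input_array(I)
  if (dim(x)[3] != model$arch$in_channels) {
    stop("input channel count does not match the model", call. = FALSE)
  }
  out <- net_forward(model$weights, x)
  if (model$arch$loss == "bce") out <- 1 / (1 + exp(-out))
  pmin(pmax(out, 0), 1)
}

#' Train the bone-suppression network
#'
#' Inputs are 4-channel stacks from [assemble_input()] (or plain images for
#' the no-edge-channel configuration); targets are bone images.  Passing a
#' pretrained `init` bundle fine-tunes from its weights and records the
#' transfer lineage in the provenance.
#'
#' @param dataset list of samples as in [train_edge_model()]
#' @param config a [train_config()] (loss `"mse"`)
#' @param init optional pretrained `model_bundle` to fine-tune from
#' @return a `model_bundle`
#' @export
train_suppressor <- function(dataset, config, init = NULL) {
  prov <- if (is.null(init)) "suppressor:scratch"
          else paste0("suppressor:finetuned<-", paste(init$provenance,
                                                      collapse = "|"))
  if (!is.null(init)) {
    cin <- dim(as_input_array(dataset[[1]]$input))[3]
    if (init$arch$in_channels != cin) {
      stop("channel mismatch between init bundle and dataset", call. = FALSE)
    }
  }
  train_network(dataset, config, init = init, provenance = prov)
}

#' Build an untrained model bundle (seeded initialization)
#'
#' Useful as the epoch-0 baseline when comparing fine-tuning against
#' training from scratch.
#'
#' @param in_channels input channel count
#' @param config a [train_config()] (supplies `n_filters`, `loss`, `seed`)
#' @return a `model_bundle` with freshly initialized weights
#' @export
untrained_model <- function(in_channels, config) {
  weights <- with_seed(config$seed, init_weights(in_channels, config$n_filters))
  structure(list(
    arch = list(id = "tiny-unet2", in_channels = in_channels,
                n_filters = config$n_filters, loss = config$loss),
    weights = weights,
    history = data.frame(epoch = integer(0), loss = numeric(0),
                         lr = numeric(0)),
    provenance = "untrained", config = config
  ), class = "model_bundle")
}

#' Evaluate the mean loss of a model on a dataset without training
#'
#' @param model a `model_bundle`
#' @param dataset list of samples
#' @return mean loss
#' @export
evaluate_loss <- function(model, dataset) {
  losses <- vapply(dataset, function(smp) {
    out <- net_forward(model$weights, as_input_array(smp$input))
    loss_grad(out, smp$target, model$arch$loss)$loss
  }, numeric(1))
  mean(losses)
}

#' Predict a bone/soft decomposition with a trained suppression network
#'
#' The bone prediction is the network output clipped to be non-negative;
#' the soft-tissue image is `I` minus the bone prediction, so
#' `I_B + I_S == I` holds exactly.
#'
#' @param model a `model_bundle` from [train_suppressor()]
#' @param I image matrix
#' @param edge_mask binary edge mask (ignored for 1-channel models)
#' @return list with `bone` and `soft`
#' @export
predict_decomposition <- function(model, I, edge_mask = NULL) {
  x <- if (model$arch$in_channels == 4) {
    if (is.null(edge_mask)) stop("model requires an edge mask", call. = FALSE)
    assemble_input(I, edge_mask)
  } else as_input_array(I)
  if (dim(x)[3] != model$arch$in_channels) {
    stop("channel mismatch", call. = FALSE)
  }
  bone <- pmax(net_forward(model$weights, x), 0)
  list(bone = bone, soft = I - bone)
}

# ---- bundle persistence (text JSON with bit-exact hex floats) --------------

#' Save / load a model bundle as JSON
#'
#' Weights are stored as hexadecimal float literals, so a load/save round
#' trip reproduces bit-identical predictions.
#'
#' @param bundle a `model_bundle`
#' @param path file path
#' @return `load_model_bundle` returns the restored `model_bundle`
#' @export
save_model_bundle <- function(bundle, path) {
  enc <- lapply(bundle$weights, function(w) {
    list(dim = if (is.null(dim(w))) length(w) else dim(w),
         hex = sprintf("%a", as.vector(w)))
  })
  obj <- list(arch = bundle$arch, weights = enc,
              history = bundle$history, provenance = bundle$provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  weights <- lapply(obj$weights, function(w) {
    v <- as.numeric(w$hex)
    if (length(w$dim) > 1) array(v, unlist(w$dim)) else v
  })
  structure(list(arch = obj$arch, weights = weights,
                 history = as.data.frame(obj$history),
                 provenance = obj$provenance),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("model_bundle [%s]: %d->%d filters, loss=%s, %d epochs (%s)\n",
              x$arch$id, x$arch$in_channels, x$arch$n_filters, x$arch$loss,
              nrow(x$history), paste(x$provenance, collapse = "|")))
  invisible(x)
}
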