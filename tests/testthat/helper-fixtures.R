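# Shared fixture builders.  Everything is generated in code; nothing is read
# from disk.

# horizontal 1-px line mask
line_mask <- function(nr = 64, nc = 64, row = 32, cols = 10:(nc - 10)) {
  m <- matrix(0, nr, nc)
  m[row, cols] <- 1
  m
}

# brute-force distance-transform encoding (direct evaluation of the
# definition: exp(-min distance to the positive set / |sigma|))
brute_dt_encode <- function(mask, sigma) {
  pos <- which(mask > 0, arr.ind = TRUE)
  out <- matrix(0, nrow(mask), ncol(mask))
  if (nrow(pos) == 0) return(out)
  for (r in seq_len(nrow(mask))) {
    for (c in seq_len(ncol(mask))) {
      d <- sqrt(min((r - pos[, 1])^2 + (c - pos[, 2])^2))
      out[r, c] <- exp(-d / abs(sigma))
    }
  }
  out
}

# brute-force mean boundary distance (double loop over positive pixels)
brute_mbd <- function(S, T) {
  ps <- which(S > 0, arr.ind = TRUE)
  pt <- which(T > 0, arr.ind = TRUE)
  d_st <- vapply(seq_len(nrow(ps)), function(i) {
    sqrt(min((ps[i, 1] - pt[, 1])^2 + (ps[i, 2] - pt[, 2])^2))
  }, numeric(1))
  d_ts <- vapply(seq_len(nrow(pt)), function(j) {
    sqrt(min((pt[j, 1] - ps[, 1])^2 + (pt[j, 2] - ps[, 2])^2))
  }, numeric(1))
  0.5 * (mean(d_st) + mean(d_ts))
}

# dense-matrix Poisson oracle: same PDE (5-point Laplacian, Dirichlet 0
# outside the region), solved with base::solve on the full matrix
dense_poisson <- function(I, region) {
  nr <- nrow(I); nc <- ncol(I)
  region <- region > 0
  region[c(1, nr), ] <- FALSE
  region[, c(1, nc)] <- FALSE
  idx <- which(region)
  if (!length(idx)) return(matrix(0, nr, nc))
  n <- length(idx)
  id <- matrix(0L, nr, nc); id[idx] <- seq_len(n)
  A <- matrix(0, n, n)
  b <- numeric(n)
  for (k in seq_len(n)) {
    r <- ((idx[k] - 1) %% nr) + 1
    c <- ((idx[k] - 1) %/% nr) + 1
    A[k, k] <- 4
    lap <- -4 * I[r, c]
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      lap <- lap + I[rr, cc]
      if (id[rr, cc] > 0) A[k, id[rr, cc]] <- -1
    }
    b[k] <- -lap
  }
  x <- solve(A, b)
  out <- matrix(0, nr, nc)
  out[idx] <- x
  out
}

# a small straight-bone scene with parallel horizontal edges (flat geometry)
flat_bone_scene <- function(nr = 96, nc = 96, row = 48, halfwidth = 6,
                            peak = 0.3, background = 0.5) {
  b <- generate_bone(cbind(c(row, row, row), c(1, nc / 2, nc)),
                     halfwidth, peak, c(nr, nc), taper = 0)
  cxr <- matrix(background, nr, nc) + b$bone
  list(bone = b, cxr = cxr,
       pair = structure(list(upper = b$upper, lower = b$lower,
                             centerline = b$centerline,
                             category = "posterior"),
                        class = "bone_pair"))
}

# desk-scale BSS configuration (192-px phantoms): the along-length
# background smoothing and opposite-point radius scale with image size;
# package defaults keep the clinical-scale values
desk_bss_config <- function(...) {
  bss_config(max_dist = 40, smooth_scale = 30, ...)
}

# memoised full pipeline runs shared between test files
.run_cache <- new.env(parent = emptyenv())
cached_suppression <- function(seed = 7, noise_sd = 0) {
  key <- paste0("s", seed, "_n", noise_sd)
  if (is.null(.run_cache[[key]])) {
    scene <- generate_phantom(phantom_config(seed = seed, noise_sd = noise_sd))
    res <- suppressWarnings(
      suppress_bones_traditional(scene$cxr, scene$edge_lists,
                                 desk_bss_config()))
    .run_cache[[key]] <- list(scene = scene, res = res)
  }
  .run_cache[[key]]
}
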