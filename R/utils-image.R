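# Low-level image primitives shared across the package.  Images are plain
# numeric matrices in [0, 1], indexed (row, col), 1-based, row 1 at the top.

#' Validate an image matrix
#' @param x object to check
#' @param name argument name used in error messages
#' @return the input, invisibly
#' @keywords internal
assert_image <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
  }
  invisible(x)
}

assert_binary <- function(x, name = deparse(substitute(x))) {
  assert_image(x, name)
  v <- unique(as.vector(x))
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("`%s` must be a binary (0/1) matrix", name), call. = FALSE)
  }
  invisible(x)
}

#' Shift a matrix by (dr, dc), filling vacated cells
#' @keywords internal
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) {
    out[rs, cs] <- m[rs - dr, cs - dc]
  }
  out
}

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# ---- distance transforms ----------------------------------------------------

# 1-D squared distance transform (Felzenszwalb & Huttenlocher lower envelope).
dt1d <- function(f) {
  n <- length(f)
  if (n == 1L) return(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      vk <- v[k]
      s <- ((f[q] + q * q) - (f[vk] + vk * vk)) / (2 * q - 2 * vk)
      if (s <= z[k] && k > 1L) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Exact squared Euclidean distance transform of a binary mask
#'
#' Returns, for every pixel, the squared Euclidean distance to the nearest
#' positive pixel (Inf-free; all-zero masks give a large sentinel distance).
#' @param mask binary matrix
#' @return numeric matrix of squared distances
#' @keywords internal
edt_squared <- function(mask) {
  big <- 1e12
  f <- ifelse(mask > 0, 0, big)
  # columns first, then rows
  d <- apply(f, 2, dt1d)
  d <- t(apply(d, 1, dt1d))
  # cap runaway sums from the sentinel
  d[d > big] <- big
  d
}

# ---- morphology -------------------------------------------------------------

#' 3x3 binary dilation / erosion
#' @keywords internal
dilate3x3 <- function(mask) {
  m <- mask > 0
  acc <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc | shift_mat(m, dr, dc, fill = FALSE) > 0
  }
  acc * 1
}

erode3x3 <- function(mask) {
  m <- mask > 0
  acc <- m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    acc <- acc & shift_mat(m, dr, dc, fill = FALSE) > 0
  }
  acc * 1
}

# Zhang-Suen thinning to 8-connected unit-width curves.
thin_skeleton <- function(mask) {
  img <- mask > 0
  if (!any(img)) return(img * 1)
  nb <- function(img) {
    # neighbours clockwise from north: p2..p9
    list(
      p2 = shift_mat(img, 1, 0, FALSE),   # value of pixel above: shift down
      p3 = shift_mat(img, 1, -1, FALSE),
      p4 = shift_mat(img, 0, -1, FALSE),
      p5 = shift_mat(img, -1, -1, FALSE),
      p6 = shift_mat(img, -1, 0, FALSE),
      p7 = shift_mat(img, -1, 1, FALSE),
      p8 = shift_mat(img, 0, 1, FALSE),
      p9 = shift_mat(img, 1, 1, FALSE)
    )
  }
  repeat {
    changed <- FALSE
    for (step in 0:1) {
      p <- nb(img)
      B <- p$p2 + p$p3 + p$p4 + p$p5 + p$p6 + p$p7 + p$p8 + p$p9
      seqs <- list(p$p2, p$p3, p$p4, p$p5, p$p6, p$p7, p$p8, p$p9, p$p2)
      A <- matrix(0, nrow(img), ncol(img))
      for (i in 1:8) A <- A + (!seqs[[i]] & seqs[[i + 1]])
      if (step == 0) {
        c1 <- !(p$p2 & p$p4 & p$p6)
        c2 <- !(p$p4 & p$p6 & p$p8)
      } else {
        c1 <- !(p$p2 & p$p4 & p$p8)
        c2 <- !(p$p2 & p$p6 & p$p8)
      }
      del <- img & B >= 2 & B <= 6 & A == 1 & c1 & c2
      if (any(del)) {
        img[del] <- FALSE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img * 1
}

# ---- filtering --------------------------------------------------------------

# Mean filter over a (2r+1)-ish square window, window truncated at borders.
# `window` is the full width; even widths use floor/ceil half-widths.
box_mean <- function(x, window) {
  lo <- floor((window - 1) / 2)
  hi <- ceiling((window - 1) / 2)
  csum <- function(m, lo, hi) {
    # running sum along rows for every column
    n <- nrow(m)
    cm <- apply(m, 2, cumsum)
    cm <- rbind(0, cm)
    upper <- pmin(n, (1:n) + hi) + 1L
    lower <- pmax(0L, (1:n) - lo - 1L) + 1L
    cm[upper, , drop = FALSE] - cm[lower, , drop = FALSE]
  }
  s <- csum(x, lo, hi)
  s <- t(csum(t(s), lo, hi))
  cnt <- csum(matrix(1, nrow(x), ncol(x)), lo, hi)
  cnt <- t(csum(t(cnt), lo, hi))
  s / cnt
}

# Moving average of a vector with edge replication, full width `k`.
moving_avg <- function(v, k) {
  n <- length(v)
  k <- max(1L, min(as.integer(k), n))
  if (k == 1L) return(v)
  lo <- floor((k - 1) / 2)
  hi <- ceiling((k - 1) / 2)
  padded <- c(rep(v[1], lo), v, rep(v[n], hi))
  cs <- c(0, cumsum(padded))
  (cs[(1:n) + k] - cs[1:n]) / k
}

# ---- interpolation ----------------------------------------------------------

#' Bilinear interpolation at continuous (row, col) coordinates
#'
#' Coordinates are clamped to the image domain.
#' @param image numeric matrix
#' @param r,c numeric vectors of row/col coordinates (1-based)
#' @return numeric vector of interpolated values
#' @keywords internal
bilinear <- function(image, r, c) {
  nr <- nrow(image); nc <- ncol(image)
  r <- pmin(pmax(r, 1), nr)
  c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); r0[nr == 1L] <- 1L
  c0 <- pmin(floor(c), nc - 1L); c0[nc == 1L] <- 1L
  r1 <- pmin(r0 + 1L, nr)
  c1 <- pmin(c0 + 1L, nc)
  fr <- r - r0
  fc <- c - c0
  i00 <- image[cbind(r0, c0)]
  i01 <- image[cbind(r0, c1)]
  i10 <- image[cbind(r1, c0)]
  i11 <- image[cbind(r1, c1)]
  i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
}

# ---- rasterization ----------------------------------------------------------

# Even-odd scanline fill of a simple polygon given by vertex vectors (pr, pc).
fill_polygon <- function(pr, pc, shape) {
  out <- matrix(0, shape[1], shape[2])
  n <- length(pr)
  if (n < 3) return(out)
  r1 <- pr; r2 <- c(pr[-1], pr[1])
  c1 <- pc; c2 <- c(pc[-1], pc[1])
  for (y in seq_len(shape[1])) {
    cross <- (r1 <= y & r2 > y) | (r2 <= y & r1 > y)
    if (!any(cross)) next
    xs <- c1[cross] + (y - r1[cross]) / (r2[cross] - r1[cross]) *
      (c2[cross] - c1[cross])
    xs <- sort(xs)
    for (i in seq(1, length(xs) - 1, by = 2)) {
      a <- ceiling(xs[i])
      b <- floor(xs[i + 1])
      a <- max(1L, a); b <- min(shape[2], b)
      if (a <= b) out[y, a:b] <- 1
    }
  }
  out
}

# Rasterize a polyline (continuous coords) into a 1-px-wide 8-connected
# binary mask: vertices are rounded and consecutive vertices joined with
# Bresenham segments (dense rounding would create thick zigzags full of
# spurious junction pixels).
rasterize_polyline <- function(points, shape) {
  out <- matrix(0, shape[1], shape[2])
  if (is.null(points) || nrow(points) < 1) return(out)
  r <- pmin(pmax(round(points[, 1]), 1), shape[1])
  c <- pmin(pmax(round(points[, 2]), 1), shape[2])
  keep <- c(TRUE, diff(r) != 0 | diff(c) != 0)
  r <- r[keep]; c <- c[keep]
  out[r[1], c[1]] <- 1
  for (i in seq_len(length(r) - 1)) {
    r0 <- r[i]; c0 <- c[i]; r1 <- r[i + 1]; c1 <- c[i + 1]
    dr <- abs(r1 - r0); dc <- abs(c1 - c0)
    sr <- sign(r1 - r0); sc <- sign(c1 - c0)
    err <- dc - dr
    while (r0 != r1 || c0 != c1) {
      e2 <- 2 * err
      if (e2 > -dr) { err <- err - dr; c0 <- c0 + sc }
      if (e2 < dc) { err <- err + dc; r0 <- r0 + sr }
      out[r0, c0] <- 1
    }
  }
  out
}

# Resample a polyline so consecutive points are at most `step` apart.
densify_polyline <- function(points, step = 0.5) {
  if (nrow(points) < 2) return(points)
  segs <- list()
  for (i in seq_len(nrow(points) - 1)) {
    p <- points[i, ]; q <- points[i + 1, ]
    len <- sqrt(sum((q - p)^2))
    k <- max(1L, ceiling(len / step))
    t <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    segs[[i]] <- cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
  }
  rbind(do.call(rbind, segs), points[nrow(points), , drop = FALSE])
}
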