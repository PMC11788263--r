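# Straightening curved bones into profile images and mapping results back.
#
# A profile image holds one column per point of the upper edge (or
# centerline): each column is the image sampled along the local normal, so
# the upper and lower bone edges become straight rows.  The sampling map
# stores the continuous (row, col) source coordinate of every profile pixel
# and makes the operation invertible.

#' Unit tangent and normal of an edge list at one point
#'
#' The tangent is a centered finite difference over `+/- window` points
#' (one-sided at the ends).  The normal is the tangent rotated 90 degrees;
#' when `toward` is given (a point or an [edge_list()]), the normal is
#' oriented to point towards it.
#'
#' @param edge an [edge_list()]
#' @param index point index (1-based)
#' @param window half-window in points for the finite difference
#' @param toward optional point `(row, col)` or edge list used to orient the
#'   normal
#' @return list with unit `tangent` and `normal` (each `(row, col)`)
#' @export
tangent_normal <- function(edge, index, window = 5, toward = NULL) {
  pts <- edge$points
  n <- nrow(pts)
  if (n < 2) stop("edge must have at least 2 points", call. = FALSE)
  if (index < 1 || index > n) stop("`index` out of range", call. = FALSE)
  i0 <- max(1, index - window)
  i1 <- min(n, index + window)
  v <- unname(pts[i1, ] - pts[i0, ])
  len <- sqrt(sum(v^2))
  if (len == 0) stop("degenerate tangent (repeated points)", call. = FALSE)
  tangent <- v / len
  normal <- c(tangent[2], -tangent[1])
  if (!is.null(toward)) {
    target <- if (inherits(toward, "edge_list")) {
      toward$points[which.min(rowSums((toward$points -
        matrix(pts[index, ], nrow(toward$points), 2, byrow = TRUE))^2)), ]
    } else toward
    if (sum(normal * (target - pts[index, ])) < 0) normal <- -normal
  }
  list(tangent = tangent, normal = normal)
}

#' Find the opposite point on the lower edge along a normal
#'
#' Returns the lower-edge point minimizing the parallelogram height
#' `h = |det(e, v)|`, where `e` is the unit normal at the upper-edge point
#' and `v` the vector to the candidate, subject to `|v| < max_dist`.  Ties
#' are broken by the smaller `|v|`.
#'
#' @param u point `(row, col)` on the upper edge
#' @param normal unit normal vector at `u`
#' @param lower an [edge_list()] with the candidate points
#' @param max_dist search radius in pixels
#' @return list with `point`, `index`, `h`, `dist`
#' @export
find_opposite_point <- function(u, normal, lower, max_dist = 100) {
  stopifnot(abs(sqrt(sum(normal^2)) - 1) < 1e-6)
  pts <- lower$points
  v_r <- pts[, 1] - u[1]
  v_c <- pts[, 2] - u[2]
  dist <- sqrt(v_r^2 + v_c^2)
  ok <- dist < max_dist
  if (!any(ok)) {
    stop("no opposite point within max_dist", call. = FALSE)
  }
  h <- abs(normal[1] * v_c - normal[2] * v_r)
  h[!ok] <- Inf
  best <- which(h == min(h))
  if (length(best) > 1) best <- best[which.min(dist[best])]
  list(point = pts[best, ], index = best, h = h[best], dist = dist[best])
}

new_profile_image <- function(values, row_upper, row_lower,
                              edge_rows = NULL, background_rows = NULL) {
  structure(list(values = values, row_of_upper_edge = row_upper,
                 row_of_lower_edge = row_lower, edge_rows = edge_rows,
                 background_rows = background_rows),
            class = "profile_image")
}

#' @export
print.profile_image <- function(x, ...) {
  cat(sprintf("profile_image: %d x %d (upper row %s, lower row %s)\n",
              nrow(x$values), ncol(x$values),
              x$row_of_upper_edge, x$row_of_lower_edge))
  invisible(x)
}

#' Sample perpendicular profiles of one bone into a profile image
#'
#' For each point `u` of the upper edge with a valid opposite point `l*`,
#' `n_inner` samples are placed evenly on the segment `u -> l*` (inclusive,
#' so both edges land on fixed rows) and `n_outer` samples extend beyond `u`
#' away from the bone at the same step.  Values are bilinearly interpolated;
#' out-of-bounds coordinates are clamped to the border.  Columns whose
#' opposite-point search fails are filled by linear interpolation across
#' neighbouring columns.
#'
#' @param image numeric matrix
#' @param pair a `bone_pair` (see [pair_upper_lower()])
#' @param n_outer samples outside the upper edge
#' @param n_inner samples spanning upper to lower edge (inclusive)
#' @param max_dist opposite-point search radius
#' @return list with `profile` (a `profile_image`) and `map` (a
#'   `sampling_map`: matrices `r`, `c` of source coordinates)
#' @export
sample_profiles <- function(image, pair, n_outer = 10, n_inner = 40,
                            max_dist = 100) {
  assert_image(image)
  up <- pair$upper
  pts <- up$points
  ncols <- nrow(pts)
  nrows <- n_outer + n_inner
  vals <- matrix(NA_real_, nrows, ncols)
  map_r <- matrix(NA_real_, nrows, ncols)
  map_c <- matrix(NA_real_, nrows, ncols)
  n_ok <- 0L
  for (k in seq_len(ncols)) {
    tn <- tangent_normal(up, k, toward = pair$lower)
    res <- tryCatch(find_opposite_point(pts[k, ], tn$normal, pair$lower,
                                        max_dist = max_dist),
                    error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    u <- pts[k, ]
    step <- (res$point - u) / (n_inner - 1)
    offs <- seq(-n_outer, n_inner - 1)
    rr <- u[1] + offs * step[1]
    cc <- u[2] + offs * step[2]
    rr <- pmin(pmax(rr, 1), nrow(image))
    cc <- pmin(pmax(cc, 1), ncol(image))
    map_r[, k] <- rr
    map_c[, k] <- cc
    vals[, k] <- bilinear(image, rr, cc)
  }
  if (n_ok < 5) stop("bone too short: fewer than 5 valid profile columns",
                     call. = FALSE)
  vals <- fill_na_columns(vals)
  map_r <- fill_na_columns(map_r)
  map_c <- fill_na_columns(map_c)
  profile <- new_profile_image(vals, row_upper = n_outer + 1,
                               row_lower = n_outer + n_inner)
  map <- structure(list(r = map_r, c = map_c), class = "sampling_map")
  list(profile = profile, map = map)
}

# Linearly interpolate NA columns from valid neighbours, per row.
fill_na_columns <- function(m) {
  bad <- apply(m, 2, function(v) any(is.na(v)))
  if (!any(bad)) return(m)
  xs <- which(!bad)
  for (r in seq_len(nrow(m))) {
    m[r, bad] <- stats::approx(xs, m[r, xs], xout = which(bad), rule = 2)$y
  }
  m
}

#' Sample centerline profiles for edge reprocessing
#'
#' Places `2 * each_side + 1` samples per column at unit steps along the
#' local normal, centered on the given curve.  The central
#' `2 * floor(each_side / 2) + 1` rows (11 for the default) are tagged as
#' the edge band and the outermost 5 rows on each side as background bands.
#'
#' @param image numeric matrix
#' @param centerline an [edge_list()] (length >= 5)
#' @param each_side samples on each side of the curve
#' @return list with `profile` and `map` as in [sample_profiles()]; the
#'   profile carries `edge_rows` and `background_rows` indices
#' @export
sample_centerline_profiles <- function(image, centerline, each_side = 10) {
  assert_image(image)
  pts <- centerline$points
  if (nrow(pts) < 5) stop("centerline too short", call. = FALSE)
  nrows <- 2L * each_side + 1L
  ncols <- nrow(pts)
  vals <- matrix(NA_real_, nrows, ncols)
  map_r <- matrix(NA_real_, nrows, ncols)
  map_c <- matrix(NA_real_, nrows, ncols)
  for (k in seq_len(ncols)) {
    tn <- tangent_normal(centerline, k)
    nvec <- if (tn$normal[1] >= 0) tn$normal else -tn$normal
    offs <- seq(-each_side, each_side)
    rr <- pmin(pmax(pts[k, 1] + offs * nvec[1], 1), nrow(image))
    cc <- pmin(pmax(pts[k, 2] + offs * nvec[2], 1), ncol(image))
    map_r[, k] <- rr
    map_c[, k] <- cc
    vals[, k] <- bilinear(image, rr, cc)
  }
  half <- floor(each_side / 2)
  edge_rows <- (each_side + 1L - half):(each_side + 1L + half)
  bg <- min(5L, each_side)
  background_rows <- c(seq_len(bg), (nrows - bg + 1L):nrows)
  profile <- new_profile_image(vals, row_upper = NA, row_lower = NA,
                               edge_rows = edge_rows,
                               background_rows = background_rows)
  list(profile = profile,
       map = structure(list(r = map_r, c = map_c), class = "sampling_map"))
}

#' Map a profile image back to image space
#'
#' Scatters each profile value to the integer pixel nearest its source
#' coordinate; collisions are averaged.  Unassigned pixels inside the
#' sampled footprint are filled with the value of the nearest assigned
#' pixel; pixels outside the footprint are 0.
#'
#' @param profile a `profile_image` (or plain matrix of matching shape)
#' @param map the `sampling_map` returned with the profile
#' @param shape output `(rows, cols)`
#' @param rows optional subset of profile rows to scatter (e.g. the edge
#'   band during edge reprocessing)
#' @return numeric matrix
#' @export
reverse_sample <- function(profile, map, shape, rows = NULL) {
  vals <- if (inherits(profile, "profile_image")) profile$values else profile
  if (length(vals) == 0 || ncol(vals) == 0) return(matrix(0, shape[1], shape[2]))
  stopifnot(identical(dim(vals), dim(map$r)))
  if (is.null(rows)) rows <- seq_len(nrow(vals))
  ri <- round(as.vector(map$r[rows, , drop = FALSE]))
  ci <- round(as.vector(map$c[rows, , drop = FALSE]))
  vv <- as.vector(vals[rows, , drop = FALSE])
  ri <- pmin(pmax(ri, 1), shape[1])
  ci <- pmin(pmax(ci, 1), shape[2])
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0, shape[1], shape[2])
  lin <- (ci - 1L) * shape[1] + ri
  sums <- rowsum(vv, lin)
  counts <- rowsum(rep(1, length(lin)), lin)
  idx <- as.integer(rownames(sums))
  acc[idx] <- sums
  cnt[idx] <- counts
  out <- matrix(0, shape[1], shape[2])
  assigned <- cnt > 0
  out[assigned] <- acc[assigned] / cnt[assigned]
  # footprint: assigned set closed with a 3x3 element (fills interior holes)
  footprint <- erode3x3(dilate3x3(assigned * 1)) > 0
  holes <- footprint & !assigned
  if (any(holes)) {
    out <- nearest_fill(out, assigned, holes)
  }
  out
}

# Fill `holes` with the value of the nearest assigned pixel.  Holes are rare
# (interior gaps of the scatter), so an exact growing-window search per hole
# pixel is cheap.
nearest_fill <- function(values, assigned, holes) {
  nr <- nrow(values); nc <- ncol(values)
  hidx <- which(holes, arr.ind = TRUE)
  for (i in seq_len(nrow(hidx))) {
    r <- hidx[i, 1]; c <- hidx[i, 2]
    rad <- 2L
    repeat {
      rs <- max(1L, r - rad):min(nr, r + rad)
      cs <- max(1L, c - rad):min(nc, c + rad)
      sub <- assigned[rs, cs, drop = FALSE]
      if (any(sub)) {
        cand <- which(sub, arr.ind = TRUE)
        dr <- rs[cand[, 1]] - r
        dc <- cs[cand[, 2]] - c
        d2 <- dr^2 + dc^2
        best <- which.min(d2)
        # nearest inside the box is globally nearest once d <= rad
        if (sqrt(d2[best]) <= rad || rad >= max(nr, nc)) {
          values[r, c] <- values[rs[cand[best, 1]], cs[cand[best, 2]]]
          break
        }
      }
      if (rad >= max(nr, nc)) break
      rad <- rad * 2L
    }
  }
  values
}
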