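# Ordered bone-edge polylines: classification of skeleton points, tracing,
# automated merging of fragments, and pairing into upper/lower bone edges.

#' Construct an edge list (ordered polyline)
#'
#' @param points matrix of `(row, col)` coordinates (floats allowed)
#' @param category one of `"anterior"`, `"posterior"`, `"clavicle"` or NA
#' @param role one of `"upper"`, `"lower"`, `"centerline"` or NA
#' @return object of class `edge_list`
#' @export
edge_list <- function(points, category = NA_character_, role = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 2) stop("`points` must be an n x 2 matrix", call. = FALSE)
  colnames(points) <- c("row", "col")
  structure(list(points = points, category = category, role = role),
            class = "edge_list")
}

#' @export
print.edge_list <- function(x, ...) {
  cat(sprintf("edge_list: %d points, category=%s, role=%s\n",
              nrow(x$points), x$category, x$role))
  invisible(x)
}

#' Classify skeleton pixels as free, connection, or junction points
#'
#' Each positive pixel is labeled by its number of positive 8-neighbours:
#' at most 1 neighbour gives a free (end) point, exactly 2 a connection
#' point, 3 or more a junction point.
#'
#' @param skeleton binary, 1-pixel-wide (skeletonized) matrix
#' @return integer matrix: 0 background, 1 free, 2 connection, 3 junction
#'   (with attribute `labels`)
#' @export
classify_skeleton_points <- function(skeleton) {
  assert_binary(skeleton)
  m <- skeleton > 0
  cnt <- matrix(0, nrow(m), ncol(m))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    cnt <- cnt + shift_mat(m, dr, dc, FALSE)
  }
  out <- matrix(0L, nrow(m), ncol(m))
  out[m & cnt <= 1] <- 1L
  out[m & cnt == 2] <- 2L
  out[m & cnt >= 3] <- 3L
  attr(out, "labels") <- c("background", "free", "connection", "junction")
  out
}

# 8-neighbours of (r, c) inside the image, in deterministic (row, col) order.
neighbours8 <- function(r, c, nr, nc) {
  dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
  dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  rr <- r + dr; cc <- c + dc
  ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
  cbind(rr[ok], cc[ok])
}

#' Trace ordered edge lists from a skeletonized mask
#'
#' Walks from each free point through connection points, terminating at free
#' or junction points.  Segments between two junctions and pure cycles
#' (opened at their topmost-leftmost pixel) are also traced, so every
#' positive pixel belongs to at least one list.  Junction pixels are shared
#' by all incident lists.  Output is deterministic: lists are oriented
#' left-to-right (ties top-to-bottom) and sorted by topmost-then-leftmost
#' start point.
#'
#' @param skeleton binary skeletonized matrix
#' @return list of [edge_list()] objects
#' @export
trace_edge_lists <- function(skeleton) {
  assert_binary(skeleton)
  lab <- classify_skeleton_points(skeleton)
  nr <- nrow(skeleton); nc <- ncol(skeleton)
  consumed <- matrix(FALSE, nr, nc)   # free/connection pixels already used
  lists <- list()

  walk <- function(start, second) {
    path <- list(start)
    prev <- start
    cur <- second
    repeat {
      path[[length(path) + 1L]] <- cur
      if (lab[cur[1], cur[2]] != 2L) break   # free or junction terminates
      nb <- neighbours8(cur[1], cur[2], nr, nc)
      cand <- nb[skeleton[nb] > 0 & !(nb[, 1] == prev[1] & nb[, 2] == prev[2]), ,
                 drop = FALSE]
      # avoid stepping back onto pixels already in this path
      if (nrow(cand) > 1) {
        inpath <- vapply(seq_len(nrow(cand)), function(i) {
          any(vapply(path, function(p)
            p[1] == cand[i, 1] && p[2] == cand[i, 2], logical(1)))
        }, logical(1))
        if (any(!inpath)) cand <- cand[!inpath, , drop = FALSE]
      }
      if (nrow(cand) == 0) break
      ord <- order(cand[, 1], cand[, 2])
      nxt <- cand[ord[1], ]
      prev <- cur
      cur <- nxt
    }
    do.call(rbind, path)
  }

  start_walks <- function(seeds) {
    for (i in seq_len(nrow(seeds))) {
      s <- seeds[i, ]
      if (consumed[s[1], s[2]]) next
      nb <- neighbours8(s[1], s[2], nr, nc)
      nb <- nb[skeleton[nb] > 0, , drop = FALSE]
      if (nrow(nb) == 0) { consumed[s[1], s[2]] <<- TRUE; next }  # isolated
      for (j in seq_len(nrow(nb))) {
        n0 <- nb[j, ]
        if (lab[n0[1], n0[2]] != 3L && consumed[n0[1], n0[2]]) next
        if (lab[s[1], s[2]] == 1L && j > 1) next   # free point: single walk
        pts <- walk(s, n0)
        for (k in seq_len(nrow(pts))) {
          if (lab[pts[k, 1], pts[k, 2]] != 3L) consumed[pts[k, 1], pts[k, 2]] <<- TRUE
        }
        lists[[length(lists) + 1L]] <<- pts
      }
    }
  }

  pos <- which(skeleton > 0, arr.ind = TRUE)
  if (nrow(pos) == 0) return(list())
  ordp <- order(pos[, 1], pos[, 2])
  pos <- pos[ordp, , drop = FALSE]

  frees <- pos[lab[pos] == 1L, , drop = FALSE]
  if (nrow(frees)) start_walks(frees)
  juncs <- pos[lab[pos] == 3L, , drop = FALSE]
  if (nrow(juncs)) start_walks(juncs)
  # remaining unconsumed connection pixels form pure cycles
  repeat {
    left <- which(skeleton > 0 & !consumed & lab == 2L, arr.ind = TRUE)
    if (nrow(left) == 0) break
    ordl <- order(left[, 1], left[, 2])
    s <- left[ordl[1], ]
    nb <- neighbours8(s[1], s[2], nr, nc)
    nb <- nb[skeleton[nb] > 0, , drop = FALSE]
    pts <- walk(s, nb[order(nb[, 1], nb[, 2])[1], ])
    for (k in seq_len(nrow(pts))) consumed[pts[k, 1], pts[k, 2]] <- TRUE
    lists[[length(lists) + 1L]] <- pts
  }

  out <- lapply(lists, function(pts) {
    if (nrow(pts) < 2) return(NULL)
    a <- pts[1, ]; b <- pts[nrow(pts), ]
    if (b[2] < a[2] || (b[2] == a[2] && b[1] < a[1])) {
      pts <- pts[nrow(pts):1, , drop = FALSE]
    }
    edge_list(pts)
  })
  out <- Filter(Negate(is.null), out)
  # drop exact duplicates (e.g. 2-point bridges traced from both junctions)
  keys <- vapply(out, function(e) paste(e$points, collapse = ","), character(1))
  out <- out[!duplicated(keys)]
  starts <- t(vapply(out, function(e) e$points[1, ], numeric(2)))
  if (length(out) > 1) out <- out[order(starts[, 1], starts[, 2])]
  out
}

# Outgoing unit tangent at an endpoint of a polyline (end = "head"/"tail"),
# pointing away from the list interior.
endpoint_tangent <- function(points, end, window = 5) {
  n <- nrow(points)
  w <- min(window, n - 1)
  v <- if (end == "tail") points[n, ] - points[n - w, ]
       else points[1, ] - points[1 + w, ]
  v / sqrt(sum(v^2))
}

#' Merge traced edge fragments belonging to the same bone edge
#'
#' Automates the interactive fragment-joining step: greedily joins pairs of
#' lists whose endpoints are within `gap_tol` pixels, whose endpoint
#' tangents are aligned within `angle_tol_deg`, and whose connecting gap is
#' aligned with the tangents (this prevents joining parallel edges of
#' neighbouring bones).  Gaps are bridged by linear interpolation; the merge
#' iterates to a fixpoint.  A `plan` of explicit index pairs reproduces
#' manual/interactive merging and bypasses the tolerances.
#'
#' @param lists list of [edge_list()] objects
#' @param gap_tol maximum endpoint distance in pixels
#' @param angle_tol_deg maximum tangent misalignment in degrees
#' @param plan optional n x 2 matrix of list indices to merge unconditionally
#' @return list of merged [edge_list()] objects
#' @export
merge_edge_lists <- function(lists, gap_tol = 10, angle_tol_deg = 30,
                             plan = NULL) {
  if (length(lists) <= 1 && is.null(plan)) return(lists)
  join <- function(a, b) {
    # bridge from tail of a to head of b at ~1 px spacing
    pa <- a$points; pb <- b$points
    p <- pa[nrow(pa), ]; q <- pb[1, ]
    gap <- sqrt(sum((q - p)^2))
    bridge <- NULL
    if (gap > 1.5) {
      k <- ceiling(gap)
      t <- seq(0, 1, length.out = k + 1)[-c(1, k + 1)]
      bridge <- cbind(p[1] + t * (q[1] - p[1]), p[2] + t * (q[2] - p[2]))
    }
    edge_list(rbind(pa, bridge, pb),
              category = if (!is.na(a$category)) a$category else b$category,
              role = a$role)
  }
  if (!is.null(plan)) {
    plan <- as.matrix(plan)
    for (i in seq_len(nrow(plan))) {
      a <- lists[[plan[i, 1]]]; b <- lists[[plan[i, 2]]]
      lists[[plan[i, 1]]] <- join(a, b)
      lists[plan[i, 2]] <- list(NULL)
    }
    return(Filter(Negate(is.null), lists))
  }

  cosmax <- cos(angle_tol_deg * pi / 180)
  repeat {
    n <- length(lists)
    if (n <= 1) break
    best <- NULL; bestd <- Inf
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- lists[[i]]; b <- lists[[j]]
      if (!is.na(a$category) && !is.na(b$category) &&
          a$category != b$category) next
      for (ea in c("head", "tail")) for (eb in c("head", "tail")) {
        p <- if (ea == "tail") a$points[nrow(a$points), ] else a$points[1, ]
        q <- if (eb == "tail") b$points[nrow(b$points), ] else b$points[1, ]
        d <- sqrt(sum((q - p)^2))
        if (d > gap_tol || d >= bestd) next
        ta <- endpoint_tangent(a$points, ea)
        tb <- endpoint_tangent(b$points, eb)
        # continuation direction: out of a, into b (i.e. -tb)
        if (sum(ta * -tb) < cosmax) next
        if (d > 1e-9) {
          g <- (q - p) / d
          if (sum(ta * g) < cosmax || sum(-tb * g) < cosmax) next
        }
        best <- list(i = i, j = j, ea = ea, eb = eb)
        bestd <- d
      }
    }
    if (is.null(best)) break
    a <- lists[[best$i]]; b <- lists[[best$j]]
    if (best$ea == "head") a$points <- a$points[nrow(a$points):1, , drop = FALSE]
    if (best$eb == "tail") b$points <- b$points[nrow(b$points):1, , drop = FALSE]
    merged <- join(a, b)
    # restore left-to-right orientation
    pm <- merged$points
    if (pm[nrow(pm), 2] < pm[1, 2]) merged$points <- pm[nrow(pm):1, , drop = FALSE]
    lists[[best$i]] <- merged
    lists[best$j] <- list(NULL)
    lists <- Filter(Negate(is.null), lists)
  }
  lists
}

#' Pair merged edges into upper/lower bone pairs
#'
#' Within each category, every edge is matched with the edge of maximal
#' arc-length overlap whose mean signed normal offset (towards larger rows)
#' is smallest positive.  The edge on the smaller-row side becomes the upper
#' edge; the centerline is the midpoint curve of matched point pairs.
#' Unpaired edges are dropped with a warning.
#'
#' @param lists list of [edge_list()] objects (tagged with categories when
#'   available)
#' @param max_offset maximum plausible bone width in pixels
#' @return list of `bone_pair` objects: `upper`, `lower`, `centerline`,
#'   `category`
#' @export
pair_upper_lower <- function(lists, max_offset = 50) {
  n <- length(lists)
  if (n < 2) {
    if (n == 1) warning("unpaired edge excluded")
    return(list())
  }
  # candidate scores for ordered pairs (upper i -> lower j)
  cand <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    a <- lists[[i]]; b <- lists[[j]]
    if (!is.na(a$category) && !is.na(b$category) &&
        a$category != b$category) next
    pa <- a$points; pb <- b$points
    offs <- numeric(0)
    hits <- 0L
    idxs <- round(seq(1, nrow(pa), length.out = min(nrow(pa), 40)))
    for (k in idxs) {
      tn <- tangent_normal(a, k)
      # normal toward larger rows
      nvec <- if (tn$normal[1] >= 0) tn$normal else -tn$normal
      res <- tryCatch(
        find_opposite_point(pa[k, ], nvec, b, max_dist = max_offset),
        error = function(e) NULL)
      if (is.null(res)) next
      off <- sum((res$point - pa[k, ]) * nvec)
      if (off > 0.5) {
        offs <- c(offs, off)
        hits <- hits + 1L
      }
    }
    if (hits >= max(3L, length(idxs) %/% 3L)) {
      cand[[length(cand) + 1L]] <- list(i = i, j = j, overlap = hits,
                                        offset = mean(offs))
    }
  }
  if (!length(cand)) {
    warning("no edges could be paired")
    return(list())
  }
  ord <- order(-vapply(cand, `[[`, numeric(1), "overlap"),
               vapply(cand, `[[`, numeric(1), "offset"))
  used <- logical(n)
  pairs <- list()
  for (k in ord) {
    cc <- cand[[k]]
    if (used[cc$i] || used[cc$j]) next
    used[cc$i] <- used[cc$j] <- TRUE
    upper <- lists[[cc$i]]; lower <- lists[[cc$j]]
    upper$role <- "upper"; lower$role <- "lower"
    pairs[[length(pairs) + 1L]] <- make_bone_pair(upper, lower,
                                                  max_offset = max_offset)
  }
  if (any(!used)) {
    warning(sprintf("%d unpaired edge(s) excluded", sum(!used)))
  }
  pairs
}

# Build a bone_pair, deriving the centerline from Eq.-5-style opposite-point
# correspondences.
make_bone_pair <- function(upper, lower, max_offset = 50) {
  pa <- upper$points
  mids <- matrix(NA_real_, nrow(pa), 2)
  for (k in seq_len(nrow(pa))) {
    tn <- tangent_normal(upper, k)
    nvec <- if (tn$normal[1] >= 0) tn$normal else -tn$normal
    res <- tryCatch(find_opposite_point(pa[k, ], nvec, lower,
                                        max_dist = max_offset),
                    error = function(e) NULL)
    if (!is.null(res)) mids[k, ] <- (pa[k, ] + res$point) / 2
  }
  ok <- stats::complete.cases(mids)
  centerline <- edge_list(mids[ok, , drop = FALSE],
                          category = upper$category, role = "centerline")
  structure(list(upper = upper, lower = lower, centerline = centerline,
                 category = upper$category), class = "bone_pair")
}

#' @export
print.bone_pair <- function(x, ...) {
  cat(sprintf("bone_pair (%s): upper %d pts, lower %d pts\n",
              x$category, nrow(x$upper$points), nrow(x$lower$points)))
  invisible(x)
}
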