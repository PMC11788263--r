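# Assembling per-bone profile results into image space, Poisson background
# correction, residual edge reprocessing, and the end-to-end traditional
# (non-learned) suppression pipeline.

#' Assemble the preliminary bone image from per-bone profiles
#'
#' Reverse-samples each bone's profile-domain bone estimate and sums the
#' per-bone images pixelwise (overlapping bones add).  When a profile
#' carries edge-row markers, only the rows between the upper and lower
#' edges are scattered: bone is zero outside its own edges by definition,
#' and the outer sampling band (which exists to anchor the background
#' estimate) would otherwise re-deposit contamination from crossing
#' structures.
#'
#' @param per_bone list of lists with `profile` (matrix or `profile_image`)
#'   and `map` (`sampling_map`)
#' @param shape output `(rows, cols)`
#' @return numeric matrix (the preliminary bone image)
#' @export
assemble_preliminary_bone <- function(per_bone, shape) {
  if (length(per_bone) < 1) stop("need at least one bone", call. = FALSE)
  out <- matrix(0, shape[1], shape[2])
  for (pb in per_bone) {
    rows <- NULL
    pr <- pb$profile
    if (inherits(pr, "profile_image") && !is.null(pr$row_of_upper_edge) &&
        !is.na(pr$row_of_upper_edge)) {
      rows <- pr$row_of_upper_edge:pr$row_of_lower_edge
    }
    out <- out + reverse_sample(pr, pb$map, shape, rows = rows)
  }
  out
}

#' Rasterize the bone region mask from edge pairs
#'
#' Fills each upper/lower edge polygon, unions across bones, and dilates
#' once with a 3x3 structuring element.
#'
#' @param pairs list of `bone_pair` objects
#' @param shape output `(rows, cols)`
#' @return binary matrix
#' @export
make_bone_region_mask <- function(pairs, shape) {
  out <- matrix(0, shape[1], shape[2])
  for (p in pairs) {
    up <- p$upper$points
    lo <- p$lower$points
    if (nrow(up) < 2 || nrow(lo) < 2) {
      warning("bone with degenerate edges skipped")
      next
    }
    poly_r <- c(up[, 1], rev(lo[, 1]))
    poly_c <- c(up[, 2], rev(lo[, 2]))
    out <- pmax(out, fill_polygon(poly_r, poly_c, shape))
    # ensure the edge curves themselves are included before dilation
    out <- pmax(out, rasterize_polyline(up, shape))
    out <- pmax(out, rasterize_polyline(lo, shape))
  }
  dilate3x3(out)
}

#' Correct the bone-image background by Poisson reconstruction
#'
#' Solves the discrete Poisson equation `lap(x) = lap(I_B0)` (5-point
#' Laplacian) over the bone-region pixels with Dirichlet condition `x = 0`
#' on all nonbone pixels, using a sparse direct solve.  The output is
#' exactly 0 outside the bone region, which pins the nonbone background to
#' zero while preserving the gradient (bone) content inside.
#'
#' When the bone region touches the image border (bones running to the edge
#' of the field of view), the image and region are reflect-padded first so
#' that the zero-Dirichlet frame sits in the virtual padding instead of
#' truncating real bone; the result is cropped back.
#'
#' @param I_B0 preliminary bone image
#' @param bone_region binary matrix
#' @param tol unused by the direct solver; kept for API stability with
#'   iterative solvers
#' @param pad reflect-padding width used when the region touches the border
#' @return corrected bone image, zero outside `bone_region`
#' @export
poisson_correct <- function(I_B0, bone_region, tol = 1e-8, pad = 8) {
  assert_image(I_B0)
  stopifnot(identical(dim(I_B0), dim(bone_region)))
  region0 <- bone_region > 0
  touches <- any(region0[c(1, nrow(I_B0)), ]) || any(region0[, c(1, ncol(I_B0))])
  if (touches && pad > 0) {
    ri <- c(pad:1, seq_len(nrow(I_B0)), nrow(I_B0) - (0:(pad - 1)))
    ci <- c(pad:1, seq_len(ncol(I_B0)), ncol(I_B0) - (0:(pad - 1)))
    out <- poisson_correct(I_B0[ri, ci], (region0 * 1)[ri, ci], tol, pad = 0)
    return(out[pad + seq_len(nrow(I_B0)), pad + seq_len(ncol(I_B0))])
  }
  nr <- nrow(I_B0); nc <- ncol(I_B0)
  region <- region0
  # Dirichlet frame: the 1-px border is always nonbone
  region[c(1, nr), ] <- FALSE
  region[, c(1, nc)] <- FALSE
  idx <- which(region)
  if (length(idx) == 0) return(matrix(0, nr, nc))
  id_map <- matrix(0L, nr, nc)
  id_map[idx] <- seq_along(idx)
  rr <- ((idx - 1L) %% nr) + 1L
  cc <- ((idx - 1L) %/% nr) + 1L
  # RHS: b = -lap(I_B0) at region pixels (A = -lap is positive definite)
  lap <- shift_mat(I_B0, 1, 0) + shift_mat(I_B0, -1, 0) +
    shift_mat(I_B0, 0, 1) + shift_mat(I_B0, 0, -1) - 4 * I_B0
  b <- -lap[idx]
  ii <- seq_along(idx)
  tri_i <- ii; tri_j <- ii; tri_x <- rep(4, length(idx))
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
    nr2 <- rr + d[1]; nc2 <- cc + d[2]
    nid <- id_map[cbind(nr2, nc2)]
    sel <- nid > 0L
    tri_i <- c(tri_i, ii[sel])
    tri_j <- c(tri_j, nid[sel])
    tri_x <- c(tri_x, rep(-1, sum(sel)))
  }
  A <- Matrix::sparseMatrix(i = tri_i, j = tri_j, x = tri_x,
                            dims = c(length(idx), length(idx)))
  x <- as.numeric(Matrix::solve(A, b))
  out <- matrix(0, nr, nc)
  out[idx] <- x
  out
}

#' Reprocess residual bone edges in the preliminary soft-tissue image
#'
#' Samples 21-row centerline-style profiles along each bone's upper and
#' lower edges (optionally also the centerline) of the preliminary soft
#' image `I - I_B1`, runs background filtering anchored on the outer 5-row
#' background bands, clustering, PCA, and smoothing with the smaller edge
#' kernel, then reverse-samples the edge bands and sums them into the
#' residual edge image.  The final bone image is `I_B1 + residual_edges`.
#'
#' @param I input image
#' @param I_B1 Poisson-corrected bone image
#' @param pairs list of `bone_pair` objects
#' @param config a [bss_config()]
#' @return list with `residual_edges` and `bone_final`
#' @export
edge_reprocess <- function(I, I_B1, pairs, config = bss_config()) {
  stopifnot(identical(dim(I), dim(I_B1)))
  soft0 <- I - I_B1
  shape <- dim(I)
  residual <- matrix(0, shape[1], shape[2])
  for (p in pairs) {
    curves <- list(p$upper, p$lower)
    if (config$reprocess_curves == "edges+centerline") {
      curves <- c(curves, list(p$centerline))
    }
    for (curve in curves) {
      res <- tryCatch({
        sp <- sample_centerline_profiles(soft0, curve,
                                         each_side = config$each_side)
        bg_margin <- min(5L, config$each_side)
        out <- suppress_profile(sp$profile, config, margin = bg_margin,
                                kernel = config$edge_kernel,
                                smooth_scale = config$edge_kernel)
        reverse_sample(out$bone_profile, sp$map, shape,
                       rows = sp$profile$edge_rows)
      }, error = function(e) {
        warning(sprintf("edge reprocessing skipped a curve: %s",
                        conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) residual <- residual + res
    }
  }
  list(residual_edges = residual, bone_final = I_B1 + residual)
}

#' Traditional (non-learned) bone suppression pipeline
#'
#' Runs the complete profile-domain pipeline: edge extraction (when binary
#' masks are supplied), perpendicular profile sampling, PCA-based blind
#' source separation, reverse sampling, Poisson background correction, and
#' residual edge reprocessing.  Returns the decomposition
#' `I = bone_final + soft_final` (exact by construction).
#'
#' @param I input image (matrix in `[0, 1]`)
#' @param edges either a list of `bone_pair` objects (manual / ground-truth
#'   edge mode) or a named list of per-category binary edge masks
#'   (detected-edge mode; masks are skeletonized, traced, merged and
#'   paired)
#' @param config a [bss_config()]
#' @return object of class `decomposition_result` with fields
#'   `bone_preliminary`, `bone_corrected`, `residual_edges`, `bone_final`,
#'   `soft_final`, `bone_region_mask`, `per_bone` diagnostics, `config`
#' @export
suppress_bones_traditional <- function(I, edges, config = bss_config()) {
  assert_image(I)
  shape <- dim(I)
  pairs <- resolve_edges(edges)
  if (length(pairs) == 0) {
    zero <- matrix(0, shape[1], shape[2])
    return(structure(list(
      bone_preliminary = zero, bone_corrected = zero, residual_edges = zero,
      bone_final = zero, soft_final = I, bone_region_mask = zero,
      per_bone = list(), config = config
    ), class = "decomposition_result"))
  }
  per_bone <- list()
  diagnostics <- list()
  for (i in seq_along(pairs)) {
    p <- pairs[[i]]
    res <- tryCatch({
      sp <- sample_profiles(I, p, n_outer = config$n_outer,
                            n_inner = config$n_inner,
                            max_dist = config$max_dist)
      out <- suppress_profile(sp$profile, config)
      bp <- new_profile_image(out$bone_profile,
                              sp$profile$row_of_upper_edge,
                              sp$profile$row_of_lower_edge)
      list(profile = bp, map = sp$map,
           diag = list(r = out$r, labels = out$labels))
    }, error = function(e) {
      warning(sprintf("bone %d skipped: %s", i, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) {
      per_bone[[length(per_bone) + 1L]] <- res
      diagnostics[[length(diagnostics) + 1L]] <- res$diag
    }
  }
  if (length(per_bone) == 0) stop("no bone could be processed", call. = FALSE)
  I_B0 <- assemble_preliminary_bone(per_bone, shape)
  mask <- make_bone_region_mask(pairs, shape)
  I_B1 <- poisson_correct(I_B0, mask)
  ep <- edge_reprocess(I, I_B1, pairs, config)
  structure(list(
    bone_preliminary = I_B0,
    bone_corrected = I_B1,
    residual_edges = ep$residual_edges,
    bone_final = ep$bone_final,
    soft_final = I - ep$bone_final,
    bone_region_mask = mask,
    per_bone = diagnostics,
    config = config
  ), class = "decomposition_result")
}

# Accept either bone pairs or per-category binary masks.
resolve_edges <- function(edges) {
  if (length(edges) == 0) return(list())
  if (inherits(edges[[1]], "bone_pair")) return(edges)
  if (all(vapply(edges, is.list, logical(1))) &&
      !is.null(edges[[1]]$upper)) {
    # phantom-style edge list bundles
    return(lapply(edges, function(e) make_bone_pair(e$upper, e$lower)))
  }
  # named list of per-category binary masks
  pairs <- list()
  for (cat in names(edges)) {
    mask <- edges[[cat]]
    if (!any(mask > 0)) next
    sk <- thin_skeleton(mask)
    traced <- trace_edge_lists(sk)
    traced <- lapply(traced, function(e) { e$category <- cat; e })
    merged <- merge_edge_lists(traced)
    pairs <- c(pairs, pair_upper_lower(merged))
  }
  pairs
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("decomposition_result: %d x %d, %d bone(s) processed\n",
              nrow(x$bone_final), ncol(x$bone_final), length(x$per_bone)))
  invisible(x)
}
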