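# Synthetic radiograph phantoms with exact ground-truth decompositions.
#
# A phantom scene is built additively: a smooth low-frequency background with
# two soft-edged elliptical lung fields, a set of long, gently curved bones
# with a raised-cosine cross-section, optional thin "corruptor" line segments
# emulating catheters or crossing structures, and optional pixel noise.  The
# corruptors and the noise are assigned to the soft-tissue component so that
# cxr = soft + bone holds exactly for every seed.

#' Phantom generator configuration
#'
#' @param shape integer vector `(rows, cols)`, at least 64 x 64.
#' @param n_anterior,n_posterior,n_clavicle counts of simulated bones per
#'   category.
#' @param bone_peak maximum bone intensity, in `(0, 1]`.
#' @param bone_halfwidth half-width of the bone cross-section in pixels
#'   (distance from centerline to either edge).
#' @param background_scale smoothness length of the background field in
#'   pixels; larger values give flatter backgrounds.
#' @param n_corruptors number of thin crossing line structures.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (assigned to the soft-tissue component).
#' @param seed integer seed; identical config + seed gives a bit-identical
#'   scene.
#' @return an object of class `phantom_config`
#' @export
phantom_config <- function(shape = c(192, 192),
                           n_anterior = 2, n_posterior = 2, n_clavicle = 1,
                           bone_peak = 0.35, bone_halfwidth = 6,
                           background_scale = 64,
                           n_corruptors = 1, noise_sd = 0, seed = 1) {
  shape <- as.integer(shape)
  if (length(shape) != 2 || any(shape < 64)) {
    stop("`shape` must be (rows, cols) with both >= 64", call. = FALSE)
  }
  if (bone_peak <= 0 || bone_peak > 1) {
    stop("`bone_peak` must be in (0, 1]", call. = FALSE)
  }
  if (any(c(n_anterior, n_posterior, n_clavicle, n_corruptors) < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  structure(list(
    shape = shape, n_anterior = n_anterior, n_posterior = n_posterior,
    n_clavicle = n_clavicle, bone_peak = bone_peak,
    bone_halfwidth = bone_halfwidth, background_scale = background_scale,
    n_corruptors = n_corruptors, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Generate the smooth background field and lung mask of a phantom
#'
#' The background is a low-pass-filtered seeded noise field around a mid-grey
#' level, depressed smoothly inside two elliptical lung fields, clipped to
#' `[0, 0.8]`.  The lung mask is the union of the two (hard) ellipses.
#'
#' @param config a [phantom_config()]
#' @return list with `background` (image) and `lung_mask` (binary image)
#' @export
generate_background <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  nr <- config$shape[1]; nc <- config$shape[2]
  field <- with_seed(config$seed, {
    noise <- matrix(stats::rnorm(nr * nc), nr, nc)
    lowpass_field(noise, config$background_scale)
  })
  sdf <- stats::sd(as.vector(field))
  if (sdf > 0) field <- field / sdf * 0.05
  bg <- 0.55 + field

  # two soft-edged elliptical lung fields
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  lung <- matrix(0, nr, nc)
  depress <- matrix(0, nr, nc)
  centers <- list(c(0.52 * nr, 0.30 * nc), c(0.52 * nr, 0.70 * nc))
  a <- 0.34 * nr; b <- 0.20 * nc
  for (ct in centers) {
    d <- ((rows - ct[1]) / a)^2 + ((cols - ct[2]) / b)^2
    lung[d <= 1] <- 1
    # wide sigmoid walls keep the background low-frequency (the depression
    # transition spans tens of pixels, as the smooth-field contract requires)
    depress <- pmax(depress, 1 / (1 + exp((d - 1) / 0.35)))
  }
  bg <- bg - 0.12 * depress
  bg <- pmin(pmax(bg, 0), 0.8)
  list(background = bg, lung_mask = lung)
}

# Keep only spatial frequencies below 1/scale cycles per pixel (plus DC).
lowpass_field <- function(noise, scale) {
  nr <- nrow(noise); nc <- ncol(noise)
  fr <- c(0:(floor(nr / 2)), -((ceiling(nr / 2) - 1):1)) / nr
  fc <- c(0:(floor(nc / 2)), -((ceiling(nc / 2) - 1):1)) / nc
  rad <- sqrt(outer(fr^2, fc^2, `+`))
  keep <- rad <= 1 / scale
  keep[1, 1] <- TRUE
  f <- stats::fft(noise)
  Re(stats::fft(f * keep, inverse = TRUE)) / (nr * nc)
}

#' Generate one bone with a raised-cosine cross-section
#'
#' The centerline is an interpolating spline through the control points
#' (parameterized by column; bones are assumed near-horizontal).  Intensity at
#' a pixel is `peak * 0.5 * (1 + cos(pi * d / halfwidth))` where `d` is the
#' perpendicular distance to the centerline, zero for `d >= halfwidth`.  The
#' upper and lower edge polylines are the centerline offset by `-halfwidth`
#' and `+halfwidth` along the local normal.
#'
#' Intensity also carries a longitudinal raised-cosine envelope ramping from
#' zero over the outermost `taper` fraction of the bone length at each end:
#' bones fade out the way ribs do towards the costal cartilage instead of
#' ending in abrupt half-disc caps (which no perpendicular profile could
#' ever sample).  The envelope makes the profile-column amplitude vary
#' along the bone while keeping the column space exactly rank one.
#'
#' @param curve_control_points matrix of `(row, col)` control points, columns
#'   strictly increasing, inside the image.
#' @param halfwidth half-width in pixels (>= 2)
#' @param peak centerline intensity (0 gives a zero image but edges are still
#'   returned)
#' @param shape image `(rows, cols)`
#' @param taper fraction of the bone length over which intensity ramps up
#'   from zero at each end (0 disables the envelope)
#' @return list with `bone` (image), `upper`, `lower`, `centerline`
#'   (edge lists, see [edge_list()])
#' @export
generate_bone <- function(curve_control_points, halfwidth, peak, shape,
                          taper = 0.1) {
  if (halfwidth < 2) stop("`halfwidth` must be >= 2", call. = FALSE)
  cp <- as.matrix(curve_control_points)
  if (any(cp[, 1] < 1 | cp[, 1] > shape[1] | cp[, 2] < 1 | cp[, 2] > shape[2])) {
    stop("control points must lie inside the image", call. = FALSE)
  }
  rowfun <- stats::splinefun(cp[, 2], cp[, 1], method = "natural")
  # emit points at ~unit arc spacing (per-column stepping under-samples
  # steep bones)
  cr <- range(cp[, 2])
  slope_max <- max(abs(rowfun(seq(cr[1], cr[2], length.out = 64), deriv = 1)))
  step <- 1 / sqrt(1 + min(slope_max, 2)^2)
  cols <- seq(cr[1], cr[2], by = step)
  rr <- rowfun(cols)
  drr <- rowfun(cols, deriv = 1)

  limr <- function(r) pmin(pmax(r, 1), shape[1])
  limc <- function(c) pmin(pmax(c, 1), shape[2])
  # unit tangent (dr, dc) ~ (drr, 1); normal points toward larger rows (down)
  tnorm <- sqrt(drr^2 + 1)
  n_r <- 1 / tnorm
  n_c <- -drr / tnorm
  if (any(rr < 1 | rr > shape[1])) {
    warning("bone centerline clipped to image bounds")
  }
  center <- cbind(limr(rr), cols)
  upper <- cbind(limr(rr - halfwidth * n_r), limc(cols - halfwidth * n_c))
  lower <- cbind(limr(rr + halfwidth * n_r), limc(cols + halfwidth * n_c))

  bone <- matrix(0, shape[1], shape[2])
  if (peak > 0) {
    dense <- densify_polyline(center, step = 0.25)
    margin <- halfwidth + 2
    cmin <- min(cols); cmax <- max(cols)
    tlen <- taper * (cmax - cmin)
    envelope <- function(ci) {
      if (tlen <= 0) return(as.numeric(ci >= cmin & ci <= cmax))
      t <- pmin(ci - cmin, cmax - ci) / tlen
      ifelse(t < 0, 0, ifelse(t >= 1, 1, 0.5 * (1 - cos(pi * t))))
    }
    for (ci in seq_len(shape[2])) {
      env <- envelope(ci)
      if (env <= 0) next
      sel <- abs(dense[, 2] - ci) <= margin
      if (!any(sel)) next
      rmin <- max(1L, floor(min(dense[sel, 1]) - margin))
      rmax <- min(shape[1], ceiling(max(dense[sel, 1]) + margin))
      rs <- rmin:rmax
      d2 <- outer(rs, dense[sel, 1], function(a, b) (a - b)^2) +
        matrix((ci - dense[sel, 2])^2, length(rs), sum(sel), byrow = TRUE)
      d <- sqrt(apply(d2, 1, min))
      prof <- ifelse(d < halfwidth,
                     env * peak * 0.5 * (1 + cos(pi * d / halfwidth)), 0)
      bone[rs, ci] <- pmax(bone[rs, ci], prof)
    }
  }
  list(
    bone = bone,
    upper = edge_list(upper, role = "upper"),
    lower = edge_list(lower, role = "lower"),
    centerline = edge_list(center, role = "centerline")
  )
}

#' Generate a complete phantom scene
#'
#' Composes background + bones + corruptor lines + noise into a CXR-like
#' image with an exact ground-truth decomposition `cxr = soft + bone`.
#' Corruptors and noise are part of the soft component.
#'
#' @param config a [phantom_config()]
#' @return an object of class `phantom_scene` with fields `cxr`, `bone`,
#'   `soft`, `edge_masks` (per category), `edge_lists` (per bone: `upper`,
#'   `lower`, `centerline`, `category`), `lung_mask`, `corruptor_mask`,
#'   `config`
#' @export
generate_phantom <- function(config) {
  if (!inherits(config, "phantom_config")) config <- do.call(phantom_config, config)
  nr <- config$shape[1]; nc <- config$shape[2]
  bgout <- generate_background(config)

  cats <- c(rep("clavicle", config$n_clavicle),
            rep("posterior", config$n_posterior),
            rep("anterior", config$n_anterior))
  n_bones <- length(cats)
  hw <- config$bone_halfwidth

  scene <- with_seed(config$seed + 1L, {
    bone <- matrix(0, nr, nc)
    lists <- list()
    masks <- list(anterior = matrix(0, nr, nc),
                  posterior = matrix(0, nr, nc),
                  clavicle = matrix(0, nr, nc))
    if (n_bones > 0) {
      # Layout: clavicles and posterior ribs are near-horizontal, gently
      # curved, and span the full image width (the method assumes long,
      # continuous bones, and ribs in tightly cropped pediatric CXRs run to
      # the lateral borders).  Anterior ribs descend steeply (~40 degrees)
      # across them, entering at the top border and exiting at the right
      # border, so bone-on-bone crossings occur by construction -- as in
      # real projections -- but each crossing corrupts only a small
      # minority of profile columns.
      n_flat <- config$n_clavicle + config$n_posterior
      top <- 0.20 * nr; bottom <- 0.80 * nr
      flat_slots <- if (n_flat > 0) {
        seq(top, bottom, length.out = n_flat + 2)[2:(n_flat + 1)]
      } else numeric(0)
      flat_i <- 0L; ant_i <- 0L
      for (i in seq_len(n_bones)) {
        if (cats[i] == "anterior") {
          # steep diagonals entering at the left border and exiting at the
          # bottom or right border, so both end caps are clipped off-image
          ant_i <- ant_i + 1L
          slope <- stats::runif(1, 0.7, 0.85)
          n_ant <- max(1L, config$n_anterior)
          r0 <- 0.04 * nr + (ant_i - 1) / n_ant * 0.30 * nr +
            stats::runif(1, 0, 2)
          c_end <- min(nc, 1 + (nr - 1.2 - r0) / slope)
          cm <- (1 + c_end) / 2
          cp <- cbind(
            r0 + slope * (c(1, cm, c_end) - 1),
            c(1, cm, c_end)
          )
        } else {
          flat_i <- flat_i + 1L
          r0 <- flat_slots[flat_i] + stats::runif(1, -1.5, 1.5)
          amp <- switch(cats[i],
            posterior = -stats::runif(1, 0.015, 0.03) * nr,
            clavicle = stats::runif(1, -0.01, 0.01) * nr)
          cm <- (1 + nc) / 2
          cp <- cbind(
            r0 + amp * c(0, 1, 0),
            c(1, cm, nc)
          )
        }
        peak <- config$bone_peak * stats::runif(1, 0.85, 1)
        b <- generate_bone(cp, hw, peak, config$shape, taper = 0)
        bone <- bone + b$bone
        b$upper$category <- cats[i]
        b$lower$category <- cats[i]
        b$centerline$category <- cats[i]
        lists[[i]] <- list(upper = b$upper, lower = b$lower,
                           centerline = b$centerline, category = cats[i])
        masks[[cats[i]]] <- pmax(masks[[cats[i]]],
                                 rasterize_polyline(b$upper$points, config$shape))
        masks[[cats[i]]] <- pmax(masks[[cats[i]]],
                                 rasterize_polyline(b$lower$points, config$shape))
      }
    }
    corr <- matrix(0, nr, nc)
    corr_mask <- matrix(0, nr, nc)
    if (config$n_corruptors > 0) {
      for (k in seq_len(config$n_corruptors)) {
        cc <- stats::runif(1, 0.25, 0.75) * nc
        slope <- stats::runif(1, -0.25, 0.25)   # near-vertical line col(row)
        rows <- seq_len(nr)
        colc <- cc + slope * (rows - nr / 2)
        for (w in seq(-1, 1, by = 0.5)) {
          ci <- pmin(pmax(round(colc + w), 1), nc)
          amp <- 0.15 * exp(-(w^2) / 1.2)
          idx <- cbind(rows, ci)
          corr[idx] <- pmax(corr[idx], amp)
          corr_mask[idx] <- 1
        }
      }
    }
    noise <- if (config$noise_sd > 0) {
      matrix(stats::rnorm(nr * nc, sd = config$noise_sd), nr, nc)
    } else matrix(0, nr, nc)
    list(bone = bone, lists = lists, masks = masks,
         corr = corr, corr_mask = corr_mask, noise = noise)
  })

  soft <- bgout$background + scene$corr + scene$noise
  cxr <- soft + scene$bone
  structure(list(
    cxr = cxr, bone = scene$bone, soft = soft,
    edge_masks = scene$masks, edge_lists = scene$lists,
    lung_mask = bgout$lung_mask, corruptor_mask = scene$corr_mask,
    config = config
  ), class = "phantom_scene")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("phantom_scene: %d x %d, %d bones, %d corruptors\n",
              nrow(x$cxr), ncol(x$cxr), length(x$edge_lists),
              x$config$n_corruptors))
  invisible(x)
}
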