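# Bone suppression inside profile images: background filtering,
# corrupted-profile clustering, PCA reconstruction, along-bone smoothing.

#' Configuration for PCA-based blind source separation
#'
#' @param smooth_scale along-bone smoothing scale (pixels) applied to the
#'   estimated background
#' @param margin samples on each profile end used as background anchors
#' @param var_threshold cumulative explained-variance fraction retained by
#'   the PCA reconstruction
#' @param smooth_kernel moving-average width (samples) for the final
#'   along-bone smoothing
#' @param edge_kernel smaller smoothing kernel used during edge reprocessing
#' @param k number of k-means clusters (fixed at 2)
#' @param max_dist opposite-point search radius for profile sampling
#' @param n_outer,n_inner profile sampling counts outside / across the bone
#' @param each_side samples per side for centerline (edge-reprocess)
#'   profiles
#' @param reprocess_curves which curves to reprocess: `"edges"` (upper and
#'   lower, the default) or `"edges+centerline"`
#' @param seed integer seed controlling k-means initialization
#' @return object of class `bss_config`
#' @export
bss_config <- function(smooth_scale = 1000, margin = 3, var_threshold = 0.95,
                       smooth_kernel = 30, edge_kernel = 10, k = 2,
                       max_dist = 100, n_outer = 10, n_inner = 40,
                       each_side = 10,
                       reprocess_curves = c("edges", "edges+centerline"),
                       seed = 1) {
  if (var_threshold <= 0 || var_threshold > 1) {
    stop("`var_threshold` must be in (0, 1]", call. = FALSE)
  }
  if (margin < 1 || smooth_kernel < 1) {
    stop("`margin` and `smooth_kernel` must be >= 1", call. = FALSE)
  }
  structure(list(
    smooth_scale = smooth_scale, margin = margin,
    var_threshold = var_threshold, smooth_kernel = smooth_kernel,
    edge_kernel = edge_kernel, k = k, max_dist = max_dist,
    n_outer = n_outer, n_inner = n_inner, each_side = each_side,
    reprocess_curves = match.arg(reprocess_curves), seed = as.integer(seed)
  ), class = "bss_config")
}

#' Remove the low-frequency background from a profile image
#'
#' Per column, the background across the profile is the straight line
#' through the means of the `margin` outermost samples at each end
#' (evaluated at the anchor-band centers); the background image is then
#' smoothed along the bone-length axis with a moving window of scale
#' `min(smooth_scale, n_cols)`.  The foreground is the input minus the
#' background, so `foreground + background` reconstructs the input exactly.
#'
#' @param profile a `profile_image` or plain matrix
#' @param config a [bss_config()]
#' @param margin overrides `config$margin` (used by edge reprocessing)
#' @param smooth_scale overrides `config$smooth_scale` (edge reprocessing
#'   keeps the background per-column with only light along-length smoothing)
#' @return list with `foreground` and `background` (plain matrices)
#' @export
filter_background <- function(profile, config = bss_config(), margin = NULL,
                              smooth_scale = NULL) {
  vals <- if (inherits(profile, "profile_image")) profile$values else profile
  m <- if (is.null(margin)) config$margin else margin
  sscale <- if (is.null(smooth_scale)) config$smooth_scale else smooth_scale
  R <- nrow(vals)
  if (R <= 2 * m) stop("profile has too few rows for the margin", call. = FALSE)
  top <- colMeans(vals[seq_len(m), , drop = FALSE])
  bot <- colMeans(vals[(R - m + 1):R, , drop = FALSE])
  p1 <- (1 + m) / 2
  p2 <- R - (m - 1) / 2
  w <- (seq_len(R) - p1) / (p2 - p1)
  background <- outer(1 - w, top) + outer(w, bot)
  kernel <- max(1L, min(as.integer(sscale), ncol(vals)))
  if (kernel > 1) {
    background <- t(apply(background, 1, moving_avg, k = kernel))
  }
  list(foreground = vals - background, background = background)
}

#' Detect and replace corrupted profiles by 2-means clustering
#'
#' Columns of the foreground profile are clustered into two groups with
#' k-means (seeded, `nstart = 10`).  The majority cluster is taken as
#' uncorrupted (ties: the cluster whose centroid is nearer the columnwise
#' median profile); corrupted columns are replaced by the mean uncorrupted
#' column.
#'
#' @param foreground plain matrix or `profile_image` (columns = profiles)
#' @param config a [bss_config()] (supplies the seed)
#' @return list with `cleaned` (matrix) and `labels` (character vector,
#'   `"uncorrupted"` / `"corrupted"`)
#' @export
cluster_profiles <- function(foreground, config = bss_config()) {
  vals <- if (inherits(foreground, "profile_image")) foreground$values else foreground
  n <- ncol(vals)
  if (n < 4) stop("need at least 4 profile columns", call. = FALSE)
  labels <- rep("uncorrupted", n)
  X <- t(vals)
  if (stats::sd(as.vector(vals)) < 1e-12 ||
      nrow(unique(X)) < 2) {
    return(list(cleaned = vals, labels = labels))
  }
  km <- with_seed(config$seed, stats::kmeans(X, centers = 2, nstart = 10))
  sizes <- tabulate(km$cluster, 2)
  if (sizes[1] != sizes[2]) {
    good <- which.max(sizes)
  } else {
    med <- apply(vals, 1, stats::median)
    dmed <- rowSums((km$centers - matrix(med, 2, nrow(vals), byrow = TRUE))^2)
    good <- which.min(dmed)
  }
  bad <- km$cluster != good
  labels[bad] <- "corrupted"
  cleaned <- vals
  if (any(bad)) {
    meancol <- rowMeans(vals[, !bad, drop = FALSE])
    cleaned[, bad] <- meancol
  }
  list(cleaned = cleaned, labels = labels)
}

#' Rank-reduced PCA reconstruction of the bone profile
#'
#' Columns are treated as observations and centered by the mean column.
#' The smallest number `r` of principal components whose cumulative
#' explained variance reaches `var_threshold` is retained, and the bone
#' profile is the mean column plus the rank-`r` reconstruction.  A
#' zero-variance input gives zero retained components and the replicated
#' mean column.
#'
#' @param cleaned matrix of profiles (columns = observations)
#' @param var_threshold cumulative variance fraction in `(0, 1]`
#' @return list with `bone_profile` (matrix), `r` (integer), `explained`
#'   (per-component variance fractions)
#' @export
pca_reconstruct <- function(cleaned, var_threshold = 0.95) {
  vals <- if (inherits(cleaned, "profile_image")) cleaned$values else cleaned
  n <- ncol(vals)
  if (n < 2) stop("need at least 2 columns", call. = FALSE)
  mu <- rowMeans(vals)
  Xc <- vals - mu
  total <- sum(Xc^2)
  if (total < 1e-24) {
    return(list(bone_profile = matrix(mu, nrow(vals), n), r = 0L,
                explained = numeric(0)))
  }
  sv <- svd(Xc)
  explained <- sv$d^2 / sum(sv$d^2)
  r <- which(cumsum(explained) >= var_threshold - 1e-12)[1]
  recon <- sv$u[, seq_len(r), drop = FALSE] %*%
    (sv$d[seq_len(r)] * t(sv$v[, seq_len(r), drop = FALSE]))
  list(bone_profile = recon + mu, r = as.integer(r), explained = explained)
}

#' Moving-average smoothing along the bone-length axis
#'
#' Per row, a moving average of width `kernel` (edge-replicated padding) is
#' applied along axis 2 (the along-bone direction).
#'
#' @param bone_profile matrix or `profile_image`
#' @param kernel moving-average width in samples
#' @return matrix of the same shape
#' @export
smooth_along_length <- function(bone_profile, kernel = 30) {
  vals <- if (inherits(bone_profile, "profile_image")) bone_profile$values else bone_profile
  if (kernel < 1) stop("`kernel` must be >= 1", call. = FALSE)
  if (kernel == 1 || ncol(vals) == 1) return(vals)
  t(apply(vals, 1, moving_avg, k = kernel))
}

# Full profile-domain suppression of one bone: background filtering,
# clustering, PCA, smoothing.  Returns the bone profile plus diagnostics.
suppress_profile <- function(profile, config, margin = NULL, kernel = NULL,
                             smooth_scale = NULL) {
  fb <- filter_background(profile, config, margin = margin,
                          smooth_scale = smooth_scale)
  cl <- cluster_profiles(fb$foreground, config)
  pc <- pca_reconstruct(cl$cleaned, config$var_threshold)
  k <- if (is.null(kernel)) config$smooth_kernel else kernel
  smooth <- smooth_along_length(pc$bone_profile, k)
  list(bone_profile = smooth, background = fb$background,
       foreground = fb$foreground, labels = cl$labels, r = pc$r,
       explained = pc$explained)
}
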