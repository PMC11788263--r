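# Distance-transform regression targets for bone-edge detection, their
# decoding back to binary edges, and the high-pass preprocessing applied to
# network inputs.

#' Encode a binary edge mask as a soft distance-transform image
#'
#' Each pixel holds `exp(-d / |sigma|)` where `d` is the exact Euclidean
#' distance to the nearest positive pixel of the mask.  Values are 1 on the
#' mask and decay towards 0 with distance; smaller `|sigma|` gives less
#' softening.
#'
#' @param mask binary matrix
#' @param sigma softening factor in pixels; must be nonzero
#' @return object of class `dt_image`: list with `values` (matrix in
#'   `[0, 1]`) and `sigma`
#' @export
distance_transform_encode <- function(mask, sigma) {
  assert_binary(mask)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma == 0) {
    stop("`sigma` must be a single nonzero number", call. = FALSE)
  }
  if (!any(mask > 0)) {
    warning("empty mask: distance-transform encoding is all zero")
    values <- matrix(0, nrow(mask), ncol(mask))
  } else {
    d <- sqrt(edt_squared(mask))
    values <- exp(-d / abs(sigma))
  }
  structure(list(values = values, sigma = sigma), class = "dt_image")
}

#' Decode network logits into a binary skeletonized edge mask
#'
#' Binarizes at `threshold` (0.8 by default, matching the fixed decoding
#' threshold used with `sigma = 5`, which yields an approximately
#' 3-pixel-wide band for a straight edge) and thins the result to
#' 1-pixel-wide curves.
#'
#' @param logits numeric matrix (e.g. predicted distance-transform values)
#' @param threshold binarization threshold
#' @return binary matrix
#' @export
edges_from_logits <- function(logits, threshold = 0.8) {
  assert_image(logits)
  thin_skeleton((logits >= threshold) * 1)
}

#' Combine per-category edge masks into one mask
#'
#' The default policy is the pixelwise union (maximum).  A literal
#' `"product"` policy (pixelwise multiplication) is also available; note that
#' for disjoint per-category edge sets the product is empty.
#'
#' @param masks list of binary matrices of equal shape
#' @param policy `"union"` (default) or `"product"`
#' @return binary matrix
#' @export
combine_category_masks <- function(masks, policy = c("union", "product")) {
  policy <- match.arg(policy)
  stopifnot(length(masks) >= 1)
  shp <- dim(masks[[1]])
  for (m in masks) {
    assert_binary(m, "masks")
    if (!identical(dim(m), shp)) stop("mask shapes differ", call. = FALSE)
  }
  out <- masks[[1]]
  for (m in masks[-1]) {
    out <- if (policy == "union") pmax(out, m) else out * m
  }
  out
}

#' Edge-preserving guided filter (self-guided)
#'
#' Standard box-filter implementation of the guided filter with the image as
#' its own guide.  Window means are truncated at the borders.
#'
#' @param image numeric matrix
#' @param window full window width in pixels (>= 3)
#' @param eps regularization factor; larger values push the output towards a
#'   plain box mean.  The default 0.02 is the unit-intensity equivalent of
#'   a regularization of 1e8 on raw 16-bit values (1e8 / 65535^2), which
#'   makes the filter a strong smoother so the residual in
#'   [preprocess_highpass()] is a genuine high-pass
#' @return filtered matrix
#' @export
guided_filter <- function(image, window = 90, eps = 0.02) {
  assert_image(image)
  if (window < 3) stop("`window` must be >= 3", call. = FALSE)
  if (window > min(dim(image))) {
    stop("`window` larger than the image", call. = FALSE)
  }
  if (eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  mu <- box_mean(image, window)
  mu2 <- box_mean(image * image, window)
  var <- pmax(mu2 - mu * mu, 0)
  a <- var / (var + eps)
  b <- mu - a * mu
  abar <- box_mean(a, window)
  bbar <- box_mean(b, window)
  abar * image + bbar
}

#' High-pass preprocessing via the guided filter
#'
#' Returns `image - guided_filter(image, window, eps)`, i.e. the
#' high-frequency residual.  This removes low-frequency content (overall
#' exposure, smooth soft-tissue shading) while retaining thin structures
#' such as bone edges, and is applied to network inputs.
#'
#' @inheritParams guided_filter
#' @return residual matrix (can be negative)
#' @export
preprocess_highpass <- function(image, window = 90, eps = 0.02) {
  image - guided_filter(image, window, eps)
}
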