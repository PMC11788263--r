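# Evaluation metrics: mean boundary distance, Weber contrast / RWC with
# region derivation, RMAE-B, the bone-suppression ratio, and masked
# PSNR/SSIM.

#' Mean boundary distance between two binary edge images
#'
#' `MBD(S, T) = 0.5 * (mean_i d(s_i, T) + mean_j d(t_j, S))` with `d` the
#' minimum Euclidean pixel distance, measured in pixels.  Zero iff the two
#' positive sets are equal.
#'
#' @param S,T binary matrices, both non-empty
#' @return numeric scalar (pixels)
#' @export
mbd <- function(S, T) {
  assert_binary(S); assert_binary(T)
  if (!any(S > 0) || !any(T > 0)) {
    stop("mbd undefined for empty masks", call. = FALSE)
  }
  dT <- sqrt(edt_squared(T))
  dS <- sqrt(edt_squared(S))
  0.5 * (mean(dT[S > 0]) + mean(dS[T > 0]))
}

#' Derive bone and soft-tissue evaluation regions
#'
#' The bone mask is the predicted bone image thresholded at 50% of its
#' maximum; `omega_B` is its 3x3 erosion and `omega_S` is the lung mask
#' minus its 3x3 dilation.
#'
#' @param predicted_bone non-negative matrix
#' @param lung_mask binary matrix
#' @return list with binary `omega_B` and `omega_S`
#' @export
derive_regions <- function(predicted_bone, lung_mask) {
  assert_image(predicted_bone)
  assert_binary(lung_mask)
  mx <- max(predicted_bone)
  if (mx <= 0) stop("all-zero predicted bone image: empty bone region",
                    call. = FALSE)
  bmask <- (predicted_bone >= 0.5 * mx) * 1
  omega_B <- erode3x3(bmask)
  omega_S <- ((lung_mask > 0) & !(dilate3x3(bmask) > 0)) * 1
  if (!any(omega_B > 0)) stop("empty bone region after erosion", call. = FALSE)
  list(omega_B = omega_B, omega_S = omega_S)
}

#' Weber contrast of an image between bone and soft-tissue regions
#'
#' `WC = (Mean(I, omega_B) - Mean(I, omega_S)) / Mean(I, omega_S)`.
#'
#' @param I image matrix
#' @param regions list with `omega_B`, `omega_S` (see [derive_regions()])
#' @return numeric scalar
#' @export
weber_contrast <- function(I, regions) {
  ob <- regions$omega_B > 0; os <- regions$omega_S > 0
  if (!any(ob) || !any(os)) stop("empty evaluation region", call. = FALSE)
  ms <- mean(I[os])
  if (ms == 0) stop("zero soft-tissue mean: Weber contrast undefined",
                    call. = FALSE)
  (mean(I[ob]) - ms) / ms
}

#' Relative Weber contrast of a suppression result
#'
#' `RWC = (WC(I) - WC(I_S)) / WC(I)`: the fraction of bone/soft contrast
#' removed by suppression.  1 is ideal (the predicted soft-tissue image has
#' zero Weber contrast); values above 1 indicate excessive suppression.
#'
#' @param I original image
#' @param I_S predicted soft-tissue image
#' @param regions list with `omega_B`, `omega_S`
#' @return numeric scalar
#' @export
rwc <- function(I, I_S, regions) {
  wc_i <- weber_contrast(I, regions)
  if (wc_i == 0) stop("zero Weber contrast in the original image",
                      call. = FALSE)
  wc_s <- weber_contrast(I_S, regions)
  (wc_i - wc_s) / wc_i
}

#' Relative mean absolute error of the bone image over the bone region
#'
#' Mean absolute difference over `omega_B`, normalized by the intensity
#' range of the true bone image over `omega_B`.  Invariant under a common
#' affine rescaling of both images.
#'
#' @param I_B_true,I_B_pred bone images
#' @param omega_B binary bone-region mask
#' @return numeric scalar (fraction; multiply by 100 for percent)
#' @export
rmae_b <- function(I_B_true, I_B_pred, omega_B) {
  ob <- omega_B > 0
  if (!any(ob)) stop("empty bone region", call. = FALSE)
  rng <- max(I_B_true[ob]) - min(I_B_true[ob])
  if (rng <= 0) stop("zero bone intensity range: RMAE-B undefined",
                     call. = FALSE)
  mean(abs(I_B_true[ob] - I_B_pred[ob])) / rng
}

#' Bone-suppression ratio
#'
#' `BSR = 1 - sum((I_S_pred - I_S_true)^2) / sum(I_B_true^2)` with sums over
#' the bone region.  1 indicates perfect suppression; 0 corresponds to no
#' suppression at all.
#'
#' @param I_S_true,I_S_pred soft-tissue images
#' @param I_B_true true bone image
#' @param omega_B binary bone-region mask
#' @return numeric scalar
#' @export
bsr <- function(I_S_true, I_S_pred, I_B_true, omega_B) {
  ob <- omega_B > 0
  if (!any(ob)) stop("empty bone region", call. = FALSE)
  denom <- sum(I_B_true[ob]^2)
  if (denom <= 0) stop("zero bone energy: BSR undefined", call. = FALSE)
  1 - sum((I_S_pred[ob] - I_S_true[ob])^2) / denom
}

#' Masked PSNR and SSIM of the soft-tissue prediction
#'
#' Both metrics are computed on the tight bounding box of `omega_B`, with
#' predicted pixels outside `omega_B` neutralized to the true values so that
#' only the bone region contributes.  The data range is taken from the true
#' image over the bounding box.  Identical images give `psnr = Inf`.
#'
#' @param I_S_true,I_S_pred soft-tissue images
#' @param omega_B binary bone-region mask
#' @return list with `psnr` (dB) and `ssim`
#' @export
psnr_ssim_s <- function(I_S_true, I_S_pred, omega_B) {
  ob <- omega_B > 0
  if (!any(ob)) stop("empty bone region", call. = FALSE)
  rows <- range(which(rowSums(ob) > 0))
  cols <- range(which(colSums(ob) > 0))
  tt <- I_S_true[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  pp <- I_S_pred[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  mm <- ob[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
  pp[!mm] <- tt[!mm]
  rng <- max(tt) - min(tt)
  if (rng <= 0) rng <- 1
  mse <- mean((tt - pp)^2)
  psnr <- if (mse == 0) Inf else 10 * log10(rng^2 / mse)
  list(psnr = psnr, ssim = ssim_uniform(tt, pp, data_range = rng))
}

# SSIM with a 7x7 uniform window (mean over valid windows), K1/K2 defaults.
ssim_uniform <- function(x, y, data_range, win = 7, K1 = 0.01, K2 = 0.03) {
  if (min(dim(x)) < win) win <- min(dim(x)) - (min(dim(x)) + 1) %% 2
  win <- max(win, 1)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  mu_x <- box_mean(x, win)
  mu_y <- box_mean(y, win)
  xx <- box_mean(x * x, win) - mu_x^2
  yy <- box_mean(y * y, win) - mu_y^2
  xy <- box_mean(x * y, win) - mu_x * mu_y
  s <- ((2 * mu_x * mu_y + C1) * (2 * xy + C2)) /
    ((mu_x^2 + mu_y^2 + C1) * (xx + yy + C2))
  # restrict to windows fully inside the image
  h <- (win - 1) %/% 2
  nr <- nrow(x); nc <- ncol(x)
  if (nr > 2 * h && nc > 2 * h) {
    s <- s[(1 + h):(nr - h), (1 + h):(nc - h), drop = FALSE]
  }
  mean(s)
}

#' Full metrics report for one decomposition
#'
#' Convenience wrapper computing every metric of the package on a predicted
#' decomposition against its ground truth.
#'
#' @param truth list with `cxr`, `bone`, `soft`, `lung_mask` (e.g. a
#'   [generate_phantom()] scene)
#' @param bone_pred,soft_pred predicted bone and soft-tissue images
#' @return list of metric values
#' @export
metrics_report <- function(truth, bone_pred, soft_pred) {
  regions <- derive_regions(bone_pred, truth$lung_mask)
  ps <- psnr_ssim_s(truth$soft, soft_pred, regions$omega_B)
  list(
    rwc = rwc(truth$cxr, soft_pred, regions),
    wc_I = weber_contrast(truth$cxr, regions),
    wc_IS = weber_contrast(soft_pred, regions),
    rmae_b = rmae_b(truth$bone, bone_pred, regions$omega_B),
    bsr = bsr(truth$soft, soft_pred, truth$bone, regions$omega_B),
    psnr_s = ps$psnr, ssim_s = ps$ssim
  )
}
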