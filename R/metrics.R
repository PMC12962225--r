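# Image-quality metrics (SSIM, PSNR, GMSD) and species-leakage percentages.
#
# All metrics operate on magnitude images normalized to the reference's 99th
# percentile, making every metric invariant to a common positive rescaling of
# image and reference.

# separable Gaussian filtering with replicate edges
gauss_kernel <- function(radius = 5L, sigma = 1.5) {
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  g / sum(g)
}

sepconv2 <- function(x, k) {
  r <- (length(k) - 1L) %/% 2L
  n1 <- nrow(x); n2 <- ncol(x)
  pad <- x[c(rep(1L, r), seq_len(n1), rep(n1, r)),
           c(rep(1L, r), seq_len(n2), rep(n2, r))]
  s <- apply(pad, 2L, function(col) stats::filter(col, k, sides = 2L))
  s <- t(apply(s, 1L, function(row) stats::filter(row, k, sides = 2L)))
  s[r + seq_len(n1), r + seq_len(n2)]
}

norm_pair <- function(img, ref) {
  stopifnot(all(dim(img) == dim(ref)))
  img <- Mod(img); ref <- Mod(ref)
  peak <- stats::quantile(ref, 0.99, names = FALSE)
  if (peak <= 0) stop("reference peak must be positive")
  list(img = img / peak, ref = ref / peak)
}

#' Structural similarity index (SSIM)
#'
#' Gaussian-windowed SSIM (11x11 window, sigma 1.5, K1 = 0.01, K2 = 0.03) of
#' the magnitude images, normalized to the reference's 99th percentile, with
#' the filter-support border excluded from pooling.
#'
#' @param img,ref equal-shape images (complex allowed; magnitudes are used).
#' @return scalar in `[-1, 1]`.
#' @export
ssim <- function(img, ref) {
  p <- norm_pair(img, ref)
  x <- p$img; y <- p$ref
  L <- 1
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  g <- gauss_kernel()
  mx <- sepconv2(x, g); my <- sepconv2(y, g)
  sxx <- sepconv2(x * x, g) - mx^2
  syy <- sepconv2(y * y, g) - my^2
  sxy <- sepconv2(x * y, g) - mx * my
  smap <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  r <- 5L
  n1 <- nrow(x); n2 <- ncol(x)
  mean(smap[(r + 1L):(n1 - r), (r + 1L):(n2 - r)])
}

#' Peak signal-to-noise ratio in dB
#'
#' `20*log10(peak(ref) / rmse)` on the normalized magnitudes, capped at 200 dB
#' for identical images.
#' @inheritParams ssim
#' @export
psnr <- function(img, ref) {
  p <- norm_pair(img, ref)
  mse <- mean((p$img - p$ref)^2)
  peak <- max(p$ref)
  if (mse == 0) return(200)
  min(200, 20 * log10(peak / sqrt(mse)))
}

#' Gradient magnitude similarity deviation (GMSD)
#'
#' Prewitt gradient magnitudes after 2x average-downsampling, similarity
#' constant c = 170 on the 0-255 scale (the original formulation); the score
#' is the standard deviation of the gradient-magnitude-similarity map.
#' Lower is better; 0 for identical images.
#' @inheritParams ssim
#' @export
gmsd <- function(img, ref) {
  p <- norm_pair(img, ref)
  x <- 255 * p$img; y <- 255 * p$ref
  down2 <- function(m) {
    n1 <- 2L * (nrow(m) %/% 2L); n2 <- 2L * (ncol(m) %/% 2L)
    m <- m[seq_len(n1), seq_len(n2)]
    0.25 * (m[seq(1, n1, 2), seq(1, n2, 2)] + m[seq(2, n1, 2), seq(1, n2, 2)] +
              m[seq(1, n1, 2), seq(2, n2, 2)] + m[seq(2, n1, 2), seq(2, n2, 2)])
  }
  x <- down2(x); y <- down2(y)
  prewitt <- function(m) {
    hx <- matrix(c(1, 0, -1, 1, 0, -1, 1, 0, -1) / 3, 3, 3)
    conv3 <- function(m, k) {
      n1 <- nrow(m); n2 <- ncol(m)
      pad <- m[c(1L, seq_len(n1), n1), c(1L, seq_len(n2), n2)]
      out <- matrix(0, n1, n2)
      for (i in 1:3) for (j in 1:3) {
        out <- out + k[i, j] * pad[i + seq_len(n1) - 1L, j + seq_len(n2) - 1L]
      }
      out
    }
    gx <- conv3(m, hx); gy <- conv3(m, t(hx))
    sqrt(gx^2 + gy^2)
  }
  gmx <- prewitt(x); gmy <- prewitt(y)
  c0 <- 170
  gms <- (2 * gmx * gmy + c0) / (gmx^2 + gmy^2 + c0)
  stats::sd(gms)
}

#' Water/fat leakage onto the silicone image (percent)
#'
#' Ratio of the mean silicone-image magnitude in the tissue ROI (outside the
#' implant) to that inside the implant ROI, times 100.
#'
#' @param sil_img silicone image.
#' @param roi_wf logical tissue (water/fat) ROI.
#' @param roi_s logical implant ROI; must be disjoint from `roi_wf`.
#' @export
leakage_swfs <- function(sil_img, roi_wf, roi_s) {
  check_rois(roi_wf, roi_s)
  100 * mean(Mod(sil_img[roi_wf])) / mean(Mod(sil_img[roi_s]))
}

#' Silicone-ROI leakage of water relative to silicone (percent)
#' @param w_img water image.
#' @param s_img silicone image.
#' @param roi_s logical implant ROI.
#' @export
leakage_ws <- function(w_img, s_img, roi_s) {
  if (!any(roi_s)) stop("empty ROI")
  100 * mean(Mod(w_img[roi_s])) / mean(Mod(s_img[roi_s]))
}

#' Silicone-ROI leakage of fat relative to silicone (percent)
#' @param f_img fat image.
#' @inheritParams leakage_ws
#' @export
leakage_fs <- function(f_img, s_img, roi_s) {
  leakage_ws(f_img, s_img, roi_s)
}

check_rois <- function(roi_wf, roi_s) {
  if (!any(roi_wf) || !any(roi_s)) stop("empty ROI")
  if (any(roi_wf & roi_s)) stop("ROIs must be disjoint")
  invisible(TRUE)
}

#' Full evaluation report for a species reconstruction
#'
#' @param rec,ref `species_images` (reconstruction and reference).
#' @param roi_implant,roi_tissue logical ROIs (e.g. from the phantom).
#' @return an `eval_report`: per-species ssim/psnr/gmsd and the three leakage
#'   percentages.
#' @export
eval_report <- function(rec, ref, roi_implant, roi_tissue) {
  sp <- c("w", "f", "s")
  out <- list()
  for (k in sp) {
    out[[paste0("ssim_", k)]] <- ssim(Mod(rec[[k]]), Mod(ref[[k]]))
    out[[paste0("psnr_", k)]] <- psnr(Mod(rec[[k]]), Mod(ref[[k]]))
    out[[paste0("gmsd_", k)]] <- gmsd(Mod(rec[[k]]), Mod(ref[[k]]))
  }
  out$leakage_swfs <- leakage_swfs(rec$s, roi_tissue, roi_implant)
  out$leakage_ws <- leakage_ws(rec$w, rec$s, roi_implant)
  out$leakage_fs <- leakage_fs(rec$f, rec$s, roi_implant)
  structure(out, class = "eval_report")
}
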