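# Per-pixel feature stack for trainable segmentation.
#
# Feature engineering targets phase-contrast appearance: the dark textured
# cell body depresses intensity and raises local SD, the bright halo rim
# produces a strong Laplacian-of-Gaussian response, and edges carry high
# gradient magnitude.

# windowed mean over a (2r+1)^2 box via integral images, edge-replicated
box_mean <- function(img, r) {
  H <- nrow(img); W <- ncol(img)
  ri <- pmin(pmax(seq(1 - r, H + r), 1), H)
  ci <- pmin(pmax(seq(1 - r, W + r), 1), W)
  p <- img[ri, ci, drop = FALSE]
  S <- apply(apply(p, 2, cumsum), 1, cumsum)  # transposed integral image
  S <- rbind(0, cbind(0, t(S)))
  n <- 2 * r + 1
  i1 <- seq_len(H); j1 <- seq_len(W)
  (S[i1 + n, j1 + n] - S[i1, j1 + n] - S[i1 + n, j1] + S[i1, j1]) / n^2
}

box_sd <- function(img, r) {
  m <- box_mean(img, r)
  m2 <- box_mean(img^2, r)
  sqrt(pmax(0, m2 - m^2))
}

laplacian4 <- function(img) {
  shift_edge(img, 1, 0) + shift_edge(img, -1, 0) +
    shift_edge(img, 0, 1) + shift_edge(img, 0, -1) - 4 * img
}

#' Extract the per-pixel feature stack used by the pixel classifier
#'
#' @param image 2-D finite intensity matrix.
#' @param scales Box half-widths (pixels) for local mean and SD features.
#' @param log_sigma Gaussian sigma for the Laplacian-of-Gaussian feature
#'   (sensitive to the bright halo rim).
#' @return Array `H x W x n_features` with feature names in
#'   `dimnames(x)[[3]]`. A constant image yields exactly zero contrast
#'   features (no division by zero occurs).
#' @export
extract_features <- function(image, scales = c(2, 5), log_sigma = 2) {
  stopifnot(is.matrix(image))
  check_finite(image, "image")
  H <- nrow(image); W <- ncol(image)
  feats <- list(intensity = image)
  for (s in scales) {
    feats[[sprintf("mean_s%d", s)]] <- box_mean(image, s)
    feats[[sprintf("sd_s%d", s)]] <- box_sd(image, s)
  }
  gx <- (shift_edge(image, 0, -1) - shift_edge(image, 0, 1)) / 2
  gy <- (shift_edge(image, -1, 0) - shift_edge(image, 1, 0)) / 2
  feats$grad_mag <- sqrt(gx^2 + gy^2)
  blurred <- if (min(H, W) > 4 * log_sigma)
    matrix(as.numeric(EBImage::gblur(image, sigma = log_sigma)), H, W)
  else image
  feats$log <- laplacian4(blurred)
  out <- array(unlist(feats, use.names = FALSE), dim = c(H, W, length(feats)),
               dimnames = list(NULL, NULL, names(feats)))
  out
}
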