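#' Peak signal-to-noise ratio
#'
#' `10 * log10(data_range^2 / MSE)` in decibels. Identical images have zero
#' MSE and would be infinite; they are reported as the finite sentinel `cap`
#' so aggregate tables stay numeric.
#'
#' @param a,b Numeric arrays of identical shape.
#' @param data_range Dynamic range of the data (1 for normalized images,
#'   `2^b` for b-bit counts).
#' @param cap Sentinel/ceiling in dB for (near-)identical images (default 100).
#' @return PSNR in dB.
#' @examples
#' psnr(matrix(0.1, 8, 8), matrix(0.2, 8, 8))  # 20 dB
#' @export
psnr <- function(a, b, data_range = 1, cap = 100) {
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical shapes", call. = FALSE)
  }
  if (data_range <= 0) stop("data_range must be positive", call. = FALSE)
  mse <- mean((as.numeric(a) - as.numeric(b))^2)
  if (mse == 0) return(cap)
  min(10 * log10(data_range^2 / mse), cap)
}

# 1-D Gaussian taps matching an 11x11 window: sigma 1.5, radius 5
.ssim_gauss <- function(sigma = 1.5, radius = 5) {
  g <- exp(-(seq(-radius, radius))^2 / (2 * sigma^2))
  g / sum(g)
}

# separable 'valid' convolution with a symmetric 1-D kernel (rows then cols)
.sep_filter_valid <- function(x, g) {
  r <- (length(g) - 1L) %/% 2L
  h <- nrow(x); w <- ncol(x)
  tmp <- matrix(0, h - 2 * r, w)
  for (k in seq_along(g)) {
    tmp <- tmp + g[k] * x[k:(h - 2 * r + k - 1), , drop = FALSE]
  }
  out <- matrix(0, h - 2 * r, w - 2 * r)
  for (k in seq_along(g)) {
    out <- out + g[k] * tmp[, k:(w - 2 * r + k - 1), drop = FALSE]
  }
  out
}

#' Structural similarity index
#'
#' Windowed SSIM with an 11x11 Gaussian weighting window (sigma = 1.5) and
#' the standard stability constants K1 = 0.01, K2 = 0.03; local statistics
#' are Gaussian-weighted population moments and the map is averaged over the
#' region where the full window fits (so boundary handling never enters).
#'
#' @param a,b Numeric matrices of identical shape, at least 11x11.
#' @param data_range Dynamic range (default 1 for normalized images).
#' @param K1,K2 Stability constants.
#' @return Scalar SSIM in \[-1, 1\]; `ssim(x, x)` is 1.
#' @export
ssim <- function(a, b, data_range = 1, K1 = 0.01, K2 = 0.03) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical shapes", call. = FALSE)
  }
  g <- .ssim_gauss()
  if (nrow(a) < length(g) || ncol(a) < length(g)) {
    stop("images smaller than the 11x11 SSIM window", call. = FALSE)
  }
  c1 <- (K1 * data_range)^2
  c2 <- (K2 * data_range)^2
  mu1 <- .sep_filter_valid(a, g)
  mu2 <- .sep_filter_valid(b, g)
  s11 <- .sep_filter_valid(a * a, g) - mu1^2
  s22 <- .sep_filter_valid(b * b, g) - mu2^2
  s12 <- .sep_filter_valid(a * b, g) - mu1 * mu2
  num <- (2 * mu1 * mu2 + c1) * (2 * s12 + c2)
  den <- (mu1^2 + mu2^2 + c1) * (s11 + s22 + c2)
  mean(num / den)
}

#' Convert an angular rate in rad/microsecond to RPM
#'
#' `omega * 1e6 * 60 / (2*pi)`, rounded to the nearest 1000 revolutions per
#' minute -- the resolution at which high-speed rotation measurements from
#' microsecond-interval single-photon sequences are quoted.
#'
#' @param omega Angular rate in rad/us (>= 0).
#' @return Rotational speed in RPM, rounded to the nearest thousand.
#' @examples
#' rad_per_us_to_rpm(0.0107)  # 102000
#' @export
rad_per_us_to_rpm <- function(omega) {
  if (!is.finite(omega) || omega < 0) {
    stop("angular rate must be a non-negative finite number", call. = FALSE)
  }
  round(omega * 1e6 * 60 / (2 * pi) / 1000) * 1000
}

#' Evaluate enhancement quality over a dataset manifest
#'
#' For every pair in a manifest (see [build_dataset()]) the measurement is
#' enhanced -- with the supplied model, or by nearest-neighbour upsampling
#' when `model` is `NULL` (the no-learning baseline) -- and compared to the
#' high-resolution ground truth by PSNR and SSIM. Per-pair rows are returned
#' together with per-condition (bit depth x illumination x scale) means.
#'
#' @param manifest Manifest list or path to a `manifest.json`.
#' @param model A trained `spad_gft` model, or `NULL` for the baseline.
#' @param data_range Dynamic range of the normalized images (default 1).
#' @return List with `pairs` (per-image data.frame) and `summary`
#'   (per-condition mean PSNR/SSIM).
#' @export
evaluate_manifest <- function(manifest, model = NULL, data_range = 1) {
  if (is.character(manifest)) {
    manifest <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  }
  entries <- manifest$pairs
  if (is.null(entries) || length(entries) == 0) {
    stop("manifest contains no pairs", call. = FALSE)
  }
  root <- manifest$root %||% "."
  missing <- character(0)
  for (e in entries) {
    for (f in c(e$hr, e$measurement)) {
      if (!file.exists(file.path(root, f))) missing <- c(missing, f)
    }
  }
  if (length(missing)) {
    stop("missing files: ", paste(unique(missing), collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(entries, function(e) {
    hr <- tiff::readTIFF(file.path(root, e$hr))
    meas <- tiff::readTIFF(file.path(root, e$measurement))  # counts / 2^b
    pred <- if (is.null(model)) {
      upsample_nearest(meas, nrow(hr) / nrow(meas))
    } else {
      enhance(meas, model)
    }
    data.frame(
      scene = e$scene, scale = e$scale, bit_depth = e$bit_depth,
      level = e$level,
      psnr = psnr(pred, hr, data_range = data_range),
      ssim = ssim(pred, hr, data_range = data_range)
    )
  })
  pairs <- do.call(rbind, rows)
  summary <- stats::aggregate(cbind(psnr, ssim) ~ scale + bit_depth + level,
                              data = pairs, FUN = mean)
  list(pairs = pairs, summary = summary)
}

#' Nearest-neighbour upsampling
#'
#' Replicates each pixel into an `s x s` block; the standard no-learning
#' baseline for super-resolution comparisons.
#'
#' @param x Numeric matrix.
#' @param s Positive integer scale.
#' @return Matrix of shape `s * dim(x)`.
#' @export
upsample_nearest <- function(x, s) {
  s <- as.integer(round(s))
  stopifnot(s >= 1)
  x[rep(seq_len(nrow(x)), each = s), rep(seq_len(ncol(x)), each = s),
    drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
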