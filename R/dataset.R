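#' Named illumination-flux multipliers
#'
#' Linear multipliers phi mapping normalized image intensity in \[0,1\] to
#' expected photons per integration window (chi = phi * intensity). The
#' defaults low/mid/high (0.5/1/2) emulate a 2x laser-power ladder such as
#' 10/20/40 mW; no absolute radiometric scale is implied.
#'
#' @param low,mid,high Positive multipliers.
#' @return Named numeric vector of flux levels.
#' @export
flux_levels <- function(low = 0.5, mid = 1, high = 2) {
  lv <- c(low = low, mid = mid, high = high)
  if (any(!is.finite(lv)) || any(lv <= 0)) {
    stop("flux multipliers must be positive", call. = FALSE)
  }
  lv
}

# block-mean (area average) downsampling by integer factor s
.block_mean <- function(m, s) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(h %% s == 0, w %% s == 0)
  # column-major: split rows into (s, h/s), cols into (s, w/s), average blocks
  a <- array(m, c(s, h / s, w))
  a <- colMeans(a)               # (h/s, w)
  a <- array(t(a), c(s, w / s, h / s))
  t(colMeans(a))                 # (h/s, w/s)
}

#' Crop and downsample a clean image into an HR/LR intensity pair
#'
#' Converts to grayscale if needed, crops a `crop_size` square (center, or a
#' seeded uniform-random position), and area-average downsamples by `scale` --
#' the photon-collection analogue of binning detector area, which is why area
#' averaging rather than an interpolating kernel is used.
#'
#' @param image Numeric matrix (or HxWx3 array) with values in \[0,1\].
#' @param crop_size Side of the square crop (default 512).
#' @param scale Integer downsampling factor; must divide `crop_size`.
#' @param crop `"center"` or `"random"`.
#' @param seed Seed for the random crop position.
#' @return List with `hr` (crop_size x crop_size) and `lr_intensity`
#'   (crop_size/scale square), both in \[0,1\].
#' @export
prepare_scene <- function(image, crop_size = 512, scale = 2,
                          crop = c("center", "random"), seed = NULL) {
  crop <- match.arg(crop)
  if (length(dim(image)) == 3L) {
    image <- .LUMA[1] * image[, , 1] + .LUMA[2] * image[, , 2] +
      .LUMA[3] * image[, , 3]
  }
  image <- as.matrix(image)
  h <- nrow(image); w <- ncol(image)
  if (h < crop_size || w < crop_size) {
    stop(sprintf("image %dx%d smaller than crop size %d", h, w, crop_size),
         call. = FALSE)
  }
  if (crop_size %% scale != 0) {
    stop("scale must divide crop_size", call. = FALSE)
  }
  off <- if (crop == "center") {
    c((h - crop_size) %/% 2L, (w - crop_size) %/% 2L)
  } else {
    with_seed(seed, c(sample.int(h - crop_size + 1L, 1L) - 1L,
                      sample.int(w - crop_size + 1L, 1L) - 1L))
  }
  hr <- image[off[1] + seq_len(crop_size), off[2] + seq_len(crop_size)]
  hr <- pmin(pmax(hr, 0), 1)
  list(hr = hr, lr_intensity = .block_mean(hr, scale))
}

#' Map normalized intensity to photon flux
#'
#' Linear, zero-preserving mapping `chi = phi * intensity`, with phi a named
#' illumination level (see [flux_levels()]) or a positive scalar.
#'
#' @param intensity Numeric matrix in \[0,1\].
#' @param level Level name (e.g. "mid") or positive scalar multiplier.
#' @param levels Named vector of multipliers; default [flux_levels()].
#' @return A [spad_flux].
#' @export
intensity_to_flux <- function(intensity, level = "mid",
                              levels = flux_levels()) {
  intensity <- as.matrix(intensity)
  if (any(intensity < 0)) stop("intensity must be non-negative", call. = FALSE)
  phi <- if (is.character(level)) {
    if (!level %in% names(levels)) {
      stop("unknown flux level '", level, "'", call. = FALSE)
    }
    levels[[level]]
  } else {
    as.numeric(level)
  }
  if (!is.finite(phi) || phi <= 0) stop("flux multiplier must be positive",
                                        call. = FALSE)
  spad_flux(phi * intensity)
}

#' Synthesize one paired SPAD measurement / ground-truth scene
#'
#' Full forward chain for one scene: crop and downsample the clean image,
#' map intensity to photon flux at the requested illumination level, simulate
#' `2^bit_depth` one-bit frames through the calibrated multi-source noise
#' model, and accumulate them into the low-bit measurement. Reproducible per
#' seed.
#'
#' @param hr Clean image in \[0,1\] (square, side divisible by `scale`), or a
#'   larger image which is then center-cropped to `crop_size`.
#' @param scale Downsampling factor in {2, 4, 8, 16} (1 allowed for
#'   denoise-only pairs).
#' @param calib A [spad_calibration] whose shape matches the LR size.
#' @param bit_depth Bit depth b; `2^b` subframes are simulated and summed.
#' @param level Illumination level name or scalar phi.
#' @param seed Integer seed.
#' @param crop_size Side of the HR crop (defaults to `nrow(hr)`).
#' @param levels Named flux multipliers.
#' @return A list of class `spad_scene_pair` with fields `hr`, `lr_intensity`,
#'   `flux`, `measurement` ([spad_lowbit]), and the condition tags.
#' @export
synthesize_pair <- function(hr, scale, calib, bit_depth, level = "mid",
                            seed = 1, crop_size = nrow(hr),
                            levels = flux_levels()) {
  stopifnot(inherits(calib, "spad_calibration"))
  sc <- prepare_scene(hr, crop_size = crop_size, scale = scale)
  if (!identical(dim(sc$lr_intensity), as.integer(calib$shape)) &&
      !identical(dim(sc$lr_intensity), calib$shape)) {
    stop(sprintf(
      "calibration shape %s does not match LR size %s",
      paste(calib$shape, collapse = "x"),
      paste(dim(sc$lr_intensity), collapse = "x")
    ), call. = FALSE)
  }
  flux <- intensity_to_flux(sc$lr_intensity, level, levels)
  stack <- simulate_frames(flux, calib, n_frames = 2L^as.integer(bit_depth),
                           seed = seed)
  level_tag <- if (is.character(level)) level else sprintf("phi=%g", level)
  meas <- accumulate_frames(stack, bit_depth, illumination = level_tag)
  structure(
    list(hr = sc$hr, lr_intensity = sc$lr_intensity, flux = flux,
         measurement = meas, scale = as.integer(scale),
         bit_depth = as.integer(bit_depth), level = level_tag,
         seed = as.integer(seed)),
    class = "spad_scene_pair"
  )
}

#' @export
print.spad_scene_pair <- function(x, ...) {
  cat(sprintf(
    "<spad_scene_pair> hr %dx%d, scale %d, %d-bit, level '%s', seed %d\n",
    nrow(x$hr), ncol(x$hr), x$scale, x$bit_depth, x$level, x$seed
  ))
  invisible(x)
}

#' Generate procedural phantom targets
#'
#' Seeded synthetic grayscale targets that stand in for natural-image
#' sources: a smooth oriented gradient background, filled disks, rectangles,
#' resolution-bar groups (triplets of parallel bars of varying width, in the
#' style of a USAF target), and hard edges, with intensities spanning \[0,1\].
#'
#' @param n Number of phantoms (>= 1).
#' @param size Image side in pixels.
#' @param seed Integer seed.
#' @return List of `n` `size x size` matrices in \[0,1\].
#' @export
generate_phantoms <- function(n, size = 512, seed = 1) {
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1", call. = FALSE)
  with_seed(seed, lapply(seq_len(n), function(i) .one_phantom(size)))
}

.one_phantom <- function(size) {
  yy <- matrix(seq(0, 1, length.out = size), size, size)
  xx <- t(yy)
  theta <- runif(1, 0, 2 * pi)
  img <- 0.15 + 0.3 * (cos(theta) * xx + sin(theta) * yy + 1) / 2

  # filled disks, one forced bright and one forced dark for dynamic range
  n_disk <- sample(2:4, 1)
  for (d in seq_len(n_disk)) {
    cy <- runif(1, 0.15, 0.85); cx <- runif(1, 0.15, 0.85)
    rad <- runif(1, 0.06, 0.2)
    val <- if (d == 1) 1 else if (d == 2) 0 else runif(1)
    img[(yy - cy)^2 + (xx - cx)^2 < rad^2] <- val
  }

  # rectangle
  y0 <- sort(sample.int(size, 2)); x0 <- sort(sample.int(size, 2))
  img[y0[1]:y0[2], x0[1]:x0[2]] <-
    0.7 * img[y0[1]:y0[2], x0[1]:x0[2]] + 0.3 * runif(1)

  # bar group: 3 parallel bars of equal width and spacing
  bw <- max(1L, as.integer(round(size * runif(1, 0.01, 0.04))))
  gy <- sample.int(max(1L, size - 6L * bw), 1)
  gx <- sample.int(max(1L, size - 8L * bw), 1)
  horiz <- runif(1) < 0.5
  for (k in 0:2) {
    b0 <- gy + k * 2L * bw
    idx <- b0:min(b0 + bw - 1L, size)
    if (horiz) {
      img[idx, gx:min(gx + 6L * bw, size)] <- 1
    } else {
      img[gx:min(gx + 6L * bw, size), idx] <- 1
    }
  }
  pmin(pmax(img, 0), 1)
}

#' Build a paired low-bit / high-resolution dataset on disk
#'
#' Crosses the scenes with every combination of scale, bit depth and
#' illumination level, synthesizes each measurement through the calibrated
#' noise model, and writes float-TIFF images plus a JSON manifest recording
#' per-pair seeds, conditions and shapes. The build is a pure function of
#' (sources, configuration, seed): re-running with the same inputs produces
#' a byte-identical manifest.
#'
#' @param source List of clean images in \[0,1\], a directory of PNG/TIFF
#'   images, or an integer number of procedural phantoms to generate.
#' @param out_dir Output directory.
#' @param scales,bit_depths,levels Condition grids.
#' @param calib A [spad_calibration] per LR shape, or a function
#'   `function(shape)` returning one; default is an ideal (noise-only-shot)
#'   sensor.
#' @param crop_size HR crop side (default 512).
#' @param seed Master seed; per-pair seeds are derived from it.
#' @param phantom_size Side of generated phantoms when `source` is a count.
#' @return The manifest (invisibly also written to
#'   `file.path(out_dir, "manifest.json")`).
#' @export
build_dataset <- function(source, out_dir, scales = c(2, 4, 8, 16),
                          bit_depths = c(4, 6, 8, 10),
                          levels = c("low", "mid", "high"),
                          calib = NULL, crop_size = 512, seed = 1,
                          phantom_size = crop_size) {
  scenes <- if (is.numeric(source) && length(source) == 1L) {
    generate_phantoms(source, size = phantom_size, seed = seed)
  } else if (is.character(source)) {
    files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    if (!length(files)) stop("no images found in ", source, call. = FALSE)
    lapply(files, read_image)
  } else if (is.list(source)) {
    if (!length(source)) stop("empty source list", call. = FALSE)
    source
  } else {
    stop("source must be a list of images, a directory, or a phantom count",
         call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  grid <- expand.grid(scene = seq_along(scenes), scale = scales,
                      bit_depth = bit_depths, level = levels,
                      stringsAsFactors = FALSE)
  pair_seeds <- with_seed(seed, sample.int(.Machine$integer.max, nrow(grid)))

  get_calib <- function(shape) {
    if (is.null(calib)) {
      spad_calibration(pde = 1, shape = shape)
    } else if (is.function(calib)) {
      calib(shape)
    } else {
      calib
    }
  }

  entries <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    lr_side <- crop_size / g$scale
    pair <- synthesize_pair(
      scenes[[g$scene]], scale = g$scale,
      calib = get_calib(c(lr_side, lr_side)),
      bit_depth = g$bit_depth, level = g$level, seed = pair_seeds[i],
      crop_size = crop_size
    )
    tag <- sprintf("s%03d_x%d_b%02d_%s", g$scene, g$scale, g$bit_depth,
                   g$level)
    hr_file <- paste0(tag, "_hr.tif")
    meas_file <- paste0(tag, "_meas.tif")
    tiff::writeTIFF(pair$hr, file.path(out_dir, hr_file), bits.per.sample = 32)
    tiff::writeTIFF(pair$measurement$counts / pair$measurement$n_subframes,
                    file.path(out_dir, meas_file), bits.per.sample = 32)
    entries[[i]] <- list(
      scene = g$scene, scale = g$scale, bit_depth = g$bit_depth,
      level = g$level, seed = pair_seeds[i],
      hr = hr_file, measurement = meas_file,
      hr_shape = dim(pair$hr), lr_shape = dim(pair$measurement$counts)
    )
  }
  manifest <- list(
    root = out_dir,
    seed = as.integer(seed),
    n_scenes = length(scenes),
    conditions = list(scales = scales, bit_depths = bit_depths,
                      levels = levels, crop_size = crop_size),
    n_pairs = nrow(grid),
    spadkit_version = as.character(utils::packageVersion("spadkit")),
    pairs = entries
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(manifest)
}
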