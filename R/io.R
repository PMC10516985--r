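#' Write a binary frame stack to multi-page TIFF with a JSON sidecar
#'
#' Frames are stored one per TIFF page as 8-bit values (0/1), alongside a
#' `<path>.json` sidecar recording the sensor shape, frame count, timing and
#' seed so the acquisition can be validated and regenerated.
#'
#' @param stack A [spad_stack].
#' @param path Output TIFF path; the sidecar is written to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "spad_stack"))
  pages <- lapply(seq_len(stack$n_frames), function(i) {
    stack$frames[, , i] / 255  # tiff stores round(v * 255): exact for 0/1
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  sidecar <- list(
    sensor_shape = c(stack$height, stack$width),
    n_frames = stack$n_frames,
    timing_ns = if (!is.null(stack$metadata$timing)) {
      unclass(stack$metadata$timing)
    } else NULL,
    seed = stack$metadata$seed,
    neighborhood = stack$metadata$neighborhood,
    spadkit_version = as.character(utils::packageVersion("spadkit"))
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a binary frame stack written by [write_stack()]
#'
#' Performs a lossless round trip: frame order is preserved, values are
#' validated to be strictly 0/1, and the sidecar metadata is checked against
#' the pixel data (mismatches error naming the offending field).
#'
#' @param path TIFF path with an adjacent `<path>.json` sidecar.
#' @return A [spad_stack].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  vals <- round(unlist(pages, use.names = FALSE) * 255)
  if (any(!vals %in% c(0, 1))) {
    stop("stack contains values outside {0, 1}: not a 1-bit acquisition",
         call. = FALSE)
  }
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  frames <- array(0L, c(h, w, length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- as.integer(round(pages[[i]] * 255))
  meta <- list()
  sidecar_path <- paste0(path, ".json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sc$n_frames) && sc$n_frames != length(pages)) {
      stop(sprintf("sidecar field 'n_frames' (%d) does not match TIFF (%d)",
                   sc$n_frames, length(pages)), call. = FALSE)
    }
    if (!is.null(sc$sensor_shape) &&
        !identical(as.integer(sc$sensor_shape), c(h, w))) {
      stop(sprintf("sidecar field 'sensor_shape' (%s) does not match TIFF (%dx%d)",
                   paste(sc$sensor_shape, collapse = "x"), h, w), call. = FALSE)
    }
    meta <- list(
      seed = sc$seed,
      neighborhood = sc$neighborhood,
      timing = if (!is.null(sc$timing_ns)) {
        do.call(spad_timing, as.list(sc$timing_ns))
      } else NULL
    )
  }
  spad_stack(frames, metadata = meta)
}

# Rec. 601 luminance weights for colour -> grayscale conversion
.LUMA <- c(0.299, 0.587, 0.114)

#' Read a grayscale image, normalized to \[0,1\]
#'
#' Reads PNG or TIFF. Colour images are converted by Rec. 601 luminance
#' weights (0.299 R + 0.587 G + 0.114 B); an alpha channel is dropped. The
#' original bit depth (when known) is recorded as attribute `original_depth`.
#'
#' @param path Image path (.png, .tif, .tiff).
#' @return Numeric matrix in \[0,1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path, info = TRUE),
    tif = ,
    tiff = tiff::readTIFF(path, info = TRUE),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  info <- attr(img, "info")
  depth <- if (!is.null(info$bit.depth)) info$bit.depth
           else if (!is.null(info$bits.per.sample)) info$bits.per.sample
           else NA_integer_
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3]
    img <- if (nc >= 3L) {
      .LUMA[1] * img[, , 1] + .LUMA[2] * img[, , 2] + .LUMA[3] * img[, , 3]
    } else {
      img[, , 1]
    }
  }
  img <- pmin(pmax(img, 0), 1)
  attr(img, "original_depth") <- depth
  img
}

#' Write a grayscale image in \[0,1\]
#'
#' PNG is written at 8 bits; TIFF at the requested bit depth (8, 16 or
#' 32-bit float for lossless storage).
#'
#' @param img Numeric matrix in \[0,1\].
#' @param path Output path (.png, .tif, .tiff).
#' @param bits Bits per sample for TIFF output (8, 16 or 32; default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, bits = 16) {
  img <- as.matrix(img)
  if (anyNA(img) || any(img < 0) || any(img > 1)) {
    stop("image values must lie in [0, 1]", call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = bits),
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  invisible(path)
}

#' Write calibration maps as float TIFFs plus a JSON summary
#'
#' One 32-bit float TIFF per map (`pde.tif`, `dcr.tif`, `p_ap.tif`,
#' `p_ct.tif`) and a `calibration.json` summary with the shape, map means and
#' optional acquisition frame count.
#'
#' @param calib A [spad_calibration].
#' @param dir Output directory (created if needed).
#' @param n_total Optional number of dark frames the calibration used.
#' @return `dir`, invisibly.
#' @export
write_calibration <- function(calib, dir, n_total = NULL) {
  stopifnot(inherits(calib, "spad_calibration"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("pde", "dcr", "p_ap", "p_ct")) {
    tiff::writeTIFF(calib[[nm]], file.path(dir, paste0(nm, ".tif")),
                    bits.per.sample = 32)
  }
  jsonlite::write_json(list(
    shape = as.integer(calib$shape),
    means = lapply(calib[c("pde", "dcr", "p_ap", "p_ct")], mean),
    n_total = n_total,
    spadkit_version = as.character(utils::packageVersion("spadkit"))
  ), file.path(dir, "calibration.json"),
  auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read calibration maps written by [write_calibration()]
#'
#' @param dir Directory containing the four map TIFFs.
#' @return A [spad_calibration].
#' @export
read_calibration <- function(dir) {
  maps <- lapply(c("pde", "dcr", "p_ap", "p_ct"), function(nm) {
    f <- file.path(dir, paste0(nm, ".tif"))
    if (!file.exists(f)) stop("missing calibration map: ", f, call. = FALSE)
    tiff::readTIFF(f)
  })
  spad_calibration(pde = maps[[1]], dcr = maps[[2]],
                   p_ap = maps[[3]], p_ct = maps[[4]])
}
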