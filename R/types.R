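#' Latent photon-flux image
#'
#' Wraps a 2-D map of expected incident photons per pixel per integration
#' window (the latent light signal chi). The flux is the Poisson expectation
#' that drives shot noise in the forward simulator; it must be finite and
#' non-negative.
#'
#' @param chi Numeric matrix of expected photon counts per integration window.
#' @return An object of class `spad_flux` with fields `chi`, `height`, `width`.
#' @examples
#' fl <- spad_flux(matrix(0.5, 8, 8))
#' fl$height
#' @export
spad_flux <- function(chi) {
  chi <- as.matrix(chi)
  storage.mode(chi) <- "double"
  if (anyNA(chi) || any(!is.finite(chi))) {
    stop("flux map must be finite and non-missing", call. = FALSE)
  }
  if (any(chi < 0)) {
    stop("flux map must be non-negative", call. = FALSE)
  }
  structure(
    list(chi = chi, height = nrow(chi), width = ncol(chi)),
    class = "spad_flux"
  )
}

#' @export
print.spad_flux <- function(x, ...) {
  cat(sprintf(
    "<spad_flux> %d x %d, chi in [%.4g, %.4g]\n",
    x$height, x$width, min(x$chi), max(x$chi)
  ))
  invisible(x)
}

#' Per-pixel sensor noise-parameter maps
#'
#' Bundles the four per-pixel maps of the multi-source SPAD noise model:
#' photon detection efficiency (PDE, the fixed-pattern response), the dark
#' count expectation per frame (Poisson), the afterpulsing probability
#' (one-frame memory), and the crosstalk trigger probability per firing
#' neighbour. Scalars are recycled to the given `shape`.
#'
#' @param pde PDE map in \[0,1\]; matrix or scalar.
#' @param dcr Dark-count expectation per frame (>= 0); matrix or scalar.
#' @param p_ap Afterpulse probability map in \[0,1\]; matrix or scalar.
#' @param p_ct Crosstalk probability map in \[0,1\]; matrix or scalar.
#' @param shape Integer `c(height, width)`; required when all maps are scalar.
#' @return An object of class `spad_calibration`.
#' @examples
#' cal <- spad_calibration(pde = 1, dcr = 0.005, p_ap = 0.08, p_ct = 0.01,
#'                         shape = c(64, 32))
#' @export
spad_calibration <- function(pde = 1, dcr = 0, p_ap = 0, p_ct = 0,
                             shape = NULL) {
  as_map <- function(m, name) {
    if (is.matrix(m)) {
      storage.mode(m) <- "double"
      return(m)
    }
    if (length(m) != 1L) stop(name, " must be a matrix or scalar", call. = FALSE)
    if (is.null(shape)) stop("shape required when maps are scalar", call. = FALSE)
    matrix(as.double(m), shape[1], shape[2])
  }
  pde <- as_map(pde, "pde"); dcr <- as_map(dcr, "dcr")
  p_ap <- as_map(p_ap, "p_ap"); p_ct <- as_map(p_ct, "p_ct")
  dims <- lapply(list(pde, dcr, p_ap, p_ct), dim)
  if (length(unique(dims)) != 1L) {
    stop("all calibration maps must share one shape", call. = FALSE)
  }
  chk01 <- function(m, name) {
    if (anyNA(m) || any(m < 0) || any(m > 1)) {
      stop(name, " must lie in [0, 1]", call. = FALSE)
    }
  }
  chk01(pde, "pde"); chk01(p_ap, "p_ap"); chk01(p_ct, "p_ct")
  if (anyNA(dcr) || any(dcr < 0)) stop("dcr must be non-negative", call. = FALSE)
  structure(
    list(pde = pde, dcr = dcr, p_ap = p_ap, p_ct = p_ct,
         shape = dim(pde)),
    class = "spad_calibration"
  )
}

#' @export
print.spad_calibration <- function(x, ...) {
  cat(sprintf("<spad_calibration> %d x %d\n", x$shape[1], x$shape[2]))
  cat(sprintf("  pde  mean %.4g   dcr  mean %.4g\n", mean(x$pde), mean(x$dcr)))
  cat(sprintf("  p_ap mean %.4g   p_ct mean %.4g\n", mean(x$p_ap), mean(x$p_ct)))
  invisible(x)
}

#' Acquisition timing configuration
#'
#' Frame timing of the SPAD acquisition, in nanoseconds. The deadtime
#' (quenching) interval is never simulated as an event source; instead
#' [validate_timing()] checks that the frame period leaves room for
#' integration plus deadtime, the condition under which asynchronous
#' deadtime noise can be neglected.
#'
#' @param integration_ns,dead_ns,readout_ns,frame_period_ns Positive durations
#'   in nanoseconds.
#' @return An object of class `spad_timing`.
#' @examples
#' spad_timing(20, 60, 80, 160)
#' @export
spad_timing <- function(integration_ns = 20, dead_ns = 60, readout_ns = 80,
                        frame_period_ns = integration_ns + dead_ns + readout_ns) {
  vals <- c(integration_ns = integration_ns, dead_ns = dead_ns,
            readout_ns = readout_ns, frame_period_ns = frame_period_ns)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all timing durations must be positive and finite", call. = FALSE)
  }
  structure(as.list(vals), class = "spad_timing")
}

#' @export
print.spad_timing <- function(x, ...) {
  cat(sprintf(
    "<spad_timing> integration %g ns, dead %g ns, readout %g ns, period %g ns\n",
    x$integration_ns, x$dead_ns, x$readout_ns, x$frame_period_ns
  ))
  invisible(x)
}

#' Stack of 1-bit single-photon frames
#'
#' An ordered sequence of binary frames I(y, x, n) as produced by a SPAD
#' array (or its simulator): each pixel of each frame is 0 or 1 depending on
#' whether an avalanche was counted during that integration window.
#'
#' @param frames 3-D integer array of 0/1 values with dims
#'   `c(height, width, n_frames)`. A matrix is treated as a single frame.
#' @param metadata Optional named list (sensor id, timing, seed, ...).
#' @return An object of class `spad_stack` with fields `frames`, `n_frames`,
#'   `height`, `width`, `metadata`.
#' @export
spad_stack <- function(frames, metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (length(dim(frames)) != 3L) {
    stop("frames must be a 3-D array [y, x, n]", call. = FALSE)
  }
  storage.mode(frames) <- "integer"
  if (anyNA(frames) || any(frames != 0L & frames != 1L)) {
    stop("frame values must be 0 or 1", call. = FALSE)
  }
  d <- dim(frames)
  if (d[3] < 1L) stop("n_frames must be >= 1", call. = FALSE)
  structure(
    list(frames = frames, height = d[1], width = d[2], n_frames = d[3],
         metadata = metadata),
    class = "spad_stack"
  )
}

#' @export
print.spad_stack <- function(x, ...) {
  cat(sprintf(
    "<spad_stack> %d x %d pixels, %d frames, mean firing rate %.4g\n",
    x$height, x$width, x$n_frames, mean(x$frames)
  ))
  invisible(x)
}

#' Low-bit-depth accumulated image
#'
#' Integer per-pixel counts formed by summing `2^bit_depth` binary subframes,
#' the standard bit-depth accumulation convention for photon-counting arrays
#' (e.g. 1024 subframes give a 10-bit image).
#'
#' @param counts Non-negative integer matrix of accumulated counts.
#' @param bit_depth Integer in 1..16; `n_subframes = 2^bit_depth`.
#' @param illumination Free-form illumination tag (e.g. "low", "mid", "high").
#' @return An object of class `spad_lowbit`.
#' @export
spad_lowbit <- function(counts, bit_depth, illumination = "") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 1L || bit_depth > 16L) {
    stop("bit_depth must be an integer in 1..16", call. = FALSE)
  }
  n_sub <- 2L^bit_depth
  if (anyNA(counts) || any(counts < 0L) || any(counts > n_sub)) {
    stop("counts must lie in [0, 2^bit_depth]", call. = FALSE)
  }
  structure(
    list(counts = counts, bit_depth = bit_depth, n_subframes = n_sub,
         illumination = as.character(illumination)),
    class = "spad_lowbit"
  )
}

#' @export
print.spad_lowbit <- function(x, ...) {
  cat(sprintf(
    "<spad_lowbit> %d x %d, %d-bit (%d subframes), illumination '%s'\n",
    nrow(x$counts), ncol(x$counts), x$bit_depth, x$n_subframes, x$illumination
  ))
  invisible(x)
}

# Run a computation under a fixed seed without disturbing the caller's RNG
# stream. RNG kind pinned so stacks are bit-identical across platforms.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed), kind = "Mersenne-Twister",
             normal.kind = "Inversion", sample.kind = "Rejection")
  }
  force(code)
}
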