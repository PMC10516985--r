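#' Per-pixel detection probability for one integration window
#'
#' Probability that a pixel counts at least one photon during a single
#' integration window, under Poisson photon arrivals with expectation chi and
#' binomial thinning by the photon detection efficiency eta: a SPAD pixel
#' counts at most one photon per window, so
#' `p_det = 1 - exp(-eta * chi)`. The map is monotone nondecreasing in both
#' chi and eta.
#'
#' @param chi A [spad_flux] object (or numeric matrix of non-negative flux).
#' @param calib A [spad_calibration] whose `pde` map supplies eta.
#' @return Numeric matrix of detection probabilities in \[0,1\].
#' @examples
#' fl <- spad_flux(matrix(log(2), 4, 4))
#' cal <- spad_calibration(pde = 1, shape = c(4, 4))
#' detection_probability(fl, cal)[1, 1]  # 0.5
#' @export
detection_probability <- function(chi, calib) {
  if (!inherits(chi, "spad_flux")) chi <- spad_flux(chi)
  stopifnot(inherits(calib, "spad_calibration"))
  if (!identical(dim(chi$chi), dim(calib$pde))) {
    stop("flux and calibration shapes differ (",
         paste(dim(chi$chi), collapse = "x"), " vs ",
         paste(dim(calib$pde), collapse = "x"), ")", call. = FALSE)
  }
  1 - exp(-calib$pde * chi$chi)
}

#' Simulate a stack of 1-bit SPAD frames
#'
#' Forward simulation of the multi-source noise model. Each frame is the OR
#' of, per pixel: a primary event (shot noise thinned by PDE, OR a Poisson
#' dark count), an afterpulse event (Bernoulli `p_ap`, conditioned on the
#' same pixel firing in the previous frame; frame 1 has none), and crosstalk
#' (each firing connected neighbour's primary/afterpulse event independently
#' triggers the pixel with its `p_ct`; single pass, so crosstalk does not
#' chain). The simulation is bit-reproducible for a fixed seed.
#'
#' @param chi A [spad_flux] (or numeric matrix).
#' @param calib A [spad_calibration] with matching shape.
#' @param n_frames Number of frames (>= 1).
#' @param seed Integer seed.
#' @param neighborhood Crosstalk neighbourhood: 4 (default) or 8.
#' @param timing Optional [spad_timing]; validated (warnings surfaced) and
#'   recorded in metadata.
#' @return A [spad_stack].
#' @seealso [simulate_dark_frames()], [accumulate_frames()]
#' @export
simulate_frames <- function(chi, calib, n_frames, seed,
                            neighborhood = 4, timing = NULL) {
  if (!inherits(chi, "spad_flux")) chi <- spad_flux(chi)
  stopifnot(inherits(calib, "spad_calibration"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) {
    stop("n_frames must be >= 1", call. = FALSE)
  }
  if (!identical(dim(chi$chi), calib$shape)) {
    stop("flux and calibration shapes differ", call. = FALSE)
  }
  if (!neighborhood %in% c(4, 8)) {
    stop("neighborhood must be 4 or 8", call. = FALSE)
  }
  if (!is.null(timing)) {
    for (wmsg in validate_timing(timing)) warning(wmsg, call. = FALSE)
  }
  frames <- with_seed(seed, .simulate_frames_cpp(
    chi$chi, calib$pde, calib$dcr, calib$p_ap, calib$p_ct,
    n_frames, as.integer(neighborhood)
  ))
  spad_stack(frames, metadata = list(
    seed = as.integer(seed), neighborhood = as.integer(neighborhood),
    timing = timing, dark = all(chi$chi == 0)
  ))
}

#' Simulate a dark-field acquisition
#'
#' Equivalent to [simulate_frames()] with zero flux: with no illumination the
#' shot and fixed-pattern terms vanish and only dark counts, afterpulsing and
#' crosstalk remain -- the regime used for noise-parameter calibration.
#'
#' @inheritParams simulate_frames
#' @return A [spad_stack].
#' @export
simulate_dark_frames <- function(calib, n_frames, seed,
                                 neighborhood = 4, timing = NULL) {
  stopifnot(inherits(calib, "spad_calibration"))
  zero <- spad_flux(matrix(0, calib$shape[1], calib$shape[2]))
  simulate_frames(zero, calib, n_frames, seed,
                  neighborhood = neighborhood, timing = timing)
}

#' Accumulate binary subframes into a low-bit image
#'
#' Sums the first `2^bit_depth` frames of a stack per pixel, the standard
#' bit-depth convention for photon-counting sensors (e.g. 1024 subframes give
#' a 10-bit image; 16 subframes give 4 bits).
#'
#' @param stack A [spad_stack] with at least `2^bit_depth` frames.
#' @param bit_depth Integer in 1..16.
#' @param illumination Illumination tag recorded on the result.
#' @return A [spad_lowbit].
#' @export
accumulate_frames <- function(stack, bit_depth, illumination = "") {
  stopifnot(inherits(stack, "spad_stack"))
  bit_depth <- as.integer(bit_depth)
  if (is.na(bit_depth) || bit_depth < 1L || bit_depth > 16L) {
    stop("bit_depth must be an integer in 1..16", call. = FALSE)
  }
  need <- 2L^bit_depth
  if (stack$n_frames < need) {
    stop(sprintf(
      "stack has %d frames but bit depth %d requires %d subframes",
      stack$n_frames, bit_depth, need
    ), call. = FALSE)
  }
  counts <- rowSums(stack$frames[, , seq_len(need), drop = FALSE], dims = 2)
  spad_lowbit(counts, bit_depth, illumination)
}

#' Check that deadtime can be neglected for a timing configuration
#'
#' The simulator never generates deadtime events; that is only valid when the
#' frame period accommodates the integration window plus the quenching
#' deadtime, so each pixel has recovered before its next window opens. This
#' check returns warnings (as a character vector) when the assumption is
#' violated, and errors on non-positive durations.
#'
#' @param timing A [spad_timing] (or a numeric vector of four durations in ns:
#'   integration, dead, readout, frame period).
#' @return Character vector of warnings; empty when the configuration is valid.
#' @examples
#' validate_timing(spad_timing(20, 60, 80, 160))  # character(0)
#' @export
validate_timing <- function(timing) {
  if (is.numeric(timing) && length(timing) == 4L) {
    timing <- spad_timing(timing[1], timing[2], timing[3], timing[4])
  }
  stopifnot(inherits(timing, "spad_timing"))
  warnings <- character(0)
  if (timing$frame_period_ns < timing$integration_ns + timing$dead_ns) {
    warnings <- c(warnings, sprintf(
      paste0("frame period (%g ns) is shorter than integration + deadtime ",
             "(%g ns): the zero-deadtime-noise assumption is violated"),
      timing$frame_period_ns, timing$integration_ns + timing$dead_ns
    ))
  }
  warnings
}
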