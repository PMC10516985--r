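#' Classify afterpulse and crosstalk events in a dark stack
#'
#' Labels every fire of a dark acquisition by its most likely noise source.
#' A fire is classified as afterpulsing when the same pixel also fired in the
#' previous frame (consecutive detections at one pixel in darkness are most
#' likely an afterpulse); otherwise it is classified as crosstalk when a
#' connected neighbour fires in the same frame. Afterpulsing takes priority
#' -- a fire that qualifies for both is labelled afterpulse only -- so the two
#' event maps are disjoint. Fires matching neither rule are residual dark
#' counts.
#'
#' The input is assumed to be a dark acquisition (no illumination); this is a
#' documented contract that cannot be checked from the data.
#'
#' @param stack A [spad_stack] with at least 2 frames.
#' @param neighborhood 4 (default) or 8; should match the crosstalk
#'   neighbourhood of the sensor model for self-consistency.
#' @return A list of class `spad_events` with 0/1 arrays `i_ap` and `i_ct`
#'   aligned to `stack$frames`, plus `neighborhood`.
#' @seealso [calibrate_from_dark()]
#' @export
classify_events <- function(stack, neighborhood = 4) {
  stopifnot(inherits(stack, "spad_stack"))
  if (stack$n_frames < 2L) {
    stop("event classification needs at least 2 frames (afterpulse context)",
         call. = FALSE)
  }
  if (!neighborhood %in% c(4, 8)) {
    stop("neighborhood must be 4 or 8", call. = FALSE)
  }
  ev <- .classify_events_cpp(stack$frames, as.integer(neighborhood))
  structure(
    list(i_ap = ev$i_ap, i_ct = ev$i_ct,
         neighborhood = as.integer(neighborhood)),
    class = "spad_events"
  )
}

# shared helper: per-pixel event ratio with 0/0 -> 0 and [0,1] clipping
.event_ratio <- function(num, clean, what) {
  est <- num / clean
  est[clean == 0] <- 0
  if (any(est > 1)) {
    warning(sprintf("%s estimates above 1 at %d pixel(s); clipped",
                    what, sum(est > 1)), call. = FALSE)
    est[est > 1] <- 1
  }
  est
}

.clean_counts <- function(stack, events) {
  rowSums(stack$frames, dims = 2) -
    rowSums(events$i_ap, dims = 2) -
    rowSums(events$i_ct, dims = 2)
}

#' Estimate the per-pixel afterpulsing probability map
#'
#' Ratio of afterpulse-classified fires to residual (clean) fires per pixel:
#' `p_ap(x,y) = sum_n i_ap / sum_n (I_dark - i_ap - i_ct)`. Pixels that never
#' fire cleanly (0/0) are estimated as 0 -- no evidence of the noise source;
#' values above 1 are clipped with a warning. The raw ratio is what the
#' calibration procedure prescribes; `debias = TRUE` additionally subtracts
#' the expected chance-coincidence count (two independent dark fires in
#' consecutive frames) from the numerator.
#'
#' @param stack A [spad_stack] (dark acquisition).
#' @param events Result of [classify_events()] on `stack`.
#' @param debias Subtract the analytic chance-coincidence rate (default FALSE).
#' @return Numeric probability matrix in \[0,1\].
#' @export
estimate_afterpulse_map <- function(stack, events, debias = FALSE) {
  stopifnot(inherits(stack, "spad_stack"), inherits(events, "spad_events"))
  num <- rowSums(events$i_ap, dims = 2)
  clean <- .clean_counts(stack, events)
  if (debias) {
    # chance coincidences: fire rate r per frame gives ~ (n-1) * r^2 expected
    # consecutive pairs from independent events
    r <- rowSums(stack$frames, dims = 2) / stack$n_frames
    num <- pmax(num - (stack$n_frames - 1) * r^2, 0)
  }
  .event_ratio(num, clean, "afterpulse")
}

#' Estimate the per-pixel crosstalk probability map
#'
#' Crosstalk analogue of [estimate_afterpulse_map()]:
#' `p_ct(x,y) = sum_n i_ct / sum_n (I_dark - i_ap - i_ct)`, with the same
#' 0/0 and clipping rules. With `debias = TRUE` the expected same-frame
#' chance coincidences between a pixel and its neighbours (independent fires)
#' are subtracted from the numerator.
#'
#' @inheritParams estimate_afterpulse_map
#' @return Numeric probability matrix in \[0,1\].
#' @export
estimate_crosstalk_map <- function(stack, events, debias = FALSE) {
  stopifnot(inherits(stack, "spad_stack"), inherits(events, "spad_events"))
  num <- rowSums(events$i_ct, dims = 2)
  clean <- .clean_counts(stack, events)
  if (debias) {
    r <- rowSums(stack$frames, dims = 2) / stack$n_frames
    # P(any neighbour fires) from neighbour marginal rates, independence
    p_none <- matrix(1, nrow(r), ncol(r))
    shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
    if (events$neighborhood == 8) {
      shifts <- c(shifts, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
    }
    for (s in shifts) p_none <- p_none * (1 - .shift_map(r, s[1], s[2]))
    num <- pmax(num - stack$n_frames * r * (1 - p_none), 0)
  }
  .event_ratio(num, clean, "crosstalk")
}

# shift a matrix by (dy, dx) with zero padding
.shift_map <- function(m, dy, dx) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  ys <- seq_len(h) + dy; xs <- seq_len(w) + dx
  ok_y <- ys >= 1 & ys <= h; ok_x <- xs >= 1 & xs <= w
  out[ok_y, ok_x] <- m[ys[ok_y], xs[ok_x]]
  out
}

#' Estimate the per-pixel dark-count map
#'
#' Residual fires per frame after removing the classified afterpulse and
#' crosstalk events: `N_dcr(x,y) = sum_n (I_dark - i_ap - i_ct) / n_total`.
#' For the small per-frame rates typical of SPAD dark acquisitions this
#' per-frame firing probability and the Poisson expectation
#' `lambda = -log(1 - p)` are nearly equal.
#'
#' @inheritParams estimate_afterpulse_map
#' @param n_total Total number of acquired frames; must equal
#'   `stack$n_frames` (guards against accumulating over a truncated stack).
#' @return Non-negative numeric matrix of per-frame dark-count rates.
#' @export
estimate_dcr_map <- function(stack, events, n_total = stack$n_frames) {
  stopifnot(inherits(stack, "spad_stack"), inherits(events, "spad_events"))
  if (n_total != stack$n_frames) {
    stop(sprintf("n_total (%d) does not match stack n_frames (%d)",
                 n_total, stack$n_frames), call. = FALSE)
  }
  .clean_counts(stack, events) / n_total
}

#' Calibrate sensor noise parameters from a dark acquisition
#'
#' Full calibration workflow: classify every fire of the dark stack as
#' afterpulse, crosstalk or residual dark count, then form the three
#' per-pixel estimator maps. The PDE map is not observable in darkness and is
#' taken from `pde` (manufacturer data) or defaults to all ones.
#'
#' @param stack A [spad_stack] dark acquisition with >= 2 frames.
#' @param pde Optional PDE map (matrix in \[0,1\]) or scalar; default 1.
#' @param neighborhood Crosstalk neighbourhood, 4 (default) or 8.
#' @param debias Debias the ratio estimators (default FALSE, the raw ratios).
#' @return A [spad_calibration].
#' @examples
#' truth <- spad_calibration(dcr = 0.01, p_ap = 0.05, shape = c(16, 16))
#' dark <- simulate_dark_frames(truth, 2000, seed = 1)
#' est <- calibrate_from_dark(dark)
#' @export
calibrate_from_dark <- function(stack, pde = 1, neighborhood = 4,
                                debias = FALSE) {
  stopifnot(inherits(stack, "spad_stack"))
  events <- classify_events(stack, neighborhood = neighborhood)
  spad_calibration(
    pde = if (is.matrix(pde)) pde else matrix(pde, stack$height, stack$width),
    dcr = estimate_dcr_map(stack, events),
    p_ap = estimate_afterpulse_map(stack, events, debias = debias),
    p_ct = estimate_crosstalk_map(stack, events, debias = debias)
  )
}
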