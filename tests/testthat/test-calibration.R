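test_that("event classification handles the canonical configurations", {
  zero <- spad_stack(array(0L, c(4, 4, 10)))
  ev <- classify_events(zero)
  expect_true(all(ev$i_ap == 0L) && all(ev$i_ct == 0L))

  # isolated pixel firing in two consecutive frames: second fire is afterpulse
  fr <- array(0L, c(5, 5, 6))
  fr[3, 3, 3] <- 1L; fr[3, 3, 4] <- 1L
  ev <- classify_events(spad_stack(fr))
  expect_equal(sum(ev$i_ap), 1L)
  expect_equal(ev$i_ap[3, 3, 4], 1L)
  expect_true(all(ev$i_ct == 0L))

  # two adjacent pixels firing in one frame, no history: both crosstalk
  fr <- array(0L, c(5, 5, 3))
  fr[2, 2, 2] <- 1L; fr[2, 3, 2] <- 1L
  ev <- classify_events(spad_stack(fr))
  expect_true(all(ev$i_ap == 0L))
  expect_equal(ev$i_ct[2, 2, 2], 1L)
  expect_equal(ev$i_ct[2, 3, 2], 1L)
  expect_equal(sum(ev$i_ct), 2L)

  expect_error(classify_events(spad_stack(array(0L, c(4, 4, 1)))), "2 frames")
})

test_that("production classifier agrees exactly with the triple-loop oracle", {
  for (s in 1:30) {
    st <- random_stack(8, 8, 50, p = 0.15, seed = s)
    ev <- classify_events(st)
    or <- classify_oracle(st$frames)
    expect_identical(ev$i_ap, or$i_ap)
    expect_identical(ev$i_ct, or$i_ct)
  }
  # 8-connected neighbourhood variant
  st <- random_stack(8, 8, 50, p = 0.15, seed = 99)
  ev <- classify_events(st, neighborhood = 8)
  or <- classify_oracle(st$frames, neighborhood = 8)
  expect_identical(ev$i_ct, or$i_ct)
})

test_that("event classes are disjoint and fires are conserved", {
  for (s in 1:10) {
    st <- random_stack(6, 6, 80, p = 0.2, seed = 100 + s)
    ev <- classify_events(st)
    expect_true(all(ev$i_ap * ev$i_ct == 0L))
    residual <- st$frames - ev$i_ap - ev$i_ct
    expect_true(all(residual >= 0L))
    expect_equal(sum(st$frames), sum(ev$i_ap) + sum(ev$i_ct) + sum(residual))
  }
})

test_that("afterpulse estimator reproduces the hand-counted ratio", {
  # one pixel: 10 clean fires plus a 3-frame run whose last two fires are
  # afterpulse-classified -> 2 afterpulses over 10 clean fires = 0.2
  fr <- array(0L, c(1, 1, 40))
  fr[1, 1, c(2, 5, 8, 11, 14, 17, 20, 23, 26, 29)] <- 1L
  fr[1, 1, 30] <- 1L; fr[1, 1, 31] <- 1L
  st <- spad_stack(fr)
  ev <- classify_events(st)
  expect_equal(sum(ev$i_ap), 2L)
  expect_equal(estimate_afterpulse_map(st, ev)[1, 1], 0.2)
  # zero events give a zero map
  z <- spad_stack(array(0L, c(3, 3, 5)))
  expect_equal(estimate_afterpulse_map(z, classify_events(z)),
               matrix(0, 3, 3))
})

test_that("crosstalk estimator reproduces the hand-counted ratio", {
  # pixel A: 8 isolated fires plus 2 frames where A and its neighbour B both
  # fire -> 2 crosstalk-classified over 8 clean = 0.25
  fr <- array(0L, c(1, 2, 40))
  fr[1, 1, seq(2, 23, by = 3)] <- 1L               # 8 isolated fires
  fr[1, 1, c(30, 35)] <- 1L; fr[1, 2, c(30, 35)] <- 1L
  st <- spad_stack(fr)
  ev <- classify_events(st)
  expect_equal(estimate_crosstalk_map(st, ev)[1, 1], 0.25)
})

test_that("dark-count estimator is the residual fire rate per frame", {
  fr <- array(0L, c(1, 1, 60000))
  fr[1, 1, seq(100, by = 200, length.out = 300)] <- 1L  # 300 isolated fires
  st <- spad_stack(fr)
  ev <- classify_events(st)
  expect_equal(estimate_dcr_map(st, ev)[1, 1], 0.005)
  expect_error(estimate_dcr_map(st, ev, n_total = 100), "does not match")
})

test_that("dark-count recovery with afterpulse/crosstalk off", {
  lam <- 0.01
  cal <- spad_calibration(dcr = lam, shape = c(32, 16))
  st <- simulate_dark_frames(cal, 20000, seed = 21)
  ev <- classify_events(st)
  est <- calibrate_from_dark(st)
  p <- 1 - exp(-lam)
  se <- sqrt(p * (1 - p) / length(st$frames))
  # conservation: residual + reclassified events restore the raw rate, which
  # is binomial around 1 - exp(-lambda)
  raw <- mean(est$dcr) + (sum(ev$i_ap) + sum(ev$i_ct)) / length(st$frames)
  expect_lt(abs(raw - p), 4 * se)
  # the residual rate itself sits just below p: chance consecutive (~p) and
  # neighbour (~4p) coincidences are classified away from the clean pool
  expect_lt(mean(est$dcr), p)
  expect_gt(mean(est$dcr), (1 - 6 * p) * p)
  # afterpulse/crosstalk estimates floor at the chance-coincidence level
  expect_gt(mean(est$p_ap), 0)
  expect_lt(mean(est$p_ap), 2 * p)
})

test_that("estimator spread shrinks like 1/sqrt(n_frames)", {
  est_at <- function(n) {
    sapply(1:8, function(s) {
      d <- simulate_dark_frames(spad_calibration(dcr = 0.01, shape = c(8, 8)),
                                n, seed = s)
      mean(calibrate_from_dark(d)$dcr)
    })
  }
  ratio <- sd(est_at(2000)) / sd(est_at(8000))
  expect_gt(ratio, 1.3)  # 4x the frames should halve the spread (~ratio 2)
  expect_lt(ratio, 3)
})

test_that("all-zero dark stacks calibrate to a zero-noise sensor", {
  st <- spad_stack(array(0L, c(6, 6, 100)))
  est <- calibrate_from_dark(st)
  expect_equal(est$dcr, matrix(0, 6, 6))
  expect_equal(est$p_ap, matrix(0, 6, 6))
  expect_equal(est$p_ct, matrix(0, 6, 6))
  expect_equal(est$pde, matrix(1, 6, 6))
})
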