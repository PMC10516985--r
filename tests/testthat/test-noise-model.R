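test_that("detection probability follows the thinned-Poisson closed form", {
  cal1 <- spad_calibration(pde = 1, shape = c(4, 4))
  expect_equal(detection_probability(matrix(0, 4, 4), cal1),
               matrix(0, 4, 4))
  expect_equal(detection_probability(matrix(log(2), 4, 4), cal1),
               matrix(0.5, 4, 4))
  cal5 <- spad_calibration(pde = 0.5, shape = c(4, 4))
  expect_equal(detection_probability(matrix(2, 4, 4), cal5),
               matrix(1 - exp(-1), 4, 4), tolerance = 1e-12)
  # monotone in both chi and eta
  p1 <- detection_probability(matrix(0.3, 4, 4), cal5)
  p2 <- detection_probability(matrix(0.6, 4, 4), cal5)
  p3 <- detection_probability(matrix(0.6, 4, 4), cal1)
  expect_true(all(p2 >= p1) && all(p3 >= p2))
})

test_that("detection probability rejects bad inputs", {
  cal <- spad_calibration(pde = 1, shape = c(4, 4))
  expect_error(detection_probability(matrix(0.5, 3, 4), cal), "shape")
  expect_error(spad_flux(matrix(-0.1, 4, 4)), "non-negative")
})

test_that("simulation with all sources off yields an all-zero stack", {
  cal <- spad_calibration(pde = 1, dcr = 0, p_ap = 0.5, p_ct = 0.5,
                          shape = c(8, 8))
  st <- simulate_frames(matrix(0, 8, 8), cal, 50, seed = 1)
  expect_true(all(st$frames == 0L))
  st_dark <- simulate_dark_frames(
    spad_calibration(shape = c(8, 8)), 50, seed = 1)
  expect_true(all(st_dark$frames == 0L))
})

test_that("dark firing rate matches 1 - exp(-lambda) with other sources off", {
  lam <- 0.01
  cal <- spad_calibration(dcr = lam, shape = c(32, 16))
  st <- simulate_dark_frames(cal, 20000, seed = 11)
  p <- 1 - exp(-lam)
  se <- sqrt(p * (1 - p) / length(st$frames))
  expect_lt(abs(mean(st$frames) - p), 4 * se)
})

test_that("simulation is bit-reproducible for a fixed seed", {
  cal <- spad_calibration(dcr = 0.02, p_ap = 0.1, p_ct = 0.05,
                          shape = c(8, 8))
  a <- simulate_dark_frames(cal, 200, seed = 42)
  b <- simulate_dark_frames(cal, 200, seed = 42)
  expect_identical(a$frames, b$frames)
  c_ <- simulate_dark_frames(cal, 200, seed = 43)
  expect_false(identical(a$frames, c_$frames))
})

test_that("afterpulse chains have geometric run lengths (mean 2 at p = 0.5)", {
  cal <- spad_calibration(dcr = 0.002, p_ap = 0.5, shape = c(16, 16))
  st <- simulate_dark_frames(cal, 20000, seed = 9)
  runs <- unlist(lapply(seq_len(16), function(y) {
    lapply(seq_len(16), function(x) {
      r <- rle(st$frames[y, x, ])
      r$lengths[r$values == 1]
    })
  }))
  expect_gt(length(runs), 5000)
  expect_lt(abs(mean(runs) - 2), 0.1)
})

test_that("raising any noise parameter never decreases firing, pointwise", {
  # identical seeds align the uniform draws, so a pointwise-larger parameter
  # set dominates frame by frame, not just in expectation
  lo <- simulate_frames(
    spad_flux(matrix(0.2, 8, 8)),
    spad_calibration(pde = 0.5, dcr = 0.005, p_ap = 0.1, p_ct = 0.02,
                     shape = c(8, 8)),
    500, seed = 5)
  hi <- simulate_frames(
    spad_flux(matrix(0.4, 8, 8)),
    spad_calibration(pde = 0.7, dcr = 0.01, p_ap = 0.2, p_ct = 0.05,
                     shape = c(8, 8)),
    500, seed = 5)
  expect_true(all(hi$frames >= lo$frames))
})

test_that("accumulation sums the first 2^b subframes and is linear", {
  set.seed(3)
  frames <- array(as.integer(runif(4 * 4 * 40) < 0.5), c(4, 4, 40))
  st <- spad_stack(frames)
  acc5 <- accumulate_frames(st, 5)
  expect_equal(acc5$n_subframes, 32L)
  expect_equal(acc5$counts, rowSums(frames[, , 1:32], dims = 2))
  # linearity under a split into two half-stacks
  first <- accumulate_frames(spad_stack(frames[, , 1:16]), 4)
  second <- accumulate_frames(spad_stack(frames[, , 17:32]), 4)
  expect_equal(acc5$counts, first$counts + second$counts)

  ones <- spad_stack(array(1L, c(3, 3, 16)))
  expect_true(all(accumulate_frames(ones, 4)$counts == 16L))
  alt <- spad_stack(array(rep(c(0L, 1L), each = 9), c(3, 3, 16)))
  expect_true(all(accumulate_frames(alt, 4)$counts == 8L))

  expect_error(accumulate_frames(st, 10), "1024")
})

test_that("ten-bit accumulation consumes 1024 subframes", {
  st <- spad_stack(array(0L, c(2, 2, 1024)))
  expect_equal(accumulate_frames(st, 10)$n_subframes, 1024L)
  expect_error(accumulate_frames(spad_stack(array(0L, c(2, 2, 1023))), 10),
               "1024")
})

test_that("timing validation enforces the zero-deadtime assumption", {
  expect_length(validate_timing(spad_timing(20, 60, 80, 160)), 0)
  w <- validate_timing(spad_timing(20, 60, 80, 50))
  expect_length(w, 1)
  expect_match(w, "deadtime")
  expect_error(spad_timing(0, 60, 80, 160), "positive")
  expect_length(validate_timing(c(20, 60, 80, 160)), 0)
})
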