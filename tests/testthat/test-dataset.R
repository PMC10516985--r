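test_that("scene preparation crops, converts and area-averages correctly", {
  const <- matrix(0.3, 64, 64)
  sc <- prepare_scene(const, crop_size = 32, scale = 4)
  expect_equal(dim(sc$hr), c(32L, 32L))
  expect_equal(dim(sc$lr_intensity), c(8L, 8L))
  expect_true(all(sc$hr == 0.3) && all(abs(sc$lr_intensity - 0.3) < 1e-12))

  # 1-pixel checkerboard averages to uniform 0.5 at scale 2
  cb <- checkerboard(32)
  sc <- prepare_scene(cb, crop_size = 32, scale = 2)
  expect_equal(sc$lr_intensity, matrix(0.5, 16, 16))

  # 512 -> scale 16 gives 32x32
  big <- matrix(runif(512 * 512), 512, 512)
  sc <- prepare_scene(big, crop_size = 512, scale = 16)
  expect_equal(dim(sc$lr_intensity), c(32L, 32L))

  expect_error(prepare_scene(matrix(0, 100, 100), crop_size = 512, scale = 2),
               "smaller than")
  # colour conversion uses the documented luminance weights
  col <- array(0, c(32, 32, 3)); col[, , 1] <- 1
  sc <- prepare_scene(col, crop_size = 32, scale = 2)
  expect_equal(sc$hr[1, 1], 0.299, tolerance = 1e-12)
})

test_that("intensity-to-flux mapping is linear and zero-preserving", {
  z <- intensity_to_flux(matrix(0, 4, 4), "mid")
  expect_true(all(z$chi == 0))
  one <- intensity_to_flux(matrix(1, 4, 4), 1)
  expect_true(all(one$chi == 1))
  a <- intensity_to_flux(matrix(0.3, 4, 4), 1)$chi
  b <- intensity_to_flux(matrix(0.3, 4, 4), 2)$chi
  expect_equal(b, 2 * a)
  expect_error(intensity_to_flux(matrix(-0.1, 4, 4), 1), "non-negative")
  expect_error(intensity_to_flux(matrix(0.5, 4, 4), "blinding"), "unknown")
})

test_that("pair synthesis is reproducible and tracks the latent intensity", {
  ph <- generate_phantoms(1, size = 64, seed = 3)[[1]]
  calib0 <- spad_calibration(pde = 1, shape = c(32, 32))
  a <- synthesize_pair(ph, 2, calib0, 10, "mid", seed = 4)
  b <- synthesize_pair(ph, 2, calib0, 10, "mid", seed = 4)
  expect_identical(a$measurement$counts, b$measurement$counts)
  expect_equal(a$measurement$n_subframes, 1024L)
  # noise-free sensor: normalized counts follow the scene intensity
  r <- cor(as.vector(a$measurement$counts / 1024),
           as.vector(a$lr_intensity))
  expect_gt(r, 0.95)
  # 4-bit pair consumes 16 subframes
  c4 <- synthesize_pair(ph, 4, spad_calibration(pde = 1, shape = c(16, 16)),
                        4, "mid", seed = 5)
  expect_equal(c4$measurement$n_subframes, 16L)
  expect_equal(dim(c4$measurement$counts), c(16L, 16L))
})

test_that("phantoms are seeded, bounded and span the dynamic range", {
  a <- generate_phantoms(4, size = 64, seed = 2)
  b <- generate_phantoms(4, size = 64, seed = 2)
  expect_identical(a, b)
  v <- unlist(a)
  expect_true(all(v >= 0 & v <= 1))
  expect_gt(diff(range(v)), 0.8)
  expect_error(generate_phantoms(0), ">= 1")
})

test_that("dataset build crosses all conditions and is deterministic", {
  out <- file.path(tempdir(), "spadkit-ds")
  unlink(out, recursive = TRUE)
  m <- build_dataset(2, out_dir = out, scales = c(2, 4), bit_depths = c(4, 6),
                     levels = c("low", "high"), crop_size = 32, seed = 7,
                     phantom_size = 32)
  expect_equal(m$n_pairs, 2 * 2 * 2 * 2)
  expect_length(m$pairs, 16)
  for (e in m$pairs) {
    expect_equal(unlist(e$hr_shape), unlist(e$lr_shape) * e$scale)
    expect_true(file.exists(file.path(out, e$hr)))
    expect_true(file.exists(file.path(out, e$measurement)))
  }
  md5_first <- tools::md5sum(file.path(out, "manifest.json"))
  unlink(out, recursive = TRUE)
  build_dataset(2, out_dir = out, scales = c(2, 4), bit_depths = c(4, 6),
                levels = c("low", "high"), crop_size = 32, seed = 7,
                phantom_size = 32)
  expect_identical(unname(tools::md5sum(file.path(out, "manifest.json"))),
                   unname(md5_first))
  expect_error(build_dataset(list(), out_dir = out), "empty")
})

test_that("dark regions of synthesized stacks re-calibrate to the sensor", {
  # closed loop at unit-test scale: a half-dark scene, simulated through a
  # noisy sensor; the dark columns re-fed to calibration recover the
  # dark-count rate
  lam <- 0.01
  truth <- spad_calibration(pde = 1, dcr = lam, shape = c(16, 16))
  img <- matrix(0, 32, 32); img[, 17:32] <- 0.8
  sc <- prepare_scene(img, crop_size = 32, scale = 2)
  flux <- intensity_to_flux(sc$lr_intensity, "mid")
  st <- simulate_frames(flux, truth, 8000, seed = 31)
  dark_part <- spad_stack(st$frames[, 1:7, , drop = FALSE])
  est <- calibrate_from_dark(dark_part)
  expect_lt(abs(mean(est$dcr) - (1 - exp(-lam))) / (1 - exp(-lam)), 0.15)
})
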