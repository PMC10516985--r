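# Naive reference implementations and fixture builders used as independent
# oracles against the production code paths.

# triple-loop event classifier: afterpulse = consecutive fire at one pixel;
# crosstalk = same-frame firing neighbour, afterpulse takes priority
classify_oracle <- function(frames, neighborhood = 4) {
  d <- dim(frames)
  i_ap <- array(0L, d)
  i_ct <- array(0L, d)
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (neighborhood == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  for (n in seq_len(d[3])) {
    for (x in seq_len(d[2])) {
      for (y in seq_len(d[1])) {
        if (frames[y, x, n] == 0L) next
        if (n > 1L && frames[y, x, n - 1L] == 1L) {
          i_ap[y, x, n] <- 1L
          next
        }
        for (o in offs) {
          yy <- y + o[1]; xx <- x + o[2]
          if (yy >= 1 && yy <= d[1] && xx >= 1 && xx <= d[2] &&
              frames[yy, xx, n] == 1L) {
            i_ct[y, x, n] <- 1L
            break
          }
        }
      }
    }
  }
  list(i_ap = i_ap, i_ct = i_ct)
}

random_stack <- function(h, w, n, p = 0.1, seed = 1) {
  set.seed(seed)
  spad_stack(array(as.integer(runif(h * w * n) < p), c(h, w, n)))
}

# 1-pixel-check checkerboard (repeating 2x2 cell)
checkerboard <- function(side) {
  outer(seq_len(side), seq_len(side), function(i, j) (i + j) %% 2)
}

# small toy training set: clean low-noise pairs through the forward model
toy_pairs <- function(n_scenes = 8, lr_side = 16, scale = 2, bit_depth = 10,
                      level = "high", seed = 5) {
  hr_side <- lr_side * scale
  ph <- generate_phantoms(n_scenes, size = hr_side, seed = seed)
  calib0 <- spad_calibration(pde = 1, shape = c(lr_side, lr_side))
  lapply(seq_along(ph), function(i) {
    pr <- synthesize_pair(ph[[i]], scale = scale, calib = calib0,
                          bit_depth = bit_depth, level = level,
                          seed = 100 + i)
    list(input = pr$measurement$counts / pr$measurement$n_subframes,
         target = pr$hr)
  })
}

# finite-difference gradient of a scalar-valued function of an array
numeric_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a
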