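#' Fixed random convolutional perceptual feature extractor
#'
#' A small frozen feature map phi(.) for the perceptual loss term: two 3x3
#' convolution + GELU stages around a 2x2 average pooling, with fixed
#' seeded He-initialized weights. Random fixed convolutional features are a
#' self-contained stand-in for a pretrained feature stack: they measure
#' multi-frequency similarity in a nonlinear feature space without requiring
#' any external weights. Any function mapping an (N,H,W,1) node to a feature
#' node can be plugged in instead (e.g. an adapter around pretrained VGG19
#' pool-3 features, when available).
#'
#' @param channels Feature channels of the two stages.
#' @param seed Seed fixing the weights.
#' @return A function `phi(node) -> node` with frozen weights.
#' @export
perceptual_extractor <- function(channels = c(8, 8), seed = 17) {
  w <- with_seed(seed, list(
    w1 = array(rnorm(3 * 3 * 1 * channels[1], sd = sqrt(2 / 9)),
               c(3, 3, 1, channels[1])),
    w2 = array(rnorm(3 * 3 * channels[1] * channels[2],
                     sd = sqrt(2 / (9 * channels[1]))),
               c(3, 3, channels[1], channels[2]))
  ))
  w1 <- ag_const(w$w1)
  w2 <- ag_const(w$w2)
  function(x) {
    y <- ag_gelu(ag_conv2d(x, w1, pad = "same"))
    d <- dim(y$value)
    if (d[2] %% 2 == 0 && d[3] %% 2 == 0) y <- ag_avgpool2(y)
    ag_gelu(ag_conv2d(y, w2, pad = "same"))
  }
}

#' Hybrid loss configuration
#'
#' Weights of the three training loss terms: `alpha` for the mean absolute
#' (L1) error, `beta` for the perceptual feature distance, `gamma` for the
#' structural term `1 - SSIM`. Defaults alpha = 0.1, beta = 10, gamma = 100.
#'
#' @param alpha,beta,gamma Non-negative weights; at least one positive.
#' @param perceptual Feature extractor `phi` (see [perceptual_extractor()]),
#'   or `NULL`. Required when `beta > 0`.
#' @return A `spad_loss_config`.
#' @export
loss_config <- function(alpha = 0.1, beta = 10, gamma = 100,
                        perceptual = if (beta > 0) perceptual_extractor()) {
  if (any(c(alpha, beta, gamma) < 0)) {
    stop("loss weights must be non-negative", call. = FALSE)
  }
  if (alpha == 0 && beta == 0 && gamma == 0) {
    stop("at least one loss weight must be positive", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 perceptual = perceptual),
            class = "spad_loss_config")
}

# differentiable SSIM on (N,H,W,1) nodes; same 11x11 Gaussian window,
# constants and valid-region averaging as the ssim() metric
.ssim_node <- function(x, y, data_range = 1, K1 = 0.01, K2 = 0.03) {
  g <- .ssim_gauss()
  kern <- ag_const(array(outer(g, g), c(length(g), length(g), 1, 1)))
  d <- dim(x$value)
  if (d[2] < length(g) || d[3] < length(g)) {
    stop("images smaller than the 11x11 SSIM window", call. = FALSE)
  }
  c1 <- (K1 * data_range)^2
  c2 <- (K2 * data_range)^2
  f <- function(z) ag_conv2d(z, kern, pad = "valid")
  mu1 <- f(x); mu2 <- f(y)
  s11 <- ag_sub(f(ag_mul(x, x)), ag_mul(mu1, mu1))
  s22 <- ag_sub(f(ag_mul(y, y)), ag_mul(mu2, mu2))
  s12 <- ag_sub(f(ag_mul(x, y)), ag_mul(mu1, mu2))
  num <- ag_mul(ag_sadd(ag_smul(ag_mul(mu1, mu2), 2), c1),
                ag_sadd(ag_smul(s12, 2), c2))
  den <- ag_mul(ag_sadd(ag_add(ag_mul(mu1, mu1), ag_mul(mu2, mu2)), c1),
                ag_sadd(ag_add(s11, s22), c2))
  ag_mean(ag_div(num, den))
}

# loss graph on nodes; returns list(total, l1, per, ssim_term) of nodes
.hybrid_loss_nodes <- function(pred, gt, config) {
  terms <- list()
  total <- NULL
  add_term <- function(total, w, term) {
    if (is.null(total)) ag_smul(term, w) else ag_add(total, ag_smul(term, w))
  }
  l1 <- ag_mean(ag_abs(ag_sub(pred, gt)))
  terms$l1 <- l1
  if (config$alpha > 0) total <- add_term(total, config$alpha, l1)
  if (config$beta > 0) {
    if (is.null(config$perceptual)) {
      stop("beta > 0 requires a perceptual extractor", call. = FALSE)
    }
    dphi <- ag_sub(config$perceptual(pred), config$perceptual(gt))
    per <- ag_sqrt(ag_mean(ag_sq(dphi)))
    terms$per <- per
    total <- add_term(total, config$beta, per)
  } else {
    terms$per <- ag_const(0)
  }
  if (config$gamma > 0) {
    st <- ag_sub(ag_const(1), .ssim_node(pred, gt))
    terms$ssim_term <- st
    total <- add_term(total, config$gamma, st)
  } else {
    terms$ssim_term <- ag_const(0)
  }
  c(list(total = total), terms)
}

#' Hybrid L1 / perceptual / SSIM training loss
#'
#' `alpha * mean|I_R - I_G| + beta * ||phi(I_R) - phi(I_G)||_2 +
#' gamma * (1 - SSIM(I_R, I_G))`, the weighted combination of pixel-wise,
#' feature-space and structural similarity. The perceptual distance is the
#' root-mean-square feature difference; the SSIM term uses the same 11x11
#' Gaussian window as [ssim()]. Zero exactly when the images are identical.
#'
#' @param pred,gt Numeric matrices or (N,H,W,1) arrays of identical shape.
#' @param config A [loss_config()].
#' @return Scalar loss, with attribute `terms` giving the three unweighted
#'   components.
#' @export
hybrid_loss <- function(pred, gt, config = loss_config()) {
  stopifnot(inherits(config, "spad_loss_config"))
  pa <- .as_nhwc(.norm_input(pred))
  ga <- .as_nhwc(.norm_input(gt))
  if (!identical(dim(pa), dim(ga))) {
    stop("prediction and ground truth shapes differ", call. = FALSE)
  }
  res <- .hybrid_loss_nodes(ag_const(pa), ag_const(ga), config)
  structure(res$total$value,
            terms = c(l1 = res$l1$value, perceptual = res$per$value,
                      ssim = res$ssim_term$value))
}

.norm_input <- function(x) {
  if (inherits(x, "spad_lowbit")) x$counts / x$n_subframes else x
}
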