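#' Gated-fusion transformer configuration
#'
#' Architecture of the enhancement network: a shallow convolutional feature
#' extractor, `n_blocks` densely connected window-attention blocks (each
#' `layers_per_block` attention layers, with the window shifted by half its
#' size on alternate layers), a gated fusion layer combining all block
#' outputs with learnable scalar weights, and a sub-pixel-convolution
#' reconstruction head upscaling by `sr_scale`.
#'
#' The defaults are deliberately small so the network trains on a CPU; widths
#' and depths scale up transparently.
#'
#' @param embed_dim Feature channels c.
#' @param n_blocks Number of dense attention blocks n.
#' @param layers_per_block Attention layers per block.
#' @param window_size Attention window side (input sides must be divisible
#'   by it).
#' @param n_heads Attention heads (must divide `embed_dim`).
#' @param mlp_ratio Expansion factor of the per-token MLP.
#' @param sr_scale Super-resolution scale s, one of 1, 2, 4.
#' @param in_channels Input image channels (1 for SPAD counts).
#' @return A `spad_net_config` list.
#' @export
network_config <- function(embed_dim = 16, n_blocks = 2, layers_per_block = 2,
                           window_size = 4, n_heads = 2, mlp_ratio = 2,
                           sr_scale = 2, in_channels = 1) {
  if (!sr_scale %in% c(1, 2, 4)) {
    stop("sr_scale must be 1, 2 or 4", call. = FALSE)
  }
  if (embed_dim %% n_heads != 0) {
    stop("embed_dim must be divisible by n_heads", call. = FALSE)
  }
  structure(list(
    embed_dim = as.integer(embed_dim), n_blocks = as.integer(n_blocks),
    layers_per_block = as.integer(layers_per_block),
    window_size = as.integer(window_size), n_heads = as.integer(n_heads),
    mlp_ratio = mlp_ratio, sr_scale = as.integer(sr_scale),
    in_channels = as.integer(in_channels)
  ), class = "spad_net_config")
}

# parameter initializers
.init_conv <- function(kh, kw, cin, cout) {
  ag_param(array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
                 c(kh, kw, cin, cout)))
}
.init_lin <- function(cin, cout, sd = 0.02) {
  ag_param(matrix(rnorm(cin * cout, sd = sd), cin, cout))
}
.init_vec <- function(n, val = 0) ag_param(rep(val, n))

#' Initialize a gated-fusion transformer model
#'
#' Builds all trainable parameters (seeded): convolution kernels with He
#' initialization, attention/MLP weights with truncated-normal-scale sd 0.02,
#' unit layer-norm gains, and gate weights initialized to `1/n_blocks` so
#' every block contributes equally before training.
#'
#' @param config A [network_config()].
#' @param seed Integer seed for the initialization.
#' @return A `spad_gft` model: list of `config`, `params` (named parameter
#'   nodes), `state` (batch-norm running statistics, mask cache), `log`.
#' @export
gft_init <- function(config, seed = 1) {
  stopifnot(inherits(config, "spad_net_config"))
  cfg <- config
  c_ <- cfg$embed_dim
  params <- with_seed(seed, {
    p <- list(
      fe_conv_w = .init_conv(3, 3, cfg$in_channels, c_),
      fe_conv_b = .init_vec(c_),
      fe_bn_gamma = .init_vec(c_, 1),
      fe_bn_beta = .init_vec(c_)
    )
    for (i in seq_len(cfg$n_blocks)) {
      pre <- sprintf("blk%d_", i)
      p[[paste0(pre, "proj_w")]] <- .init_conv(1, 1, i * c_, c_)
      p[[paste0(pre, "proj_b")]] <- .init_vec(c_)
      for (l in seq_len(cfg$layers_per_block)) {
        lp <- sprintf("%sstl%d_", pre, l)
        p[[paste0(lp, "ln1_g")]] <- .init_vec(c_, 1)
        p[[paste0(lp, "ln1_b")]] <- .init_vec(c_)
        p[[paste0(lp, "qkv_w")]] <- .init_lin(c_, 3 * c_)
        p[[paste0(lp, "qkv_b")]] <- .init_vec(3 * c_)
        p[[paste0(lp, "proj_w")]] <- .init_lin(c_, c_)
        p[[paste0(lp, "proj_b")]] <- .init_vec(c_)
        p[[paste0(lp, "ln2_g")]] <- .init_vec(c_, 1)
        p[[paste0(lp, "ln2_b")]] <- .init_vec(c_)
        hidden <- round(cfg$mlp_ratio * c_)
        p[[paste0(lp, "mlp1_w")]] <- .init_lin(c_, hidden)
        p[[paste0(lp, "mlp1_b")]] <- .init_vec(hidden)
        p[[paste0(lp, "mlp2_w")]] <- .init_lin(hidden, c_)
        p[[paste0(lp, "mlp2_b")]] <- .init_vec(c_)
      }
    }
    p$gates <- ag_param(rep(1 / cfg$n_blocks, cfg$n_blocks))
    p$rec_conv1_w <- .init_conv(3, 3, c_, c_)
    p$rec_conv1_b <- .init_vec(c_)
    p$rec_up_w <- .init_conv(3, 3, c_, cfg$in_channels * cfg$sr_scale^2)
    p$rec_up_b <- .init_vec(cfg$in_channels * cfg$sr_scale^2)
    # output head starts near mid-gray with low variance, so optimization
    # begins in the image range rather than an arbitrary offset
    p$rec_out_w <- ag_param(array(
      rnorm(9 * cfg$in_channels^2, sd = 0.1 * sqrt(2 / (9 * cfg$in_channels))),
      c(3, 3, cfg$in_channels, cfg$in_channels)))
    p$rec_out_b <- .init_vec(cfg$in_channels, 0.5)
    p
  })
  state <- new.env(parent = emptyenv())
  state$running_mean <- rep(0, c_)
  state$running_var <- rep(1, c_)
  state$mask_cache <- list()
  structure(list(config = cfg, params = params, state = state,
                 log = NULL, seed = as.integer(seed)),
            class = "spad_gft")
}

#' @export
print.spad_gft <- function(x, ...) {
  n_par <- sum(vapply(x$params, function(p) length(p$value), numeric(1)))
  cat(sprintf(
    "<spad_gft> c=%d, %d blocks x %d layers, window %d, heads %d, scale x%d (%d parameters)\n",
    x$config$embed_dim, x$config$n_blocks, x$config$layers_per_block,
    x$config$window_size, x$config$n_heads, x$config$sr_scale, n_par
  ))
  if (!is.null(x$log)) {
    cat(sprintf("  trained %d steps, final loss %.4g\n",
                nrow(x$log), x$log$loss[nrow(x$log)]))
  }
  invisible(x)
}

## ---- window partition helpers ---------------------------------------------

# (N,H,W,C) -> (N*gh*gw, win^2, C); batch index runs image-fastest, then
# window row, then window column; token index runs window-row-fastest
.win_partition <- function(x, win) {
  d <- dim(x$value)
  gh <- d[2] / win; gw <- d[3] / win
  y <- ag_reshape(x, c(d[1], win, gh, win, gw, d[4]))
  y <- ag_aperm(y, c(1, 3, 5, 2, 4, 6))
  ag_reshape(y, c(d[1] * gh * gw, win * win, d[4]))
}

.win_merge <- function(x, win, N, H, W) {
  gh <- H / win; gw <- W / win
  C <- dim(x$value)[3]
  y <- ag_reshape(x, c(N, gh, gw, win, win, C))
  y <- ag_aperm(y, c(1, 4, 2, 5, 3, 6))
  ag_reshape(y, c(N, H, W, C))
}

# Attention mask for shifted windows: region ids are assigned on the
# unshifted grid with the canonical three slices per axis; windows of the id
# map (partitioned without rolling) then reproduce the contiguity structure
# of the rolled feature windows, and tokens from different original regions
# are barred from attending by a large negative bias.
.swin_mask <- function(H, W, win, shift) {
  reg <- function(n) {
    r <- integer(n)
    r[seq_len(n - win)] <- 0L
    r[(n - win + 1):(n - shift)] <- 1L
    r[(n - shift + 1):n] <- 2L
    r
  }
  ids <- outer(reg(H), reg(W), function(a, b) 3L * a + b)
  gh <- H / win; gw <- W / win
  a <- array(ids, c(win, gh, win, gw))
  a <- aperm(a, c(2, 4, 1, 3))          # (gh, gw, wr, wc)
  idw <- matrix(a, gh * gw, win * win)  # windows x tokens (gh fastest)
  t_ <- win * win
  mask <- array(0, c(gh * gw, t_, t_))
  for (k in seq_len(gh * gw)) {
    same <- outer(idw[k, ], idw[k, ], "==")
    mask[k, , ][!same] <- -1e4
  }
  mask
}

# one Swin-style attention layer on a feature map node (N,H,W,C)
.stl_forward <- function(x, p, lp, cfg, state, shift) {
  d <- dim(x$value)
  N <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  win <- cfg$window_size
  if (H %% win != 0 || W %% win != 0) {
    stop(sprintf("feature sides %dx%d not divisible by window size %d",
                 H, W, win), call. = FALSE)
  }
  nh <- cfg$n_heads
  hd <- C / nh
  if (shift > 0) x <- ag_roll(x, -shift, -shift)
  tok <- .win_partition(x, win)            # (B, T, C)
  B <- dim(tok$value)[1]; t_ <- win * win

  shortcut <- tok
  tok <- ag_layernorm(tok, p[[paste0(lp, "ln1_g")]], p[[paste0(lp, "ln1_b")]])
  flat <- ag_reshape(tok, c(B * t_, C))
  qkv <- ag_add_rowbias(ag_matmul(flat, p[[paste0(lp, "qkv_w")]]),
                        p[[paste0(lp, "qkv_b")]])
  qkv <- ag_reshape(qkv, c(B, t_, 3 * C))
  split_heads <- function(z) {
    z <- ag_reshape(z, c(B, t_, hd, nh))
    z <- ag_aperm(z, c(1, 4, 2, 3))        # (B, nh, T, hd)
    ag_reshape(z, c(B * nh, t_, hd))
  }
  q <- split_heads(ag_slice_last(qkv, 1, C))
  k <- split_heads(ag_slice_last(qkv, C + 1, 2 * C))
  v <- split_heads(ag_slice_last(qkv, 2 * C + 1, 3 * C))
  scores <- ag_smul(ag_bmm(q, ag_btrans(k)), 1 / sqrt(hd))
  if (shift > 0) {
    key <- sprintf("%dx%d_w%d_s%d", H, W, win, shift)
    maskw <- state$mask_cache[[key]]
    if (is.null(maskw)) {
      maskw <- .swin_mask(H, W, win, shift)
      state$mask_cache[[key]] <- maskw
    }
    nw <- dim(maskw)[1]
    win_of <- rep(rep(seq_len(nw), each = N), times = nh)
    scores <- ag_sadd(scores, maskw[win_of, , , drop = FALSE])
  }
  attn <- ag_softmax_last(scores)
  out <- ag_bmm(attn, v)                   # (B*nh, T, hd)
  out <- ag_reshape(out, c(B, nh, t_, hd))
  out <- ag_aperm(out, c(1, 3, 4, 2))      # (B, T, hd, nh)
  out <- ag_reshape(out, c(B * t_, C))
  out <- ag_add_rowbias(ag_matmul(out, p[[paste0(lp, "proj_w")]]),
                        p[[paste0(lp, "proj_b")]])
  out <- ag_reshape(out, c(B, t_, C))
  tok <- ag_add(shortcut, out)

  shortcut <- tok
  tok <- ag_layernorm(tok, p[[paste0(lp, "ln2_g")]], p[[paste0(lp, "ln2_b")]])
  flat <- ag_reshape(tok, c(B * t_, C))
  hid <- ag_gelu(ag_add_rowbias(ag_matmul(flat, p[[paste0(lp, "mlp1_w")]]),
                                p[[paste0(lp, "mlp1_b")]]))
  flat <- ag_add_rowbias(ag_matmul(hid, p[[paste0(lp, "mlp2_w")]]),
                         p[[paste0(lp, "mlp2_b")]])
  tok <- ag_add(shortcut, ag_reshape(flat, c(B, t_, C)))

  x <- .win_merge(tok, win, N, H, W)
  if (shift > 0) x <- ag_roll(x, shift, shift)
  x
}

## ---- module forward passes ------------------------------------------------

# all *_nodes functions take and return ag nodes; the exported wrappers below
# operate on plain arrays

.shallow_nodes <- function(model, x, training = FALSE) {
  p <- model$params
  y <- ag_conv2d(x, p$fe_conv_w, p$fe_conv_b, pad = "same")
  y <- ag_batchnorm(y, p$fe_bn_gamma, p$fe_bn_beta, model$state,
                    training = training)
  ag_gelu(y)
}

.dcstb_nodes <- function(model, feats, i, training = FALSE) {
  p <- model$params
  cfg <- model$config
  pre <- sprintf("blk%d_", i)
  x <- if (length(feats) == 1L) feats[[1]] else ag_concat_ch(feats)
  x <- ag_conv2d(x, p[[paste0(pre, "proj_w")]], p[[paste0(pre, "proj_b")]],
                 pad = "same")
  for (l in seq_len(cfg$layers_per_block)) {
    shift <- if (l %% 2 == 0) cfg$window_size %/% 2L else 0L
    x <- .stl_forward(x, p, sprintf("%sstl%d_", pre, l), cfg, model$state,
                      shift)
  }
  x
}

.gated_fusion_nodes <- function(feats, gates) {
  acc <- NULL
  for (i in seq_along(feats)) {
    wi <- ag_slice_gate(gates, i)
    term <- ag_scale(feats[[i]], wi)
    acc <- if (is.null(acc)) term else ag_add(acc, term)
  }
  acc
}

# scalar element of the gate-weight vector as its own node
ag_slice_gate <- function(gates, i) {
  n <- length(gates$value)
  ag_node(gates$value[i], list(gates), function(g) {
    out <- rep(0, n)
    out[i] <- g
    list(out)
  })
}

.reconstruct_nodes <- function(model, f0, fdf) {
  p <- model$params
  cfg <- model$config
  y <- ag_add(f0, fdf)
  y <- ag_gelu(ag_conv2d(y, p$rec_conv1_w, p$rec_conv1_b, pad = "same"))
  y <- ag_conv2d(y, p$rec_up_w, p$rec_up_b, pad = "same")
  y <- ag_pixel_shuffle(y, cfg$sr_scale)
  ag_conv2d(y, p$rec_out_w, p$rec_out_b, pad = "same")
}

.gft_forward_nodes <- function(model, x, training = FALSE) {
  cfg <- model$config
  f0 <- .shallow_nodes(model, x, training)
  feats <- list(f0)
  blocks <- vector("list", cfg$n_blocks)
  for (i in seq_len(cfg$n_blocks)) {
    bi <- .dcstb_nodes(model, feats, i, training)
    blocks[[i]] <- bi
    feats <- c(feats, list(bi))
  }
  fdf <- .gated_fusion_nodes(blocks, model$params$gates)
  out <- .reconstruct_nodes(model, f0, fdf)
  list(output = out, f0 = f0, blocks = blocks, fdf = fdf)
}

# coerce an image / batch to a (N,H,W,Cin) array
.as_nhwc <- function(x, cin = 1) {
  if (is.matrix(x)) {
    array(x, c(1, nrow(x), ncol(x), cin))
  } else if (length(dim(x)) == 3L) {
    array(x, c(dim(x), cin))
  } else {
    x
  }
}

#' Shallow feature extraction
#'
#' Convolution + batch normalization + GELU activation mapping a normalized
#' low-quality image (h, w, c_in) to the low-frequency feature map
#' (h, w, c). These shallow features are also skip-connected directly into
#' the reconstruction head so low-frequency content survives the deep path.
#'
#' @param model A `spad_gft` model.
#' @param x Image matrix in \[0,1\], or an (N,H,W,Cin) array.
#' @param training Use batch statistics (TRUE) or running statistics (FALSE).
#' @return Feature array (N,H,W,C).
#' @export
shallow_extract <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "spad_gft"))
  x <- .as_nhwc(x, model$config$in_channels)
  .shallow_nodes(model, ag_const(x), training)$value
}

#' Densely connected attention block
#'
#' Runs block `i` on the dense feature list `F_0, ..., F_{i-1}`: channel
#' concatenation, a 1x1 projection back to c channels, then
#' `layers_per_block` window-attention layers with the window grid shifted by
#' half a window on alternate layers (masked so tokens never attend across
#' the wrap-around seam).
#'
#' @param model A `spad_gft` model.
#' @param feats List of feature arrays (N,H,W,C): the shallow features plus
#'   all earlier block outputs.
#' @param i Block index.
#' @return Feature array (N,H,W,C).
#' @export
dcstb_forward <- function(model, feats, i = length(feats)) {
  stopifnot(inherits(model, "spad_gft"))
  .dcstb_nodes(model, lapply(feats, ag_const), i, training = FALSE)$value
}

#' Gated fusion of block outputs
#'
#' Learnable scalar-weighted sum `F_DF = sum_i w_i F_i` over the dense block
#' outputs. Exact identities: all-zero weights give zero; a one-hot weight
#' vector returns that block's features unchanged; the map is linear in the
#' features.
#'
#' @param feats List of equally shaped numeric arrays.
#' @param weights Numeric gate weights, one per feature.
#' @return Numeric array, the fused features.
#' @export
gated_fusion <- function(feats, weights) {
  if (length(feats) < 1L) stop("need at least one feature map", call. = FALSE)
  if (length(weights) != length(feats)) {
    stop(sprintf("got %d weights for %d feature maps", length(weights),
                 length(feats)), call. = FALSE)
  }
  acc <- feats[[1]] * weights[1]
  for (i in seq_along(feats)[-1]) acc <- acc + feats[[i]] * weights[i]
  acc
}

#' Reconstruction head
#'
#' Aggregates shallow and deep-fusion features (`F_0 + F_DF`) and maps them
#' to the output image through convolution and sub-pixel (pixel-shuffle)
#' upsampling by the configured scale.
#'
#' @param model A `spad_gft` model.
#' @param f0,fdf Feature arrays (N,H,W,C).
#' @return Output array (N, s*H, s*W, c_in).
#' @export
reconstruct <- function(model, f0, fdf) {
  stopifnot(inherits(model, "spad_gft"))
  .reconstruct_nodes(model, ag_const(f0), ag_const(fdf))$value
}

#' Full forward pass of the gated-fusion transformer
#'
#' @param model A `spad_gft` model.
#' @param x Normalized input image (matrix in \[0,1\]) or (N,H,W,Cin) batch.
#' @param training Batch-norm mode.
#' @return Output array (N, s*H, s*W, c_in); for a single matrix input, the
#'   (s*H, s*W) matrix.
#' @export
gft_forward <- function(model, x, training = FALSE) {
  stopifnot(inherits(model, "spad_gft"))
  was_matrix <- is.matrix(x)
  xa <- .as_nhwc(x, model$config$in_channels)
  out <- .gft_forward_nodes(model, ag_const(xa), training)$output$value
  if (was_matrix) matrix(out[1, , , 1], dim(out)[2], dim(out)[3]) else out
}

#' Enhance a low-bit SPAD measurement
#'
#' Normalizes the counts by `2^bit_depth`, pads (edge replication) to a
#' multiple of the attention window if needed, runs the network in eval mode
#' and clips the result to \[0,1\]. Deterministic for fixed weights.
#'
#' @param x A [spad_lowbit] measurement, or an already normalized matrix in
#'   \[0,1\].
#' @param model A trained `spad_gft`.
#' @param pad Pad inputs whose sides are not divisible by the window size
#'   (TRUE, default) or error (FALSE).
#' @return Enhanced image matrix in \[0,1\] of shape `s * dim(input)`.
#' @export
enhance <- function(x, model, pad = TRUE) {
  stopifnot(inherits(model, "spad_gft"))
  img <- if (inherits(x, "spad_lowbit")) x$counts / x$n_subframes else as.matrix(x)
  h <- nrow(img); w <- ncol(img)
  win <- model$config$window_size
  ph <- (win - h %% win) %% win
  pw <- (win - w %% win) %% win
  if ((ph > 0 || pw > 0) && !pad) {
    stop(sprintf("input %dx%d not divisible by window size %d (set pad = TRUE)",
                 h, w, win), call. = FALSE)
  }
  if (ph > 0) img <- rbind(img, img[rep(h, ph), , drop = FALSE])
  if (pw > 0) img <- cbind(img, img[, rep(w, pw), drop = FALSE])
  out <- gft_forward(model, img, training = FALSE)
  s <- model$config$sr_scale
  out <- out[seq_len(s * h), seq_len(s * w), drop = FALSE]
  pmin(pmax(out, 0), 1)
}
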