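# Minimal tape-based reverse-mode automatic differentiation.
#
# Values are plain numeric arrays; a node is an environment holding the value,
# its parents and a backward closure mapping the node's gradient to the
# parents' gradients. Nodes record a global creation order, so reverse
# traversal in decreasing order is a valid topological order of the tape.
# Only nodes flagged `requires` (parameters and their descendants)
# participate in the backward pass.

.ag <- new.env(parent = emptyenv())
.ag$counter <- 0L

ag_node <- function(value, parents = list(), backward = NULL,
                    requires = NULL) {
  if (is.null(requires)) {
    requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  }
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$backward <- backward
  e$requires <- requires
  e$grad <- NULL
  .ag$counter <- .ag$counter + 1L
  e$ord <- .ag$counter
  class(e) <- "ag_node"
  e
}

#' Create a trainable parameter node
#'
#' Wraps a numeric array as a leaf of the differentiation tape that
#' accumulates gradients during [ag_backward()].
#'
#' @param value Numeric array.
#' @return An `ag_node`.
#' @keywords internal
#' @export
ag_param <- function(value) ag_node(value, requires = TRUE)

#' @rdname ag_param
#' @export
ag_const <- function(value) ag_node(value, requires = FALSE)

as_ag <- function(x) if (inherits(x, "ag_node")) x else ag_const(x)

ag_value <- function(x) if (inherits(x, "ag_node")) x$value else x

#' @export
print.ag_node <- function(x, ...) {
  d <- dim(x$value)
  cat(sprintf("<ag_node> %s%s\n",
              if (is.null(d)) paste0("len ", length(x$value))
              else paste(d, collapse = "x"),
              if (x$requires) " [requires grad]" else ""))
  invisible(x)
}

#' Reverse-mode gradient accumulation
#'
#' Accumulates gradients of a scalar root node into every reachable parameter
#' node's `$grad` field. Call [ag_zero_grad()] on the parameters between
#' steps.
#'
#' @param root Scalar `ag_node` (e.g. a loss).
#' @param grad Seed gradient (default 1).
#' @keywords internal
#' @export
ag_backward <- function(root, grad = 1) {
  if (!root$requires) return(invisible(NULL))
  # collect reachable requiring nodes
  nodes <- vector("list", 256L)
  n_nodes <- 0L
  seen <- new.env(parent = emptyenv())
  stack <- vector("list", 256L)
  stack[[1L]] <- root
  top <- 1L
  while (top > 0L) {
    nd <- stack[[top]]
    top <- top - 1L
    key <- as.character(nd$ord)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    n_nodes <- n_nodes + 1L
    if (n_nodes > length(nodes)) nodes <- c(nodes, vector("list", length(nodes)))
    nodes[[n_nodes]] <- nd
    for (p in nd$parents) {
      if (p$requires) {
        top <- top + 1L
        if (top > length(stack)) stack <- c(stack, vector("list", length(stack)))
        stack[[top]] <- p
      }
    }
  }
  nodes <- nodes[seq_len(n_nodes)]
  ord <- order(vapply(nodes, function(nd) nd$ord, integer(1)),
               decreasing = TRUE)
  if (length(grad) == 1L && length(root$value) > 1L) {
    grad <- array(grad, dim(root$value) %||% length(root$value))
  }
  root$grad <- grad
  for (nd in nodes[ord]) {
    if (is.null(nd$grad) || is.null(nd$backward)) next
    pgrads <- nd$backward(nd$grad)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$requires || is.null(pgrads[[i]])) next
      p$grad <- if (is.null(p$grad)) pgrads[[i]] else p$grad + pgrads[[i]]
    }
    if (!identical(nd, root)) nd$grad <- NULL  # free intermediate grads
  }
  invisible(NULL)
}

#' @rdname ag_backward
#' @param params List of parameter nodes.
#' @export
ag_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

## ---- elementwise ----------------------------------------------------------

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ag_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_div <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

# multiply a tensor by a scalar parameter node (gate weight)
ag_scale <- function(x, s) {
  x <- as_ag(x); s <- as_ag(s)
  xv <- x$value; sv <- as.numeric(s$value)
  ag_node(xv * sv, list(x, s),
          function(g) list(g * sv, sum(g * xv)))
}

# multiply / add a plain numeric constant
ag_smul <- function(x, k) {
  x <- as_ag(x)
  ag_node(x$value * k, list(x), function(g) list(g * k))
}

ag_sadd <- function(x, k) {
  x <- as_ag(x)
  ag_node(x$value + k, list(x), function(g) list(g))
}

ag_abs <- function(x) {
  x <- as_ag(x)
  xv <- x$value
  ag_node(abs(xv), list(x), function(g) list(g * sign(xv)))
}

ag_sq <- function(x) {
  x <- as_ag(x)
  xv <- x$value
  ag_node(xv * xv, list(x), function(g) list(2 * g * xv))
}

ag_sqrt <- function(x) {
  x <- as_ag(x)
  v <- sqrt(x$value)
  ag_node(v, list(x), function(g) list(g / (2 * pmax(v, 1e-12))))
}

ag_relu <- function(x) {
  x <- as_ag(x)
  xv <- x$value
  ag_node(pmax(xv, 0), list(x), function(g) list(g * (xv > 0)))
}

# exact GELU: x * Phi(x)
ag_gelu <- function(x) {
  x <- as_ag(x)
  xv <- x$value
  ph <- stats::pnorm(xv)
  ag_node(xv * ph, list(x),
          function(g) list(g * (ph + xv * stats::dnorm(xv))))
}

## ---- reductions -----------------------------------------------------------

ag_sum <- function(x) {
  x <- as_ag(x)
  n <- length(x$value); d <- dim(x$value)
  ag_node(sum(x$value), list(x),
          function(g) list(array(g, d %||% n)))
}

ag_mean <- function(x) {
  x <- as_ag(x)
  n <- length(x$value); d <- dim(x$value)
  ag_node(mean(x$value), list(x),
          function(g) list(array(g / n, d %||% n)))
}

## ---- shape ----------------------------------------------------------------

ag_reshape <- function(x, dims) {
  x <- as_ag(x)
  old <- dim(x$value) %||% length(x$value)
  v <- x$value
  dim(v) <- dims
  ag_node(v, list(x), function(g) {
    dim(g) <- old
    list(g)
  })
}

ag_aperm <- function(x, perm) {
  x <- as_ag(x)
  inv <- order(perm)
  ag_node(aperm(x$value, perm), list(x),
          function(g) list(aperm(g, inv)))
}

# concatenate 4-D tensors (N,H,W,C_i) along the channel axis
ag_concat_ch <- function(xs) {
  xs <- lapply(xs, as_ag)
  vals <- lapply(xs, function(x) x$value)
  dims <- dim(vals[[1]])
  chans <- vapply(vals, function(v) dim(v)[4], numeric(1))
  out <- array(0, c(dims[1:3], sum(chans)))
  off <- 0L
  for (v in vals) {
    cc <- dim(v)[4]
    out[, , , off + seq_len(cc)] <- v
    off <- off + cc
  }
  ag_node(out, xs, function(g) {
    res <- vector("list", length(xs))
    off <- 0L
    for (i in seq_along(xs)) {
      cc <- chans[i]
      res[[i]] <- g[, , , off + seq_len(cc), drop = FALSE]
      off <- off + cc
    }
    res
  })
}

# slice the last axis of a 3-D or 4-D tensor
ag_slice_last <- function(x, from, to) {
  x <- as_ag(x)
  nd <- length(dim(x$value))
  d <- dim(x$value)
  v <- if (nd == 3L) x$value[, , from:to, drop = FALSE]
       else x$value[, , , from:to, drop = FALSE]
  ag_node(v, list(x), function(g) {
    full <- array(0, d)
    if (nd == 3L) full[, , from:to] <- g else full[, , , from:to] <- g
    list(full)
  })
}

# circular shift of the spatial axes (dims 2, 3) of a 4-D tensor
ag_roll <- function(x, sh, sw) {
  x <- as_ag(x)
  d <- dim(x$value)
  iy <- ((seq_len(d[2]) - 1 - sh) %% d[2]) + 1
  ix <- ((seq_len(d[3]) - 1 - sw) %% d[3]) + 1
  riy <- ((seq_len(d[2]) - 1 + sh) %% d[2]) + 1
  rix <- ((seq_len(d[3]) - 1 + sw) %% d[3]) + 1
  ag_node(x$value[, iy, ix, , drop = FALSE], list(x),
          function(g) list(g[, riy, rix, , drop = FALSE]))
}

## ---- linear algebra -------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b), function(g) {
    list(g %*% t(bv), t(av) %*% g)
  })
}

# add a bias vector to every row of a 2-D matrix
ag_add_rowbias <- function(x, b) {
  x <- as_ag(x); b <- as_ag(b)
  bv <- b$value
  ag_node(sweep(x$value, 2, bv, "+"), list(x, b),
          function(g) list(g, colSums(g)))
}

# batched matrix multiply: (B,n,k) x (B,k,m) -> (B,n,m)
ag_bmm <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  da <- dim(av); db <- dim(bv)
  out <- array(0, c(da[1], da[2], db[3]))
  for (i in seq_len(da[1])) {
    out[i, , ] <- matrix(av[i, , ], da[2], da[3]) %*%
      matrix(bv[i, , ], db[2], db[3])
  }
  ag_node(out, list(a, b), function(g) {
    ga <- array(0, da); gb <- array(0, db)
    for (i in seq_len(da[1])) {
      gi <- matrix(g[i, , ], da[2], db[3])
      ai <- matrix(av[i, , ], da[2], da[3])
      bi <- matrix(bv[i, , ], db[2], db[3])
      ga[i, , ] <- gi %*% t(bi)
      gb[i, , ] <- t(ai) %*% gi
    }
    list(ga, gb)
  })
}

# transpose the last two axes of a 3-D tensor
ag_btrans <- function(x) ag_aperm(x, c(1, 3, 2))

## ---- normalization and attention pieces -----------------------------------

# softmax over the last axis of a 3-D tensor
ag_softmax_last <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  m <- apply(x$value, c(1, 2), max)
  ex <- exp(x$value - array(rep(m, d[3]), d))
  tot <- rowSums(ex, dims = 2)
  y <- ex / array(rep(tot, d[3]), d)
  ag_node(y, list(x), function(g) {
    s <- rowSums(g * y, dims = 2)
    list(y * (g - array(rep(s, d[3]), d)))
  })
}

# layer normalization over the last (channel) axis of a 3-D tensor,
# with learnable per-channel gain and shift
ag_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$value)
  C <- d[length(d)]
  mu <- rowMeans(x$value, dims = 2)
  xc <- x$value - array(rep(mu, C), d)
  va <- rowMeans(xc * xc, dims = 2)
  inv <- 1 / sqrt(va + eps)
  invf <- array(rep(inv, C), d)
  xh <- xc * invf
  gv <- gamma$value; bv <- beta$value
  gfull <- array(rep(gv, each = prod(d[-length(d)])), d)
  ag_node(xh * gfull + array(rep(bv, each = prod(d[-length(d)])), d),
          list(x, gamma, beta), function(g) {
    dxh <- g * gfull
    m1 <- rowMeans(dxh, dims = 2)
    m2 <- rowMeans(dxh * xh, dims = 2)
    dx <- invf * (dxh - array(rep(m1, C), d) - xh * array(rep(m2, C), d))
    dgamma <- apply(g * xh, length(d), sum)
    dbeta <- apply(g, length(d), sum)
    list(dx, dgamma, dbeta)
  })
}

# batch normalization over (N,H,W) per channel of a 4-D tensor.
# `state` carries running statistics (running_mean / running_var),
# updated in training mode and used verbatim in eval mode.
ag_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  d <- dim(x$value)
  C <- d[4]; m <- prod(d[1:3])
  xm <- x$value
  dim(xm) <- c(m, C)
  gv <- gamma$value; bv <- beta$value
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu, "-")
    va <- colMeans(xc * xc)
    state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
    state$running_var <- (1 - momentum) * state$running_var +
      momentum * va * m / max(m - 1, 1)
    inv <- 1 / sqrt(va + eps)
    xh <- sweep(xc, 2, inv, "*")
    out <- sweep(sweep(xh, 2, gv, "*"), 2, bv, "+")
    dim(out) <- d
    ag_node(out, list(x, gamma, beta), function(g) {
      dim(g) <- c(m, C)
      dxh <- sweep(g, 2, gv, "*")
      m1 <- colMeans(dxh)
      m2 <- colMeans(dxh * xh)
      dx <- sweep(sweep(dxh, 2, m1, "-") - sweep(xh, 2, m2, "*"), 2, inv, "*")
      dim(dx) <- d
      list(dx, colSums(g * xh), colSums(g))
    })
  } else {
    inv <- 1 / sqrt(state$running_var + eps)
    xh <- sweep(sweep(xm, 2, state$running_mean, "-"), 2, inv, "*")
    out <- sweep(sweep(xh, 2, gv, "*"), 2, bv, "+")
    dim(out) <- d
    ag_node(out, list(x, gamma, beta), function(g) {
      dim(g) <- c(m, C)
      dx <- sweep(sweep(g, 2, gv, "*"), 2, inv, "*")
      dim(dx) <- d
      list(dx, colSums(g * xh), colSums(g))
    })
  }
}

## ---- convolution ----------------------------------------------------------

# 2-D convolution on channels-last tensors (N,H,W,Cin) with kernel
# (kh,kw,Cin,Cout); pad "same" (odd kernels) or "valid"; stride 1.
# im2col formulation: patch columns ordered channel-fastest, then kernel row,
# then kernel column, matching the (Cin,kh,kw,Cout) reshape of the kernel.
ag_conv2d <- function(x, w, b = NULL, pad = c("same", "valid")) {
  pad <- match.arg(pad)
  x <- as_ag(x); w <- as_ag(w)
  if (!is.null(b)) b <- as_ag(b)
  xv <- x$value; wv <- w$value
  dx <- dim(xv); dw <- dim(wv)
  N <- dx[1]; H <- dx[2]; W <- dx[3]; Cin <- dx[4]
  kh <- dw[1]; kw <- dw[2]; Cout <- dw[4]
  stopifnot(dw[3] == Cin)
  if (pad == "same") {
    ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
    Ho <- H; Wo <- W
    xp <- array(0, c(N, H + 2 * ph, W + 2 * pw, Cin))
    xp[, ph + seq_len(H), pw + seq_len(W), ] <- xv
  } else {
    ph <- 0L; pw <- 0L
    Ho <- H - kh + 1L; Wo <- W - kw + 1L
    xp <- xv
  }
  rows <- N * Ho * Wo
  cols <- matrix(0, rows, kh * kw * Cin)
  for (j in seq_len(kw)) {
    for (i in seq_len(kh)) {
      blk <- xp[, i:(i + Ho - 1L), j:(j + Wo - 1L), , drop = FALSE]
      dim(blk) <- c(rows, Cin)
      cols[, (((j - 1L) * kh + i - 1L) * Cin) + seq_len(Cin)] <- blk
    }
  }
  wmat <- aperm(wv, c(3, 1, 2, 4))
  dim(wmat) <- c(Cin * kh * kw, Cout)
  out <- cols %*% wmat
  if (!is.null(b)) out <- sweep(out, 2, b$value, "+")
  dim(out) <- c(N, Ho, Wo, Cout)
  parents <- if (is.null(b)) list(x, w) else list(x, w, b)
  ag_node(out, parents, function(g) {
    dim(g) <- c(rows, Cout)
    dwmat <- crossprod(cols, g)
    dim(dwmat) <- c(Cin, kh, kw, Cout)
    dwv <- aperm(dwmat, c(2, 3, 1, 4))
    dcols <- g %*% t(wmat)
    dxp <- array(0, dim(xp))
    for (j in seq_len(kw)) {
      for (i in seq_len(kh)) {
        blk <- dcols[, (((j - 1L) * kh + i - 1L) * Cin) + seq_len(Cin)]
        dim(blk) <- c(N, Ho, Wo, Cin)
        dxp[, i:(i + Ho - 1L), j:(j + Wo - 1L), ] <-
          dxp[, i:(i + Ho - 1L), j:(j + Wo - 1L), , drop = FALSE] + blk
      }
    }
    dxv <- if (pad == "same") {
      dxp[, ph + seq_len(H), pw + seq_len(W), , drop = FALSE]
    } else {
      dxp
    }
    if (is.null(b)) list(dxv, dwv) else list(dxv, dwv, colSums(g))
  })
}

# 2x2 average pooling of a 4-D tensor (even spatial dims)
ag_avgpool2 <- function(x) {
  x <- as_ag(x)
  d <- dim(x$value)
  stopifnot(d[2] %% 2 == 0, d[3] %% 2 == 0)
  i1 <- seq(1, d[2], by = 2); i2 <- i1 + 1
  j1 <- seq(1, d[3], by = 2); j2 <- j1 + 1
  v <- 0.25 * (x$value[, i1, j1, , drop = FALSE] +
               x$value[, i2, j1, , drop = FALSE] +
               x$value[, i1, j2, , drop = FALSE] +
               x$value[, i2, j2, , drop = FALSE])
  ag_node(v, list(x), function(g) {
    out <- array(0, d)
    out[, i1, j1, ] <- g * 0.25
    out[, i2, j1, ] <- g * 0.25
    out[, i1, j2, ] <- g * 0.25
    out[, i2, j2, ] <- g * 0.25
    list(out)
  })
}

# pixel shuffle: (N,H,W,C*r^2) -> (N,rH,rW,C); channel index decomposes as
# c + C*(col offset) + C*r*(row offset), composed from reshape/aperm so the
# gradient follows automatically.
ag_pixel_shuffle <- function(x, r) {
  x <- as_ag(x)
  d <- dim(x$value)
  if (r == 1) return(x)
  C <- d[4] / (r * r)
  stopifnot(C == round(C))
  y <- ag_reshape(x, c(d[1], d[2], d[3], C, r, r))
  y <- ag_aperm(y, c(1, 6, 2, 5, 3, 4))
  ag_reshape(y, c(d[1], r * d[2], r * d[3], C))
}
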