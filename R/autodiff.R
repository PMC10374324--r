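# Minimal reverse-mode automatic differentiation over numeric arrays.
#
# Every node is an environment of class "adTensor" holding the forward value,
# an accumulated gradient, its parent nodes and a backward closure that maps
# the node's gradient to gradients for each parent. Operations are coarse
# (whole feature maps), so the R-level graph overhead is negligible next to
# the BLAS work inside conv2d.

.ad_state <- new.env(parent = emptyenv())
.ad_state$grad_enabled <- TRUE
.ad_state$counter <- 0

# evaluate expr with graph construction disabled (inference mode)
ad_no_grad <- function(expr) {
  old <- .ad_state$grad_enabled
  .ad_state$grad_enabled <- FALSE
  on.exit(.ad_state$grad_enabled <- old)
  force(expr)
}

ad_tensor <- function(value, requires = FALSE) {
  e <- new.env(parent = emptyenv())
  .ad_state$counter <- .ad_state$counter + 1
  e$id <- .ad_state$counter
  e$value <- value
  e$grad <- NULL
  e$parents <- list()
  e$backfn <- NULL
  e$requires <- requires
  class(e) <- "adTensor"
  e
}

ad_param <- function(value) ad_tensor(value, requires = TRUE)

is_ad <- function(x) inherits(x, "adTensor")

ad_const <- function(x) if (is_ad(x)) x else ad_tensor(x)

ad_node <- function(value, parents, backfn) {
  req <- .ad_state$grad_enabled &&
    any(vapply(parents, function(p) p$requires, TRUE))
  e <- ad_tensor(value, requires = req)
  if (req) {
    e$parents <- parents
    e$backfn <- backfn
  }
  e
}

# Topological order by depth-first search, then reverse sweep.
ad_backward <- function(root, grad = NULL) {
  if (is.null(grad)) grad <- array(1, dim = dim(root$value) %||% length(root$value))
  order <- list()
  seen <- new.env(parent = emptyenv())
  stack <- list(list(node = root, phase = 0L))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top$node
    key <- as.character(node$id)
    if (top$phase == 0L) {
      if (!is.null(seen[[key]]) || !node$requires) next
      seen[[key]] <- TRUE
      stack[[length(stack) + 1L]] <- list(node = node, phase = 1L)
      for (p in node$parents) {
        stack[[length(stack) + 1L]] <- list(node = p, phase = 0L)
      }
    } else {
      order[[length(order) + 1L]] <- node
    }
  }
  # order is now children-before-parents when traversed from the end
  grads <- new.env(parent = emptyenv())
  root$grad <- grad
  for (i in rev(seq_along(order))) {
    node <- order[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    pg <- node$backfn(node$grad)
    for (j in seq_along(node$parents)) {
      p <- node$parents[[j]]
      if (!p$requires || is.null(pg[[j]])) next
      if (is.null(p$grad)) p$grad <- pg[[j]] else p$grad <- p$grad + pg[[j]]
    }
    if (!identical(node, root) && length(node$parents)) node$grad <- NULL
  }
  invisible(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# ---- elementwise arithmetic -------------------------------------------------

ad_add <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_node(a$value + b$value, list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  ad_node(a$value - b$value, list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  av <- a$value; bv <- b$value
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  av <- a$value; bv <- b$value
  ad_node(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

# multiply by a plain scalar constant
ad_scale <- function(a, k) {
  ad_node(a$value * k, list(a), function(g) list(g * k))
}

ad_neg <- function(a) ad_scale(a, -1)

# scalar tensor s (length-1) times array tensor a
ad_smul <- function(s, a) {
  sv <- as.numeric(s$value); av <- a$value
  ad_node(sv * av, list(s, a),
          function(g) list(sum(g * av), sv * g))
}

ad_exp <- function(a) {
  v <- exp(a$value)
  ad_node(v, list(a), function(g) list(g * v))
}

ad_log <- function(a) {
  av <- a$value
  ad_node(log(av), list(a), function(g) list(g / av))
}

ad_sqrt <- function(a) {
  v <- sqrt(a$value)
  ad_node(v, list(a), function(g) list(g / (2 * v)))
}

ad_square <- function(a) {
  av <- a$value
  ad_node(av * av, list(a), function(g) list(2 * av * g))
}

ad_powc <- function(a, g) {
  if (g == 0) return(ad_tensor(array(1, dim(a$value) %||% length(a$value))))
  av <- a$value
  ad_node(av^g, list(a), function(gr) list(gr * g * av^(g - 1)))
}

ad_tanh <- function(a) {
  v <- tanh(a$value)
  ad_node(v, list(a), function(g) list(g * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$value))
  ad_node(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_atan <- function(a) {
  av <- a$value
  ad_node(atan(av), list(a), function(g) list(g / (1 + av * av)))
}

ad_relu <- function(a) {
  av <- a$value
  mask <- av > 0
  ad_node(av * mask, list(a), function(g) list(g * mask))
}

ad_leaky <- function(a, slope = 0.1) {
  av <- a$value
  mask <- av > 0
  ad_node(ifelse(mask, av, slope * av), list(a),
          function(g) list(g * ifelse(mask, 1, slope)))
}

# numerically stable softplus: log(1 + e^x) = max(x, 0) + log1p(e^{-|x|})
ad_softplus <- function(a) {
  av <- a$value
  v <- pmax(av, 0) + log1p(exp(-abs(av)))
  s <- 1 / (1 + exp(-av))
  ad_node(v, list(a), function(g) list(g * s))
}

ad_mish <- function(a) {
  av <- a$value
  sp <- pmax(av, 0) + log1p(exp(-abs(av)))
  tsp <- tanh(sp)
  sig <- 1 / (1 + exp(-av))
  ad_node(av * tsp, list(a),
          function(g) list(g * (tsp + av * (1 - tsp * tsp) * sig)))
}

# elementwise max/min of two tensors; subgradient follows the winner
ad_max2 <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  av <- a$value; bv <- b$value
  mask <- av >= bv
  ad_node(pmax(av, bv), list(a, b),
          function(g) list(g * mask, g * !mask))
}

ad_min2 <- function(a, b) {
  a <- ad_const(a); b <- ad_const(b)
  av <- a$value; bv <- b$value
  mask <- av <= bv
  ad_node(pmin(av, bv), list(a, b),
          function(g) list(g * mask, g * !mask))
}

ad_clamp <- function(a, lo, hi) {
  av <- a$value
  mask <- av >= lo & av <= hi
  ad_node(pmin(pmax(av, lo), hi), list(a), function(g) list(g * mask))
}

# straight-through clamp: clamps the value but passes the gradient
# unchanged, so saturated units (e.g. box log-sizes) can recover
ad_clamp_st <- function(a, lo, hi) {
  ad_node(pmin(pmax(a$value, lo), hi), list(a), function(g) list(g))
}

ad_sum <- function(a) {
  dm <- dim(a$value) %||% length(a$value)
  ad_node(sum(a$value), list(a),
          function(g) list(array(as.numeric(g), dim = dm)))
}

ad_mean <- function(a) {
  n <- length(a$value)
  ad_scale(ad_sum(a), 1 / n)
}

ad_detach <- function(a) ad_tensor(a$value)

# ---- shape ops --------------------------------------------------------------

# concatenate (H,W,Ci) tensors along the channel dimension
ad_concat_c <- function(tensors) {
  vals <- lapply(tensors, function(t) t$value)
  dims <- lapply(vals, dim)
  H <- dims[[1]][1]; W <- dims[[1]][2]
  cs <- vapply(dims, function(d) d[3], 0)
  stopifnot(all(vapply(dims, function(d) d[1] == H && d[2] == W, TRUE)))
  out <- array(0, c(H, W, sum(cs)))
  off <- 0L
  for (i in seq_along(vals)) {
    out[, , off + seq_len(cs[i])] <- vals[[i]]
    off <- off + cs[i]
  }
  offs <- c(0L, cumsum(cs))
  ad_node(out, tensors, function(g) {
    lapply(seq_along(tensors), function(i) {
      g[, , (offs[i] + 1):offs[i + 1], drop = FALSE]
    })
  })
}

# take a channel subset of an (H,W,C) tensor
ad_slice_c <- function(a, idx) {
  av <- a$value
  dm <- dim(av)
  ad_node(av[, , idx, drop = FALSE], list(a), function(g) {
    full <- array(0, dm)
    full[, , idx] <- g
    list(full)
  })
}

# per-channel mean over H,W: (H,W,C) -> length-C vector
ad_chan_mean <- function(a) {
  av <- a$value
  dm <- dim(av)
  M <- dm[1] * dm[2]
  v <- colMeans(matrix(av, nrow = M, ncol = dm[3]))
  ad_node(v, list(a), function(g) {
    list(array(rep(g / M, each = M), dim = dm))
  })
}

# broadcast a length-C vector to (H,W,C)
ad_chan_bcast <- function(v, H, W) {
  vv <- as.numeric(v$value)
  C <- length(vv)
  ad_node(array(rep(vv, each = H * W), dim = c(H, W, C)), list(v),
          function(g) list(colSums(matrix(g, nrow = H * W, ncol = C))))
}

# nearest-neighbour 2x upsample
ad_upsample2 <- function(a) {
  av <- a$value
  dm <- dim(av)
  H <- dm[1]; W <- dm[2]
  v <- av[rep(seq_len(H), each = 2), rep(seq_len(W), each = 2), , drop = FALSE]
  ad_node(v, list(a), function(g) {
    o <- seq(1, 2 * H, by = 2); p <- seq(1, 2 * W, by = 2)
    list(g[o, p, , drop = FALSE] + g[o + 1, p, , drop = FALSE] +
         g[o, p + 1, , drop = FALSE] + g[o + 1, p + 1, , drop = FALSE])
  })
}

# ---- convolution, pooling, batch norm --------------------------------------

# x: (H,W,Cin); weight: matrix (Cout x k*k*Cin); bias: length Cout or NULL
ad_conv2d <- function(x, weight, bias = NULL, k, stride = 1L, pad = NULL) {
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  xv <- x$value
  dm <- dim(xv)
  H <- dm[1]; W <- dm[2]; C <- dm[3]
  Wm <- weight$value
  Cout <- nrow(Wm)
  cols <- cpp_im2col(xv, H, W, C, k, stride, pad)
  out_mat <- Wm %*% cols
  if (!is.null(bias)) out_mat <- out_mat + bias$value
  Hout <- (H + 2 * pad - k) %/% stride + 1L
  Wout <- (W + 2 * pad - k) %/% stride + 1L
  out <- array(t(out_mat), dim = c(Hout, Wout, Cout))
  parents <- if (is.null(bias)) list(x, weight) else list(x, weight, bias)
  ad_node(out, parents, function(g) {
    gm <- t(matrix(g, nrow = Hout * Wout, ncol = Cout))  # Cout x N
    dW <- gm %*% t(cols)
    dcols <- crossprod(Wm, gm)
    dx <- array(cpp_col2im(dcols, H, W, C, k, stride, pad), dim = dm)
    if (is.null(bias)) list(dx, dW) else list(dx, dW, rowSums(gm))
  })
}

ad_maxpool_same <- function(x, k) {
  xv <- x$value
  dm <- dim(xv)
  res <- cpp_maxpool_same(xv, dm[1], dm[2], dm[3], k)
  v <- array(res$value, dim = dm)
  arg <- res$argmax
  ad_node(v, list(x), function(g) {
    dx <- numeric(length(xv))
    gs <- as.numeric(g)
    # scatter-add gradients to argmax positions
    agg <- rowsum(gs, arg)
    dx[as.integer(rownames(agg))] <- agg
    list(array(dx, dim = dm))
  })
}

# Normalization over the spatial positions of each channel of one sample.
# Because the engine processes one image at a time, the same per-sample
# statistics are used in training AND inference (instance-style batch
# norm): the two modes see identical activations and inference stays
# deterministic. `state` still tracks running moments (checkpoint
# diagnostics; set use_sample_stats = FALSE to normalize with them).
ad_batchnorm <- function(x, gamma, beta, state, training = TRUE,
                         momentum = 0.1, eps = 1e-5,
                         use_sample_stats = TRUE) {
  xv <- x$value
  dm <- dim(xv)
  M <- dm[1] * dm[2]; C <- dm[3]
  xm <- matrix(xv, nrow = M, ncol = C)
  if (training || use_sample_stats) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    if (training) {
      state$running_mean <- (1 - momentum) * state$running_mean + momentum * mu
      state$running_var <- (1 - momentum) * state$running_var + momentum * va
    }
  } else {
    mu <- state$running_mean
    va <- state$running_var
  }
  istd <- 1 / sqrt(va + eps)
  xhat <- (xm - rep(mu, each = M)) * rep(istd, each = M)
  gv <- gamma$value; bv <- beta$value
  y <- array(xhat * rep(gv, each = M) + rep(bv, each = M), dim = dm)
  ad_node(y, list(x, gamma, beta), function(g) {
    gm <- matrix(g, nrow = M, ncol = C)
    dgamma <- colSums(gm * xhat)
    dbeta <- colSums(gm)
    dxhat <- gm * rep(gv, each = M)
    if (training) {
      # standard batch-norm backward (statistics depend on x)
      t1 <- colSums(dxhat)
      t2 <- colSums(dxhat * xhat)
      dxm <- (dxhat - rep(t1 / M, each = M) -
                xhat * rep(t2 / M, each = M)) * rep(istd, each = M)
    } else {
      dxm <- dxhat * rep(istd, each = M)
    }
    list(array(dxm, dim = dm), dgamma, dbeta)
  })
}

# Fast-normalized weighted fusion (EfficientDet style): given n inputs of
# identical shape and a length-n raw-weight parameter, w_i = relu(r_i) /
# (sum relu(r_j) + eps), output = sum w_i x_i.
ad_wfuse <- function(inputs, raw, eps = 1e-4) {
  rv <- as.numeric(raw$value)
  r <- pmax(rv, 0)
  S <- sum(r) + eps
  w <- r / S
  vals <- lapply(inputs, function(t) t$value)
  out <- w[1] * vals[[1]]
  if (length(vals) > 1) for (i in 2:length(vals)) out <- out + w[i] * vals[[i]]
  ad_node(out, c(inputs, list(raw)), function(g) {
    a <- vapply(vals, function(v) sum(g * v), 0)
    dr <- (a - sum(w * a)) / S
    dr[rv <= 0] <- 0
    c(lapply(seq_along(inputs), function(i) w[i] * g), list(dr))
  })
}
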