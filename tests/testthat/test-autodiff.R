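# Numeric-differentiation checks of the reverse-mode engine: every layer
# gradient is compared against central differences on small random inputs.

test_that("convolution forward matches a direct sliding-window computation", {
  set.seed(10)
  H <- 5L; W <- 6L; Cin <- 3L; Cout <- 4L; k <- 3L
  x0 <- array(rnorm(H * W * Cin), c(H, W, Cin))
  W0 <- matrix(rnorm(Cout * k * k * Cin), Cout)
  b0 <- rnorm(Cout)
  out <- gd$ad_conv2d(gd$ad_tensor(x0), gd$ad_tensor(W0), gd$ad_tensor(b0),
                      k = k, stride = 1L)
  pad <- 1L
  xp <- array(0, c(H + 2, W + 2, Cin))
  xp[1 + 1:H, 1 + 1:W, ] <- x0
  for (co in 1:Cout) for (ho in c(1L, 3L, 5L)) for (wo in c(2L, 6L)) {
    patch <- xp[ho + 0:(k - 1), wo + 0:(k - 1), , drop = FALSE]
    expect_equal(out$value[ho, wo, co],
                 sum(as.numeric(patch) * W0[co, ]) + b0[co], tolerance = 1e-12)
  }
})

test_that("convolution gradients match numeric differentiation", {
  set.seed(11)
  x0 <- array(rnorm(4 * 5 * 2), c(4, 5, 2))
  W0 <- matrix(rnorm(3 * 9 * 2), 3)
  b0 <- rnorm(3)
  wts <- array(rnorm(4 * 5 * 3), c(4, 5, 3))
  x <- gd$ad_param(x0); Wp <- gd$ad_param(W0); bp <- gd$ad_param(b0)
  l <- gd$ad_sum(gd$ad_mul(gd$ad_conv2d(x, Wp, bp, k = 3L), gd$ad_tensor(wts)))
  gd$ad_backward(l)
  fx <- function(v) sum(gd$ad_conv2d(gd$ad_tensor(array(v, dim(x0))),
                                     gd$ad_tensor(W0), gd$ad_tensor(b0),
                                     k = 3L)$value * wts)
  fW <- function(v) sum(gd$ad_conv2d(gd$ad_tensor(x0),
                                     gd$ad_tensor(matrix(v, 3)),
                                     gd$ad_tensor(b0), k = 3L)$value * wts)
  expect_lt(max(abs(x$grad - num_grad(fx, x0))), 1e-6)
  expect_lt(max(abs(Wp$grad - matrix(num_grad(fW, as.numeric(W0)), 3))), 1e-6)
  expect_equal(as.numeric(bp$grad), as.numeric(num_grad(
    function(v) sum(gd$ad_conv2d(gd$ad_tensor(x0), gd$ad_tensor(W0),
                                 gd$ad_tensor(v), k = 3L)$value * wts), b0)),
    tolerance = 1e-6)
})

test_that("batch-norm gradients match numeric differentiation", {
  set.seed(12)
  C <- 3L
  x0 <- array(rnorm(4 * 5 * C), c(4, 5, C))
  g0 <- rnorm(C); b0 <- rnorm(C)
  wts <- array(rnorm(length(x0)), dim(x0))
  mk_state <- function() {
    st <- new.env()
    st$running_mean <- numeric(C); st$running_var <- rep(1, C)
    st
  }
  x <- gd$ad_param(x0); gp <- gd$ad_param(g0); bp <- gd$ad_param(b0)
  y <- gd$ad_batchnorm(x, gp, bp, mk_state(), training = TRUE)
  gd$ad_backward(gd$ad_sum(gd$ad_mul(y, gd$ad_tensor(wts))))
  f <- function(v) {
    y <- gd$ad_batchnorm(gd$ad_tensor(array(v, dim(x0))), gd$ad_tensor(g0),
                         gd$ad_tensor(b0), mk_state(), training = TRUE)
    sum(y$value * wts)
  }
  expect_lt(max(abs(x$grad - num_grad(f, x0))), 1e-6)
})

test_that("pooling, upsampling, activations and fusion backprop correctly", {
  set.seed(13)
  x0 <- array(rnorm(6 * 6 * 2), c(6, 6, 2))
  wts <- array(rnorm(length(x0)), dim(x0))
  for (op in list(function(t) gd$ad_maxpool_same(t, 3L),
                  function(t) gd$ad_mish(t),
                  function(t) gd$ad_leaky(t, 0.1),
                  function(t) gd$ad_simam(t, 1e-4))) {
    x <- gd$ad_param(x0)
    gd$ad_backward(gd$ad_sum(gd$ad_mul(op(x), gd$ad_tensor(wts))))
    f <- function(v) sum(op(gd$ad_tensor(array(v, dim(x0))))$value * wts)
    expect_lt(max(abs(x$grad - num_grad(f, x0))), 1e-5)
  }
  # upsample: output weights shape differs
  x <- gd$ad_param(x0)
  w2 <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  gd$ad_backward(gd$ad_sum(gd$ad_mul(gd$ad_upsample2(x), gd$ad_tensor(w2))))
  f <- function(v) sum(gd$ad_upsample2(gd$ad_tensor(array(v, dim(x0))))$value * w2)
  expect_lt(max(abs(x$grad - num_grad(f, x0))), 1e-6)
  # weighted fusion: gradients for inputs and raw weights
  raw0 <- c(1, 0.4, 2)
  ins0 <- lapply(1:3, function(i) array(rnorm(12), c(3, 4, 1)))
  wf <- array(rnorm(12), c(3, 4, 1))
  ins <- lapply(ins0, gd$ad_param)
  raw <- gd$ad_param(raw0)
  gd$ad_backward(gd$ad_sum(gd$ad_mul(gd$ad_wfuse(ins, raw), gd$ad_tensor(wf))))
  fr <- function(v) {
    r <- pmax(v, 0); w <- r / (sum(r) + 1e-4)
    sum((w[1] * ins0[[1]] + w[2] * ins0[[2]] + w[3] * ins0[[3]]) * wf)
  }
  expect_lt(max(abs(raw$grad - num_grad(fr, raw0))), 1e-6)
  expect_lt(max(abs(ins[[1]]$grad - wf * (pmax(raw0, 0) / (sum(pmax(raw0, 0)) + 1e-4))[1])), 1e-9)
})

test_that("graphs with shared nodes accumulate gradients once per path", {
  x <- gd$ad_param(c(2, 3))
  y <- gd$ad_mul(x, x)            # x^2, shares x twice
  z <- gd$ad_add(y, gd$ad_mul(x, gd$ad_tensor(c(5, 5))))
  gd$ad_backward(gd$ad_sum(z))
  expect_equal(as.numeric(x$grad), 2 * c(2, 3) + 5)
})

test_that("inference mode builds no graph and frees buffers", {
  x0 <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  Wp <- gd$ad_param(matrix(rnorm(4 * 9 * 2), 4))
  out <- gd$ad_no_grad(gd$ad_conv2d(gd$ad_tensor(x0), Wp, NULL, k = 3L))
  expect_false(out$requires)
  expect_length(out$parents, 0)
})
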