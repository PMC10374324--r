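# Layer builders on top of the autodiff engine. A "net" is an environment
# holding a named parameter list and batch-norm running statistics; layer
# constructors register their parameters there and return forward closures.

new_net <- function() {
  net <- new.env(parent = emptyenv())
  net$params <- list()
  net$state <- list()
  net
}

reg_param <- function(net, name, value) {
  p <- ad_param(value)
  net$params[[name]] <- p
  p
}

he_init <- function(fan_in, n) stats::rnorm(n, sd = sqrt(2 / fan_in))

# Conv -> BatchNorm -> activation. act: "mish" (CBM), "leaky" (CBL) or
# "linear" (head output, no BN).
conv_block <- function(net, name, cin, cout, k = 3L, stride = 1L,
                       act = "mish", bn = TRUE) {
  Wn <- paste0(name, ".w")
  weight <- reg_param(net, Wn, matrix(he_init(k * k * cin, cout * k * k * cin),
                                      nrow = cout))
  bias <- NULL
  if (!bn) bias <- reg_param(net, paste0(name, ".b"), numeric(cout))
  gamma <- beta <- NULL
  state <- NULL
  if (bn) {
    gamma <- reg_param(net, paste0(name, ".bn.gamma"), rep(1, cout))
    beta <- reg_param(net, paste0(name, ".bn.beta"), numeric(cout))
    state <- new.env(parent = emptyenv())
    state$running_mean <- numeric(cout)
    state$running_var <- rep(1, cout)
    net$state[[paste0(name, ".bn")]] <- state
  }
  function(x, training = FALSE) {
    y <- ad_conv2d(x, weight, bias, k = k, stride = stride)
    if (bn) y <- ad_batchnorm(y, gamma, beta, state, training = training)
    switch(act,
           mish = ad_mish(y),
           leaky = ad_leaky(y, 0.1),
           linear = y,
           stop("unknown activation"))
  }
}

# fast-normalized fusion node over n same-shape inputs; raw weights are
# learnable scalars initialized to 1
fusion_node <- function(net, name, n, eps = 1e-4) {
  raw <- reg_param(net, paste0(name, ".w"), rep(1, n))
  function(inputs) ad_wfuse(inputs, raw, eps = eps)
}

# residual block: 1x1 reduce, 3x3 restore, additive skip (channels c)
res_block <- function(net, name, c) {
  c1 <- conv_block(net, paste0(name, ".conv1"), c, c, k = 1L)
  c2 <- conv_block(net, paste0(name, ".conv2"), c, c, k = 3L)
  function(x, training = FALSE) ad_add(x, c2(c1(x, training), training))
}

# CSP stage of the backbone: stride-2 downsample, channel split into a
# bypass and a residual-stack branch, merge by concatenation, then an
# optional SimAM refinement.
csp_stage <- function(net, name, cin, cout, n_blocks, attention = TRUE,
                      lambda = 1e-4) {
  ch <- cout %/% 2L
  down <- conv_block(net, paste0(name, ".down"), cin, cout, k = 3L, stride = 2L)
  split_bypass <- conv_block(net, paste0(name, ".split0"), cout, ch, k = 1L)
  split_main <- conv_block(net, paste0(name, ".split1"), cout, ch, k = 1L)
  blocks <- lapply(seq_len(n_blocks), function(i) {
    res_block(net, sprintf("%s.res%d", name, i), ch)
  })
  post <- conv_block(net, paste0(name, ".post"), ch, ch, k = 1L)
  merge <- conv_block(net, paste0(name, ".merge"), 2L * ch, cout, k = 1L)
  function(x, training = FALSE) {
    d <- down(x, training)
    b0 <- split_bypass(d, training)
    b1 <- split_main(d, training)
    for (blk in blocks) b1 <- blk(b1, training)
    b1 <- post(b1, training)
    y <- merge(ad_concat_c(list(b1, b0)), training)
    if (attention) ad_simam(y, lambda) else y
  }
}

# SPP: conv triple, parallel max-pools (5/9/13, stride 1, same padding)
# concatenated with the identity, conv triple back down.
spp_block <- function(net, name, cin, kernels = c(5L, 9L, 13L)) {
  ch <- cin %/% 2L
  pre1 <- conv_block(net, paste0(name, ".pre1"), cin, ch, k = 1L, act = "leaky")
  pre2 <- conv_block(net, paste0(name, ".pre2"), ch, cin, k = 3L, act = "leaky")
  pre3 <- conv_block(net, paste0(name, ".pre3"), cin, ch, k = 1L, act = "leaky")
  post1 <- conv_block(net, paste0(name, ".post1"), ch * (length(kernels) + 1L),
                      ch, k = 1L, act = "leaky")
  post2 <- conv_block(net, paste0(name, ".post2"), ch, cin, k = 3L, act = "leaky")
  post3 <- conv_block(net, paste0(name, ".post3"), cin, ch, k = 1L, act = "leaky")
  function(x, training = FALSE) {
    y <- pre3(pre2(pre1(x, training), training), training)
    pools <- lapply(kernels, function(k) ad_maxpool_same(y, k))
    z <- ad_concat_c(c(pools, list(y)))
    post3(post2(post1(z, training), training), training)
  }
}

# five consecutive 1x1/3x3 convolutions (channel c in and out)
five_conv <- function(net, name, c) {
  convs <- list(
    conv_block(net, paste0(name, ".c1"), c, c, k = 1L, act = "leaky"),
    conv_block(net, paste0(name, ".c2"), c, 2L * c, k = 3L, act = "leaky"),
    conv_block(net, paste0(name, ".c3"), 2L * c, c, k = 1L, act = "leaky"),
    conv_block(net, paste0(name, ".c4"), c, 2L * c, k = 3L, act = "leaky"),
    conv_block(net, paste0(name, ".c5"), 2L * c, c, k = 1L, act = "leaky"))
  function(x, training = FALSE) {
    for (cv in convs) x <- cv(x, training)
    x
  }
}

# convolution group: 3x3 then 1x1 standard convolutions
conv_group <- function(net, name, cin, cout) {
  c1 <- conv_block(net, paste0(name, ".c1"), cin, 2L * cout, k = 3L, act = "leaky")
  c2 <- conv_block(net, paste0(name, ".c2"), 2L * cout, cout, k = 1L, act = "leaky")
  function(x, training = FALSE) c2(c1(x, training), training)
}
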