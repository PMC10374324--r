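# The detection network: SAM-CSPDarkNet-53 backbone (five CSP stages with
# SimAM refinement after each), SPP on the deepest stage, a path-aggregation
# neck with fast-normalized weighted fusion and a jump connection on the
# bottom-up path, and three YOLO heads. For a 608 px input and base width 32
# the backbone taps have shapes 76x76x256, 38x38x512 and 19x19x1024.

#' Mish activation
#'
#' \code{x * tanh(log(1 + exp(x)))}, evaluated with an overflow-safe
#' softplus so large |x| are exact.
#'
#' @param x numeric vector or array.
#' @return same shape.
#' @examples
#' mish(0); mish(1)  # 0, ~0.8651
#' @export
mish <- function(x) {
  sp <- pmax(x, 0) + log1p(exp(-abs(x)))
  x * tanh(sp)
}

#' Fast-normalized weighted fusion (pure function)
#'
#' Combines same-shape arrays with weights
#' \code{w_i = relu(raw_i) / (sum relu(raw_j) + eps)}: non-negative,
#' summing to one up to eps.
#'
#' @param inputs list of numeric arrays of identical shape.
#' @param raw_weights one raw scalar per input.
#' @param eps stabilizer, default 1e-4.
#' @return list(output, weights).
#' @export
fastNormalizedFusion <- function(inputs, raw_weights, eps = 1e-4) {
  if (length(inputs) != length(raw_weights))
    stop("need one raw weight per input")
  dims <- lapply(inputs, dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stop("fusion inputs must share one shape")
  r <- pmax(raw_weights, 0)
  w <- r / (sum(r) + eps)
  out <- inputs[[1]] * w[1]
  if (length(inputs) > 1) {
    for (i in 2:length(inputs)) out <- out + inputs[[i]] * w[i]
  }
  list(output = out, weights = w)
}

default_anchor_set <- function(input_size) {
  # generic priors scaled to the input; replaced by kmeansAnchors in practice
  base <- input_size / 608
  w <- c(21, 28, 30, 40, 40, 49, 55, 66, 69) * base
  h <- c(34, 52, 82, 63, 106, 146, 77, 209, 114) * base
  anchorSet(w, h)
}

#' Build the detection model
#'
#' Assembles backbone, SPP, weighted-fusion neck and three heads with
#' freshly initialized (seeded) parameters.
#'
#' @param input_size square input side, a multiple of 32 (default 608).
#' @param classes character vector of class names (default "grape").
#' @param anchors an \linkS4class{AnchorSet} (9 anchors); a generic default
#'   scaled to the input size is used if omitted.
#' @param base_channels stem width; 32 reproduces the full-size backbone
#'   (stage widths 64/128/256/512/1024), smaller values give reduced models
#'   for desk-scale experiments.
#' @param stage_repeats residual-block counts of the five stages,
#'   default c(1, 2, 8, 8, 4).
#' @param attention logical (SimAM on/off), or a logical vector of length 5
#'   for a per-stage mask.
#' @param lambda SimAM energy regularization, default 1e-4.
#' @param seed RNG seed for weight initialization.
#' @return A \linkS4class{YoloModel}.
#' @export
yoloModel <- function(input_size = 608L, classes = "grape", anchors = NULL,
                      base_channels = 32L, stage_repeats = c(1L, 2L, 8L, 8L, 4L),
                      attention = TRUE, lambda = 1e-4, seed = 0L) {
  input_size <- as.integer(input_size)
  if (input_size %% 32L != 0L) stop("input_size must be a multiple of 32")
  if (length(stage_repeats) != 5L) stop("stage_repeats must have length 5")
  att <- if (length(attention) == 1L) rep(attention, 5L) else attention
  if (length(att) != 5L) stop("attention must be length 1 or 5")
  if (is.null(anchors)) anchors <- default_anchor_set(input_size)
  num_classes <- length(classes)
  cfg <- list(input_size = input_size, classes = classes,
              num_classes = num_classes, base_channels = as.integer(base_channels),
              stage_repeats = as.integer(stage_repeats), attention = att,
              lambda = lambda, anchors = anchors, seed = as.integer(seed))
  net <- new_net()
  with_local_seed(seed, build_graph(net, cfg))
  methods::new("YoloModel", config = cfg, net = net)
}

build_graph <- function(net, cfg) {
  b <- cfg$base_channels
  cs <- b * c(2L, 4L, 8L, 16L, 32L)      # stage output widths
  stem <- conv_block(net, "backbone.stem", 3L, b, k = 3L)
  stages <- lapply(1:5, function(i) {
    csp_stage(net, sprintf("backbone.stage%d", i),
              cin = if (i == 1L) b else cs[i - 1L], cout = cs[i],
              n_blocks = cfg$stage_repeats[i], attention = cfg$attention[i],
              lambda = cfg$lambda)
  })
  n5 <- cs[5] %/% 2L; n4 <- cs[4] %/% 2L; n3 <- cs[3] %/% 2L
  spp <- spp_block(net, "neck.spp", cs[5])                 # -> n5 channels
  td5 <- conv_block(net, "neck.td5", n5, n4, k = 1L, act = "leaky")
  proj4 <- conv_block(net, "neck.proj4", cs[4], n4, k = 1L, act = "leaky")
  fuse4 <- fusion_node(net, "neck.fuse4", 2L)
  mid4 <- five_conv(net, "neck.mid4", n4)
  td4 <- conv_block(net, "neck.td4", n4, n3, k = 1L, act = "leaky")
  proj3 <- conv_block(net, "neck.proj3", cs[3], n3, k = 1L, act = "leaky")
  fuse3 <- fusion_node(net, "neck.fuse3", 2L)
  out3 <- five_conv(net, "neck.out3", n3)
  down3 <- conv_block(net, "neck.down3", n3, n4, k = 3L, stride = 2L, act = "leaky")
  fuse4b <- fusion_node(net, "neck.fuse4b", 3L)            # w0 P4'' + w1 Down(P3'') + w2 P4
  group4 <- conv_group(net, "neck.group4", n4, n4)
  down4 <- conv_block(net, "neck.down4", n4, n5, k = 3L, stride = 2L, act = "leaky")
  group5 <- conv_group(net, "neck.group5", 2L * n5, n5)
  hc <- 3L * (5L + cfg$num_classes)
  head3a <- conv_block(net, "head.p3.conv", n3, 2L * n3, k = 3L, act = "leaky")
  head3b <- conv_block(net, "head.p3.out", 2L * n3, hc, k = 1L, act = "linear", bn = FALSE)
  head4a <- conv_block(net, "head.p4.conv", n4, 2L * n4, k = 3L, act = "leaky")
  head4b <- conv_block(net, "head.p4.out", 2L * n4, hc, k = 1L, act = "linear", bn = FALSE)
  head5a <- conv_block(net, "head.p5.conv", n5, 2L * n5, k = 3L, act = "leaky")
  head5b <- conv_block(net, "head.p5.out", 2L * n5, hc, k = 1L, act = "linear", bn = FALSE)

  net$backbone_forward <- function(x, training = FALSE) {
    y <- stem(x, training)
    taps <- vector("list", 5L)
    for (i in 1:5) {
      y <- stages[[i]](y, training)
      taps[[i]] <- y
    }
    list(P3 = taps[[3]], P4 = taps[[4]], P5 = taps[[5]])
  }
  net$spp_forward <- function(P5, training = FALSE) spp(P5, training)
  net$neck_forward <- function(P3, P4, P5s, training = FALSE) {
    u5 <- ad_upsample2(td5(P5s, training))
    p4p <- proj4(P4, training)
    m4 <- mid4(fuse4(list(u5, p4p)), training)             # P4''
    u4 <- ad_upsample2(td4(m4, training))
    p3p <- proj3(P3, training)
    o3 <- out3(fuse3(list(u4, p3p)), training)             # P3'' (output, 76x76)
    d3 <- down3(o3, training)
    o4 <- group4(fuse4b(list(m4, d3, p4p)), training)      # P4'''' (38x38)
    d4 <- down4(o4, training)
    o5 <- group5(ad_concat_c(list(d4, P5s)), training)     # P5'''' (19x19)
    list(P3 = o3, P4 = o4, P5 = o5)
  }
  net$head_forward <- function(fused, training = FALSE) {
    list(P3 = head3b(head3a(fused$P3, training), training),
         P4 = head4b(head4a(fused$P4, training), training),
         P5 = head5b(head5a(fused$P5, training), training))
  }
  invisible(net)
}

check_input <- function(model, image) {
  assert_image(image)
  d <- dim(image)
  sz <- model@config$input_size
  if (d[1] != sz || d[2] != sz || d[3] != 3L)
    stop(sprintf("expected a %dx%dx3 input, got %dx%dx%d", sz, sz, d[1], d[2], d[3]))
}

#' Backbone forward pass
#'
#' Runs the five CSP stages and returns the three tap feature grids
#' (strides 8, 16, 32) as plain arrays.
#'
#' @param model a \linkS4class{YoloModel}.
#' @param image (S, S, 3) array with S = the model's input size, values
#'   either [0, 255] (scaled internally) or already [0, 1].
#' @return list(P3, P4, P5) of (H, W, C) arrays.
#' @export
backboneForward <- function(model, image) {
  check_input(model, image)
  x <- normalize_input(image)
  taps <- ad_no_grad(model@net$backbone_forward(ad_tensor(x), training = FALSE))
  lapply(taps, function(t) t$value)
}

#' SPP forward pass
#'
#' @param model a \linkS4class{YoloModel}.
#' @param P5 deepest backbone tap, (S/32, S/32, C5) array.
#' @return array with the same spatial size and C5/2 channels.
#' @export
sppForward <- function(model, P5) {
  ad_no_grad(model@net$spp_forward(ad_tensor(P5), training = FALSE))$value
}

#' Weighted-fusion neck forward pass
#'
#' Top-down fusion with learned fast-normalized weights, then the bottom-up
#' path whose stride-16 node combines the top-down mid map, the downsampled
#' fine output and a jump connection from the backbone tap.
#'
#' @param model a \linkS4class{YoloModel}.
#' @param P3,P4 backbone taps (arrays); \code{P5s} the SPP output.
#' @param P5s SPP-processed deepest tap.
#' @return list(P3, P4, P5) fused arrays at strides 8/16/32.
#' @export
panplusForward <- function(model, P3, P4, P5s) {
  out <- ad_no_grad(model@net$neck_forward(ad_tensor(P3), ad_tensor(P4),
                                           ad_tensor(P5s), training = FALSE))
  lapply(out, function(t) t$value)
}

#' YOLO head forward pass
#'
#' @param model a \linkS4class{YoloModel}.
#' @param fused list(P3, P4, P5) of fused arrays.
#' @return list of raw prediction grids, each with 3 * (5 + C) channels.
#' @export
yoloHeadForward <- function(model, fused) {
  tf <- lapply(fused, ad_tensor)
  out <- ad_no_grad(model@net$head_forward(tf, training = FALSE))
  lapply(out, function(t) t$value)
}

normalize_input <- function(image) {
  if (max(image) > 1.5) image / 255 else image
}

# full forward to raw head grids; tensors when training (for the loss),
# plain arrays otherwise
model_forward <- function(model, image, training = FALSE) {
  check_input(model, image)
  run <- function() {
    net <- model@net
    x <- ad_tensor(normalize_input(image))
    taps <- net$backbone_forward(x, training)
    p5s <- net$spp_forward(taps$P5, training)
    fused <- net$neck_forward(taps$P3, taps$P4, p5s, training)
    net$head_forward(fused, training)
  }
  if (training) run() else lapply(ad_no_grad(run()), function(t) t$value)
}

#' Raw prediction grids for an input image
#'
#' Runs the whole network in inference mode.
#'
#' @param model a \linkS4class{YoloModel}.
#' @param image (S, S, 3) array at the model input size.
#' @return list(P3, P4, P5) raw head arrays.
#' @export
forwardNetwork <- function(model, image) model_forward(model, image, training = FALSE)
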