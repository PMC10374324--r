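# Weight checkpointing and YAML run configuration.

#' Save model weights
#'
#' Writes the architecture configuration, all parameter values and the
#' batch-norm running statistics to an RDS file.
#'
#' @param model a \linkS4class{YoloModel}.
#' @param path output file.
#' @export
saveModelWeights <- function(model, path) {
  net <- model@net
  saveRDS(list(
    config = model@config,
    params = lapply(net$params, function(p) p$value),
    state = lapply(net$state, function(s) list(running_mean = s$running_mean,
                                               running_var = s$running_var))),
    path)
  invisible(path)
}

#' Load model weights
#'
#' Rebuilds the architecture recorded in the checkpoint and restores its
#' parameters and batch-norm statistics.
#'
#' @param path checkpoint written by \code{\link{saveModelWeights}}.
#' @return a \linkS4class{YoloModel}.
#' @export
loadModelWeights <- function(path) {
  ck <- readRDS(path)
  cfg <- ck$config
  model <- yoloModel(input_size = cfg$input_size, classes = cfg$classes,
                     anchors = cfg$anchors, base_channels = cfg$base_channels,
                     stage_repeats = cfg$stage_repeats,
                     attention = cfg$attention, lambda = cfg$lambda,
                     seed = cfg$seed)
  net <- model@net
  if (!setequal(names(net$params), names(ck$params)))
    stop("checkpoint parameters do not match the rebuilt architecture")
  for (nm in names(ck$params)) net$params[[nm]]$value <- ck$params[[nm]]
  for (nm in names(ck$state)) {
    net$state[[nm]]$running_mean <- ck$state[[nm]]$running_mean
    net$state[[nm]]$running_var <- ck$state[[nm]]$running_var
  }
  model
}

#' Read a YAML run configuration
#'
#' Builds the model, schedule and loss configuration from one YAML file.
#' Recognized blocks: \code{model} (input_size, classes, base_channels,
#' stage_repeats, attention, anchors file), \code{schedule} (stage1,
#' stage2, scale_range, mosaic, seed) and \code{loss} (focal alpha / gamma /
#' enabled, label_smoothing, lambda_conf/cls/loc).
#'
#' @param path YAML file.
#' @param seed weight-init seed override (optional).
#' @return list(model, schedule, loss_cfg).
#' @export
readRunConfig <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  m <- y$model %||% list()
  anch <- NULL
  if (!is.null(m$anchors_file)) anch <- readAnchorsYaml(m$anchors_file)
  model <- yoloModel(
    input_size = m$input_size %||% 608L,
    classes = m$classes %||% "grape",
    anchors = anch,
    base_channels = m$base_channels %||% 32L,
    stage_repeats = unlist(m$stage_repeats %||% c(1L, 2L, 8L, 8L, 4L)),
    attention = m$attention %||% TRUE,
    seed = seed %||% (y$seed %||% 0L))
  s <- y$schedule %||% list()
  # a key present but set to null disables the stage; a missing key keeps
  # the default
  stage_or <- function(key, default) {
    if (key %in% names(s)) s[[key]] else default
  }
  schedule <- trainingSchedule(
    stage1 = stage_or("stage1",
                      list(epochs = 30L, batch = 8L, lr0 = 1e-3, frozen = TRUE)),
    stage2 = stage_or("stage2",
                      list(epochs = 10L, batch = 2L, lr0 = 1e-4, frozen = FALSE)),
    scale_range = unlist(s$scale_range %||% c(0.7, 0.9)),
    mosaic = s$mosaic %||% FALSE,
    seed = s$seed %||% (y$seed %||% 0L))
  l <- y$loss %||% list()
  f <- l$focal %||% list()
  loss_cfg <- lossConfig(
    lambda_conf = l$lambda_conf %||% 1, lambda_cls = l$lambda_cls %||% 1,
    lambda_loc = l$lambda_loc %||% 1,
    label_smoothing = l$label_smoothing %||% 0.005,
    focal = focalConfig(alpha = f$alpha %||% 0.75, gamma = f$gamma %||% 2,
                        enabled = f$enabled %||% TRUE))
  list(model = model, schedule = schedule, loss_cfg = loss_cfg)
}

#' Write anchors to YAML
#'
#' @param anchors an \linkS4class{AnchorSet}.
#' @param path output .yaml file.
#' @export
writeAnchorsYaml <- function(anchors, path) {
  a <- anchors(anchors)
  yaml::write_yaml(list(anchors = lapply(seq_len(nrow(a)), function(i) {
    list(width = a$width[i], height = a$height[i])
  }), accuracy = clusterAccuracy(anchors)), path)
  invisible(path)
}

#' Read anchors from YAML
#'
#' @param path file written by \code{\link{writeAnchorsYaml}}.
#' @return an \linkS4class{AnchorSet}.
#' @export
readAnchorsYaml <- function(path) {
  y <- yaml::read_yaml(path)
  w <- vapply(y$anchors, function(a) a$width, 0)
  h <- vapply(y$anchors, function(a) a$height, 0)
  anchorSet(w, h, accuracy = y$accuracy %||% NA_real_)
}
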