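test_that("cosine annealing hits its endpoints and midpoint", {
  expect_equal(cosineLr(0, 100, 1e-3), 1e-3)
  expect_equal(cosineLr(100, 100, 1e-3), 1e-5)
  expect_equal(cosineLr(50, 100, 1e-3), (1e-3 + 1e-5) / 2)
  expect_equal(cosineLr(250, 100, 1e-3), 1e-5)   # clamped past the end
  expect_error(cosineLr(-1, 100, 1e-3), "non-negative")
})

test_that("random-scale resize is a seeded similarity transform", {
  img <- rand_image(64)
  boxes <- data.frame(xmin = 10, ymin = 12, xmax = 34, ymax = 40,
                      class = "grape")
  # collapsed range: a plain letterbox
  plain <- randomScaleResize(img, boxes, 96L, scale_range = c(1, 1), seed = 1)
  lb <- letterboxImage(img, 96L)
  expect_equal(plain$image, lb$image)
  r1 <- randomScaleResize(img, boxes, 96L, seed = 7)
  r2 <- randomScaleResize(img, boxes, 96L, seed = 7)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$boxes, r2$boxes)
  # box area scales by exactly s^2 relative to the plain letterbox
  a0 <- (plain$boxes$xmax - plain$boxes$xmin) * (plain$boxes$ymax - plain$boxes$ymin)
  a1 <- (r1$boxes$xmax - r1$boxes$xmin) * (r1$boxes$ymax - r1$boxes$ymin)
  expect_equal(a1 / a0, r1$scale^2, tolerance = 1e-12)
  expect_true(r1$scale >= 0.7 && r1$scale <= 0.9)
})

test_that("stage 1 freezes the backbone bit-for-bit", {
  fx <- smoke_fixture()
  m <- tiny_model(anchors = fx$anchors)
  before <- lapply(m@net$params[grep("^backbone\\.", names(m@net$params))],
                   function(p) p$value)
  ds <- list(list(image = fx$s1$image, annotation = fx$s1$annotation))
  sch <- trainingSchedule(stage1 = list(epochs = 2L, batch = 1L, lr0 = 1e-3,
                                        frozen = TRUE),
                          stage2 = NULL, scale_range = NULL, seed = 1)
  fit <- fitYolo(m, ds, sch, lossConfig())
  after <- lapply(m@net$params[grep("^backbone\\.", names(m@net$params))],
                  function(p) p$value)
  expect_identical(before, after)
  # neck weights did move
  expect_false(identical(m@net$params[["neck.mid4.c1.w"]]$value,
                         tiny_model(anchors = fx$anchors)@net$params[["neck.mid4.c1.w"]]$value))
  expect_equal(nrow(fit$history), 2L)
  expect_error(fitYolo(m, list(), sch), "empty")
})

test_that("training histories are reproducible under a fixed seed", {
  fx <- smoke_fixture()
  ds <- list(list(image = fx$s1$image, annotation = fx$s1$annotation),
             list(image = fx$s2$image, annotation = fx$s2$annotation))
  sch <- trainingSchedule(stage1 = list(epochs = 3L, batch = 2L, lr0 = 1e-3,
                                        frozen = FALSE),
                          stage2 = NULL, scale_range = c(0.7, 0.9), seed = 4)
  h1 <- fitYolo(tiny_model(anchors = fx$anchors), ds, sch, lossConfig())$history
  h2 <- fitYolo(tiny_model(anchors = fx$anchors), ds, sch, lossConfig())$history
  expect_identical(h1, h2)
  # two-stage run: history covers both stages and the lr restarts
  sch2 <- trainingSchedule(stage1 = list(epochs = 2L, batch = 2L, lr0 = 1e-3,
                                         frozen = TRUE),
                           stage2 = list(epochs = 2L, batch = 1L, lr0 = 1e-4,
                                         frozen = FALSE),
                           scale_range = NULL, seed = 4)
  h3 <- fitYolo(tiny_model(anchors = fx$anchors), ds, sch2, lossConfig())$history
  expect_equal(nrow(h3), 4L)
  expect_equal(h3$stage, c(1, 1, 2, 2))
  expect_lt(max(h3$lr[h3$stage == 2]), min(1e-3, h3$lr[1]))
})

test_that("toggling focal loss changes only the conf and cls components", {
  fx <- smoke_fixture()
  an <- fx$anchors
  boxes <- data.frame(xmin = c(10, 40), ymin = c(12, 50),
                      xmax = c(26, 60), ymax = c(34, 80), class = "grape")
  tg <- buildTargets(boxes, an, 96L, "grape")
  set.seed(41)
  heads <- lapply(tg, function(t) array(rnorm(t$S^2 * 18, sd = 0.5),
                                        c(t$S, t$S, 18)))
  on <- totalLoss(heads, tg, an, lossConfig(), 1L)
  off <- totalLoss(heads, tg, an,
                   lossConfig(focal = focalConfig(enabled = FALSE)), 1L)
  expect_equal(on$components["loc"], off$components["loc"], tolerance = 1e-12)
  expect_false(isTRUE(all.equal(on$components["conf"], off$components["conf"])))
})

test_that("mosaic composition keeps boxes inside their quadrants", {
  fx <- smoke_fixture()
  ds <- list(list(image = fx$s1$image, annotation = fx$s1$annotation),
             list(image = fx$s2$image, annotation = fx$s2$annotation))
  ms <- gd$mosaic_sample(ds, 96L, seed = 2)
  expect_equal(dim(ms$image), c(96, 96, 3))
  if (nrow(ms$boxes)) {
    expect_true(all(ms$boxes$xmin >= 0 & ms$boxes$xmax <= 96))
    expect_true(all(ms$boxes$ymin >= 0 & ms$boxes$ymax <= 96))
    expect_true(all(ms$boxes$xmax > ms$boxes$xmin))
  }
  ms2 <- gd$mosaic_sample(ds, 96L, seed = 2)
  expect_identical(ms, ms2)
})

test_that("YAML run configuration and anchors round-trip", {
  fx <- smoke_fixture()
  fa <- withr::local_tempfile(fileext = ".yaml")
  writeAnchorsYaml(fx$anchors, fa)
  back <- readAnchorsYaml(fa)
  expect_equal(anchors(back), anchors(fx$anchors), tolerance = 1e-6)
  fy <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "model:", "  input_size: 96", "  base_channels: 8",
    "  stage_repeats: [1, 1, 1, 1, 1]",
    sprintf("  anchors_file: %s", fa),
    "schedule:",
    "  stage1: {epochs: 1, batch: 2, lr0: 0.001, frozen: true}",
    "  stage2: ~",
    "  scale_range: [0.7, 0.9]",
    "loss:", "  label_smoothing: 0.005",
    "  focal: {alpha: 0.75, gamma: 2}",
    "seed: 3"), fy)
  run <- readRunConfig(fy)
  expect_equal(modelConfig(run$model)$input_size, 96L)
  expect_equal(anchors(modelConfig(run$model)$anchors), anchors(fx$anchors),
               tolerance = 1e-6)
  expect_equal(run$loss_cfg$focal$alpha, 0.75)
  expect_equal(length(run$schedule$stages), 1L)
})
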