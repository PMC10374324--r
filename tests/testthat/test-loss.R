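test_that("focal BCE evaluates its closed forms", {
  expect_equal(focalBce(0.5, 1), 0.75 * 0.25 * log(2), tolerance = 1e-12)
  expect_equal(round(focalBce(0.5, 1), 4), 0.1300)
  expect_lt(focalBce(1 - 1e-7, 1), 1e-12)
  # gamma = 0, alpha = 0.5 halves the plain BCE everywhere
  grid <- expand.grid(p = seq(0.05, 0.95, by = 0.1), y = c(0, 1))
  bce <- -(grid$y * log(grid$p) + (1 - grid$y) * log(1 - grid$p))
  expect_equal(focalBce(grid$p, grid$y, alpha = 0.5, gamma = 0), 0.5 * bce,
               tolerance = 1e-12)
})

test_that("focal modulation down-weights easy positives more", {
  bce <- function(p) -log(p)
  r_easy <- focalBce(0.9, 1) / bce(0.9)
  r_hard <- focalBce(0.6, 1) / bce(0.6)
  expect_lt(r_easy, r_hard)
})

test_that("CIoU loss evaluates its closed forms", {
  expect_equal(ciouLoss(c(3, 4, 10, 12), c(3, 4, 10, 12)), 0)
  # hand evaluation: IoU = 1/7, rho^2 = 2, c^2 = 18, equal aspect so v = 0
  expect_equal(ciouLoss(c(0, 0, 2, 2), c(1, 1, 3, 3)), 1 - 1 / 7 + 2 / 18,
               tolerance = 1e-12)
  expect_equal(ciouLoss(c(0, 0, 2, 2), c(1, 1, 3, 3)), 0.9683, tolerance = 1e-4)
  # same aspect ratio at different scale: the v term vanishes
  a <- c(0, 0, 4, 8); b <- c(1, 2, 3, 6)
  iou <- boxIoU(a, b)
  rho2 <- (2 - 2)^2 + (4 - 4)^2
  expect_equal(ciouLoss(a, b), 1 - iou + rho2 / (4^2 + 8^2), tolerance = 1e-12)
})

test_that("CIoU is bounded below by the IoU shortfall", {
  with_seed_test(8, {
    for (i in 1:30) {
      a <- c(runif(2, 0, 30), 0, 0); a[3] <- a[1] + runif(1, 1, 20)
      a[4] <- a[2] + runif(1, 1, 20)
      b <- c(runif(2, 0, 30), 0, 0); b[3] <- b[1] + runif(1, 1, 20)
      b[4] <- b[2] + runif(1, 1, 20)
      expect_gte(ciouLoss(a, b), 1 - boxIoU(a, b) - 1e-12)
    }
  })
})

test_that("gradient descent on CIoU aligns a box within 500 steps", {
  # single toy pair, Adam on the raw (tx, ty, tw, th) parametrization
  ps <- lapply(c(0.4, -0.6, 0.7, -0.7), function(v) gd$ad_param(array(v, c(1, 1, 1))))
  gt <- list(gx = array(13, c(1, 1, 1)), gy = array(17, c(1, 1, 1)),
             gw = array(14, c(1, 1, 1)), gh = array(18, c(1, 1, 1)))
  opt <- list(m = rep(0, 4), v = rep(0, 4))
  for (it in 1:500) {
    px <- gd$ad_scale(gd$ad_add(gd$ad_sigmoid(ps[[1]]), gd$ad_tensor(array(1, c(1, 1, 1)))), 8)
    py <- gd$ad_scale(gd$ad_add(gd$ad_sigmoid(ps[[2]]), gd$ad_tensor(array(2, c(1, 1, 1)))), 8)
    pw <- gd$ad_scale(gd$ad_exp(ps[[3]]), 10)
    ph <- gd$ad_scale(gd$ad_exp(ps[[4]]), 14)
    ci <- gd$ad_ciou_grid(px, py, pw, ph, gt$gx, gt$gy, gt$gw, gt$gh)
    for (p in ps) p$grad <- NULL
    gd$ad_backward(ci)
    for (j in 1:4) {
      g <- as.numeric(ps[[j]]$grad)
      opt$m[j] <- 0.9 * opt$m[j] + 0.1 * g
      opt$v[j] <- 0.999 * opt$v[j] + 0.001 * g^2
      ps[[j]]$value <- ps[[j]]$value -
        0.02 * (opt$m[j] / (1 - 0.9^it)) / (sqrt(opt$v[j] / (1 - 0.999^it)) + 1e-8)
    }
  }
  ctr <- c((plogis(ps[[1]]$value) + 1) * 8, (plogis(ps[[2]]$value) + 2) * 8)
  wh <- c(exp(ps[[3]]$value) * 10, exp(ps[[4]]$value) * 14)
  pb <- c(ctr[1] - wh[1] / 2, ctr[2] - wh[2] / 2,
          ctr[1] + wh[1] / 2, ctr[2] + wh[2] / 2)
  expect_gt(boxIoU(pb, c(6, 8, 20, 26)), 0.99)
})

test_that("target assignment places each box at one cell on one scale", {
  an <- anchorSet(rep(c(6, 10, 16), 3), rep(c(8, 14, 20), 3))
  boxes <- data.frame(xmin = 6, ymin = 8, xmax = 20, ymax = 26, class = "grape")
  tg <- buildTargets(boxes, an, 32L, "grape")
  expect_equal(sum(vapply(tg, function(t) sum(t$obj), 0)), 1)
  # empty annotation: all-noobj masks on every scale
  tg0 <- buildTargets(boxes[0, ], an, 32L, "grape")
  for (t in tg0) {
    expect_equal(sum(t$obj), 0)
    expect_equal(sum(t$noobj), length(t$noobj))
  }
  # two boxes in different cells give two disjoint obj entries
  boxes2 <- rbind(boxes,
                  data.frame(xmin = 22, ymin = 6, xmax = 30, ymax = 18,
                             class = "grape"))
  tg2 <- buildTargets(boxes2, an, 32L, "grape")
  expect_equal(sum(vapply(tg2, function(t) sum(t$obj), 0)), 2)
  for (t in tg2) expect_true(all(t$obj + (1 - t$noobj) <= 1 + 1e-12 | t$obj == 1))
  # obj and noobj masks are disjoint
  for (t in tg2) expect_equal(sum(t$obj * t$noobj), 0)
  expect_error(buildTargets(data.frame(xmin = -40, ymin = 2, xmax = -10,
                                       ymax = 12, class = "grape"),
                            an, 32L, "grape"))
})

test_that("confidence loss equals a brute-force per-cell summation", {
  an <- anchorSet(rep(c(6, 10, 16), 3), rep(c(8, 14, 20), 3))
  boxes <- data.frame(xmin = 6, ymin = 8, xmax = 20, ymax = 26, class = "grape")
  tg <- buildTargets(boxes, an, 32L, "grape")
  cfg <- lossConfig()
  set.seed(21)
  for (g in 1:3) {
    t1 <- tg[[g]]
    h <- array(rnorm(t1$S^2 * 18), c(t1$S, t1$S, 18))
    ours <- confidenceLoss(h, t1, cfg, 1L)
    brute <- 0
    for (iy in seq_len(t1$S)) for (ix in seq_len(t1$S)) for (a in 1:3) {
      p <- plogis(h[iy, ix, (a - 1) * 6 + 5])
      if (t1$obj[iy, ix, a] == 1) brute <- brute + focalBce(p, 1)
      else if (t1$noobj[iy, ix, a] == 1) brute <- brute + focalBce(p, 0)
    }
    expect_equal(ours, brute, tolerance = 1e-10)
  }
  # an empty image leaves only the no-object term
  tg0 <- buildTargets(boxes[0, ], an, 32L, "grape")
  h <- array(rnorm(4 * 4 * 18), c(4, 4, 18))
  ours0 <- confidenceLoss(h, tg0[[1]], cfg, 1L)
  probs <- plogis(h[, , c(5, 11, 17)])
  expect_equal(ours0, sum(focalBce(probs, 0)), tolerance = 1e-10)
})

test_that("classification loss smooths labels and vanishes without objects", {
  eps <- 0.005
  expect_equal(1 - eps / 2, 0.9975)
  an <- anchorSet(rep(c(6, 10, 16), 3), rep(c(8, 14, 20), 3))
  boxes <- data.frame(xmin = 6, ymin = 8, xmax = 20, ymax = 26, class = "grape")
  tg <- buildTargets(boxes, an, 32L, "grape")
  g <- which(vapply(tg, function(t) sum(t$obj), 0) == 1)
  t1 <- tg[[g]]
  set.seed(22)
  h <- array(rnorm(t1$S^2 * 18), c(t1$S, t1$S, 18))
  cfg <- lossConfig()
  ours <- classificationLoss(h, t1, cfg, 1L)
  idx <- which(t1$obj == 1, arr.ind = TRUE)[1, ]
  p <- plogis(h[idx[1], idx[2], (idx[3] - 1) * 6 + 6])
  expect_equal(ours, focalBce(p, 0.9975), tolerance = 1e-10)
  # no objects at all: zero classification loss
  tg0 <- buildTargets(boxes[0, ], an, 32L, "grape")
  expect_equal(classificationLoss(h, tg0[[g]], cfg, 1L), 0)
  # eps = 0 reduces to the plain (focal-weighted) target of 1
  cfg0 <- lossConfig(label_smoothing = 0)
  expect_equal(classificationLoss(h, t1, cfg0, 1L), focalBce(p, 1),
               tolerance = 1e-10)
})

test_that("total loss composes its per-scale terms and honours the lambdas", {
  fx <- smoke_fixture()
  an <- fx$anchors
  boxes <- data.frame(xmin = c(10, 40), ymin = c(12, 50),
                      xmax = c(26, 60), ymax = c(34, 80), class = "grape")
  tg <- buildTargets(boxes, an, 96L, "grape")
  set.seed(23)
  heads <- lapply(tg, function(t) array(rnorm(t$S^2 * 18, sd = 0.5),
                                        c(t$S, t$S, 18)))
  cfg <- lossConfig()
  l <- totalLoss(heads, tg, an, cfg, 1L, batch_size = 2)
  expect_equal(l$total, sum(l$components), tolerance = 1e-10)
  expect_true(all(l$components >= 0))
  # lambda_loc = 0 removes the location term exactly
  l0 <- totalLoss(heads, tg, an, lossConfig(lambda_loc = 0), 1L, batch_size = 2)
  expect_equal(l0$total, unname(l$total - l$components["loc"]), tolerance = 1e-10)
  # batch division is exact
  l1 <- totalLoss(heads, tg, an, cfg, 1L, batch_size = 1)
  expect_equal(l$total, l1$total / 2, tolerance = 1e-12)
})
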