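test_that("zero logits decode to cell centers with the anchor's size", {
  S <- 4L; C <- 1L
  grid <- array(0, c(S, S, 18))
  anc <- rbind(c(10, 14), c(20, 24), c(30, 40))
  dets <- decodeGrid(grid, anc, stride = 8L, classes = "grape", imageId = "z")
  # cell (0,0), anchor 1: center at stride/2, exact anchor size
  first <- dets[abs(dets$xmin - (4 - 5)) < 1e-9 &
                  abs(dets$ymin - (4 - 7)) < 1e-9, ][1, ]
  expect_equal(first$xmax - first$xmin, 10)
  expect_equal(first$ymax - first$ymin, 14)
  expect_equal(unique(round(dets$score, 10)), 0.25)  # sigmoid(0)^2
  # strongly negative objectness drives scores to ~0
  grid[, , 5] <- -40
  d2 <- decodeGrid(grid, anc, 8L, "grape")
  expect_lt(max(d2$score[seq_len(S * S)]), 1e-15)
  expect_error(decodeGrid(array(0, c(4, 4, 17)), anc, 8L, "grape"), "channels")
})

test_that("decoding inverts the target encoding", {
  fx <- smoke_fixture()
  an <- fx$anchors
  am <- as.matrix(anchors(an))
  box <- data.frame(xmin = 18, ymin = 22, xmax = 42, ymax = 58, class = "grape")
  tg <- buildTargets(box, an, 96L, "grape")
  g <- which(vapply(tg, function(t) sum(t$obj), 0) == 1)
  t1 <- tg[[g]]
  idx <- which(t1$obj == 1, arr.ind = TRUE)[1, ]   # (iy, ix, a)
  stride <- t1$stride
  aidx <- (g - 1) * 3 + idx[3]
  cx <- (box$xmin + box$xmax) / 2; cy <- (box$ymin + box$ymax) / 2
  grid <- array(-40, c(t1$S, t1$S, 18))            # objectness off everywhere
  off <- (idx[3] - 1) * 6
  grid[idx[1], idx[2], off + 1] <- qlogis(cx / stride - (idx[2] - 1))
  grid[idx[1], idx[2], off + 2] <- qlogis(cy / stride - (idx[1] - 1))
  grid[idx[1], idx[2], off + 3] <- log((box$xmax - box$xmin) / am[aidx, 1])
  grid[idx[1], idx[2], off + 4] <- log((box$ymax - box$ymin) / am[aidx, 2])
  grid[idx[1], idx[2], off + 5] <- 40
  grid[idx[1], idx[2], off + 6] <- 40
  dets <- decodeGrid(grid, am[(g - 1) * 3 + 1:3, ], stride, "grape")
  top <- dets[which.max(dets$score), ]
  expect_equal(as.numeric(top[c("xmin", "ymin", "xmax", "ymax")]),
               as.numeric(box[1, 1:4]), tolerance = 1e-4)
})

test_that("NMS keeps a score-sorted subset with bounded overlap", {
  expect_equal(nrow(nonMaxSuppression(NULL)), 0L)
  d <- data.frame(imageId = "a", class = "grape", score = c(0.9, 0.8),
                  xmin = c(0, 1), ymin = c(0, 1), xmax = c(10, 11),
                  ymax = c(10, 11))
  expect_gt(boxIoU(as.numeric(d[1, 4:7]), as.numeric(d[2, 4:7])), 0.45)
  kept <- nonMaxSuppression(d, 0.45, 0.5)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$score, 0.9)
  # disjoint boxes all survive
  d2 <- data.frame(imageId = "a", class = "grape", score = c(0.9, 0.7, 0.6),
                   xmin = c(0, 20, 40), ymin = 0, xmax = c(10, 30, 50), ymax = 10)
  expect_equal(nrow(nonMaxSuppression(d2, 0.45, 0.5)), 3L)
  # property: subset, sorted, pairwise IoU below threshold
  with_seed_test(9, {
    n <- 40
    dd <- data.frame(imageId = "a", class = "grape", score = runif(n),
                     xmin = runif(n, 0, 50), ymin = runif(n, 0, 50))
    dd$xmax <- dd$xmin + runif(n, 5, 25); dd$ymax <- dd$ymin + runif(n, 5, 25)
    kept <- nonMaxSuppression(dd, 0.45, 0.2)
    expect_true(all(kept$score %in% dd$score))
    expect_true(!is.unsorted(rev(kept$score)))
    if (nrow(kept) > 1) {
      for (i in 1:(nrow(kept) - 1)) for (j in (i + 1):nrow(kept)) {
        expect_lte(boxIoU(as.numeric(kept[i, 4:7]), as.numeric(kept[j, 4:7])),
                   0.45)
      }
    }
  })
})

test_that("letterbox mapping round-trips boxes within a pixel", {
  img <- rand_image(96)[1:60, , ]   # non-square 60 x 96
  lb <- letterboxImage(img, 96L)
  expect_equal(dim(lb$image), c(96, 96, 3))
  boxes <- data.frame(xmin = c(5, 40), ymin = c(8, 20), xmax = c(30, 90),
                      ymax = c(25, 55), class = "grape")
  fwd <- boxes
  fwd$xmin <- fwd$xmin * lb$scale + lb$pad_x
  fwd$xmax <- fwd$xmax * lb$scale + lb$pad_x
  fwd$ymin <- fwd$ymin * lb$scale + lb$pad_y
  fwd$ymax <- fwd$ymax * lb$scale + lb$pad_y
  back <- gd$unletterbox_boxes(fwd, lb, 96, 60)
  expect_equal(back$xmin, boxes$xmin, tolerance = 1)
  expect_equal(back$ymax, boxes$ymax, tolerance = 1)
})

test_that("detection output is clipped, deterministic and file-readable", {
  fx <- smoke_fixture()
  m <- tiny_model(anchors = fx$anchors)
  img <- fx$s1$image
  d1 <- detectObjects(m, img, conf_threshold = 0.2)
  d2 <- detectObjects(m, img, conf_threshold = 0.2)
  expect_identical(d1, d2)
  if (nrow(d1)) {
    expect_true(all(d1$xmin >= 0 & d1$xmax <= dim(img)[2]))
    expect_true(all(d1$ymin >= 0 & d1$ymax <= dim(img)[1]))
  }
  f <- withr::local_tempfile(fileext = ".png")
  writeImageArray(img, f)
  d3 <- detectObjects(m, f, conf_threshold = 0.2)
  expect_true(all(c("imageId", "class", "score", "xmin", "ymin", "xmax",
                    "ymax") %in% names(d3)))
  expect_error(detectObjects(m, "no_such_file.png"), "cannot read")
})
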