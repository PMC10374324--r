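test_that("precision, recall and F1 reproduce the foggy-weather table rows", {
  for (i in seq_len(nrow(table7))) {
    r <- table7[i, ]
    prf <- precisionRecallF1(r$tp, r$fp, r$fn)
    expect_equal(round(100 * unname(prf["precision"]), 2), r$precision)
    expect_equal(round(100 * unname(prf["recall"]), 2), r$recall)
    expect_equal(round(100 * unname(prf["f1"]), 2), r$f1)
  }
  expect_equal(unname(precisionRecallF1(0, 5, 5)), c(0, 0, 0))
  expect_error(precisionRecallF1(0, 0, 0, zero_division = FALSE), "denominator")
  expect_error(precisionRecallF1(-1, 0, 0), "non-negative")
})

gts2 <- data.frame(imageId = "a", class = "grape",
                   xmin = c(0, 50), ymin = c(0, 50),
                   xmax = c(10, 60), ymax = c(10, 60))

det_row <- function(score, box, id = "a") {
  data.frame(imageId = id, class = "grape", score = score,
             xmin = box[1], ymin = box[2], xmax = box[3], ymax = box[4])
}

test_that("matching follows the greedy VOC protocol", {
  perfect <- rbind(det_row(0.9, c(0, 0, 10, 10)), det_row(0.8, c(50, 50, 60, 60)))
  m <- matchDetections(perfect, gts2)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))
  m0 <- matchDetections(perfect[0, ], gts2)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0L, 0L, 2L))
  # duplicate detections of one object: 1 TP + 1 FP
  dup <- rbind(det_row(0.9, c(0, 0, 10, 10)), det_row(0.8, c(1, 1, 11, 11)))
  md <- matchDetections(dup, gts2)
  expect_equal(c(md$tp, md$fp, md$fn), c(1L, 1L, 1L))
})

test_that("average precision matches hand-enumerated P-R areas", {
  one <- det_row(0.9, c(0, 0, 10, 10))
  expect_equal(averagePrecision(one, gts2[1, ]), 1)
  # rank pattern TP, FP, TP over 2 ground truths
  dets <- rbind(det_row(0.9, c(0, 0, 10, 10)),
                det_row(0.8, c(100, 100, 110, 110)),
                det_row(0.7, c(50, 50, 60, 60)))
  expect_equal(averagePrecision(dets, gts2), 0.5 * 1 + 0.5 * (2 / 3),
               tolerance = 1e-12)
  expect_equal(averagePrecision(dets, gts2), 0.8333, tolerance = 1e-4)
  expect_error(averagePrecision(dets, gts2[0, ]), "ground-truth")
})

test_that("AP agrees with an exhaustive-ordering oracle on small sets", {
  # five candidate boxes, three of them true matches; every score ordering
  boxes <- list(c(0, 0, 10, 10), c(50, 50, 60, 60), c(30, 0, 40, 10),
                c(80, 80, 90, 90), c(0, 30, 10, 40))
  gts <- data.frame(imageId = "a", class = "grape",
                    xmin = c(0, 50, 0), ymin = c(0, 50, 30),
                    xmax = c(10, 60, 10), ymax = c(10, 60, 40))
  perms <- list(1:5, c(3, 1, 2, 5, 4), c(5, 4, 3, 2, 1), c(2, 4, 1, 3, 5))
  for (ord in perms) {
    scores <- seq(0.9, 0.5, length.out = 5)[order(ord)]
    dets <- do.call(rbind, lapply(seq_along(boxes), function(i) {
      det_row(scores[i], boxes[[i]])
    }))
    m <- matchDetections(dets, gts)
    expect_equal(averagePrecision(dets, gts),
                 ap_oracle(m$tp_flags, nrow(gts)), tolerance = 1e-12)
  }
})

test_that("the P-R curve is monotone in recall and integrates to the AP", {
  with_seed_test(31, {
    n <- 25
    gts <- data.frame(imageId = "a", class = "grape",
                      xmin = seq(0, 240, by = 20), ymin = 0,
                      xmax = seq(10, 250, by = 20), ymax = 10)
    dets <- do.call(rbind, lapply(1:n, function(i) {
      gt <- gts[sample(nrow(gts), 1), ]
      jit <- runif(1, 0, 8)
      det_row(runif(1), c(gt$xmin + jit, gt$ymin, gt$xmax + jit, gt$ymax))
    }))
    pts <- prCurvePoints(dets, gts)
    expect_true(!is.unsorted(pts$recall))
    expect_equal(gd$ap_from_points(pts, nrow(gts), "all"),
                 averagePrecision(dets, gts), tolerance = 1e-12)
    # CSV export round-trips
    f <- withr::local_tempfile(fileext = ".csv")
    prCurvePoints(dets, gts, path = f)
    expect_equal(utils::read.csv(f), pts, tolerance = 1e-12)
  })
})

test_that("AP is invariant to how detections are split across images", {
  with_seed_test(32, {
    gts1 <- data.frame(imageId = "a", class = "grape",
                       xmin = c(0, 50, 100), ymin = 0,
                       xmax = c(10, 60, 110), ymax = 10)
    dets1 <- rbind(det_row(0.9, c(0, 0, 10, 10)),
                   det_row(0.7, c(50, 52, 60, 62)),
                   det_row(0.6, c(200, 0, 210, 10)),
                   det_row(0.5, c(100, 0, 110, 10)))
    # same geometry, second half attributed to image "b"
    gts_split <- gts1; gts_split$imageId[3] <- "b"
    dets_split <- dets1; dets_split$imageId[3:4] <- "b"
    dets_split$xmin[3] <- 200; dets_split$xmax[3] <- 210
    expect_equal(averagePrecision(dets1, gts1),
                 averagePrecision(dets_split, gts_split), tolerance = 1e-12)
  })
})

test_that("the 11-point interpolation stays close to the exact area", {
  dets <- rbind(det_row(0.9, c(0, 0, 10, 10)),
                det_row(0.8, c(100, 100, 110, 110)),
                det_row(0.7, c(50, 50, 60, 60)))
  ap11 <- averagePrecision(dets, gts2, interpolation = "11point")
  expect_gte(ap11, 0.5)
  expect_lte(ap11, 1)
})

test_that("evaluateDetections reports a coherent operating point", {
  dets <- rbind(det_row(0.9, c(0, 0, 10, 10)),
                det_row(0.3, c(50, 50, 60, 60)))
  rep <- evaluateDetections(dets, gts2, score_thresh = 0.5)
  expect_equal(c(rep$tp, rep$fp, rep$fn), c(1, 0, 1))
  expect_equal(unname(rep$precision), 1)
  expect_equal(unname(rep$recall), 0.5)
  expect_equal(rep$ap, 1)   # both detections are correct in ranked order
})
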