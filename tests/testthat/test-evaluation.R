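two_instance_map <- function() {
  m <- matrix(0L, 30, 30)
  m[2:11, 2:11] <- 1L     # 100 px
  m[15:24, 15:24] <- 2L   # 100 px
  m
}

test_that("perfect predictions score 1 at every level", {
  gt <- two_instance_map()
  d <- detection_eval(gt, gt, 0.7)
  expect_equal(c(d$precision, d$recall, d$f1), c(1, 1, 1))
  s <- segmentation_eval(gt, gt)
  expect_equal(c(s$precision, s$recall, s$f1), c(1, 1, 1))
})

test_that("threshold arithmetic sorts matched pairs into TP/FP/FN", {
  gt <- two_instance_map()
  pred <- matrix(0L, 30, 30)
  pred[2:11, 2:11] <- 1L        # IoU 1 with gt 1 -> TP
  pred[15:24, 11:20] <- 2L      # IoU 60/140 = 0.43 with gt 2 -> below 0.7
  r <- detection_eval(pred, gt, 0.7)
  expect_equal(c(r$tp, r$fp, r$fn), c(1L, 1L, 1L))
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 0.5)

  # zero predictions: recall 0, flagged
  r0 <- detection_eval(matrix(0L, 30, 30), gt, 0.7)
  expect_equal(c(r0$tp, r0$fn), c(0L, 2L))
  expect_equal(r0$recall, 0)
  expect_true(r0$undefined)
})

test_that("metrics are invariant to instance id permutation", {
  gt <- two_instance_map()
  perm <- gt
  perm[gt == 1L] <- 9L; perm[gt == 2L] <- 4L
  expect_equal(as.data.frame(detection_eval(perm, gt, 0.7)),
               as.data.frame(detection_eval(gt, gt, 0.7)))
  expect_equal(as.data.frame(segmentation_eval(perm, gt)),
               as.data.frame(segmentation_eval(gt, gt)))
})

test_that("marker-level scoring merges same-cap markers and counts strays", {
  gt <- two_instance_map()
  mk <- tibble::tibble(row = c(5, 20), col = c(5, 20),
                       elevation = c(1, 1))
  r <- marker_detection_eval(mk, gt, 18)
  expect_equal(c(r$tp, r$fp, r$fn), c(2L, 0L, 0L))
  expect_equal(r$recall, 1)

  # two markers inside the same cap merge to one TP, no FP
  mk2 <- tibble::tibble(row = c(4, 8), col = c(4, 8), elevation = c(1, 1))
  r2 <- marker_detection_eval(mk2, gt, 18)
  expect_equal(c(r2$tp, r2$fp, r2$fn), c(1L, 0L, 1L))

  # a marker on background is a false positive
  mk3 <- tibble::tibble(row = c(5, 28), col = c(5, 2), elevation = c(1, 1))
  r3 <- marker_detection_eval(mk3, gt, 18)
  expect_equal(r3$fp, 1L)
})

test_that("pixel pooling matches constructed counts", {
  gt <- matrix(0L, 30, 30); gt[6:15, 6:15] <- 1L        # 100 px
  pred <- matrix(0L, 30, 30); pred[6:15, 6:25] <- 1L    # dilated: FP = TP
  r <- segmentation_eval(pred, gt)
  expect_equal(c(r$tp, r$fp, r$fn), c(100L, 100L, 0L))
  expect_equal(r$precision, 0.5)
  expect_equal(r$recall, 1)
  expect_equal(r$f1, 2 / 3)

  r0 <- segmentation_eval(matrix(0L, 30, 30), gt)
  expect_equal(r0$recall, 0)
})

test_that("f1 is zero iff tp is zero (property over random reports)", {
  withr::with_seed(23, {
    for (i in 1:20) {
      tp <- sample(0:5, 1); fp <- sample(0:5, 1); fn <- sample(0:5, 1)
      r <- capseg:::eval_report(tp, fp, fn, "detection-instance")
      expect_equal(r$f1 == 0, tp == 0L)
      expect_gte(r$f1, 0); expect_lte(r$f1, 1)
      if (tp > 0) {
        expect_lte(r$f1, max(r$precision, r$recall) + 1e-12)
        expect_gte(r$f1, min(r$precision, r$recall) - 1e-12)
      }
    }
  })
})

test_that("tracking consistency follows the no-swap no-interruption rule", {
  perfect <- tidyr::expand_grid(frame = 0:4, gt_id = 1:4) |>
    dplyr::mutate(pred_id = gt_id)
  expect_equal(as.numeric(tracking_consistency(perfect)), 100)

  # one of four tracks switches id -> 75%
  sw <- perfect
  sw$pred_id[sw$gt_id == 3 & sw$frame >= 3] <- 9L
  expect_equal(as.numeric(tracking_consistency(sw)), 75)

  # an interruption (missed frame) breaks a track even if the id resumes
  gap <- perfect
  gap$pred_id[gap$gt_id == 2 & gap$frame == 2] <- NA_integer_
  expect_equal(as.numeric(tracking_consistency(gap)), 75)

  expect_error(tracking_consistency(perfect[0, ]),
               class = "capseg_undefined_metric_error")
})

test_that("tidiers expose reports and tracks as tibbles", {
  gt <- two_instance_map()
  r <- detection_eval(gt, gt, 0.7)
  td <- tidy(r)
  expect_equal(td$value[td$metric == "f1"], 1)
  expect_s3_class(glance(r), "tbl_df")

  tr <- track_sequence(rep(list(gt), 2))
  expect_true(all(c("frame", "global_id", "area_px") %in% names(tidy(tr))))
  g <- glance(tr)
  expect_equal(g$n_frames, 2)
  expect_equal(g$n_tracks, 2)
})
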