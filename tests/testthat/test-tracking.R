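test_that("mask IoU counts pixels", {
  a <- block_mask(8, 8, 1:2, 1:2)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, block_mask(8, 8, 5:6, 5:6)), 0)
  # 2x2 blocks sharing a 2x1 column: 2 / 6
  b <- block_mask(8, 8, 1:2, 2:3)
  expect_equal(mask_iou(a, b), 2 / 6)
  expect_equal(mask_iou(a & FALSE, a & FALSE), 0)
})

test_that("assignment equals the exhaustive-permutation optimum", {
  withr::with_seed(42, {
    for (i in 1:60) {
      nr <- sample(1:6, 1); nc <- sample(1:6, 1)
      iou <- matrix(runif(nr * nc), nr, nc)
      iou[runif(nr * nc) < 0.3] <- 0  # sparsity, incl. all-zero rows
      acc <- assign_iou(iou, tau = 0)
      expect_equal(sum(acc$iou), brute_force_assignment_total(iou),
                   tolerance = 1e-9)
      # one-to-one
      expect_false(any(duplicated(acc$prev)))
      expect_false(any(duplicated(acc$curr)))
    }
  })
})

test_that("greedy-suboptimal structures are solved globally", {
  # greedy would take 0.9 then be stuck with 0.1+0.1; optimum is 0.8*3
  iou <- matrix(c(0.9, 0.8, 0.0,
                  0.8, 0.1, 0.8,
                  0.0, 0.8, 0.1), 3, 3, byrow = TRUE)
  acc <- assign_iou(iou, tau = 0)
  expect_equal(sum(acc$iou), brute_force_assignment_total(iou))
})

test_that("associate inherits ids, mints fresh ones, reports losses", {
  prev <- matrix(0L, 20, 20)
  prev[2:6, 2:6] <- 7L; prev[12:16, 12:16] <- 9L
  # identity: same map matches itself completely
  a <- associate(prev, prev, tau = 0.1)
  expect_equal(sort(a$matches$global_id), c(7L, 9L))
  expect_length(a$new_ids, 0)
  expect_length(a$lost_ids, 0)
  expect_equal(a$relabelled, prev, ignore_attr = TRUE)

  # empty current frame: everything lost
  a2 <- associate(prev, matrix(0L, 20, 20), tau = 0.1)
  expect_equal(sort(a2$lost_ids), c(7L, 9L))
  expect_equal(nrow(a2$matches), 0)

  # shifted instance + a newcomer: id inherited, fresh id > all prior
  curr <- matrix(0L, 20, 20)
  curr[3:7, 2:6] <- 1L           # overlaps prev id 7
  curr[12:16, 2:5] <- 2L         # new
  a3 <- associate(prev, curr, tau = 0.1)
  expect_equal(a3$matches$global_id[a3$matches$curr_id == 1L], 7L)
  expect_true(all(a3$new_ids > 9L))
  expect_equal(a3$lost_ids, 9L)
})

test_that("matches below tau are rejected", {
  prev <- matrix(0L, 10, 10); prev[1:5, 1:5] <- 1L
  curr <- matrix(0L, 10, 10); curr[5, 5] <- 1L  # IoU = 1/25
  a <- associate(prev, curr, tau = 0.1)
  expect_equal(nrow(a$matches), 0)
  expect_length(a$new_ids, 1)
})

test_that("a static sequence preserves every identity", {
  lab <- matrix(0L, 30, 30)
  lab[2:8, 2:8] <- 1L; lab[15:22, 15:22] <- 2L; lab[2:8, 20:26] <- 3L
  tr <- track_sequence(rep(list(lab), 5))
  expect_equal(nrow(tr$states), 3)
  expect_true(all(tr$states$state == "active"))
  for (m in tr$maps) expect_equal(m, lab, ignore_attr = TRUE)
  asn <- match_tracks_to_gt(tr$maps, rep(list(lab), 5))
  expect_equal(as.numeric(tracking_consistency(asn)), 100)
})

test_that("harvested ids go inactive, then terminate, and are never reused", {
  mk_map <- function(with_b) {
    m <- matrix(0L, 30, 30)
    m[2:8, 2:8] <- 1L
    if (with_b) m[15:22, 15:22] <- 2L
    m
  }
  maps <- c(rep(list(mk_map(TRUE)), 3), rep(list(mk_map(FALSE)), 6))
  cfg <- pipeline_config(max_missed = 3)
  tr <- track_sequence(maps, cfg)
  st <- tr$states
  expect_equal(st$state[st$global_id == 2L], "terminated")
  expect_equal(st$last_seen[st$global_id == 2L], 2)
  # never reassigned: id 2 absent from all later maps
  for (t in 4:9) expect_false(2L %in% tr$maps[[t]])
  expect_equal(st$state[st$global_id == 1L], "active")
})

test_that("an inactive track re-matches within the grace window, id intact", {
  a_only <- matrix(0L, 30, 30); a_only[2:8, 2:8] <- 1L
  both <- a_only; both[15:22, 15:22] <- 2L
  maps <- list(both, a_only, a_only, both)  # instance 2 blinks off 2 frames
  tr <- track_sequence(maps, pipeline_config(max_missed = 3))
  expect_equal(sort(unique(as.integer(tr$maps[[4]]))), c(0L, 1L, 2L))
  # with re-matching disabled the reappearance gets a fresh id
  tr2 <- track_sequence(maps, pipeline_config(rematch_inactive = FALSE))
  expect_equal(sort(unique(as.integer(tr2$maps[[4]]))), c(0L, 1L, 3L))
})

test_that("a new cap gets a fresh id strictly greater than all prior ids", {
  base <- matrix(0L, 30, 30); base[2:8, 2:8] <- 1L
  later <- base; later[20:26, 20:26] <- 5L
  tr <- track_sequence(list(base, base, later))
  ids3 <- setdiff(unique(as.integer(tr$maps[[3]])), 0L)
  expect_setequal(ids3, c(1L, 2L))
  expect_equal(max(tr$states$global_id), 2L)
})

test_that("tracking on a noiseless growth sequence is fully consistent", {
  caps <- data.frame(row = c(30, 30, 75), col = c(30, 80, 55),
                     radius = c(8, 9, 10), apex = c(6, 7, 8),
                     growth_rate = 0.05)
  spec <- scene_spec(110, 110, caps, depth_noise_sd = 0, speckle_sd = 0,
                     seed = 5)
  sq <- render_sequence(spec, 5)
  run <- run_pipeline(sq$frames)
  asn <- match_tracks_to_gt(run$tracks$maps, sq$gt_maps)
  expect_equal(as.numeric(tracking_consistency(asn)), 100)
})
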