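test_that("coverage counts enumerate mask membership per pixel", {
  a <- block_mask(10, 10, 1:4, 1:4)
  b <- block_mask(10, 10, 6:9, 6:9)
  cc <- coverage_count(list(a, b))
  expect_true(all(cc %in% 0:1))
  expect_equal(sum(cc), sum(a) + sum(b))

  b2 <- block_mask(10, 10, 4:7, 4:7)  # shares pixel (4,4) with a
  cc2 <- coverage_count(list(a, b2))
  expect_equal(cc2[4, 4], 2L)
  expect_equal(sum(cc2 == 2L), 1L)

  cc3 <- coverage_count(list(a, a, a))
  expect_equal(unique(cc3[a]), 3L)
  expect_equal(unique(cc3[!a]), 0L)
})

test_that("ridge map is zero on constants and linear in step height", {
  expect_lt(max(ridge_map(matrix(0.5, 20, 20))), 1e-12)
  step_of <- function(h) {
    v <- matrix(0, 20, 20); v[, 11:20] <- h
    ridge_map(v)
  }
  r1 <- step_of(0.3); r2 <- step_of(0.6)
  expect_equal(which.max(colSums(r1)) %in% 10:11, TRUE)
  expect_equal(r2, 2 * r1, tolerance = 1e-9)
})

test_that("Sobel gradient equals a naive convolution oracle", {
  withr::with_seed(19, {
    m <- matrix(runif(15 * 12), 15, 12)
    kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
    expect_equal(capseg:::sobel_convolve(m, kx), naive_convolve3(m, kx),
                 tolerance = 1e-12)
    expect_equal(capseg:::sobel_convolve(m, t(kx)), naive_convolve3(m, t(kx)),
                 tolerance = 1e-12)
  })
})

test_that("non-overlapping masks pass through resolution unchanged", {
  a <- block_mask(30, 30, 2:9, 2:9)
  b <- block_mask(30, 30, 15:24, 15:24)
  elev <- make_elev(matrix(0.5, 30, 30) * (a | b))
  lab <- resolve_overlaps(list(`1` = a, `2` = b), elev)
  expect_equal(lab == 1L, a)
  expect_equal(lab == 2L, b)
})

test_that("contested pixels split along the depth valley, one owner each", {
  # two overlapping discs with a valley on the midline
  v <- pmax(cap_field(40, 60, 20, 22, 11, 6), cap_field(40, 60, 20, 38, 11, 6))
  elev <- make_elev(capseg:::minmax01(v))
  a <- cap_field(40, 60, 20, 22, 11, 1) > 0   # full discs claim the overlap
  b <- cap_field(40, 60, 20, 38, 11, 1) > 0
  expect_gt(sum(a & b), 0)
  lab <- resolve_overlaps(list(`1` = a, `2` = b), elev)
  cc <- coverage_count(capseg:::label_map_to_masks(lab))
  expect_lte(max(cc), 1)
  expect_equal(lab[20, 22], 1L)
  expect_equal(lab[20, 38], 2L)
  # non-contested pixels never change owner
  expect_true(all(lab[a & !b] %in% c(0L, 1L)))
  expect_true(all(lab[b & !a] %in% c(0L, 2L)))
  # the split should land near the true midline column 30
  boundary_cols <- range(which(colSums(lab == 1L) > 0))
  expect_lte(boundary_cols[2], 32)
})

test_that("a mask nested inside another keeps only its eroded core's region", {
  outer_m <- block_mask(40, 40, 5:35, 5:35)
  inner <- block_mask(40, 40, 12:20, 12:20)
  # elevation: inner cap higher
  v <- matrix(0, 40, 40); v[outer_m] <- 0.3; v[inner] <- 0.8
  lab <- resolve_overlaps(list(`1` = outer_m, `2` = inner),
                          make_elev(v))
  # inner is fully contested (its exclusive region is empty) -> dropped,
  # outer takes the remainder
  expect_true(all(lab[inner] %in% c(0L, 1L)))
  expect_true(2L %in% attr(lab, "dropped") || any(lab == 2L))
})

test_that("resolution is deterministic and preserves instance identity", {
  spec <- cojoined_pair_spec()
  rf <- render_frame(spec, 0)
  em <- preprocess_frame(rf$frame)
  fg <- otsu_foreground(rf$frame$rgb)
  seg <- segment_frame(em, fg, detect_markers(em))
  l1 <- resolve_overlaps(seg, em)
  l2 <- resolve_overlaps(seg, em)
  expect_identical(l1, l2)
})
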