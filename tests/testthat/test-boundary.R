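# Radially symmetric test patch from a profile f(r) over Chebyshev radius,
# so a ray along theta = 0 samples the profile exactly.
profile_patch <- function(f) {
  n <- 2L * (length(f) - 1L) + 1L
  ctr <- (n + 1L) %/% 2L
  v <- outer(seq_len(n), seq_len(n),
             function(i, j) f[pmax(abs(i - ctr), abs(j - ctr)) + 1L])
  make_patch(v)
}

test_that("patch extraction normalizes, reflects at borders, centers the apex", {
  v <- cap_field(60, 60, 30, 30, 9, 5) + 0.001
  p <- extract_patch(make_elev(v), c(30, 30), 23)
  expect_equal(dim(p$values), c(23, 23))
  expect_equal(p$values[12, 12], 1)  # apex at center after min-max
  expect_equal(min(p$values), 0)
  expect_false(p$degenerate)

  # 5 px from the border still yields a full 23x23 patch
  p2 <- extract_patch(make_elev(v), c(5, 30), 23)
  expect_equal(dim(p2$values), c(23, 23))

  # constant elevation -> degenerate all-zero patch
  p3 <- extract_patch(make_elev(matrix(3, 40, 40)), c(20, 20), 23)
  expect_true(p3$degenerate)
  expect_equal(unique(as.vector(p3$values)), 0)
  expect_error(extract_patch(make_elev(v), c(0, 10)),
               class = "capseg_dimension_error")
})

test_that("ring-level radial gradient matches its definition", {
  # constant patch -> all-zero profile
  g0 <- radial_gradient(make_patch(matrix(0.5, 23, 23)))
  expect_equal(g0$G, rep(0, 10))

  # Chebyshev cone with slope 0.05 per ring -> G(r) = 0.05 everywhere
  cone <- profile_patch(1 - 0.05 * (0:11))
  gc <- radial_gradient(cone)
  expect_equal(gc$G, rep(0.05, 10), tolerance = 1e-12)
  expect_equal(gc$signed, rep(0.05, 10), tolerance = 1e-12)
  expect_equal(gc$K, 8 * (1:10))

  # random patches against the naive triple-loop oracle
  withr::with_seed(3, {
    for (i in 1:5) {
      v <- matrix(runif(23 * 23), 23, 23)
      got <- radial_gradient(make_patch(v))
      want <- naive_radial_gradient(v)
      expect_equal(got$G, want$G, tolerance = 1e-12)
      expect_equal(got$signed, want$signed, tolerance = 1e-12)
      expect_true(all(got$G >= 0))
    }
  })
})

test_that("overlap limit finds the rise after the fall", {
  iso <- profile_patch(c(seq(1, 0.3, length.out = 9), 0.3, 0.3, 0.3))
  expect_equal(overlap_limit(iso, 0), 11)           # never rises
  valley <- profile_patch(c(1, .9, .8, .7, .6, .5, .4, .5, .6, .7, .8, .9))
  expect_equal(overlap_limit(valley, 0), 6)          # rises after ring 6
  expect_equal(overlap_limit(valley, pi / 2), 6)     # symmetric patch
  rising <- profile_patch((0:11) / 11)
  expect_equal(overlap_limit(rising, 0), 1)          # immediate rise
})

test_that("boundary tracing puts primaries on a sharp cap edge", {
  v <- cap_field(23, 23, 12, 12, 8, 1)
  v[v > 0] <- v[v > 0] + 1   # sharp pedestal edge at radius 8
  pts <- trace_boundary(make_patch(capseg:::minmax01(v)))
  expect_gt(nrow(pts), 60)
  expect_true(all(abs(pts$primary_r - 8) <= 1))
  # backup never outranks primary
  has_b <- !is.na(pts$backup_g)
  expect_true(all(pts$backup_g[has_b] <= pts$primary_g[has_b]))
  expect_true(all(pts$primary_r <= pts$limit))

  # flat patch -> empty point set
  expect_equal(nrow(trace_boundary(make_patch(matrix(0, 23, 23)))), 0)
})

test_that("rays toward a touching neighbor stop at the overlap limit", {
  v <- pmax(cap_field(40, 60, 20, 20, 10, 6), cap_field(40, 60, 20, 36, 10, 6))
  p <- extract_patch(make_elev(v), c(20, 20), 23)
  pts <- trace_boundary(p)
  toward <- pts[cos(pts$theta) > 0.9, ]   # rays pointing at the neighbor
  away <- pts[cos(pts$theta) < -0.9, ]
  expect_true(all(toward$limit < 11))
  expect_true(all(toward$primary_r <= toward$limit))
  expect_true(all(away$limit == 11))
})

fake_contour <- function(radii, backup = NA_real_) {
  n <- length(radii)
  tibble::tibble(theta = seq(0, 2 * pi, length.out = n + 1)[-(n + 1)],
                 primary_r = radii, primary_g = 1,
                 backup_r = backup, backup_g = ifelse(is.na(backup), NA, 0.5),
                 limit = 50L)
}

test_that("refinement drops the spike, keeps consensus, honors backups", {
  radii <- rep(20, 72); radii[10] <- 45
  out <- refine_boundary(fake_contour(radii))
  expect_equal(nrow(out), 71)
  expect_true(all(out$r == 20))

  # same outlier but with a sane backup: replaced, not dropped
  out2 <- refine_boundary(fake_contour(radii, backup = 20))
  expect_equal(nrow(out2), 72)
  expect_true(all(out2$r == 20))

  # all radii equal: SD = 0, nothing removed by the global pass
  out3 <- refine_boundary(fake_contour(rep(9, 72)))
  expect_equal(nrow(out3), 72)

  expect_error(refine_boundary(fake_contour(c(5, 6))),
               class = "capseg_degenerate_error")
})

test_that("hull rasterization fills, intersects foreground, dominates the raw polygon", {
  sq <- tibble::tibble(theta = c(0, pi / 2, pi, 3 * pi / 2) + pi / 4,
                       r = sqrt(2) * 5)
  m <- points_to_mask(sq, c(20, 20), NULL, c(40, 40))
  expect_true(all(m[16:24, 16:24]))
  expect_false(any(m[1:13, ]))

  fg <- matrix(FALSE, 40, 40); fg[, 20:40] <- TRUE
  m2 <- points_to_mask(sq, c(20, 20), fg, c(40, 40))
  expect_equal(m2, m & fg)

  # collinear points -> degenerate hull
  lin <- tibble::tibble(theta = c(0, 0, pi), r = c(2, 4, 3))
  expect_error(points_to_mask(lin, c(20, 20), NULL, c(40, 40)),
               class = "capseg_degenerate_error")

  # hull area >= shoelace area of the theta-ordered raw polygon
  withr::with_seed(31, {
    for (i in 1:5) {
      n <- 12
      pts <- tibble::tibble(theta = sort(runif(n, 0, 2 * pi)),
                            r = runif(n, 3, 12))
      mask <- points_to_mask(pts, c(20, 20), NULL, c(40, 40))
      x <- pts$r * cos(pts$theta); y <- pts$r * sin(pts$theta)
      shoelace <- abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
      expect_gte(sum(mask), shoelace - n)  # rasterization slack
    }
  })
})

test_that("segment_frame produces one mask per cap and drops degenerates", {
  spec <- demo_bed_spec(seed = 77)
  rf <- render_frame(spec, 0)
  em <- preprocess_frame(rf$frame)
  fg <- otsu_foreground(rf$frame$rgb)
  mk <- detect_markers(em)
  seg <- segment_frame(em, fg, mk)
  expect_equal(length(seg$masks), 5)
  cc <- coverage_count(seg$masks)
  expect_lte(max(cc), 1)  # well-separated caps -> pairwise disjoint

  # zero markers -> empty label map
  seg0 <- segment_frame(em, fg, mk[0, ])
  expect_equal(length(seg0$masks), 0)
  expect_true(all(seg0$labels == 0))
})
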