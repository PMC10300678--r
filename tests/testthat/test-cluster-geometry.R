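test_that("circle geometry has the prescribed spacing and inward axes", {
  # N = 2: antiparallel, facing each other at distance R(2 + eps)
  c2 <- build_circle(2, 0.4)
  d <- sqrt(sum((c2$positions[1, ] - c2$positions[2, ])^2))
  expect_equal(d, 2.4, tolerance = 1e-12)
  expect_equal(c2$orientations[1, ], -c2$orientations[2, ], tolerance = 1e-12)
  # N = 6, eps = 0.5: circle radius 2.5 R
  c6 <- build_circle(6, 0.5)
  expect_equal(sqrt(rowSums(c6$positions^2)), rep(2.5, 6), tolerance = 1e-12)
  # orientations point at the centre
  for (i in 1:6) {
    to_centre <- -c6$positions[i, ] / sqrt(sum(c6$positions[i, ]^2))
    expect_equal(sum(c6$orientations[i, ] * to_centre), 1, tolerance = 1e-12)
  }
  expect_error(build_circle(1, 0.5), "N >= 2")
  expect_error(build_circle(6, 0.5, walls = "bottom", h = 2.5), "gap")
})

test_that("filled circle is a ring plus a vertical central squirmer", {
  f7 <- build_filled_circle(7, 0.5)
  expect_equal(nrow(f7$positions), 7)
  # hexagonal ring: ring radius equals the neighbour spacing
  expect_equal(sqrt(sum(f7$positions[1, ]^2)), 2.5, tolerance = 1e-12)
  expect_equal(f7$orientations[7, ], c(0, 1, 0))
  down <- build_filled_circle(7, 0.5, centre_up = FALSE)
  expect_equal(down$orientations[7, ], c(0, -1, 0))
  # ring-centre overlap rejected for small rings
  expect_error(build_filled_circle(5, 0.5), "overlap|spacing")
  # 6 ring pairs + 6 centre-ring pairs
  expect_equal(nrow(neighbour_pairs(f7)), 12)
})

test_that("partial circles fill the hexagonal template towards the barycentre", {
  p7 <- build_partial_circle(7, 0.5)
  f7 <- build_filled_circle(7, 0.5)
  # same site set as the filled hexagon (up to ordering)
  d <- as.matrix(dist(rbind(p7$positions, f7$positions)))[1:7, 8:14]
  expect_true(all(apply(d, 1, min) < 1e-9))
  # compact triangle: all three mutually adjacent, pointing at the barycentre
  p3 <- build_partial_circle(3, 0.5)
  dd <- dist(p3$positions)
  expect_true(all(abs(dd - 2.5) < 1e-9))
  bary <- colMeans(p3$positions)
  for (i in 1:3) {
    expect_gt(sum(p3$orientations[i, ] * (bary - p3$positions[i, ])), 0)
  }
  expect_error(build_partial_circle(8, 0.5), "2 <= N <= 7")
})

test_that("neighbour detection uses the one-radius surface-gap cutoff", {
  c5 <- build_circle(5, 0.5)
  np <- neighbour_pairs(c5)
  expect_equal(nrow(np), 5)         # ring topology only
  expect_equal(np$eps, rep(0.5, 5), tolerance = 1e-12)
  expect_equal(nrow(neighbour_pairs(build_circle(2, 0.5))), 1)
  # gap of 1.5 R: no interaction
  expect_equal(nrow(neighbour_pairs(build_circle(2, 1.5))), 0)
  # generators are deterministic
  expect_identical(build_circle(5, 0.5), build_circle(5, 0.5))
})
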