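test_that("count_crossings handles transversal, disjoint and tangent cases", {
  path <- rbind(c(0, 0), c(0, 2))
  expect_identical(count_crossings(path, rbind(c(-1, 1), c(1, 1))), 1L)
  expect_identical(count_crossings(path, rbind(c(5, 5), c(6, 5))), 0L)
  # endpoint tangency and collinear overlap are not crossings
  expect_identical(count_crossings(path, rbind(c(0, 1), c(1, 1))), 0L)
  expect_identical(count_crossings(path, rbind(c(0, 0.5), c(0, 1.5))), 0L)
  # zero-length path segments contribute nothing
  expect_identical(
    count_crossings(rbind(c(0, 0), c(0, 0), c(0, 2)), rbind(c(-1, 1), c(1, 1))), 1L)
  expect_error(count_crossings(rbind(c(0, 0), c(NA, 1)), path), "non-finite")
})

test_that("zig-zag crossing count matches the brute-force enumerator", {
  k <- 7L
  zig <- cbind(seq_len(k + 1L), rep(c(1, -1), length.out = k + 1L))
  line <- rbind(c(-10, 0), c(20, 0))
  expect_identical(count_crossings(zig, line), k)
  expect_identical(count_crossings(zig, line), oracle_crossings(zig, line))
})

test_that("count_crossings agrees with the oracle on random small instances", {
  set.seed(42)
  for (rep in 1:25) {
    path <- matrix(runif(2 * sample(2:10, 1), 0, 10), ncol = 2)
    feats <- lapply(seq_len(sample(1:3, 1)), function(i)
      matrix(runif(2 * sample(2:10, 1), 0, 10), ncol = 2))
    expect_identical(count_crossings(path, feats),
                     as.integer(oracle_crossings(path, feats)))
  }
})

test_that("crossing count is symmetric for single segments", {
  set.seed(7)
  for (rep in 1:20) {
    a <- matrix(runif(4), 2); b <- matrix(runif(4), 2)
    expect_identical(count_crossings(a, b), count_crossings(b, a))
  }
})

test_that("point-in-polygon is boundary-inclusive and matches the winding oracle", {
  sq <- lc_rect(0, 0, 1, 1)
  expect_identical(count_points_in_polygon(c(0.5, 0.5), sq), 1L)
  expect_identical(count_points_in_polygon(c(2, 2), sq), 0L)
  expect_identical(count_points_in_polygon(rbind(c(0, 0), c(1, 0.5), c(0.5, 1)), sq), 3L)
  set.seed(11)
  pts <- cbind(runif(1000, 0, 2), runif(1000, 0, 2))
  ours <- points_in_polygon(pts, sq)
  oracle <- vapply(seq_len(1000), function(i)
    oracle_point_in_ring(pts[i, ], sq$parts[[1]][[1]]), TRUE)
  expect_identical(ours, oracle)
  # non-convex ring too
  ring <- rbind(c(0, 0), c(4, 0), c(4, 4), c(2, 1.5), c(0, 4))
  pol <- lc_polygon(ring)
  ours <- points_in_polygon(pts * 2, pol)
  oracle <- vapply(seq_len(1000), function(i)
    oracle_point_in_ring(pts[i, ] * 2, ring), TRUE)
  expect_identical(ours, oracle)
  expect_error(lc_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))), "zero area")
})

test_that("minimum convex polygon matches gift wrapping and is convex", {
  tri <- minimum_convex_polygon(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_equal(polygon_area(tri), 0.5)
  set.seed(3)
  pts <- matrix(rnorm(400), ncol = 2)
  mcp <- minimum_convex_polygon(pts)
  hull_ring <- mcp$parts[[1]][[1]]
  oracle <- oracle_hull(pts)
  expect_setequal(apply(round(hull_ring, 9), 1, paste, collapse = ","),
                  apply(round(oracle, 9), 1, paste, collapse = ","))
  expect_true(all(points_in_polygon(pts, mcp)))
  # hull of hull is the hull
  mcp2 <- minimum_convex_polygon(hull_ring)
  expect_equal(polygon_area(mcp2), polygon_area(mcp))
  # convexity: consecutive edge cross products share a sign
  n <- nrow(hull_ring)
  e1 <- hull_ring[c(2:n, 1), ] - hull_ring
  e2 <- e1[c(2:n, 1), ]
  crossp <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  expect_true(all(crossp > 0) || all(crossp < 0))
  expect_error(minimum_convex_polygon(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(minimum_convex_polygon(rbind(c(0, 0), c(1, 1), c(2, 2))), "collinear")
})

test_that("polygon union covers both inputs with the right area", {
  a <- lc_rect(0, 0, 1, 1)
  expect_equal(polygon_area(union_polygons(a, lc_rect(3, 3, 4, 4))), 2)
  # containment: a inside b returns b
  b <- lc_rect(-1, -1, 2, 2)
  expect_equal(polygon_area(union_polygons(a, b)), 9)
  # overlap: inclusion-exclusion
  u <- union_polygons(a, lc_rect(0.5, 0.5, 1.5, 1.5))
  expect_equal(polygon_area(u), 1.75)
  set.seed(5)
  pts <- cbind(runif(200, 0, 1), runif(200, 0, 1))
  expect_true(all(points_in_polygon(pts, u)))
})

test_that("buffering dilates with the closed-form area for convex shapes", {
  r <- lc_rect(0, 0, 10, 4)
  expect_equal(polygon_area(buffer_polygon(r, 0)), 40)
  b5 <- buffer_polygon(r, 5)
  expect_equal(polygon_area(b5), 40 + 2 * (10 + 4) * 5 + 25 * pi, tolerance = 0.01)
  # containment of input boundary
  set.seed(9)
  t <- runif(1000, 0, 4)
  side <- sample(1:4, 1000, replace = TRUE)
  bd <- cbind(ifelse(side <= 2, t * 2.5, ifelse(side == 3, 0, 10)),
              ifelse(side <= 2, ifelse(side == 1, 0, 4), t))
  expect_true(all(points_in_polygon(bd, b5)))
  # area strictly increasing in distance
  areas <- vapply(c(0, 1, 2.5, 5, 9), function(d) polygon_area(buffer_polygon(r, d)), 0)
  expect_true(all(diff(areas) > 0))
  expect_error(buffer_polygon(r, -1), "unsupported")
  # non-convex dilation still contains the input and grows
  ring <- rbind(c(0, 0), c(10, 0), c(10, 10), c(5, 3), c(0, 10))
  pol <- lc_polygon(ring)
  bn <- buffer_polygon(pol, 2)
  expect_true(all(points_in_polygon(ring, bn)))
  expect_gt(polygon_area(bn), polygon_area(pol))
})

test_that("rigid motions preserve shape and crossing structure", {
  path <- rbind(c(0, 0), c(3, 4), c(1, 7), c(-2, 2))
  expect_equal(rotate_path(path, 0, c(0, 0)), path)
  expect_equal(rotate_path(rbind(c(0, 0), c(1, 0)), pi, c(0, 0)),
               rbind(c(0, 0), c(-1, 0)), tolerance = 1e-12)
  rp <- rotate_path(path, 1.234, c(5, -2))
  lens <- function(p) sqrt(diff(p[, 1])^2 + diff(p[, 2])^2)
  expect_equal(lens(rp), lens(path), tolerance = 1e-9)
  expect_equal(translate_path(rbind(c(0, 0), c(3, 4)), c(10, 10)),
               rbind(c(10, 10), c(13, 14)))
  expect_equal(translate_path(path, path[1, ]), path)
  # crossing count invariant under co-rotation and co-translation
  feat <- rbind(c(-1, 3), c(4, 3), c(2, 8))
  base <- count_crossings(path, feat)
  for (th in c(0.3, 2.1, 4.5)) {
    expect_identical(count_crossings(rotate_path(path, th, c(1, 1)),
                                     rotate_path(feat, th, c(1, 1))), base)
  }
  shift <- c(100, -50)
  expect_identical(count_crossings(translate_path(path, path[1, ] + shift),
                                   feat + rep(shift, each = 3)), base)
})

test_that("uniform polygon sampling stays inside and fills the shape", {
  set.seed(21)
  tri <- lc_polygon(rbind(c(0, 0), c(4, 0), c(0, 4)))
  pts <- sample_points_in_polygon(tri, 500)
  expect_true(all(points_in_polygon(pts, tri)))
  expect_equal(colMeans(pts), c(4 / 3, 4 / 3), tolerance = 0.15)
})
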