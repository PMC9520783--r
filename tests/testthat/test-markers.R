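test_that("rgb_to_hsv matches the closed-form primaries and grays", {
  expect_equal(as.numeric(rgb_to_hsv(rbind(c(0, 255, 0)))), c(1 / 3, 1, 1))
  expect_equal(as.numeric(rgb_to_hsv(rbind(c(255, 0, 0)))), c(0, 1, 1))
  expect_equal(as.numeric(rgb_to_hsv(rbind(c(128, 128, 128)))),
               c(0, 0, 128 / 255))
  expect_error(rgb_to_hsv(rbind(c(-1, 0, 0))), class = "opmcoreg_error_input")
  expect_error(rgb_to_hsv(rbind(c(256, 0, 0))), class = "opmcoreg_error_input")
})

test_that("the default HSV window admits green and rejects red/gray", {
  v <- matrix(0, 3, 3)
  cloud <- point_cloud(v, colors = rbind(c(0, 255, 0),    # green
                                         c(255, 0, 0),    # red: h = 0 < 0.2
                                         c(90, 90, 90)))  # gray: s = 0 < 0.3
  sel <- select_by_hsv(cloud, hsv_range())
  expect_identical(sel$indices, 1L)
  expect_error(select_by_hsv(point_cloud(v), hsv_range()),
               class = "opmcoreg_error_input")
})

test_that("select_by_hsv equals a brute-force per-vertex check on random colours", {
  set.seed(30)
  n <- 500
  cols <- matrix(sample(0:255, 3 * n, replace = TRUE), ncol = 3)
  cloud <- point_cloud(matrix(runif(3 * n), ncol = 3), colors = cols)
  rng <- hsv_range(h = c(0.1, 0.5), s = c(0.2, 0.9), v = c(0.3, 1))
  sel <- tryCatch(select_by_hsv(cloud, rng)$indices,
                  opmcoreg_error_marker_count = function(e) integer(0))
  oracle <- which(vapply(seq_len(n), function(i) {
    hsv <- grDevices::rgb2hsv(cols[i, 1], cols[i, 2], cols[i, 3],
                              maxColorValue = 255)
    hsv[1] >= 0.1 && hsv[1] <= 0.5 && hsv[2] >= 0.2 && hsv[2] <= 0.9 &&
      hsv[3] >= 0.3 && hsv[3] <= 1
  }, logical(1)))
  expect_setequal(sel, oracle)
})

test_that("cluster_markers finds well-separated patches and their centroids", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(100, 0, 0), c(101, 0, 0))
  cloud <- point_cloud(pts)
  sel <- region_selection(1:4)
  ms <- cluster_markers(cloud, sel, linkage_radius = 10, min_cluster_size = 1,
                        expected_k = 2)
  cent <- ms$centroids[order(ms$centroids$x), ]
  expect_equal(cent$x, c(0.5, 100.5))
  expect_equal(cent$n, c(2L, 2L))
  expect_error(
    cluster_markers(cloud, sel, linkage_radius = 10, min_cluster_size = 1,
                    expected_k = 3),
    class = "opmcoreg_error_marker_count")
})

test_that("cluster centroids recover seeded Gaussian blob centers", {
  set.seed(31)
  centers <- rbind(c(0, 0, 0), c(60, 0, 0), c(0, 80, 40))
  pts <- do.call(rbind, lapply(1:3, function(i) {
    sweep(matrix(rnorm(150, sd = 1), ncol = 3), 2, centers[i, ], "+")
  }))
  ord <- sample(nrow(pts))  # clustering must not depend on vertex order
  cloud <- point_cloud(pts[ord, ])
  ms <- cluster_markers(cloud, region_selection(seq_len(nrow(pts))),
                        linkage_radius = 5, min_cluster_size = 5,
                        expected_k = 3)
  got <- as.matrix(ms$centroids[, c("x", "y", "z")])
  for (i in 1:3) {
    d <- sqrt(colSums((t(got) - centers[i, ])^2))
    expect_lt(min(d), 0.5)
  }
})

test_that("marker matching recovers the generating permutation for scalene layouts", {
  # triangle with sides 80/100/120 plus an off-plane fourth point
  d2 <- function(a, b) sqrt(sum((a - b)^2))
  tri <- rbind(c(0, 0, 0), c(80, 0, 0), c(12.5, 99.21568, 0))
  expect_equal(d2(tri[1, ], tri[2, ]), 80, tolerance = 1e-4)
  expect_equal(d2(tri[1, ], tri[3, ]), 100, tolerance = 1e-4)
  expect_equal(d2(tri[2, ], tri[3, ]), 120, tolerance = 1e-4)

  set.seed(32)
  for (trial in 1:10) {
    perm <- sample(3)
    motion <- random_rigid_transform()
    detected <- transform_points(tri[perm, ], motion)
    m <- match_markers(tri, detected)
    # detected row j came from designed row perm[j], so designed row i must
    # be assigned detected row match(i, perm)
    expect_identical(m$permutation, match(seq_len(3), perm))
    expect_lt(m$fre, 1e-6)
    expect_lt(rotation_angle(compose(invert(m$transform), motion)), 1e-6)
  }
})

test_that("identity layouts and equilateral symmetry behave as specified", {
  quad <- rbind(c(0, 0, 0), c(70, 0, 0), c(20, 55, 10), c(-10, 20, 60))
  m <- match_markers(quad, quad)
  expect_identical(m$permutation, 1:4)
  expect_equal(m$fre, 0, tolerance = 1e-9)
  expect_equal(m$transform$rotation, diag(3), tolerance = 1e-9)

  eq <- rbind(c(0, 0, 0), c(100, 0, 0), c(50, 50 * sqrt(3), 0))
  expect_error(match_markers(eq, eq), class = "opmcoreg_error_ambiguity")

  expect_error(match_markers(quad, quad[1:3, ]),
               class = "opmcoreg_error_marker_count")
  many <- matrix(runif(27, 0, 100), ncol = 3)
  expect_error(match_markers(rbind(quad, many[1:5, ]),
                             rbind(quad, many[1:5, ])),
               class = "opmcoreg_error_unsupported")
})

test_that("marker matching is invariant to detected ordering and rigid motion", {
  quad <- rbind(c(0, 0, 0), c(70, 0, 0), c(20, 55, 10), c(-10, 20, 60))
  set.seed(33)
  base <- match_markers(quad, transform_points(quad, random_rigid_transform()))
  for (trial in 1:5) {
    q <- random_rigid_transform()
    shuffled <- sample(4)
    m <- match_markers(quad, transform_points(quad[shuffled, ], q))
    expect_equal(m$fre, base$fre, tolerance = 1e-9)
    # recovered map still sends designed point i to its own image
    expect_equal(transform_points(quad, m$transform),
                 transform_points(quad, q), tolerance = 1e-6)
  }
})
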