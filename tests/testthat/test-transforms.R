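test_that("rigid_transform rejects reflections, scale, and bad shapes", {
  expect_s3_class(rigid_transform(), "rigid_transform")
  expect_error(rigid_transform(diag(c(1, 1, -1))), class = "opmcoreg_error_input")
  expect_error(rigid_transform(2 * diag(3)), class = "opmcoreg_error_input")
  expect_error(rigid_transform(diag(3), c(1, 2)), class = "opmcoreg_error_input")
  expect_error(rigid_transform(matrix(rnorm(9), 3)), class = "opmcoreg_error_input")
})

test_that("kabsch_align recovers identity, pure translation, and a known rotation", {
  tri <- rbind(c(0, 0, 0), c(100, 0, 0), c(0, 100, 0))
  fit <- kabsch_align(tri, tri)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(fit$fre, 0, tolerance = 1e-12)

  shift <- c(10, -5, 3)
  fit <- kabsch_align(tri, sweep(tri, 2, shift, "+"))
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$transform$translation, shift, tolerance = 1e-12)
  expect_equal(fit$fre, 0, tolerance = 1e-12)

  scalene <- rbind(c(0, 0, 0), c(80, 0, 0), c(30, 60, 0))
  fit <- kabsch_align(scalene, scalene %*% t(rot_z(90)))
  expect_equal(fit$transform$rotation, rot_z(90), tolerance = 1e-9)
  expect_equal(transform_points(c(80, 0, 0), fit$transform), c(0, 80, 0),
               tolerance = 1e-9)
  expect_lt(fit$fre, 1e-9)
})

test_that("kabsch_align flags degenerate and mismatched inputs", {
  line <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_error(kabsch_align(line, line), class = "opmcoreg_error_degenerate")
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))
  expect_error(kabsch_align(dup, dup), class = "opmcoreg_error_degenerate")
  tri <- rbind(c(0, 0, 0), c(80, 0, 0), c(30, 60, 0))
  expect_error(kabsch_align(tri, tri[1:2, ]), class = "opmcoreg_error_input")
  expect_error(kabsch_align(tri[1:2, ], tri[1:2, ]), class = "opmcoreg_error_input")
})

test_that("kabsch_align recovers random rigid motions and never returns a reflection", {
  set.seed(42)
  for (i in 1:200) {
    truth <- random_rigid_transform(max_angle = pi, max_translation = 200)
    pts <- matrix(runif(30, -100, 100), ncol = 3)
    fit <- kabsch_align(pts, transform_points(pts, truth))
    expect_lt(rotation_angle(compose(invert(fit$transform), truth)), 1e-7)
    expect_lt(sqrt(sum((fit$transform$translation - truth$translation)^2)), 1e-7)
  }
  # mirrored targets: determinant stays +1, residual error instead
  set.seed(7)
  for (i in 1:20) {
    pts <- matrix(runif(30, -100, 100), ncol = 3)
    mirrored <- pts %*% diag(c(-1, 1, 1))
    fit <- kabsch_align(pts, mirrored)
    expect_equal(det(fit$transform$rotation), 1, tolerance = 1e-9)
    expect_gt(fit$fre, 0)
  }
})

test_that("compose and invert satisfy group identities and frame tagging", {
  t1 <- rigid_transform(rot_z(30), c(5, 5, 5), from = "device", to = "head")
  expect_equal(compose(rigid_transform(from = "head", to = "head"), t1)$rotation,
               t1$rotation)
  rt <- compose(invert(t1), t1)
  expect_equal(rt$rotation, diag(3), tolerance = 1e-12)
  expect_equal(rt$translation, c(0, 0, 0), tolerance = 1e-12)
  expect_identical(rt$from, "device")
  expect_identical(rt$to, "device")

  t2 <- rigid_transform(rot_z(45), c(0, 1, 2), from = "head", to = "mri")
  set.seed(1)
  p <- matrix(runif(300, -50, 50), ncol = 3)
  expect_equal(transform_points(p, compose(t2, t1)),
               transform_points(transform_points(p, t1), t2), tolerance = 1e-9)
  expect_error(compose(t1, t2), class = "opmcoreg_error_frame")

  # inversion round-trips random points
  set.seed(2)
  tf <- random_rigid_transform()
  expect_equal(transform_points(transform_points(p, tf), invert(tf)), p,
               tolerance = 1e-9)
  expect_equal(invert(rigid_transform(translation = c(3, 0, 0)))$translation,
               c(-3, 0, 0))
})

test_that("point and direction mapping are isometries", {
  set.seed(3)
  tf <- random_rigid_transform()
  p <- matrix(runif(150, -80, 80), ncol = 3)
  expect_equal(as.matrix(dist(transform_points(p, tf))), as.matrix(dist(p)),
               tolerance = 1e-9)

  d <- p / sqrt(rowSums(p^2))
  rd <- transform_directions(d, tf)
  expect_equal(sqrt(rowSums(rd^2)), rep(1, nrow(d)), tolerance = 1e-12)
  expect_equal(rd %*% t(rd), d %*% t(d), tolerance = 1e-9)  # angles preserved
  expect_equal(transform_directions(c(1, 0, 0),
                                    rigid_transform(rot_z(90), c(9, 9, 9))),
               c(0, 1, 0), tolerance = 1e-12)
  expect_error(transform_directions(c(0, 0, 0), tf),
               class = "opmcoreg_error_input")
  expect_error(transform_points(c(1, NA, 0), tf), class = "opmcoreg_error_input")
})

test_that("tibble input to transform_points comes back as a tibble", {
  tf <- rigid_transform(translation = c(1, 2, 3))
  tb <- tibble::tibble(x = c(0, 1), y = c(0, 1), z = c(0, 1), tag = c("a", "b"))
  out <- transform_points(tb, tf)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$x, c(1, 2))
  expect_equal(out$tag, c("a", "b"))
})

test_that("build_head_frame implements the mid-ear/nasion convention", {
  hf <- build_head_frame(c(0, 100, 0), c(-75, 0, 0), c(75, 0, 0))
  expect_equal(transform_points(c(0, 100, 0), hf), c(100, 0, 0), tolerance = 1e-12)
  expect_equal(transform_points(c(-75, 0, 0), hf), c(0, 75, 0), tolerance = 1e-12)
  expect_equal(transform_points(c(75, 0, 0), hf), c(0, -75, 0), tolerance = 1e-12)

  # canonical fiducials give the identity
  hf0 <- build_head_frame(c(100, 0, 0), c(0, 75, 0), c(0, -75, 0))
  expect_equal(hf0$rotation, diag(3), tolerance = 1e-12)
  expect_equal(hf0$translation, c(0, 0, 0), tolerance = 1e-12)

  expect_error(build_head_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
               class = "opmcoreg_error_degenerate")
})

test_that("build_head_frame undoes any rigid motion of canonical fiducials", {
  nas <- c(100, 0, 0); lpa <- c(0, 75, 0); rpa <- c(0, -75, 0)
  set.seed(4)
  for (i in 1:25) {
    q <- random_rigid_transform()
    hf <- build_head_frame(transform_points(nas, q), transform_points(lpa, q),
                           transform_points(rpa, q))
    rt <- compose(hf, rigid_transform(q$rotation, q$translation))
    expect_lt(max(abs(rt$rotation - diag(3))), 1e-9)
    expect_lt(sqrt(sum(rt$translation^2)), 1e-9)
  }
})

test_that("homogeneous round-trip preserves transforms exactly", {
  set.seed(5)
  tf <- random_rigid_transform(from = "head", to = "mri")
  back <- from_homogeneous(as_homogeneous(tf), from = "head", to = "mri")
  expect_equal(back$rotation, tf$rotation, tolerance = 1e-15)
  expect_equal(back$translation, tf$translation, tolerance = 1e-15)
})
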