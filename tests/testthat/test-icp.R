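test_that("coarse_match enforces the four-pair minimum and recovers known motions", {
  pts <- rbind(c(0, 0, 0), c(50, 0, 0), c(0, 50, 0), c(10, 20, 40))
  fit <- coarse_match(pts, pts)
  expect_equal(fit$transform$rotation, diag(3), tolerance = 1e-12)
  expect_equal(fit$fre, 0, tolerance = 1e-12)

  set.seed(20)
  truth <- random_rigid_transform()
  fit <- coarse_match(pts, transform_points(pts, truth))
  expect_lt(rotation_angle(compose(invert(fit$transform), truth)), 1e-9)

  expect_error(coarse_match(pts[1:3, ], pts[1:3, ]),
               class = "opmcoreg_error_input", regexp = "four")
})

test_that("region cropping and sphere selection agree with brute force", {
  set.seed(21)
  v <- matrix(runif(300, -50, 50), ncol = 3)
  pc <- point_cloud(v, colors = matrix(128, 100, 3),
                    faces = matrix(c(0L, 1L, 2L), 1))
  sel <- region_selection(11:20)
  cropped <- crop_region(pc, sel)
  expect_equal(n_vertices(cropped), 10)
  expect_identical(unname(as.matrix(cropped$vertices[, c("x", "y", "z")])),
                   v[11:20, ])
  expect_true(has_colors <- "r" %in% names(cropped$vertices))
  expect_null(cropped$faces)
  expect_error(crop_region(pc, region_selection(101)),
               class = "opmcoreg_error_input")
  expect_error(region_selection(integer(0)), class = "opmcoreg_error_input")

  center <- c(0, 0, 0)
  sel2 <- select_by_sphere(pc, center, 30)
  oracle <- which(sqrt(rowSums(sweep(v, 2, center)^2)) <= 30)
  expect_setequal(sel2$indices, oracle)
  # radius beyond the extent selects everything
  expect_length(select_by_sphere(pc, center, 1e4)$indices, 100)
  # tight radius around one isolated vertex selects exactly it
  sel3 <- select_by_sphere(pc, v[7, ], 1e-6)
  expect_identical(sel3$indices, 7L)
})

test_that("compiled nearest-neighbour search matches the plain-R oracle", {
  set.seed(22)
  for (trial in 1:5) {
    src <- matrix(runif(3 * sample(5:200, 1), -100, 100), ncol = 3)
    tgt <- matrix(runif(3 * sample(5:200, 1), -100, 100), ncol = 3)
    nn <- nearest_neighbors(src, tgt)
    oracle <- nn_oracle(src, tgt)
    expect_identical(nn$target, oracle$index)
    expect_equal(nn$distance, oracle$distance, tolerance = 1e-12)
  }
  # ties break to the lowest target index
  nn <- nearest_neighbors(rbind(c(0, 0, 0)), rbind(c(1, 0, 0), c(-1, 0, 0)))
  expect_identical(nn$target, 1L)
})

test_that("ICP on identical clouds is a fixed point", {
  sphere <- fib_sphere(500)
  res <- icp_register(sphere, sphere)
  expect_lt(max(abs(res$transform$rotation - diag(3))), 1e-9)
  expect_lt(sqrt(sum(res$transform$translation^2)), 1e-9)
  expect_equal(res$rms, 0, tolerance = 1e-12)
  expect_lte(res$iterations, 2)
  expect_true(res$converged)
})

test_that("ICP recovers a small rigid offset of a dense scalp surface", {
  ph <- test_phantom()
  scalp <- as.matrix(ph$scalp_head$vertices[, c("x", "y", "z")])
  truth <- rigid_transform(rot_z(3), c(2, 1, -1))
  moved <- transform_points(scalp, invert(truth))
  res <- icp_register(moved, scalp,
                      params = icp_params(convergence_tol = 1e-6))
  mismatch <- compose(invert(res$transform), truth)
  expect_lt(sqrt(sum(mismatch$translation^2)), 0.05)
  expect_lt(rotation_angle(mismatch) * 180 / pi, 0.05)
  expect_true(res$converged)
})

test_that("non-overlapping clouds with a distance cap fail registration", {
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  far <- sweep(cube, 2, c(1000, 0, 0), "+")
  expect_error(
    icp_register(cube, far, params = icp_params(max_pair_distance = 10)),
    class = "opmcoreg_error_registration")
})

test_that("retained-pair RMS is monotone non-increasing across iterations", {
  ph <- test_phantom()
  set.seed(23)
  for (s in 1:3) {
    sc <- simulate_scan(ph, colored = FALSE, noise_sigma = 0.5, seed = s)
    init <- perturb_transform(invert(sc$scan_pose), 4, 4)
    res <- icp_register(crop_region(sc$cloud, sc$face_region), ph$scalp_head,
                        init = init)
    expect_true(all(diff(res$rms_history) <= 1e-9))
  }
})

test_that("ICP is equivariant under a common rigid motion of both clouds", {
  ph <- test_phantom()
  sc <- simulate_scan(ph, colored = FALSE, noise_sigma = 0.3, seed = 9)
  src <- crop_region(sc$cloud, sc$face_region)
  set.seed(24)
  init <- perturb_transform(invert(sc$scan_pose), 3, 3)
  base <- icp_register(src, ph$scalp_head, init = init)

  q <- random_rigid_transform(max_angle = pi / 2, max_translation = 100)
  res_q <- icp_register(transform_cloud(src, q),
                        transform_cloud(ph$scalp_head, q),
                        init = compose(q, compose(init, invert(q))))
  expect_equal(res_q$rms, base$rms, tolerance = 1e-6)
  conj <- compose(q, compose(base$transform, invert(q)))
  expect_lt(rotation_angle(compose(invert(res_q$transform), conj)), 1e-6)
  expect_lt(sqrt(sum((res_q$transform$translation - conj$translation)^2)), 1e-4)
})

test_that("icp_params validates its ranges", {
  expect_error(icp_params(trim_fraction = 0.5), class = "opmcoreg_error_input")
  expect_error(icp_params(convergence_tol = 0), class = "opmcoreg_error_input")
  expect_error(icp_params(max_iterations = 0), class = "opmcoreg_error_input")
  expect_s3_class(icp_params(trim_fraction = 0), "icp_params")
})
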