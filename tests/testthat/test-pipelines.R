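test_that("stylus pipeline recovers ground truth exactly without noise", {
  ph <- test_phantom()
  dig <- simulate_fastrak(ph, noise_sigma = 0, seed = 1)
  res <- run_fastrak(ph$sensors_device, ph$designed_refs, dig, ph$mri_scalp,
                     mri_fiducials = ph$mri_fiducials)
  err <- sensor_errors(res, ph)
  expect_lt(max(err$pos), 1e-6)
  expect_lt(max(err$deg), 1e-6 * 180 / pi)
  expect_equal(res$fre_transform1, 0, tolerance = 1e-9)
})

test_that("stylus pipeline stays below 2 mm / 1 degree under digitization noise", {
  ph <- test_phantom()
  pos <- deg <- numeric(20)
  for (s in 1:20) {
    dig <- simulate_fastrak(ph, noise_sigma = 0.5, seed = s)
    res <- run_fastrak(ph$sensors_device, ph$designed_refs, dig, ph$mri_scalp,
                       mri_fiducials = ph$mri_fiducials)
    err <- sensor_errors(res, ph)
    pos[s] <- mean(err$pos)
    deg[s] <- mean(err$deg)
  }
  expect_lt(mean(pos), 2)
  expect_lt(mean(deg), 1)
})

test_that("stylus pipeline validates its inputs", {
  ph <- test_phantom()
  dig <- simulate_fastrak(ph, noise_sigma = 0, seed = 1)
  dig$helmet_refs <- dig$helmet_refs[1:2, ]
  expect_error(
    run_fastrak(ph$sensors_device, ph$designed_refs, dig, ph$mri_scalp),
    class = "opmcoreg_error_input")
})

test_that("structured-light pipeline recovers ground truth without noise", {
  ph <- test_phantom()
  sc <- simulate_scan(ph, colored = TRUE, noise_sigma = 0, seed = 2)
  res <- run_structured_light(ph$sensors_device, ph$designed_refs, sc$cloud,
                              sc$face_picks, sc$face_pairs, sc$face_region,
                              ph$mri_scalp)
  err <- sensor_errors(res, ph)
  expect_lt(max(err$pos), 1e-3)
  expect_lt(max(err$deg), 0.01)
})

test_that("structured-light pipeline stays below 2.5 mm under scan noise", {
  ph <- test_phantom()
  pos <- numeric(10)
  for (s in 1:10) {
    sc <- simulate_scan(ph, colored = TRUE, noise_sigma = 0.3, seed = s)
    res <- run_structured_light(ph$sensors_device, ph$designed_refs, sc$cloud,
                                sc$face_picks, sc$face_pairs, sc$face_region,
                                ph$mri_scalp)
    pos[s] <- mean(sensor_errors(res, ph)$pos)
  }
  expect_lt(mean(pos), 2.5)
})

test_that("structured-light pipeline propagates marker and colour failures", {
  ph <- test_phantom()
  sc <- simulate_scan(ph, colored = FALSE, noise_sigma = 0, seed = 2)
  expect_error(
    run_structured_light(ph$sensors_device, ph$designed_refs, sc$cloud,
                         sc$face_picks, sc$face_pairs, sc$face_region,
                         ph$mri_scalp),
    class = "opmcoreg_error_input")
  # demanding a wrong marker count raises a marker-count error
  sc2 <- simulate_scan(ph, colored = TRUE, noise_sigma = 0, seed = 2)
  refs5 <- rbind(ph$designed_refs,
                 tibble::tibble(label = "M9", x = 0, y = 0, z = 0))
  expect_error(
    run_structured_light(ph$sensors_device, refs5, sc2$cloud, sc2$face_picks,
                         sc2$face_pairs, sc2$face_region, ph$mri_scalp),
    class = "opmcoreg_error_marker_count")
})

test_that("laser pipeline recovers ground truth and reports the helmet fit", {
  ph <- test_phantom()
  sc <- simulate_scan(ph, colored = FALSE, noise_sigma = 0, seed = 3)
  res <- run_laser(ph$sensors_device, ph$designed_helmet, sc$cloud,
                   sc$face_picks, sc$helmet_pairs, sc$helmet_region,
                   sc$face_pairs, sc$face_region, ph$mri_scalp)
  err <- sensor_errors(res, ph)
  expect_lt(max(err$pos), 0.05)
  expect_false(is.null(res$icp_rms_transform1))
  expect_lt(res$icp_rms_transform1, 1e-6)

  short <- lapply(sc$helmet_pairs, function(m) m[1:3, ])
  expect_error(
    run_laser(ph$sensors_device, ph$designed_helmet, sc$cloud, sc$face_picks,
              short, sc$helmet_region, sc$face_pairs, sc$face_region,
              ph$mri_scalp),
    class = "opmcoreg_error_input")
})

test_that("moving the MRI rigidly moves the recovered sensors identically", {
  ph <- test_phantom()
  dig <- simulate_fastrak(ph, noise_sigma = 0, seed = 4)
  base <- run_fastrak(ph$sensors_device, ph$designed_refs, dig, ph$mri_scalp,
                      mri_fiducials = ph$mri_fiducials)
  set.seed(44)
  q <- random_rigid_transform(max_angle = pi / 4, max_translation = 50)
  fid_q <- ph$mri_fiducials
  fid_q[, c("x", "y", "z")] <- transform_points(
    as.matrix(ph$mri_fiducials[, c("x", "y", "z")]), q)
  moved <- run_fastrak(ph$sensors_device, ph$designed_refs, dig,
                       transform_cloud(ph$mri_scalp, q), mri_fiducials = fid_q)
  expect_equal(sensor_xyz(moved$sensors_mri),
               transform_points(sensor_xyz(base$sensors_mri), q),
               tolerance = 1e-6)
})

test_that("tri-axis arrays keep orthonormal orientation triads through pipelines", {
  ph <- make_phantom(phantom_spec(seed = 6, n_lat = 44, n_lon = 72,
                                  tri_axis = TRUE))
  dig <- simulate_fastrak(ph, noise_sigma = 0, seed = 5)
  res <- run_fastrak(ph$sensors_device, ph$designed_refs, dig, ph$mri_scalp,
                     mri_fiducials = ph$mri_fiducials)
  s <- res$sensors_mri
  expect_equal(n_axes(s), 3)
  for (i in seq_len(nrow(s))) {
    triad <- rbind(sensor_ori(s, 1)[i, ], sensor_ori(s, 2)[i, ],
                   sensor_ori(s, 3)[i, ])
    expect_equal(triad %*% t(triad), diag(3), tolerance = 1e-9)
  }
  # all three axes rotated identically: triad relations match the truth's
  truth <- ph$sensors_mri
  for (k in 1:3) {
    expect_equal(sensor_ori(s, k), sensor_ori(truth, k), tolerance = 1e-9)
  }
})

test_that("report prints the errors and warns beyond the quality bounds", {
  ph <- test_phantom()
  dig <- simulate_fastrak(ph, noise_sigma = 0.3, seed = 6)
  res <- run_fastrak(ph$sensors_device, ph$designed_refs, dig, ph$mri_scalp,
                     mri_fiducials = ph$mri_fiducials)
  expect_output(expect_no_warning(report(res)), "face ICP RMS")

  bad <- res
  bad$icp_rms_transform2 <- 2.5
  expect_warning(capture.output(report(bad)), "2.0 mm quality bound")
  bad2 <- res
  bad2$icp_rms_transform1 <- 0.9
  expect_warning(capture.output(report(bad2)), "0.8 mm quality bound")
  ok <- res
  ok$icp_rms_transform2 <- 1.2
  expect_no_warning(capture.output(report(ok)))
})

test_that("tidiers and glance expose the result as tibbles", {
  ph <- test_phantom()
  dig <- simulate_fastrak(ph, noise_sigma = 0, seed = 7)
  res <- run_fastrak(ph$sensors_device, ph$designed_refs, dig, ph$mri_scalp,
                     mri_fiducials = ph$mri_fiducials)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), nrow(ph$sensors_device))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$device, "fastrak")
  expect_s3_class(autoplot(res, mri_scalp = ph$mri_scalp), "ggplot")
})
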