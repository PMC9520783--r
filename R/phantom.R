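# Seeded synthetic phantom: an ellipsoidal head with a nose bump, a rigid
# helmet as an offset surface carrying sensor slots and coloured reference
# markers, and per-device simulated measurements (stylus digitization,
# structured-light scan, laser scan) with known ground-truth transforms.
#
# The simulated measurements sample the *vertices* of the phantom meshes
# (plus deterministic marker-patch points), so in the noiseless limit every
# digitized or scanned point has an exact counterpart on the reference
# surface and the pipelines recover the ground truth to machine precision.
# Real scans resample the surface continuously; see the methods vignette for
# what this simplification does and does not validate.

#' Phantom specification
#'
#' Parameters of the synthetic head/helmet phantom. Defaults describe an
#' adult-head-sized ellipsoid (semi-axes 90 x 70 x 100 mm), a 12 mm nose
#' bump (the asymmetry that makes face registration and the head frame
#' well-posed), a rigid helmet floating 6 mm above the scalp with 85 sensor
#' slots, and 4 reference markers in an asymmetric layout. Noise defaults per
#' modality: stylus 0.5 mm, structured-light scan 0.3 mm, laser scan 0.1 mm.
#'
#' @param scalp_semiaxes Ellipsoid semi-axes (mm): anterior-posterior, left,
#'   up.
#' @param nose_amplitude Radial nose-bump amplitude (mm).
#' @param nose_width Angular nose-bump width (radians).
#' @param standoff Helmet standoff above the scalp (mm).
#' @param n_sensors Number of sensor slots.
#' @param n_markers Number of helmet reference markers (3–5).
#' @param n_lat,n_lon Mesh resolution (latitude x longitude grid).
#' @param noise_fastrak,noise_structured_light,noise_laser Default isotropic
#'   Gaussian noise sigma (mm) per modality.
#' @param tri_axis If `TRUE`, sensors carry three orthonormal orientation
#'   vectors (radial first) instead of one.
#' @param seed Integer seed fixing every stochastic draw (ground-truth
#'   transforms included).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(scalp_semiaxes = c(90, 70, 100),
                         nose_amplitude = 12, nose_width = 0.25,
                         standoff = 6, n_sensors = 85, n_markers = 4,
                         n_lat = 64, n_lon = 108,
                         noise_fastrak = 0.5, noise_structured_light = 0.3,
                         noise_laser = 0.1, tri_axis = FALSE, seed = 1) {
  if (any(scalp_semiaxes <= 0) || standoff <= 0 || nose_amplitude < 0) {
    abort_input("Phantom lengths must be positive.")
  }
  if (n_sensors < 1) abort_input("`n_sensors` must be >= 1.")
  if (n_markers < 3 || n_markers > 5) {
    abort_input("`n_markers` must be between 3 and 5.")
  }
  structure(list(scalp_semiaxes = as.numeric(scalp_semiaxes),
                 nose_amplitude = nose_amplitude, nose_width = nose_width,
                 standoff = standoff, n_sensors = as.integer(n_sensors),
                 n_markers = as.integer(n_markers),
                 n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
                 noise_fastrak = noise_fastrak,
                 noise_structured_light = noise_structured_light,
                 noise_laser = noise_laser,
                 tri_axis = isTRUE(tri_axis), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Nose bump direction: anterior, 25 degrees below the ear-level plane.
NOSE_ELEVATION <- -25 * pi / 180

# Scalp surface point(s) at spherical parameters (theta latitude, phi
# longitude), vectorized. Ellipsoid plus a radial Gaussian nose bump.
scalp_surface <- function(theta, phi, spec) {
  u <- cbind(cos(theta) * cos(phi), cos(theta) * sin(phi), sin(theta))
  base <- sweep(u, 2, spec$scalp_semiaxes, "*")
  d0 <- c(cos(NOSE_ELEVATION), 0, sin(NOSE_ELEVATION))
  ang <- acos(pmin(1, pmax(-1, u %*% d0)))
  amp <- spec$nose_amplitude * exp(-ang^2 / (2 * spec$nose_width^2))
  r <- sqrt(rowSums(base^2))
  base * (1 + as.numeric(amp) / r)
}

# Outward unit normals of the scalp surface, by finite differences of the
# parameterization.
scalp_normal <- function(theta, phi, spec) {
  eps <- 1e-5
  dth <- (scalp_surface(theta + eps, phi, spec) -
            scalp_surface(theta - eps, phi, spec)) / (2 * eps)
  dph <- (scalp_surface(theta, phi + eps, spec) -
            scalp_surface(theta, phi - eps, spec)) / (2 * eps)
  n <- cbind(dth[, 2] * dph[, 3] - dth[, 3] * dph[, 2],
             dth[, 3] * dph[, 1] - dth[, 1] * dph[, 3],
             dth[, 1] * dph[, 2] - dth[, 2] * dph[, 1])
  n <- n / sqrt(rowSums(n^2))
  p <- scalp_surface(theta, phi, spec)
  flip <- rowSums(n * p) < 0
  n[flip, ] <- -n[flip, ]
  n
}

helmet_surface <- function(theta, phi, spec) {
  scalp_surface(theta, phi, spec) + spec$standoff * scalp_normal(theta, phi, spec)
}

# Parameter-grid masks partitioning the head into the helmet coverage, the
# exposed face area, and the remaining exposed scalp.
helmet_mask_fun <- function(theta, phi) {
  theta >= 22 * pi / 180 | (cos(phi) < -0.08 & theta >= -40 * pi / 180)
}
face_mask_fun <- function(theta, phi) {
  theta <= 12 * pi / 180 & cos(phi) > 0.17
}

# Triangulate a (lat x lon) grid, phi-wrapping, restricted to vertices with
# keep = TRUE. Returns 0-based faces referring to the order of kept vertices.
grid_faces <- function(n_lat, n_lon, keep) {
  idx <- matrix(NA_integer_, n_lat, n_lon)
  idx[keep] <- seq_len(sum(keep))
  quads <- expand.grid(i = seq_len(n_lat - 1), j = seq_len(n_lon))
  j2 <- ifelse(quads$j == n_lon, 1L, quads$j + 1L)
  a <- idx[cbind(quads$i, quads$j)]
  b <- idx[cbind(quads$i + 1L, quads$j)]
  c_ <- idx[cbind(quads$i, j2)]
  d <- idx[cbind(quads$i + 1L, j2)]
  ok <- !is.na(a) & !is.na(b) & !is.na(c_) & !is.na(d)
  rbind(cbind(a[ok], b[ok], d[ok]), cbind(a[ok], d[ok], c_[ok])) - 1L
}

# Greedy farthest-point sampling; deterministic (starts at the highest
# vertex, ties to the lowest index).
farthest_point_sample <- function(pts, n) {
  m <- nrow(pts)
  if (n >= m) return(seq_len(m))
  sel <- integer(n)
  sel[1] <- which.max(pts[, 3])
  d2 <- rowSums(sweep(pts, 2, pts[sel[1], ])^2)
  for (k in seq_len(n - 1)) {
    sel[k + 1] <- which.max(d2)
    d2 <- pmin(d2, rowSums(sweep(pts, 2, pts[sel[k + 1], ])^2))
  }
  sel
}

# Marker slot parameters (theta, phi in degrees) on the helmet; an
# asymmetric, scalene layout so correspondence matching is unambiguous.
MARKER_SLOTS <- rbind(c(70, 10), c(35, 100), c(45, 215), c(55, 320), c(30, 170))

# Deterministic marker-patch sample points around a parametric center:
# concentric rings (radii ~1.3/2.6/3.9 mm) mapped through the local metric
# onto the helmet offset surface, so patch points lie exactly on the surface.
marker_patch_points <- function(theta0, phi0, spec) {
  eps <- 1e-5
  s_th <- sqrt(sum(((scalp_surface(theta0 + eps, phi0, spec) -
                       scalp_surface(theta0 - eps, phi0, spec)) / (2 * eps))^2))
  s_ph <- sqrt(sum(((scalp_surface(theta0, phi0 + eps, spec) -
                       scalp_surface(theta0, phi0 - eps, spec)) / (2 * eps))^2))
  radii <- c(1.3, 2.6, 3.9)
  counts <- c(6L, 12L, 18L)
  th <- theta0
  ph <- phi0
  for (r in seq_along(radii)) {
    alpha <- 2 * pi * (seq_len(counts[r]) - 1) / counts[r]
    th <- c(th, theta0 + radii[r] * cos(alpha) / s_th)
    ph <- c(ph, phi0 + radii[r] * sin(alpha) / s_ph)
  }
  helmet_surface(th, ph, spec)
}

#' Generate the synthetic head/helmet phantom
#'
#' Builds the full phantom from a [phantom_spec()]: the triangulated scalp
#' surface (head frame and, through the ground-truth transform, the MRI
#' frame), the helmet offset surface with sensor slots (inward radial
#' orientations) and labelled reference markers, and the ground-truth
#' device-to-head and head-to-MRI transforms drawn from the seed. The
#' designed reference points are the device-frame centroids of the
#' deterministic marker-patch point sets. All randomness flows from
#' `spec$seed`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `opm_phantom` with elements including
#'   `scalp_head`/`mri_scalp` ([point_cloud()]s), `helmet_head`/
#'   `designed_helmet`, `sensors_device`/`sensors_head`/`sensors_mri`
#'   ([sensor_array()]s; `sensors_mri` is the ground truth), `designed_refs`
#'   (labelled device-frame marker points), `fiducials_head`,
#'   `mri_fiducials`, `face_indices`/`exposed_indices` (into the scalp mesh),
#'   `marker_patches`, and `truth` (`t1` device to head, `t2` head to MRI).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, {
    theta <- seq(-60 * pi / 180, 88 * pi / 180, length.out = spec$n_lat)
    phi <- seq(0, 2 * pi, length.out = spec$n_lon + 1)[-(spec$n_lon + 1)]
    # (lat, lon) matrix layout, lat varying fastest: row i = theta[i], col j
    # = phi[j]. Vertex parameters are jittered within their grid cell: real
    # scans and segmentations are not lattice-sampled, and a strictly regular
    # grid gives point-to-point ICP spurious lattice-shift minima.
    n <- spec$n_lat * spec$n_lon
    th <- rep(theta, times = spec$n_lon) +
      runif(n, -0.35, 0.35) * (theta[2] - theta[1])
    ph <- rep(phi, each = spec$n_lat) +
      runif(n, -0.35, 0.35) * (phi[2] - phi[1])
    scalp_v <- scalp_surface(th, ph, spec)
    keep_all <- matrix(TRUE, spec$n_lat, spec$n_lon)
    scalp_faces <- grid_faces(spec$n_lat, spec$n_lon, keep_all)
    scalp_head <- point_cloud(scalp_v, faces = scalp_faces)

    hm <- matrix(helmet_mask_fun(th, ph), spec$n_lat, spec$n_lon)
    fm <- matrix(face_mask_fun(th, ph), spec$n_lat, spec$n_lon)
    helmet_idx <- which(as.vector(hm))
    helmet_v <- helmet_surface(th[helmet_idx], ph[helmet_idx], spec)
    helmet_faces <- grid_faces(spec$n_lat, spec$n_lon, hm)
    helmet_head <- point_cloud(helmet_v, faces = helmet_faces)

    face_indices <- which(as.vector(fm))
    exposed_indices <- which(!as.vector(hm))

    # sensor slots: spread over the helmet, pointing inward along the normal
    slot_idx <- farthest_point_sample(helmet_v, spec$n_sensors)
    slot_th <- th[helmet_idx][slot_idx]
    slot_ph <- ph[helmet_idx][slot_idx]
    pos <- helmet_v[slot_idx, , drop = FALSE]
    nrm <- scalp_normal(slot_th, slot_ph, spec)
    sens <- tibble(label = sprintf("S%03d", seq_len(spec$n_sensors)),
                   x = pos[, 1], y = pos[, 2], z = pos[, 3],
                   ox1 = -nrm[, 1], oy1 = -nrm[, 2], oz1 = -nrm[, 3])
    if (spec$tri_axis) {
      eps <- 1e-5
      tang <- (scalp_surface(slot_th + eps, slot_ph, spec) -
                 scalp_surface(slot_th - eps, slot_ph, spec)) / (2 * eps)
      tang <- tang - rowSums(tang * -nrm) * -nrm
      tang <- tang / sqrt(rowSums(tang^2))
      t2v <- cbind(-nrm[, 2] * tang[, 3] + nrm[, 3] * tang[, 2],
                   -nrm[, 3] * tang[, 1] + nrm[, 1] * tang[, 3],
                   -nrm[, 1] * tang[, 2] + nrm[, 2] * tang[, 1])
      sens$ox2 <- tang[, 1]; sens$oy2 <- tang[, 2]; sens$oz2 <- tang[, 3]
      sens$ox3 <- t2v[, 1]; sens$oy3 <- t2v[, 2]; sens$oz3 <- t2v[, 3]
    }
    sensors_head <- sensor_array(sens)

    # marker patches + designed reference points (patch centroids)
    slots <- MARKER_SLOTS[seq_len(spec$n_markers), , drop = FALSE] * pi / 180
    marker_patches <- lapply(seq_len(spec$n_markers), function(i) {
      marker_patch_points(slots[i, 1], slots[i, 2], spec)
    })
    centroids <- t(vapply(marker_patches, colMeans, numeric(3)))

    fid <- rbind(nasion = scalp_surface(0, 0, spec),
                 lpa = scalp_surface(0, pi / 2, spec),
                 rpa = scalp_surface(0, -pi / 2, spec))
    fiducials_head <- tibble(label = c("nasion", "lpa", "rpa"),
                             x = fid[, 1], y = fid[, 2], z = fid[, 3])

    t1 <- random_rigid_transform(max_angle = 20 * pi / 180,
                                 max_translation = 30,
                                 from = "device", to = "head")
    t2 <- random_rigid_transform(max_angle = 20 * pi / 180,
                                 max_translation = 30,
                                 from = "head", to = "mri")
    t1_inv <- invert(t1)

    designed_refs <- xyz_tibble(transform_points(centroids, t1_inv))
    designed_refs <- tibble(label = sprintf("M%d", seq_len(spec$n_markers)),
                            designed_refs)

    mri_fid <- transform_points(fid, t2)
    structure(list(
      spec = spec,
      scalp_head = scalp_head,
      mri_scalp = transform_cloud(scalp_head, t2),
      helmet_head = helmet_head,
      designed_helmet = transform_cloud(helmet_head, t1_inv),
      sensors_head = sensors_head,
      sensors_device = transform_sensors(sensors_head, t1_inv),
      sensors_mri = transform_sensors(sensors_head, t2),
      designed_refs = designed_refs,
      marker_patches = marker_patches,
      fiducials_head = fiducials_head,
      mri_fiducials = tibble(label = fiducials_head$label,
                             x = mri_fid[, 1], y = mri_fid[, 2],
                             z = mri_fid[, 3]),
      face_indices = face_indices,
      exposed_indices = exposed_indices,
      truth = list(t1 = t1, t2 = t2)),
      class = "opm_phantom")
  })
}

#' @export
print.opm_phantom <- function(x, ...) {
  cat(sprintf(
    "<opm_phantom> scalp %d vertices, helmet %d vertices, %d sensors, %d markers (seed %d)\n",
    n_vertices(x$scalp_head), n_vertices(x$helmet_head),
    nrow(x$sensors_head), nrow(x$designed_refs), x$spec$seed))
  invisible(x)
}

add_noise <- function(m, sigma) {
  if (sigma <= 0) return(m)
  m + matrix(rnorm(length(m), sd = sigma), nrow = nrow(m))
}

#' Simulate a stylus digitization of the phantom
#'
#' Emulates the electromagnetic-stylus workflow: the three fiducials,
#' `n_scalp_points` scalp samples drawn from the exposed (helmet-free) scalp
#' vertices, and the helmet reference points, all expressed in a random
#' digitizer frame and perturbed by isotropic Gaussian noise.
#'
#' @param phantom An `opm_phantom`.
#' @param noise_sigma Noise sigma (mm); defaults to the spec's stylus noise.
#' @param n_scalp_points Number of digitized scalp points.
#' @param seed Seed for the digitizer pose, sampling, and noise.
#' @return A [digitized_points()] object; the ground-truth digitizer pose
#'   (head to digitizer) is attached as attribute `digitizer_pose`.
#' @export
simulate_fastrak <- function(phantom, noise_sigma = phantom$spec$noise_fastrak,
                             n_scalp_points = 200, seed = 1) {
  stopifnot(inherits(phantom, "opm_phantom"))
  if (n_scalp_points < 3) abort_input("`n_scalp_points` must be >= 3.")
  withr::with_seed(as.integer(seed), {
    pose <- random_rigid_transform(max_angle = 30 * pi / 180,
                                   max_translation = 100,
                                   from = "head", to = "digitizer")
    scalp_all <- cloud_xyz(phantom$scalp_head)
    idx <- sample(phantom$exposed_indices,
                  min(n_scalp_points, length(phantom$exposed_indices)))
    scalp <- add_noise(transform_points(scalp_all[idx, , drop = FALSE], pose),
                       noise_sigma)
    fid <- add_noise(transform_points(
      as_xyz(phantom$fiducials_head, "fiducials"), pose), noise_sigma)
    refs_head <- transform_points(as_xyz(phantom$designed_refs, "refs"),
                                  phantom$truth$t1)
    refs <- add_noise(transform_points(refs_head, pose), noise_sigma)
    out <- digitized_points(
      fiducials = tibble(label = phantom$fiducials_head$label,
                         x = fid[, 1], y = fid[, 2], z = fid[, 3]),
      scalp_points = scalp,
      helmet_refs = tibble(label = phantom$designed_refs$label,
                           x = refs[, 1], y = refs[, 2], z = refs[, 3]))
    attr(out, "digitizer_pose") <- pose
    out
  })
}

# Assemble part colours: skin for the face, gray for the helmet, saturated
# green for the marker patches; skin and gray are kept far from the default
# green HSV window so colour selection is exact by construction.
scan_colors <- function(n_face, n_helmet, n_patch) {
  skin <- cbind(pmin(255, pmax(0, 230 + round(runif(n_face, -10, 10)))),
                pmin(255, pmax(0, 180 + round(runif(n_face, -10, 10)))),
                pmin(255, pmax(0, 150 + round(runif(n_face, -10, 10)))))
  gv <- 120 + round(runif(n_helmet, -20, 20))
  gray <- cbind(gv, gv, gv)
  green <- cbind(round(runif(n_patch, 0, 25)),
                 round(runif(n_patch, 210, 255)),
                 round(runif(n_patch, 0, 25)))
  rbind(skin, gray, green)
}

#' Simulate an optical surface scan of the phantom
#'
#' Emulates a structured-light or laser scan of the subject wearing the
#' helmet: the face area of the scalp, the helmet surface, and the marker
#' patches, expressed in a random scanner frame and perturbed by isotropic
#' Gaussian noise. When `colored = TRUE` marker patches are painted saturated
#' green and everything else skin/gray, so the default HSV window selects
#' exactly the markers. Alongside the cloud, the scriptable equivalents of
#' the GUI interactions are returned: the three face picks, the face/helmet
#' region selections, and the coarse landmark pairs.
#'
#' @param phantom An `opm_phantom`.
#' @param colored If `TRUE`, per-vertex RGB colour is attached.
#' @param noise_sigma Noise sigma (mm); defaults to the spec's modality noise
#'   (structured-light when coloured, laser otherwise).
#' @param density Optional scan sampling density (points/mm^2); `NULL` keeps
#'   every surface vertex. Marker-patch points are always kept.
#' @param seed Seed for the scanner pose, subsampling, colours, and noise.
#' @return A list of class `phantom_scan`: `cloud` (the [point_cloud()] in
#'   the scanner frame), `face_region`/`helmet_region`
#'   ([region_selection()]s), `face_picks` (3 x 3, nasion/left/right order),
#'   `face_pairs` and `helmet_pairs` (lists with `source`/`target` K x 3
#'   matrices), and `scan_pose` (ground truth, head to scan).
#' @export
simulate_scan <- function(phantom, colored = TRUE,
                          noise_sigma = if (colored)
                            phantom$spec$noise_structured_light
                          else phantom$spec$noise_laser,
                          density = NULL, seed = 1) {
  stopifnot(inherits(phantom, "opm_phantom"))
  spec <- phantom$spec
  withr::with_seed(as.integer(seed), {
    pose <- random_rigid_transform(max_angle = 30 * pi / 180,
                                   max_translation = 100,
                                   from = "head", to = "scan")
    scalp_v <- cloud_xyz(phantom$scalp_head)
    face_pts <- scalp_v[phantom$face_indices, , drop = FALSE]
    helmet_pts <- cloud_xyz(phantom$helmet_head)
    if (!is.null(density)) {
      if (density <= 0) abort_input("`density` must be positive (points/mm^2).")
      keep_frac <- function(cloud, sub_idx = NULL) {
        a <- mesh_area(cloud, sub_idx)
        n <- if (is.null(sub_idx)) n_vertices(cloud) else length(sub_idx)
        min(1, density * a / n)
      }
      ff <- keep_frac(phantom$scalp_head, phantom$face_indices)
      hf <- keep_frac(phantom$helmet_head)
      fk <- sort(sample(nrow(face_pts), max(3, round(ff * nrow(face_pts)))))
      hk <- sort(sample(nrow(helmet_pts), max(3, round(hf * nrow(helmet_pts)))))
      face_pts <- face_pts[fk, , drop = FALSE]
      helmet_pts <- helmet_pts[hk, , drop = FALSE]
    }
    patch_pts <- do.call(rbind, phantom$marker_patches)
    all_head <- rbind(face_pts, helmet_pts, patch_pts)
    v <- add_noise(transform_points(all_head, pose), noise_sigma)
    nf <- nrow(face_pts); nh <- nrow(helmet_pts); np <- nrow(patch_pts)
    cols <- if (colored) scan_colors(nf, nh, np) else NULL
    cloud <- point_cloud(v, colors = cols)

    face_region <- region_selection(seq_len(nf), "face area")
    helmet_region <- region_selection(nf + seq_len(nh + np), "helmet area")

    picks_head <- rbind(scalp_surface(0, 0, spec),
                        scalp_surface(-10 * pi / 180, 45 * pi / 180, spec),
                        scalp_surface(-10 * pi / 180, -45 * pi / 180, spec))
    face_picks <- transform_points(picks_head, pose)

    # coarse pairs: spread landmarks; source side as realized (noisy) scan
    # coordinates, target side exact in the destination frame
    fp_idx <- farthest_point_sample(face_pts, 4)
    face_pairs <- list(source = v[fp_idx, , drop = FALSE],
                       target = transform_points(
                         face_pts[fp_idx, , drop = FALSE], phantom$truth$t2))
    hp_idx <- farthest_point_sample(helmet_pts, 4)
    helmet_pairs <- list(
      source = transform_points(helmet_pts[hp_idx, , drop = FALSE],
                                invert(phantom$truth$t1)),
      target = v[nf + hp_idx, , drop = FALSE])

    structure(list(cloud = cloud, face_region = face_region,
                   helmet_region = helmet_region, face_picks = face_picks,
                   face_pairs = face_pairs, helmet_pairs = helmet_pairs,
                   scan_pose = pose, colored = colored,
                   n_face = nf, n_helmet = nh, n_patch = np),
              class = "phantom_scan")
  })
}

#' @export
print.phantom_scan <- function(x, ...) {
  cat(sprintf("<phantom_scan> %d vertices (%d face, %d helmet, %d marker)%s\n",
              n_vertices(x$cloud), x$n_face, x$n_helmet, x$n_patch,
              if (x$colored) ", coloured" else ""))
  invisible(x)
}

# Total triangle area (mm^2) of a mesh, optionally restricted to faces whose
# vertices all belong to sub_idx.
mesh_area <- function(cloud, sub_idx = NULL) {
  f <- cloud$faces
  if (is.null(f)) abort_input("Cloud has no faces; cannot compute area.")
  f <- f + 1L
  if (!is.null(sub_idx)) {
    inset <- logical(n_vertices(cloud))
    inset[sub_idx] <- TRUE
    f <- f[inset[f[, 1]] & inset[f[, 2]] & inset[f[, 3]], , drop = FALSE]
  }
  v <- cloud_xyz(cloud)
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}
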