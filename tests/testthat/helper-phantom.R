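# Shared fixtures. Phantoms are deterministic in their seed, so they are
# cached per (seed, size) within a test run to keep the suite fast.

.phantom_cache <- new.env(parent = emptyenv())

# Reduced-resolution phantom for unit tests; full default resolution where a
# test needs the study-scale geometry.
test_phantom <- function(seed = 1, full = FALSE) {
  key <- paste0("s", seed, if (full) "_full" else "_small")
  if (is.null(.phantom_cache[[key]])) {
    spec <- if (full) {
      phantom_spec(seed = seed)
    } else {
      phantom_spec(seed = seed, n_lat = 44, n_lon = 72)
    }
    .phantom_cache[[key]] <- make_phantom(spec)
  }
  .phantom_cache[[key]]
}

sensor_xyz <- function(sensors) unname(as.matrix(sensors[, c("x", "y", "z")]))

sensor_ori <- function(sensors, k = 1) {
  unname(as.matrix(sensors[, paste0(c("ox", "oy", "oz"), k)]))
}

# Mean per-channel position error (mm) and orientation error (deg) of a
# co-registration result against the phantom's ground truth.
sensor_errors <- function(result, phantom) {
  dp <- sensor_xyz(result$sensors_mri) - sensor_xyz(phantom$sensors_mri)
  cosang <- rowSums(sensor_ori(result$sensors_mri) * sensor_ori(phantom$sensors_mri))
  list(pos = sqrt(rowSums(dp^2)),
       deg = acos(pmin(1, pmax(-1, cosang))) * 180 / pi)
}

# O(N*M) nearest-neighbour oracle in plain R, independent of the compiled
# search used by the package.
nn_oracle <- function(source, target) {
  idx <- integer(nrow(source))
  d <- numeric(nrow(source))
  for (i in seq_len(nrow(source))) {
    di <- sqrt(colSums((t(target) - source[i, ])^2))
    idx[i] <- which.min(di)
    d[i] <- di[idx[i]]
  }
  list(index = idx, distance = d)
}

# Rotation matrix about z built independently of the package (closed form).
rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

# Quasi-uniform points on a sphere (Fibonacci lattice).
fib_sphere <- function(n, radius = 100) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

# Perturb a transform by a given translation magnitude (mm) and rotation
# magnitude (deg), drawn directions from the current RNG.
perturb_transform <- function(transform, mm, deg) {
  ax <- rnorm(3)
  dir <- rnorm(3)
  delta <- rigid_transform(
    opmcoreg:::rotation_about_axis(ax, deg * pi / 180),
    dir / sqrt(sum(dir^2)) * mm)
  tf <- compose(delta, rigid_transform(transform$rotation, transform$translation))
  rigid_transform(tf$rotation, tf$translation)
}
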