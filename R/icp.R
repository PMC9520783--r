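# Surface registration: coarse landmark-pair initialization and trimmed
# point-to-point iterative closest point (ICP) refinement. Correspondences run
# from the (transformed) source points to target *vertices*; the denser,
# segmented surface is the target in every pipeline.

#' ICP parameters
#'
#' Tuning parameters for trimmed point-to-point ICP. Defaults:
#' `max_iterations = 100`, `convergence_tol = 1e-4` mm (change in retained-pair
#' RMS between iterations), `trim_fraction = 0.1` (worst 10% of correspondences
#' discarded each iteration), `max_pair_distance` unset.
#'
#' @param max_iterations Maximum number of ICP iterations (>= 1).
#' @param convergence_tol Convergence tolerance on the change in RMS (mm, > 0).
#' @param trim_fraction Fraction of worst correspondences discarded per
#'   iteration, in `[0, 0.5)`.
#' @param max_pair_distance Optional hard cap (mm) on correspondence distance;
#'   pairs beyond it are discarded. `NULL` disables the cap.
#' @return An object of class `icp_params`.
#' @export
icp_params <- function(max_iterations = 100, convergence_tol = 1e-4,
                       trim_fraction = 0.1, max_pair_distance = NULL) {
  if (!is.numeric(max_iterations) || max_iterations < 1) {
    abort_input("`max_iterations` must be >= 1.")
  }
  if (!is.numeric(convergence_tol) || convergence_tol <= 0) {
    abort_input("`convergence_tol` must be > 0 (mm).")
  }
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 0.5) {
    abort_input("`trim_fraction` must lie in [0, 0.5).")
  }
  if (!is.null(max_pair_distance) &&
      (!is.numeric(max_pair_distance) || max_pair_distance <= 0)) {
    abort_input("`max_pair_distance` must be NULL or a positive distance (mm).")
  }
  structure(list(max_iterations = as.integer(max_iterations),
                 convergence_tol = as.numeric(convergence_tol),
                 trim_fraction = as.numeric(trim_fraction),
                 max_pair_distance = max_pair_distance),
            class = "icp_params")
}

#' Coarse alignment from picked landmark pairs
#'
#' Rigid initialization from at least four ordered pairs of corresponding
#' points picked on the two surfaces, solved by Kabsch alignment. The FRE of
#' the pairs is returned as the coarse-match quality.
#'
#' @param pairs_source,pairs_target K x 3 corresponding points (K >= 4), in
#'   the source and target frames respectively.
#' @param from,to Optional frame tags.
#' @return A `kabsch_alignment` (transform + `fre`).
#' @export
coarse_match <- function(pairs_source, pairs_target, from = NULL, to = NULL) {
  s <- as_xyz(pairs_source, "pairs_source")
  t <- as_xyz(pairs_target, "pairs_target")
  if (nrow(s) != nrow(t)) {
    abort_input("Coarse-match point sets must have equal length.")
  }
  if (nrow(s) < 4) {
    abort_input("Coarse matching requires at least four sets of corresponding points.")
  }
  kabsch_align(s, t, from = from, to = to)
}

#' Nearest-neighbour correspondences between point sets
#'
#' For each source point, finds the closest target point (exhaustive search,
#' ties to the lowest target index).
#'
#' @param source,target N x 3 / M x 3 matrices, data frames, or
#'   [point_cloud()]s.
#' @return A tibble with columns `source` (row index), `target` (matched
#'   target row index), `distance` (mm).
#' @export
nearest_neighbors <- function(source, target) {
  s <- if (is_point_cloud(source)) cloud_xyz(source) else as_xyz(source, "source")
  t <- if (is_point_cloud(target)) cloud_xyz(target) else as_xyz(target, "target")
  nn <- nn_bruteforce(s, t)
  tibble(source = seq_len(nrow(s)), target = nn$index, distance = nn$distance)
}

#' Trimmed iterative closest point registration
#'
#' Registers a source point set onto a target surface (its vertices) by
#' alternating nearest-neighbour correspondence, trimming (the
#' `trim_fraction` worst pairs and any pair beyond `max_pair_distance` are
#' discarded), and Kabsch least-squares alignment on the retained pairs, until
#' the retained-pair RMS changes by less than `convergence_tol` or
#' `max_iterations` is reached. The reported `rms` is the root-mean-square of
#' retained correspondence distances at the final iteration — the fitting
#' error shown to users for quality control.
#'
#' @param source,target [point_cloud()]s or N x 3 point sets (mm). The target
#'   should be the denser/segmented surface.
#' @param init Optional initial [rigid_transform()] (e.g. from
#'   [coarse_match()]); defaults to identity. The returned transform has
#'   `init` composed in.
#' @param params An [icp_params()].
#' @return An object of class `icp_result`: `transform`, `rms` (mm),
#'   `iterations`, `converged`, `rms_history`, `n_retained`.
#' @export
icp_register <- function(source, target, init = NULL, params = icp_params()) {
  stopifnot(inherits(params, "icp_params"))
  s <- if (is_point_cloud(source)) cloud_xyz(source) else as_xyz(source, "source")
  t <- if (is_point_cloud(target)) cloud_xyz(target) else as_xyz(target, "target")
  if (nrow(s) < 3 || nrow(t) < 3) {
    abort_input("ICP needs at least 3 points in both source and target.")
  }
  if (is.null(init)) init <- rigid_transform()
  stopifnot(is_rigid_transform(init))
  cur <- rigid_transform(init$rotation, init$translation)
  n_keep <- max(3L, ceiling((1 - params$trim_fraction) * nrow(s)))
  rms_history <- numeric(0)
  prev_rms <- Inf
  converged <- FALSE
  iter <- 0L
  n_retained <- NA_integer_
  for (iter in seq_len(params$max_iterations)) {
    moved <- sweep(s %*% t(cur$rotation), 2, cur$translation, "+")
    nn <- nn_bruteforce(moved, t)
    keep <- order(nn$distance)[seq_len(min(n_keep, length(nn$distance)))]
    if (!is.null(params$max_pair_distance)) {
      keep <- keep[nn$distance[keep] <= params$max_pair_distance]
    }
    if (length(keep) < 3) {
      abort_registration(sprintf(
        "ICP failed: only %d valid correspondences remain (need >= 3); surfaces may not overlap.",
        length(keep)))
    }
    fit <- kabsch_align(moved[keep, , drop = FALSE],
                        t[nn$index[keep], , drop = FALSE])
    cur <- compose(fit$transform, cur)
    # RMS over the retained pairs after this iteration's alignment
    rms <- fit$fre
    rms_history <- c(rms_history, rms)
    n_retained <- length(keep)
    if (is.finite(prev_rms) && abs(prev_rms - rms) < params$convergence_tol) {
      converged <- TRUE
      break
    }
    prev_rms <- rms
  }
  final <- rigid_transform(cur$rotation, cur$translation,
                           from = init$from, to = init$to)
  structure(list(transform = final, rms = rms_history[length(rms_history)],
                 iterations = iter, converged = converged,
                 rms_history = rms_history, n_retained = n_retained,
                 params = params),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> rms = %.6g mm after %d iteration(s)%s, %d retained pairs\n",
              x$rms, x$iterations,
              if (x$converged) " (converged)" else " (not converged)",
              x$n_retained))
  invisible(x)
}

#' @rdname tidy_opmcoreg
#' @export
glance.icp_result <- function(x, ...) {
  tibble(rms = x$rms, iterations = x$iterations, converged = x$converged,
         n_retained = x$n_retained)
}

#' @rdname tidy_opmcoreg
#' @export
tidy.icp_result <- function(x, ...) {
  tibble(iteration = seq_along(x$rms_history), rms = x$rms_history)
}
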