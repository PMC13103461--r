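# Paired-point rigid registration.
#
# The planned bone segment (landmarks in the plan frame) is registered to
# the probe-acquired fiducials (reference frame) with Horn's closed-form
# absolute-orientation solution: the optimal rotation is the unit quaternion
# maximizing q' N q for the 4 x 4 symmetric matrix N built from the
# cross-covariance of the centered point sets, i.e. the eigenvector of N
# with the largest eigenvalue. The quaternion parameterization cannot
# produce a reflection, so det(R) = +1 always, including near-planar
# fiducial configurations where an unconstrained least-squares solution
# could flip.

landmarks_or_points <- function(x, arg) {
  if (inherits(x, "landmark_set")) x$points else as_points(x, arg)
}

check_correspondence <- function(moving, fixed) {
  m <- landmarks_or_points(moving, "moving")
  f <- landmarks_or_points(fixed, "fixed")
  if (nrow(m) != nrow(f))
    emnav_stop("emnav_correspondence_error", sprintf(
      "point sets differ in size (%d vs %d)", nrow(m), nrow(f)))
  if (nrow(m) < 3L)
    emnav_stop("emnav_degenerate_error",
               "at least 3 point pairs are required for rigid registration")
  list(m = m, f = f)
}

#' Rigid registration by Horn's quaternion method
#'
#' Finds the rigid transform (rotation + translation, no scaling) minimizing
#' the sum of squared distances between the transformed moving points and
#' the fixed points, with correspondence given by order.
#'
#' @param moving,fixed `landmark_set` objects or n x 3 matrices (n >= 3,
#'   equal n, moving points not collinear); index k of `moving` corresponds
#'   to index k of `fixed`.
#' @return A `rigid_transform` from the moving frame to the fixed frame
#'   (frame labels are taken from the landmark sets when supplied).
#' @examples
#' plan <- rbind(c(0, 0, 0), c(30, 0, 0), c(0, 30, 0), c(0, 0, 30))
#' meas <- plan + matrix(rep(c(10, -5, 2), each = 4), ncol = 3)
#' horn_register(plan, meas)
#' @export
horn_register <- function(moving, fixed) {
  pts <- check_correspondence(moving, fixed)
  m <- pts$m; f <- pts$f
  mc <- colMeans(m); fc <- colMeans(f)
  M <- sweep(m, 2, mc)
  Fm <- sweep(f, 2, fc)
  sv <- svd(M)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    emnav_stop("emnav_degenerate_error",
               "moving landmarks are collinear (or coincident); registration is underdetermined")
  S <- crossprod(M, Fm)          # S[i, j] = sum_k M[k, i] * F[k, j]
  N <- matrix(c(
    S[1,1] + S[2,2] + S[3,3], S[2,3] - S[3,2],          S[3,1] - S[1,3],          S[1,2] - S[2,1],
    S[2,3] - S[3,2],          S[1,1] - S[2,2] - S[3,3], S[1,2] + S[2,1],          S[3,1] + S[1,3],
    S[3,1] - S[1,3],          S[1,2] + S[2,1],         -S[1,1] + S[2,2] - S[3,3], S[2,3] + S[3,2],
    S[1,2] - S[2,1],          S[3,1] + S[1,3],          S[2,3] + S[3,2],         -S[1,1] - S[2,2] + S[3,3]),
    nrow = 4, byrow = TRUE)
  eg <- eigen(N, symmetric = TRUE)
  # top eigenvalue ties (degenerate symmetric data): any top-space vector is
  # optimal; take the first and canonicalize to w >= 0, with a warning
  if (length(eg$values) > 1 &&
      eg$values[1] - eg$values[2] < 1e-9 * max(abs(eg$values[1]), 1))
    warning("degenerate fiducial geometry: optimal rotation is not unique",
            call. = FALSE)
  q <- quat_canonical(quat_normalize(eg$vectors[, 1]))
  R <- quat_to_matrix(q)
  tr <- fc - as.numeric(R %*% mc)
  src <- if (inherits(moving, "landmark_set")) moving$frame else "plan"
  dst <- if (inherits(fixed, "landmark_set")) fixed$frame else "reference"
  rigid_transform(q, tr, src, dst)
}

#' Fiducial registration error
#'
#' Residual misfit of the registration fiducials after the transform is
#' applied: by default the root-mean-square of the per-fiducial residual
#' distances (the registration-literature standard); a mean-absolute-residual
#' variant is available for sensitivity checks.
#'
#' @param t The registering `rigid_transform` (moving frame to fixed frame).
#' @param moving,fixed The fiducial sets used for the registration.
#' @param type `"rms"` (default) or `"mean"`.
#' @return FRE in mm.
#' @export
compute_fre <- function(t, moving, fixed, type = c("rms", "mean")) {
  type <- match.arg(type)
  m <- landmarks_or_points(moving, "moving")
  f <- landmarks_or_points(fixed, "fixed")
  if (nrow(m) != nrow(f))
    emnav_stop("emnav_correspondence_error", sprintf(
      "point sets differ in size (%d vs %d)", nrow(m), nrow(f)))
  if (nrow(m) == 0L)
    emnav_stop("emnav_degenerate_error", "no fiducials to evaluate")
  res <- row_norms(rt_apply(t, m) - f)
  if (type == "rms") sqrt(mean(res^2)) else mean(res)
}

#' Target registration error
#'
#' Distance at a clinically relevant target point between its position under
#' the estimated registration and its true position. In simulation mode the
#' truth is a known ground-truth transform; in physical/replay mode it is a
#' probe-measured target point in the fixed frame.
#'
#' @param estimated Estimated `rigid_transform` (plan frame to reference frame).
#' @param target Length-3 target point in the plan (moving) frame, mm.
#' @param truth Ground-truth `rigid_transform` over the same frames
#'   (simulation mode).
#' @param measured Length-3 measured target position in the reference frame
#'   (physical mode); exactly one of `truth`/`measured` must be given.
#' @return TRE in mm.
#' @export
compute_tre <- function(estimated, target, truth = NULL, measured = NULL) {
  check_rt(estimated, "estimated")
  target <- as.numeric(target)
  if (is.null(truth) == is.null(measured))
    emnav_stop("emnav_schema_error",
               "provide exactly one of 'truth' (transform) or 'measured' (point)")
  ref <- if (!is.null(truth)) {
    check_rt(truth, "truth")
    if (!identical(truth$source_frame, estimated$source_frame) ||
        !identical(truth$target_frame, estimated$target_frame))
      emnav_stop("emnav_frame_error",
                 "estimated and truth transforms must map the same frames")
    rt_apply(truth, target)
  } else as.numeric(measured)
  sqrt(sum((rt_apply(estimated, target) - ref)^2))
}

#' Center of gravity of a point cloud
#'
#' Unweighted arithmetic centroid; used as the TRE-CENTER evaluation point
#' of the graft.
#'
#' @param cloud n x 3 matrix of points, mm (non-empty).
#' @return Length-3 centroid, mm.
#' @export
center_of_gravity <- function(cloud) {
  cloud <- as_points(cloud, "cloud")
  if (nrow(cloud) == 0L)
    emnav_stop("emnav_schema_error", "empty cloud has no center of gravity")
  colMeans(cloud)
}

#' Predicted mean-squared target registration error
#'
#' First-order prediction of the expected TRE^2 at a target for isotropic
#' fiducial localization error: `FLE2 / N * (1 + (1/3) * sum_k d_k^2 / f_k^2)`
#' where `d_k` is the target's distance from the k-th principal axis of the
#' fiducial configuration and `f_k` is the RMS fiducial distance from that
#' axis.
#'
#' @param fiducials n x 3 matrix of fiducial positions, mm.
#' @param target Length-3 target position, mm (same frame).
#' @param fle2 Expected squared fiducial localization error, mm^2 (for
#'   isotropic per-axis noise of standard deviation sigma, `fle2 = 3 sigma^2`).
#' @return Predicted mean TRE^2, mm^2.
#' @export
predict_tre_squared <- function(fiducials, target, fle2) {
  fid <- as_points(fiducials, "fiducials")
  n <- nrow(fid)
  if (n < 3L)
    emnav_stop("emnav_degenerate_error", "need >= 3 fiducials")
  ctr <- colMeans(fid)
  C <- sweep(fid, 2, ctr)
  eg <- eigen(crossprod(C) / n, symmetric = TRUE)
  axes <- eg$vectors                      # principal axes through the centroid
  tg <- as.numeric(target) - ctr
  ratio <- 0
  for (k in 1:3) {
    v <- axes[, k]
    # squared distance from the line through the centroid along v
    d2_target <- sum(tg^2) - sum(tg * v)^2
    proj <- C %*% v
    f2 <- mean(rowSums(C^2) - proj^2)     # mean squared fiducial distance
    ratio <- ratio + d2_target / f2
  }
  fle2 / n * (1 + ratio / 3)
}

#' Registration session with repeat attempts
#'
#' Runs landmark acquisition and registration repeatedly until an acceptance
#' policy is satisfied or attempts are exhausted, mirroring the
#' intraoperative workflow in which the surgeon may repeat a registration
#' whose error values are too high. No default error thresholds are imposed:
#' the acceptance policy must be supplied.
#'
#' @param plan_landmarks `landmark_set` of planned fiducials (plan frame).
#' @param acquire_fn Function of the attempt index returning the acquired
#'   fiducial `landmark_set` (reference frame) for that attempt.
#' @param targets Named list of target points in the plan frame (e.g.
#'   `list(TRE_CONDYLE = ..., TRE_CENTER = ...)`); may be empty.
#' @param accept_policy Function of a `registration_result` returning
#'   `TRUE`/`FALSE`, or a list with optional elements `fre_mm` and `tre_mm`
#'   (scalar thresholds; all computed TREs must be under `tre_mm`).
#' @param max_attempts Attempt budget (default 10).
#' @param truth Optional ground-truth `rigid_transform` for simulation-mode
#'   TREs; without it, targets are evaluated against `measured_targets`.
#' @param measured_targets Optional named list of probe-measured target
#'   points in the reference frame (physical mode).
#' @param fre_type FRE definition, `"rms"` or `"mean"`.
#' @return A `registration_result`: `transform`, `fre_mm`, `tre_mm` (named
#'   numeric), `attempt_index`, `accepted`.
#' @export
registration_session <- function(plan_landmarks, acquire_fn, targets = list(),
                                 accept_policy, max_attempts = 10L,
                                 truth = NULL, measured_targets = NULL,
                                 fre_type = "rms") {
  accept <- if (is.function(accept_policy)) accept_policy else {
    thr <- accept_policy
    function(res) {
      ok <- TRUE
      if (!is.null(thr$fre_mm)) ok <- ok && res$fre_mm <= thr$fre_mm
      if (!is.null(thr$tre_mm) && length(res$tre_mm))
        ok <- ok && all(res$tre_mm <= thr$tre_mm)
      ok
    }
  }
  best <- NULL
  for (attempt in seq_len(max_attempts)) {
    fixed <- acquire_fn(attempt)
    tr <- horn_register(plan_landmarks, fixed)
    fre <- compute_fre(tr, plan_landmarks, fixed, type = fre_type)
    tre <- vapply(names(targets), function(nm) {
      if (!is.null(truth))
        compute_tre(tr, targets[[nm]], truth = truth)
      else if (!is.null(measured_targets) && !is.null(measured_targets[[nm]]))
        compute_tre(tr, targets[[nm]], measured = measured_targets[[nm]])
      else NA_real_
    }, numeric(1))
    res <- structure(list(transform = tr, fre_mm = fre, tre_mm = tre,
                          attempt_index = attempt, accepted = FALSE),
                     class = "registration_result")
    if (is.null(best) || res$fre_mm < best$fre_mm) best <- res
    if (isTRUE(accept(res))) {
      res$accepted <- TRUE
      return(res)
    }
  }
  emnav_stop("emnav_rejection_error", sprintf(
    "no registration accepted within %d attempts (best FRE %.3f mm)",
    max_attempts, best$fre_mm), data = list(best = best))
}

#' @export
print.registration_result <- function(x, ...) {
  cat(sprintf("registration_result: attempt %d, %s\n", x$attempt_index,
              if (x$accepted) "accepted" else "not accepted"))
  cat(sprintf("  FRE: %.3f mm\n", x$fre_mm))
  for (nm in names(x$tre_mm))
    cat(sprintf("  TRE %s: %.3f mm\n", nm, x$tre_mm[[nm]]))
  print(x$transform)
  invisible(x)
}
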