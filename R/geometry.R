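# Pose algebra for 6-DOF rigid transforms.
#
# Conventions (fixed once, documented in the I/O schema): quaternions are
# w-first (w, x, y, z), unit norm, active rotations in right-handed frames;
# all translations and points are in millimetres. Frames are explicit string
# labels ("tracker", "reference", "plan", "sensor:<id>") and every public
# operation checks that frames chain, because tracker-frame and
# reference-frame quantities must never be mixed silently.

QUAT_TOL <- 1e-9

#' Normalize a quaternion to unit length
#' @param q Numeric length-4 quaternion, w-first.
#' @return Unit quaternion.
#' @keywords internal
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n < 1e-12)
    emnav_stop("emnav_schema_error", "zero-norm quaternion")
  q / n
}

# Canonical sign: w >= 0 resolves the q / -q ambiguity.
quat_canonical <- function(q) if (q[1] < 0) -q else q

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Convert a unit quaternion to a rotation matrix
#'
#' @param q Unit quaternion, w-first.
#' @return 3 x 3 proper rotation matrix (det = +1).
#' @export
quat_to_matrix <- function(q) {
  q <- quat_normalize(as.numeric(q))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y * y + z * z), 2 * (x * y - w * z),     2 * (x * z + w * y),
    2 * (x * y + w * z),     1 - 2 * (x * x + z * z), 2 * (y * z - w * x),
    2 * (x * z - w * y),     2 * (y * z + w * x),     1 - 2 * (x * x + y * y)),
    nrow = 3, byrow = TRUE)
}

#' Convert a rotation matrix to a unit quaternion
#'
#' Uses Shepperd's branch selection for numerical stability; the returned
#' quaternion has w >= 0 (the sign ambiguity is resolved canonically).
#'
#' @param R 3 x 3 orthonormal matrix with det(R) = +1 (checked to 1e-6).
#' @return Unit quaternion, w-first.
#' @export
matrix_to_quat <- function(R) {
  R <- unname(as.matrix(R))
  if (!all(dim(R) == c(3L, 3L)))
    emnav_stop("emnav_schema_error", "rotation must be a 3 x 3 matrix")
  if (max(abs(crossprod(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
    emnav_stop("emnav_schema_error",
               "rotation matrix is not orthonormal with det +1")
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else if (R[1, 1] > R[2, 2] && R[1, 1] > R[3, 3]) {
    s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
    q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
           (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
  } else if (R[2, 2] > R[3, 3]) {
    s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
    q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
           0.25 * s, (R[2, 3] + R[3, 2]) / s)
  } else {
    s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
    q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
           (R[2, 3] + R[3, 2]) / s, 0.25 * s)
  }
  quat_canonical(quat_normalize(q))
}

#' Construct a rigid transform
#'
#' A rigid transform maps points expressed in `source_frame` into
#' `target_frame` as `R p + t`. Rotation may be given as a w-first unit
#' quaternion or a 3 x 3 rotation matrix; translation is in millimetres.
#'
#' @param rotation Length-4 quaternion (w, x, y, z) or 3 x 3 rotation matrix.
#' @param translation Length-3 numeric vector, mm.
#' @param source_frame,target_frame Frame labels.
#' @return An object of class `rigid_transform` with elements `q`, `t`,
#'   `source_frame`, `target_frame`.
#' @examples
#' T1 <- rigid_transform(c(1, 0, 0, 0), c(10, -5, 2), "plan", "reference")
#' rt_apply(T1, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation = c(1, 0, 0, 0), translation = c(0, 0, 0),
                            source_frame = "source", target_frame = "target") {
  if (is.matrix(rotation)) {
    q <- matrix_to_quat(rotation)
  } else {
    rotation <- as.numeric(rotation)
    if (length(rotation) != 4L)
      emnav_stop("emnav_schema_error", "quaternion must have 4 components (w, x, y, z)")
    if (abs(sqrt(sum(rotation^2)) - 1) > 1e-6)
      emnav_stop("emnav_schema_error", "quaternion is not unit norm")
    q <- quat_canonical(quat_normalize(rotation))
  }
  translation <- as.numeric(translation)
  if (length(translation) != 3L || !all(is.finite(translation)))
    emnav_stop("emnav_schema_error", "translation must be 3 finite numbers (mm)")
  structure(list(q = q, t = translation,
                 source_frame = as.character(source_frame),
                 target_frame = as.character(target_frame)),
            class = "rigid_transform")
}

#' Identity transform between two frames
#' @param source_frame,target_frame Frame labels (equal by default).
#' @return A `rigid_transform`.
#' @export
rt_identity <- function(source_frame = "source", target_frame = source_frame) {
  rigid_transform(c(1, 0, 0, 0), c(0, 0, 0), source_frame, target_frame)
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid_transform: %s -> %s\n", x$source_frame, x$target_frame))
  cat(sprintf("  q (wxyz): %s\n", paste(signif(x$q, 6), collapse = " ")))
  cat(sprintf("  t (mm):   %s\n", paste(signif(x$t, 6), collapse = " ")))
  invisible(x)
}

#' Rotation matrix of a rigid transform
#' @param t A `rigid_transform`.
#' @return 3 x 3 rotation matrix.
#' @export
rt_rotation <- function(t) quat_to_matrix(t$q)

#' 4 x 4 homogeneous matrix of a rigid transform
#' @param t A `rigid_transform`.
#' @return 4 x 4 homogeneous transformation matrix.
#' @export
rt_matrix <- function(t) {
  m <- diag(4)
  m[1:3, 1:3] <- rt_rotation(t)
  m[1:3, 4] <- t$t
  m
}

check_rt <- function(t, arg = "transform") {
  if (!inherits(t, "rigid_transform"))
    emnav_stop("emnav_schema_error", sprintf("'%s' must be a rigid_transform", arg))
  t
}

#' Compose two rigid transforms
#'
#' `rt_compose(a, b)` is the transform that applies `b` first, then `a`;
#' frames must chain: `a$source_frame == b$target_frame`.
#'
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform` from `b$source_frame` to `a$target_frame`.
#' @export
rt_compose <- function(a, b) {
  check_rt(a, "a"); check_rt(b, "b")
  if (!identical(a$source_frame, b$target_frame))
    emnav_stop("emnav_frame_error", sprintf(
      "cannot compose: a maps %s -> %s but b maps %s -> %s",
      a$source_frame, a$target_frame, b$source_frame, b$target_frame))
  q <- quat_canonical(quat_normalize(quat_multiply(a$q, b$q)))
  tr <- as.numeric(quat_to_matrix(a$q) %*% b$t) + a$t
  rigid_transform(q, tr, b$source_frame, a$target_frame)
}

#' Invert a rigid transform
#' @param t A `rigid_transform`.
#' @return The inverse transform, with source/target frames swapped.
#' @export
rt_invert <- function(t) {
  check_rt(t)
  qi <- quat_canonical(quat_conjugate(t$q))
  ti <- as.numeric(-(quat_to_matrix(qi) %*% t$t))
  rigid_transform(qi, ti, t$target_frame, t$source_frame)
}

#' Apply a rigid transform to points
#'
#' @param t A `rigid_transform`.
#' @param p Length-3 point or n x 3 matrix of points in `t$source_frame`, mm.
#' @param frame Optional frame label of `p`; checked against
#'   `t$source_frame` when given.
#' @return Transformed point(s), same shape as the input.
#' @export
rt_apply <- function(t, p, frame = NULL) {
  check_rt(t)
  if (!is.null(frame) && !identical(frame, t$source_frame))
    emnav_stop("emnav_frame_error", sprintf(
      "points are in frame '%s' but transform expects '%s'", frame, t$source_frame))
  vec <- is.null(dim(p))
  m <- as_points(p, "p")
  out <- m %*% t(rt_rotation(t)) +
    matrix(t$t, nrow = nrow(m), ncol = 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' A timestamped 6-DOF sensor reading
#'
#' @param timestamp Time in seconds.
#' @param sensor_id Sensor label; the pose's source frame is
#'   `"sensor:<sensor_id>"` unless the supplied pose already carries frames.
#' @param pose A `rigid_transform` mapping the sensor frame into the tracker
#'   (field-generator) frame, or a list with `q` and `t` components.
#' @return An object of class `pose_sample`.
#' @export
pose_sample <- function(timestamp, sensor_id, pose) {
  if (!inherits(pose, "rigid_transform")) {
    trans <- if (!is.null(pose$t)) pose$t else pose$p
    pose <- rigid_transform(pose$q, trans,
                            paste0("sensor:", sensor_id), "tracker")
  }
  structure(list(timestamp = as.numeric(timestamp),
                 sensor_id = as.character(sensor_id),
                 pose = pose),
            class = "pose_sample")
}

#' Sensor pose relative to the reference sensor
#'
#' All navigation measurements are taken relative to a reference sensor fixed
#' to immobile anatomy (the zygomatic bone), so the result is invariant to
#' any rigid motion (head movement) applied simultaneously to both sensors in
#' the tracker frame.
#'
#' @param sensor,reference `pose_sample` objects whose poses map into the
#'   same tracker frame.
#' @param tol_s Maximum allowed timestamp skew in seconds (default 0.005,
#'   half a 40 Hz sample interval).
#' @return A `rigid_transform` mapping the sensor frame into the reference
#'   sensor frame.
#' @export
relative_pose <- function(sensor, reference, tol_s = 0.005) {
  if (!inherits(sensor, "pose_sample") || !inherits(reference, "pose_sample"))
    emnav_stop("emnav_schema_error", "relative_pose expects two pose_sample objects")
  if (!identical(sensor$pose$target_frame, reference$pose$target_frame))
    emnav_stop("emnav_frame_error", "pose samples are not expressed in the same tracker frame")
  if (abs(sensor$timestamp - reference$timestamp) > tol_s)
    emnav_stop("emnav_sync_error", sprintf(
      "timestamp skew %.4f s exceeds tolerance %.4f s",
      abs(sensor$timestamp - reference$timestamp), tol_s))
  rt_compose(rt_invert(reference$pose), sensor$pose)
}
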