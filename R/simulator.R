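# Synthetic phantom and tracking-data generator.
#
# Stand-in for physical model surgery: a parametric mandible-like geometry
# (prism segments along an arc, not an anatomical mesh — the math under test
# does not care about anatomical realism) with artificial landmarks, known
# ground-truth registrations, and simulated sensor/probe streams. With all
# noise parameters at zero the full pipeline recovers the truth exactly,
# which anchors every downstream correctness test.

# Deterministic per-purpose substream seed derived from the global seed.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  (as.integer(seed) + 7919L * (h %% 100003L)) %% 2147483647L
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# Small random rigid transform: rotation angle_deg about a random axis,
# translation of norm trans_mm in a random direction.
random_rigid <- function(trans_mm, angle_deg, source_frame, target_frame) {
  axis <- stats::rnorm(3); axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  q <- c(cos(th / 2), sin(th / 2) * axis)
  dir <- stats::rnorm(3); dir <- dir / sqrt(sum(dir^2))
  rigid_transform(q, trans_mm * dir, source_frame, target_frame)
}

#' Phantom specification
#'
#' @param seed Integer master seed; named substreams per sensor/landmark are
#'   derived from it, so a fixed seed reproduces the case exactly.
#' @param mandible_cloud_size,graft_cloud_size Points per object cloud.
#' @param n_fiducials_mandible,n_fiducials_graft Registration fiducials per
#'   object (>= 4).
#' @param n_segments Fibular segments in the graft, 2..4.
#' @param graft_shape_error_mm Magnitude of shape deviation of the assembled
#'   graft from the plan, mm (emulates segments that do not fit perfectly).
#' @param fle_sigma_mm Per-axis fiducial localization noise, mm. Default
#'   0.3 mm, the order of magnitude of electromagnetic tracker accuracy.
#' @param stream_rate_hz Probe/pose stream rate (default 40).
#' @param nav_rate_hz Navigation update rate (default 25).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(seed = 1L, mandible_cloud_size = 1200L,
                         graft_cloud_size = 900L, n_fiducials_mandible = 5L,
                         n_fiducials_graft = 5L, n_segments = 3L,
                         graft_shape_error_mm = 0, fle_sigma_mm = 0.3,
                         stream_rate_hz = 40, nav_rate_hz = 25) {
  if (n_fiducials_mandible < 4L || n_fiducials_graft < 4L)
    emnav_stop("emnav_spec_error", "need >= 4 fiducials per object")
  if (!(n_segments %in% 2:4))
    emnav_stop("emnav_spec_error", "n_segments must be in 2..4")
  if (graft_shape_error_mm < 0 || fle_sigma_mm < 0)
    emnav_stop("emnav_spec_error", "noise magnitudes must be >= 0")
  structure(list(seed = as.integer(seed),
                 mandible_cloud_size = as.integer(mandible_cloud_size),
                 graft_cloud_size = as.integer(graft_cloud_size),
                 n_fiducials_mandible = as.integer(n_fiducials_mandible),
                 n_fiducials_graft = as.integer(n_fiducials_graft),
                 n_segments = as.integer(n_segments),
                 graft_shape_error_mm = graft_shape_error_mm,
                 fle_sigma_mm = fle_sigma_mm,
                 stream_rate_hz = stream_rate_hz,
                 nav_rate_hz = nav_rate_hz),
            class = "phantom_spec")
}

# Deterministic points on the surface of a box prism between polyline nodes
# a and b, cross-section half-width hw (mm). Uses a low-discrepancy lattice
# so the layout is reproducible without consuming RNG state.
prism_points <- function(a, b, hw, n) {
  axis <- b - a
  len <- sqrt(sum(axis^2))
  u <- axis / len
  # any perpendicular pair
  w <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v1 <- w - sum(w * u) * u; v1 <- v1 / sqrt(sum(v1^2))
  v2 <- c(u[2] * v1[3] - u[3] * v1[2],
          u[3] * v1[1] - u[1] * v1[3],
          u[1] * v1[2] - u[2] * v1[1])
  i <- seq_len(n)
  s <- (i * 0.6180339887498949) %% 1          # golden-ratio lattice
  t2 <- (i * 0.7548776662466927) %% 1
  side <- i %% 4L
  off1 <- ifelse(side < 2L, hw, -hw)
  t(vapply(i, function(k) {
    along <- a + s[k] * len * u
    if (side[k] %% 2L == 0L)
      along + off1[k] * v1 + (2 * t2[k] - 1) * hw * v2
    else
      along + (2 * t2[k] - 1) * hw * v1 + off1[k] * v2
  }, numeric(3)))
}

#' Generate a synthetic reconstruction case
#'
#' Builds the planned residual mandible and a multi-segment graft laid out
#' as connected prisms along a mandible-like arc, with registration
#' fiducials, the clinically relevant target points CON (reconstructed
#' condyle, free end of segment 1), ANG (jaw angle, the inter-segment
#' corner) and JUN (junction with the residual mandible), ground-truth
#' registrations, and sensor pose streams. Deterministic for a fixed seed.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `synthetic_case`: `spec`, `plan` (named list
#'   of `planned_object`s), `fiducials` (plan-frame `landmark_set` per
#'   object), `targets` (plan-frame `landmark_set`: CON/ANG/JUN, graft
#'   center), `segment_of` (segment index per graft landmark),
#'   `truth_registration` (per object, plan -> reference),
#'   `truth_final_pose` (graft placement, reference -> reference), `streams`.
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  if (!inherits(spec, "phantom_spec"))
    emnav_stop("emnav_spec_error", "'spec' must be a phantom_spec")
  ns <- spec$n_segments
  # mandible-like arc in the plan frame: condyle top, down the ramus to the
  # angle, then along the body to the junction with the residual mandible
  ramus_top <- c(45, 55, 0)
  angle_pt <- c(50, 0, 0)
  junction <- c(0, -12, 28)
  # polyline nodes: segment 1 starts at the condyle; the last segment ends
  # at the junction; intermediate nodes interpolate along ramus then body
  nodes <- switch(as.character(ns),
    "2" = list(ramus_top, angle_pt, junction),
    "3" = list(ramus_top, angle_pt,
               angle_pt + 0.5 * (junction - angle_pt), junction),
    "4" = list(ramus_top, ramus_top + 0.5 * (angle_pt - ramus_top), angle_pt,
               angle_pt + 0.5 * (junction - angle_pt), junction))
  hw <- 6  # prism half-width, mm (fibular cross-section scale)

  per_seg <- ceiling(spec$graft_cloud_size / ns)
  seg_clouds <- lapply(seq_len(ns), function(k)
    prism_points(unlist(nodes[[k]]), unlist(nodes[[k + 1]]), hw, per_seg))
  graft_cloud <- do.call(rbind, seg_clouds)[seq_len(spec$graft_cloud_size), ,
                                            drop = FALSE]

  # residual mandible: a prism continuing past the junction
  mand_cloud <- prism_points(junction, junction + c(-55, -6, 14), 7,
                             spec$mandible_cloud_size)

  # artificial accuracy landmarks: two per segment (prism corners, exactly
  # on the polyline ends offset sideways), named S<k>a / S<k>b
  lm_names <- character(0); lm_pts <- NULL; seg_of <- integer(0)
  for (k in seq_len(ns)) {
    a <- unlist(nodes[[k]]); b <- unlist(nodes[[k + 1]])
    mid <- (a + b) / 2
    lm_names <- c(lm_names, sprintf("S%da", k), sprintf("S%db", k))
    lm_pts <- rbind(lm_pts, a + c(0, 0, hw), mid + c(0, 0, -hw))
    seg_of <- c(seg_of, k, k)
  }
  graft_landmarks <- landmark_set(lm_names, lm_pts, "plan")

  # registration fiducials: well-spread, non-collinear, deterministic
  with_seed(substream_seed(spec$seed, "fiducials"), {
    fid_graft <- graft_cloud[round(seq(1, nrow(graft_cloud),
                                       length.out = spec$n_fiducials_graft)), ,
                             drop = FALSE] +
      matrix(stats::runif(3 * spec$n_fiducials_graft, -1, 1),
             ncol = 3) * 2
    fid_mand <- mand_cloud[round(seq(1, nrow(mand_cloud),
                                     length.out = spec$n_fiducials_mandible)), ,
                           drop = FALSE] +
      matrix(stats::runif(3 * spec$n_fiducials_mandible, -1, 1), ncol = 3) * 2
  })
  fiducials <- list(
    residual_mandible = landmark_set(
      sprintf("FM%d", seq_len(spec$n_fiducials_mandible)), fid_mand, "plan"),
    graft = landmark_set(
      sprintf("FG%d", seq_len(spec$n_fiducials_graft)), fid_graft, "plan"))

  targets <- landmark_set(
    c("CON", "ANG", "JUN", "CENTER"),
    rbind(ramus_top, angle_pt, junction, center_of_gravity(graft_cloud)),
    "plan")

  # ground-truth registrations: where each physical object actually sits in
  # the reference frame during surgery
  truth_registration <- list(
    residual_mandible = with_seed(substream_seed(spec$seed, "truth_mandible"),
      random_rigid(40, 25, "plan", "reference")),
    graft = with_seed(substream_seed(spec$seed, "truth_graft"),
      random_rigid(60, 40, "plan", "reference")))

  # assembled-graft shape error: a small rigid offset of the distal half of
  # the physical graft relative to the plan (plate-fixation distortion)
  shape_offset <- if (spec$graft_shape_error_mm > 0)
    with_seed(substream_seed(spec$seed, "shape"),
      random_rigid(spec$graft_shape_error_mm, 0.5 * spec$graft_shape_error_mm,
                   "plan", "plan"))
  else rt_identity("plan")

  plan <- list(
    residual_mandible = planned_object("residual_mandible", mand_cloud,
      fiducials$residual_mandible),
    graft = planned_object("graft", graft_cloud, graft_landmarks))

  # reference-sensor and object-sensor pose streams in the tracker frame
  t0 <- seq(0, by = 1 / spec$stream_rate_hz, length.out = 40L)
  mk_stream <- function(sensor_id, base) {
    lapply(t0, function(tt) pose_sample(tt, sensor_id,
      rigid_transform(base$q, base$t, paste0("sensor:", sensor_id), "tracker")))
  }
  ref_base <- with_seed(substream_seed(spec$seed, "ref_pose"),
    random_rigid(120, 60, "sensor:reference", "tracker"))
  mand_base <- with_seed(substream_seed(spec$seed, "mand_pose"),
    random_rigid(100, 50, "sensor:mandible", "tracker"))
  graft_base <- with_seed(substream_seed(spec$seed, "graft_pose"),
    random_rigid(90, 45, "sensor:graft", "tracker"))
  streams <- list(reference = mk_stream("reference", ref_base),
                  mandible = mk_stream("mandible", mand_base),
                  graft = mk_stream("graft", graft_base))

  structure(list(spec = spec, plan = plan, fiducials = fiducials,
                 targets = targets, segment_of = seg_of,
                 shape_offset = shape_offset,
                 truth_registration = truth_registration,
                 truth_final_pose = rt_identity("reference"),
                 streams = streams),
            class = "synthetic_case")
}

#' Simulate a probe-tip stream at a landmark
#'
#' Emulates holding the tracked pointer on a landmark: Gaussian tremble
#' around the true position (in the reference frame), with optional slip
#' events that displace the probe by more than the restart threshold at a
#' given sample and remain stable afterwards.
#'
#' @param case A `synthetic_case`.
#' @param landmark_name Name in the object's fiducial set or in `targets`.
#' @param object Which object the landmark belongs to
#'   (`"graft"` or `"residual_mandible"`).
#' @param tremble_sigma_mm Per-axis tremble standard deviation, mm.
#' @param slip_events List of `list(index =, offset =)` entries; `offset`
#'   (length-3, mm) is added from `index` onwards.
#' @param n Number of samples (default 180, enough for restarts).
#' @param seed Substream seed.
#' @return n x 3 matrix of probe-tip points in the reference frame, mm.
#' @export
simulate_probe_stream <- function(case, landmark_name, object = "graft",
                                  tremble_sigma_mm = 0, slip_events = list(),
                                  n = 180L, seed = 1L) {
  if (!inherits(case, "synthetic_case"))
    emnav_stop("emnav_spec_error", "'case' must be a synthetic_case")
  fid <- case$fiducials[[object]]
  truth_plan <- if (landmark_name %in% fid$names) landmark_point(fid, landmark_name)
    else landmark_point(case$targets, landmark_name)
  truth_ref <- rt_apply(case$truth_registration[[object]], truth_plan)
  pts <- matrix(truth_ref, nrow = n, ncol = 3, byrow = TRUE)
  if (tremble_sigma_mm > 0)
    pts <- pts + with_seed(substream_seed(seed, paste0("probe:", landmark_name)),
      matrix(stats::rnorm(3 * n, sd = tremble_sigma_mm), ncol = 3))
  for (ev in slip_events) {
    idx <- ev$index
    off <- as.numeric(ev$offset)
    if (sqrt(sum(off^2)) <= 0.5)
      emnav_stop("emnav_spec_error", "slip offset must exceed 0.5 mm")
    if (idx >= 1 && idx <= n)
      pts[idx:n, ] <- pts[idx:n, , drop = FALSE] +
        matrix(off, n - idx + 1L, 3, byrow = TRUE)
  }
  pts
}

#' Acquire all fiducials of an object from simulated probe streams
#'
#' Convenience wrapper running [acquire_landmark()] on one simulated stream
#' per fiducial; with zero tremble this returns the exact true fiducial
#' positions in the reference frame.
#'
#' @param case A `synthetic_case`.
#' @param object `"graft"` or `"residual_mandible"`.
#' @param tremble_sigma_mm Per-axis tremble, mm.
#' @param config An [acquisition_config()].
#' @param seed Substream seed.
#' @return A `landmark_set` in the reference frame.
#' @export
acquire_fiducials <- function(case, object = "graft", tremble_sigma_mm = 0,
                              config = acquisition_config(), seed = 1L) {
  fid <- case$fiducials[[object]]
  pts <- t(vapply(fid$names, function(nm) {
    stream <- simulate_probe_stream(case, nm, object = object,
                                    tremble_sigma_mm = tremble_sigma_mm,
                                    n = 4L * config$n_samples,
                                    seed = substream_seed(seed, nm))
    acquire_landmark(stream, config)$mean_point
  }, numeric(3)))
  landmark_set(fid$names, pts, "reference")
}

#' Simulate graft placement with a known error
#'
#' Applies a placement error (in the reference frame) to the graft's true
#' pose after fixation; the induced displacement of each target point is
#' then known in closed form, which makes lever-arm effects (the
#' free-standing condyle moving most for a rotation about the junction)
#' directly checkable.
#'
#' @param case A `synthetic_case`.
#' @param placement_error `rigid_transform` reference -> reference with
#'   translation norm <= 20 mm and rotation angle <= 15 degrees.
#' @return The case with `truth_final_pose` set, graft stream updated, and
#'   `target_deviations_mm` (named: displacement of CON/ANG/JUN/CENTER).
#' @export
simulate_placement <- function(case, placement_error) {
  check_rt(placement_error, "placement_error")
  ang <- 2 * acos(min(1, abs(placement_error$q[1]))) * 180 / pi
  if (sqrt(sum(placement_error$t^2)) > 20 || ang > 15)
    emnav_stop("emnav_spec_error",
               "placement error out of range (<= 20 mm, <= 15 degrees)")
  case$truth_final_pose <- placement_error
  targ_ref <- rt_apply(case$truth_registration$graft, case$targets$points)
  moved <- rt_apply(placement_error, targ_ref)
  dev <- row_norms(moved - targ_ref)
  names(dev) <- case$targets$names
  case$target_deviations_mm <- dev
  # graft sensor stream reflects the error: conjugate the reference-frame
  # error into the tracker frame and compose it onto each graft pose
  ref0 <- case$streams$reference[[1]]$pose      # reference sensor is static
  pe <- rigid_transform(placement_error$q, placement_error$t,
                        ref0$source_frame, ref0$source_frame)
  err_tracker <- rt_compose(ref0, rt_compose(pe, rt_invert(ref0)))
  case$streams$graft <- lapply(case$streams$graft, function(ps)
    pose_sample(ps$timestamp, ps$sensor_id, rt_compose(err_tracker, ps$pose)))
  case
}
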