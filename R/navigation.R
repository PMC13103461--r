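# Real-time bone-segment navigation.
#
# The tracked and planned bone segments are the same virtual point cloud, so
# correspondence is by index and no nearest-neighbour search is performed
# (nearest-neighbour matching would mask rotational error). Each tick
# computes the per-point Euclidean deviation d_k = ||q_k - p_k|| between the
# tracked cloud p and the planned cloud q and encodes it on a color scale
# running from dark green (deviations under 1 mm) to dark red (over 4 mm).

#' A planned bone segment (virtual 3D object)
#'
#' @param object_id Label, e.g. `"residual_mandible"` or `"graft"`.
#' @param cloud n x 3 point cloud in the plan frame, mm (non-empty).
#' @param landmarks Optional `landmark_set` in the plan frame.
#' @param target_pose `rigid_transform` plan -> reference; identity by
#'   convention, since the plan itself defines the target position.
#' @return An object of class `planned_object`.
#' @export
planned_object <- function(object_id, cloud, landmarks = NULL,
                           target_pose = rt_identity("plan", "reference")) {
  cloud <- as_points(cloud, "cloud")
  if (nrow(cloud) == 0L)
    emnav_stop("emnav_schema_error", "planned object needs a non-empty cloud")
  if (!is.null(landmarks)) {
    if (!inherits(landmarks, "landmark_set"))
      emnav_stop("emnav_schema_error", "'landmarks' must be a landmark_set")
    if (!identical(landmarks$frame, "plan"))
      emnav_stop("emnav_frame_error", "object landmarks must be in the plan frame")
  }
  structure(list(object_id = as.character(object_id), cloud = cloud,
                 landmarks = landmarks, target_pose = target_pose),
            class = "planned_object")
}

#' Current tracked cloud of a registered object
#'
#' The plan cloud is first placed in the reference frame by the registration
#' transform; any sensor motion since registration (relative pose now versus
#' at registration time) is then applied on top. With no motion since
#' registration the tracked cloud equals the registered plan cloud.
#'
#' @param obj A `planned_object`.
#' @param registration `rigid_transform` plan -> reference from registration.
#' @param rel_now Current sensor pose relative to the reference sensor.
#' @param rel_at_registration Sensor pose relative to the reference sensor
#'   at registration time.
#' @return n x 3 tracked cloud in the reference frame, mm.
#' @export
tracked_cloud <- function(obj, registration, rel_now, rel_at_registration) {
  check_rt(registration, "registration")
  check_rt(rel_now, "rel_now"); check_rt(rel_at_registration, "rel_at_registration")
  motion <- rt_compose(rel_now, rt_invert(rel_at_registration))
  placed <- rt_apply(registration, obj$cloud)
  rt_apply(motion, placed)
}

#' Point-by-point Euclidean distances between corresponding clouds
#'
#' @param tracked,planned n x 3 clouds with index correspondence, mm.
#' @param object_id Label carried into the result.
#' @param timestamp Time of the measurement, seconds.
#' @return An object of class `distance_map`: `object_id`, `distances_mm`,
#'   `colors` (filled by [color_encode()]), `timestamp`.
#' @examples
#' a <- rbind(c(0, 0, 0), c(1, 1, 1))
#' pointwise_distance(a, a + matrix(c(3, 4, 0), 2, 3, byrow = TRUE))
#' @export
pointwise_distance <- function(tracked, planned, object_id = "object",
                               timestamp = NA_real_) {
  tracked <- as_points(tracked, "tracked")
  planned <- as_points(planned, "planned")
  if (nrow(tracked) != nrow(planned))
    emnav_stop("emnav_correspondence_error", sprintf(
      "clouds differ in size (%d vs %d)", nrow(tracked), nrow(planned)))
  structure(list(object_id = as.character(object_id),
                 distances_mm = row_norms(planned - tracked),
                 colors = NULL,
                 timestamp = as.numeric(timestamp)),
            class = "distance_map")
}

#' @export
print.distance_map <- function(x, ...) {
  d <- x$distances_mm
  cat(sprintf("distance_map '%s': %d points, min %.3f / mean %.3f / max %.3f mm\n",
              x$object_id, length(d), min(d), mean(d), max(d)))
  invisible(x)
}

#' Color scale for deviation maps
#'
#' Deviations below `lower_mm` map to `lower_color` (dark green: on target)
#' and above `upper_mm` to `upper_color` (dark red: far off). In between,
#' continuous mode interpolates linearly in RGB between the two endpoint
#' colors; binned mode steps through `bin_width_mm`-wide bins. Both are
#' monotone in the deviation.
#'
#' @param lower_mm,upper_mm Scale endpoints in mm (defaults 1.0 and 4.0).
#' @param lower_color,upper_color Endpoint colors (any R color spec).
#' @param interpolation `"continuous"` (default) or `"binned"`.
#' @param bin_width_mm Bin width for binned mode, mm (default 1.0).
#' @return An object of class `color_scale`.
#' @export
color_scale <- function(lower_mm = 1.0, upper_mm = 4.0,
                        lower_color = "#006400", upper_color = "#8B0000",
                        interpolation = c("continuous", "binned"),
                        bin_width_mm = 1.0) {
  if (!(lower_mm < upper_mm))
    emnav_stop("emnav_schema_error", "lower_mm must be < upper_mm")
  structure(list(lower_mm = lower_mm, upper_mm = upper_mm,
                 lower_color = lower_color, upper_color = upper_color,
                 interpolation = match.arg(interpolation),
                 bin_width_mm = bin_width_mm),
            class = "color_scale")
}

#' Encode distances as colors
#'
#' @param dmap A `distance_map`.
#' @param scale A [color_scale()].
#' @return The `distance_map` with `colors` filled (hex strings, one per point).
#' @export
color_encode <- function(dmap, scale = color_scale()) {
  if (!inherits(dmap, "distance_map"))
    emnav_stop("emnav_schema_error", "'dmap' must be a distance_map")
  d <- dmap$distances_mm
  lo <- grDevices::col2rgb(scale$lower_color)[, 1]
  hi <- grDevices::col2rgb(scale$upper_color)[, 1]
  # fraction of the way from the lower to the upper endpoint, clamped
  f <- (d - scale$lower_mm) / (scale$upper_mm - scale$lower_mm)
  f <- pmin(pmax(f, 0), 1)
  if (scale$interpolation == "binned") {
    nb <- ceiling((scale$upper_mm - scale$lower_mm) / scale$bin_width_mm)
    f <- ifelse(f >= 1, 1,
                floor((d - scale$lower_mm) / scale$bin_width_mm) / nb)
    f <- pmin(pmax(f, 0), 1)
  }
  rgb_mat <- round_half_away(outer(f, hi - lo) +
                               matrix(lo, length(f), 3, byrow = TRUE))
  dmap$colors <- grDevices::rgb(rgb_mat[, 1], rgb_mat[, 2], rgb_mat[, 3],
                                maxColorValue = 255)
  dmap
}

#' Navigation scene
#'
#' Holds the registered objects and their per-sensor poses between ticks.
#'
#' @param objects Named list of `planned_object`s; names are sensor ids.
#' @param registrations Named list of registering transforms
#'   (plan -> reference), one per object.
#' @param rel_at_registration Named list of sensor-relative poses captured at
#'   registration time, one per object.
#' @param scale A [color_scale()].
#' @param stale_timeout_s Poses older than this at tick time mark the object
#'   `tracking_lost` (default 0.5 s).
#' @return An object of class `nav_scene`.
#' @export
nav_scene <- function(objects, registrations, rel_at_registration,
                      scale = color_scale(), stale_timeout_s = 0.5) {
  ids <- names(objects)
  if (is.null(ids) || !setequal(ids, names(registrations)) ||
      !setequal(ids, names(rel_at_registration)))
    emnav_stop("emnav_schema_error",
               "objects, registrations and rel_at_registration must share names")
  state <- lapply(ids, function(id) list(
    object = objects[[id]],
    registration = registrations[[id]],
    rel_at_registration = rel_at_registration[[id]],
    last_pose = rel_at_registration[[id]],
    last_t = -Inf,
    last_map = NULL))
  names(state) <- ids
  structure(list(state = state, scale = scale,
                 stale_timeout_s = stale_timeout_s),
            class = "nav_scene")
}

#' One navigation update tick
#'
#' Recomputes tracked clouds, distances and colors for all objects from the
#' latest sensor poses (nominally at 25 Hz). Objects whose pose is stale
#' beyond the scene timeout are marked `tracking_lost` and keep their last
#' distance map unchanged.
#'
#' @param scene A [nav_scene()].
#' @param pose_updates Named list of current sensor-relative
#'   `rigid_transform`s (subset of the scene's objects).
#' @param timestamp Tick time, seconds.
#' @return List with `scene` (updated state) and `maps`: per object a
#'   `distance_map` carrying `summary` (min/max/mean distance and
#'   `fraction_under_lower`) and a `tracking_lost` flag.
#' @export
navigation_tick <- function(scene, pose_updates = list(), timestamp = 0) {
  if (!inherits(scene, "nav_scene"))
    emnav_stop("emnav_schema_error", "'scene' must be a nav_scene")
  maps <- list()
  for (id in names(scene$state)) {
    st <- scene$state[[id]]
    if (!is.null(pose_updates[[id]])) {
      st$last_pose <- pose_updates[[id]]
      st$last_t <- timestamp
    }
    lost <- (timestamp - st$last_t) > scene$stale_timeout_s
    if (lost && !is.null(st$last_map)) {
      dm <- st$last_map            # colors unchanged, only flagged
      dm$tracking_lost <- TRUE
    } else {
      trk <- tracked_cloud(st$object, st$registration, st$last_pose,
                           st$rel_at_registration)
      planned <- rt_apply(st$object$target_pose, st$object$cloud)
      dm <- pointwise_distance(trk, planned, object_id = st$object$object_id,
                               timestamp = timestamp)
      dm <- color_encode(dm, scene$scale)
      dm$tracking_lost <- lost
      d <- dm$distances_mm
      dm$summary <- list(min_mm = min(d), max_mm = max(d), mean_mm = mean(d),
                         fraction_under_lower = mean(d < scene$scale$lower_mm))
    }
    st$last_map <- dm
    scene$state[[id]] <- st
    maps[[id]] <- dm
  }
  list(scene = scene, maps = maps)
}

#' Save a navigation scene snapshot
#'
#' Serializes the final scene (clouds, transforms, last distance maps,
#' timestamps) to JSON so the stored scene can be re-evaluated
#' postoperatively; [load_snapshot()] restores it and recomputing the
#' distance maps reproduces the stored ones exactly.
#'
#' @param scene A [nav_scene()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
snapshot <- function(scene, path) {
  if (!inherits(scene, "nav_scene"))
    emnav_stop("emnav_schema_error", "'scene' must be a nav_scene")
  ser_rt <- function(t) list(q = t$q, t = t$t,
                             source_frame = t$source_frame,
                             target_frame = t$target_frame)
  out <- list(
    scale = unclass(scene$scale),
    stale_timeout_s = scene$stale_timeout_s,
    objects = lapply(scene$state, function(st) list(
      object_id = st$object$object_id,
      cloud = st$object$cloud,
      target_pose = ser_rt(st$object$target_pose),
      landmarks = if (!is.null(st$object$landmarks)) list(
        names = st$object$landmarks$names,
        points = st$object$landmarks$points,
        frame = st$object$landmarks$frame),
      registration = ser_rt(st$registration),
      rel_at_registration = ser_rt(st$rel_at_registration),
      last_pose = ser_rt(st$last_pose),
      last_t = st$last_t,
      last_map = if (!is.null(st$last_map)) list(
        object_id = st$last_map$object_id,
        distances_mm = st$last_map$distances_mm,
        colors = st$last_map$colors,
        timestamp = st$last_map$timestamp))))
  # 17 significant digits round-trip doubles exactly, so re-evaluating a
  # loaded snapshot reproduces the stored distance maps bit for bit
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Load a navigation scene snapshot
#' @param path File written by [snapshot()].
#' @return A `nav_scene` equivalent to the saved one.
#' @export
load_snapshot <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  de_rt <- function(x) rigid_transform(unlist(x$q), unlist(x$t),
                                       x$source_frame, x$target_frame)
  sc <- raw$scale
  scale <- color_scale(sc$lower_mm, sc$upper_mm, sc$lower_color, sc$upper_color,
                       sc$interpolation, sc$bin_width_mm)
  state <- lapply(raw$objects, function(o) {
    lm <- if (!is.null(o$landmarks))
      landmark_set(o$landmarks$names, o$landmarks$points, o$landmarks$frame)
    obj <- planned_object(o$object_id, o$cloud, lm, de_rt(o$target_pose))
    last_map <- if (!is.null(o$last_map)) {
      dm <- structure(list(object_id = o$last_map$object_id,
                           distances_mm = as.numeric(o$last_map$distances_mm),
                           colors = o$last_map$colors,
                           timestamp = o$last_map$timestamp),
                      class = "distance_map")
      dm
    }
    list(object = obj, registration = de_rt(o$registration),
         rel_at_registration = de_rt(o$rel_at_registration),
         last_pose = de_rt(o$last_pose), last_t = o$last_t,
         last_map = last_map)
  })
  structure(list(state = state, scale = scale,
                 stale_timeout_s = raw$stale_timeout_s),
            class = "nav_scene")
}
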