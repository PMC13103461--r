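#' Named 3D landmark set in a declared frame
#'
#' Ordered, uniquely named fiducial/target points; the order defines the
#' correspondence used by paired-point registration.
#'
#' @param names Character vector of unique landmark names.
#' @param points n x 3 matrix (or length-3 vector for n = 1) of coordinates, mm.
#' @param frame Frame label the coordinates are expressed in.
#' @return An object of class `landmark_set`.
#' @examples
#' landmark_set(c("A", "B", "C"), rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)), "plan")
#' @export
landmark_set <- function(names, points, frame = "plan") {
  points <- as_points(points)
  names <- as.character(names)
  if (length(names) != nrow(points))
    emnav_stop("emnav_schema_error", "one name per landmark point required")
  if (anyDuplicated(names))
    emnav_stop("emnav_schema_error", "landmark names must be unique")
  structure(list(names = names, points = points, frame = as.character(frame)),
            class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("landmark_set: %d points in frame '%s'\n", nrow(x$points), x$frame))
  df <- data.frame(name = x$names, x_mm = x$points[, 1],
                   y_mm = x$points[, 2], z_mm = x$points[, 3])
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
length.landmark_set <- function(x) nrow(x$points)

#' Extract one landmark's coordinates by name
#' @param ls A `landmark_set`.
#' @param name Landmark name.
#' @return Length-3 numeric vector, mm.
#' @export
landmark_point <- function(ls, name) {
  i <- match(name, ls$names)
  if (is.na(i))
    emnav_stop("emnav_correspondence_error",
               sprintf("landmark '%s' not present", name))
  ls$points[i, ]
}

#' Apply a rigid transform to a landmark set
#' @param t A `rigid_transform` whose source frame matches `ls$frame`.
#' @param ls A `landmark_set`.
#' @return The transformed `landmark_set`, in `t$target_frame`.
#' @export
transform_landmarks <- function(t, ls) {
  if (!inherits(ls, "landmark_set"))
    emnav_stop("emnav_schema_error", "'ls' must be a landmark_set")
  if (!identical(ls$frame, t$source_frame))
    emnav_stop("emnav_frame_error", sprintf(
      "landmarks are in frame '%s' but transform expects '%s'",
      ls$frame, t$source_frame))
  landmark_set(ls$names, rt_apply(t, ls$points), t$target_frame)
}
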