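# File formats.
#
# Landmarks: CSV with columns name,x_mm,y_mm,z_mm,frame or an equivalent
# JSON object. Clouds: CSV point lists (x_mm,y_mm,z_mm) or ASCII STL / PLY
# surfaces, whose vertices are used as the cloud. Pose streams: JSON lines,
# one sample per line {"t": s, "sensor": id, "q": [w,x,y,z], "p": [x,y,z]},
# or a CSV dialect with columns t,sensor,qw,qx,qy,qz,px,py,pz. All
# coordinates are millimetres; no other unit is accepted.

file_ext <- function(path) tolower(tools::file_ext(path))

#' Read a landmark set from CSV or JSON
#'
#' @param path File with columns/fields `name`, `x_mm`, `y_mm`, `z_mm` and
#'   a per-file or per-row `frame`.
#' @return A `landmark_set`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    emnav_stop("emnav_schema_error", sprintf("no such file: %s", path))
  if (file_ext(path) == "json") {
    raw <- jsonlite::read_json(path, simplifyVector = TRUE)
    need <- c("names", "points", "frame")
    if (!all(need %in% names(raw)))
      emnav_stop("emnav_schema_error", sprintf(
        "landmark JSON %s must carry fields %s", path, paste(need, collapse = ", ")))
    return(landmark_set(raw$names, raw$points, raw$frame))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x_mm", "y_mm", "z_mm")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    emnav_stop("emnav_schema_error", sprintf(
      "landmark CSV %s is missing column(s): %s (coordinates must be in mm)",
      path, paste(missing_cols, collapse = ", ")))
  frame <- if ("frame" %in% names(df)) {
    if (length(unique(df$frame)) != 1L)
      emnav_stop("emnav_schema_error",
                 sprintf("%s mixes frames; one frame per landmark file", path))
    df$frame[1]
  } else "plan"
  landmark_set(df$name, cbind(df$x_mm, df$y_mm, df$z_mm), frame)
}

#' Write a landmark set to CSV or JSON
#' @param ls A `landmark_set`.
#' @param path Destination (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(ls, path) {
  if (!inherits(ls, "landmark_set"))
    emnav_stop("emnav_schema_error", "'ls' must be a landmark_set")
  if (file_ext(path) == "json") {
    jsonlite::write_json(list(names = ls$names, points = ls$points,
                              frame = ls$frame),
                         path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(data.frame(name = ls$names, x_mm = ls$points[, 1],
                                y_mm = ls$points[, 2], z_mm = ls$points[, 3],
                                frame = ls$frame),
                     path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

# ASCII STL: vertices appear once per facet, so corners shared by several
# triangles are duplicated. Exact-match dedup (bitwise-equal coordinates,
# first occurrence kept) makes the cloud index stable across save/load.
read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1]))
    emnav_stop("emnav_schema_error", sprintf(
      "%s is not ASCII STL (binary STL is not supported)", path))
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (!length(vl))
    emnav_stop("emnav_schema_error", sprintf("no vertices found in %s", path))
  parts <- strsplit(trimws(vl), "\\s+")
  bad <- which(lengths(parts) != 4L)
  if (length(bad))
    emnav_stop("emnav_schema_error", sprintf(
      "malformed vertex line in %s: '%s'", path, vl[bad[1]]))
  m <- do.call(rbind, lapply(parts, function(p) as.numeric(p[2:4])))
  if (anyNA(m))
    emnav_stop("emnav_schema_error", sprintf("non-numeric vertex in %s", path))
  m[!duplicated(m), , drop = FALSE]
}

read_ply_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || trimws(lines[1]) != "ply")
    emnav_stop("emnav_schema_error", sprintf("%s is not a PLY file", path))
  if (!any(grepl("format ascii", lines)))
    emnav_stop("emnav_schema_error", sprintf(
      "%s: only ASCII PLY is supported", path))
  hdr_end <- grep("^\\s*end_header", lines)[1]
  vline <- grep("^\\s*element\\s+vertex\\s+\\d+", lines[seq_len(hdr_end)], value = TRUE)
  if (is.na(hdr_end) || !length(vline))
    emnav_stop("emnav_schema_error", sprintf("malformed PLY header in %s", path))
  nv <- as.integer(sub(".*vertex\\s+(\\d+).*", "\\1", vline[1]))
  body <- lines[(hdr_end + 1):(hdr_end + nv)]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  if (anyNA(m))
    emnav_stop("emnav_schema_error", sprintf("non-numeric vertex in %s", path))
  m
}

#' Read a point cloud
#'
#' Accepts CSV point lists (columns `x_mm`, `y_mm`, `z_mm`), ASCII STL
#' (facet vertices, deduplicated exactly in first-occurrence order) or
#' ASCII PLY (vertex elements, in file order).
#'
#' @param path Cloud file (`.csv`, `.stl`, `.ply`).
#' @return n x 3 matrix of points, mm.
#' @export
read_cloud <- function(path) {
  if (!file.exists(path))
    emnav_stop("emnav_schema_error", sprintf("no such file: %s", path))
  switch(file_ext(path),
    stl = read_stl_ascii(path),
    ply = read_ply_ascii(path),
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE)
      need <- c("x_mm", "y_mm", "z_mm")
      miss <- setdiff(need, names(df))
      if (length(miss))
        emnav_stop("emnav_schema_error", sprintf(
          "cloud CSV %s is missing column(s): %s (mm required)",
          path, paste(miss, collapse = ", ")))
      as_points(cbind(df$x_mm, df$y_mm, df$z_mm), "cloud")
    },
    emnav_stop("emnav_schema_error", sprintf(
      "unsupported cloud format '%s' (csv, stl or ply)", file_ext(path))))
}

#' Write a point cloud as CSV
#' @param cloud n x 3 matrix, mm.
#' @param path Destination `.csv`.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path) {
  cloud <- as_points(cloud, "cloud")
  utils::write.csv(data.frame(x_mm = cloud[, 1], y_mm = cloud[, 2],
                              z_mm = cloud[, 3]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a 6-DOF pose stream
#'
#' JSON-lines (one sample per line: `t` seconds, `sensor`, `q` w-first unit
#' quaternion, `p` position in mm, tracker frame) or the CSV dialect with
#' columns `t,sensor,qw,qx,qy,qz,px,py,pz`. Timestamps must be
#' non-decreasing per sensor.
#'
#' @param path Stream file (`.jsonl`/`.ndjson` or `.csv`).
#' @return List of `pose_sample` objects in file order.
#' @export
read_pose_stream <- function(path) {
  if (!file.exists(path))
    emnav_stop("emnav_schema_error", sprintf("no such file: %s", path))
  samples <- if (file_ext(path) == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    need <- c("t", "sensor", "qw", "qx", "qy", "qz", "px", "py", "pz")
    miss <- setdiff(need, names(df))
    if (length(miss))
      emnav_stop("emnav_schema_error", sprintf(
        "stream CSV %s is missing column(s): %s", path, paste(miss, collapse = ", ")))
    lapply(seq_len(nrow(df)), function(i)
      pose_sample(df$t[i], df$sensor[i],
                  list(q = c(df$qw[i], df$qx[i], df$qy[i], df$qz[i]),
                       p = c(df$px[i], df$py[i], df$pz[i]))))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[i]), error = function(e)
        emnav_stop("emnav_schema_error", sprintf(
          "%s line %d: invalid JSON (%s)", path, i, conditionMessage(e))))
      if (!all(c("t", "sensor", "q", "p") %in% names(rec)))
        emnav_stop("emnav_schema_error", sprintf(
          "%s line %d: fields t, sensor, q, p required", path, i))
      pose_sample(rec$t, rec$sensor, list(q = unlist(rec$q), p = unlist(rec$p)))
    })
  }
  ts <- vapply(samples, function(s) s$timestamp, numeric(1))
  ids <- vapply(samples, function(s) s$sensor_id, character(1))
  for (id in unique(ids))
    if (is.unsorted(ts[ids == id]))
      emnav_stop("emnav_schema_error", sprintf(
        "timestamps for sensor '%s' in %s are not non-decreasing", id, path))
  samples
}

# pose_sample list -> internal plain-list records (shared by writers)
stream_records <- function(samples) lapply(samples, function(s) list(
  t = s$timestamp, sensor = s$sensor_id, q = s$pose$q, p = s$pose$t))

#' Write a 6-DOF pose stream
#' @param samples List of `pose_sample` objects.
#' @param path Destination (`.jsonl` or `.csv`).
#' @return `path`, invisibly.
#' @export
write_pose_stream <- function(samples, path) {
  recs <- stream_records(samples)
  if (file_ext(path) == "csv") {
    df <- do.call(rbind, lapply(recs, function(r) data.frame(
      t = r$t, sensor = r$sensor, qw = r$q[1], qx = r$q[2], qy = r$q[3],
      qz = r$q[4], px = r$p[1], py = r$p[2], pz = r$p[3])))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (r in recs)
      writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = I(17)), con)
  }
  invisible(path)
}

#' Write an analysis/registration report
#'
#' JSON report carrying full-precision values; a CSV companion with values
#' printed to 6 significant digits is written alongside when `csv = TRUE`
#' and the report flattens to scalars.
#'
#' @param report Named list (or `agreement_report` / `registration_result`).
#' @param path Destination `.json`.
#' @param csv Also write a flattened CSV next to `path`.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv = FALSE) {
  if (inherits(report, "registration_result")) {
    tr <- report$transform
    report <- list(transform = list(q = tr$q, t = tr$t,
                                    source_frame = tr$source_frame,
                                    target_frame = tr$target_frame),
                   fre_mm = report$fre_mm, tre_mm = as.list(report$tre_mm),
                   attempt_index = report$attempt_index,
                   accepted = report$accepted)
  }
  report <- unclass(report)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  if (csv) {
    flat <- unlist(report)
    num <- suppressWarnings(as.numeric(flat))
    shown <- ifelse(is.na(num), as.character(flat), signif(num, 6))
    utils::write.csv(data.frame(key = names(flat), value = shown),
                     sub("\\.json$", ".csv", path), row.names = FALSE)
  }
  invisible(path)
}
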