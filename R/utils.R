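#' @keywords internal
"_PACKAGE"

# Classed condition helper: every user-facing failure carries a subclass of
# "emnav_error" so callers (and the CLI) can map error kinds to exit codes.
emnav_stop <- function(class, message, data = NULL, call. = FALSE) {
  cond <- structure(
    class = c(class, "emnav_error", "error", "condition"),
    list(message = message, call = if (call.) sys.call(-1) else NULL,
         data = data)
  )
  stop(cond)
}

# Coerce a point (length-3 vector) or point set (n x 3) to an n x 3 matrix.
as_points <- function(p, arg = "points") {
  if (is.data.frame(p)) p <- as.matrix(p)
  if (is.null(dim(p))) {
    if (length(p) != 3L)
      emnav_stop("emnav_schema_error",
                 sprintf("'%s' must be a length-3 vector or an n x 3 matrix", arg))
    p <- matrix(as.numeric(p), nrow = 1L)
  }
  p <- unname(as.matrix(p))
  if (ncol(p) != 3L)
    emnav_stop("emnav_schema_error", sprintf("'%s' must have 3 columns", arg))
  storage.mode(p) <- "double"
  if (!all(is.finite(p)))
    emnav_stop("emnav_schema_error", sprintf("'%s' contains non-finite coordinates", arg))
  p
}

# Euclidean norms of the rows of an n x 3 matrix.
row_norms <- function(m) sqrt(rowSums(m * m))

#' Round half away from zero
#'
#' Rounds to `digits` decimals with ties going away from zero, the convention
#' used when printing per-case tables (base [round()] rounds ties to even).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @examples
#' round_half_away(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_away <- function(x, digits = 0) {
  s <- 10^digits
  # small guard against binary representation of decimal ties (e.g. 2.155)
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}
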