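# Internal validation helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Classed error used across the package so callers (and the CLI wrapper) can
# dispatch on a machine-readable category.
pv_error <- function(category, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(
    class = c(paste0("pv_", category), "pv_error", "error", "condition"),
    list(message = msg, call = NULL, category = category)
  ))
}

check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stopf("'%s' must be a single finite number", name)
  if (positive && x <= 0)
    stopf("'%s' must be > 0", name)
  invisible(x)
}

# Coerce a length-k vector, k-column matrix or data frame to a numeric matrix
# with k columns (one row per point).
as_point_matrix <- function(x, k, name = "points") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.numeric(x) && is.null(dim(x))) {
    if (length(x) != k)
      stopf("'%s' must have %d coordinates", name, k)
    x <- matrix(x, nrow = 1L)
  }
  if (!is.matrix(x) || !is.numeric(x) || ncol(x) != k)
    stopf("'%s' must be an n x %d numeric matrix", name, k)
  storage.mode(x) <- "double"
  x
}

as_pixel_matrix <- function(x, name = "pixels") as_point_matrix(x, 2L, name)

row_norms <- function(m) sqrt(rowSums(m * m))

deg2rad <- function(x) x * (pi / 180)
rad2deg <- function(x) x * (180 / pi)
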