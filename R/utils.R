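#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a master seed and an index.
# Kept below 2^31 so it is always a valid R integer.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483629) * 48271 %% 2147483629 +
               (as.double(i) * 7919) %% 2147483629) %% 2147483629L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

#' Test whether points fall inside a polygon
#'
#' Ray-casting (even-odd rule) point-in-polygon test, vectorised over points.
#' Points exactly on an edge follow the half-open convention of the crossing
#' test and are assigned deterministically.
#'
#' @param px,py numeric vectors of point coordinates.
#' @param poly two-column matrix of polygon vertices (closed or open ring).
#' @return logical vector, `TRUE` for points inside the polygon.
#' @export
point_in_polygon <- function(px, py, poly) {
  poly <- as.matrix(poly)
  stopifnot(ncol(poly) == 2, nrow(poly) >= 3)
  # drop duplicated closing vertex if present
  n <- nrow(poly)
  if (all(poly[1, ] == poly[n, ])) poly <- poly[-n, , drop = FALSE]
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Logical H x W mask of pixels whose centers fall inside `poly`
# (coordinates: x = column - 0.5, y = row - 0.5).
pixel_mask_from_polygon <- function(dim_hw, poly) {
  h <- dim_hw[1]; w <- dim_hw[2]
  cx <- rep(seq_len(w) - 0.5, each = h)
  cy <- rep(seq_len(h) - 0.5, times = w)
  matrix(point_in_polygon(cx, cy, poly), nrow = h, ncol = w)
}

# Rectangle polygon covering a full H x W raster extent.
full_extent_polygon <- function(dim_hw) {
  h <- dim_hw[1]; w <- dim_hw[2]
  cbind(x = c(0, w, w, 0), y = c(0, 0, h, h))
}

# Hash of an R object, used to stamp pipeline outputs with their config.
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
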