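#' Gray-level co-occurrence matrix
#'
#' Quantizes a patch to `levels` gray levels by equal-width binning between
#' the patch minimum and maximum, then counts co-occurring level pairs at
#' the given displacement. Pairs are counted in both directions, so the
#' matrix is symmetric; entries are normalized to sum to 1. A constant patch
#' maps to a single level and yields all mass in one diagonal cell.
#'
#' @param patch numeric matrix, at least 2 x 2.
#' @param levels number of gray levels (>= 2).
#' @param distance pixel displacement distance.
#' @param angle displacement direction in degrees: 0, 45, 90 or 135.
#' @return `levels` x `levels` normalized symmetric matrix.
#' @export
glcm_matrix <- function(patch, levels = 32, distance = 1, angle = 0) {
  patch <- as.matrix(patch)
  if (nrow(patch) < 2 || ncol(patch) < 2) stop("patch must be at least 2 x 2")
  if (levels < 2) stop("levels must be >= 2")
  if (!angle %in% c(0, 45, 90, 135)) stop("angle must be one of 0, 45, 90, 135")
  rng <- range(patch)
  q <- if (rng[1] == rng[2]) {
    matrix(1L, nrow(patch), ncol(patch))
  } else {
    pmin(floor((patch - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  }
  d <- distance
  off <- switch(as.character(angle),
                "0"   = c(0, d),
                "45"  = c(-d, d),
                "90"  = c(-d, 0),
                "135" = c(-d, -d))
  h <- nrow(q); w <- ncol(q)
  rows <- seq_len(h); cols <- seq_len(w)
  r1 <- rows[rows + off[1] >= 1 & rows + off[1] <= h]
  c1 <- cols[cols + off[2] >= 1 & cols + off[2] <= w]
  if (length(r1) == 0 || length(c1) == 0) {
    stop("displacement larger than patch")
  }
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- matrix(tabulate((a - 1L) * levels + b, nbins = levels * levels),
                   levels, levels, byrow = TRUE)
  counts <- counts + t(counts)
  counts / sum(counts)
}

#' Texture statistics of a normalized co-occurrence matrix
#'
#' The eight classic statistics, with `P` the normalized matrix, indices
#' `i, j` the gray levels, and `mu`, `sigma^2` the mean and variance of the
#' (symmetric) marginal distribution:
#' mean `ME = sum(i P)`, variance `VA = sum((i - mu)^2 P)`,
#' dissimilarity `DI = sum(|i - j| P)`, contrast `CON = sum((i - j)^2 P)`,
#' homogeneity `HO = sum(P / (1 + (i - j)^2))`, second moment
#' `SE = sum(P^2)`, correlation `COR = sum((i - mu)(j - mu) P) / sigma^2`
#' (defined as 1 when `sigma^2 = 0`), and entropy `EN = -sum(P log P)`
#' (natural log by default, with `0 log 0 = 0`).
#'
#' @param P normalized symmetric co-occurrence matrix (entries sum to 1).
#' @param log_base base of the entropy logarithm (`exp(1)` or 2).
#' @return named numeric vector `ME, VA, DI, CON, HO, SE, COR, EN`.
#' @export
glcm_features <- function(P, log_base = exp(1)) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("co-occurrence matrix must be square")
  if (abs(sum(P) - 1) > 1e-8 || any(P < 0)) {
    stop("matrix is not a normalized co-occurrence matrix (entries must be ",
         ">= 0 and sum to 1)")
  }
  L <- nrow(P)
  i <- matrix(seq_len(L), L, L)
  j <- t(i)
  pi_marg <- rowSums(P)
  mu <- sum(seq_len(L) * pi_marg)
  sigma2 <- sum((seq_len(L) - mu)^2 * pi_marg)
  nz <- P > 0
  en <- -sum(P[nz] * log(P[nz])) / log(log_base)
  c(ME = mu,
    VA = sigma2,
    DI = sum(abs(i - j) * P),
    CON = sum((i - j)^2 * P),
    HO = sum(P / (1 + (i - j)^2)),
    SE = sum(P^2),
    COR = if (sigma2 == 0) 1 else sum((i - mu) * (j - mu) * P) / sigma2,
    EN = en)
}

#' Angle-averaged GLCM texture of a patch
#'
#' Computes [glcm_features()] for each displacement angle and averages them
#' feature-wise (the standard rotation-robust summary).
#'
#' @inheritParams glcm_matrix
#' @param angles displacement angles to average over.
#' @inheritParams glcm_features
#' @return named numeric vector of the eight statistics.
#' @export
glcm_texture <- function(patch, levels = 32, distance = 1,
                         angles = c(0, 45, 90, 135), log_base = exp(1)) {
  feats <- vapply(angles, function(a) {
    glcm_features(glcm_matrix(patch, levels, distance, a), log_base = log_base)
  }, numeric(8))
  rowMeans(feats)
}

#' Per-band GLCM texture features of a plot
#'
#' For each of the six multispectral bands, takes the rectangular patch
#' bounding the in-polygon pixels and computes the angle-averaged texture
#' statistics. Feature names are namespaced `tex.<slot>.<stat>`, e.g.
#' `tex.band6.COR`.
#'
#' @param stack `band_stack` object.
#' @param polygon plot polygon (default: full raster extent).
#' @inheritParams glcm_texture
#' @return named numeric vector of 48 features (6 bands x 8 statistics).
#' @export
texture_features <- function(stack, polygon = NULL, levels = 32, distance = 1,
                             angles = c(0, 45, 90, 135)) {
  dims <- dim(stack$ms)[1:2]
  polygon <- polygon %||% full_extent_polygon(dims)
  mask <- pixel_mask_from_polygon(dims, polygon)
  if (!any(mask)) stop("polygon does not intersect raster for plot ",
                       stack$plot_id)
  rr <- range(which(rowSums(mask) > 0))
  cr <- range(which(colSums(mask) > 0))
  out <- numeric(0)
  for (b in seq_len(6)) {
    patch <- stack$ms[rr[1]:rr[2], cr[1]:cr[2], b]
    f <- glcm_texture(patch, levels = levels, distance = distance,
                      angles = angles)
    names(f) <- paste0("tex.band", b, ".", names(f))
    out <- c(out, f)
  }
  out
}
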