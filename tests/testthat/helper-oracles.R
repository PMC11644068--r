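# Independent brute-force oracles used to check the implementation.

# Exhaustive pair-enumeration GLCM oracle: explicit loop over every pixel
# pair at the displacement, counting both directions.
oracle_glcm <- function(patch, levels, distance = 1, angle = 0) {
  rng <- range(patch)
  q <- if (rng[1] == rng[2]) {
    matrix(1L, nrow(patch), ncol(patch))
  } else {
    pmin(floor((patch - rng[1]) / (rng[2] - rng[1]) * levels) + 1L, levels)
  }
  off <- switch(as.character(angle),
                "0" = c(0, distance), "45" = c(-distance, distance),
                "90" = c(-distance, 0), "135" = c(-distance, -distance))
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(q))) {
    for (cl in seq_len(ncol(q))) {
      r2 <- r + off[1]; c2 <- cl + off[2]
      if (r2 >= 1 && r2 <= nrow(q) && c2 >= 1 && c2 <= ncol(q)) {
        counts[q[r, cl], q[r2, c2]] <- counts[q[r, cl], q[r2, c2]] + 1
        counts[q[r2, c2], q[r, cl]] <- counts[q[r2, c2], q[r, cl]] + 1
      }
    }
  }
  counts / sum(counts)
}

# Literal double-loop texture statistics oracle.
oracle_glcm_features <- function(P) {
  L <- nrow(P)
  marg <- rowSums(P)
  mu <- sum(seq_len(L) * marg)
  sigma2 <- sum((seq_len(L) - mu)^2 * marg)
  me <- va <- di <- con <- ho <- se <- cor_num <- en <- 0
  for (i in seq_len(L)) {
    for (j in seq_len(L)) {
      p <- P[i, j]
      me <- me + i * p
      va <- va + (i - mu)^2 * p
      di <- di + abs(i - j) * p
      con <- con + (i - j)^2 * p
      ho <- ho + p / (1 + (i - j)^2)
      se <- se + p^2
      cor_num <- cor_num + (i - mu) * (j - mu) * p
      if (p > 0) en <- en - p * log(p)
    }
  }
  c(ME = me, VA = va, DI = di, CON = con, HO = ho, SE = se,
    COR = if (sigma2 == 0) 1 else cor_num / sigma2, EN = en)
}

# Per-pixel loop oracle for polygon band means.
oracle_band_means <- function(stack, poly) {
  dims <- dim(stack$ms)
  out <- numeric(6)
  cnt <- 0
  for (b in 1:6) {
    s <- 0; n <- 0
    for (r in seq_len(dims[1])) {
      for (cl in seq_len(dims[2])) {
        if (agbfusion::point_in_polygon(cl - 0.5, r - 0.5, poly)) {
          s <- s + stack$ms[r, cl, b]; n <- n + 1
        }
      }
    }
    out[b] <- s / n
  }
  names(out) <- stack$band_roles
  out
}

# Loop-based regression metrics oracle.
oracle_metrics <- function(y, yhat) {
  n <- length(y)
  ss_res <- 0; ss_tot <- 0; ae <- 0
  yb <- sum(y) / n
  for (i in seq_len(n)) {
    ss_res <- ss_res + (y[i] - yhat[i])^2
    ss_tot <- ss_tot + (y[i] - yb)^2
    ae <- ae + abs(y[i] - yhat[i])
  }
  rmse <- sqrt(ss_res / n)
  c(r2 = 1 - ss_res / ss_tot, rmse = rmse, mae = ae / n, rrmse = rmse / yb)
}

# Exhaustive-search Otsu oracle: threshold maximizing between-class variance
# over 256 candidate cut points.
oracle_otsu_cc <- function(v) {
  cand <- seq(min(v), max(v), length.out = 258)[2:257]
  best <- -Inf; thr <- cand[1]
  for (t in cand) {
    hi <- v > t
    if (!any(hi) || all(hi)) next
    b <- mean(hi) * (1 - mean(hi)) * (mean(v[hi]) - mean(v[!hi]))^2
    if (b > best) { best <- b; thr <- t }
  }
  mean(v > thr)
}
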