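test_that("band means match constant, symmetry and per-pixel oracles", {
  expect_equal(unlist(extract_band_means(constant_stack(0.37))[3:8]),
               setNames(rep(0.37, 6), band_roles()), tolerance = 1e-15)

  # polygon covering exactly the left half of a two-valued image
  ms <- array(0.2, dim = c(20, 20, 6))
  ms[, 1:5, ] <- 0.6  # left half of the polygon window is 0.6, right 0.2
  stk <- make_stack(ms)
  half_poly <- cbind(x = c(0, 10, 10, 0), y = c(0, 0, 20, 20))
  bm <- extract_band_means(stk, half_poly)
  expect_equal(unname(unlist(bm[3:8])), rep(0.4, 6), tolerance = 1e-15)

  set.seed(42)
  stk <- make_stack(array(runif(32 * 32 * 6), dim = c(32, 32, 6)))
  poly <- cbind(x = c(3, 29, 25, 5), y = c(2, 6, 30, 27))
  got <- unlist(extract_band_means(stk, poly)[3:8])
  expect_equal(got, oracle_band_means(stk, poly), tolerance = 1e-12)

  outside <- cbind(x = c(100, 110, 110), y = c(100, 100, 110))
  expect_error(extract_band_means(stk, outside), "does not intersect")
})

test_that("the vegetation-index bank has 14 indices with the documented formulas", {
  expect_length(vi_bank(), 14)
  m <- list(blue = 0.08, green = 0.2, red = 0.1, red_edge = 0.3, nir = 0.5)
  v <- compute_vis(m)
  expect_length(v, 14)
  expect_equal(unname(v["NDVI"]), 0.4 / 0.6, tolerance = 1e-12)
  expect_equal(unname(v["SR"]), 5.0, tolerance = 1e-12)
  expect_equal(unname(v["GCI"]), 1.5, tolerance = 1e-12)
  expect_equal(unname(v["RECI"]), 0.5 / 0.3 - 1, tolerance = 1e-12)
  expect_equal(unname(v["NDRE"]), 0.25, tolerance = 1e-12)
  expect_equal(unname(v["TDVI"]), (0.5 + 0.4 / 0.6)^2, tolerance = 1e-12)
  expect_equal(unname(v["WDRVI"]), (0.05 - 0.1) / (0.05 + 0.1),
               tolerance = 1e-12)

  # NIR == R forces NDVI to 0 and WDRVI negative
  v2 <- compute_vis(list(green = 0.2, red = 0.4, red_edge = 0.3, nir = 0.4))
  expect_equal(unname(v2["NDVI"]), 0)
  expect_lt(v2["WDRVI"], 0)

  # optional 15th index
  v3 <- compute_vis(m, include_grndvi = TRUE)
  expect_length(v3, 15)
  expect_equal(unname(v3["GRNDVI"]), (0.5 - 0.3) / (0.5 + 0.3),
               tolerance = 1e-12)

  # zero denominators propagate as flagged missing values
  v4 <- compute_vis(list(green = 0, red = 0, red_edge = 0.3, nir = 0.5))
  expect_true(is.na(v4["GRVI"]))
  expect_true(all(c("GRVI", "SR", "MCARI") %in% attr(v4, "flagged")))
})

test_that("vegetation indices depend only on band means, not pixel arrangement", {
  set.seed(7)
  ms <- array(runif(24 * 24 * 6), dim = c(24, 24, 6))
  perm <- sample(24 * 24)
  ms_perm <- array(apply(ms, 3, function(b) b[perm]), dim = dim(ms))
  v1 <- compute_vis(extract_band_means(make_stack(ms)))
  v2 <- compute_vis(extract_band_means(make_stack(ms_perm)))
  expect_equal(v1, v2, tolerance = 1e-12)
})

test_that("GLCM matrix matches hand enumeration and normalization contract", {
  # 2x2 patch [[0,0],[1,1]], 2 levels, horizontal offset:
  # pairs (0,0) and (1,1), each counted once -> 0.5 / 0.5 on the diagonal
  P <- glcm_matrix(matrix(c(0, 1, 0, 1), 2, 2), levels = 2, angle = 0)
  expect_equal(P, matrix(c(0.5, 0, 0, 0.5), 2, 2), tolerance = 1e-15)

  Pc <- glcm_matrix(matrix(5, 4, 4), levels = 8)
  expect_equal(sum(Pc == 1), 1)
  expect_equal(Pc[1, 1], 1)

  set.seed(3)
  for (i in 1:10) {
    patch <- matrix(runif(36), 6, 6)
    for (a in c(0, 45, 90, 135)) {
      P <- glcm_matrix(patch, levels = 8, angle = a)
      expect_equal(sum(P), 1, tolerance = 1e-12)
      expect_equal(P, t(P), tolerance = 1e-15)
    }
  }
})

test_that("GLCM texture statistics match closed forms and the loop oracle", {
  # single-entry matrix: degenerate texture
  f <- glcm_features(glcm_matrix(matrix(1, 3, 3), levels = 4))
  expect_equal(unname(f[c("HO", "SE", "CON", "EN")]), c(1, 1, 0, 0),
               tolerance = 1e-15)

  # uniform LxL matrix: SE = 1/L^2, EN = 2 log L
  L <- 5
  U <- matrix(1 / L^2, L, L)
  fu <- glcm_features(U)
  expect_equal(unname(fu["SE"]), 1 / L^2, tolerance = 1e-12)
  expect_equal(unname(fu["EN"]), 2 * log(L), tolerance = 1e-12)
  expect_equal(unname(glcm_features(U, log_base = 2)["EN"]), 2 * log2(L),
               tolerance = 1e-12)

  set.seed(11)
  for (i in 1:10) {
    patch <- matrix(runif(49), 7, 7)
    P <- glcm_matrix(patch, levels = 6, angle = 45)
    expect_equal(glcm_features(P), oracle_glcm_features(P), tolerance = 1e-12)
  }

  expect_error(glcm_features(matrix(1, 2, 2)), "not a normalized")
})

test_that("GLCM features are invariant to adding a constant to the patch", {
  set.seed(5)
  patch <- matrix(runif(64), 8, 8)
  expect_equal(glcm_texture(patch, levels = 16),
               glcm_texture(patch + 3.7, levels = 16), tolerance = 1e-12)
})

test_that("per-plot texture extraction yields 8 statistics for each of 6 bands", {
  stk <- render_plot_image(make_truth(cc = 0.5), size = 32, seed = 4)
  tex <- texture_features(stk)
  expect_length(tex, 48)
  expect_true(all(grepl("^tex\\.band[1-6]\\.(ME|VA|DI|CON|HO|SE|COR|EN)$",
                        names(tex))))
  ho <- tex[grepl("\\.HO$", names(tex))]
  se <- tex[grepl("\\.SE$", names(tex))]
  expect_true(all(ho > 0 & ho <= 1))
  expect_true(all(se > 0 & se <= 1))
  expect_true(all(tex[grepl("\\.CON$", names(tex))] >= 0))
  expect_true(all(abs(tex[grepl("\\.COR$", names(tex))]) <= 1))
})

test_that("canopy cover recovers known masks and is scale-invariant", {
  for (s in 1:5) {
    cc <- c(0.15, 0.3, 0.5, 0.7, 0.9)[s]
    stk <- render_plot_image(make_truth(cc = cc), size = 128, seed = s)
    res <- canopy_cover(stk)
    expect_equal(res$method, "otsu")
    expect_lt(abs(res$cc - mean(stk$mask)), 0.05)
  }

  # Otsu split agrees with an exhaustive between-class-variance search
  stk <- render_plot_image(make_truth(cc = 0.4), size = 128, seed = 9)
  exg <- 2 * stk$rgb[, , 2] - stk$rgb[, , 1] - stk$rgb[, , 3]
  expect_equal(canopy_cover(stk)$cc, oracle_otsu_cc(as.vector(exg)),
               tolerance = 0.02)

  # scaling the index image by a positive constant leaves cc unchanged
  stk2 <- stk
  stk2$rgb <- stk$rgb * 0.5
  expect_equal(canopy_cover(stk2)$cc, canopy_cover(stk)$cc, tolerance = 1e-12)

  # unimodal (all-soil) histogram falls back to the fixed threshold
  soil <- render_plot_image(make_truth(cc = 0), size = 64, seed = 2)
  expect_warning(res0 <- canopy_cover(soil), "not bimodal")
  expect_equal(res0$method, "fixed")
  expect_lte(res0$cc, 0.05)

  # NDVI route works on the multispectral stack
  res_ndvi <- canopy_cover(render_plot_image(make_truth(cc = 0.5), size = 128,
                                             seed = 3), index = "ndvi")
  expect_lt(abs(res_ndvi$cc - 0.5), 0.05)
})

test_that("NDVI tracks true AGB on synthetic scenes (growth-phase signal)", {
  ft <- cached_features()
  truth <- cached_scene()$truth
  expect_gt(cor(ft$vi.NDVI, truth$true_agb, method = "spearman"), 0.5)
})
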