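# Fixtures built in code; the rendered default scene is cached per session
# because several files need it.

.fixture_cache <- new.env(parent = emptyenv())

cached_scene <- function() {
  if (is.null(.fixture_cache$scene)) {
    .fixture_cache$scene <- generate_dataset(scene_config(), seed = 101)
  }
  .fixture_cache$scene
}

cached_features <- function() {
  if (is.null(.fixture_cache$features)) {
    .fixture_cache$features <- build_feature_table(cached_scene())
  }
  .fixture_cache$features
}

make_truth <- function(cc = 0.5, plot_id = "P1", agb = 1.5,
                       date = "2023-07-20") {
  data.frame(plot_id = plot_id, flight_date = as.Date(date), stage = "S2",
             gpr = 0.4, true_agb = agb, true_cc = cc,
             stringsAsFactors = FALSE)
}

# A band_stack with fully specified pixel values (no randomness).
make_stack <- function(ms, rgb = NULL, plot_id = "P1") {
  if (is.null(rgb)) {
    rgb <- array(0, dim = c(dim(ms)[1], dim(ms)[2], 3))
    rgb[, , 1] <- ms[, , 4]; rgb[, , 2] <- ms[, , 2]; rgb[, , 3] <- ms[, , 1]
  }
  structure(list(ms = ms, rgb = rgb, band_roles = band_roles(), mask = NULL,
                 plot_id = plot_id, flight_date = as.Date("2023-07-20")),
            class = "band_stack")
}

constant_stack <- function(value = 0.3, h = 20, w = 20) {
  make_stack(array(value, dim = c(h, w, 6)))
}

# Synthetic regression table with namespaced feature columns, for the
# selection and model operations.
synthetic_table <- function(n = 200, seed = 1, n_vi = 6, n_tex = 4,
                            informative = "vi.F1", noise_sd = 0.3) {
  withr::with_seed(seed, {
    out <- data.frame(stage = rep(c("S1", "S2", "S3", "S4"), length.out = n))
    for (i in seq_len(n_vi)) out[[paste0("vi.F", i)]] <- rnorm(n)
    for (i in seq_len(n_tex)) out[[paste0("tex.band1.T", i)]] <- rnorm(n)
    out$cc <- runif(n)
    out$gdd <- runif(n, 100, 900)
    out$gpr <- runif(n)
    out$agb <- out[[informative]] + rnorm(n, 0, noise_sd)
    out
  })
}
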