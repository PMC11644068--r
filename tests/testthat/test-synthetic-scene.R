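test_that("experiment designs have the factorial layout and plot counts", {
  e1 <- build_design("E1")
  e2 <- build_design("E2")
  e3 <- build_design("E3")
  expect_equal(nrow(e1), 18)
  expect_equal(nrow(e2), 40)
  expect_equal(nrow(e3), 36)
  expect_setequal(unique(e1$density), c(52500, 60000, 75000))
  expect_setequal(unique(e1$cultivar_id), c("Z27", "Z19"))
  expect_setequal(unique(e2$n_rate), c(0, 50, 100, 250, 400))
  expect_setequal(unique(e3$n_rate), c(0, 120, 240))
  expect_setequal(unique(e3$k_rate), c(0, 120, 240, 360))
  expect_equal(unique(e3$cultivar_id), "Z35")
  # fully crossed within each block
  expect_true(all(table(e1$block) == 6))
  expect_true(all(table(e2$cultivar_id, e2$n_rate) == 4))
  expect_true(all(table(e3$n_rate, e3$k_rate) == 3))
  # counts invariant over randomization seeds
  for (s in 1:10) {
    expect_equal(nrow(build_design("E1", seed = s)), 18)
    expect_equal(nrow(build_design("E2", seed = s)), 40)
    expect_equal(nrow(build_design("E3", seed = s)), 36)
  }
  expect_identical(build_design("E2", seed = 4), build_design("E2", seed = 4))
  expect_error(build_design("E9"), "unknown experiment_id")
})

test_that("simulated weather is daily, deterministic, with bounded diurnal range", {
  w1 <- simulate_weather("2023-07-10", "2023-07-10", seed = 5)
  expect_equal(nrow(w1), 1)
  expect_identical(simulate_weather("2023-06-01", "2023-08-31", seed = 9),
                   simulate_weather("2023-06-01", "2023-08-31", seed = 9))
  w <- simulate_weather("2023-07-01", "2023-08-29", seed = 3)
  expect_equal(nrow(w), 60)
  expect_true(all(w$t_max - w$t_min > 0))
  expect_true(all(w$t_max - w$t_min <= 20))
  expect_error(simulate_weather("2023-08-01", "2023-07-01"), "reversed")
})

test_that("latent AGB follows the logistic growth model", {
  plot <- build_design("E3")[1, ]
  cv <- cultivar_catalog()[cultivar_catalog()$cultivar_id == "Z35", ]
  p0 <- growth_params(noise_sdlog = 0, cc_noise_sd = 0)

  # near-zero biomass at emergence (logistic lower asymptote)
  early <- simulate_agb(plot, cv, cv$emergence_date, params = p0)
  expect_lt(early$true_agb, 0.1)

  # determinism with zero noise
  a1 <- simulate_agb(plot, cv, "2023-08-01", params = p0, seed = 1)
  a2 <- simulate_agb(plot, cv, "2023-08-01", params = p0, seed = 999)
  expect_identical(a1$true_agb, a2$true_agb)

  # mean response monotone non-decreasing in GPR
  g <- seq(0, 1, by = 0.01)
  resp <- agb_response(g, plot$density, plot$n_rate, plot$k_rate)
  expect_true(all(diff(resp) >= 0))

  expect_error(simulate_agb(plot, cv, "2023-05-01"), "precedes emergence")
})

test_that("sampled AGB mean matches the analytic curve mean (Monte Carlo)", {
  sc <- generate_dataset(scene_config(), seed = 7, render = FALSE)
  truth <- sc$truth
  mu <- agb_response(truth$gpr, truth$density, truth$n_rate, truth$k_rate)
  diff <- truth$true_agb - mu   # mean-one multiplicative noise => E[diff] = 0
  expect_lt(abs(mean(diff)), 3 * sd(diff) / sqrt(nrow(truth)))
})

test_that("rendered vegetation fraction matches true cover and degenerate covers", {
  stk0 <- render_plot_image(make_truth(cc = 0), size = 64, seed = 1)
  expect_false(any(stk0$mask))
  expect_lte(suppressWarnings(canopy_cover(stk0))$cc, 0.05)

  stk1 <- render_plot_image(make_truth(cc = 1), size = 64, seed = 1)
  expect_true(all(stk1$mask))
  expect_gte(suppressWarnings(canopy_cover(stk1))$cc, 0.95)

  # clumped placement: exact mask counting within 3/sqrt(H*W)
  for (s in 1:5) {
    cc <- c(0.2, 0.35, 0.5, 0.65, 0.8)[s]
    stk <- render_plot_image(make_truth(cc = cc), size = 128, seed = s)
    expect_lt(abs(mean(stk$mask) - cc), 3 / sqrt(128 * 128))
  }

  # i.i.d. placement available as the degenerate option
  stk <- render_plot_image(make_truth(cc = 0.5), size = 128, clumped = FALSE,
                           seed = 2)
  expect_lt(abs(mean(stk$mask) - 0.5), 0.05)

  bad <- default_endmembers()
  bad$veg["nir"] <- 1.4
  expect_error(render_plot_image(make_truth(), endmembers = bad), "\\[0, 1\\]")
  bad2 <- default_endmembers()
  bad2$veg["red"] <- 0.9
  expect_error(render_plot_image(make_truth(), endmembers = bad2), "red")
  expect_error(render_plot_image(make_truth(), size = 8), "at least 16")
})

test_that("generate_dataset yields the study sample counts and is reproducible", {
  sc <- generate_dataset(scene_config(), seed = 3, render = FALSE)
  expect_equal(nrow(sc$truth), 376)  # 4 flights x (18 + 40 + 36) plots
  expect_equal(sum(table(sc$truth$experiment_id) / 4), 94)

  e1 <- generate_dataset(scene_config(experiments = "E1"), seed = 3,
                         render = FALSE)
  expect_equal(nrow(e1$truth), 72)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scene(generate_dataset(scene_config(experiments = "E1"), seed = 11,
                               render = FALSE), d1, overwrite = TRUE)
  write_scene(generate_dataset(scene_config(experiments = "E1"), seed = 11,
                               render = FALSE), d2, overwrite = TRUE)
  expect_identical(readBin(file.path(d1, "ground_truth.csv"), "raw", 1e6),
                   readBin(file.path(d2, "ground_truth.csv"), "raw", 1e6))
  expect_error(
    write_scene(generate_dataset(scene_config(experiments = "E1"), seed = 11,
                                 render = FALSE), d1),
    "overwrite")
})

test_that("a written scene reads back with identical truth and rasters", {
  sc <- generate_dataset(scene_config(experiments = "E1",
                                      flights = flight_schedule()[1, ],
                                      image_size = 32), seed = 5)
  d <- withr::local_tempdir()
  write_scene(sc, d, overwrite = TRUE)
  back <- read_scene(d)
  expect_equal(back$truth$true_agb, sc$truth$true_agb, tolerance = 1e-12)
  expect_equal(back$truth$plot_id, sc$truth$plot_id)
  k <- names(sc$stacks)[1]
  expect_equal(back$stacks[[k]]$ms, sc$stacks[[k]]$ms, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$polygons[["E1-01"]], sc$polygons[["E1-01"]],
               ignore_attr = TRUE)
})
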