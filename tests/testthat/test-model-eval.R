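test_that("metrics match hand computations and the loop oracle", {
  expect_equal(metrics(c(1, 2, 3), c(1, 2, 3)),
               c(r2 = 1, rmse = 0, mae = 0, rrmse = 0))
  expect_equal(metrics(c(0, 2), c(1, 1)),
               c(r2 = 0, rmse = 1, mae = 1, rrmse = 1))
  y <- c(1, 2, 3, 4)
  expect_equal(unname(metrics(y, rep(mean(y), 4))["r2"]), 0)

  set.seed(13)
  for (i in 1:5) {
    y <- rnorm(50, 10)
    yh <- y + rnorm(50)
    expect_equal(metrics(y, yh), oracle_metrics(y, yh), tolerance = 1e-12)
  }
  expect_error(metrics(1:3, 1:2), "equal non-zero length")
  expect_warning(m <- metrics(c(-1, 1), c(0, 0)), "rRMSE undefined")
  expect_true(is.na(m["rrmse"]))
})

test_that("stratified split is disjoint, exhaustive, sized and reproducible", {
  truth <- generate_dataset(scene_config(), seed = 4, render = FALSE)$truth
  sp <- split_train_test(truth, fraction = 2/3, seed = 1)
  expect_equal(nrow(sp$train) + nrow(sp$test), 376)
  expect_true(nrow(sp$train) %in% c(250, 251))
  key <- function(d) paste(d$plot_id, d$flight_date)
  expect_length(intersect(key(sp$train), key(sp$test)), 0)
  expect_setequal(c(key(sp$train), key(sp$test)), key(truth))
  # stratification keeps stage proportions
  expect_true(all(abs(table(sp$train$stage) - 251 / 4) <= 1))

  sp2 <- split_train_test(truth, fraction = 2/3, seed = 1)
  expect_identical(sp, sp2)

  expect_error(split_train_test(truth, fraction = 0), "strictly between")
  expect_error(split_train_test(truth, fraction = 1), "strictly between")
  tiny <- truth[1:5, ]
  tiny$stage <- c("S1", "S1", "S2", "S2", "S3")
  expect_error(split_train_test(tiny), "stratum smaller than 2")
})

test_that("fusion enumeration covers all non-empty subsets", {
  combos <- enumerate_fusions()
  expect_length(combos, 31)
  expect_length(enumerate_fusions("VIs"), 1)
  expect_true("VIs+CC+GDD+GPR" %in% names(combos))
  singletons <- vapply(combos, attr, logical(1), "baseline")
  expect_equal(sum(singletons), 5)
  expect_error(enumerate_fusions(character(0)), "non-empty")
})

test_that("models recover exact linear structure and reject degenerate designs", {
  n <- 60
  tab <- data.frame(stage = rep(c("S1", "S2"), n / 2),
                    vi.x = seq_len(n) / 10)
  tab$agb <- 2 * tab$vi.x + 1          # exact linear target
  sp <- split_train_test(tab, seed = 2)
  res <- fit_predict(model_spec("SLR"), sp$train, sp$test, "VIs")
  expect_equal(res$r2_test, 1, tolerance = 1e-10)
  expect_lt(res$rmse_test, 1e-10)

  # exact collinearity rejected for MLR
  tab$vi.y <- 2 * tab$vi.x
  sp <- split_train_test(tab, seed = 2)
  expect_error(fit_predict(model_spec("MLR"), sp$train, sp$test, "VIs"),
               "singular|collinear")
})

test_that("MLR test R2 is near zero when the target is independent of features", {
  r2s <- vapply(1:20, function(s) {
    tab <- synthetic_table(n = 300, seed = 100 + s, n_vi = 5, n_tex = 0)
    tab$agb <- withr::with_seed(200 + s, rnorm(300))  # sever the link
    sp <- split_train_test(tab, seed = s)
    fit_predict(model_spec("MLR", seed = s), sp$train, sp$test, "VIs")$r2_test
  }, numeric(1))
  expect_lte(mean(r2s), 0.05)
})

test_that("all six algorithms fit, are deterministic, and respect selections", {
  tab <- synthetic_table(n = 120, seed = 21)
  sp <- split_train_test(tab, seed = 3)
  for (kind in c("RF", "PLSR", "MLR", "SLR", "Ridge", "Lasso")) {
    r1 <- fit_predict(model_spec(kind, seed = 4), sp$train, sp$test,
                      c("VIs", "GPR"))
    r2 <- fit_predict(model_spec(kind, seed = 4), sp$train, sp$test,
                      c("VIs", "GPR"))
    expect_identical(r1, r2)
    expect_true(r1$r2_train <= 1 && r1$r2_test <= 1)
    expect_true(r1$mae_test <= r1$rmse_test + 1e-12)
    expect_gte(r1$rrmse_test, 0)
  }
  sel <- pearson_rank(tab, k_vi = 2, k_tex = 1)
  r <- fit_predict(model_spec("MLR"), sp$train, sp$test, "VIs", selection = sel)
  expect_equal(r$combo, "VIs")
  # single-feature groups work for the penalized models too
  r_gpr <- fit_predict(model_spec("Ridge"), sp$train, sp$test, "GPR")
  expect_equal(r_gpr$combo, "GPR")
})

test_that("run_comparison fills the grid, ranks best combos, and survives failures", {
  tab <- synthetic_table(n = 120, seed = 31)
  combos <- enumerate_fusions(c("VIs", "GPR"))
  rep <- run_comparison(tab, selections = list(none = NULL),
                        models = c("MLR", "Ridge"), combos = combos, seed = 5)
  expect_equal(nrow(rep$results), 2 * 3)
  expect_equal(nrow(rep$best), 2)
  for (m in c("MLR", "Ridge")) {
    sub <- rep$results[rep$results$model == m, ]
    expect_equal(rep$best$combo[rep$best$model == m],
                 sub$combo[order(-sub$r2_test, sub$rrmse_test, sub$combo)][1])
  }

  # degenerate single-combo grid equals the direct fit
  one <- run_comparison(tab, selections = list(none = NULL), models = "MLR",
                        combos = enumerate_fusions("VIs"), seed = 5)
  sp <- split_train_test(tab, seed = 5)
  direct <- fit_predict(model_spec("MLR", seed = 5), sp$train, sp$test, "VIs")
  expect_equal(one$results[, names(direct)], direct)

  # a failing cell is recorded and the grid continues
  tab$vi.dup <- tab$vi.F1
  rep2 <- run_comparison(tab, selections = list(none = NULL),
                         models = c("MLR", "Ridge"),
                         combos = enumerate_fusions(c("VIs", "GPR")), seed = 5)
  expect_true(!is.null(rep2$errors) && nrow(rep2$errors) >= 1)
  expect_true(all(rep2$errors$model == "MLR"))
  # 2 models x 3 combos: every cell lands in results or errors
  expect_equal(nrow(rep2$results) + nrow(rep2$errors), 6)
})
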