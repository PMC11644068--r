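#' Regression evaluation metrics
#'
#' `R2 = 1 - sum((pred - obs)^2) / sum((obs - mean(obs))^2)`,
#' `RMSE = sqrt(mean((obs - pred)^2))`, `MAE = mean(|obs - pred|)`,
#' `rRMSE = RMSE / mean(obs)` (dimensionless; undefined and returned as `NA`
#' with a warning when the observed mean is zero).
#'
#' @param y_obs,y_pred numeric vectors of equal, non-zero length.
#' @return named numeric vector `r2, rmse, mae, rrmse`.
#' @export
metrics <- function(y_obs, y_pred) {
  if (length(y_obs) != length(y_pred) || length(y_obs) == 0) {
    stop("y_obs and y_pred must have equal non-zero length")
  }
  res <- y_obs - y_pred
  ss_tot <- sum((y_obs - mean(y_obs))^2)
  rmse <- sqrt(mean(res^2))
  ybar <- mean(y_obs)
  rrmse <- if (ybar == 0) {
    warning("observed mean is zero; rRMSE undefined")
    NA_real_
  } else rmse / ybar
  c(r2 = 1 - sum(res^2) / ss_tot,
    rmse = rmse,
    mae = mean(abs(res)),
    rrmse = rrmse)
}

#' Stratified train/test split
#'
#' Random holdout split, stratified by growth stage by default. The train
#' size equals `round(nrow(table) * fraction)`, allocated across strata by
#' largest remainder so each stratum contributes proportionally and keeps at
#' least one row on each side.
#'
#' @param table data.frame to split.
#' @param fraction train fraction, strictly in (0, 1); default 2/3.
#' @param seed integer seed; the same seed reproduces the split.
#' @param stratify_by stratification column name, or `NULL` for a simple
#'   random split. `"plot_id"` gives a plot-grouped split surrogate
#'   (stratification by plot keeps the same fraction of each plot's dates).
#' @return list with disjoint, exhaustive data.frames `train` and `test`.
#' @export
split_train_test <- function(table, fraction = 2/3, seed = 1L,
                             stratify_by = "stage") {
  if (nrow(table) == 0) stop("table is empty")
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    stop("fraction must be strictly between 0 and 1")
  }
  strata <- if (is.null(stratify_by)) rep("all", nrow(table))
            else as.character(table[[stratify_by]])
  tab <- table(strata)
  if (any(tab < 2)) {
    stop("stratum smaller than 2: ", paste(names(tab)[tab < 2], collapse = ", "))
  }
  n_train <- round(nrow(table) * fraction)
  n_train <- min(max(n_train, length(tab)), nrow(table) - length(tab))
  quota <- as.numeric(tab) * fraction
  base <- pmin(pmax(floor(quota), 1), as.numeric(tab) - 1)
  rem <- n_train - sum(base)
  if (rem > 0) {
    ord <- order(-(quota - floor(quota)), names(tab))
    for (k in ord) {
      if (rem == 0) break
      if (base[k] < tab[k] - 1) { base[k] <- base[k] + 1; rem <- rem - 1 }
    }
  } else if (rem < 0) {
    ord <- order(quota - floor(quota), names(tab))
    for (k in ord) {
      if (rem == 0) break
      if (base[k] > 1) { base[k] <- base[k] - 1; rem <- rem + 1 }
    }
  }
  idx_train <- withr::with_seed(seed, {
    unlist(lapply(seq_along(tab), function(k) {
      rows <- which(strata == names(tab)[k])
      sample(rows, base[k])
    }))
  })
  list(train = table[sort(idx_train), , drop = FALSE],
       test = table[setdiff(seq_len(nrow(table)), idx_train), , drop = FALSE])
}

#' Enumerate feature-group fusion combinations
#'
#' All non-empty subsets of the feature groups. Single-group subsets are
#' flagged as the single-feature baselines.
#'
#' @param groups character vector of group names.
#' @return list of character vectors; each has attribute `baseline`
#'   (`TRUE` for singletons) and the list is labelled `"A+B"` style.
#' @export
enumerate_fusions <- function(groups = c("VIs", "Texture", "CC", "GDD", "GPR")) {
  if (length(groups) == 0) stop("groups must be non-empty")
  n <- length(groups)
  combos <- list()
  for (k in seq_len(n)) {
    sets <- utils::combn(groups, k, simplify = FALSE)
    combos <- c(combos, sets)
  }
  combos <- lapply(combos, function(s) {
    attr(s, "baseline") <- length(s) == 1
    s
  })
  names(combos) <- vapply(combos, paste, character(1), collapse = "+")
  combos
}

#' Model specification
#'
#' @param kind one of `"RF"`, `"PLSR"`, `"MLR"`, `"SLR"`, `"Ridge"`,
#'   `"Lasso"`.
#' @param trees random-forest tree count.
#' @param max_comp maximum PLS components considered in cross-validation.
#' @param nfolds folds for the Ridge/Lasso/PLSR cross-validation.
#' @param seed integer seed used by stochastic learners and CV folds.
#' @return list of class `model_spec`.
#' @export
model_spec <- function(kind = c("RF", "PLSR", "MLR", "SLR", "Ridge", "Lasso"),
                       trees = 500, max_comp = 10, nfolds = 5, seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, trees = trees, max_comp = max_comp,
                 nfolds = nfolds, seed = seed), class = "model_spec")
}

# Resolve a fusion combo into concrete feature-table columns, restricted to
# selection-confirmed features for the VIs and Texture groups.
resolve_combo_features <- function(table, combo, selection = NULL) {
  groups <- feature_groups(names(table))
  pick <- function(grp) {
    cols <- names(table)[groups %in% grp]
    if (!is.null(selection) && grp %in% c("VIs", "Texture")) {
      cols <- intersect(cols, selection$confirmed)
    }
    cols
  }
  feats <- unlist(lapply(combo, function(g) {
    switch(g, VIs = pick("VIs"), Texture = pick("Texture"),
           CC = pick("CC"), GDD = pick("GDD"), GPR = pick("GPR"),
           stop("unknown feature group: ", g))
  }), use.names = FALSE)
  if (length(feats) == 0) stop("combo resolves to no features: ",
                               paste(combo, collapse = "+"))
  feats
}

#' Fit one model on a train/test split and evaluate
#'
#' Fits the specified algorithm on the training partition only, using the
#' features of the given fusion combo (restricted, for the VIs and Texture
#' groups, to the selection-confirmed features when a selection result is
#' supplied), and reports metrics on both partitions. Predictors are
#' z-scored with train-fitted parameters for Ridge, Lasso and PLSR. Rows
#' with missing feature values are dropped listwise (count reported via
#' message). SLR uses the single feature with the highest absolute train
#' correlation with the target.
#'
#' @param spec [model_spec()].
#' @param train,test data.frame partitions from [split_train_test()].
#' @param combo character vector of feature groups.
#' @param selection optional `selection_result`.
#' @param target target column name.
#' @return one-row data.frame: model, combo, n_train, n_test, and
#'   `r2/rmse/rrmse/mae` for train and test.
#' @export
fit_predict <- function(spec, train, test, combo, selection = NULL,
                        target = "agb") {
  stopifnot(inherits(spec, "model_spec"))
  feats <- resolve_combo_features(train, combo, selection)
  ok_tr <- stats::complete.cases(train[, c(feats, target)])
  ok_te <- stats::complete.cases(test[, c(feats, target)])
  if (any(!ok_tr) || any(!ok_te)) {
    message("listwise deletion: dropped ", sum(!ok_tr), " train and ",
            sum(!ok_te), " test rows with missing features")
  }
  x_tr <- as.matrix(train[ok_tr, feats, drop = FALSE])
  x_te <- as.matrix(test[ok_te, feats, drop = FALSE])
  y_tr <- train[[target]][ok_tr]
  y_te <- test[[target]][ok_te]
  if (nrow(x_tr) < 3) stop("too few complete training rows")

  standardize <- spec$kind %in% c("Ridge", "Lasso", "PLSR")
  if (standardize) {
    mu <- colMeans(x_tr)
    sd <- apply(x_tr, 2, stats::sd)
    sd[sd == 0] <- 1
    x_tr <- sweep(sweep(x_tr, 2, mu), 2, sd, "/")
    x_te <- sweep(sweep(x_te, 2, mu), 2, sd, "/")
  }

  pred <- switch(spec$kind,
    RF = {
      dat <- data.frame(x_tr, check.names = FALSE)
      dat$.y <- y_tr
      fit <- ranger::ranger(dependent.variable.name = ".y", data = dat,
                            num.trees = spec$trees, num.threads = 1,
                            seed = spec$seed)
      list(tr = stats::predict(fit, data.frame(x_tr, check.names = FALSE))$predictions,
           te = stats::predict(fit, data.frame(x_te, check.names = FALSE))$predictions)
    },
    MLR = ,
    SLR = {
      if (spec$kind == "SLR") {
        r <- abs(apply(x_tr, 2, function(v) {
          if (stats::sd(v) == 0) 0 else stats::cor(v, y_tr)
        }))
        best <- sort(names(r)[r == max(r)])[1]
        x_tr <- x_tr[, best, drop = FALSE]
        x_te <- x_te[, best, drop = FALSE]
      }
      dat <- data.frame(x_tr, check.names = FALSE)
      dat$.y <- y_tr
      fit <- stats::lm(.y ~ ., data = dat)
      if (anyNA(stats::coef(fit))) {
        stop("singular design (collinear features) for ", spec$kind,
             " on combo ", paste(combo, collapse = "+"))
      }
      list(tr = unname(stats::predict(fit, data.frame(x_tr, check.names = FALSE))),
           te = unname(stats::predict(fit, data.frame(x_te, check.names = FALSE))))
    },
    Ridge = ,
    Lasso = {
      # glmnet needs >= 2 columns; pad single-feature designs with a zero column
      pad <- ncol(x_tr) == 1
      if (pad) {
        x_tr <- cbind(x_tr, .pad = 0)
        x_te <- cbind(x_te, .pad = 0)
      }
      alpha <- if (spec$kind == "Ridge") 0 else 1
      fit <- withr::with_seed(spec$seed,
        glmnet::cv.glmnet(x_tr, y_tr, alpha = alpha, nfolds = spec$nfolds,
                          standardize = FALSE))
      list(tr = as.numeric(stats::predict(fit, x_tr, s = "lambda.min")),
           te = as.numeric(stats::predict(fit, x_te, s = "lambda.min")))
    },
    PLSR = {
      ncomp_max <- max(1, min(spec$max_comp, ncol(x_tr), nrow(x_tr) - 2))
      ncomp <- if (ncomp_max == 1) 1 else {
        cv_err <- withr::with_seed(spec$seed, {
          folds <- sample(rep_len(seq_len(spec$nfolds), nrow(x_tr)))
          sapply(seq_len(ncomp_max), function(nc) {
            errs <- vapply(seq_len(spec$nfolds), function(f) {
              tr <- folds != f
              fit <- suppressMessages(mixOmics::pls(
                x_tr[tr, , drop = FALSE], y_tr[tr], ncomp = nc,
                mode = "regression", scale = FALSE))
              p <- stats::predict(fit, x_tr[!tr, , drop = FALSE])$predict[, 1, nc]
              mean((y_tr[!tr] - p)^2)
            }, numeric(1))
            mean(errs)
          })
        })
        which.min(cv_err)
      }
      fit <- suppressMessages(mixOmics::pls(x_tr, y_tr, ncomp = ncomp,
                                            mode = "regression", scale = FALSE))
      list(tr = stats::predict(fit, x_tr)$predict[, 1, ncomp],
           te = stats::predict(fit, x_te)$predict[, 1, ncomp])
    }
  )
  m_tr <- metrics(y_tr, pred$tr)
  m_te <- metrics(y_te, pred$te)
  data.frame(model = spec$kind, combo = paste(combo, collapse = "+"),
             n_train = length(y_tr), n_test = length(y_te),
             r2_train = m_tr["r2"], rmse_train = m_tr["rmse"],
             rrmse_train = m_tr["rrmse"], mae_train = m_tr["mae"],
             r2_test = m_te["r2"], rmse_test = m_te["rmse"],
             rrmse_test = m_te["rrmse"], mae_test = m_te["mae"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the full model x fusion-combination comparison
#'
#' Evaluates every model on every fusion combination for each selection
#' route, on a single shared stratified holdout split, and reports the best
#' combination per model (highest test R2, ties broken by lower test rRMSE).
#' Individual model failures are recorded and the grid continues.
#'
#' @param table feature table from [build_feature_table()].
#' @param selections named list of `selection_result` objects (one per
#'   route), or `list(none = NULL)` to use all features per group.
#' @param models character vector of model kinds.
#' @param combos list from [enumerate_fusions()] (default: all 31 subsets
#'   of the five groups).
#' @param fraction,seed,stratify_by passed to [split_train_test()].
#' @param target target column name.
#' @return list of class `eval_report`: `results` (one row per route x
#'   model x combo), `best` (one row per route x model), `errors`, `split`.
#' @export
run_comparison <- function(table, selections = list(none = NULL),
                           models = c("RF", "PLSR", "MLR", "SLR", "Ridge", "Lasso"),
                           combos = enumerate_fusions(),
                           fraction = 2/3, seed = 1L, stratify_by = "stage",
                           target = "agb") {
  split <- split_train_test(table, fraction = fraction, seed = seed,
                            stratify_by = stratify_by)
  results <- list()
  errors <- list()
  for (route in names(selections)) {
    sel <- selections[[route]]
    for (kind in models) {
      spec <- model_spec(kind, seed = seed)
      for (ci in seq_along(combos)) {
        res <- tryCatch(
          fit_predict(spec, split$train, split$test, combos[[ci]],
                      selection = sel, target = target),
          error = function(e) e)
        if (inherits(res, "error")) {
          errors[[length(errors) + 1]] <- data.frame(
            route = route, model = kind, combo = names(combos)[ci],
            message = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          res$route <- route
          results[[length(results) + 1]] <- res
        }
      }
    }
  }
  results <- if (length(results)) do.call(rbind, results) else NULL
  errors <- if (length(errors)) do.call(rbind, errors) else NULL
  best <- NULL
  if (!is.null(results)) {
    parts <- split(results, list(results$route, results$model), drop = TRUE)
    best <- do.call(rbind, lapply(parts, function(d) {
      d[order(-d$r2_test, d$rrmse_test, d$combo), ][1, ]
    }))
    rownames(best) <- NULL
  }
  structure(list(results = results, best = best, errors = errors,
                 split = split), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", if (is.null(x$results)) 0 else nrow(x$results),
      "evaluations;", if (is.null(x$errors)) 0 else nrow(x$errors),
      "failures\n")
  if (!is.null(x$best)) {
    cat("best combination per route x model (by test R2):\n")
    print(x$best[, c("route", "model", "combo", "r2_test", "rrmse_test",
                     "mae_test")], digits = 3)
  }
  invisible(x)
}

#' Repeated-holdout evaluation of one model/combo
#'
#' Convenience wrapper: repeats [split_train_test()] + [fit_predict()]
#' over several seeds and returns the test metrics per repeat.
#'
#' @inheritParams fit_predict
#' @param table feature table.
#' @param seeds integer vector of split seeds.
#' @param fraction,stratify_by passed to [split_train_test()].
#' @return data.frame, one row per seed, with the [fit_predict()] columns.
#' @export
repeated_holdout <- function(table, spec, combo, selection = NULL,
                             seeds = 1:5, fraction = 2/3,
                             stratify_by = "stage", target = "agb") {
  out <- lapply(seeds, function(s) {
    sp <- split_train_test(table, fraction = fraction, seed = s,
                           stratify_by = stratify_by)
    spec$seed <- s
    res <- fit_predict(spec, sp$train, sp$test, combo, selection = selection,
                       target = target)
    res$seed <- s
    res
  })
  do.call(rbind, out)
}
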