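#' Pearson top-k feature ranking
#'
#' Ranks vegetation-index and texture features by the absolute Pearson
#' correlation of each feature with the target over pooled complete rows,
#' and confirms the top `k_vi` indices and top `k_tex` texture features.
#' Constant features (undefined correlation) are auto-rejected with a
#' warning. Ties at the k-th rank are broken by lexicographic feature name.
#'
#' @param table feature table (data.frame) with namespaced feature columns.
#' @param target name of the target column (default `"agb"`).
#' @param k_vi,k_tex number of vegetation indices / texture features to keep.
#' @return list of class `selection_result`: `method`, `confirmed`,
#'   `rejected`, `tentative` (empty), `scores` (named |r|, `NA` for
#'   constant features).
#' @export
pearson_rank <- function(table, target = "agb", k_vi = 5, k_tex = 3) {
  groups <- feature_groups(names(table))
  cand <- names(table)[groups %in% c("VIs", "Texture")]
  if (length(cand) == 0) stop("no vi.* or tex.* candidate columns in table")
  keep <- stats::complete.cases(table[, c(cand, target)])
  if (sum(keep) < 3) stop("need at least 3 complete rows")
  y <- table[[target]][keep]
  if (stats::var(y) == 0) stop("target has zero variance")
  scores <- vapply(cand, function(f) {
    x <- table[[f]][keep]
    if (stats::var(x) == 0) NA_real_ else abs(stats::cor(x, y))
  }, numeric(1))
  if (anyNA(scores)) {
    warning("constant features auto-rejected: ",
            paste(names(scores)[is.na(scores)], collapse = ", "))
  }
  top_k <- function(grp, k) {
    s <- scores[feature_groups(names(scores)) == grp & !is.na(scores)]
    if (length(s) == 0) return(character(0))
    ord <- order(-s, names(s))  # |r| descending, ties lexicographic
    names(s)[ord][seq_len(min(k, length(s)))]
  }
  confirmed <- c(top_k("VIs", k_vi), top_k("Texture", k_tex))
  structure(list(method = "pearson",
                 confirmed = confirmed,
                 rejected = setdiff(cand, confirmed),
                 tentative = character(0),
                 scores = scores, k_vi = k_vi, k_tex = k_tex),
            class = "selection_result")
}

#' Per-cultivar correlation diagnostics
#'
#' Pearson correlation of each feature with the target within each cultivar
#' (a reported diagnostic; pooled correlations drive [pearson_rank()]).
#'
#' @inheritParams pearson_rank
#' @param features columns to report (default: all vi./tex./cc/gdd/gpr).
#' @return matrix of correlations, features x cultivars.
#' @export
pearson_by_cultivar <- function(table, target = "agb", features = NULL) {
  groups <- feature_groups(names(table))
  features <- features %||% names(table)[!is.na(groups)]
  cvs <- sort(unique(table$cultivar_id))
  out <- sapply(cvs, function(cv) {
    sub <- table[table$cultivar_id == cv, ]
    vapply(features, function(f) {
      ok <- stats::complete.cases(sub[, c(f, target)])
      if (sum(ok) < 3 || stats::var(sub[[f]][ok]) == 0) return(NA_real_)
      stats::cor(sub[[f]][ok], sub[[target]][ok])
    }, numeric(1))
  })
  out
}

#' Variance-inflation-factor screening
#'
#' Computes `VIF = 1 / (1 - R^2)` for each candidate, where `R^2` comes from
#' an ordinary least-squares regression of that feature on all the others,
#' and iteratively drops the highest-VIF feature until all remaining VIFs
#' are at or below `threshold`. Exactly collinear features have infinite VIF
#' and are dropped first; ties are broken by lexicographic feature name.
#'
#' @param table feature table.
#' @param candidates names of candidate feature columns.
#' @param threshold maximum acceptable VIF (default 10).
#' @return data.frame with one row per candidate: `feature`, `vif` (the
#'   value when retained at the end, or when dropped), `retained`,
#'   `drop_order` (`NA` for retained features).
#' @export
vif_screen <- function(table, candidates, threshold = 10) {
  candidates <- sort(candidates)
  keep <- stats::complete.cases(table[, candidates, drop = FALSE])
  if (sum(keep) < length(candidates) + 2) {
    stop("need at least length(candidates) + 2 complete rows")
  }
  x <- as.data.frame(table[keep, candidates, drop = FALSE])
  vif_of <- function(f, others) {
    if (length(others) == 0) return(1)
    fit <- stats::lm(stats::reformulate(sprintf("`%s`", others),
                                        response = sprintf("`%s`", f)),
                     data = x)
    y <- x[[f]]
    r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  active <- candidates
  dropped <- character(0)
  drop_vif <- numeric(0)
  repeat {
    vifs <- vapply(active, function(f) vif_of(f, setdiff(active, f)),
                   numeric(1))
    if (length(active) <= 1 || all(vifs <= threshold)) break
    worst <- active[vifs == max(vifs)][1]  # active is sorted -> lexicographic
    dropped <- c(dropped, worst)
    drop_vif <- c(drop_vif, vifs[worst])
    active <- setdiff(active, worst)
  }
  final <- vapply(active, function(f) vif_of(f, setdiff(active, f)), numeric(1))
  out <- data.frame(feature = candidates, vif = NA_real_, retained = FALSE,
                    drop_order = NA_integer_, stringsAsFactors = FALSE)
  out$retained <- out$feature %in% active
  out$vif[match(active, out$feature)] <- final
  out$vif[match(dropped, out$feature)] <- drop_vif
  out$drop_order[match(dropped, out$feature)] <- seq_along(dropped)
  out
}

#' Boruta shadow-feature selection
#'
#' Wrapper selection around a random-forest regressor. Each iteration,
#' every candidate feature is copied and row-permuted into a "shadow"
#' feature; a random forest is fitted on real + shadow features; a real
#' feature scores a "hit" when its permutation importance exceeds the
#' maximum shadow importance. After `max_iter` iterations a two-sided
#' binomial test of the hit count against p = 0.5, Bonferroni-corrected
#' across candidates at level `alpha`, classifies features as confirmed
#' (significantly more hits) or rejected (significantly fewer). Undecided
#' features are tentative; with `resolve_tentative = TRUE` they are resolved
#' by comparing each feature's median importance to the median of the
#' per-iteration shadow maxima.
#'
#' @param table feature table.
#' @param target target column name.
#' @param candidates candidate feature columns (default: all vi./tex./cc/
#'   gdd/gpr columns).
#' @param max_iter number of shadow iterations (default 100).
#' @param alpha significance level before Bonferroni correction.
#' @param num_trees trees per random forest (default 200).
#' @param seed integer seed; results are bit-reproducible.
#' @param resolve_tentative resolve undecided features by the median rule.
#' @return `selection_result` list: `method`, `confirmed`, `rejected`,
#'   `tentative`, `scores` (median importance), `hits`, `iterations`,
#'   `shadow_max_median`.
#' @export
boruta_select <- function(table, target = "agb", candidates = NULL,
                          max_iter = 100, alpha = 0.05, num_trees = 200,
                          seed = 1L, resolve_tentative = TRUE) {
  groups <- feature_groups(names(table))
  candidates <- candidates %||% names(table)[!is.na(groups)]
  if (length(candidates) < 2) stop("need at least 2 candidate features")
  keep <- stats::complete.cases(table[, c(candidates, target)])
  if (sum(keep) < 20) stop("need at least 20 complete rows")
  x <- as.matrix(table[keep, candidates, drop = FALSE])
  y <- table[[target]][keep]
  if (stats::var(y) == 0) stop("target has zero variance")
  p <- length(candidates)

  hits <- stats::setNames(integer(p), candidates)
  imp_hist <- matrix(NA_real_, nrow = p, ncol = max_iter,
                     dimnames = list(candidates, NULL))
  shadow_max <- numeric(max_iter)
  if (max_iter > 0) {
    withr::with_seed(seed, {
      for (it in seq_len(max_iter)) {
        shadows <- apply(x, 2, sample)
        colnames(shadows) <- paste0(".shadow.", candidates)
        dat <- data.frame(cbind(x, shadows), check.names = FALSE)
        dat$.y <- y
        fit <- ranger::ranger(
          dependent.variable.name = ".y", data = dat,
          num.trees = num_trees, importance = "permutation",
          num.threads = 1,
          seed = derive_seed(seed, it))
        imp <- fit$variable.importance
        s_max <- max(imp[startsWith(names(imp), ".shadow.")])
        real <- imp[candidates]
        hits <- hits + (real > s_max)
        imp_hist[, it] <- real
        shadow_max[it] <- s_max
      }
    })
  }

  if (max_iter > 0) {
    p_hi <- stats::pbinom(hits - 1, max_iter, 0.5, lower.tail = FALSE)
    p_lo <- stats::pbinom(hits, max_iter, 0.5)
    p_two <- pmin(2 * pmin(p_hi, p_lo), 1)
    cutoff <- alpha / p
    confirmed <- candidates[p_two <= cutoff & hits > max_iter / 2]
    rejected <- candidates[p_two <= cutoff & hits < max_iter / 2]
    tentative <- setdiff(candidates, c(confirmed, rejected))
    med_imp <- apply(imp_hist, 1, stats::median)
    med_shadow <- stats::median(shadow_max)
    if (resolve_tentative && length(tentative) > 0) {
      up <- tentative[med_imp[tentative] > med_shadow]
      confirmed <- c(confirmed, up)
      rejected <- c(rejected, setdiff(tentative, up))
      tentative <- character(0)
    }
  } else {
    confirmed <- character(0)
    rejected <- character(0)
    tentative <- candidates
    med_imp <- stats::setNames(rep(NA_real_, p), candidates)
    med_shadow <- NA_real_
  }
  structure(list(method = "boruta", confirmed = confirmed,
                 rejected = rejected, tentative = tentative,
                 scores = med_imp, hits = hits, iterations = max_iter,
                 shadow_max_median = med_shadow,
                 alpha = alpha, num_trees = num_trees, seed = seed),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result>", x$method, "\n",
      " confirmed:", paste(x$confirmed, collapse = ", "), "\n",
      " rejected: ", length(x$rejected), "features\n",
      " tentative:", length(x$tentative), "features\n")
  invisible(x)
}
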