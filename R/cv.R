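# Mean T value of a rotating inner cross-validation. `sets` is a list of
# feature tables (trial sets); each in turn is the validation set while
# the others are pooled as the optimization set. `fit_fun(x, y)` returns
# a fitted model. Acc_o is the training accuracy on the optimization
# sets; Acc_v, Pre_v, Rec_v come from the held-out validation set. Folds
# whose validation metrics are undefined (single-class validation set)
# are dropped from the average.
inner_cv_t <- function(sets, fit_fun, weights = c(0.2, 0.2, 0.3, 0.3)) {
  ts <- vapply(seq_along(sets), function(v) {
    val <- sets[[v]]
    opt <- do.call(rbind, sets[-v])
    if (length(unique(opt$label)) < 2L) return(NA_real_)
    model <- fit_fun(feature_matrix(opt), opt$label)
    acc_o <- confusion_metrics(opt$label,
                               predict(model, opt)$label)$acc
    mv <- confusion_metrics(val$label, predict(model, val)$label)
    if (is.na(mv$pre) || is.na(mv$rec)) return(NA_real_)
    t_value(mv$acc, acc_o, mv$pre, mv$rec, weights)
  }, 0)
  if (all(is.na(ts))) NA_real_ else mean(ts, na.rm = TRUE)
}

#' Inner-cross-validation selection of the CSVM costs
#'
#' Grid search over `(R, C) = (2^i, 2^j)`: for every combination, each of
#' the training sets serves once as validation set while the other two are
#' pooled for fitting, and the T value ([t_value()]) is averaged over the
#' rotations. Ties on the mean T break toward the smallest `C`, then the
#' smallest `R`.
#'
#' @param train_sets list of feature tables (one per trial set).
#' @param spec a [classifier_spec()].
#' @return A list with chosen `R`, `C`, their exponents, the achieved mean
#'   `T`, and the full `trace` of the grid.
#' @export
inner_select_csvm <- function(train_sets, spec = classifier_spec()) {
  grid <- expand.grid(c_exp = spec$c_exponents, r_exp = spec$r_exponents)
  if (!nrow(grid)) stop("empty hyperparameter grid")
  grid$T <- vapply(seq_len(nrow(grid)), function(i) {
    R <- 2^grid$r_exp[i]; C <- 2^grid$c_exp[i]
    inner_cv_t(train_sets,
               function(x, y) train_csvm(x, y, R = R, C = C,
                                         scale = spec$scale),
               spec$t_weights)
  }, 0)
  if (all(is.na(grid$T))) stop("all inner folds were degenerate")
  ord <- order(-grid$T, grid$c_exp, grid$r_exp, na.last = TRUE)
  best <- grid[ord[1L], ]
  list(R = 2^best$r_exp, C = 2^best$c_exp,
       r_exp = best$r_exp, c_exp = best$c_exp, T = best$T, trace = grid)
}

#' Bayesian-optimization selection of the random-forest size
#'
#' Optimizes the number of trees `N_T` and minimum leaf size `N_L` by a
#' seeded Gaussian-process/expected-improvement search whose objective is
#' the same rotating inner-cross-validation mean T as
#' [inner_select_csvm()].
#'
#' @param train_sets list of feature tables (one per trial set).
#' @param spec a [classifier_spec()].
#' @param seed integer seed controlling both the optimizer and the
#'   forests it evaluates.
#' @return A list with chosen `n_trees`, `min_leaf`, the achieved mean
#'   `T`, and the optimizer `history`.
#' @export
select_rf <- function(train_sets, spec = classifier_spec(), seed = 1L) {
  obj <- function(p) {
    v <- inner_cv_t(train_sets,
                    function(x, y) train_rf(x, y, n_trees = p[1L],
                                            min_leaf = p[2L], seed = seed),
                    spec$t_weights)
    if (is.na(v)) -1 else v
  }
  res <- bayes_opt(obj, lower = c(spec$rf_trees[1L], spec$rf_leaf[1L]),
                   upper = c(spec$rf_trees[2L], spec$rf_leaf[2L]),
                   n_iter = spec$rf_iterations, seed = seed)
  list(n_trees = res$par[1L], min_leaf = res$par[2L], T = res$value,
       history = res$history)
}

#' Fit a pain-state classifier under double cross-validation
#'
#' The core estimator: for one subject's labeled window-feature table, the
#' trials are partitioned into `outer_folds` equal sets. Each set is held
#' out once for testing while the remaining sets are both the refitting
#' data and the material for the inner rotation that tunes the
#' hyperparameters (cost factors `R`, `C` of the cost-sensitive linear
#' SVM, or `N_T`, `N_L` of the random forest) by the mean T value. The
#' tuned model is refitted on all training windows and evaluated on the
#' held-out trials, yielding per-fold and mean accuracy, precision,
#' recall and F1 (pain is the positive class). A final model is refitted
#' on all trials with the best-tuning fold's hyperparameters for use on
#' new data ([predict.painflex()], [predict_stream()]).
#'
#' @param features feature table from [build_feature_table()] (columns
#'   `trial_id`, `label`, and the window features).
#' @param classifier `"csvm"` or `"rf"`.
#' @param spec a [classifier_spec()].
#' @param seed integer seed for fold assignment and the forest/optimizer.
#' @return An object of class `painflex`: `folds` (per-fold test trials,
#'   hyperparameters, metrics and model), `metrics` (per-fold table),
#'   `mean_metrics`, `final_model`, `classifier`, `spec`, `seed`.
#' @seealso [summary.painflex()], [run_experiment2()]
#' @export
painflex <- function(features, classifier = c("csvm", "rf"),
                     spec = classifier_spec(), seed = 1L) {
  classifier <- match.arg(classifier)
  stopifnot(all(c("trial_id", "label") %in% names(features)))
  seeds <- derive_seeds(seed, 2L + spec$outer_folds)
  fold_sets <- make_outer_folds(features$trial_id, seed = seeds[1L],
                                n_folds = spec$outer_folds)
  subset_trials <- function(trials)
    features[features$trial_id %in% trials, , drop = FALSE]
  folds <- lapply(seq_along(fold_sets), function(f) {
    test <- subset_trials(fold_sets[[f]])
    train_sets <- lapply(fold_sets[-f], subset_trials)
    train <- do.call(rbind, train_sets)
    if (classifier == "csvm") {
      sel <- inner_select_csvm(train_sets, spec)
      model <- train_csvm(feature_matrix(train), train$label,
                          R = sel$R, C = sel$C, scale = spec$scale)
      params <- list(R = sel$R, C = sel$C)
    } else {
      sel <- select_rf(train_sets, spec, seed = seeds[2L + f])
      model <- train_rf(feature_matrix(train), train$label,
                        n_trees = sel$n_trees, min_leaf = sel$min_leaf,
                        seed = seeds[2L + f])
      params <- list(n_trees = sel$n_trees, min_leaf = sel$min_leaf)
    }
    m <- confusion_metrics(test$label, predict(model, test)$label)
    list(test_trials = fold_sets[[f]], params = params, tuning_T = sel$T,
         metrics = m, model = model)
  })
  metrics <- do.call(rbind, lapply(folds, function(f)
    as.data.frame(f$metrics)))
  metrics <- cbind(fold = seq_len(nrow(metrics)), metrics)
  mean_metrics <- colMeans(metrics[, c("acc", "pre", "rec", "f1")],
                           na.rm = TRUE)
  # Final model for deployment: hyperparameters of the fold whose inner
  # tuning achieved the highest mean T (first on ties).
  best <- which.max(vapply(folds, function(f) f$tuning_T, 0))
  bp <- folds[[best]]$params
  final <- if (classifier == "csvm")
    train_csvm(feature_matrix(features), features$label,
               R = bp$R, C = bp$C, scale = spec$scale)
  else
    train_rf(feature_matrix(features), features$label,
             n_trees = bp$n_trees, min_leaf = bp$min_leaf,
             seed = seeds[2L])
  structure(list(classifier = classifier, spec = spec, seed = seed,
                 fold_trials = fold_sets, folds = folds, metrics = metrics,
                 mean_metrics = mean_metrics, final_model = final,
                 n_windows = nrow(features),
                 call = match.call()),
            class = "painflex")
}

#' @export
print.painflex <- function(x, ...) {
  cat(sprintf(
    "<painflex> %s pain-state classifier, %d-fold outer CV on %d windows\n",
    toupper(x$classifier), length(x$folds), x$n_windows))
  cat(sprintf("  mean test metrics: Acc %.3f | Pre %.3f | Rec %.3f | F1 %.3f\n",
              x$mean_metrics["acc"], x$mean_metrics["pre"],
              x$mean_metrics["rec"], x$mean_metrics["f1"]))
  invisible(x)
}

#' Per-fold summary of a double-cross-validation fit
#'
#' @param object a [painflex()] fit.
#' @param ... unused.
#' @return Invisibly, the per-fold metrics table with chosen
#'   hyperparameters.
#' @export
summary.painflex <- function(object, ...) {
  tab <- object$metrics
  tab$params <- vapply(object$folds, function(f)
    paste(names(f$params), unlist(f$params), sep = "=", collapse = ", "),
    "")
  print(object)
  cat("\nPer outer fold:\n")
  print(tab, row.names = FALSE, digits = 4)
  invisible(tab)
}

#' @export
coef.painflex <- function(object, ...) {
  if (object$classifier != "csvm")
    stop("coefficients are defined for the linear CSVM only")
  coef(object$final_model)
}

#' Predict pain state for new windows
#'
#' Applies the deployment (final) model of a [painflex()] fit.
#'
#' @param object a [painflex()] fit.
#' @param newdata feature table or matrix of windows.
#' @param ... unused.
#' @return A data frame with `score` and `label` per window.
#' @export
predict.painflex <- function(object, newdata, ...) {
  predict(object$final_model, newdata)
}

#' Greedy sequential forward selection of features
#'
#' Starting from the empty set, repeatedly adds the feature whose addition
#' maximizes the rotating inner-cross-validation mean T (with fixed CSVM
#' costs, since re-tuning inside every candidate evaluation is not
#' affordable and does not change the greedy ranking materially). The
#' full-set baseline on the same trial sets is reported alongside.
#'
#' @param features labeled feature table.
#' @param spec a [classifier_spec()].
#' @param R,C fixed CSVM costs used during selection.
#' @param seed seed for the trial-set assignment.
#' @param max_steps stop after this many selected features.
#' @return A list with `steps` (data frame: feature added, mean T after
#'   adding it) and `baseline_T` (full feature set, same folds).
#' @export
sequential_forward_selection <- function(features, spec = classifier_spec(),
                                         R = 1, C = 1, seed = 1L,
                                         max_steps = NULL) {
  trials <- unique(features$trial_id)
  grp <- with_seed(seed, split(sample(trials),
                               rep_len(seq_len(spec$inner_folds),
                                       length(trials))))
  sets <- lapply(grp, function(tr)
    features[features$trial_id %in% tr, , drop = FALSE])
  all_feats <- colnames(feature_matrix(features))
  if (length(all_feats) < 2L) stop("need >= 2 features")
  obj <- function(cols) {
    inner_cv_t(sets, function(x, y)
      train_csvm(x[, cols, drop = FALSE], y, R = R, C = C,
                 scale = spec$scale),
      spec$t_weights)
  }
  baseline <- obj(all_feats)
  chosen <- character(0)
  steps <- data.frame(feature = character(0), T = numeric(0))
  if (is.null(max_steps)) max_steps <- length(all_feats)
  while (length(chosen) < min(max_steps, length(all_feats))) {
    remaining <- setdiff(all_feats, chosen)
    tt <- vapply(remaining, function(f) obj(c(chosen, f)), 0)
    best <- which.max(tt)
    chosen <- c(chosen, remaining[best])
    steps <- rbind(steps, data.frame(feature = remaining[best],
                                     T = tt[best]))
  }
  list(steps = steps, baseline_T = baseline, selected = chosen)
}
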