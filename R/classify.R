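#' Classifier and double-cross-validation specification
#'
#' Settings for the pain/painless classifiers and their nested tuning.
#' The cost-sensitive SVM grid is given as base-2 exponents for the
#' misclassification cost `C` and the positive-class cost factor `R`
#' (slack of pain-class samples is penalized `R*C`, painless-class slack
#' `C`). The random forest is tuned over the number of trees `N_T` and
#' the minimum leaf size `N_L` by seeded Bayesian optimization of the same
#' inner-cross-validation T value.
#'
#' @param preset `"desk"` (default) uses a coarse exponent grid
#'   `-8, -4, 0, 4, 8` and 10 optimizer iterations, sized for interactive
#'   runs; `"full"` uses every integer exponent in `-20..20` and 30
#'   iterations.
#' @param c_exponents,r_exponents base-2 exponent vectors for `C` and `R`
#'   (override the preset).
#' @param rf_trees,rf_leaf integer ranges `c(min, max)` for `N_T`, `N_L`.
#' @param rf_iterations Bayesian-optimization evaluations (including the
#'   seeded initial design).
#' @param t_weights the four T-value weights (validation accuracy,
#'   optimization accuracy, validation precision, validation recall).
#' @param outer_folds,inner_folds fold counts of the double
#'   cross-validation (trials are partitioned at the trial level).
#' @param scale z-score features with training-fold statistics before the
#'   SVM.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(preset = c("desk", "full"),
                            c_exponents = NULL, r_exponents = NULL,
                            rf_trees = c(10L, 200L), rf_leaf = c(1L, 50L),
                            rf_iterations = NULL,
                            t_weights = c(0.2, 0.2, 0.3, 0.3),
                            outer_folds = 4L, inner_folds = 3L,
                            scale = TRUE) {
  preset <- match.arg(preset)
  if (is.null(c_exponents))
    c_exponents <- if (preset == "desk") seq(-8, 8, by = 4) else -20:20
  if (is.null(r_exponents))
    r_exponents <- if (preset == "desk") seq(-8, 8, by = 4) else -20:20
  if (is.null(rf_iterations))
    rf_iterations <- if (preset == "desk") 10L else 30L
  stopifnot(length(c_exponents) >= 1L, length(r_exponents) >= 1L,
            abs(sum(t_weights) - 1) < 1e-12, outer_folds >= 2L,
            inner_folds >= 2L, rf_iterations >= 1L,
            rf_trees[1] >= 1L, rf_leaf[1] >= 1L)
  structure(list(c_exponents = c_exponents, r_exponents = r_exponents,
                 rf_trees = as.integer(rf_trees),
                 rf_leaf = as.integer(rf_leaf),
                 rf_iterations = as.integer(rf_iterations),
                 t_weights = t_weights,
                 outer_folds = as.integer(outer_folds),
                 inner_folds = as.integer(inner_folds),
                 scale = isTRUE(scale)),
            class = "classifier_spec")
}

#' Partition trials into outer cross-validation folds
#'
#' Seeded random partition of the trial identifiers into `n_folds` equal
#' sets; all windows of a trial stay in its set, so no fold mixes windows
#' of one trial between training and testing.
#'
#' @param trial_ids vector of trial identifiers.
#' @param seed integer seed (NULL leaves the RNG state alone).
#' @param n_folds number of outer folds.
#' @return A list of `n_folds` vectors of trial ids.
#' @export
make_outer_folds <- function(trial_ids, seed = NULL, n_folds = 4L) {
  trial_ids <- unique(trial_ids)
  if (length(trial_ids) %% n_folds != 0L)
    stop(length(trial_ids), " trials cannot be split into ", n_folds,
         " equal sets")
  perm <- with_seed(seed, sample(trial_ids))
  split(perm, rep(seq_len(n_folds), each = length(trial_ids) / n_folds))
}

label_factor <- function(label) factor(label, levels = PF_LABELS)

#' Train a cost-sensitive linear SVM
#'
#' Soft-margin linear SVM in which the slack of pain-class samples
#' (label +1) is penalized `R*C` and painless-class slack `C`, fitted with
#' the LIBSVM solver via \pkg{e1071} using per-class weights. Features are
#' optionally z-scored with statistics of the training data only; the
#' statistics travel with the model.
#'
#' @param x numeric feature matrix (windows x features).
#' @param y labels (`painless`/`pain`).
#' @param R positive-class cost factor.
#' @param C misclassification cost.
#' @param scale z-score features with training statistics.
#' @return An object of class `csvm_model` whose decision score is
#'   positive for predicted pain.
#' @export
train_csvm <- function(x, y, R = 1, C = 1, scale = TRUE) {
  x <- as.matrix(x)
  y <- label_factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contain a single class")
  ctr <- rep(0, ncol(x)); scl <- rep(1, ncol(x))
  if (scale) {
    ctr <- colMeans(x)
    scl <- apply(x, 2L, sd)
    scl[scl == 0 | !is.finite(scl)] <- 1
    x <- sweep(sweep(x, 2L, ctr), 2L, scl, "/")
  }
  fit <- e1071::svm(x, y, kernel = "linear", cost = C,
                    class.weights = c(pain = R, painless = 1),
                    scale = FALSE)
  # e1071 signs decision values toward the first label it encounters;
  # record the flip needed so that positive score always means pain.
  dv <- attr(stats::predict(fit, x[1L, , drop = FALSE],
                            decision.values = TRUE), "decision.values")
  pos_class <- strsplit(colnames(dv), "/")[[1L]][1L]
  structure(list(kind = "csvm", fit = fit, R = R, C = C,
                 center = ctr, scale = scl,
                 flip = if (pos_class == "pain") 1 else -1,
                 features = colnames(x)),
            class = c("csvm_model", "painflex_model"))
}

#' Train a pain/painless random forest
#'
#' Probability forest (via \pkg{ranger}) with `n_trees` trees and minimum
#' leaf size `min_leaf`; the decision score is `P(pain) - 1/2`, positive
#' for predicted pain.
#'
#' @param x numeric feature matrix.
#' @param y labels (`painless`/`pain`).
#' @param n_trees number of trees (`N_T`).
#' @param min_leaf minimum node size (`N_L`).
#' @param seed integer seed for the forest's bootstrap draws.
#' @return An object of class `rf_model`.
#' @export
train_rf <- function(x, y, n_trees = 100L, min_leaf = 1L, seed = 1L) {
  y <- label_factor(y)
  if (nlevels(droplevels(y)) < 2L)
    stop("training data contain a single class")
  d <- as.data.frame(x)
  fit <- ranger::ranger(x = d, y = y, num.trees = as.integer(n_trees),
                        min.node.size = as.integer(min_leaf),
                        probability = TRUE, num.threads = 1L,
                        seed = as.integer(seed))
  structure(list(kind = "rf", fit = fit, n_trees = as.integer(n_trees),
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed),
                 features = colnames(d)),
            class = c("rf_model", "painflex_model"))
}

#' Decision scores and labels of a fitted pain-state model
#'
#' @param object a `csvm_model` or `rf_model`.
#' @param newdata feature matrix or feature table (metadata columns are
#'   dropped automatically).
#' @param ... unused.
#' @return A data frame with `score` (positive means pain) and `label`.
#' @export
predict.painflex_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata) && any(c("label", "trial_id") %in%
                                         names(newdata)))
    feature_matrix(newdata) else as.matrix(newdata)
  if (!all(object$features %in% colnames(x)))
    stop("feature columns do not match the model (",
         ncol(x), " vs ", length(object$features), ")")
  x <- x[, object$features, drop = FALSE]
  if (object$kind == "csvm") {
    x <- sweep(sweep(x, 2L, object$center), 2L, object$scale, "/")
    pr <- stats::predict(object$fit, x, decision.values = TRUE)
    score <- object$flip * as.numeric(attr(pr, "decision.values"))
  } else {
    pr <- stats::predict(object$fit, data = as.data.frame(x),
                         num.threads = 1L)
    score <- pr$predictions[, "pain"] - 0.5
  }
  data.frame(score = score,
             label = ifelse(score > 0, "pain", "painless"))
}

#' Linear SVM weight vector
#'
#' The hyperplane normal (on the z-scored feature scale) and intercept,
#' oriented so that a positive decision value means pain.
#'
#' @param object a `csvm_model`.
#' @param ... unused.
#' @return Named numeric vector of feature weights with attribute
#'   `intercept`.
#' @export
coef.csvm_model <- function(object, ...) {
  w <- object$flip * drop(t(object$fit$coefs) %*% object$fit$SV)
  structure(stats::setNames(w, object$features),
            intercept = -object$flip * object$fit$rho)
}
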