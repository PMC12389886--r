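#' Hyperparameter-selection T value
#'
#' Weighted criterion used by the inner cross-validation:
#' `T = 0.2 Acc_v + 0.2 Acc_o + 0.3 Pre_v + 0.3 Rec_v`, combining the
#' validation-set accuracy, the optimization-set accuracy and the
#' validation-set precision and recall.
#'
#' @param acc_v,acc_o,pre_v,rec_v component metrics in `[0, 1]`; `NA`
#'   components (degenerate folds) make the result `NA`.
#' @param weights the four weights (must sum to 1).
#' @return The scalar T value.
#' @export
t_value <- function(acc_v, acc_o, pre_v, rec_v,
                    weights = c(0.2, 0.2, 0.3, 0.3)) {
  v <- c(acc_v, acc_o, pre_v, rec_v)
  stopifnot(length(v) == 4L, abs(sum(weights) - 1) < 1e-12)
  if (any(v < 0 | v > 1, na.rm = TRUE))
    stop("metric components must lie in [0, 1]")
  sum(weights * v)
}

#' Binary confusion counts and classification metrics
#'
#' `pain` is the positive class. Precision is undefined when nothing is
#' predicted positive and recall when nothing is positive; undefined
#' metrics are returned as `NA` and should be excluded from averages.
#'
#' @param truth,pred equal-length vectors over `painless`/`pain`.
#' @return Named list: `TP`, `TN`, `FP`, `FN`, `acc`, `pre`, `rec`, `f1`.
#' @export
confusion_metrics <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  bad <- setdiff(unique(c(truth, pred)), PF_LABELS)
  if (length(bad)) stop("labels outside {painless, pain}: ",
                        paste(bad, collapse = ", "))
  tp <- sum(truth == "pain" & pred == "pain")
  tn <- sum(truth == "painless" & pred == "painless")
  fp <- sum(truth == "painless" & pred == "pain")
  fn <- sum(truth == "pain" & pred == "painless")
  pre <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(pre) && !is.na(rec) && pre + rec > 0)
    2 * pre * rec / (pre + rec) else NA_real_
  list(TP = tp, TN = tn, FP = fp, FN = fn,
       acc = (tp + tn) / length(truth), pre = pre, rec = rec, f1 = f1)
}

#' Cohort aggregation of per-subject metrics
#'
#' Mean and sample (n-1) standard deviation of each metric across
#' subjects, the "Mean +/- std" row of a cohort performance table.
#'
#' @param x a data frame or matrix of per-subject metric values (one row
#'   per subject), or a list of [painflex()] fits whose per-subject mean
#'   metrics are aggregated.
#' @return A data frame with rows `mean` and `sd`.
#' @export
aggregate_subjects <- function(x) {
  if (is.list(x) && !is.data.frame(x) && inherits(x[[1L]], "painflex"))
    x <- do.call(rbind, lapply(x, function(f) f$mean_metrics))
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need >= 2 subjects to aggregate")
  out <- rbind(mean = colMeans(x), sd = apply(x, 2L, sd))
  as.data.frame(out)
}

#' Paired t-test across subjects
#'
#' Two-sided paired Student t-test on per-subject value pairs, with the
#' significance-star convention `* p < 0.05`, `** p < 0.01`,
#' `*** p < 0.001`.
#'
#' @param a,b equal-length per-subject values, paired by position.
#' @param name optional label for the compared quantity.
#' @return An object of class `paired_comparison`: `name`, `t`, `df`,
#'   `p`, `stars`, `mean_diff`, `degenerate` (all differences zero).
#' @export
paired_t <- function(a, b, name = NULL) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  d <- a - b
  degenerate <- sd(d) == 0
  if (degenerate && all(d == 0)) {
    t <- 0; p <- 1
  } else if (degenerate) {
    t <- sign(mean(d)) * Inf; p <- 0
  } else {
    ht <- t.test(a, b, paired = TRUE)
    t <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(name = name, t = t, df = length(a) - 1L, p = p,
                 stars = p_stars(p), mean_diff = mean(d),
                 degenerate = degenerate),
            class = "paired_comparison")
}

p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("Paired t-test%s: t(%d) = %.4f, p = %.4f %s%s\n",
              if (is.null(x$name)) "" else paste0(" [", x$name, "]"),
              x$df, x$t, x$p, x$stars,
              if (x$degenerate) " (degenerate: zero-variance differences)"
              else ""))
  invisible(x)
}
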