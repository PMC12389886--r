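#' Per-subject feature normalization
#'
#' Normalizes every feature column within each subject so that per-state
#' means are comparable across subjects: z-score by default (per-subject
#' mean 0, sd 1), or min-max to `[0, 1]`. Zero-variance (or zero-range)
#' features are flagged and left unscaled.
#'
#' @param features feature table with a `subject` column (added by
#'   [synth_cohort()] pipelines, or supply your own).
#' @param method `"zscore"` or `"minmax"`.
#' @return The feature table with normalized feature columns; attribute
#'   `unscaled` lists `(subject, feature)` pairs left untouched.
#' @export
normalize_per_subject <- function(features, method = c("zscore",
                                                       "minmax")) {
  method <- match.arg(method)
  stopifnot("subject" %in% names(features))
  cols <- colnames(feature_matrix(features))
  unscaled <- list()
  for (s in unique(features$subject)) {
    rows <- features$subject == s
    if (sum(rows) < 2L) stop("subject ", s, " has fewer than 2 windows")
    for (cn in cols) {
      v <- features[rows, cn]
      if (method == "zscore") {
        sdv <- sd(v)
        if (is.na(sdv) || sdv == 0) {
          unscaled[[length(unscaled) + 1L]] <- c(s, cn); next
        }
        features[rows, cn] <- (v - mean(v)) / sdv
      } else {
        rg <- range(v)
        if (diff(rg) == 0) {
          unscaled[[length(unscaled) + 1L]] <- c(s, cn); next
        }
        features[rows, cn] <- (v - rg[1L]) / diff(rg)
      }
    }
  }
  attr(features, "unscaled") <- unscaled
  features
}

#' Per-subject painless/pain state means
#'
#' Averages each (normalized) feature over the painless and over the pain
#' windows of every subject. Subjects missing one of the states are
#' excluded with a warning.
#'
#' @param features (normalized) feature table with `subject` and `label`
#'   columns.
#' @return A data frame with `subject`, `label` and one column per
#'   feature; two rows per retained subject.
#' @export
state_means <- function(features) {
  stopifnot(all(c("subject", "label") %in% names(features)))
  keep <- vapply(split(features$label, features$subject),
                 function(l) all(PF_LABELS %in% l), TRUE)
  drop <- names(keep)[!keep]
  if (length(drop)) {
    warning("excluding subject(s) missing a state: ",
            paste(drop, collapse = ", "))
    features <- features[!features$subject %in% drop, , drop = FALSE]
  }
  cols <- colnames(feature_matrix(features))
  out <- aggregate(features[, cols, drop = FALSE],
                   by = list(subject = features$subject,
                             label = features$label), FUN = mean)
  out[order(out$subject, out$label), , drop = FALSE]
}

#' Paired feature tests between pain states across subjects
#'
#' For each feature, a two-sided paired t-test of the per-subject pain
#' mean against the painless mean ([paired_t()]), with the usual
#' significance stars and, additionally, a Holm-adjusted p-value column
#' for users who want family-wise control.
#'
#' @param means output of [state_means()].
#' @return A data frame: `feature`, `t`, `df`, `p`, `stars`, `p_holm`.
#' @export
feature_state_tests <- function(means) {
  cols <- setdiff(names(means), c("subject", "label"))
  pain <- means[means$label == "pain", ]
  painless <- means[means$label == "painless", ]
  stopifnot(identical(pain$subject, painless$subject))
  res <- do.call(rbind, lapply(cols, function(cn) {
    ct <- paired_t(pain[[cn]], painless[[cn]], name = cn)
    data.frame(feature = cn, t = ct$t, df = ct$df, p = ct$p,
               stars = ct$stars)
  }))
  res$p_holm <- p.adjust(res$p, method = "holm")
  rownames(res) <- NULL
  res
}
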