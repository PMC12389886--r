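# Independent brute-force oracles, coded directly from the defining
# formulas and kept free of any package internals.

# Sample entropy: literal O(N^2) evaluation. B^m averages, over the
# N-m+1 templates, the fraction of the other templates within Chebyshev
# distance r; likewise at m+1; SampEn = -ln(B^{m+1}/B^m).
oracle_sampen <- function(x, m, r) {
  bm <- function(mm) {
    nt <- length(x) - mm + 1L
    tpl <- sapply(seq_len(nt), function(i) x[i:(i + mm - 1L)])
    tpl <- matrix(tpl, nrow = mm)
    bi <- sapply(seq_len(nt), function(i) {
      d <- apply(abs(tpl - tpl[, i]), 2L, max)
      sum(d[-i] <= r) / (nt - 1L)
    })
    mean(bi)
  }
  -log(bm(m + 1L) / bm(m))
}

# Direct evaluation of the time-domain feature formulas.
oracle_td <- function(x) {
  n <- length(x)
  xb <- sum(x) / n
  c(RMS = sqrt(sum(x^2) / n),
    MAV = sum(abs(x)) / n,
    VAR = sum((x - xb)^2) / (n - 1),
    WL = sum(abs(x[-1] - x[-n])))
}

# Literal majority filter over raw labels.
oracle_majority <- function(labels, width, mode = "causal") {
  n <- length(labels)
  half <- (width - 1L) %/% 2L
  sapply(seq_len(n), function(i) {
    idx <- if (mode == "causal") max(1L, i - width + 1L):i
    else max(1L, i - half):min(n, i + half)
    votes <- labels[idx]
    if (sum(votes == "pain") > length(votes) / 2) "pain" else "painless"
  })
}

# Textbook paired t statistic.
oracle_paired_t <- function(a, b) {
  d <- a - b
  n <- length(d)
  mean(d) / (sd(d) / sqrt(n))
}

# Small, quickly generated synthetic fixtures -------------------------

# Short full-rate trial (2 s flexion + 1 s hold at 2000 Hz).
short_cfg <- function(...) {
  synth_config(flexion_s = 2, hold_s = 1, ...)
}

# Scaled-down cohort config for cheap multi-cohort simulations.
tiny_cfg <- function(n_trials = 4L, ...) {
  synth_config(fs = 400, flexion_s = 2, hold_s = 1,
               n_trials = n_trials, mains_mV = 0, ...)
}

# Two-class Gaussian toy feature table grouped into trials, linearly
# separable unless `sep` is small.
toy_features <- function(n_trials = 8L, per_trial = 12L, sep = 3,
                         seed = 1L, p = 4L) {
  withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_trials), function(tr) {
      lab <- rep(c("painless", "pain"), length.out = per_trial)
      mu <- ifelse(lab == "pain", sep / 2, -sep / 2)
      f <- sapply(seq_len(p), function(j)
        rnorm(per_trial, mean = if (j == 1L) mu else 0))
      colnames(f) <- paste0("F", seq_len(p))
      cbind(data.frame(trial_id = tr,
                       onset_s = seq_len(per_trial) * 0.125,
                       end_s = seq_len(per_trial) * 0.125 + 0.25,
                       label = lab), f)
    }))
  })
}
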