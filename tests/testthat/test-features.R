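test_that("window enumeration follows the window/step arithmetic", {
  mk_trial <- function(dur_s, fs = 2000) {
    n <- round(dur_s * fs)
    s <- matrix(rnorm(n * 4, sd = 0.05), ncol = 4,
                dimnames = list(NULL, c("MRF", "MVM", "MBF-CL", "MS")))
    trial_segment(s, fs, t_start = 0, t_pain = dur_s * 0.9,
                  t_end = dur_s)
  }
  w <- slide_windows(mk_trial(1.0))
  expect_identical(nrow(w), 7L)
  expect_equal(w$onset, seq(0, 1500, by = 250) + 1)
  expect_identical(nrow(slide_windows(mk_trial(0.25))), 1L)
  expect_error(slide_windows(mk_trial(0.2)), "shorter than one window")
})

test_that("phase labeling matches the hold-phase window count", {
  cfg2 <- synth_config(flexion_s = 10, hold_s = 3)
  tr <- synth_trial(cfg2, 1)
  w <- slide_windows(tr)
  expect_identical(nrow(w), 103L)
  expect_identical(sum(w$label == "pain"), 23L)
  # the end-time straddle rule flags straddling windows as pain too
  w2 <- slide_windows(tr, feature_config(label_rule = "end"))
  expect_gt(sum(w2$label == "pain"), 23L)
  # a trial observed only during flexion yields only painless windows
  tr$t_pain <- tr$t_end - 1e-9
  expect_true(all(slide_windows(tr)$label == "painless"))
})

test_that("time-domain features match their defining formulas", {
  expect_equal(time_domain_features(rep(2.5, 10)),
               c(RMS = 2.5, MAV = 2.5, VAR = 0, WL = 0))
  expect_equal(time_domain_features(c(1, -1, 1, -1)),
               c(RMS = 1, MAV = 1, VAR = 4 / 3, WL = 6))
  x <- withr::with_seed(5, rnorm(500))
  expect_equal(time_domain_features(x), oracle_td(x), tolerance = 1e-12)
})

test_that("ZC and SSC count guarded crossings and extrema", {
  expect_equal(threshold_counts(rep(0, 100)), c(ZC = 0L, SSC = 0L))
  N <- 50
  alt <- rep(c(1, -1), length.out = N)
  expect_equal(threshold_counts(alt), c(ZC = N - 1L, SSC = N - 2L))
  # 100 Hz sine over a 250 ms window: direct count as oracle
  t <- (0:499) / 2000
  s <- sin(2 * pi * 100 * t)
  direct <- sum(s[-500] * s[-1] < 0)
  expect_equal(unname(threshold_counts(s)["ZC"]), direct)
  expect_true(abs(direct - 50) <= 1)
  # guard suppresses sub-threshold noise crossings
  expect_equal(unname(threshold_counts(alt * 0.001)["ZC"]), 0L)
})

test_that("spectral features sit where the power is", {
  fs <- 2000; N <- 500
  t <- (0:(N - 1)) / fs
  s100 <- sin(2 * pi * 100 * t)
  sp <- spectral_features(s100, fs)
  expect_lt(abs(sp["MNF"] - 100), 4)
  expect_lt(abs(sp["MDF"] - 100), 4)
  two <- sin(2 * pi * 60 * t) + sin(2 * pi * 180 * t)
  expect_lt(abs(spectral_features(two, fs)["MNF"] - 120), 4)
  # exact bin -> all power at one frequency -> MDF equals it
  f0 <- 25 * fs / N  # an exact DFT bin (100 Hz)
  exact <- cos(2 * pi * f0 * t)
  expect_equal(unname(spectral_features(exact, fs)["MDF"]), f0)
  expect_true(all(is.na(spectral_features(rep(0, N), fs))))
})

test_that("wavelet packets conserve energy and localize frequency", {
  expect_equal(unname(wpt_features(rep(0, 500))), rep(0, 24))
  for (seed in 1:5) {
    x <- withr::with_seed(seed, rnorm(500, sd = 0.1))
    nodes <- wpt_decompose(x, 3)
    expect_length(nodes, 8L)
    expect_equal(sum(vapply(nodes, function(v) sum(v^2), 0)),
                 sum(x^2), tolerance = 1e-9)
  }
  # white noise spreads energy roughly evenly across the 8 bands
  ratios <- vapply(1:100, function(seed) {
    x <- withr::with_seed(1000 + seed, rnorm(500))
    e <- vapply(wpt_decompose(x, 3), function(v) sum(v^2), 0)
    max(e) / min(e)
  }, 0)
  expect_lt(mean(ratios), 3)
  # a pure tone lands in its frequency-ordered band (bands of 125 Hz)
  t <- (0:499) / 2000
  for (f0 in c(60, 300, 700, 940)) {
    e <- vapply(wpt_decompose(sin(2 * pi * f0 * t), 3),
                function(v) sum(v^2), 0)
    expect_equal(which.max(e), floor(f0 / 125) + 1)
  }
})

test_that("sample entropy equals the brute-force definition", {
  for (seed in 1:8) {
    n <- withr::with_seed(seed, sample(30:200, 1))
    x <- withr::with_seed(seed + 100, rnorm(n))
    r <- 0.2 * sd(x)
    o <- oracle_sampen(x, 2, r)
    if (is.finite(o)) {
      expect_equal(as.numeric(sample_entropy(x, 2, 0.2)), o,
                   tolerance = 1e-12)
    } else {
      expect_true(isTRUE(attr(sample_entropy(x, 2, 0.2), "capped")))
    }
  }
  # every pair within tolerance -> perfectly regular -> zero entropy
  x <- withr::with_seed(3, rnorm(60))
  expect_equal(as.numeric(sample_entropy(x, 2, r_coeff = 10)), 0)
  # constant window: r = 0, degenerate, capped and flagged
  se <- sample_entropy(rep(1, 60), 2, 0.2)
  expect_true(attr(se, "capped"))
  N <- 60; m <- 2
  expect_equal(as.numeric(se), -log(2 / ((N - m - 1) * (N - m))))
  # matches at m but none at m+1: capped and flagged
  x <- c(0, 0, 0, 10, 20, 30)
  expect_false(is.finite(oracle_sampen(x, 2, 0.2 * sd(x))))
  se2 <- sample_entropy(x, 2, 0.2)
  expect_true(isTRUE(attr(se2, "capped")))
})

test_that("feature vectors scale as amplitudes, not as labels", {
  x <- withr::with_seed(11, rnorm(500, sd = 0.2))
  k <- 3.7
  # eps = 0: the amplitude guard itself is not scale-free, so exact
  # ZC/SSC invariance holds for amplitudes far above the guard
  cfg0 <- feature_config(eps_mV = 0)
  f1 <- painflex:::channel_features(x, 2000, cfg0)
  f2 <- painflex:::channel_features(k * x, 2000, cfg0)
  lin <- c("RMS", "MAV", "WL", paste0("WPTRMS_", 1:8))
  quad <- c("VAR", paste0("WPTVAR_", 1:8), paste0("WPTEnergy_", 1:8))
  inv <- c("ZC", "SSC", "MNF", "MDF", "SampEn")
  expect_equal(f2[lin], k * f1[lin], tolerance = 1e-9)
  expect_equal(f2[quad], k^2 * f1[quad], tolerance = 1e-9)
  expect_equal(f2[inv], f1[inv], tolerance = 1e-9)
  expect_lte(f1["MAV"], f1["RMS"])
  # MAV <= RMS on arbitrary windows
  for (seed in 1:20) {
    y <- withr::with_seed(seed, rnorm(100) * runif(1, 0.01, 10))
    td <- time_domain_features(y)
    expect_lte(td["MAV"], td["RMS"])
  }
})

test_that("the feature table has the contracted shape and labels", {
  tr <- synth_trial(short_cfg(), 2)
  ft <- build_feature_table(tr)
  expect_identical(ncol(ft), 4L + 132L)
  expect_identical(nrow(ft), nrow(slide_windows(tr)))
  expect_identical(colnames(ft)[5], "MRF_RMS")
  expect_true("MVM_WPTEnergy_3" %in% colnames(ft))
  expect_true("MBF.CL_SampEn" %in% colnames(ft))
  expect_identical(sum(ft$label == "pain"),
                   sum(slide_windows(tr)$label == "pain"))
})

test_that("pain modulation moves amplitude up and frequency down", {
  cfg <- synth_config()
  hold_up <- flex_dn <- 0L
  for (seed in 1:3) {
    ft <- build_feature_table(bandpass_notch(synth_trial(cfg, seed)))
    early <- ft$onset_s < 2.5           # first flexion quartile
    hold <- ft$label == "pain"
    for (ch in c("MRF", "MVM")) {
      up <- all(colMeans(ft[hold, paste0(ch, c("_RMS", "_MAV", "_VAR",
                                               "_WL"))]) >
                  colMeans(ft[early, paste0(ch, c("_RMS", "_MAV",
                                                  "_VAR", "_WL"))]))
      dn <- all(colMeans(ft[hold, paste0(ch, c("_MNF", "_MDF"))]) <
                  colMeans(ft[early, paste0(ch, c("_MNF", "_MDF"))]))
      hold_up <- hold_up + up
      flex_dn <- flex_dn + dn
    }
  }
  expect_identical(hold_up, 6L)
  expect_identical(flex_dn, 6L)
})
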