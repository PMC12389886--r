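# A deterministic 1-D model: an SVM trained on F1 = -1 (painless) vs
# F1 = +1 (pain), whose boundary sits at 0 by symmetry, so the sign of
# F1 dictates the label.
threshold_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      x <- matrix(c(rep(-1, 20) + seq(-0.1, 0.1, length.out = 20),
                    rep(1, 20) + seq(-0.1, 0.1, length.out = 20)),
                  dimnames = list(NULL, "F1"))
      y <- rep(c("painless", "pain"), each = 20)
      cache <<- train_csvm(x, y, R = 1, C = 10, scale = FALSE)
    }
    cache
  }
})

ramp_stream <- function(values, step = 0.125) {
  ft <- data.frame(trial_id = 1L,
                   onset_s = seq_along(values) * step - step,
                   end_s = seq_along(values) * step - step + 0.25,
                   label = "painless", F1 = as.numeric(values))
  predict_stream(threshold_model(), ft)
}
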