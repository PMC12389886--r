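# Seeded Bayesian optimization (Gaussian process + expected improvement)
# over an integer box. Small and self-contained: squared-exponential
# kernel on inputs rescaled to the unit square, observation jitter for
# the mildly noisy cross-validated objective, EI maximized over a random
# candidate pool. All randomness is drawn up front from `seed` so the
# objective may use the RNG freely.
bayes_opt <- function(objective, lower, upper, n_iter, seed,
                      n_init = NULL, pool_size = 256L,
                      lengthscale = 0.3, noise = 1e-4) {
  d <- length(lower)
  if (is.null(n_init)) n_init <- min(5L, n_iter)
  n_ei <- max(0L, n_iter - n_init)
  draws <- with_seed(seed, {
    init <- unique(t(vapply(seq_len(4L * n_init), function(i)
      vapply(seq_len(d), function(j)
        sample(lower[j]:upper[j], 1L), 0L), integer(d))))[seq_len(n_init), ,
                                                          drop = FALSE]
    pools <- lapply(seq_len(n_ei), function(i)
      t(vapply(seq_len(pool_size), function(k)
        vapply(seq_len(d), function(j)
          sample(lower[j]:upper[j], 1L), 0L), integer(d))))
    list(init = init, pools = pools)
  })
  scale01 <- function(x)
    sweep(sweep(x, 2L, lower), 2L, pmax(upper - lower, 1L), "/")
  kmat <- function(a, b) {
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
    exp(-0.5 * pmax(d2, 0) / lengthscale^2)
  }
  X <- draws$init
  y <- apply(X, 1L, function(p) objective(p))
  for (it in seq_len(n_ei)) {
    cand <- draws$pools[[it]]
    seen <- apply(X, 1L, paste, collapse = ",")
    cand <- cand[!apply(cand, 1L, paste, collapse = ",") %in% seen, ,
                 drop = FALSE]
    if (!nrow(cand)) break
    Xs <- scale01(X); Cs <- scale01(cand)
    ys <- (y - mean(y)) / max(sd(y), 1e-9)
    K <- kmat(Xs, Xs) + diag(noise + 1e-8, nrow(Xs))
    Kc <- kmat(Cs, Xs)
    a <- solve(K, ys)
    mu <- drop(Kc %*% a)
    v <- pmax(1 - rowSums((Kc %*% solve(K)) * Kc), 1e-12)
    s <- sqrt(v)
    imp <- mu - max(ys)
    z <- imp / s
    ei <- imp * pnorm(z) + s * dnorm(z)
    pick <- cand[which.max(ei), ]
    X <- rbind(X, pick)
    y <- c(y, objective(pick))
  }
  best <- which.max(y)
  list(par = X[best, ], value = y[best],
       history = cbind(as.data.frame(X), objective = y))
}
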