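# Daubechies-4 (8-tap) analysis filters, orthonormal. `g` is the usual
# quadrature-mirror highpass g[n] = (-1)^n h[N-1-n].
DB4_LO <- c(-0.010597401785069032, 0.0328830116668852,
            0.030841381835560764, -0.18703481171909309,
            -0.027983769416859854, 0.6308807679298589,
            0.7148465705529157, 0.2303778133088965)
DB4_HI <- rev(DB4_LO) * rep_len(c(1, -1), length(DB4_LO))

# One periodized analysis step: y[k] = sum_n f[n] x[(2k + n) mod L],
# k = 0..L/2-1. With the circulant even-shift structure and the
# orthonormal db4 pair this is an exactly energy-preserving L x L
# orthogonal transform (lowpass stacked on highpass).
per_step_idx <- local({
  cache <- new.env(parent = emptyenv())
  function(L, nf) {
    key <- paste0(L, "_", nf)
    idx <- cache[[key]]
    if (is.null(idx)) {
      idx <- outer(seq_len(nf) - 1L, 2L * (0:(L %/% 2L - 1L)),
                   "+") %% L + 1L
      cache[[key]] <- idx
    }
    idx
  }
})

per_step <- function(x, f) {
  idx <- per_step_idx(length(x), length(f))
  as.numeric(crossprod(matrix(x[idx], nrow = length(f)), f))
}

#' Wavelet packet decomposition (periodized db4)
#'
#' Full binary-tree decomposition of a window into `2^level` terminal
#' sub-bands using the Daubechies-4 wavelet with periodized boundaries.
#' The window is zero-padded to the next multiple of `2^level` so that the
#' transform is exactly orthogonal and the summed coefficient energy
#' equals the window energy (Parseval). Terminal nodes are returned in
#' frequency-ascending order: after the highpass branch the sub-band
#' spectrum is mirrored by downsampling, so the children of mirrored
#' nodes are swapped.
#'
#' @param x numeric window samples.
#' @param level decomposition depth (3 gives 8 sub-bands).
#' @return A list of `2^level` coefficient vectors, lowest frequency band
#'   first.
#' @export
wpt_decompose <- function(x, level = 3) {
  if (level < 1L) stop("`level` must be >= 1")
  block <- 2L^level
  if (length(x) < length(DB4_LO))
    stop("window too short for the db4 filter (need >= ", length(DB4_LO),
         " samples)")
  pad <- (block - length(x) %% block) %% block
  if (pad) x <- c(x, numeric(pad))
  rec <- function(v, lev, mirrored) {
    if (lev == 0L) return(list(v))
    a <- per_step(v, DB4_LO)
    d <- per_step(v, DB4_HI)
    lo <- rec(a, lev - 1L, mirrored)
    hi <- rec(d, lev - 1L, !mirrored)
    if (mirrored) c(hi, lo) else c(lo, hi)
  }
  rec(x, as.integer(level), FALSE)
}
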