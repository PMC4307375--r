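# Convergence diagnostics for stacked-chain draw vectors.

# Split-chain potential scale reduction factor. Each chain is split in half,
# giving 2 * n_chains sequences; Rhat = sqrt(((m-1)/m * W + B/m) / W) with W
# the mean within-sequence variance and B/m the between-sequence variance of
# sequence means. Returns NA for degenerate (constant) draws.
split_rhat <- function(draws, n_chains) {
  m <- length(draws) %/% n_chains
  if (m < 4L) return(NA_real_)
  half <- m %/% 2L
  seqs <- lapply(seq_len(n_chains), function(ch) {
    x <- draws[((ch - 1L) * m + 1L):(ch * m)]
    list(x[seq_len(half)], x[(half + 1L):(2L * half)])
  })
  seqs <- unlist(seqs, recursive = FALSE)
  w <- mean(vapply(seqs, stats::var, numeric(1)))
  if (!is.finite(w) || w == 0) return(NA_real_)
  b <- half * stats::var(vapply(seqs, mean, numeric(1)))
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective sample size from the autocorrelation function, summed until the
# first non-positive estimate (initial positive sequence), per chain then
# pooled.
effective_size <- function(draws, n_chains) {
  m <- length(draws) %/% n_chains
  if (m < 4L) return(NA_real_)
  ess_one <- function(x) {
    if (stats::var(x) == 0) return(NA_real_)
    rho <- stats::acf(x, lag.max = min(m - 1L, 200L), plot = FALSE,
                      demean = TRUE)$acf[-1L]
    pos <- which(rho <= 0)
    if (length(pos) > 0L) rho <- rho[seq_len(pos[1L] - 1L)]
    m / (1 + 2 * sum(rho))
  }
  sum(vapply(seq_len(n_chains), function(ch)
    ess_one(draws[((ch - 1L) * m + 1L):(ch * m)]), numeric(1)))
}
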