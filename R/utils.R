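`%||%` <- function(a, b) if (is.null(a)) b else a

## Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Otsu threshold on a numeric vector (maximizes between-class variance).
## EBImage::otsu() only accepts whole Image objects, but adhesion counting
## needs a threshold over the pixels of one cell at a time.
otsu_threshold <- function(x, levels = 256L) {
  x <- x[is.finite(x)]
  if (!length(x) || diff(range(x)) == 0) return(NA_real_)
  br <- seq(min(x), max(x), length.out = levels + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins = levels)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w1 <- cumsum(p)
  mu1 <- cumsum(p * mids)
  mu_t <- mu1[levels]
  sb2 <- (mu_t * w1 - mu1)^2 / (w1 * (1 - w1))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

## Draw from a normal truncated to [lo, hi] by inverse-CDF (vectorized).
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd <= 0) return(rep(min(max(mean, lo), hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 1e-12) return(rep(min(max(mean, lo), hi), n))
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}
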