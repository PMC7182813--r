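## Seed hygiene: generators are pure functions of (spec, seed); the caller's
## RNG stream is restored afterwards.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  code
}

## One truncated-normal draw by inverse-CDF transform: deterministic draw
## count (no rejection), degenerate sd = 0 returns the mean.
rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(upper, max(lower, mean)))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(1, lo, hi), mean, sd)
}

rtruncnorm_n <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(min(upper, max(lower, mean)), n))
  lo <- stats::pnorm(lower, mean, sd)
  hi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, lo, hi), mean, sd)
}
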