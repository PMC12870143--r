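#' @keywords internal
"_PACKAGE"

## Run `expr` under a local RNG state seeded with `seed`, restoring the
## caller's RNG afterwards.  seed = NULL uses (and advances) the global RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

## Derive a stream of child seeds from one master seed, so that independent
## stages (covariates, forces, outcomes, ...) do not share RNG streams.
## Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

## Truncated-normal sampling by inverse CDF; exact and vectorised.
## Degenerate sd = 0 returns the (clamped) mean.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  zero <- sd <= 0
  out[zero] <- pmin(pmax(mean[zero], lower), upper)
  if (any(!zero)) {
    m <- mean[!zero]; s <- sd[!zero]
    plo <- pnorm(lower, m, s)
    phi <- pnorm(upper, m, s)
    u <- runif(sum(!zero), plo, phi)
    out[!zero] <- qnorm(u, m, s)
  }
  out
}

## Mean of a normal(mean, sd) truncated to [lower, upper] (closed form).
trunc_norm_mean <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd <= 0) return(min(max(mean, lower), upper))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  mean - sd * (dnorm(b) - dnorm(a)) / z
}

## Gamma draws parameterised by mean and sd (always-positive durations).
## sd = 0 degenerates to the mean.
rgamma_ms <- function(n, mean, sd) {
  mean <- rep_len(mean, n)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  zero <- sd <= 0
  out[zero] <- mean[zero]
  if (any(!zero)) {
    m <- mean[!zero]; s <- sd[!zero]
    shape <- (m / s)^2
    out[!zero] <- rgamma(sum(!zero), shape = shape, rate = shape / m)
  }
  out
}

stop_if_not_records <- function(records, cols) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop("`records` must be a non-empty data frame", call. = FALSE)
  }
  missing <- setdiff(cols, names(records))
  if (length(missing)) {
    stop("`records` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  invisible(records)
}
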