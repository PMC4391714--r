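# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run code under a temporary RNG state; restores .Random.seed on exit so
# simulation calls do not disturb the caller's stream.
local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Vectorised Pearson chi-squared statistic for 2x2 tables [[a, b], [c, d]],
# one degree of freedom, optional Yates continuity correction. Returns NA
# where a margin is zero (test undefined).
pearson_chisq_2x2 <- function(a, b, c, d, correct = FALSE) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  denom <- as.numeric(r1) * r2 * c1 * c2
  num <- abs(as.numeric(a) * d - as.numeric(b) * c)
  if (correct) num <- pmax(0, num - n / 2)
  stat <- n * num^2 / denom
  stat[denom == 0] <- NA_real_
  stat
}

pearson_chisq_p <- function(a, b, c, d, correct = FALSE) {
  stat <- pearson_chisq_2x2(a, b, c, d, correct = correct)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

is_icd3 <- function(code) grepl("^[A-Z][0-9]{2}$", code)

# ATC codes at any of the standard hierarchy levels (1, 3, 4, 5 or 7 chars)
is_atc <- function(code) {
  grepl("^[A-Z]([0-9]{2}([A-Z]([A-Z]([0-9]{2})?)?)?)?$", code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
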