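# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Weighted mean with positive-weight checking left to callers.
wtd_mean <- function(x, w) sum(w * x) / sum(w)

# Weighted population variance (divisor sum(w)).
wtd_var <- function(x, w) {
  m <- wtd_mean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

# Weighted skewness m3 / m2^(3/2); NaN when the data are constant.
wtd_skewness <- function(x, w) {
  m <- wtd_mean(x, w)
  m2 <- sum(w * (x - m)^2) / sum(w)
  m3 <- sum(w * (x - m)^3) / sum(w)
  m3 / m2^1.5
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg),
       call. = FALSE)
}
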