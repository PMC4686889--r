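# internal helpers shared across modules

# log(sum(exp(x))) without overflow; -Inf-safe
logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise sd of a numeric matrix (n >= 2 columns)
row_sds <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  sqrt(rowSums((x - mu)^2) / (n - 1))
}

# seed the RNG when asked; NULL leaves the current stream untouched
use_seed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number.")
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  invisible(NULL)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_bad <- if (strict_lower) x <= lower else x < lower
  hi_bad <- if (strict_upper) x >= upper else x > upper
  if (lo_bad || hi_bad) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}
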