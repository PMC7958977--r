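#' @keywords internal
"_PACKAGE"

# internal validators -------------------------------------------------------

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single probability in [0, 1], got %s",
          name, deparse(substitute(x)))
  invisible(x)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper)
    stopf("`%s` must be a single number in [%s, %s]", name, lower, upper)
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Derive a stream of child seeds from one integer seed, kept inside the
# 32-bit integer range R requires.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12347L) %% 2147483647)
}
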