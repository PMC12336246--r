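# internal helpers shared across modules

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                              strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("`%s` must be a single finite number", name)
  if (strict_lower && x <= lower)
    stopf("`%s` must be > %g (got %g)", name, lower, x)
  if (!strict_lower && x < lower)
    stopf("`%s` must be >= %g (got %g)", name, lower, x)
  if (x > upper)
    stopf("`%s` must be <= %g (got %g)", name, upper, x)
  invisible(x)
}

# lengths are mm at every module boundary; dynamics work in SI internally
MM_PER_M <- 1000

mm_to_m <- function(x) x / MM_PER_M
m_to_mm <- function(x) x * MM_PER_M

# wrap angles into [0, 2*pi)
wrap_angle <- function(theta) theta %% (2 * pi)
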