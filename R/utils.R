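# internal helpers shared across modules

# round-half-up: round(2.5) in base R is banker's rounding, which would make
# causal counts depend on parity; half-up is the convention used throughout.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ldrisk <- function(..., call. = FALSE) stop(..., call. = call.)

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop_ldrisk(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          strict_lower = FALSE, strict_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x)
  if (ok) {
    ok <- if (strict_lower) x > lower else x >= lower
    if (ok) ok <- if (strict_upper) x < upper else x <= upper
  }
  if (!ok) stop_ldrisk(sprintf("`%s` must be a single number in %s%s, %s%s",
                               name,
                               if (strict_lower) "(" else "[", format(lower),
                               format(upper), if (strict_upper) ")" else "]"))
  as.numeric(x)
}

# population (1/n) and sample (1/(n-1)) column standard deviations
col_sds <- function(x, method = c("population", "sample")) {
  method <- match.arg(method)
  n <- nrow(x)
  m <- colMeans(x)
  ss <- colMeans(x^2) - m^2
  ss[ss < 0] <- 0
  if (method == "sample") ss <- ss * n / (n - 1)
  sqrt(ss)
}

var_pop <- function(x) mean((x - mean(x))^2)
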