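# Internal numeric helpers shared across modules.

# Trapezoid rule on an arbitrary (sorted) abscissa. Works for complex y.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0 * y[1])
  sum((y[-1] + y[-n]) * (x[-1] - x[-n])) / 2
}

# Cumulative trapezoid, same conventions as trapz().
cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) * (x[-1] - x[-n])) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_frag <- function(...) stop(..., call. = FALSE)

# Columns `x` and one of `u`/`f`/`g` identify a gridded density table.
density_cols <- function(data) {
  for (v in c("u", "f", "g")) if (v %in% names(data)) return(v)
  stop_frag("expected a density column named 'u', 'f' or 'g'")
}
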