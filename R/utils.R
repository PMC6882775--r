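#' @keywords internal
"_PACKAGE"

# clamp to [lo, hi]
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stop_if_not <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}

# Check a numeric vector for a uniform time grid (relative tolerance on step).
is_uniform_grid <- function(t, tol = 1e-6) {
  if (length(t) < 2L) return(TRUE)
  dt <- diff(t)
  (max(dt) - min(dt)) <= tol * stats::median(dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
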