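#' Build a symmetric up-then-down PEEP step protocol
#'
#' Generates the ordered sequence of PEEP levels for a ramp that starts at
#' 0 cmH2O, rises to `peep_max` in increments of `step`, and descends back
#' to 0 by the same increments.  Each endpoint appears once (at the start
#' and at the end) and the peak appears once, so a 0-to-15-by-3 ramp has
#' 11 steps.
#'
#' @param peep_max Highest PEEP of the ramp (cmH2O); must be a non-negative
#'   multiple of `step`.
#' @param step Increment between consecutive PEEP levels (cmH2O); > 0.
#' @return A data.frame with one row per protocol step: `step` (1-based
#'   index), `peep` (cmH2O) and `direction` (`"up"` for the ascending limb
#'   including the peak, `"down"` for the descending limb).
#' @examples
#' generate_protocol(15, 3)   # the 11-step ramp 0,3,...,15,...,3,0
#' @export
generate_protocol <- function(peep_max, step) {
  stop_if_not(is.numeric(step) && length(step) == 1L && step > 0,
              "`step` must be a single positive number")
  stop_if_not(is.numeric(peep_max) && length(peep_max) == 1L && peep_max >= 0,
              "`peep_max` must be a single non-negative number")
  k <- peep_max / step
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf("`peep_max` (%g) is not a multiple of `step` (%g)",
                 peep_max, step), call. = FALSE)
  }
  k <- as.integer(round(k))
  up <- seq(0, peep_max, by = step)
  down <- rev(up)[-1L]
  peep <- c(up, down)
  data.frame(
    step = seq_along(peep),
    peep = peep,
    direction = c(rep("up", length(up)), rep("down", length(down))),
    stringsAsFactors = FALSE
  )
}
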