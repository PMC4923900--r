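#' Log-transform sampling days
#'
#' Maps sampling days onto the transformed time scale used throughout the
#' regression stage, `T_j = log(t_j)`.  Working on log time stops the late
#' sampling days (13 and 27 in the default design) from dominating the
#' polynomial fit, because they are far apart on the raw day axis but carry
#' no more replicates than the early days.
#'
#' The log base only rescales the time axis by a positive constant; after
#' the per-probe standardisation applied before clustering, all downstream
#' cluster inputs are identical for any base.  Natural log is the default.
#'
#' @param days numeric vector of sampling days; all must be > 0.
#' @param base base of the logarithm (default natural log).
#' @return numeric vector, `log(days, base)`; strictly order-preserving.
#' @examples
#' transform_times(c(1, 3, 7, 13, 27))
#' @export
transform_times <- function(days, base = exp(1)) {
  if (!is.numeric(days) || length(days) == 0L)
    stop_input("'days' must be a non-empty numeric vector")
  if (any(!is.finite(days)) || any(days <= 0))
    stop_input("all days must be finite and strictly positive (got: %s)",
               paste(days[!is.finite(days) | days <= 0], collapse = ", "))
  log(days, base = base)
}

# default sampling-day grid of the emulated study design
DEFAULT_DAY_GRID <- c(1, 3, 7, 13, 27)

# per-arm replicate numbers on that grid (n = 10 per day, 15 at day 27)
DEFAULT_GROUP_SIZES <- c(10, 10, 10, 10, 15)

TREATMENT_LEVELS <- c("control", "ba", "gh")
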