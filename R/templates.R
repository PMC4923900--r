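## planted temporal templates
##
## A template is a vector of per-day multipliers over the sampling grid; the
## planted treatment effect for a probe is amplitude * multiplier(day) in the
## affected arm only.  Multipliers are peak-normalised (max |.| = 1) so that
## "amplitude" is the peak log-intensity effect.

#' Library of canonical temporal response templates
#'
#' Six named shapes covering the qualitative time-course behaviours a
#' treated-versus-control contrast can show on the default 5-day grid:
#' an early peak at day 3 decaying back towards control by day 27, a
#' transient response confined to day 1, a sustained constant offset, a late
#' rise maximal at day 27, an extreme-amplitude singleton shape (a probe so
#' far from everything else that it clusters alone), and the null template.
#'
#' @param day_grid sampling days the multipliers are evaluated on.
#' @return data frame with columns `template_id`, `shape`, and one
#'   `day_<d>` multiplier column per grid day.
#' @examples
#' template_library()
#' @export
template_library <- function(day_grid = DEFAULT_DAY_GRID) {
  shapes <- list(
    early_peak_decay  = c(0.55, 1.00, 0.65, 0.30, 0.05),
    transient_day1    = c(1.00, 0.45, 0.05, 0.00, 0.00),
    sustained         = c(1.00, 1.00, 1.00, 1.00, 1.00),
    late_rise         = c(0.05, 0.10, 0.25, 0.55, 1.00),
    singleton_extreme = c(0.10, 1.00, 0.30, 0.10, 0.80),
    null              = c(0.00, 0.00, 0.00, 0.00, 0.00)
  )
  if (length(day_grid) != 5L)
    stop_input("template_library is defined on a 5-day grid")
  out <- data.frame(template_id = names(shapes),
                    shape = names(shapes),
                    stringsAsFactors = FALSE)
  m <- do.call(rbind, shapes)
  colnames(m) <- paste0("day_", day_grid)
  cbind(out, m, row.names = NULL)
}

# orthonormal shape basis over the transformed time grid: the z-scored
# linear term and the z-scored quadratic residual.  Any degree-2 fitted
# treated-minus-control difference, once centred, lies in their span.
shape_basis <- function(day_grid = DEFAULT_DAY_GRID) {
  tt <- transform_times(day_grid)
  p1 <- (tt - mean(tt)) / sd(tt)
  r <- residuals(lm(I(tt^2) ~ tt))
  p2 <- r / sd(r)
  cbind(p1 = p1, p2 = p2)
}

# family of quadratic-shape templates at angles theta on the (p1, p2)
# circle; equal power for every theta because p1 and p2 are orthonormal
circle_templates <- function(theta, day_grid = DEFAULT_DAY_GRID) {
  B <- shape_basis(day_grid)
  m <- sapply(theta, function(a) cos(a) * B[, 1] + sin(a) * B[, 2])
  m / max(abs(m))   # common peak normalisation keeps powers equal
}

# angle whose circle template peaks at day 3 (an early-peak shape); used to
# phase the preset template wheels so the first template is interpretable
early_peak_phase <- function(day_grid = DEFAULT_DAY_GRID) {
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  m <- circle_templates(th, day_grid)
  peaked <- which(apply(m, 2, which.max) == 2L)
  # among day-3-peaked angles, pick the one decaying furthest by day 27
  th[peaked[which.min(m[5, peaked])]]
}

# named template wheel: k equally spaced quadratic shapes starting at the
# early-peak phase
template_wheel <- function(k, day_grid = DEFAULT_DAY_GRID) {
  th <- early_peak_phase(day_grid) + 2 * pi * (seq_len(k) - 1) / k
  m <- circle_templates(th, day_grid)
  colnames(m) <- sprintf("wheel%02d_of%02d", seq_len(k), k)
  rownames(m) <- paste0("day_", day_grid)
  m
}
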