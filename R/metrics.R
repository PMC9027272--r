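#' Classify a simulation outcome
#'
#' A run ends `"Alive"` when both species are still present at the end,
#' `"Extinction"` otherwise.  For agent runs "present" means a positive
#' count; for lattice runs a species is declared extinct when its final
#' mean density falls below `eps`.
#'
#' @param result An `rp_run` object from [run_pde()] or [run_mas()].
#' @param eps Extinction threshold.  Defaults to the run's configured
#'   `extinction_eps` for lattice runs and to 1 (i.e. a zero count) for
#'   agent runs.
#' @return `"Alive"` or `"Extinction"`.
#' @export
classify_outcome <- function(result, eps = NULL) {
  stopifnot(inherits(result, "rp_run"))
  r_fin <- result$replicase_series[length(result$replicase_series)]
  p_fin <- result$parasite_series[length(result$parasite_series)]
  if (length(r_fin) == 0L) stop("empty series")
  if (inherits(result, "rp_pde_run")) {
    if (is.null(eps)) eps <- result$config$extinction_eps
    r_fin <- r_fin / result$ncell
    p_fin <- p_fin / result$ncell
  } else if (is.null(eps)) {
    eps <- 1
  }
  if (r_fin < eps || p_fin < eps) "Extinction" else "Alive"
}

#' Oscillation statistics of a recorded trace
#'
#' Discards a burn-in fraction of the trace (the initial transient away
#' from the uniform starting state), then reports the extrema and mean of
#' the remaining window, plus a period estimate: the mean spacing of the
#' autocorrelation-function peaks.  The period is flagged undefined when
#' the trace is constant or no secondary autocorrelation peak reaches the
#' `prominence` threshold.
#'
#' @param trace A numeric series sampled at regular intervals.
#' @param burn_in Fraction of the trace to discard from the front
#'   (default 0.5).
#' @param prominence Minimal autocorrelation value for a peak to count.
#' @return A list with `min`, `max`, `mean`, `period` (in samples;
#'   `NA` when undefined), and `period_defined`.
#' @examples
#' x <- sin(2 * pi * (1:600) / 50)
#' trace_statistics(x, burn_in = 0)$period   # ~50
#' @export
trace_statistics <- function(trace, burn_in = 0.5, prominence = 0.2) {
  if (!is.numeric(trace) || length(trace) < 2L)
    stop("'trace' must be a numeric series")
  if (burn_in < 0 || burn_in >= 1) stop("'burn_in' must lie in [0, 1)")
  start <- floor(length(trace) * burn_in) + 1L
  w <- trace[start:length(trace)]
  if (length(w) < 2L) stop("post-burn-in window too short")
  out <- list(min = min(w), max = max(w), mean = mean(w),
              period = NA_real_, period_defined = FALSE)
  if (stats::sd(w) == 0) return(out)
  lag_max <- length(w) %/% 2L
  if (lag_max >= 2L) {
    ac <- as.numeric(stats::acf(w, lag.max = lag_max, plot = FALSE,
                                demean = TRUE)$acf)[-1L]   # drop lag 0
    n <- length(ac)
    if (n >= 3L) {
      is_peak <- c(FALSE, ac[2:(n - 1)] > ac[1:(n - 2)] &
                     ac[2:(n - 1)] >= ac[3:n], FALSE)
      peaks <- which(is_peak & ac >= prominence)
      if (length(peaks) > 0L) {
        out$period <- mean(diff(c(0L, peaks)))
        out$period_defined <- TRUE
      }
    }
  }
  out
}

#' Traveling-wave persistence condition
#'
#' In the surviving spatial regime the population cycles locally between
#' expansion and parasite-driven collapse; the system persists globally
#' when an expanding front can cover the minimal regrowth area within one
#' cycle: \eqn{\pi (v T)^2 \ge P}, where `v` is the wavefront expansion
#' velocity, `T` the cycle period, and `P` the smallest area a population
#' must cover to be able to regrow.  All three are measured (or supplied)
#' quantities; the model does not predict them in closed form.
#'
#' @param v Wavefront expansion velocity (length/time).
#' @param T_cycle Cycle period (time).
#' @param P_area Minimal regrowth area (length squared).
#' @return `TRUE` if the wave condition holds.
#' @examples
#' wave_condition(v = 1, T_cycle = 2, P_area = 12)  # pi*4 >= 12
#' @export
wave_condition <- function(v, T_cycle, P_area) {
  vals <- c(v = v, T_cycle = T_cycle, P_area = P_area)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("'v', 'T_cycle', and 'P_area' must be finite and >= 0")
  pi * (v * T_cycle)^2 >= P_area
}
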