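#' @export
print.rp_run <- function(x, ...) {
  kind <- if (inherits(x, "rp_pde_run")) "Reaction-diffusion" else
    "Multi-agent"
  n <- length(x$times)
  cat(sprintf("%s run: %d recorded steps, outcome %s\n",
              kind, n - 1L, x$outcome))
  cat(sprintf("  final replicases = %.6g, parasites = %.6g\n",
              x$replicase_series[n], x$parasite_series[n]))
  af <- x$affinity_series[n]
  if (is.finite(af))
    cat(sprintf("  final mean affinity/kP = %.4f\n", af))
  invisible(x)
}

#' @export
summary.rp_run <- function(object, burn_in = 0.5, ...) {
  n <- length(object$times)
  af <- object$affinity_series
  stats <- if (sum(is.finite(af)) > 4L) {
    trace_statistics(af[is.finite(af)], burn_in = burn_in)
  }
  out <- list(
    kind = if (inherits(object, "rp_pde_run")) "pde" else "mas",
    steps = n - 1L,
    outcome = object$outcome,
    final_replicases = object$replicase_series[n],
    final_parasites = object$parasite_series[n],
    affinity = stats)
  class(out) <- "summary.rp_run"
  out
}

#' @export
print.summary.rp_run <- function(x, ...) {
  cat(sprintf("Run (%s), %d steps, outcome: %s\n", x$kind, x$steps,
              x$outcome))
  cat(sprintf("  final replicases %.6g, parasites %.6g\n",
              x$final_replicases, x$final_parasites))
  if (!is.null(x$affinity)) {
    a <- x$affinity
    cat(sprintf("  affinity (post burn-in): min %.4f, max %.4f, mean %.4f\n",
                a$min, a$max, a$mean))
    if (a$period_defined)
      cat(sprintf("  oscillation period ~ %.1f samples\n", a$period))
  }
  invisible(x)
}

#' Time-series view of a simulation run
#'
#' @param x An `rp_run` object.
#' @param row.names,optional Ignored (standard generic arguments).
#' @param ... Ignored.
#' @return A data frame with one row per recorded step.
#' @export
as.data.frame.rp_run <- function(x, row.names = NULL, optional = FALSE,
                                 ...) {
  d <- data.frame(step = x$step, time = x$times,
                  total_r = x$replicase_series,
                  total_p = x$parasite_series,
                  mean_a = x$affinity_series)
  if (!is.null(x$resource_series)) d$total_n <- x$resource_series
  if (!is.null(x$trace)) d$trace_a <- x$trace
  if (!is.null(x$min_kP)) { d$min_kP <- x$min_kP; d$max_kP <- x$max_kP }
  d
}

#' Plot the population time series of a run
#'
#' Replicase and parasite series (log-ready totals or counts) on a common
#' axis, with the mean affinity/replication probability overlaid on a
#' secondary scale.
#'
#' @param x An `rp_run` object.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.rp_run <- function(x, ...) {
  d <- as.data.frame(x)
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  matplot(d$time, cbind(d$total_r, d$total_p), type = "l", lty = 1,
          col = c("gray40", "firebrick"), xlab = "time",
          ylab = "population total", ...)
  ok <- is.finite(d$mean_a)
  if (any(ok)) {
    usr <- par("usr")
    par(new = TRUE)
    plot(d$time[ok], d$mean_a[ok], type = "l", col = "steelblue",
         axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1),
         xlim = usr[1:2])
    graphics::axis(4, col.axis = "steelblue")
    graphics::mtext("mean affinity / kP", side = 4, line = 2.5,
                    col = "steelblue", cex = 0.9)
  }
  legend("topright", c("replicases", "parasites", "affinity"),
         lty = 1, col = c("gray40", "firebrick", "steelblue"), bty = "n",
         cex = 0.8)
  invisible(x)
}

#' Display a lattice field as an image
#'
#' @param x An `rp_grid_state`.
#' @param field Which field to draw.
#' @param ... Passed to [graphics::image()].
#' @export
plot.rp_grid_state <- function(x, field = c("r", "p", "a", "n"), ...) {
  field <- match.arg(field)
  graphics::image(x[[field]], col = gray(seq(0, 1, length.out = 64)),
                  axes = FALSE, main = sprintf("%s at t = %g", field, x$t),
                  ...)
  invisible(x)
}
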