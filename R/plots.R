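# base-graphics diagnostics

#' @describeIn generate_ovary long-axis cross-section of the model: follicle
#'   centers in the (z, x) plane with the ovary outline, point size scaled by
#'   follicle diameter.
#' @param x,y,... standard plot-method arguments.
#' @export
plot.ovary_model <- function(x, y, ...) {
  f <- x$follicles
  a <- x$semi_axes
  th <- seq(0, 2 * pi, length.out = 361)
  plot(a[1] * cos(th), a[2] * sin(th), type = "l", asp = 1,
       xlab = "z - a (long axis, um)", ylab = "x (um)",
       main = "Synthetic ovary, mid-organ cross-section", ...)
  if (x$cortex_thickness < min(a)) {
    graphics::lines((a[1] - x$cortex_thickness) * cos(th),
                    (a[2] - x$cortex_thickness) * sin(th), lty = 2)
  }
  if (nrow(f)) {
    stage <- factor(f$stage, levels = STAGES)
    graphics::points(f$cz, f$cx, col = as.integer(stage) + 1L,
                     cex = 0.3 + f$d_follicle / 400, pch = 1)
    graphics::legend("topright", legend = STAGES, col = seq_along(STAGES) + 1L,
                     pch = 1, bty = "n", cex = 0.8)
  }
  invisible(x)
}

#' @describeIn overcount_experiment mean sections hit per object against
#'   diameter, with the analytic (d + t)/t line; the gated mode stays flat at
#'   one count per follicle.
#' @param x,y,... standard plot-method arguments.
#' @export
plot.overcount_table <- function(x, y, ...) {
  s <- x$summary
  prof <- s[s$mode == "profile_presence", ]
  plot(prof$diameter, prof$mean_sections_per_object,
       xlab = "object diameter (um)", ylab = "mean sections hit per object",
       main = "Overcounting of large objects under profile counting",
       pch = 19, ...)
  graphics::lines(prof$diameter, prof$analytic_sections, lty = 2)
  graphics::legend("topleft", legend = c("simulated", "(d + t) / t"),
                   pch = c(19, NA), lty = c(NA, 2), bty = "n")
  invisible(x)
}
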