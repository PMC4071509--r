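# base-graphics plot methods; stable branches solid, unstable dashed,
# following the usual bifurcation-diagram conventions

#' @export
plot.trajectory <- function(x, ...) {
  graphics::matplot(x$time, cbind(x$x_glucose, x$y_lactate), type = "l",
                    lty = 1, col = c("steelblue4", "firebrick"),
                    xlab = "time", ylab = "level",
                    main = "Tumour metabolic trajectory", ylim = c(0, 1), ...)
  graphics::legend("bottomright",
                   c("hypoxic glycolysis (x_glucose)",
                     "oxygenated lactate respiration (y_lactate)"),
                   lty = 1, col = c("steelblue4", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
plot.bifurcation_branch <- function(x, coord = c("y_lactate", "x_glucose"),
                                    log = "x", ...) {
  coord <- match.arg(coord)
  st <- x$stability == "stable"
  graphics::plot(x$swept_value[st], x[[coord]][st], pch = 16, cex = 0.4,
                 col = "steelblue4", log = log, ylim = c(0, 1),
                 xlab = attr(x, "swept"), ylab = coord,
                 main = sprintf("Bifurcation diagram (%s fixed at %g)",
                                setdiff(c("Tx", "Ty"), attr(x, "swept")),
                                attr(x, "fixed_value")), ...)
  graphics::points(x$swept_value[!st], x[[coord]][!st], pch = 1, cex = 0.4,
                   col = "firebrick")
  f <- attr(x, "folds")
  if (nrow(f) && !is.null(f$critical))
    graphics::abline(v = f$critical, lty = 3, col = "grey40")
  graphics::legend("right", c("stable", "unstable", "fold"),
                   pch = c(16, 1, NA), lty = c(NA, NA, 3),
                   col = c("steelblue4", "firebrick", "grey40"), bty = "n")
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  cls <- attr(x, "coupling_class")
  lev <- c("weak", "bistable", "strong")
  z <- matrix(match(cls, lev), nrow(cls), ncol(cls))
  graphics::image(attr(x, "Tx_grid"), attr(x, "Ty_grid"), z,
                  col = c("grey85", "goldenrod2", "grey25"),
                  xlab = "Tx (hypoxic exploration rate)",
                  ylab = "Ty (oxygenated exploration rate)", log = "xy",
                  main = "Metabolic coupling zones", ...)
  graphics::legend("topright", lev, fill = c("grey85", "goldenrod2", "grey25"),
                   bg = "white")
  invisible(x)
}

#' @export
plot.basin_map <- function(x, ...) {
  res <- length(unique(x$x_glucose0))
  z <- matrix(x$attractor, res, res)
  graphics::image(unique(x$x_glucose0), unique(x$y_glucose0), z,
                  col = c("lightsteelblue", "navajowhite"),
                  xlab = "initial x_glucose", ylab = "initial y_glucose",
                  main = "Basins of attraction", ...)
  fps <- attr(x, "fixed_points")
  graphics::points(fps$x_glucose, fps$y_glucose,
                   pch = ifelse(fps$stability == "stable", 16, 4),
                   cex = 1.2)
  invisible(x)
}
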