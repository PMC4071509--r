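#' Joint state of the two tumour subpopulations
#'
#' A point on the product of two probability simplices: `x` is the strategy
#' mix of the hypoxic population, `y` that of the oxygenated population.
#' Component 1 is the glucose fraction, component 2 the lactate fraction.
#' The reporting coordinates of the model are `x[1]` (hypoxic glycolysis
#' level) and `y[2]` (oxygenated lactate-fuelled respiration level).
#'
#' @param x,y numeric probability vectors of length 2 (non-negative, summing
#'   to 1 within `1e-12`).
#' @return An object of class `"population_state"`.
#' @export
population_state <- function(x, y) {
  for (nm in c("x", "y")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || any(!is.finite(v)) || any(v < 0))
      stop(sprintf("'%s' must be a non-negative numeric vector of length 2", nm),
           call. = FALSE)
    if (abs(sum(v) - 1) > 1e-12)
      stop(sprintf("'%s' must sum to 1 within 1e-12 (got %.15g)", nm, sum(v)),
           call. = FALSE)
  }
  structure(list(x = as.numeric(x), y = as.numeric(y)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("hypoxic    x = (%.6g glucose, %.6g lactate)\n", x$x[1], x$x[2]))
  cat(sprintf("oxygenated y = (%.6g glucose, %.6g lactate)\n", x$y[1], x$y[2]))
  invisible(x)
}

#' Exploration (genomic instability) rates of the two populations
#'
#' Temperature-like, dimensionless rates weighting random strategy
#' exploration against payoff-driven selection: `Tx` for the hypoxic and
#' `Ty` for the oxygenated population.  `T = 0` is pure exploitation
#' (classical replicator dynamics); large `T` randomises strategy choice.
#'
#' @param Tx,Ty non-negative finite exploration rates.
#' @return An object of class `"exploration_rates"`.
#' @export
exploration_rates <- function(Tx, Ty = Tx) {
  structure(list(Tx = .check_scalar(Tx, "Tx", nonneg = TRUE),
                 Ty = .check_scalar(Ty, "Ty", nonneg = TRUE)),
            class = "exploration_rates")
}

.as_rates <- function(rates) {
  if (inherits(rates, "exploration_rates")) return(rates)
  if (is.numeric(rates) && length(rates) == 2L)
    return(exploration_rates(rates[1], rates[2]))
  stop("'rates' must be exploration_rates() or a numeric c(Tx, Ty)",
       call. = FALSE)
}

.check_interior <- function(v, nm, T) {
  if (T > 0 && any(v <= 0))
    stop(sprintf("state '%s' lies on the simplex boundary; the exploration ",
                 nm),
         "term (T > 0) requires a strictly interior state", call. = FALSE)
}

#' Single-population replicator field with Boltzmann exploration
#'
#' The growth rate of strategy `i` is its payoff advantage over the
#' population mean, plus an exploration flux
#' `T * x_i * sum_j x_j log(x_j / x_i)` that drives the mix towards the
#' Boltzmann distribution over the payoffs.
#'
#' @param x interior probability vector (any number of strategies).
#' @param rewards numeric payoff vector, one entry per strategy.
#' @param T non-negative exploration rate.
#' @return Numeric vector `dx` with `sum(dx) == 0` up to rounding.
#' @examples
#' single_population_field(c(0.5, 0.5), c(2, 0), T = 1)   # c(0.5, -0.5)
#' @export
single_population_field <- function(x, rewards, T) {
  if (!is.numeric(x) || length(x) < 2L || any(!is.finite(x)) || any(x < 0))
    stop("'x' must be a non-negative probability vector", call. = FALSE)
  if (abs(sum(x) - 1) > 1e-12)
    stop("'x' must sum to 1 within 1e-12", call. = FALSE)
  if (!is.numeric(rewards) || length(rewards) != length(x) ||
      any(!is.finite(rewards)))
    stop("'rewards' must be a finite vector matching length(x)", call. = FALSE)
  T <- .check_scalar(T, "T", nonneg = TRUE)
  .check_interior(x, "x", T)
  sel <- x * (rewards - sum(x * rewards))
  if (T == 0) return(sel)
  # sum_j x_j log(x_j/x_i) = sum_j x_j log x_j - log x_i
  ent <- sum(x * log(x))
  sel + T * x * (ent - log(x))
}

#' Coupled replicator-exploration vector field of the two populations
#'
#' Time derivatives of the joint state under selection on expected ATP
#' payoffs (`A %*% y` for hypoxic, `B %*% x` for oxygenated) and Boltzmann
#' exploration at rates `Tx`, `Ty`.
#'
#' @param state a [population_state()]; must be strictly interior whenever
#'   the corresponding exploration rate is positive.
#' @param game a [bimatrix_game()].
#' @param rates an [exploration_rates()] object or numeric `c(Tx, Ty)`.
#' @return A list with components `dx` and `dy`, each summing to 0 up to
#'   rounding (the flow conserves both simplices).
#' @examples
#' g <- build_symbiosis_game(metabolic_yields())
#' st <- population_state(c(0.7, 0.3), c(0.4, 0.6))
#' replicator_exploration_field(st, g, exploration_rates(0.5))
#' @export
replicator_exploration_field <- function(state, game, rates) {
  stopifnot(inherits(state, "population_state"),
            inherits(game, "bimatrix_game"))
  rates <- .as_rates(rates)
  list(dx = single_population_field(state$x, drop(game$A %*% state$y), rates$Tx),
       dy = single_population_field(state$y, drop(game$B %*% state$x), rates$Ty))
}

# raw 4-vector field used by the integrator; clamps at eps before the log
# terms (for T > 0 the boundary is repelling, so clamping cannot create
# spurious attractors) and projects the derivative onto the simplex tangent
.field_raw <- function(s, game, rates, eps = 1e-12) {
  x <- pmax(s[1:2], eps); x <- x / sum(x)
  y <- pmax(s[3:4], eps); y <- y / sum(y)
  rx <- drop(game$A %*% y); ry <- drop(game$B %*% x)
  dx <- x * (rx - sum(x * rx))
  dy <- y * (ry - sum(y * ry))
  if (rates$Tx > 0) dx <- dx + rates$Tx * x * (sum(x * log(x)) - log(x))
  if (rates$Ty > 0) dy <- dy + rates$Ty * y * (sum(y * log(y)) - log(y))
  c(dx, dy)
}

#' Integrate the coupled replicator-exploration dynamics
#'
#' Adaptive explicit Runge-Kutta integration (Dormand-Prince via
#' [deSolve::ode()]) of the full four-component state.  Components are
#' clamped at `1e-12` and renormalised before each field evaluation;
#' emitted states are renormalised onto the simplex whenever drift exceeds
#' `1e-12`.  Convergence is declared on the field norm at the terminal
#' state (`tol_field`), not on state stagnation - near fold points the
#' dynamics are slow and stagnation would be misleading.
#'
#' @param state0 initial [population_state()], strictly interior.
#' @param game a [bimatrix_game()].
#' @param rates an [exploration_rates()] or numeric `c(Tx, Ty)`.
#' @param t_end final time (> 0).
#' @param n_out number of equally spaced output times (>= 2).
#' @param rtol,atol relative / absolute integrator tolerances.
#' @param tol_field field max-norm below which the terminal state counts as
#'   converged.
#' @return A data frame of class `"trajectory"` with columns `time`,
#'   `x_glucose`, `x_lactate`, `y_glucose`, `y_lactate`; attributes
#'   `converged` (logical) and `terminal_state` (a `population_state`).
#' @examples
#' g <- build_symbiosis_game(metabolic_yields())
#' tr <- integrate_dynamics(population_state(c(.5, .5), c(.5, .5)), g,
#'                          exploration_rates(1), t_end = 50)
#' attr(tr, "converged")
#' @export
integrate_dynamics <- function(state0, game, rates, t_end = 100, n_out = 201,
                               rtol = 1e-9, atol = 1e-12, tol_field = 1e-10) {
  stopifnot(inherits(state0, "population_state"),
            inherits(game, "bimatrix_game"))
  rates <- .as_rates(rates)
  t_end <- .check_scalar(t_end, "t_end", positive = TRUE)
  .check_interior(state0$x, "x", rates$Tx)
  .check_interior(state0$y, "y", rates$Ty)

  times <- seq(0, t_end, length.out = max(2L, as.integer(n_out)))
  sol <- deSolve::ode(
    y = c(state0$x, state0$y), times = times,
    func = function(t, s, p) list(.field_raw(s, game, rates)),
    parms = NULL, method = "ode45", rtol = rtol, atol = atol)
  if (any(!is.finite(sol[, -1])))
    stop("integration produced non-finite states (boundary blow-up); ",
         "check the initial state and rates", call. = FALSE)

  states <- unname(as.matrix(sol[, -1, drop = FALSE]))
  # renormalise emitted states whenever simplex drift exceeds 1e-12
  for (cols in list(1:2, 3:4)) {
    s <- rowSums(states[, cols, drop = FALSE])
    bad <- abs(s - 1) > 1e-12
    if (any(bad))
      states[bad, cols] <- states[bad, cols, drop = FALSE] / s[bad]
  }
  states <- pmin(pmax(states, 0), 1)

  term <- states[nrow(states), ]
  fin <- .field_raw(term, game, rates)
  out <- data.frame(time = sol[, 1],
                    x_glucose = states[, 1], x_lactate = states[, 2],
                    y_glucose = states[, 3], y_lactate = states[, 4])
  class(out) <- c("trajectory", "data.frame")
  attr(out, "converged") <- max(abs(fin)) < tol_field
  attr(out, "terminal_state") <- population_state(term[1:2] / sum(term[1:2]),
                                                  term[3:4] / sum(term[3:4]))
  attr(out, "rates") <- rates
  out
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d states on t = [%g, %g], %s\n", nrow(x),
              x$time[1], x$time[nrow(x)],
              if (isTRUE(attr(x, "converged"))) "converged" else "not converged"))
  print(attr(x, "terminal_state"))
  invisible(x)
}
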