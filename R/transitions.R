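.stable_count <- function(fps) sum(fps$stability == "stable")

.fps_or_null <- function(game, rates, ...) {
  tryCatch(find_fixed_points(game, rates, ...), error = function(e) NULL)
}

#' One-parameter bifurcation sweep over an exploration rate
#'
#' Runs [find_fixed_points()] along a grid of one exploration rate with the
#' other held fixed, records every fixed point, and flags fold (critical
#' transition) intervals where the count of stable equilibria changes
#' between adjacent grid values.  Each fold can be refined by bisection with
#' [refine_fold()] (done automatically when `refine = TRUE`).
#'
#' @param game a [bimatrix_game()].
#' @param swept `"Tx"` or `"Ty"`: which rate is swept.
#' @param fixed_value value of the non-swept rate.
#' @param grid strictly increasing vector of positive swept-rate values.
#' @param seed seed for the root-search random starts.
#' @param n_starts random starts per grid value (see [find_fixed_points()]).
#' @param refine refine each detected fold by bisection to width `1e-4`.
#' @return A data frame of class `"bifurcation_branch"` (one row per fixed
#'   point per grid value; columns `swept_value`, `x_glucose`, `y_glucose`,
#'   `y_lactate`, `residual`, `stability`).  Attributes: `swept`,
#'   `fixed_value`, `grid`, `stable_count` (per grid value, `NA` for failed
#'   values), `folds` (data frame of bracketing intervals, with refined
#'   `critical` values when `refine = TRUE`) and `game`.
#' @examples
#' \donttest{
#' g <- build_symbiosis_game(metabolic_yields())
#' br <- sweep_bifurcation(g, "Tx", fixed_value = 0.5,
#'                         grid = exp(seq(log(0.5), log(8), length.out = 61)))
#' attr(br, "folds")
#' }
#' @export
sweep_bifurcation <- function(game, swept = c("Tx", "Ty"), fixed_value, grid,
                              seed = 1, n_starts = 50, refine = TRUE) {
  swept <- match.arg(swept)
  fixed_value <- .check_scalar(fixed_value, "fixed_value", positive = TRUE)
  if (!is.numeric(grid) || length(grid) < 2L || any(grid <= 0) ||
      any(diff(grid) <= 0))
    stop("'grid' must be a strictly increasing vector of positive values",
         call. = FALSE)

  mk_rates <- function(val)
    if (swept == "Tx") exploration_rates(val, fixed_value)
    else exploration_rates(fixed_value, val)

  pts <- vector("list", length(grid))
  counts <- rep(NA_integer_, length(grid))
  for (k in seq_along(grid)) {
    fps <- .fps_or_null(game, mk_rates(grid[k]), n_starts = n_starts,
                        seed = seed)
    if (is.null(fps)) next
    counts[k] <- .stable_count(fps)
    pts[[k]] <- data.frame(swept_value = grid[k],
                           x_glucose = fps$x_glucose,
                           y_glucose = fps$y_glucose,
                           y_lactate = fps$y_lactate,
                           residual = fps$residual,
                           stability = fps$stability,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, pts[!vapply(pts, is.null, logical(1))])
  rownames(out) <- NULL
  class(out) <- c("bifurcation_branch", "data.frame")

  ok <- which(!is.na(counts))
  folds <- data.frame(lower = numeric(), upper = numeric(),
                      count_lower = integer(), count_upper = integer())
  if (length(ok) >= 2L) {
    adj <- ok[-length(ok)]
    nxt <- ok[-1]
    chg <- which(nxt - adj == 1L & counts[adj] != counts[nxt])
    if (length(chg))
      folds <- data.frame(lower = grid[adj[chg]], upper = grid[nxt[chg]],
                          count_lower = counts[adj[chg]],
                          count_upper = counts[nxt[chg]])
  }
  attr(out, "swept") <- swept
  attr(out, "fixed_value") <- fixed_value
  attr(out, "grid") <- grid
  attr(out, "stable_count") <- counts
  attr(out, "game") <- game
  attr(out, "seed") <- seed
  attr(out, "n_starts") <- n_starts
  attr(out, "folds") <- folds
  if (refine && nrow(folds)) {
    folds$critical <- vapply(seq_len(nrow(folds)), function(i)
      refine_fold(out, fold = i)$critical, numeric(1))
    attr(out, "folds") <- folds
  }
  out
}

#' @export
print.bifurcation_branch <- function(x, ...) {
  cat(sprintf("Bifurcation sweep of %s (other rate fixed at %g), %d grid values\n",
              attr(x, "swept"), attr(x, "fixed_value"),
              length(attr(x, "grid"))))
  cnt <- attr(x, "stable_count")
  cat(sprintf("stable-equilibrium counts: %s\n",
              paste(rle(as.character(cnt))$values, collapse = " -> ")))
  f <- attr(x, "folds")
  if (nrow(f)) {
    cat("folds (stable-count changes):\n")
    print.data.frame(f, row.names = FALSE)
  } else cat("no folds detected\n")
  invisible(x)
}

#' Refine a fold to a critical parameter value by bisection
#'
#' Bisects the swept parameter inside a bracketing interval across which the
#' stable-equilibrium count changes, until the bracket is narrower than
#' `tol`.  If a midpoint count matches neither endpoint (a root was missed),
#' the search retries once with doubled multi-start density before failing.
#'
#' @param branch a [sweep_bifurcation()] result.
#' @param fold which row of `attr(branch, "folds")` to refine.
#' @param tol final bracket width (in swept-parameter units).
#' @return A list with `critical` (bracket midpoint), `bracket`, and the
#'   stable counts on each side.
#' @export
refine_fold <- function(branch, fold = 1L, tol = 1e-4) {
  stopifnot(inherits(branch, "bifurcation_branch"))
  folds <- attr(branch, "folds")
  if (fold < 1L || fold > nrow(folds))
    stop("no such fold in this branch", call. = FALSE)
  game <- attr(branch, "game"); swept <- attr(branch, "swept")
  fixed_value <- attr(branch, "fixed_value")
  seed <- attr(branch, "seed"); n_starts <- attr(branch, "n_starts")
  mk_rates <- function(val)
    if (swept == "Tx") exploration_rates(val, fixed_value)
    else exploration_rates(fixed_value, val)
  count_at <- function(val, ns) {
    fps <- .fps_or_null(game, mk_rates(val), n_starts = ns, seed = seed)
    if (is.null(fps)) NA_integer_ else .stable_count(fps)
  }
  lo <- folds$lower[fold]; hi <- folds$upper[fold]
  clo <- folds$count_lower[fold]; chi <- folds$count_upper[fold]
  ns <- n_starts
  retried <- FALSE
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    cm <- count_at(mid, ns)
    if (is.na(cm) || (cm != clo && cm != chi)) {
      if (!retried) { retried <- TRUE; ns <- 2L * ns; next }
      stop(sprintf("fold refinement lost the stable-count change at %s = %g ",
                   swept, mid),
           "(midpoint count matches neither bracket endpoint)", call. = FALSE)
    }
    if (cm == clo) lo <- mid else hi <- mid
  }
  list(critical = (lo + hi) / 2, bracket = c(lo, hi),
       count_lower = clo, count_upper = chi)
}

#' Quasi-static forward/backward tracking across a sweep (hysteresis)
#'
#' Tracks the occupied stable equilibrium along the sweep grid in both
#' directions: starting from the attractor at one end, each next grid value
#' keeps the nearest stable fixed point (continuity), jumping only when the
#' occupied branch disappears at a fold.  Inside a bistable window the
#' forward and backward passes occupy different branches - the hysteresis
#' signature of a critical transition.
#'
#' @param branch a [sweep_bifurcation()] result.
#' @return A data frame of class `"hysteresis_loop"`: per grid value, the
#'   occupied `(x_glucose, y_lactate)` for the `forward` and `backward`
#'   passes, and `split` (whether the two passes differ by more than
#'   `1e-6`).
#' @export
hysteresis_loop <- function(branch) {
  stopifnot(inherits(branch, "bifurcation_branch"))
  grid <- attr(branch, "grid")
  track <- function(idx) {
    occ_u <- occ_v <- rep(NA_real_, length(grid))
    prev <- NULL
    for (k in idx) {
      pts <- branch[branch$swept_value == grid[k] &
                    branch$stability == "stable", , drop = FALSE]
      if (!nrow(pts)) next
      if (is.null(prev)) {
        j <- 1L
      } else {
        d <- pmax(abs(pts$x_glucose - prev[1]), abs(pts$y_glucose - prev[2]))
        j <- which.min(d)
      }
      prev <- c(pts$x_glucose[j], pts$y_glucose[j])
      occ_u[k] <- pts$x_glucose[j]; occ_v[k] <- pts$y_glucose[j]
    }
    list(u = occ_u, v = occ_v)
  }
  fw <- track(seq_along(grid))
  bw <- track(rev(seq_along(grid)))
  out <- data.frame(
    swept_value = grid,
    forward_x_glucose = fw$u, forward_y_lactate = 1 - fw$v,
    backward_x_glucose = bw$u, backward_y_lactate = 1 - bw$v)
  out$split <- pmax(abs(fw$u - bw$u), abs(fw$v - bw$v)) > 1e-6
  class(out) <- c("hysteresis_loop", "data.frame")
  attr(out, "swept") <- attr(branch, "swept")
  out
}

#' Strength of metabolic coupling at a stable equilibrium
#'
#' A tumour state is a *strong* metabolic coupling when at least half of
#' each population plays its symbiotic action - hypoxic cells on glucose
#' (exporting lactate) and oxygenated cells on lactate - and *weak*
#' otherwise.  Requiring the majority in both populations is the stricter
#' reading of "at least half of the tumour cells participate".
#'
#' @param fp a one-row `fixed_points` data frame, a [population_state()],
#'   or any list/row with `x_glucose` and `y_lactate` entries.
#' @return `"strong"` or `"weak"`.
#' @export
classify_coupling <- function(fp) {
  if (inherits(fp, "population_state")) {
    u <- fp$x[1]; w <- fp$y[2]
  } else {
    u <- fp$x_glucose[1]; w <- fp$y_lactate[1]
  }
  if (!is.finite(u) || !is.finite(w))
    stop("cannot classify coupling: missing state coordinates", call. = FALSE)
  if (u >= 0.5 && w >= 0.5) "strong" else "weak"
}

#' Map basins of attraction of the stable equilibria
#'
#' Integrates the coupled dynamics from a regular grid of interior initial
#' conditions on `(x_glucose, y_glucose)` until the field norm drops below
#' `tol_field` (extending the time horizon in chunks), then assigns each
#' start to the nearest stable fixed point within `match_tol`.
#' Non-convergent starts are flagged with attractor `NA`, never dropped.
#'
#' @param game a [bimatrix_game()].
#' @param rates [exploration_rates()] with positive rates.
#' @param resolution grid points per axis.
#' @param seed seed for the fixed-point search.
#' @param t_chunk integration time per chunk.
#' @param max_chunks maximum number of chunks per start.
#' @param tol_field convergence threshold on the field max-norm.  The
#'   default (`1e-8`) is looser than the fixed-point residual tolerance
#'   because the integrator's local error bounds the attainable field norm;
#'   with attraction rates of order the payoff scale it still pins the
#'   terminal state well inside `match_tol` of its attractor.
#' @param match_tol maximum distance to a stable fixed point for assignment.
#' @param ... further arguments (e.g. `rtol`, `atol`) passed on to
#'   [integrate_dynamics()].
#' @return A data frame of class `"basin_map"` with columns `x_glucose0`,
#'   `y_glucose0`, `attractor` (row index into the stable-attractor table,
#'   `NA` when non-convergent) and `converged`.  Attributes: `attractors`
#'   (the stable rows of [find_fixed_points()]), `fixed_points` (all roots,
#'   including the saddle whose stable manifold forms the basin boundary),
#'   `rates` and `game`.
#' @export
basin_map <- function(game, rates, resolution = 21, seed = 1, t_chunk = 50,
                      max_chunks = 12, tol_field = 1e-8, match_tol = 1e-4,
                      ...) {
  stopifnot(inherits(game, "bimatrix_game"))
  rates <- .as_rates(rates)
  fps <- find_fixed_points(game, rates, seed = seed)
  stab <- fps[fps$stability == "stable", , drop = FALSE]
  gr <- seq_len(resolution) / (resolution + 1)
  grid <- expand.grid(x_glucose0 = gr, y_glucose0 = gr)
  attractor <- rep(NA_integer_, nrow(grid))
  converged <- rep(FALSE, nrow(grid))
  for (k in seq_len(nrow(grid))) {
    st <- population_state(c(grid$x_glucose0[k], 1 - grid$x_glucose0[k]),
                           c(grid$y_glucose0[k], 1 - grid$y_glucose0[k]))
    for (chunk in seq_len(max_chunks)) {
      tr <- integrate_dynamics(st, game, rates, t_end = t_chunk, n_out = 2,
                               tol_field = tol_field, ...)
      st <- attr(tr, "terminal_state")
      if (attr(tr, "converged")) break
    }
    if (!attr(tr, "converged")) next
    converged[k] <- TRUE
    if (nrow(stab)) {
      d <- pmax(abs(stab$x_glucose - st$x[1]), abs(stab$y_glucose - st$y[1]))
      j <- which.min(d)
      if (d[j] <= match_tol) attractor[k] <- j
    }
  }
  out <- cbind(grid, attractor = attractor, converged = converged)
  class(out) <- c("basin_map", "data.frame")
  attr(out, "attractors") <- stab
  attr(out, "fixed_points") <- fps
  attr(out, "rates") <- rates
  attr(out, "game") <- game
  out
}

#' Two-parameter phase diagram of metabolic coupling zones
#'
#' Evaluates [find_fixed_points()] on the tensor grid `Tx_grid x Ty_grid`
#' and classifies every cell: `"bistable"` when two stable equilibria
#' coexist, otherwise `"strong"` or `"weak"` metabolic coupling of the
#' unique stable state ([classify_coupling()]).  Zone borders trace the
#' critical (fold) values of the exploration rates.
#'
#' @param game a [bimatrix_game()].
#' @param Tx_grid,Ty_grid strictly increasing vectors of positive rates.
#' @param seed seed for the root searches.
#' @param n_starts random starts per cell.
#' @return A long-format data frame of class `"phase_diagram"` with columns
#'   `Tx`, `Ty`, `n_stable` (`NA` on solver failure, recorded not
#'   interpolated) and `coupling`.  Attributes `Tx_grid`, `Ty_grid`,
#'   `stable_count` (matrix, `Tx` by `Ty`), `coupling_class` (matrix),
#'   `game`, `seed`.
#' @examples
#' \donttest{
#' g <- build_symbiosis_game(metabolic_yields())
#' pd <- phase_diagram(g, exp(seq(log(.5), log(8), length.out = 31)),
#'                        exp(seq(log(.05), log(4), length.out = 31)))
#' table(pd$coupling)
#' }
#' @export
phase_diagram <- function(game, Tx_grid, Ty_grid, seed = 1, n_starts = 50) {
  stopifnot(inherits(game, "bimatrix_game"))
  for (nm in c("Tx_grid", "Ty_grid")) {
    g <- get(nm)
    if (!is.numeric(g) || length(g) < 2L || any(g <= 0) || any(diff(g) <= 0))
      stop(sprintf("'%s' must be strictly increasing and positive", nm),
           call. = FALSE)
  }
  nS <- matrix(NA_integer_, length(Tx_grid), length(Ty_grid))
  cls <- matrix(NA_character_, length(Tx_grid), length(Ty_grid))
  for (j in seq_along(Ty_grid)) for (i in seq_along(Tx_grid)) {
    fps <- .fps_or_null(game, exploration_rates(Tx_grid[i], Ty_grid[j]),
                        n_starts = n_starts, seed = seed)
    if (is.null(fps)) next
    stab <- fps[fps$stability == "stable", , drop = FALSE]
    nS[i, j] <- nrow(stab)
    cls[i, j] <- if (nrow(stab) >= 2L) "bistable"
                 else if (nrow(stab) == 1L) classify_coupling(stab)
                 else NA_character_
  }
  out <- data.frame(Tx = rep(Tx_grid, times = length(Ty_grid)),
                    Ty = rep(Ty_grid, each = length(Tx_grid)),
                    n_stable = as.vector(nS),
                    coupling = as.vector(cls), stringsAsFactors = FALSE)
  class(out) <- c("phase_diagram", "data.frame")
  attr(out, "Tx_grid") <- Tx_grid
  attr(out, "Ty_grid") <- Ty_grid
  attr(out, "stable_count") <- nS
  attr(out, "coupling_class") <- cls
  attr(out, "game") <- game
  attr(out, "seed") <- seed
  attr(out, "n_starts") <- n_starts
  out
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Phase diagram on %d x %d (Tx, Ty) grid\n",
              length(attr(x, "Tx_grid")), length(attr(x, "Ty_grid"))))
  print(table(coupling = x$coupling, useNA = "ifany"))
  invisible(x)
}

#' Track the occupied tumour state along a therapy path in rate space
#'
#' Follows a straight line in the `(Tx, Ty)` plane (e.g. a therapy that
#' perturbs the genomic-instability rates, or a lactate-shuttle inhibition
#' protocol re-expressed as a rate change) and tracks which attractor the
#' tumour occupies by continuity: at each step the nearest stable fixed
#' point to the previously occupied state.  A step where that nearest
#' attractor jumps farther than `jump_tol` marks a forced critical
#' transition (the occupied branch vanished at a fold).
#'
#' @param diagram a [phase_diagram()] (supplies the game and the grid hull)
#'   or a [bimatrix_game()] (then the hull check is skipped).
#' @param from,to numeric `c(Tx, Ty)` endpoints; must lie within the
#'   diagram's grid hull.
#' @param n_steps number of path points (>= 2).
#' @param state0 optional [population_state()] selecting the initially
#'   occupied attractor (nearest stable fixed point); default: the stable
#'   fixed point with the highest lactate-respiration level `y_lactate`
#'   at `from` (the fully developed symbiotic state).
#' @param jump_tol occupied-state jump (max-norm on `(x_glucose,
#'   y_glucose)`) that flags a forced transition.
#' @param seed seed for the root searches.
#' @return A data frame of class `"therapy_path"`: per step `Tx`, `Ty`,
#'   `n_stable`, occupied `x_glucose` / `y_lactate`, `coupling` of the
#'   occupied state, and `forced_transition`.
#' @export
therapy_path <- function(diagram, from, to, n_steps = 50, state0 = NULL,
                         jump_tol = 0.2, seed = 1) {
  if (inherits(diagram, "phase_diagram")) {
    game <- attr(diagram, "game")
    hull_x <- range(attr(diagram, "Tx_grid"))
    hull_y <- range(attr(diagram, "Ty_grid"))
    inside <- function(p) p[1] >= hull_x[1] && p[1] <= hull_x[2] &&
                          p[2] >= hull_y[1] && p[2] <= hull_y[2]
    if (!inside(from) || !inside(to))
      stop("'from' and 'to' must lie within the diagram's (Tx, Ty) grid hull",
           call. = FALSE)
  } else if (inherits(diagram, "bimatrix_game")) {
    game <- diagram
  } else stop("'diagram' must be a phase_diagram or a bimatrix_game",
              call. = FALSE)
  stopifnot(length(from) == 2L, length(to) == 2L, n_steps >= 2L)
  if (any(c(from, to) <= 0))
    stop("path endpoints must have positive rates", call. = FALSE)

  al <- seq(0, 1, length.out = n_steps)
  Txs <- from[1] + al * (to[1] - from[1])
  Tys <- from[2] + al * (to[2] - from[2])
  occ_u <- occ_v <- rep(NA_real_, n_steps)
  n_st <- rep(NA_integer_, n_steps)
  coup <- rep(NA_character_, n_steps)
  forced <- rep(FALSE, n_steps)
  prev <- NULL
  for (k in seq_len(n_steps)) {
    fps <- .fps_or_null(game, exploration_rates(Txs[k], Tys[k]), seed = seed)
    if (is.null(fps)) next
    stab <- fps[fps$stability == "stable", , drop = FALSE]
    n_st[k] <- nrow(stab)
    if (!nrow(stab)) next
    if (is.null(prev)) {
      j <- if (!is.null(state0)) {
        which.min(pmax(abs(stab$x_glucose - state0$x[1]),
                       abs(stab$y_glucose - state0$y[1])))
      } else which.max(stab$y_lactate)
    } else {
      d <- pmax(abs(stab$x_glucose - prev[1]), abs(stab$y_glucose - prev[2]))
      j <- which.min(d)
      if (d[j] > jump_tol) forced[k] <- TRUE
    }
    prev <- c(stab$x_glucose[j], stab$y_glucose[j])
    occ_u[k] <- stab$x_glucose[j]; occ_v[k] <- stab$y_glucose[j]
    coup[k] <- classify_coupling(stab[j, , drop = FALSE])
  }
  out <- data.frame(step = seq_len(n_steps), Tx = Txs, Ty = Tys,
                    n_stable = n_st, x_glucose = occ_u,
                    y_lactate = 1 - occ_v, coupling = coup,
                    forced_transition = forced, stringsAsFactors = FALSE)
  class(out) <- c("therapy_path", "data.frame")
  attr(out, "game") <- game
  out
}

#' @export
print.therapy_path <- function(x, ...) {
  cat(sprintf("Therapy path (%g, %g) -> (%g, %g), %d steps\n",
              x$Tx[1], x$Ty[1], x$Tx[nrow(x)], x$Ty[nrow(x)], nrow(x)))
  nf <- sum(x$forced_transition, na.rm = TRUE)
  if (nf) cat(sprintf("forced critical transitions at step(s): %s\n",
                      paste(which(x$forced_transition), collapse = ", ")))
  else cat("no forced critical transition along the path\n")
  cat(sprintf("coupling: %s\n",
              paste(rle(x$coupling[!is.na(x$coupling)])$values,
                    collapse = " -> ")))
  invisible(x)
}
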