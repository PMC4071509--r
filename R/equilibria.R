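#' Boltzmann (logit) response to a payoff vector
#'
#' The probability of selecting metabolic pathway `i` is proportional to
#' `exp(r_i / T)`.  `T` trades exploration against exploitation: as `T -> 0`
#' the response concentrates on the payoff argmax, as `T -> Inf` it tends to
#' uniform.  Computed with max-subtraction so large payoff/`T` ratios cannot
#' overflow.
#'
#' @param rewards finite numeric payoff vector.
#' @param T strictly positive exploration rate (the `T = 0` limit is handled
#'   by pure Nash / vertex analysis, not here).
#' @return A probability vector of the same length, strictly positive and
#'   summing to 1 exactly (up to one final normalisation).
#' @examples
#' boltzmann_response(c(2, 0), T = 1)   # exp(2)/(exp(2)+1), 1/(exp(2)+1)
#' @export
boltzmann_response <- function(rewards, T) {
  if (!is.numeric(rewards) || any(!is.finite(rewards)))
    stop("'rewards' must be finite numeric", call. = FALSE)
  T <- .check_scalar(T, "T")
  if (T <= 0) stop("'T' must be strictly positive", call. = FALSE)
  z <- rewards / T
  w <- exp(z - max(z))
  w / sum(w)
}

#' Self-consistency defect of a state under the mutual Boltzmann map
#'
#' Interior fixed points of the coupled replicator-exploration dynamics are
#' exactly the states where each population's mix equals the Boltzmann
#' response to its expected payoffs: `x = boltzmann_response(A y, Tx)` and
#' `y = boltzmann_response(B x, Ty)`.  This returns the max-norm of the
#' defect, which is zero precisely at interior fixed points of the flow.
#'
#' @param state an interior [population_state()].
#' @param game a [bimatrix_game()].
#' @param rates [exploration_rates()] with both rates strictly positive.
#' @return A non-negative scalar.
#' @export
fixed_point_residual <- function(state, game, rates) {
  stopifnot(inherits(state, "population_state"),
            inherits(game, "bimatrix_game"))
  rates <- .as_rates(rates)
  if (rates$Tx <= 0 || rates$Ty <= 0)
    stop("fixed_point_residual requires Tx > 0 and Ty > 0", call. = FALSE)
  max(abs(c(state$x - boltzmann_response(drop(game$A %*% state$y), rates$Tx),
            state$y - boltzmann_response(drop(game$B %*% state$x), rates$Ty))))
}

#' Jacobian of the reduced two-dimensional dynamics
#'
#' In reduced coordinates `(u, v) = (x_glucose, y_glucose)` with
#' `x_lactate = 1 - u`, `y_lactate = 1 - v`, the flow is
#' `du/dt = u(1-u) (Dx(v) + Tx log((1-u)/u))` (and symmetrically for `v`),
#' where `Dx(v)` is the payoff gap between the two hypoxic actions.  The
#' partial derivatives are analytic:
#' `d(du)/du = (1-2u)(Dx + Tx log((1-u)/u)) - Tx`,
#' `d(du)/dv = u(1-u) Dx'`.
#'
#' @inheritParams fixed_point_residual
#' @return A 2x2 numeric matrix, rows/columns ordered `(u, v)`.
#' @export
reduced_jacobian <- function(state, game, rates) {
  stopifnot(inherits(state, "population_state"),
            inherits(game, "bimatrix_game"))
  rates <- .as_rates(rates)
  if (any(c(state$x, state$y) <= 0))
    stop("reduced_jacobian requires a strictly interior state", call. = FALSE)
  da <- game$A[1, ] - game$A[2, ]; dda <- da[1] - da[2]
  db <- game$B[1, ] - game$B[2, ]; ddb <- db[1] - db[2]
  u <- state$x[1]; mu <- state$x[2]
  v <- state$y[1]; mv <- state$y[2]
  Dx <- da[2] + dda * v
  Dy <- db[2] + ddb * u
  J11 <- (mu - u) * (Dx + rates$Tx * (log(mu) - log(u))) - rates$Tx
  J22 <- (mv - v) * (Dy + rates$Ty * (log(mv) - log(v))) - rates$Ty
  matrix(c(J11, v * mv * ddb, u * mu * dda, J22), 2, 2,
         dimnames = list(c("du", "dv"), c("u", "v")))
}

# --- multi-start solver internals -----------------------------------------
#
# The root search runs in logit coordinates z = (zx, zy) with
# u = sigma(zx), v = sigma(zy).  Fixed points satisfy zx = Dx(v)/Tx and
# zy = Dy(u)/Ty; near-vertex roots (small T) have |z| of order max|payoff|/T
# and are represented exactly where probability coordinates would round to
# 0/1.  The solver combines a vectorised mutual-Boltzmann fixed-point
# pre-pass (a contraction in the mono-stable and saturated regimes, finding
# stable roots) with a vectorised damped Newton iteration from the raw
# starts (which also converges to the unstable saddle of bistable regimes).

.fp_resid_z <- function(zx, zy, da2, dda, db2, ddb, Tx, Ty) {
  list(F1 = zx - (da2 + dda * .sigma(zy)) / Tx,
       F2 = zy - (db2 + ddb * .sigma(zx)) / Ty)
}

.fp_newton <- function(zx, zy, da2, dda, db2, ddb, Tx, Ty,
                       max_iter = 80L, tol = 1e-13) {
  n <- length(zx)
  idx <- seq_len(n)                      # indices still being iterated
  for (it in seq_len(max_iter)) {
    ax <- zx[idx]; ay <- zy[idx]
    Fv <- .fp_resid_z(ax, ay, da2, dda, db2, ddb, Tx, Ty)
    nrm <- pmax(abs(Fv$F1), abs(Fv$F2))
    live <- is.finite(nrm) & nrm > tol * pmax(1, abs(ax), abs(ay))
    idx <- idx[live]
    if (!length(idx)) break
    ax <- ax[live]; ay <- ay[live]
    F1 <- Fv$F1[live]; F2 <- Fv$F2[live]; nrm <- nrm[live]
    J12 <- -dda * .dsigma(ay) / Tx        # dF1/dzy
    J21 <- -ddb * .dsigma(ax) / Ty        # dF2/dzx
    det <- 1 - J12 * J21
    sing <- abs(det) < 1e-12
    d1 <- ifelse(sing, F1, (F1 - J12 * F2) / det)
    d2 <- ifelse(sing, F2, (F2 - J21 * F1) / det)
    d1 <- pmin(pmax(d1, -1e7), 1e7)
    d2 <- pmin(pmax(d2, -1e7), 1e7)
    # damped step: halve until the residual norm does not increase
    lam <- rep(1, length(idx))
    zx_t <- ax - d1; zy_t <- ay - d2
    for (h in seq_len(25L)) {
      Ft <- .fp_resid_z(zx_t, zy_t, da2, dda, db2, ddb, Tx, Ty)
      nt <- pmax(abs(Ft$F1), abs(Ft$F2))
      bad <- !is.finite(nt) | nt > nrm
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
      zx_t[bad] <- ax[bad] - lam[bad] * d1[bad]
      zy_t[bad] <- ay[bad] - lam[bad] * d2[bad]
    }
    zx[idx] <- zx_t; zy[idx] <- zy_t
  }
  Fv <- .fp_resid_z(zx, zy, da2, dda, db2, ddb, Tx, Ty)
  nrm <- pmax(abs(Fv$F1), abs(Fv$F2))
  ok <- is.finite(nrm) & nrm <= 1e-11 * pmax(1, abs(zx), abs(zy))
  list(zx = zx[ok], zy = zy[ok])
}

.fp_picard <- function(zx, zy, da2, dda, db2, ddb, Tx, Ty, n_iter = 100L) {
  idx <- seq_along(zx)
  for (it in seq_len(n_iter)) {
    ax <- zx[idx]; ay <- zy[idx]
    zx_n <- (da2 + dda * .sigma(ay)) / Tx
    zy_n <- (db2 + ddb * .sigma(ax)) / Ty
    moved <- pmax(abs(zx_n - ax), abs(zy_n - ay)) >
      1e-14 * pmax(1, abs(zx_n), abs(zy_n))
    zx[idx] <- zx_n; zy[idx] <- zy_n
    idx <- idx[moved]
    if (!length(idx)) break
  }
  list(zx = zx, zy = zy)
}

#' Locate all interior fixed points at given exploration rates
#'
#' Multi-start root search on the mutual Boltzmann self-consistency system
#' in reduced logit coordinates: a deterministic 11x11 grid on
#' `(x_glucose, y_glucose) in [0.02, 0.98]^2` plus `n_starts` seeded random
#' starts, each polished by damped Newton iteration (with a contraction-map
#' pre-pass), deduplicated at distance `1e-6` in probability coordinates,
#' and classified by the eigenvalues of the reduced Jacobian.  Working in
#' logit coordinates keeps near-vertex roots (small `T`) exactly
#' representable and the self-consistency system well conditioned.
#'
#' @param game a [bimatrix_game()].
#' @param rates [exploration_rates()] with `Tx > 0`, `Ty > 0`.
#' @param n_starts number of seeded random starts added to the grid.
#' @param seed integer seed for the random starts.
#' @param grid_n side length of the deterministic start grid.
#' @param dedup_tol roots closer than this (max-norm on `(u, v)`) are merged.
#' @param tol_eig eigenvalue real parts within `tol_eig` of zero give the
#'   `"marginal"` classification (these occur exactly at folds).
#' @return A data frame of class `"fixed_points"`, sorted by `x_glucose`,
#'   with columns `x_glucose`, `x_lactate`, `y_glucose`, `y_lactate`,
#'   `zx`, `zy` (logit coordinates), `residual` (self-consistency defect,
#'   max-norm), `lambda1_re`, `lambda1_im`, `lambda2_re`, `lambda2_im` and
#'   `stability` (`"stable"`, `"unstable"` or `"marginal"`).
#' @examples
#' g <- build_symbiosis_game(metabolic_yields())
#' find_fixed_points(g, exploration_rates(2, 0.5))   # bistable: 3 roots
#' @export
find_fixed_points <- function(game, rates, n_starts = 50, seed = 1,
                              grid_n = 11, dedup_tol = 1e-6, tol_eig = 1e-8) {
  stopifnot(inherits(game, "bimatrix_game"))
  rates <- .as_rates(rates)
  if (rates$Tx <= 0 || rates$Ty <= 0)
    stop("find_fixed_points requires Tx > 0 and Ty > 0 (use pure_nash / ",
         "nash_limit_check for the T = 0 limit)", call. = FALSE)
  da <- game$A[1, ] - game$A[2, ]; dda <- unname(da[1] - da[2])
  db <- game$B[1, ] - game$B[2, ]; ddb <- unname(db[1] - db[2])
  da2 <- unname(da[2]); db2 <- unname(db[2])
  Tx <- rates$Tx; Ty <- rates$Ty

  gr <- seq(0.02, 0.98, length.out = grid_n)
  starts <- as.matrix(expand.grid(u = gr, v = gr))
  if (n_starts > 0) {
    extra <- .with_seed(.substream_seed(seed, "root-search"),
                        matrix(stats::runif(2 * n_starts), ncol = 2))
    starts <- rbind(starts, extra)
  }
  z0x <- stats::qlogis(starts[, 1]); z0y <- stats::qlogis(starts[, 2])

  pic <- .fp_picard(z0x, z0y, da2, dda, db2, ddb, Tx, Ty)
  new <- .fp_newton(c(z0x, pic$zx), c(z0y, pic$zy),
                    da2, dda, db2, ddb, Tx, Ty)
  zx <- new$zx; zy <- new$zy
  if (length(zx) == 0L)
    stop("no fixed point converged; this should be impossible for finite ",
         "payoffs and positive rates - please report the game and rates",
         call. = FALSE)

  dedup <- function(zx, zy) {
    u <- .sigma(zx); v <- .sigma(zy)
    keep_zx <- numeric(0); keep_zy <- numeric(0)
    ord <- order(u, v)
    for (k in ord) {
      if (length(keep_zx) == 0L ||
          all(pmax(abs(.sigma(keep_zx) - u[k]),
                   abs(.sigma(keep_zy) - v[k])) > dedup_tol)) {
        keep_zx <- c(keep_zx, zx[k]); keep_zy <- c(keep_zy, zy[k])
      }
    }
    list(zx = keep_zx, zy = keep_zy)
  }
  roots <- dedup(zx, zy)

  # generic 2x2 systems have an odd number of interior roots; an even count
  # signals a missed saddle - retry from midpoints between found roots
  if (length(roots$zx) %% 2L == 0L && length(roots$zx) >= 2L) {
    u <- sort(.sigma(roots$zx))
    mids <- stats::qlogis(pmin(pmax((u[-1] + u[-length(u)]) / 2,
                                    1e-12), 1 - 1e-12))
    midv <- stats::qlogis(rep(0.5, length(mids)))
    new2 <- .fp_newton(c(roots$zx, mids), c(roots$zy, midv),
                       da2, dda, db2, ddb, Tx, Ty)
    roots <- dedup(new2$zx, new2$zy)
  }

  u <- .sigma(roots$zx);  mu <- .sigma(-roots$zx)
  v <- .sigma(roots$zy);  mv <- .sigma(-roots$zy)
  n <- length(u)
  lam1 <- lam2 <- complex(n)
  residual <- numeric(n)
  stability <- character(n)
  for (k in seq_len(n)) {
    st <- population_state(c(u[k], mu[k]), c(v[k], mv[k]))
    residual[k] <- fixed_point_residual(st, game, rates)
    Dx <- da2 + dda * v[k]; Dy <- db2 + ddb * u[k]
    J11 <- (mu[k] - u[k]) * (Dx - Tx * roots$zx[k]) - Tx
    J22 <- (mv[k] - v[k]) * (Dy - Ty * roots$zy[k]) - Ty
    J <- matrix(c(J11, v[k] * mv[k] * ddb, u[k] * mu[k] * dda, J22), 2, 2)
    ev <- eigen(J, only.values = TRUE)$values
    ev <- as.complex(ev)
    lam1[k] <- ev[1]; lam2[k] <- ev[2]
    re <- Re(ev)
    stability[k] <- if (any(abs(re) < tol_eig)) "marginal"
                    else if (all(re < 0)) "stable" else "unstable"
  }
  out <- data.frame(
    x_glucose = u, x_lactate = mu, y_glucose = v, y_lactate = mv,
    zx = roots$zx, zy = roots$zy, residual = residual,
    lambda1_re = Re(lam1), lambda1_im = Im(lam1),
    lambda2_re = Re(lam2), lambda2_im = Im(lam2),
    stability = stability, stringsAsFactors = FALSE)
  out <- out[order(out$x_glucose), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("fixed_points", "data.frame")
  attr(out, "game") <- game
  attr(out, "rates") <- rates
  out
}

#' @export
print.fixed_points <- function(x, ...) {
  r <- attr(x, "rates")
  cat(sprintf("Fixed points at Tx = %g, Ty = %g (%d found: %d stable, %d unstable, %d marginal)\n",
              r$Tx, r$Ty, nrow(x), sum(x$stability == "stable"),
              sum(x$stability == "unstable"), sum(x$stability == "marginal")))
  print.data.frame(
    data.frame(x_glucose = signif(x$x_glucose, 6),
               y_lactate = signif(x$y_lactate, 6),
               residual = signif(x$residual, 3),
               re_lambda1 = signif(x$lambda1_re, 6),
               re_lambda2 = signif(x$lambda2_re, 6),
               stability = x$stability),
    row.names = FALSE)
  invisible(x)
}

#' Verify the small-T limit: stable fixed points approach strict pure Nash
#'
#' At `Tx = Ty = 0` the stable rest points of the coupled replicator
#' dynamics are Nash equilibria.  This check takes every strict pure Nash
#' equilibrium of the game and verifies that at small positive exploration
#' rates a stable fixed point exists near the corresponding simplex vertex,
#' and that the distance shrinks when the rate is halved.
#'
#' @param game a [bimatrix_game()] .
#' @param T_small small positive rate; default `1e-3 * max(|payoff|)`.
#' @param seed seed passed to [find_fixed_points()].
#' @return A data frame of class `"nash_limit_check"` with one row per
#'   (strict equilibrium, rate) pair: columns `hypoxic`, `oxygenated`
#'   (action indices), `T`, `distance` (max-norm from the vertex to the
#'   nearest stable fixed point).  Zero rows when the game has no strict
#'   pure Nash equilibrium.
#' @export
nash_limit_check <- function(game, T_small = NULL, seed = 1) {
  stopifnot(inherits(game, "bimatrix_game"))
  if (is.null(T_small))
    T_small <- 1e-3 * max(abs(c(game$A, game$B)), 1e-8)
  T_small <- .check_scalar(T_small, "T_small", positive = TRUE)
  eq <- pure_nash(game)
  eq <- eq[!eq$weak, , drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(eq))) {
    vert <- c(u = as.numeric(eq$hypoxic[k] == 1L),
              v = as.numeric(eq$oxygenated[k] == 1L))
    for (Tk in c(T_small, T_small / 2)) {
      fps <- find_fixed_points(game, exploration_rates(Tk, Tk), seed = seed)
      stab <- fps[fps$stability == "stable", , drop = FALSE]
      d <- if (nrow(stab)) min(pmax(abs(stab$x_glucose - vert["u"]),
                                    abs(stab$y_glucose - vert["v"]))) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        hypoxic = eq$hypoxic[k], oxygenated = eq$oxygenated[k],
        T = Tk, distance = d)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hypoxic = integer(), oxygenated = integer(),
               T = numeric(), distance = numeric())
  rownames(out) <- NULL
  class(out) <- c("nash_limit_check", "data.frame")
  attr(out, "game") <- game
  out
}
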