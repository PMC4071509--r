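fd_jacobian <- function(state, game, rates, h = 1e-7) {
  # central differences on the reduced flow (du/dt, dv/dt)
  red <- function(u, v) {
    f <- replicator_exploration_field(
      population_state(c(u, 1 - u), c(v, 1 - v)), game, rates)
    c(f$dx[1], f$dy[1])
  }
  u <- state$x[1]; v <- state$y[1]
  cbind((red(u + h, v) - red(u - h, v)) / (2 * h),
        (red(u, v + h) - red(u, v - h)) / (2 * h))
}

test_that("Boltzmann response: symmetry, closed form, and limits", {
  expect_equal(boltzmann_response(c(1, 1, 1), T = 2), rep(1 / 3, 3))
  expect_equal(boltzmann_response(c(2, 0), T = 1),
               c(exp(2) / (exp(2) + 1), 1 / (exp(2) + 1)), tolerance = 1e-15)
  expect_lt(max(abs(boltzmann_response(c(5, -3), T = 1e6) - 0.5)), 1e-5)
  # overflow safety at tiny T
  p <- boltzmann_response(c(1000, 0), T = 1e-3)
  expect_equal(sum(p), 1)
  expect_true(all(is.finite(p)))
  expect_error(boltzmann_response(c(1, 0), T = 0), "positive")
  expect_error(boltzmann_response(c(1, 0), T = -1), "positive")
})

test_that("self-consistency residual is zero exactly at fixed points", {
  g <- default_game()
  r <- exploration_rates(1.2, 0.6)
  fps <- find_fixed_points(g, r)
  for (k in seq_len(nrow(fps))) {
    st <- population_state(c(fps$x_glucose[k], fps$x_lactate[k]),
                           c(fps$y_glucose[k], fps$y_lactate[k]))
    expect_lt(fixed_point_residual(st, g, r), 1e-10)
    f <- replicator_exploration_field(st, g, r)
    expect_lt(max(abs(c(f$dx, f$dy))), 1e-10)
  }
  # strictly positive away from fixed points: uniform with unequal rewards
  st <- population_state(c(0.5, 0.5), c(0.5, 0.5))
  expect_gt(fixed_point_residual(st, g, r), 1e-3)
})

test_that("residual and field norm vanish together on random games", {
  set.seed(21)
  for (rep in 1:25) {
    g <- random_game(seed = 3000 + rep, payoff_range = c(-1, 2))
    r <- exploration_rates(runif(1, 0.1, 2), runif(1, 0.1, 2))
    fps <- find_fixed_points(g, r)
    for (k in seq_len(nrow(fps))) {
      st <- population_state(c(fps$x_glucose[k], fps$x_lactate[k]),
                             c(fps$y_glucose[k], fps$y_lactate[k]))
      expect_lt(fixed_point_residual(st, g, r), 1e-10)
      f <- replicator_exploration_field(st, g, r)
      expect_lt(max(abs(c(f$dx, f$dy))), 1e-10)
    }
    st <- random_interior_state()
    res <- fixed_point_residual(st, g, r)
    f <- replicator_exploration_field(st, g, r)
    # a generic random state is far from equilibrium in both measures
    if (res > 1e-4) expect_gt(max(abs(c(f$dx, f$dy))), 1e-12)
  }
})

test_that("the default game is bistable at moderate Tx and small Ty", {
  fps <- find_fixed_points(default_game(), exploration_rates(2, 0.5))
  expect_equal(nrow(fps), 3L)
  expect_equal(sum(fps$stability == "stable"), 2L)
  expect_equal(sum(fps$stability == "unstable"), 1L)
  # the saddle separates the two stable states in oxygenated coordinate
  ord <- order(fps$y_lactate)
  expect_equal(fps$stability[ord], c("stable", "unstable", "stable"))
})

test_that("stability labels agree with perturbed long-time integration", {
  g <- default_game()
  r <- exploration_rates(2, 0.5)
  fps <- find_fixed_points(g, r)
  stab <- fps[fps$stability == "stable", ]
  saddle <- fps[fps$stability == "unstable", ]
  for (k in seq_len(nrow(stab))) {
    # nudge each coordinate towards the simplex centre to stay interior
    du <- ifelse(stab$x_glucose[k] > 0.5, -1e-3, 1e-3)
    dv <- ifelse(stab$y_glucose[k] > 0.5, -1e-3, 1e-3)
    st <- population_state(
      c(stab$x_glucose[k] + du, stab$x_lactate[k] - du),
      c(stab$y_glucose[k] + dv, stab$y_lactate[k] - dv))
    tr <- integrate_dynamics(st, g, r, t_end = 200)
    term <- attr(tr, "terminal_state")
    expect_lt(abs(term$x[1] - stab$x_glucose[k]), 1e-5)
    expect_lt(abs(term$y[1] - stab$y_glucose[k]), 1e-5)
  }
  # perturbing the saddle leads away from it
  st <- population_state(c(saddle$x_glucose, saddle$x_lactate),
                         c(saddle$y_glucose + 1e-3, saddle$y_lactate - 1e-3))
  tr <- integrate_dynamics(st, g, r, t_end = 300)
  expect_gt(abs(attr(tr, "terminal_state")$y[1] - saddle$y_glucose), 0.1)
})

test_that("high-T contraction: unique fixed point near uniform", {
  g <- default_game()
  maxpay <- max(abs(c(g$A, g$B)))
  # at T = 100 * max payoff the deviation obeys the logit law |u - 1/2|
  # <= max payoff gap / (4T); uniqueness holds by contraction
  fps <- find_fixed_points(g, exploration_rates(100 * maxpay, 100 * maxpay))
  expect_equal(nrow(fps), 1L)
  gap_x <- max(abs(g$A[1, ] - g$A[2, ]))
  gap_y <- max(abs(g$B[1, ] - g$B[2, ]))
  expect_lt(abs(fps$x_glucose - 0.5), gap_x / (4 * 100 * maxpay) * 1.01)
  expect_lt(abs(fps$y_glucose - 0.5), gap_y / (4 * 100 * maxpay) * 1.01)
  # far enough into the high-T regime the state is uniform to 1e-4
  fps2 <- find_fixed_points(g, exploration_rates(1e4 * maxpay, 1e4 * maxpay))
  expect_equal(nrow(fps2), 1L)
  expect_lt(max(abs(c(fps2$x_glucose, fps2$y_glucose) - 0.5)), 1e-4)
})

test_that("T = 0 is rejected by the fixed-point solver", {
  expect_error(find_fixed_points(default_game(), exploration_rates(0, 1)),
               "Tx > 0")
})

test_that("generic parameter draws give an odd number of fixed points", {
  set.seed(22)
  n_checked <- 0
  for (rep in 1:60) {
    g <- random_game(seed = 4000 + rep, payoff_range = c(-2, 2))
    r <- exploration_rates(runif(1, 0.05, 1.5), runif(1, 0.05, 1.5))
    fps <- find_fixed_points(g, r)
    if (any(fps$stability == "marginal")) next   # degenerate (at a fold)
    n_checked <- n_checked + 1
    expect_equal(nrow(fps) %% 2L, 1L,
                 info = sprintf("game %d: %d roots", rep, nrow(fps)))
  }
  expect_gt(n_checked, 40)
})

test_that("analytic reduced Jacobian matches central finite differences", {
  set.seed(23)
  for (rep in 1:30) {
    g <- random_game(seed = 5000 + rep, payoff_range = c(-1, 2))
    r <- exploration_rates(runif(1, 0.2, 2), runif(1, 0.2, 2))
    st <- random_interior_state()
    J <- reduced_jacobian(st, g, r)
    Jfd <- fd_jacobian(st, g, r)
    expect_equal(unname(J), unname(Jfd), tolerance = 1e-6)
  }
})

test_that("Jacobian of a symmetric game commutes with the population swap", {
  A <- rbind(c(1, 0), c(0, 1))
  g <- bimatrix_game(A, A)                     # coordination game, B = A
  r <- exploration_rates(0.3, 0.3)
  fps <- find_fixed_points(g, r)
  sym <- fps[abs(fps$x_glucose - fps$y_glucose) < 1e-10, ]
  expect_gt(nrow(sym), 0)
  st <- population_state(c(sym$x_glucose[1], sym$x_lactate[1]),
                         c(sym$y_glucose[1], sym$y_lactate[1]))
  J <- reduced_jacobian(st, g, r)
  expect_equal(J[1, 1], J[2, 2], tolerance = 1e-12)
  expect_equal(J[1, 2], J[2, 1], tolerance = 1e-12)
})

test_that("converged trajectories end where the Jacobian is contracting", {
  g <- default_game()
  r <- exploration_rates(1, 1)
  tr <- integrate_dynamics(population_state(c(0.4, 0.6), c(0.6, 0.4)), g, r,
                           t_end = 300)
  term <- attr(tr, "terminal_state")
  ev <- eigen(reduced_jacobian(term, g, r), only.values = TRUE)$values
  expect_true(all(Re(ev) < 0))
})

test_that("small-T stable fixed points converge to the strict pure Nash", {
  chk <- nash_limit_check(default_game())
  expect_equal(nrow(chk), 2L)            # one strict Nash, two T values
  expect_equal(unique(chk$hypoxic), 1L)  # hypoxic glucose
  expect_equal(unique(chk$oxygenated), 2L)  # oxygenated lactate
  expect_true(all(chk$distance < 1e-6))
  expect_lte(chk$distance[2], chk$distance[1])   # shrinks as T halves

  # a game with no strict pure Nash yields an empty report
  zero <- bimatrix_game(matrix(0, 2, 2), matrix(0, 2, 2))
  expect_equal(nrow(nash_limit_check(zero, T_small = 0.01)), 0L)
})

test_that("fixed points survive a config round-trip to 1e-12", {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  for (s in c(31, 32, 33)) {
    g <- random_game(seed = s, payoff_range = c(0, 3))
    grid1 <- list(min = 0.5, max = 8, n = 11L, log = TRUE)
    cfg <- list(rates = list(Tx = 0.7, Ty = 0.9), seed = 1L,
                game = g,
                sweep = list(parameter = "Tx", fixed_value = 0.5, grid = grid1),
                phase = list(Tx = grid1, Ty = grid1),
                basins = list(resolution = 21L),
                tolerances = list(fp = 1e-12, field = 1e-10, eig = 1e-8),
                output = list(dir = ".", timestamp = TRUE))
    save_config(cfg, tmp)
    back <- load_config(tmp)
    f1 <- find_fixed_points(g, exploration_rates(0.7, 0.9))
    f2 <- find_fixed_points(back$game, back$rates)
    expect_equal(f1$x_glucose, f2$x_glucose, tolerance = 1e-12)
    expect_equal(f1$y_glucose, f2$y_glucose, tolerance = 1e-12)
  }
})
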