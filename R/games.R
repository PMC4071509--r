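#' ATP yield parameters of the tumour metabolic symbiosis game
#'
#' Bundles the three ATP yields that parameterise the glucose/lactate game
#' between the hypoxic and oxygenated tumour subpopulations.  The defaults
#' follow the classical stoichiometry: anaerobic glycolysis nets 2 mol ATP
#' per mol glucose, while full oxidation of the 2 mol lactate produced from
#' one glucose yields about 36 mol ATP.  `G_o`, the aerobic glucose yield of
#' an oxygenated cell, is a configurable default (36, the same aerobic yield
#' per glucose as per 2 lactate); the empirical validity condition of the
#' model is `L > G_o/2` (see [check_symbiosis_condition()]).
#'
#' @param G_h ATP yield of a hypoxic cell metabolising glucose (mol ATP per
#'   encounter).
#' @param G_o ATP yield of an oxygenated cell metabolising glucose.
#' @param L ATP yield of an oxygenated cell respiring lactate.
#' @return An object of class `"metabolic_yields"`.
#' @examples
#' metabolic_yields()            # default tumour stoichiometry
#' metabolic_yields(G_h = 4, G_o = 30, L = 28)
#' @seealso [build_symbiosis_game()], [check_symbiosis_condition()]
#' @export
metabolic_yields <- function(G_h = 2, G_o = 36, L = 36) {
  structure(list(
    G_h = .check_scalar(G_h, "G_h", positive = TRUE),
    G_o = .check_scalar(G_o, "G_o", positive = TRUE),
    L   = .check_scalar(L, "L", positive = TRUE)
  ), class = "metabolic_yields")
}

#' @export
print.metabolic_yields <- function(x, ...) {
  cat("Metabolic ATP yields (mol ATP per encounter)\n")
  cat(sprintf("  G_h (hypoxic, glucose)    : %g\n", x$G_h))
  cat(sprintf("  G_o (oxygenated, glucose) : %g\n", x$G_o))
  cat(sprintf("  L   (oxygenated, lactate) : %g\n", x$L))
  cat(sprintf("  symbiosis condition L > G_o/2 : %s\n",
              if (x$L > x$G_o / 2) "holds" else "VIOLATED"))
  invisible(x)
}

#' Construct a 2x2 bimatrix game between the two tumour subpopulations
#'
#' Both matrices are indexed own-action x opponent-action, so the expected
#' payoff of the hypoxic (row) population is `A %*% y` and that of the
#' oxygenated (column) population is `B %*% x`.  Action index 1 is glucose,
#' index 2 is lactate, for both populations.
#'
#' @param A 2x2 numeric payoff matrix of the hypoxic population; `A[i, j]` is
#'   the hypoxic payoff for playing action `i` against oxygenated action `j`.
#' @param B 2x2 numeric payoff matrix of the oxygenated population, indexed by
#'   its own action first: `B[i, j]` is the oxygenated payoff for playing `i`
#'   against hypoxic action `j`.
#' @param actions character vector of length 2 with the action labels.
#' @return An object of class `"bimatrix_game"`.
#' @export
bimatrix_game <- function(A, B, actions = c("glucose", "lactate")) {
  for (nm in c("A", "B")) {
    M <- get(nm)
    if (!is.matrix(M) || !identical(dim(M), c(2L, 2L)) || !is.numeric(M) ||
        any(!is.finite(M)))
      stop(sprintf("'%s' must be a finite numeric 2x2 matrix", nm),
           call. = FALSE)
  }
  if (length(actions) != 2L) stop("'actions' must have length 2", call. = FALSE)
  dimnames(A) <- list(hypoxic = actions, oxygenated = actions)
  dimnames(B) <- list(oxygenated = actions, hypoxic = actions)
  structure(list(A = A, B = B, actions = as.character(actions)),
            class = "bimatrix_game")
}

#' @export
print.bimatrix_game <- function(x, ...) {
  cat("2x2 bimatrix game (rows = own action, columns = opponent action)\n")
  cat("A (hypoxic payoffs):\n"); print(x$A)
  cat("B (oxygenated payoffs):\n"); print(x$B)
  invisible(x)
}

#' Build the tumour metabolic symbiosis game from ATP yields
#'
#' Payoff construction: when both populations use glucose the glucose yield
#' is shared (`G_h/2`, `G_o/2`); a hypoxic cell keeps the full `G_h` when the
#' oxygenated population is on lactate; hypoxic cells cannot metabolise
#' lactate, so the hypoxic lactate row is zero; an oxygenated cell on lactate
#' earns `L` only while the hypoxic population performs glycolysis, because
#' hypoxic glycolysis is the sole lactate source in the tumour.
#'
#' @param yields a [metabolic_yields()] object.
#' @return A `"bimatrix_game"` with
#'   `A = rbind(c(G_h/2, G_h), c(0, 0))` and
#'   `B = rbind(c(G_o/2, G_o), c(L, 0))`.
#' @examples
#' g <- build_symbiosis_game(metabolic_yields())
#' pure_nash(g)
#' @export
build_symbiosis_game <- function(yields = metabolic_yields()) {
  if (!inherits(yields, "metabolic_yields"))
    yields <- do.call(metabolic_yields, as.list(yields))
  A <- rbind(c(yields$G_h / 2, yields$G_h),
             c(0,              0))
  B <- rbind(c(yields$G_o / 2, yields$G_o),
             c(yields$L,       0))
  g <- bimatrix_game(A, B)
  attr(g, "yields") <- yields
  g
}

#' Does the empirical symbiosis condition L > G_o/2 hold?
#'
#' When the lactate yield exceeds half the aerobic glucose yield, the
#' symbiosis game has a unique pure Nash equilibrium (hypoxic glycolysis,
#' oxygenated lactate respiration).  When the condition fails that uniqueness
#' claim is void and a warning is emitted.
#'
#' @param yields a [metabolic_yields()] object.
#' @return `TRUE` iff `L > G_o/2` strictly.
#' @export
check_symbiosis_condition <- function(yields) {
  if (!inherits(yields, "metabolic_yields"))
    yields <- do.call(metabolic_yields, as.list(yields))
  ok <- yields$L > yields$G_o / 2
  if (!ok)
    warning("L <= G_o/2: the unique-pure-Nash property of the symbiosis game ",
            "does not hold for these yields", call. = FALSE)
  ok
}

#' Enumerate the pure Nash equilibria of a 2x2 bimatrix game
#'
#' Checks all four pure strategy profiles for the no-unilateral-improvement
#' condition.  Weak equilibria - profiles where some deviation yields exactly
#' the same payoff - are included and flagged in the `weak` column.
#'
#' @param game a [bimatrix_game()].
#' @return A data frame of class `"pure_nash"` with one row per equilibrium
#'   and columns `hypoxic`, `oxygenated` (action indices, 1 = glucose),
#'   `hypoxic_action`, `oxygenated_action` (labels), `payoff_hypoxic`,
#'   `payoff_oxygenated` and `weak`.  Zero rows if no pure equilibrium exists.
#' @examples
#' pure_nash(build_symbiosis_game(metabolic_yields(G_h = 2, G_o = 36, L = 36)))
#' @export
pure_nash <- function(game) {
  stopifnot(inherits(game, "bimatrix_game"))
  A <- game$A; B <- game$B
  rows <- list()
  for (i in 1:2) for (j in 1:2) {
    # hypoxic plays i vs oxygenated j; oxygenated plays j vs hypoxic i
    row_ok <- A[i, j] >= A[3 - i, j]
    col_ok <- B[j, i] >= B[3 - j, i]
    if (row_ok && col_ok) {
      weak <- (A[i, j] == A[3 - i, j]) || (B[j, i] == B[3 - j, i])
      rows[[length(rows) + 1L]] <- data.frame(
        hypoxic = i, oxygenated = j,
        hypoxic_action = game$actions[i], oxygenated_action = game$actions[j],
        payoff_hypoxic = A[i, j], payoff_oxygenated = B[j, i],
        weak = weak, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(hypoxic = integer(), oxygenated = integer(),
               hypoxic_action = character(), oxygenated_action = character(),
               payoff_hypoxic = numeric(), payoff_oxygenated = numeric(),
               weak = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("pure_nash", "data.frame")
  attr(out, "game") <- game
  out
}

#' @export
print.pure_nash <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("No pure Nash equilibrium.\n")
  } else {
    cat(sprintf("%d pure Nash equilibri%s:\n", nrow(x),
                if (nrow(x) == 1L) "um" else "a"))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Draw a random 2x2 bimatrix game
#'
#' Fixture generator for property testing: both payoff matrices have i.i.d.
#' uniform entries on `payoff_range`.  Reproducible - the same seed always
#' yields the same game - and leaves the caller's RNG stream untouched.
#'
#' @param seed integer seed.
#' @param payoff_range numeric length-2 vector, `c(min, max)` of the uniform
#'   payoff distribution.
#' @return A [bimatrix_game()].
#' @export
random_game <- function(seed, payoff_range = c(0, 1)) {
  if (missing(seed)) stop("'seed' is required", call. = FALSE)
  if (!is.numeric(payoff_range) || length(payoff_range) != 2L ||
      any(!is.finite(payoff_range)) || payoff_range[2] <= payoff_range[1])
    stop("'payoff_range' must be a finite c(min, max) with max > min",
         call. = FALSE)
  .with_seed(seed, {
    vals <- stats::runif(8, payoff_range[1], payoff_range[2])
    bimatrix_game(matrix(vals[1:4], 2, 2), matrix(vals[5:8], 2, 2))
  })
}
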