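#' Gorilla Troops Optimizer parameters
#'
#' @param N Population size (>= 2).
#' @param Tmax Number of iterations (>= 0).
#' @param D Dimensionality of the search domain.
#' @param p Migration probability in `[0, 1]`; probability that an
#'   exploration move jumps to a uniformly random point ("unknown place").
#' @param beta Violence coefficient scaling the conflict vector `A` in the
#'   competition-for-adult-females move.
#' @param w Exploitation switch threshold: follow-the-silverback is used
#'   while the decaying coefficient `C >= w`, competition otherwise.
#' @param lower,upper Bound vectors (length `D`, or scalars recycled).
#' @param seed Integer seed used by [gto_optimize()].
#'
#' @return A `gto_params` list.
#' @export
gto_params <- function(N = 10L, Tmax = 10L, D = 16L, p = 0.03, beta = 3,
                       w = 0.8, lower = 0, upper = 1, seed = 1L) {
  N <- as.integer(N); Tmax <- as.integer(Tmax); D <- as.integer(D)
  lower <- rep_len(as.numeric(lower), D)
  upper <- rep_len(as.numeric(upper), D)
  stopifnot(N >= 2L, Tmax >= 0L, D >= 1L, p >= 0, p <= 1,
            all(lower <= upper))
  structure(list(N = N, Tmax = Tmax, D = D, p = p, beta = beta, w = w,
                 lower = lower, upper = upper, seed = as.integer(seed)),
            class = "gto_params")
}

clip_bounds <- function(x, lower, upper) pmin(pmax(x, lower), upper)

#' Initialize a gorilla population
#'
#' Positions are drawn uniformly inside the bounds,
#' `X = rand * (UB - LB) + LB` elementwise (row-major: the `D` draws for
#' member 1 come first). Candidate positions `GX` start as a copy of `X`;
#' fitness is unset until the first [gto_greedy_update()].
#'
#' @param params A [gto_params] object.
#' @return A `gto_population`: list with `X`, `GX` (`N x D` matrices),
#'   `fitness` (length `N`, `NA` until evaluated), `silverback` (index of
#'   best member), `history` (best-fitness trace, grows with each greedy
#'   update) and `n_skipped` (count of non-finite fitness evaluations).
#' @export
gto_init_population <- function(params) {
  n <- params$N; d <- params$D
  r <- matrix(stats::runif(n * d), nrow = n, ncol = d, byrow = TRUE)
  X <- sweep(sweep(r, 2, params$upper - params$lower, "*"), 2,
             params$lower, "+")
  structure(list(X = X, GX = X, fitness = rep(NA_real_, n),
                 silverback = NA_integer_, history = numeric(0),
                 n_skipped = 0L),
            class = "gto_population")
}

# Iteration-level decay coefficients, consumed from the current RNG stream in
# the order r4, l. C decays linearly to 0 at t = Tmax.
gto_coefficients <- function(t, Tmax) {
  r4 <- stats::runif(1)
  F_ <- cos(2 * r4) + 1
  C <- F_ * (1 - t / max(Tmax, 1L))
  l <- stats::runif(1, -1, 1)
  list(C = C, F = F_, l = l, L = C * l)
}

#' Exploration step (migration / approach / known-place moves)
#'
#' Proposes a candidate position `GX` for every member. Iteration-level
#' coefficients are drawn first (`r4` then `l`, giving
#' `C = (cos(2 r4) + 1)(1 - t/Tmax)` and `L = C l`). Then, member-major, a
#' branch draw `rand ~ U(0,1)` selects one of three moves:
#'
#' * `rand < p`: migration to an unknown place,
#'   `GX = (UB - LB) r1 + LB` with `r1` a fresh `U(0,1)` vector;
#' * `rand >= 0.5`: approach another gorilla,
#'   `GX = (r2 - C) X_r + L H` with `r2 ~ U(0,1)`, `Z ~ U(-C, C)` per
#'   dimension, `H = Z * X_i`, and `X_r` a uniformly drawn member;
#' * otherwise: migration to a known place,
#'   `GX = X_i - L (L (X_i - X_r) + r3 (X_i - X_r))` with `r3 ~ U(0,1)`.
#'
#' Per-member draw order is: branch draw, then branch-specific draws in the
#' order written above (branch 2: r2, Z, member index; branch 3: member
#' index, r3). Candidates are clipped to the bounds.
#'
#' @param pop A `gto_population`.
#' @param params A [gto_params].
#' @param t Current iteration (1-based, `t <= Tmax`).
#' @return The population with updated `GX`.
#' @export
gto_exploration <- function(pop, params, t) {
  co <- gto_coefficients(t, params$Tmax)
  n <- params$N
  lb <- params$lower; ub <- params$upper
  for (i in seq_len(n)) {
    xi <- pop$X[i, ]
    branch <- stats::runif(1)
    if (branch < params$p) {
      r1 <- stats::runif(params$D)
      gx <- (ub - lb) * r1 + lb
    } else if (branch >= 0.5) {
      r2 <- stats::runif(1)
      Z <- stats::runif(params$D, -co$C, co$C)
      H <- Z * xi
      xr <- pop$X[sample.int(n, 1L), ]
      gx <- (r2 - co$C) * xr + co$L * H
    } else {
      xr <- pop$X[sample.int(n, 1L), ]
      r3 <- stats::runif(1)
      gx <- xi - co$L * (co$L * (xi - xr) + r3 * (xi - xr))
    }
    pop$GX[i, ] <- clip_bounds(gx, lb, ub)
  }
  pop
}

#' Exploitation step (follow-the-silverback / competition moves)
#'
#' Draws the iteration-level coefficients (`r4` then `l`, as in
#' [gto_exploration()]) and compares the decay coefficient `C` with the
#' threshold `w`:
#'
#' * `C >= w` (follow the silverback): `GX = L M (X_i - X_sb) + X_i`, with
#'   `g = 2^L` and `M = (|colMeans(X)|^g)^(1/g)` elementwise over the
#'   current positions. No per-member draws.
#' * `C < w` (competition for adult females): per member, `r5 ~ U(0,1)`
#'   gives the impact force `Q = 2 r5 - 1`; a further `U(0,1)` draw selects
#'   the form of the violence vector `E` (per-dimension standard normals if
#'   `>= 0.5`, a broadcast scalar normal otherwise), `A = beta E`, and
#'   `GX = X_sb - (X_sb Q - X_i Q) A`.
#'
#' Per-member draw order in the competition branch: r5, the E-form draw,
#' then the normal draw(s). Candidates are clipped to the bounds.
#'
#' @inheritParams gto_exploration
#' @return The population with updated `GX`.
#' @export
gto_exploitation <- function(pop, params, t) {
  co <- gto_coefficients(t, params$Tmax)
  n <- params$N
  lb <- params$lower; ub <- params$upper
  sb <- pop$X[pop$silverback, ]
  if (co$C >= params$w) {
    g <- 2^co$L
    M <- (abs(colMeans(pop$X))^g)^(1 / g)
    for (i in seq_len(n)) {
      gx <- co$L * M * (pop$X[i, ] - sb) + pop$X[i, ]
      pop$GX[i, ] <- clip_bounds(gx, lb, ub)
    }
  } else {
    for (i in seq_len(n)) {
      r5 <- stats::runif(1)
      Q <- 2 * r5 - 1
      E <- if (stats::runif(1) >= 0.5) stats::rnorm(params$D)
           else stats::rnorm(1)
      A <- params$beta * E
      gx <- sb - (sb * Q - pop$X[i, ] * Q) * A
      pop$GX[i, ] <- clip_bounds(gx, lb, ub)
    }
  }
  pop
}

#' Greedy candidate acceptance and silverback reassignment
#'
#' Evaluates the fitness of every candidate `GX` and replaces `X_i` by
#' `GX_i` iff the candidate fitness is strictly lower. Members whose
#' candidate evaluates to a non-finite fitness are skipped (position kept)
#' and counted in `n_skipped`. The silverback is reassigned to the global
#' minimum and the running best is appended to `history` (a non-increasing
#' trace).
#'
#' @param pop A `gto_population` with current positions `X` and candidates
#'   `GX`. On the first call `fitness` may be `NA`; current positions are
#'   then evaluated too.
#' @param fitness_fn Function mapping a length-`D` numeric vector to a
#'   scalar fitness (minimized).
#' @return The updated population.
#' @export
gto_greedy_update <- function(pop, fitness_fn) {
  n <- nrow(pop$X)
  if (anyNA(pop$fitness)) {
    pop$fitness <- vapply(seq_len(n),
                          function(i) fitness_fn(pop$X[i, ]), 0)
    if (identical(pop$X, pop$GX)) { # fresh population: candidates are copies
      pop$silverback <- which.min(pop$fitness)
      pop$history <- c(pop$history, pop$fitness[pop$silverback])
      return(pop)
    }
  }
  for (i in seq_len(n)) {
    fgx <- fitness_fn(pop$GX[i, ])
    if (!is.finite(fgx)) {
      pop$n_skipped <- pop$n_skipped + 1L
      next
    }
    if (fgx < pop$fitness[i]) {
      pop$X[i, ] <- pop$GX[i, ]
      pop$fitness[i] <- fgx
    }
  }
  pop$silverback <- which.min(pop$fitness)
  pop$history <- c(pop$history, pop$fitness[pop$silverback])
  pop
}

#' Run the Gorilla Troops Optimizer
#'
#' Initializes the population once, then performs `Tmax` iterations, each
#' consisting of an exploration step followed by greedy acceptance, and an
#' exploitation step followed by greedy acceptance. The silverback (best
#' member) is returned. With `Tmax = 0` the best member of the random
#' initial population is returned.
#'
#' The run consumes a single RNG stream seeded from `params$seed`, in a
#' fixed documented order (initialization row-major; then per iteration:
#' exploration coefficients, member-major exploration draws, exploitation
#' coefficients, member-major exploitation draws), so seeded runs are
#' bit-reproducible. `fitness_fn` must not disturb the global RNG stream
#' (wrap stochastic objectives with [preserve_rng()]).
#'
#' @param fitness_fn Objective to minimize over the box.
#' @param params A [gto_params].
#' @param callback Optional `function(t, pop)` called after each completed
#'   iteration (used for checkpointing).
#' @param state Optional checkpoint list (as captured by a callback via
#'   [gto_capture_state()]) to resume from.
#' @return List with `best_solution`, `best_fitness`, `history` (data frame:
#'   iteration, best_fitness), `trace` (fine-grained per-greedy-update best
#'   trace) and `population`.
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- gto_optimize(sphere, gto_params(N = 10, Tmax = 50, D = 5,
#'                                        lower = -1, upper = 1, seed = 7))
#' res$best_fitness
#' @export
gto_optimize <- function(fitness_fn, params, callback = NULL, state = NULL) {
  if (is.null(state)) {
    set.seed(params$seed)
    pop <- gto_init_population(params)
    pop <- gto_greedy_update(pop, fitness_fn) # evaluates X; GX == X here
    best_per_iter <- numeric(0)
    t0 <- 1L
  } else {
    pop <- state$pop
    best_per_iter <- state$best_per_iter
    t0 <- state$t + 1L
    assign(".Random.seed", state$random_seed, envir = globalenv())
  }
  if (params$Tmax >= t0) {
    for (t in seq.int(t0, params$Tmax)) {
      pop <- gto_exploration(pop, params, t)
      pop <- gto_greedy_update(pop, fitness_fn)
      pop <- gto_exploitation(pop, params, t)
      pop <- gto_greedy_update(pop, fitness_fn)
      best_per_iter <- c(best_per_iter, pop$fitness[pop$silverback])
      if (!is.null(callback)) callback(t, pop)
    }
  }
  list(best_solution = pop$X[pop$silverback, ],
       best_fitness = pop$fitness[pop$silverback],
       history = data.frame(iteration = seq_along(best_per_iter),
                            best_fitness = best_per_iter),
       trace = pop$history,
       population = pop)
}

#' Capture optimizer state for checkpointing
#'
#' Bundles the population, the per-iteration best trace and the current RNG
#' state so a run can be resumed with the `state` argument of
#' [gto_optimize()] and continue on the identical random stream.
#'
#' @param t Last completed iteration.
#' @param pop The population after iteration `t`.
#' @param best_per_iter Numeric vector of per-iteration best fitness.
#' @return A checkpoint list.
#' @export
gto_capture_state <- function(t, pop, best_per_iter) {
  list(t = t, pop = pop, best_per_iter = best_per_iter,
       random_seed = get(".Random.seed", envir = globalenv()))
}

#' Run a function on its own RNG stream
#'
#' Evaluates `expr` after seeding with `seed`, then restores the caller's
#' RNG state. Used to keep stochastic fitness functions from perturbing the
#' optimizer's documented random stream (and to make fitness evaluations
#' deterministic per solution).
#'
#' @param seed Integer seed for the inner stream.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
preserve_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Write a per-iteration optimizer history to CSV
#'
#' @param result A [gto_optimize()] result.
#' @param path Output CSV path (columns: iteration, best_fitness, then the
#'   silverback solution elements).
#' @return `path`, invisibly.
#' @export
write_gto_history <- function(result, path) {
  h <- result$history
  if (nrow(h) == 0L)
    h <- data.frame(iteration = 0L, best_fitness = result$best_fitness)
  sol <- matrix(result$best_solution, nrow = nrow(h),
                ncol = length(result$best_solution), byrow = TRUE)
  colnames(sol) <- paste0("x", seq_len(ncol(sol)))
  utils::write.csv(cbind(h, sol), path, row.names = FALSE)
  invisible(path)
}
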