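#' Configuration for the multi-verse optimizer family
#'
#' Collects every search-control scalar used by [optimize_mvo()]. The
#' defaults are the settings used throughout the experiment harness:
#' population 50, 1000 iterations, wormhole existence probability growing
#' linearly from 0.5 to 1, exploitation-accuracy exponent 6, and gradient
#' weight 0.7. Setting `alpha = 0` removes the gradient scaling entirely and
#' yields the plain multi-verse optimizer (MVO); any `alpha > 0` gives the
#' hybrid gradient variant (GMVO).
#'
#' @param lb,ub Numeric vectors of per-dimension lower and upper box bounds.
#'   Scalars are recycled to length `d`.
#' @param d Problem dimension. Defaults to `max(length(lb), length(ub))`.
#' @param n Population size (number of universes), at least 2.
#' @param M Maximum number of iterations, at least 0. `M = 0` evaluates only
#'   the random initial population.
#' @param P_min,P_max Lower and upper bounds of the wormhole existence
#'   probability, both in \[0, 1\] with `P_min <= P_max`.
#' @param chi Exploitation-accuracy exponent (> 0) of the traveling distance
#'   rate schedule.
#' @param alpha Gradient weight (>= 0). `alpha = 0` is plain MVO.
#' @param delta_x_interval Length-2 numeric `(low, high]` interval from which
#'   the finite-difference step is drawn uniformly, independently for every
#'   universe and dimension at each iteration (a different step for each
#'   candidate solution increases population diversity around the best
#'   universe); `0 < low < high`. The default `(1e-12, 1e-3]` keeps the
#'   nominal upper bound 0.001 while bounding the step away from zero so the
#'   gradient scale never divides by zero.
#' @param eps Small positive stabilizer added to the estimated gradient
#'   direction.
#' @param s_max Clip bound for the per-dimension gradient scale:
#'   `S` is truncated to `[-s_max, s_max]` before scaling the traveling
#'   distance rate. Because the finite-difference step is at most 0.001,
#'   the raw ratio explodes whenever the best and worst universes are not
#'   yet close, which would turn every wormhole jump into a saturated jump
#'   onto the box boundary; the clip keeps the adjusted rate inside a
#'   bounded multiple of the plain schedule while leaving the
#'   gradient-driven modulation intact once the population has contracted.
#'   Default 2. `Inf` disables clipping (the raw ratio).
#' @param seed Integer seed controlling every random draw of a run.
#'
#' @return An object of class `"mvo_config"` (a validated list).
#' @seealso [optimize_mvo()], [gradient_scale()]
#' @export
#' @examples
#' cfg <- mvo_config(lb = -5, ub = 5, d = 10, n = 50, M = 500)
#' cfg$alpha
mvo_config <- function(lb = -10, ub = 10, d = max(length(lb), length(ub)),
                       n = 50L, M = 1000L, P_min = 0.5, P_max = 1,
                       chi = 6, alpha = 0.7,
                       delta_x_interval = c(1e-12, 1e-3),
                       eps = 1e-10, s_max = 2, seed = 1L) {
  lb <- rep_len(as.numeric(lb), d)
  ub <- rep_len(as.numeric(ub), d)
  stopifnot(
    d >= 1, n >= 2, M >= 0,
    is.finite(P_min), is.finite(P_max),
    P_min >= 0, P_max <= 1, P_min <= P_max,
    chi > 0, alpha >= 0,
    length(delta_x_interval) == 2,
    delta_x_interval[1] > 0,
    delta_x_interval[1] < delta_x_interval[2],
    eps >= 0, s_max > 0
  )
  if (any(lb >= ub)) stop("every lower bound must be strictly below its upper bound")
  structure(
    list(lb = lb, ub = ub, d = as.integer(d), n = as.integer(n),
         M = as.integer(M), P_min = P_min, P_max = P_max, chi = chi,
         alpha = alpha, delta_x_interval = as.numeric(delta_x_interval),
         eps = eps, s_max = s_max, seed = as.integer(seed)),
    class = "mvo_config"
  )
}

#' @export
print.mvo_config <- function(x, ...) {
  variant <- if (x$alpha > 0) "GMVO (gradient multi-verse optimizer)" else "MVO"
  cat(variant, "\n")
  cat(sprintf("  d = %d, n = %d, M = %d\n", x$d, x$n, x$M))
  cat(sprintf("  P_w: %.3g -> %.3g, chi = %g, alpha = %g\n",
              x$P_min, x$P_max, x$chi, x$alpha))
  cat(sprintf("  box: [%.3g, %.3g] (first dimension), seed = %d\n",
              x$lb[1], x$ub[1], x$seed))
  invisible(x)
}

#' Normalize a fitness vector to unit Euclidean norm
#'
#' The normalized inflation rates drive both the per-object exchange
#' probability and the roulette-wheel donor selection. An all-zero vector is
#' returned unchanged (the degenerate case where every universe has zero
#' loss).
#'
#' @param fitness Numeric vector of finite fitness (inflation rate) values.
#' @return Numeric vector of the same length with unit Euclidean norm
#'   (unless all-zero).
#' @export
#' @examples
#' normalize_fitness(c(3, 4)) # c(0.6, 0.8)
normalize_fitness <- function(fitness) {
  if (length(fitness) < 1) stop("fitness must have at least one entry")
  if (any(!is.finite(fitness))) stop("fitness contains non-finite entries")
  nrm <- sqrt(sum(fitness^2))
  if (nrm == 0) return(fitness)
  fitness / nrm
}

#' Roulette-wheel selection over (possibly negative) weights
#'
#' Selects an index with probability proportional to
#' `w_i - min(w) + shift`. The caller passes the negated normalized fitness
#' `-F~`, so the best universes (smallest fitness, hence largest `-F~`)
#' carry the most mass; the tiny positive `shift` makes the masses a valid
#' probability vector even when all weights coincide.
#'
#' @param weights Numeric vector of finite selection weights.
#' @param u Uniform draw(s) in \[0, 1) used for selection; defaults to one
#'   draw from the current RNG stream. Supplying a vector returns one index
#'   per draw.
#' @param shift Tiny positive mass added to every entry (default `1e-9`).
#' @return Integer index (or vector of indices) in `1:length(weights)`.
#' @export
#' @examples
#' set.seed(1)
#' roulette_wheel_select(c(-0.9, -0.1))
roulette_wheel_select <- function(weights, u = stats::runif(1), shift = 1e-9) {
  n <- length(weights)
  if (n < 1) stop("weights must be non-empty")
  if (any(!is.finite(weights))) stop("weights contain non-finite entries")
  p <- weights - min(weights) + shift
  cs <- cumsum(p)
  idx <- findInterval(u * cs[n], cs, left.open = TRUE) + 1L
  pmin(idx, n)
}

#' Wormhole existence probability schedule
#'
#' Grows linearly from `P_min` at iteration 0 to `P_max` at iteration `M`,
#' shifting effort from exploration to exploitation as the search proceeds.
#'
#' @param m Iteration number, `0 <= m <= M`.
#' @param cfg An [mvo_config()].
#' @return The wormhole probability at iteration `m`.
#' @export
wormhole_probability <- function(m, cfg) {
  if (any(m < 0) || any(m > cfg$M)) stop("iteration m must lie in [0, M]")
  cfg$P_min + m * (cfg$P_max - cfg$P_min) / cfg$M
}

#' Traveling distance rate schedule
#'
#' The shrinking step-size factor `1 - (m/M)^(1/chi)` of wormhole jumps:
#' 1 at iteration 0, 0 at iteration `M`, strictly decreasing in between, so
#' late iterations search ever closer to the incumbent best universe.
#'
#' @inheritParams wormhole_probability
#' @return The traveling distance rate at iteration `m`.
#' @export
traveling_distance_rate <- function(m, cfg) {
  if (any(m < 0) || any(m > cfg$M)) stop("iteration m must lie in [0, M]")
  1 - (m / cfg$M)^(1 / cfg$chi)
}

#' Per-dimension gradient scaling of the traveling distance rate
#'
#' The hybrid variant rescales the wormhole step in each dimension by
#' `S_j = 1 + alpha * (x_best_j - x_worst_j + eps) / (2 * delta_x_j)`.
#' The difference between the best and worst universes estimates the
#' (negated) gradient direction by a central finite difference whose
#' positions have been replaced by those two solutions; `delta_x` is the
#' step vector (the optimizer draws an independent step for every universe
#' and dimension at each iteration and applies this formula row-wise), and
#' `eps` guards the all-equal case. The result is truncated to `[-s_max, s_max]` (see
#' [mvo_config()]) so the adjusted traveling distance rate stays a bounded
#' multiple of the plain schedule. With `alpha = 0` the scale is
#' identically 1 and the update reduces to plain MVO.
#'
#' @param x_best,x_worst Numeric vectors: the incumbent best universe and
#'   the worst universe of the current population.
#' @param delta_x Strictly positive numeric vector of finite-difference
#'   steps, same length as `x_best`.
#' @param cfg An [mvo_config()] supplying `alpha` and `eps`.
#' @return Numeric vector `S` of per-dimension scale factors.
#' @export
#' @examples
#' cfg <- mvo_config(d = 1, alpha = 0.7, eps = 0)
#' gradient_scale(0.001, 0, 0.0005, cfg) # 1.7
gradient_scale <- function(x_best, x_worst, delta_x, cfg) {
  stopifnot(length(x_best) == length(x_worst),
            length(delta_x) == length(x_best))
  if (any(delta_x <= 0)) stop("every delta_x entry must be strictly positive")
  S <- 1 + cfg$alpha * (x_best - x_worst + cfg$eps) / (2 * delta_x)
  pmin(pmax(S, -cfg$s_max), cfg$s_max)
}

#' Construct a universe population state
#'
#' Bundles the population matrix with its fitness, normalized fitness,
#' fitness-sorted copy, and the elitist best / current worst records used by
#' the exchange and wormhole moves. The elitist best is kept outside the
#' population and is never degraded: if a `best` from an earlier iteration
#' is supplied and still beats the current population, it is retained.
#'
#' @param positions `n x d` numeric matrix, one universe per row, all
#'   entries inside `[cfg$lb, cfg$ub]`.
#' @param fitness Length-`n` numeric fitness vector (non-finite entries are
#'   treated as the worst observed finite value for normalization and
#'   sorting, and as `+Inf` for records).
#' @param cfg An [mvo_config()].
#' @param best,best_fitness Optional elitist record carried over from a
#'   previous state.
#' @param iteration Iteration counter attached to the state.
#' @return An object of class `"universe_state"`.
#' @export
universe_state <- function(positions, fitness, cfg,
                           best = NULL, best_fitness = Inf, iteration = 0L) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(n == length(fitness), ncol(positions) == cfg$d)
  finite <- is.finite(fitness)
  capped <- fitness
  if (!all(finite)) {
    capped[!finite] <- if (any(finite)) max(fitness[finite]) else 1
  }
  ord <- order(capped)
  cur_best_i <- ord[1]
  if (is.null(best) || fitness[cur_best_i] < best_fitness) {
    best <- positions[cur_best_i, ]
    best_fitness <- fitness[cur_best_i]
  }
  structure(
    list(positions = positions,
         fitness = fitness,
         normalized_fitness = normalize_fitness(capped),
         sorted_positions = positions[ord, , drop = FALSE],
         sorted_fitness = fitness[ord],
         best = best, best_fitness = best_fitness,
         worst = positions[ord[n], ], worst_fitness = fitness[ord[n]],
         iteration = as.integer(iteration)),
    class = "universe_state"
  )
}

# Exchange pass over a raw position matrix. Draw order (column-major, i.e.
# dimension-by-dimension): one n x d uniform matrix r1, then one uniform per
# entry with r1 < Fnorm[i], consumed in column-major order of those entries.
.exchange_pass <- function(positions, Fnorm, sorted_positions, shift = 1e-9) {
  n <- nrow(positions); d <- ncol(positions)
  r1 <- matrix(stats::runif(n * d), n, d)
  hit <- which(r1 < Fnorm[row(r1)])
  if (length(hit)) {
    u <- stats::runif(length(hit))
    donors <- roulette_wheel_select(-sort_normalized(Fnorm), u, shift)
    cols <- ((hit - 1L) %/% n) + 1L
    positions[hit] <- sorted_positions[cbind(donors, cols)]
  }
  positions
}

# Normalized fitness of the *sorted* population: ascending order.
sort_normalized <- function(Fnorm) sort(Fnorm)

# Wormhole pass over a raw position matrix. Draw order: when alpha > 0, an
# n x d matrix of delta_x steps first (an independent step per universe and
# dimension); then one n x d uniform matrix r2; then, for the entries with
# r2 < Pw in column-major order, a vector r3 (alpha = 0 only) followed by a
# vector r4. Updated entries are clamped to the box.
.wormhole_pass <- function(positions, best, worst, m, cfg) {
  n <- nrow(positions); d <- ncol(positions)
  Pw <- wormhole_probability(m, cfg)
  tdr <- traveling_distance_rate(m, cfg)
  if (cfg$alpha > 0) {
    DX <- matrix(stats::runif(n * d, cfg$delta_x_interval[1],
                              cfg$delta_x_interval[2]), n, d)
    num <- matrix(best - worst + cfg$eps, n, d, byrow = TRUE)
    S <- 1 + cfg$alpha * num / (2 * DX)
    S <- pmin(pmax(S, -cfg$s_max), cfg$s_max)
  }
  r2 <- matrix(stats::runif(n * d), n, d)
  fire <- which(r2 < Pw)
  if (length(fire)) {
    k <- length(fire)
    cols <- ((fire - 1L) %/% n) + 1L
    width <- cfg$ub[cols] - cfg$lb[cols]
    if (cfg$alpha == 0) {
      r3 <- stats::runif(k)
      r4 <- stats::runif(k)
      sgn <- ifelse(r3 < 0.5, 1, -1)
      val <- best[cols] + sgn * tdr * (width * r4 + cfg$lb[cols])
    } else {
      r4 <- stats::runif(k)
      val <- best[cols] + tdr * S[fire] * (width * r4 + cfg$lb[cols])
    }
    positions[fire] <- pmin(pmax(val, cfg$lb[cols]), cfg$ub[cols])
  }
  positions
}

#' Exchange objects between universes through white/black-hole tunnels
#'
#' The exploration move: for every universe `i` and object (dimension) `j`,
#' a uniform draw `r1` below the universe's normalized fitness replaces
#' `x_ij` by the same object of a donor universe picked by roulette-wheel
#' selection on the negated sorted normalized fitness, so low-fitness (good)
#' universes donate most often. Universes with high normalized fitness
#' (poor solutions) are overwritten most.
#'
#' Draws are consumed from the current RNG stream in a fixed documented
#' order: an `n x d` matrix of `r1` values (column-major), then one uniform
#' per firing entry in column-major order.
#'
#' @param state A [universe_state()] with current fitness.
#' @param cfg An [mvo_config()].
#' @return A new `universe_state` with updated positions; the fitness slots
#'   are carried over unchanged and must be re-evaluated before the next
#'   move.
#' @export
exchange_objects <- function(state, cfg) {
  pos <- .exchange_pass(state$positions, state$normalized_fitness,
                        state$sorted_positions)
  universe_state(pos, state$fitness, cfg,
                 best = state$best, best_fitness = state$best_fitness,
                 iteration = state$iteration)
}

#' Wormhole jump of objects towards the incumbent best universe
#'
#' The exploitation move: each object independently fires with the wormhole
#' probability of iteration `m`, and a firing object is re-positioned at
#' `x_best_j + v_T * ((ub_j - lb_j) * r4 + lb_j)` with the traveling
#' distance rate `v_T` of iteration `m`. Plain MVO (`alpha = 0`) carries a
#' random sign branch on an extra draw `r3`; the gradient variant drops the
#' sign branch and instead scales `v_T` per dimension by [gradient_scale()]
#' (the sign is carried by the estimated gradient direction). Updated
#' positions are clamped to the box.
#'
#' Draw order per call: an `n x d` matrix of finite-difference steps, one
#' per universe and dimension (only when `alpha > 0`), an `n x d` matrix of
#' `r2` values, then for the firing entries in column-major order a vector
#' of `r3` draws (only when `alpha = 0`) followed by a vector of `r4`
#' draws.
#'
#' @param state A [universe_state()] with a current elitist best and worst.
#' @param m Iteration number in `[0, M]`.
#' @param cfg An [mvo_config()].
#' @return A new `universe_state` with updated positions (fitness stale, as
#'   for [exchange_objects()]).
#' @export
wormhole_update <- function(state, m, cfg) {
  pos <- .wormhole_pass(state$positions, state$best, state$worst, m, cfg)
  universe_state(pos, state$fitness, cfg,
                 best = state$best, best_fitness = state$best_fitness,
                 iteration = as.integer(m))
}

#' Minimize a black-box objective with MVO / GMVO
#'
#' Runs the full population search: `n` universes are initialized uniformly
#' in the box, and each iteration evaluates the objective, sorts and
#' normalizes the fitness, applies the white/black-hole exchange
#' ([exchange_objects()]) and then the wormhole jump ([wormhole_update()]).
#' An elitist record of the best solution ever evaluated is kept outside
#' the population, so the convergence history is non-increasing. The whole
#' trajectory is reproducible from `cfg$seed`.
#'
#' An objective value that is not finite is recorded as `+Inf` (the universe
#' becomes the worst) with a warning.
#'
#' @param objective Function mapping a length-`d` numeric vector to a scalar.
#' @param cfg An [mvo_config()].
#' @param trace_file Optional path; if given, a CSV with columns
#'   `iteration,best_fitness` is written for convergence plots.
#' @return An object of class `"mvo_result"`: a list with `best_position`,
#'   `best_fitness`, `history` (best-so-far fitness per iteration, length
#'   `M`, or length 1 when `M = 0`), `evaluations`, and the final
#'   `population` matrix with its `fitness`.
#' @export
#' @examples
#' sphere <- function(x) sum(x^2)
#' res <- optimize_mvo(sphere, mvo_config(lb = -5, ub = 5, d = 3,
#'                                        n = 20, M = 50, seed = 42))
#' res$best_fitness
optimize_mvo <- function(objective, cfg, trace_file = NULL) {
  stopifnot(inherits(cfg, "mvo_config"))
  set.seed(cfg$seed)
  n <- cfg$n; d <- cfg$d
  evals <- 0L
  warned <- FALSE
  eval_one <- function(x) {
    evals <<- evals + 1L
    v <- objective(x)
    if (!is.finite(v)) {
      if (!warned) {
        warning("objective returned a non-finite value; recorded as +Inf")
        warned <<- TRUE
      }
      v <- Inf
    }
    v
  }
  u0 <- matrix(stats::runif(n * d), n, d)
  positions <- sweep(sweep(u0, 2, cfg$ub - cfg$lb, `*`), 2, cfg$lb, `+`)
  fitness <- apply(positions, 1, eval_one)
  state <- universe_state(positions, fitness, cfg)

  if (cfg$M == 0) {
    history <- state$best_fitness
  } else {
    history <- numeric(cfg$M)
    for (m in seq_len(cfg$M)) {
      pos <- .exchange_pass(state$positions, state$normalized_fitness,
                            state$sorted_positions)
      pos <- .wormhole_pass(pos, state$best, state$worst, m, cfg)
      fitness <- apply(pos, 1, eval_one)
      state <- universe_state(pos, fitness, cfg,
                              best = state$best,
                              best_fitness = state$best_fitness,
                              iteration = m)
      history[m] <- state$best_fitness
    }
  }
  if (!is.null(trace_file)) {
    utils::write.csv(
      data.frame(iteration = seq_along(history), best_fitness = history),
      trace_file, row.names = FALSE)
  }
  structure(
    list(best_position = state$best, best_fitness = state$best_fitness,
         history = history, evaluations = evals,
         population = state$positions, fitness = state$fitness,
         config = cfg),
    class = "mvo_result"
  )
}

#' @export
print.mvo_result <- function(x, ...) {
  cat("MVO/GMVO result\n")
  cat(sprintf("  best fitness: %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  cat(sprintf("  iterations: %d (alpha = %g)\n",
              length(x$history), x$config$alpha))
  invisible(x)
}
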