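## Choosing the number of edge nodes per state.
##
## The profit objective trades three terms: delay falls as 1/k with the node
## count k; the state's share of the total node budget K should match its
## danger ratio (p + d)/n (deaths plus dangerous cases over all bites); and
## node cost C(k) is paid. Profit(k) = 1/k - (k/K - (p + d)/n) - C(k) is
## maximised over integer k in [1, K] by PSO, quantum-behaved PSO, or
## exhaustive scan.

#' Hop-delay magnitude as a function of edge-node count
#'
#' Delay is inversely proportional to the node count: `delay_constant / k`.
#'
#' @param k edge-node count, >= 1.
#' @param delay_constant proportionality scale (hop-delay units).
#' @return delay magnitude.
#' @export
delay <- function(k, delay_constant = 1) {
  fm_assert(all(k >= 1), "planner", "k must be >= 1, got %s", paste(k, collapse = ","))
  delay_constant / k
}

#' Signed gap between budget share and danger ratio
#'
#' `k/K - (p + d)/n`; the objective drives this towards zero so each state's
#' node share matches its danger ratio.
#'
#' @param k candidate node count for the state.
#' @param K total node budget across all states.
#' @param epi one state's epidemiology: list/row with `n`, `d`, `p`.
#' @return signed value.
#' @export
danger_gap <- function(k, K, epi) {
  fm_assert(epi$n >= 1, "planner", "state bite count n must be >= 1")
  k / K - (epi$p + epi$d) / epi$n
}

#' Planner problem definition
#'
#' @param K total edge-node budget, >= 1.
#' @param epi one state's epidemiology (`n`, `d`, `p` with `p + d <= n`).
#' @param cost either a single non-negative per-node price (so
#'   `C(k) = cost * k`) or a non-decreasing function of k.
#' @param delay_constant scale of the hop delay reported alongside plans.
#' @return a `planner_problem`.
#' @export
planner_problem <- function(K, epi, cost = 0, delay_constant = 1) {
  fm_assert(K >= 1, "planner", "budget K must be >= 1")
  fm_assert(epi$n >= 1 && epi$d >= 0 && epi$p >= 0 && epi$p + epi$d <= epi$n,
            "planner", "invalid state epidemiology (need n >= 1, d, p >= 0, p + d <= n)")
  cost_fn <- if (is.function(cost)) cost else {
    fm_assert(is.numeric(cost) && cost >= 0, "planner", "per-node cost must be >= 0")
    function(k) cost * k
  }
  structure(list(K = as.integer(K), epi = epi, cost = cost_fn,
                 delay_constant = delay_constant),
            class = "planner_problem")
}

#' Profit of deploying k edge nodes
#'
#' `Profit(k) = 1/k - (k/K - (p + d)/n) - C(k)`, defined on integer k >= 1.
#'
#' @param k integer node count, >= 1.
#' @param problem a [planner_problem()].
#' @return profit value.
#' @export
#' @examples
#' pr <- planner_problem(K = 10, epi = list(n = 100, d = 4, p = 6))
#' profit(2, pr)  # 0.5 - (0.2 - 0.1) - 0 = 0.4
profit <- function(k, problem) {
  fm_assert(inherits(problem, "planner_problem"), "planner", "expected a planner_problem")
  fm_assert(length(k) == 1 && is.finite(k) && k >= 1 && k == round(k), "planner",
            "k must be a single integer >= 1, got %s", format(k))
  1 / k - danger_gap(k, problem$K, problem$epi) - problem$cost(k)
}

#' Swarm configuration for PSO / QPSO
#'
#' @param s swarm size, >= 2.
#' @param iterations iteration count, >= 1.
#' @param omega PSO inertia weight, in [0, 1].
#' @param c1,c2 PSO acceleration constants.
#' @param alpha QPSO contraction-expansion coefficient, in (0, 1]
#'   (protocol value 0.7).
#' @param seed integer seed.
#' @return a `swarm_config`.
#' @export
swarm_config <- function(s = 30L, iterations = 100L, omega = 0.7,
                         c1 = 1.5, c2 = 1.5, alpha = 0.7, seed = 0L) {
  fm_assert(s >= 2, "config", "swarm size must be >= 2")
  fm_assert(iterations >= 1, "config", "iterations must be >= 1")
  fm_assert(alpha > 0 && alpha <= 1, "config", "alpha must lie in (0, 1]")
  fm_assert(omega >= 0 && omega <= 1, "config", "omega must lie in [0, 1]")
  structure(list(s = as.integer(s), iterations = as.integer(iterations),
                 omega = omega, c1 = c1, c2 = c2, alpha = alpha,
                 seed = as.integer(seed)),
            class = "swarm_config")
}

## integer evaluation: positions move continuously, the objective is read at
## round(x) clamped to [1, K]
eval_positions <- function(x, objective, K) {
  vapply(clamp(round(x), 1, K), objective, numeric(1))
}

init_swarm <- function(config, objective, K) {
  x <- stats::runif(config$s, 1, K)
  fit <- eval_positions(x, objective, K)
  g <- which.max(fit)
  list(x = x, v = numeric(config$s), pbest = x, pbest_fit = fit,
       gbest = x[g], gbest_fit = fit[g], K = K)
}

refresh_bests <- function(state, fit) {
  upd <- fit > state$pbest_fit
  state$pbest[upd] <- state$x[upd]
  state$pbest_fit[upd] <- fit[upd]
  g <- which.max(state$pbest_fit)
  state$gbest <- state$pbest[g]
  state$gbest_fit <- state$pbest_fit[g]
  state
}

#' One PSO iteration
#'
#' Velocity update
#' `v <- omega v + c1 phi1 (P - x) + c2 phi2 (Pg - x)` with fresh uniform
#' draws `phi1`, `phi2` per particle, then `x <- x + v`, clamped to `[1, K]`;
#' personal and global bests are refreshed from the new fitness.
#'
#' @param state swarm state from a previous step (or internal init).
#' @param config a [swarm_config()].
#' @param objective function of integer k.
#' @return updated state.
#' @export
pso_step <- function(state, config, objective) {
  phi1 <- stats::runif(config$s)
  phi2 <- stats::runif(config$s)
  state$v <- config$omega * state$v +
    config$c1 * phi1 * (state$pbest - state$x) +
    config$c2 * phi2 * (state$gbest - state$x)
  state$x <- clamp(state$x + state$v, 1, state$K)
  refresh_bests(state, eval_positions(state$x, objective, state$K))
}

#' One quantum-behaved PSO iteration
#'
#' Per particle: the local attractor is `PP = phi P + (1 - phi) Pg`; the mean
#' best `m_best` is the mean of all personal bests; the new position is
#' `PP +/- alpha |m_best - x| ln(1/u)` with the sign positive when `b >= 0.5`
#' (`phi`, `u`, `b` fresh uniform draws, `u` from the open interval). No
#' velocities are kept.
#'
#' @inheritParams pso_step
#' @return updated state.
#' @export
qpso_step <- function(state, config, objective) {
  phi <- stats::runif(config$s)
  u <- stats::runif(config$s)
  u[u == 0] <- .Machine$double.eps        # open-interval draw
  b <- stats::runif(config$s)
  pp <- phi * state$pbest + (1 - phi) * state$gbest
  mbest <- mean(state$pbest)
  sgn <- ifelse(b >= 0.5, 1, -1)
  state$x <- clamp(pp + sgn * config$alpha * abs(mbest - state$x) * log(1 / u),
                   1, state$K)
  refresh_bests(state, eval_positions(state$x, objective, state$K))
}

#' Optimise the edge-node count for one state
#'
#' @param problem a [planner_problem()].
#' @param config a [swarm_config()] (ignored by the brute method).
#' @param method `"qpso"` (default), `"pso"`, or `"brute"` (exhaustive scan
#'   of k in 1..K — the oracle).
#' @return list with integer `k_star`, `profit`, and `trace` (best profit per
#'   iteration, non-decreasing; length 1 for brute).
#' @export
#' @examples
#' pr <- planner_problem(K = 10, epi = list(n = 100, d = 4, p = 6))
#' optimize_edges(pr, method = "brute")$k_star
optimize_edges <- function(problem, config = swarm_config(), method = "qpso") {
  fm_assert(method %in% c("pso", "qpso", "brute"), "planner",
            "unknown method '%s' (options: pso, qpso, brute)", method)
  objective <- function(k) profit(k, problem)
  K <- problem$K
  if (method == "brute") {
    vals <- vapply(seq_len(K), objective, numeric(1))
    k <- which.max(vals)
    return(list(k_star = as.integer(k), profit = vals[k], trace = vals[k],
                method = method))
  }
  step_fn <- if (method == "pso") pso_step else qpso_step
  with_seed(config$seed, {
    state <- init_swarm(config, objective, K)
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      state <- step_fn(state, config, objective)
      trace[it] <- state$gbest_fit
    }
    k <- as.integer(clamp(round(state$gbest), 1, K))
    list(k_star = k, profit = state$gbest_fit, trace = trace, method = method)
  })
}

#' Plan edge nodes for every state in an epidemiology table
#'
#' @param epi data.frame with columns `state`, `n`, `d`, `p`.
#' @param K total edge-node budget.
#' @param cost per-node price or cost function.
#' @param config a [swarm_config()].
#' @param method optimisation method, as in [optimize_edges()].
#' @return named list (per state) of [optimize_edges()] results with the
#'   state's hop delay at the chosen k.
#' @export
plan_edges <- function(epi, K, cost = 0, config = swarm_config(), method = "qpso") {
  validate_state_table(epi)
  out <- list()
  for (i in seq_len(nrow(epi))) {
    pr <- planner_problem(K, as.list(epi[i, ]), cost = cost)
    cfg <- config
    cfg$seed <- stage_seed(config$seed, paste0("state", i))
    res <- optimize_edges(pr, cfg, method)
    res$delay <- delay(res$k_star, pr$delay_constant)
    out[[as.character(epi$state[i])]] <- res
  }
  out
}
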