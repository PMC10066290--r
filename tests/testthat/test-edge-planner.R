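toy_epi <- list(n = 100, d = 4, p = 6)   # danger ratio 0.1

test_that("delay is inversely proportional to the node count", {
  expect_equal(delay(1, 5), 5)
  expect_equal(delay(4, 12), 3)
  c0 <- 3.7
  expect_equal(delay(2, c0) / delay(4, c0), 2)
  expect_true(all(diff(delay(1:20, 1)) < 0))   # strictly decreasing
  expect_error(delay(0, 1), class = "fangmark_planner")
})

test_that("danger gap is the signed budget-share / danger-ratio difference", {
  expect_equal(danger_gap(2, 10, toy_epi), 0.1)
  expect_equal(danger_gap(1, 10, toy_epi), 0)          # 0.1 - 0.1
  expect_equal(danger_gap(1, 1, list(n = 50, d = 0, p = 0)), 1)
  expect_error(danger_gap(1, 10, list(n = 0, d = 0, p = 0)),
               class = "fangmark_planner")
})

test_that("profit evaluates the objective and decomposes exactly", {
  pr <- planner_problem(K = 10, epi = toy_epi)
  expect_equal(profit(2, pr), 0.5 - 0.1)
  # zero gap: profit is exactly 1/k
  expect_equal(profit(1, pr), 1)                       # gap 0 at k = 1
  # cost self-cancellation
  pr0 <- planner_problem(K = 10, epi = toy_epi,
                         cost = function(k) 1 / k - danger_gap(k, 10, toy_epi))
  expect_equal(profit(3, pr0), 0)
  expect_error(profit(0, pr), class = "fangmark_planner")
  expect_error(profit(2.5, pr), class = "fangmark_planner")
  # decomposition identity for every k
  prc <- planner_problem(K = 10, epi = toy_epi, cost = 0.02)
  for (k in 1:10) {
    expect_equal(profit(k, prc) + prc$cost(k) + danger_gap(k, 10, toy_epi), 1 / k)
  }
})

test_that("pso_step follows the velocity update equations", {
  cfg0 <- swarm_config(s = 3, omega = 0, c1 = 0, c2 = 0)
  state <- list(x = c(2, 5, 8), v = c(1, -1, 2), pbest = c(2, 5, 8),
                pbest_fit = c(0, 1, 0), gbest = 5, gbest_fit = 1, K = 10)
  obj <- function(k) -abs(k - 5)
  set.seed(1)
  out <- pso_step(state, cfg0, obj)
  expect_equal(out$x, state$x)                 # Eq. collapses: nothing moves
  expect_equal(out$v, c(0, 0, 0))
  # attraction terms vanish when P = Pg = x: velocity becomes omega * v
  cfgw <- swarm_config(s = 2, omega = 0.5, c1 = 1.5, c2 = 1.5)
  st2 <- list(x = c(4, 4), v = c(2, -2), pbest = c(4, 4), pbest_fit = c(0, 0),
              gbest = 4, gbest_fit = 0, K = 10)
  set.seed(2)
  out2 <- pso_step(st2, cfgw, obj)
  expect_equal(out2$v, 0.5 * st2$v)
  # single-step hand evaluation with the same seeded draws
  cfg <- swarm_config(s = 2, omega = 0.7, c1 = 1.5, c2 = 1.5)
  st <- list(x = c(2, 7), v = c(0.5, -0.5), pbest = c(3, 6), pbest_fit = c(-2, -1),
             gbest = 6, gbest_fit = -1, K = 10)
  set.seed(42)
  phi1 <- runif(2); phi2 <- runif(2)
  v_exp <- 0.7 * st$v + 1.5 * phi1 * (st$pbest - st$x) + 1.5 * phi2 * (st$gbest - st$x)
  x_exp <- pmin(pmax(st$x + v_exp, 1), 10)
  set.seed(42)
  out3 <- pso_step(st, cfg, obj)
  expect_equal(out3$v, v_exp)
  expect_equal(out3$x, x_exp)
})

test_that("qpso_step honours the attractor and mean-best identities", {
  cfg <- swarm_config(s = 3, alpha = 0.7)
  obj <- function(k) -abs(k - 4)
  # all personal bests identical and x at the mean best: positions stay put
  st <- list(x = c(4, 4, 4), v = numeric(3), pbest = c(4, 4, 4),
             pbest_fit = rep(obj(4), 3), gbest = 4, gbest_fit = obj(4), K = 10)
  set.seed(3)
  out <- qpso_step(st, cfg, obj)
  expect_equal(out$x, c(4, 4, 4))   # |m_best - x| = 0 and PP = P = Pg
  expect_equal(out$gbest, 4)
})

test_that("optimize_edges: brute oracle, swarm agreement, monotone trace", {
  pr <- planner_problem(K = 10, epi = toy_epi, cost = 0.01)
  brute <- optimize_edges(pr, method = "brute")
  expect_equal(brute$profit, max(vapply(1:10, function(k) profit(k, pr), numeric(1))))
  expect_equal(profit(brute$k_star, pr), brute$profit)
  cfg <- swarm_config(s = 30, iterations = 100, alpha = 0.7, seed = 1)
  q <- optimize_edges(pr, cfg, method = "qpso")
  expect_identical(q$k_star, brute$k_star)
  p <- optimize_edges(pr, cfg, method = "pso")
  expect_identical(p$k_star, brute$k_star)
  expect_true(all(diff(q$trace) >= 0))
  expect_true(all(diff(p$trace) >= 0))
  # determinism: identical seeds give identical traces
  expect_identical(q$trace, optimize_edges(pr, cfg, method = "qpso")$trace)
  expect_error(optimize_edges(pr, cfg, method = "anneal"), class = "fangmark_planner")
})

test_that("swarms recover the brute-force optimum on random problems", {
  hits_q <- 0; hits_p <- 0
  n_prob <- 10
  for (i in seq_len(n_prob)) {
    set.seed(1000 + i)
    K <- sample(5:50, 1)
    n <- sample(50:2000, 1)
    d <- rbinom(1, n, 0.03); p <- rbinom(1, n - d, 0.08)
    pr <- planner_problem(K, list(n = n, d = d, p = p), cost = runif(1, 0, 0.05))
    best <- optimize_edges(pr, method = "brute")$profit
    cfg <- swarm_config(s = 30, iterations = 150, omega = 0.7, c1 = 1.5,
                        c2 = 1.5, alpha = 0.7, seed = i)
    if (abs(optimize_edges(pr, cfg, "qpso")$profit - best) < 1e-12) hits_q <- hits_q + 1
    if (abs(optimize_edges(pr, cfg, "pso")$profit - best) < 1e-12) hits_p <- hits_p + 1
  }
  expect_gte(hits_q, n_prob - 1)
  expect_gte(hits_p, n_prob - 1)
})

test_that("plan_edges runs per state and reports delays", {
  epi <- generate_state_table(3, seed = 5)
  plan <- plan_edges(epi, K = 15, cost = 0.01,
                     config = swarm_config(iterations = 40, seed = 2))
  expect_named(plan, as.character(epi$state))
  for (i in seq_len(nrow(epi))) {
    res <- plan[[i]]
    expect_true(res$k_star >= 1 && res$k_star <= 15)
    expect_equal(res$delay, 1 / res$k_star)
  }
})
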