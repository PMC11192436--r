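# toy_stats (helper-fixtures.R): toolbox {MINI: r = 3.0, c = 8; WADD: r = 3.2,
# c = 16} on problem P1, where MINI chooses B and WADD chooses A.

test_that("strategy selection matches hand arithmetic on the worked triples", {
  expect_equal(select_strategy(c("MINI", "WADD"), 0, toy_stats, "P1"), "WADD")
  expect_equal(select_strategy(c("MINI", "WADD"), 0.1, toy_stats, "P1"), "MINI")
  # delta = 0.025: both score 2.8 -> uniform random tie
  picks <- vapply(1:200, function(i) {
    withr::with_seed(i, select_strategy(c("MINI", "WADD"), 0.025, toy_stats, "P1"))
  }, character(1))
  expect_setequal(unique(picks), c("MINI", "WADD"))
  expect_gt(mean(picks == "MINI"), 0.3)
  expect_lt(mean(picks == "MINI"), 0.7)
  expect_error(select_strategy(c("MINI", "PH"), 0, toy_stats, "P1"),
               "missing strategies")
})

test_that("agent parameter validation enforces the declared ranges", {
  expect_error(agent_params(character(0), 1, 0.1), "nonempty")
  expect_error(agent_params(c("MINI", "MINI"), 1, 0.1), "duplicates")
  expect_error(agent_params("MINI", -1, 0.1))
  expect_error(agent_params("MINI", 1, 0.6))
  expect_silent(agent_params(strategy_ids()[1:7], 0, 0))
})

test_that("choice probability follows the trembling-hand mixture", {
  det_a <- agent_params("WADD", 0, 0.1)
  expect_equal(choice_probability("P1", det_a, toy_stats, seed = 1), 0.9)
  det_b <- agent_params("MINI", 0, 0.1)
  expect_equal(choice_probability("P1", det_b, toy_stats, seed = 1), 0.1)
  # epsilon = 0.5 collapses to 0.5 exactly, whatever the strategy does
  expect_equal(choice_probability("P1", agent_params("WADD", 0, 0.5), toy_stats,
                                  seed = 1), 0.5)
  # bounded in [eps, 1 - eps] even under selection ties
  tied <- agent_params(c("MINI", "WADD"), 0.025, 0.2)
  pr <- choice_probability("P1", tied, toy_stats, reps = 400, seed = 2)
  expect_gte(pr, 0.2)
  expect_lte(pr, 0.8)
  expect_lt(abs(pr - 0.5), 0.15)
})

test_that("log-likelihood reproduces closed-form single-agent arithmetic", {
  one_a <- data.frame(problem_id = "P1", choice = "A", stringsAsFactors = FALSE)
  one_b <- data.frame(problem_id = "P1", choice = "B", stringsAsFactors = FALSE)
  wadd <- function(e) agent_params("WADD", 0, e)
  expect_equal(log_likelihood(one_a, wadd(0.2), toy_stats, seed = 1), log(0.8))
  expect_equal(log_likelihood(one_b, wadd(0.2), toy_stats, seed = 1), log(0.2))
  # 10 deterministic matched trials at epsilon = 0.26 -> 10 * log(0.74)
  ids <- sprintf("q%02d", 1:10)
  st10 <- structure(list(
    strategies = "WADD", problem_ids = ids,
    r = matrix(1, 1, 10, dimnames = list("WADD", ids)),
    cost = matrix(16, 1, 10, dimnames = list("WADD", ids)),
    p_a = matrix(1, 1, 10, dimnames = list("WADD", ids)),
    reps = 1), class = "strategy_stats")
  all_a <- data.frame(problem_id = ids, choice = "A", stringsAsFactors = FALSE)
  expect_equal(log_likelihood(all_a, wadd(0.26), st10, seed = 1), 10 * log(0.74))
  # epsilon = 0 with a contradicted deterministic prediction is an error
  expect_error(log_likelihood(one_b, wadd(0), toy_stats, seed = 1), "epsilon = 0")
  expect_equal(log_likelihood(one_a, wadd(0), toy_stats, seed = 1), 0)
})

test_that("selection follows the linear payoff-cost trade-off across delta", {
  probs <- random_problems(25, seed = 61)
  st <- compute_strategy_stats(strategy_ids(), probs, reps = 30, seed = 7)
  deltas <- seq(0, 20, by = 0.5)
  withr::with_seed(71, for (k in 1:10) {
    tb <- sample(strategy_ids(), sample(2:5, 1))
    for (col in sample(length(probs), 4)) {
      costs <- vapply(deltas, function(d) selected_cost(tb, d, st, col), numeric(1))
      expect_true(all(diff(costs) <= 1e-9),
                  label = sprintf("cost non-increasing for {%s}", paste(tb, collapse = ",")))
      # delta = 0 maximizes payoff; very large delta minimizes cost
      s0 <- select_strategy(tb, 0, st, col)
      expect_equal(st$r[s0, col], max(st$r[tb, col]))
      s_inf <- select_strategy(tb, 1e6, st, col)
      expect_equal(st$cost[s_inf, col], min(st$cost[tb, col]))
    }
  })
})

test_that("simulated choices honor the parameters and the seed", {
  probs <- random_problems(30, seed = 67)
  st <- compute_strategy_stats(strategy_ids(), probs, reps = 30, seed = 8)
  # epsilon = 0, toolbox {WADD}: always the higher-EV option on non-tied problems
  sim <- simulate_choices(agent_params("WADD", 0, 0), probs, n_reps = 2,
                          seed = 5, stats = st)
  for (i in seq_len(nrow(sim))) {
    p <- probs[[match(sim$problem_id[i], vapply(probs, function(q) q$id, character(1)))]]
    if (abs(expected_value(p$a) - expected_value(p$b)) > 1e-9) {
      expect_equal(sim$choice[i], if (expected_value(p$a) > expected_value(p$b)) "A" else "B")
    }
  }
  # epsilon = 0.5: choice frequencies hover around one half
  sim5 <- simulate_choices(agent_params("WADD", 0, 0.5), probs, n_reps = 60,
                           seed = 6, stats = st)
  expect_lt(abs(mean(sim5$choice == "A") - 0.5), 0.05)
  # bitwise determinism
  expect_identical(
    simulate_choices(agent_params(c("MINI", "WADD"), 1, 0.2), probs, 3, seed = 9, stats = st),
    simulate_choices(agent_params(c("MINI", "WADD"), 1, 0.2), probs, 3, seed = 9, stats = st)
  )
})

test_that("grid fit equals brute-force enumeration on a micro-grid", {
  probs <- random_problems(8, seed = 73)
  st <- compute_strategy_stats(c("MINI", "PH", "WADD"), probs, reps = 20, seed = 3)
  truth <- agent_params(c("MINI", "WADD"), 0.3, 0.15)
  dat <- simulate_choices(truth, probs, n_reps = 1, seed = 4, stats = st)
  grid <- list(sizes = 1:2, delta = c(0, 0.5, 1, 2), eps = c(0.1, 0.2, 0.3))
  fit <- fit_participant(dat, st, candidate_strategies = c("MINI", "PH", "WADD"),
                         toolbox_sizes = grid$sizes, delta_grid = grid$delta,
                         epsilon_grid = grid$eps, reps = 10, seed = 21)
  oracle <- enumerate_fit(dat, st, c("MINI", "PH", "WADD"), grid$sizes,
                          grid$delta, grid$eps, reps = 10, seed = 21)
  expect_equal(fit$log_lik, oracle$best_ll)
  expect_equal(length(fit$params$toolbox), oracle$min_size)
  expect_true(fit_in_argmax(fit, oracle))
})

test_that("equal-likelihood maxima prefer the smaller toolbox", {
  # MINI and MAXI decide identically on these problems (A dominates or is
  # dominated), so every toolbox over them has the same likelihood
  pa <- choice_problem(gamble(c(10, 5), c(0.5, 0.5)), gamble(c(4, 2), c(0.5, 0.5)), id = "d1")
  pb <- choice_problem(gamble(c(9, 6), c(0.5, 0.5)), gamble(c(3, 1), c(0.5, 0.5)), id = "d2")
  st <- compute_strategy_stats(c("MINI", "MAXI"), list(pa, pb), reps = 10, seed = 1)
  dat <- data.frame(problem_id = c("d1", "d2"), choice = "A", stringsAsFactors = FALSE)
  fit <- fit_participant(dat, st, candidate_strategies = c("MINI", "MAXI"),
                         toolbox_sizes = 1:2, delta_grid = 0,
                         epsilon_grid = c(0.1, 0.2), reps = 5, seed = 2)
  expect_equal(length(fit$params$toolbox), 1L)
  expect_gt(fit$n_ties_at_max, 1L)
})

test_that("fitted likelihood is at least the likelihood at the generating parameters", {
  probs <- random_problems(40, seed = 79)
  st <- compute_strategy_stats(strategy_ids(), probs, reps = 30, seed = 11)
  truth <- agent_params(c("PH", "EQW"), 0.5, 0.2)
  dat <- simulate_choices(truth, probs, n_reps = 1, seed = 12, stats = st)
  fit <- fit_participant(dat, st, grid = "desk", seed = 13)
  ll_truth <- log_likelihood(dat, truth, st, reps = 20, seed = 13)
  expect_gte(fit$log_lik, ll_truth - 1e-9)
})

test_that("posterior predictive recovers a self-generated dataset", {
  probs <- random_problems(40, seed = 83)
  st <- compute_strategy_stats(strategy_ids(), probs, reps = 30, seed = 14)
  params <- agent_params("WADD", 0, 0.01)
  dat <- simulate_choices(params, probs, n_reps = 1, seed = 15, stats = st)
  ppc <- posterior_predictive(params, probs, dat, stats = st, reps = 50, seed = 16)
  expect_gt(ppc$match_proportion, 0.9)
  # normalized strategy counts sum to the number of trials
  expect_equal(sum(ppc$strategy_counts), length(probs))
  expect_true(all(c("overall", "gain", "loss", "mixed") %in% names(ppc$decision_quality)))
  noisy <- agent_params("WADD", 0, 0.5)
  ppc5 <- posterior_predictive(noisy, probs, dat, stats = st, reps = 50, seed = 17)
  expect_lt(abs(ppc5$match_proportion - 0.5), 0.07)
})
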