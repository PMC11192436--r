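test_that("the default problem set matches the study design", {
  probs <- generate_problem_set(problem_set_config(), seed = 1)
  expect_length(probs, 105)
  domains <- vapply(probs, function(p) p$domain, character(1))
  expect_equal(unname(table(domains)[c("gain", "loss", "mixed")]),
               c(41, 31, 33), ignore_attr = TRUE)
  has_safe <- vapply(probs, function(p) {
    length(p$a$payoffs) == 1L || length(p$b$payoffs) == 1L
  }, logical(1))
  expect_equal(sum(has_safe), 9)
  # two risky two-outcome gambles everywhere else
  expect_true(all(vapply(probs[!has_safe], function(p) {
    length(p$a$payoffs) == 2L && length(p$b$payoffs) == 2L
  }, logical(1))))
  # no EV or CV ties: decision quality and risk aversion defined everywhere
  for (p in probs) {
    expect_false(is.na(decision_quality(p, "A")))
    expect_false(is.na(risk_aversion_indicator(p, "A")))
  }
})

test_that("problem generation is reproducible and configurable", {
  expect_identical(generate_problem_set(problem_set_config(), seed = 2),
                   generate_problem_set(problem_set_config(), seed = 2))
  one <- generate_problem_set(
    problem_set_config(n_gain = 1, n_loss = 0, n_mixed = 0, n_safe = 0), seed = 3)
  expect_length(one, 1)
  expect_equal(one[[1]]$domain, "gain")
  expect_error(problem_set_config(n_gain = 2, n_loss = 1, n_mixed = 5, n_safe = 4),
               "n_safe exceeds")
})

test_that("dominance exclusion removes first-order dominated pairs", {
  cfg <- problem_set_config(n_gain = 15, n_loss = 5, n_mixed = 5, n_safe = 0,
                            exclude_dominated = TRUE)
  probs <- generate_problem_set(cfg, seed = 4)
  fosd <- rrchoice:::fosd
  for (p in probs) {
    expect_false(fosd(p$a, p$b) || fosd(p$b, p$a))
  }
})

test_that("generated populations carry a faithful ground-truth table", {
  probs <- generate_problem_set(
    problem_set_config(n_gain = 10, n_loss = 6, n_mixed = 6, n_safe = 2), seed = 5)
  pop_cfg <- population_config(n_younger = 4, n_older = 4)
  pop <- generate_population(pop_cfg, probs, seed = 6)
  expect_equal(nrow(pop$truth), 8)
  expect_equal(nrow(pop$choices), 8 * length(probs))
  expect_equal(sort(unique(pop$choices$age_group)), c("older", "younger"))
  expect_true(all(pop$truth$epsilon >= 0.01 & pop$truth$epsilon <= 0.5))
  expect_true(all(pop$truth$delta >= 0))
  sizes <- vapply(strsplit(pop$truth$toolbox, ","), length, integer(1))
  expect_true(all(sizes >= 1 & sizes <= 7))
  expect_identical(pop, generate_population(pop_cfg, probs, seed = 6))
})

test_that("error-free agents with the EV strategy achieve perfect decision quality", {
  probs <- generate_problem_set(
    problem_set_config(n_gain = 8, n_loss = 5, n_mixed = 5, n_safe = 2), seed = 7)
  sim <- simulate_choices(agent_params("WADD", 0, 0), probs, n_reps = 2, seed = 8)
  pid <- vapply(probs, function(p) p$id, character(1))
  dq <- mapply(function(id, ch) decision_quality(probs[[match(id, pid)]], ch),
               sim$problem_id, sim$choice)
  expect_equal(mean(dq, na.rm = TRUE), 1)
})

test_that("recovery scoring is exact on identity and detects mismatched ids", {
  truth <- data.frame(
    participant_id = c("a1", "a2"), age_group = "younger",
    toolbox = c("MINI,WADD", "EQW"), delta = c(1, 2), epsilon = c(0.1, 0.2),
    stringsAsFactors = FALSE
  )
  fits <- truth[c("participant_id", "toolbox", "delta", "epsilon")]
  sc <- score_recovery(truth, fits)
  expect_equal(sc$summary$mean_jaccard, 1)
  expect_equal(sc$summary$mean_abs_delta_error, 0)
  expect_equal(sc$summary$prop_epsilon_within, 1)
  bad <- fits
  bad$participant_id <- c("a1", "zz")
  expect_error(score_recovery(truth, bad), "ids")
})

test_that("the random-subset Jaccard baseline sits well below perfect overlap", {
  truth <- data.frame(
    participant_id = sprintf("a%d", 1:10), age_group = "younger",
    toolbox = replicate(10, paste(sort(sample(strategy_ids(), 3)), collapse = ",")),
    delta = 1, epsilon = 0.1, stringsAsFactors = FALSE
  )
  base <- random_jaccard_baseline(truth, truth, n_draws = 3000, seed = 9)
  # analytic expectation for two random 3-subsets of 11 is about 0.2
  expect_gt(base, 0.05)
  expect_lt(base, 0.45)
})

test_that("generated datasets round-trip through the CSV layer", {
  probs <- generate_problem_set(
    problem_set_config(n_gain = 6, n_loss = 4, n_mixed = 4, n_safe = 2), seed = 10)
  pop <- generate_population(population_config(n_younger = 2, n_older = 2),
                             probs, seed = 11)
  pdir <- withr::local_tempdir()
  write_problems(probs, file.path(pdir, "problems.csv"))
  write_choices(pop$choices[c("participant_id", "age_group", "problem_id", "choice")],
                file.path(pdir, "choices.csv"))
  probs2 <- read_problems(file.path(pdir, "problems.csv"))
  expect_equal(vapply(probs2, function(p) p$id, character(1)),
               vapply(probs, function(p) p$id, character(1)))
  ch2 <- read_choices(file.path(pdir, "choices.csv"))
  expect_equal(ch2$choice, pop$choices$choice)
})
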