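test_that("expected value and coefficient of variation match hand arithmetic", {
  expect_equal(expected_value(p1$a), 3.2)
  expect_equal(expected_value(p1$b), 3.0)
  expect_equal(expected_value(p2$a), -3.2)
  # SD = 1.6, EV = 3.2
  expect_equal(coefficient_of_variation(p1$a), 0.5)
  expect_equal(coefficient_of_variation(p1$b), 0.0)
  expect_true(is.na(coefficient_of_variation(gamble(c(1, -1), c(0.5, 0.5)))))
})

test_that("gamble validation rejects malformed inputs", {
  expect_error(gamble(numeric(0), numeric(0)), "at least one outcome")
  expect_error(gamble(c(1, 2), c(0.5, 0.6)), "sum to 1")
  expect_error(gamble(c(1, 2), c(1.2, -0.2)), "0, 1")
  expect_silent(gamble(c(1, 2), c(0.5 + 1e-12, 0.5)))
})

test_that("EV is linear in payoffs and CV is scale invariant", {
  gs <- withr::with_seed(5, replicate(50, {
    pr <- runif(1, 0.05, 0.95)
    gamble(sample(-50:50, 2), c(pr, 1 - pr))
  }, simplify = FALSE))
  for (g in gs) {
    k <- 3.7
    scaled <- gamble(k * g$payoffs, g$probs)
    expect_equal(expected_value(scaled), k * expected_value(g))
    if (!is.na(coefficient_of_variation(g))) {
      expect_equal(coefficient_of_variation(scaled), coefficient_of_variation(g))
      flipped <- gamble(-g$payoffs, g$probs)
      expect_equal(coefficient_of_variation(flipped), coefficient_of_variation(g))
    }
  }
})

test_that("domain classification follows outcome signs", {
  expect_equal(p1$domain, "gain")
  expect_equal(p2$domain, "loss")
  pm <- choice_problem(gamble(c(5, -5), c(0.5, 0.5)), gamble(1, 1))
  expect_equal(pm$domain, "mixed")
  expect_error(choice_problem(gamble(0, 1), gamble(c(0, 0), c(0.5, 0.5))),
               "all payoffs are zero")
})

test_that("degenerate problems with identical options are rejected", {
  expect_error(choice_problem(gamble(c(4, 0), c(0.8, 0.2)),
                              gamble(c(0, 4), c(0.2, 0.8))),
               "identical")
})

test_that("decision quality and risk aversion behave as indicators", {
  expect_equal(decision_quality(p1, "A"), 1)
  expect_equal(decision_quality(p1, "B"), 0)
  expect_equal(risk_aversion_indicator(p1, "B"), 1)
  expect_equal(risk_aversion_indicator(p1, "A"), 0)
  # EV tie -> undefined
  tie <- choice_problem(gamble(c(4, 0), c(0.5, 0.5)), gamble(2, 1))
  expect_true(is.na(decision_quality(tie, "A")))
  # both options safe: CVs tie at zero
  safe2 <- choice_problem(gamble(3, 1), gamble(5, 1))
  expect_true(is.na(risk_aversion_indicator(safe2, "A")))
})

test_that("indicators are complementary across the two choices when defined", {
  probs <- random_problems(200, seed = 11)
  for (p in probs) {
    dq <- c(decision_quality(p, "A"), decision_quality(p, "B"))
    ra <- c(risk_aversion_indicator(p, "A"), risk_aversion_indicator(p, "B"))
    if (!anyNA(dq)) expect_equal(sum(dq), 1)
    if (!anyNA(ra)) expect_equal(sum(ra), 1)
    expect_equal(is.na(dq[1]), is.na(dq[2]))
    expect_equal(is.na(ra[1]), is.na(ra[2]))
  }
})

test_that("problem and choice CSV round-trips are lossless", {
  problems <- c(list(p1, p2), random_problems(20, seed = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_problems(problems, path)
  back <- read_problems(path)
  expect_equal(length(back), length(problems))
  for (i in seq_along(problems)) {
    expect_equal(back[[i]]$id, problems[[i]]$id)
    expect_equal(back[[i]]$domain, problems[[i]]$domain)
    expect_equal(back[[i]]$a$payoffs, problems[[i]]$a$payoffs)
    expect_equal(back[[i]]$a$probs, problems[[i]]$a$probs)
    expect_equal(back[[i]]$b$payoffs, problems[[i]]$b$payoffs)
  }

  choices <- data.frame(
    participant_id = c("s1", "s1", "s2"),
    age_group = c("younger", "younger", "older"),
    problem_id = c("P1", "P2", "P1"),
    choice = c("A", "B", "B"),
    stringsAsFactors = FALSE
  )
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_choices(choices, cpath)
  expect_equal(read_choices(cpath), choices)
})

test_that("choice dataset validation enforces the schema", {
  bad_dup <- data.frame(
    participant_id = c("s1", "s1"), age_group = "younger",
    problem_id = c("P1", "P1"), choice = c("A", "B")
  )
  expect_error(validate_choices(bad_dup), "at most once")
  bad_choice <- data.frame(
    participant_id = "s1", age_group = "younger",
    problem_id = "P1", choice = "C"
  )
  expect_error(validate_choices(bad_choice), "'A' or 'B'")
  ok <- data.frame(
    participant_id = "s1", age_group = "younger",
    problem_id = "P9", choice = "A"
  )
  expect_error(validate_choices(ok, problems = list(p1)), "unknown problems")
})
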