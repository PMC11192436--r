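# Shared fixtures: the two hand-worked problems used throughout, plus a
# random-problem generator for property-style tests.

p1 <- choice_problem(gamble(c(4, 0), c(0.8, 0.2)), gamble(3, 1), id = "P1")
p2 <- choice_problem(gamble(c(-4, 0), c(0.8, 0.2)), gamble(-3, 1), id = "P2")

# small random problem: two two-outcome gambles (or one safe option), any
# domain; intentionally permits EV/CV ties and duplicate outcome values so
# the tie paths get exercised
random_problem <- function(id = "r") {
  draw_option <- function() {
    if (stats::runif(1) < 0.15) {
      return(gamble(sample(-20:20, 1), 1))
    }
    pr <- sample(seq(0.05, 0.95, by = 0.05), 1)
    gamble(sample(-20:20, 2, replace = TRUE), c(pr, 1 - pr))
  }
  repeat {
    a <- draw_option()
    b <- draw_option()
    p <- tryCatch(choice_problem(a, b, id = id), error = function(e) NULL)
    if (!is.null(p)) return(p)
  }
}

random_problems <- function(n, seed) {
  withr::with_seed(seed, lapply(seq_len(n), function(i) {
    random_problem(id = sprintf("r%04d", i))
  }))
}

# minimal hand-built strategy_stats for worked selection examples:
# toolbox {MINI: r = 3.0, c = 8; WADD: r = 3.2, c = 16} on one problem
toy_stats <- structure(
  list(
    strategies = c("MINI", "WADD"),
    problem_ids = "P1",
    r = matrix(c(3.0, 3.2), 2, 1, dimnames = list(c("MINI", "WADD"), "P1")),
    cost = matrix(c(8, 16), 2, 1, dimnames = list(c("MINI", "WADD"), "P1")),
    p_a = matrix(c(0, 1), 2, 1, dimnames = list(c("MINI", "WADD"), "P1")),
    reps = 1
  ),
  class = "strategy_stats"
)
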