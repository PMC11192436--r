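#' Count the elementary information processes of one strategy execution
#'
#' The cost of a strategy on a problem is the number of elementary
#' information processes (EIPs) in its execution trace: reads, comparisons,
#' differences, additions, multiplications, eliminations, and the final
#' choice. Early-stopping strategies (the priority heuristic) yield
#' path-dependent counts; random tie-breaking never changes the count.
#'
#' @param strategy One of [strategy_ids()].
#' @param p A [choice_problem()].
#' @return Positive integer EIP count.
#' @export
count_eips <- function(strategy, p) {
  length(strategy_decision(strategy, p)$trace) + 1L  # + final CHOOSE
}

#' Read a fixed cost scheme from a YAML file
#'
#' A cost scheme file maps strategy ids to fixed EIP counts, overriding the
#' default trace-based counting, e.g. `MINI: 8`. Useful for auditing how the
#' cost ordering, rather than the exact counts, drives the analysis.
#'
#' @param path YAML file path.
#' @return Named numeric vector keyed by strategy id.
#' @export
read_cost_scheme <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- vapply(raw, as.numeric, numeric(1))
  unknown <- setdiff(names(out), strategy_ids())
  if (length(unknown) > 0L) {
    stop("unknown strategies in cost scheme: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Expected payoff and cost of strategies on problems
#'
#' For every strategy and problem, simulates the strategy's choice `reps`
#' times and averages: the expected payoff `r` is the expected value of the
#' gamble the strategy selects (objective EV of the chosen option, not a
#' realized draw), and the cost `c` is the EIP count of the execution trace.
#' Strategies are deterministic up to random tie-breaking, so only the
#' payoff of tie-prone cells actually varies across repetitions; costs do
#' not depend on how ties are resolved.
#'
#' @param strategies Character vector of strategy ids (default all 11).
#' @param problems Nonempty list of [choice_problem()] objects.
#' @param reps Simulation repetitions used for averaging (default 100).
#' @param seed Optional integer seed.
#' @param cost_scheme Optional named numeric vector (or result of
#'   [read_cost_scheme()]) of fixed per-strategy costs; strategies absent
#'   from the scheme fall back to trace counting.
#' @return An object of class `strategy_stats` with matrices `r`, `cost`,
#'   and `p_a` (the structural probability of choosing A: 0, 0.5, or 1),
#'   rows = strategies, columns = problems.
#' @export
compute_strategy_stats <- function(strategies = strategy_ids(), problems,
                                   reps = 100, seed = NULL, cost_scheme = NULL) {
  if (length(strategies) == 0L) stop("empty strategy list", call. = FALSE)
  if (length(problems) == 0L) stop("empty problem list", call. = FALSE)
  stopifnot(reps >= 1)
  strategies <- unname(vapply(strategies, match.arg, character(1),
                              choices = strategy_ids()))
  problem_ids <- vapply(problems, function(p) p$id, character(1))
  if (anyDuplicated(problem_ids) > 0L) stop("duplicate problem ids", call. = FALSE)

  run <- function() {
    dims <- list(strategies, problem_ids)
    r <- matrix(NA_real_, length(strategies), length(problems), dimnames = dims)
    cost <- matrix(NA_real_, length(strategies), length(problems), dimnames = dims)
    p_a <- matrix(NA_real_, length(strategies), length(problems), dimnames = dims)
    for (si in seq_along(strategies)) {
      s <- strategies[si]
      for (pi in seq_along(problems)) {
        p <- problems[[pi]]
        d <- strategy_decision(s, p)
        n_eips <- length(d$trace) + 1L
        if (!is.null(cost_scheme) && s %in% names(cost_scheme)) {
          n_eips <- cost_scheme[[s]]
        }
        cost[si, pi] <- n_eips
        ev_a <- expected_value(p$a)
        ev_b <- expected_value(p$b)
        if (is.na(d$choice)) {
          p_a[si, pi] <- 0.5
          picks <- sample(c(ev_a, ev_b), reps, replace = TRUE)
          r[si, pi] <- mean(picks)
        } else {
          p_a[si, pi] <- as.numeric(d$choice == "A")
          r[si, pi] <- if (d$choice == "A") ev_a else ev_b
        }
      }
    }
    structure(
      list(strategies = strategies, problem_ids = problem_ids,
           r = r, cost = cost, p_a = p_a, reps = reps),
      class = "strategy_stats"
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.strategy_stats <- function(x, ...) {
  cat(sprintf("<strategy_stats> %d strategies x %d problems, %d reps\n",
              length(x$strategies), length(x$problem_ids), x$reps))
  cat("  mean cost by strategy:\n")
  print(round(rowMeans(x$cost), 2))
  invisible(x)
}

#' Tidy view of strategy statistics
#' @param x A `strategy_stats` object.
#' @param ... Unused.
#' @return Data frame with columns strategy, problem_id, r, c.
#' @export
as.data.frame.strategy_stats <- function(x, ...) {
  data.frame(
    strategy = rep(x$strategies, times = length(x$problem_ids)),
    problem_id = rep(x$problem_ids, each = length(x$strategies)),
    r = as.vector(x$r),
    c = as.vector(x$cost),
    stringsAsFactors = FALSE
  )
}

#' Write strategy statistics to a tidy CSV
#' @param stats A `strategy_stats` object.
#' @param path Output path.
#' @export
write_strategy_stats <- function(stats, path) {
  utils::write.csv(as.data.frame(stats), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

stats_subset <- function(stats, strategies) {
  missing <- setdiff(strategies, stats$strategies)
  if (length(missing) > 0L) {
    stop("stats missing strategies: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  strategies
}
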