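#' Strategy identifiers
#'
#' The eleven risky-choice heuristics implemented by the package, in their
#' standard abbreviations: MINI (minimax), MAXI (maximax), LL (least-likely),
#' ML (most-likely), BTA (better-than-average), EQW (equal-weight), TALLY
#' (tallying), PROB (probable), LEX (lexicographic), PH (priority heuristic),
#' WADD (weighted-additive).
#'
#' @return Character vector of the 11 strategy ids.
#' @export
strategy_ids <- function() {
  c("MINI", "MAXI", "LL", "ML", "BTA", "EQW", "TALLY", "PROB", "LEX", "PH", "WADD")
}

#' Elementary information process kinds
#'
#' Fixed taxonomy of the atomic mental operations counted as strategy cost.
#' @return Character vector of EIP kinds.
#' @export
eip_kinds <- function() {
  c("READ", "COMPARE", "DIFFERENCE", "ADD", "PRODUCT", "ELIMINATE", "CHOOSE")
}

# trace helpers: traces are character vectors over eip_kinds()
eips <- function(kind, n) if (n > 0L) rep(kind, n) else character(0)

# score comparison with exact-tie tolerance; NA means indifference
choose_by_score <- function(s_a, s_b) {
  if (is.infinite(s_a) && is.infinite(s_b) && s_a == s_b) return(NA_character_)
  if (abs(s_a - s_b) < 1e-9) return(NA_character_)
  if (s_a > s_b) "A" else "B"
}

# most likely outcome of a gamble; probability ties resolved toward the
# higher payoff (documented convention)
most_likely <- function(g, rank = 1L) {
  ord <- order(-g$probs, -g$payoffs)
  idx <- ord[min(rank, length(ord))]
  list(payoff = g$payoffs[idx], prob = g$probs[idx])
}

# worst outcome value and its total probability (duplicates pooled)
worst_outcome <- function(g) {
  m <- min(g$payoffs)
  list(payoff = m, prob = sum(g$probs[g$payoffs == m]))
}

best_outcome <- function(g) {
  m <- max(g$payoffs)
  list(payoff = m, prob = sum(g$probs[g$payoffs == m]))
}

# ---- individual strategies ---------------------------------------------------
# each returns list(choice = "A"/"B"/NA (indifferent), trace = character)

.strat_MINI <- function(p) {
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  trace <- c(eips("READ", na + nb), eips("COMPARE", (na - 1) + (nb - 1)),
             eips("COMPARE", 1))
  list(choice = choose_by_score(min(p$a$payoffs), min(p$b$payoffs)), trace = trace)
}

.strat_MAXI <- function(p) {
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  trace <- c(eips("READ", na + nb), eips("COMPARE", (na - 1) + (nb - 1)),
             eips("COMPARE", 1))
  list(choice = choose_by_score(max(p$a$payoffs), max(p$b$payoffs)), trace = trace)
}

.strat_LL <- function(p) {
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  trace <- c(eips("READ", na + nb), eips("COMPARE", (na - 1) + (nb - 1)),
             eips("READ", 2), eips("COMPARE", 1))
  # lower probability of the worst outcome is better
  list(choice = choose_by_score(-worst_outcome(p$a)$prob, -worst_outcome(p$b)$prob),
       trace = trace)
}

.strat_ML <- function(p) {
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  trace <- c(eips("READ", na + nb), eips("COMPARE", (na - 1) + (nb - 1)),
             eips("READ", 2), eips("COMPARE", 1))
  list(choice = choose_by_score(most_likely(p$a)$payoff, most_likely(p$b)$payoff),
       trace = trace)
}

.strat_BTA <- function(p) {
  x <- problem_payoffs(p)
  n <- length(x)
  grand <- mean(x)
  count_a <- sum(p$a$payoffs >= grand - 1e-12)
  count_b <- sum(p$b$payoffs >= grand - 1e-12)
  trace <- c(eips("READ", n), eips("ADD", n - 1), eips("PRODUCT", 1),
             eips("COMPARE", n), eips("COMPARE", 1))
  list(choice = choose_by_score(count_a, count_b), trace = trace)
}

.strat_EQW <- function(p) {
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  trace <- c(eips("READ", na + nb), eips("ADD", (na - 1) + (nb - 1)),
             eips("COMPARE", 1))
  list(choice = choose_by_score(sum(p$a$payoffs), sum(p$b$payoffs)), trace = trace)
}

.strat_TALLY <- function(p) {
  # On signed payoffs the stated loss-domain substitution reduces to the same
  # four criteria as the gain version, so one signed rule serves all domains:
  # tally for the higher minimum, higher maximum, lower probability of the
  # minimum, higher probability of the maximum; within-criterion ties give no
  # mark to either option.
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  wa <- worst_outcome(p$a); wb <- worst_outcome(p$b)
  ba <- best_outcome(p$a); bb <- best_outcome(p$b)
  mark <- function(v_a, v_b) c(v_a > v_b + 1e-9, v_b > v_a + 1e-9)
  tallies <- mark(wa$payoff, wb$payoff) +        # higher minimum
    mark(ba$payoff, bb$payoff) +                 # higher maximum
    mark(-wa$prob, -wb$prob) +                   # lower p(minimum)
    mark(ba$prob, bb$prob)                       # higher p(maximum)
  prob_reads <- function(n) if (n == 1L) 1L else 2L
  trace <- c(eips("READ", na + nb),
             eips("COMPARE", 2 * ((na - 1) + (nb - 1))),
             eips("READ", prob_reads(na) + prob_reads(nb)),
             eips("COMPARE", 4), eips("COMPARE", 1))
  list(choice = choose_by_score(tallies[1], tallies[2]), trace = trace)
}

.strat_PROB <- function(p) {
  prob_mean <- function(g) {
    keep <- g$probs >= 0.5 - 1e-12
    if (!any(keep)) -Inf else mean(g$payoffs[keep])
  }
  k <- function(g) sum(g$probs >= 0.5 - 1e-12)
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  ka <- k(p$a); kb <- k(p$b)
  trace <- c(eips("READ", na + nb), eips("COMPARE", na + nb),
             eips("ELIMINATE", (na - ka) + (nb - kb)),
             eips("READ", ka + kb),
             eips("ADD", max(ka - 1, 0) + max(kb - 1, 0)),
             eips("PRODUCT", (ka >= 2) + (kb >= 2)),
             eips("COMPARE", 1))
  list(choice = choose_by_score(prob_mean(p$a), prob_mean(p$b)), trace = trace)
}

.strat_LEX <- function(p) {
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  trace <- c(eips("READ", na + nb), eips("COMPARE", (na - 1) + (nb - 1)),
             eips("READ", 2), eips("COMPARE", 1))
  first <- choose_by_score(most_likely(p$a)$payoff, most_likely(p$b)$payoff)
  if (!is.na(first)) {
    return(list(choice = first, trace = trace))
  }
  # second most likely outcome; a safe option keeps its single payoff
  trace <- c(trace, eips("READ", 2), eips("COMPARE", 1))
  second <- choose_by_score(most_likely(p$a, 2L)$payoff, most_likely(p$b, 2L)$payoff)
  list(choice = second, trace = trace)
}

.strat_PH <- function(p) {
  # Attribute order: minimum (worst) outcome, probability of the minimum,
  # maximum outcome, all on signed payoffs. Aspiration level for the first
  # attribute is 1/10 of the maximum gain (gain and mixed problems) or 1/10
  # of the largest absolute loss (loss problems); the probability aspiration
  # is fixed at 0.1 of the probability scale.
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  x <- problem_payoffs(p)
  aspiration <- 0.1 * if (p$domain == "loss") max(abs(x)) else max(x)
  wa <- worst_outcome(p$a); wb <- worst_outcome(p$b)
  trace <- c(eips("READ", na + nb), eips("COMPARE", (na - 1) + (nb - 1)),
             eips("COMPARE", na + nb - 1), eips("PRODUCT", 1),
             eips("DIFFERENCE", 1), eips("COMPARE", 1))
  if (abs(wa$payoff - wb$payoff) >= aspiration - 1e-9) {
    return(list(choice = choose_by_score(wa$payoff, wb$payoff), trace = trace))
  }
  trace <- c(trace, eips("READ", 2), eips("DIFFERENCE", 1), eips("COMPARE", 1))
  if (abs(wa$prob - wb$prob) >= 0.1 - 1e-9) {
    return(list(choice = choose_by_score(-wa$prob, -wb$prob), trace = trace))
  }
  trace <- c(trace, eips("COMPARE", (na - 1) + (nb - 1)), eips("COMPARE", 1))
  list(choice = choose_by_score(max(p$a$payoffs), max(p$b$payoffs)), trace = trace)
}

.strat_WADD <- function(p) {
  na <- length(p$a$payoffs); nb <- length(p$b$payoffs)
  trace <- c(eips("READ", 2 * (na + nb)), eips("PRODUCT", na + nb),
             eips("ADD", (na - 1) + (nb - 1)), eips("COMPARE", 1))
  list(choice = choose_by_score(expected_value(p$a), expected_value(p$b)),
       trace = trace)
}

strategy_fun <- function(strategy) {
  strategy <- match.arg(strategy, strategy_ids())
  get(paste0(".strat_", strategy), mode = "function")
}

#' Apply a choice strategy to a problem
#'
#' Executes one heuristic on one choice problem and returns its decision
#' together with the trace of elementary information processes (EIPs) it
#' performed. Strategies are deterministic up to indifference; when a rule is
#' indifferent between the options the choice is resolved uniformly at random
#' using R's current random number stream, and the `tie` flag is set.
#'
#' @param strategy One of [strategy_ids()].
#' @param p A [choice_problem()].
#' @return A list of class `decision` with elements `choice` (`"A"`/`"B"`),
#'   `tie` (logical), and `eip_trace` (character vector over [eip_kinds()],
#'   ending in `CHOOSE`).
#' @examples
#' p1 <- choice_problem(gamble(c(4, 0), c(0.8, 0.2)), gamble(3, 1))
#' apply_strategy("MINI", p1)$choice  # "B": 3 beats a minimum of 0
#' @export
apply_strategy <- function(strategy, p) {
  stopifnot(inherits(p, "choice_problem"))
  res <- strategy_fun(strategy)(p)
  tie <- is.na(res$choice)
  choice <- if (tie) sample(c("A", "B"), 1L) else res$choice
  structure(
    list(choice = choice, tie = tie, eip_trace = c(res$trace, "CHOOSE")),
    class = "decision"
  )
}

#' @export
print.decision <- function(x, ...) {
  cat(sprintf("<decision> %s%s, %d EIPs\n", x$choice,
              if (x$tie) " (tie, random)" else "", length(x$eip_trace)))
  invisible(x)
}

# structural decision without consuming randomness: choice "A"/"B"/NA
strategy_decision <- function(strategy, p) strategy_fun(strategy)(p)

#' Decision profile of a strategy
#'
#' Monte-Carlo probability of choosing option A on each problem. Strategies
#' are deterministic up to indifference, so non-tied problems yield exactly 0
#' or 1; indifferent problems are resolved by `reps` uniform tie-breaks.
#'
#' @param strategy One of [strategy_ids()].
#' @param problems Nonempty list of [choice_problem()] objects.
#' @param reps Number of simulated executions per problem.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector, one P(choose A) per problem.
#' @export
decision_profile <- function(strategy, problems, reps = 100, seed = NULL) {
  if (length(problems) == 0L) stop("empty problem list", call. = FALSE)
  stopifnot(reps >= 1)
  run <- function() {
    vapply(problems, function(p) {
      d <- strategy_decision(strategy, p)
      if (is.na(d$choice)) mean(sample(c(1, 0), reps, replace = TRUE))
      else as.numeric(d$choice == "A")
    }, numeric(1))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Risk profile of a strategy
#'
#' Proportion of simulated choices that select the lower-CV (less risky)
#' option, overall and by problem domain. Problems on which the
#' risk-aversion indicator is undefined (CV tie or undefined CV) are
#' excluded; it is an error if no problem has a defined indicator.
#'
#' @inheritParams decision_profile
#' @return List with `overall` (scalar) and `by_domain` (named vector).
#' @export
risk_profile <- function(strategy, problems, reps = 100, seed = NULL) {
  if (length(problems) == 0L) stop("empty problem list", call. = FALSE)
  stopifnot(reps >= 1)
  run <- function() {
    per_problem <- lapply(problems, function(p) {
      ria <- c(A = risk_aversion_indicator(p, "A"), B = risk_aversion_indicator(p, "B"))
      if (all(is.na(ria))) return(NULL)
      d <- strategy_decision(strategy, p)
      val <- if (is.na(d$choice)) {
        mean(ria[sample(c("A", "B"), reps, replace = TRUE)])
      } else {
        ria[[d$choice]]
      }
      list(domain = p$domain, value = val)
    })
    per_problem <- Filter(Negate(is.null), per_problem)
    if (length(per_problem) == 0L) {
      stop("no problem has a defined risk-aversion indicator", call. = FALSE)
    }
    vals <- vapply(per_problem, `[[`, numeric(1), "value")
    doms <- vapply(per_problem, `[[`, character(1), "domain")
    list(overall = mean(vals),
         by_domain = tapply(vals, factor(doms, c("gain", "loss", "mixed")), mean))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
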