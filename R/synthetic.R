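#' Configuration for a synthetic choice-problem set
#'
#' Defaults emulate the design of the behavioral study the analysis is built
#' around: 105 problems (41 gain, 31 loss, 33 mixed), mostly pairs of
#' two-outcome risky gambles, 9 problems pairing a risky gamble against a
#' safe option. Outcome magnitudes and the probability grid of the original
#' problems are unpublished, so the generator uses integer payoffs up to 100
#' money units and probabilities on a 0.05 grid; both are configurable.
#'
#' @param n_gain,n_loss,n_mixed Problem counts per domain (defaults 41/31/33).
#' @param n_safe Number of problems containing a safe option (default 9;
#'   allocated to the gain and loss domains).
#' @param max_magnitude Largest absolute integer payoff (default 100).
#' @param prob_grid Allowed outcome probabilities (default 0.05 ... 0.95 in
#'   steps of 0.05).
#' @param allow_ties Permit EV or CV ties between options (default FALSE:
#'   problems are rejection-sampled so that decision quality and risk
#'   aversion are defined on every problem).
#' @param exclude_dominated Reject problems with a first-order
#'   stochastically dominant option (default FALSE).
#' @return List of class `problem_set_config`.
#' @export
problem_set_config <- function(n_gain = 41, n_loss = 31, n_mixed = 33,
                               n_safe = 9, max_magnitude = 100,
                               prob_grid = seq(0.05, 0.95, by = 0.05),
                               allow_ties = FALSE, exclude_dominated = FALSE) {
  stopifnot(n_gain >= 0, n_loss >= 0, n_mixed >= 0, n_safe >= 0,
            max_magnitude >= 2, all(prob_grid > 0), all(prob_grid < 1))
  if (n_safe > n_gain + n_loss) {
    stop("n_safe exceeds the number of gain and loss problems", call. = FALSE)
  }
  if (n_gain + n_loss + n_mixed < 1L) {
    stop("at least one problem must be requested", call. = FALSE)
  }
  structure(
    list(n_gain = n_gain, n_loss = n_loss, n_mixed = n_mixed, n_safe = n_safe,
         max_magnitude = max_magnitude, prob_grid = prob_grid,
         allow_ties = allow_ties, exclude_dominated = exclude_dominated),
    class = "problem_set_config"
  )
}

# first-order stochastic dominance of g1 over g2
fosd <- function(g1, g2) {
  ts <- sort(unique(c(g1$payoffs, g2$payoffs)))
  cdf <- function(g, t) sum(g$probs[g$payoffs <= t + 1e-12])
  c1 <- vapply(ts, cdf, numeric(1), g = g1)
  c2 <- vapply(ts, cdf, numeric(1), g = g2)
  all(c1 <= c2 + 1e-12) && any(c1 < c2 - 1e-12)
}

#' Generate a synthetic choice-problem set
#'
#' Draws problems by rejection sampling under the configured constraints:
#' exact domain counts, the configured number of safe-option problems, no
#' degenerate (identical-option or all-zero) problems, and, unless
#' `allow_ties`, options that differ in both expected value and coefficient
#' of variation with both CVs defined.
#'
#' @param config A [problem_set_config()].
#' @param seed Optional integer seed; the same seed reproduces the set.
#' @return List of [choice_problem()] objects.
#' @export
generate_problem_set <- function(config = problem_set_config(), seed = NULL) {
  stopifnot(inherits(config, "problem_set_config"))
  run <- function() {
    draw_risky <- function(domain, min_gap = 0L) {
      repeat {
        mags <- sort(sample.int(config$max_magnitude, 2L))
        pr <- sample(config$prob_grid, 1L)
        pay <- switch(domain,
          gain = c(mags[2], sample(c(0L, mags[1]), 1L)),
          loss = -c(mags[2], sample(c(0L, mags[1]), 1L)),
          mixed = c(mags[2], -mags[1]) * sample(c(1, -1), 1L)
        )
        if (pay[1] != pay[2] && abs(pay[1] - pay[2]) > min_gap) {
          return(gamble(pay, c(pr, 1 - pr)))
        }
      }
    }
    # the safe payoff lies strictly between the risky option's outcomes, as
    # in standard risky-vs-safe designs (otherwise one option dominates)
    draw_safe_between <- function(risky) {
      between <- seq(min(risky$payoffs) + 1L, max(risky$payoffs) - 1L)
      gamble(between[sample.int(length(between), 1L)], 1)
    }
    ok <- function(p) {
      ev_a <- expected_value(p$a); ev_b <- expected_value(p$b)
      if (!config$allow_ties) {
        cv_a <- coefficient_of_variation(p$a)
        cv_b <- coefficient_of_variation(p$b)
        if (abs(ev_a - ev_b) < 1e-6) return(FALSE)
        if (is.na(cv_a) || is.na(cv_b) || abs(cv_a - cv_b) < 1e-6) return(FALSE)
      }
      if (config$exclude_dominated && (fosd(p$a, p$b) || fosd(p$b, p$a))) return(FALSE)
      TRUE
    }
    # allocate safe-option problems to the gain then the loss domain
    n_safe_gain <- min(config$n_safe, config$n_gain)
    n_safe_loss <- config$n_safe - n_safe_gain
    if (n_safe_loss > config$n_loss) {
      stop("cannot place all safe-option problems in the gain and loss domains",
           call. = FALSE)
    }
    plan <- data.frame(
      domain = rep(c("gain", "loss", "mixed"),
                   times = c(config$n_gain, config$n_loss, config$n_mixed)),
      safe = FALSE, stringsAsFactors = FALSE
    )
    plan$safe[which(plan$domain == "gain")[seq_len(n_safe_gain)]] <- TRUE
    if (n_safe_loss > 0L) {
      plan$safe[which(plan$domain == "loss")[seq_len(n_safe_loss)]] <- TRUE
    }
    lapply(seq_len(nrow(plan)), function(i) {
      domain <- plan$domain[i]
      repeat {
        a <- draw_risky(domain, min_gap = if (plan$safe[i]) 1L else 0L)
        b <- if (plan$safe[i]) draw_safe_between(a) else draw_risky(domain)
        p <- tryCatch(
          choice_problem(a, b, id = sprintf("p%03d", i), domain = domain),
          error = function(e) NULL
        )
        if (!is.null(p) && ok(p)) return(p)
      }
    })
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Configuration for a synthetic agent population
#'
#' Describes two age groups of simulated agents characterized by a strategy
#' toolbox, a cost weight `delta`, and a trembling-hand error `epsilon`.
#' The default distributions center on the group-level summaries typical of
#' this paradigm: toolboxes of about three strategies, `delta` around 2
#' with a long right tail and mass near zero, `epsilon` around 0.26. The
#' default group difference is in the toolbox composition only: the younger
#' group's sampling weights favor probability-sensitive strategies (MINI,
#' LL, PH), the older group's favor outcome-only strategies (EQW, MAXI).
#'
#' @param n_younger,n_older Agents per group.
#' @param toolbox_sizes Possible toolbox sizes.
#' @param toolbox_size_probs Sampling probabilities of the sizes.
#' @param weights_younger,weights_older Named strategy sampling weights;
#'   strategies absent from the vector get weight 1.
#' @param delta_mean,delta_sd Parameters of the (truncated-at-zero) normal
#'   distribution of `delta`.
#' @param epsilon_mean,epsilon_sd Normal distribution of `epsilon`, clipped
#'   to `epsilon_range`.
#' @param epsilon_range Admissible `epsilon` interval.
#' @return List of class `population_config`.
#' @export
population_config <- function(n_younger = 20, n_older = 20,
                              toolbox_sizes = 2:4,
                              toolbox_size_probs = c(0.3, 0.45, 0.25),
                              weights_younger = c(MINI = 3, LL = 3, PH = 3),
                              weights_older = c(EQW = 3, MAXI = 3),
                              delta_mean = 2, delta_sd = 3,
                              epsilon_mean = 0.26, epsilon_sd = 0.06,
                              epsilon_range = c(0.01, 0.5)) {
  stopifnot(n_younger >= 0, n_older >= 0,
            length(toolbox_sizes) == length(toolbox_size_probs),
            all(toolbox_sizes >= 1), all(toolbox_sizes <= 7),
            epsilon_range[1] >= 0, epsilon_range[2] <= 0.5)
  structure(
    list(n_younger = n_younger, n_older = n_older,
         toolbox_sizes = toolbox_sizes,
         toolbox_size_probs = toolbox_size_probs / sum(toolbox_size_probs),
         weights_younger = weights_younger, weights_older = weights_older,
         delta_mean = delta_mean, delta_sd = delta_sd,
         epsilon_mean = epsilon_mean, epsilon_sd = epsilon_sd,
         epsilon_range = epsilon_range),
    class = "population_config"
  )
}

draw_agent <- function(config, group) {
  w <- stats::setNames(rep(1, length(strategy_ids())), strategy_ids())
  extra <- if (group == "younger") config$weights_younger else config$weights_older
  w[names(extra)] <- extra
  size <- sample(config$toolbox_sizes, 1L, prob = config$toolbox_size_probs)
  toolbox <- sample(strategy_ids(), size, prob = w)
  delta <- max(0, stats::rnorm(1, config$delta_mean, config$delta_sd))
  epsilon <- min(max(stats::rnorm(1, config$epsilon_mean, config$epsilon_sd),
                     config$epsilon_range[1]), config$epsilon_range[2])
  agent_params(toolbox, delta, epsilon)
}

#' Generate a synthetic agent population and its choices
#'
#' Draws agents from a [population_config()], simulates each agent's choices
#' on the problem set with [simulate_choices()], and returns the choice
#' dataset together with the ground-truth parameter table used for
#' parameter-recovery scoring.
#'
#' @param pop_config A [population_config()].
#' @param problems List of [choice_problem()] objects.
#' @param seed Optional integer seed.
#' @param stats Optional precomputed [compute_strategy_stats()] over all 11
#'   strategies; computed (seeded) when omitted.
#' @return List with `choices` (choice data frame) and `truth` (data frame
#'   with one row per agent: participant_id, age_group, toolbox as a
#'   comma-separated string, delta, epsilon).
#' @export
generate_population <- function(pop_config = population_config(), problems,
                                seed = NULL, stats = NULL) {
  stopifnot(inherits(pop_config, "population_config"))
  run <- function() {
    if (is.null(stats)) stats <- compute_strategy_stats(strategy_ids(), problems)
    groups <- c(rep("younger", pop_config$n_younger),
                rep("older", pop_config$n_older))
    choices <- vector("list", length(groups))
    truth <- vector("list", length(groups))
    for (i in seq_along(groups)) {
      agent <- draw_agent(pop_config, groups[i])
      id <- sprintf("agent_%03d", i)
      ch <- simulate_choices(agent, problems, n_reps = 1, stats = stats,
                             id_prefix = id, age_group = groups[i])
      ch$participant_id <- id
      choices[[i]] <- ch
      truth[[i]] <- data.frame(
        participant_id = id, age_group = groups[i],
        toolbox = paste(sort(agent$toolbox), collapse = ","),
        delta = agent$delta, epsilon = agent$epsilon,
        stringsAsFactors = FALSE
      )
    }
    list(choices = validate_choices(do.call(rbind, choices), problems),
         truth = do.call(rbind, truth))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

parse_toolbox <- function(x) strsplit(x, ",", fixed = TRUE)[[1]]

jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))

#' Turn a list of fits into a parameter table
#'
#' @param fits Named list of [fit_participant()] results (names =
#'   participant ids).
#' @return Data frame with participant_id, toolbox, delta, epsilon,
#'   log_lik, n_ties_at_max.
#' @export
fits_to_df <- function(fits) {
  stopifnot(length(fits) > 0L, !is.null(names(fits)))
  do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    data.frame(
      participant_id = id,
      toolbox = paste(sort(f$params$toolbox), collapse = ","),
      delta = f$params$delta, epsilon = f$params$epsilon,
      log_lik = f$log_lik, n_ties_at_max = f$n_ties_at_max,
      stringsAsFactors = FALSE
    )
  }))
}

#' Score parameter recovery against the ground truth
#'
#' Compares fitted agent parameters with the generating ones: the Jaccard
#' overlap of the recovered and true toolboxes, signed and absolute errors
#' of `delta` and `epsilon`, the proportion of agents with `epsilon`
#' recovered within a stated tolerance, and across-agent correlations.
#'
#' @param truth Ground-truth table from [generate_population()].
#' @param fits Data frame from [fits_to_df()] (or a named list of fits).
#' @param epsilon_tolerance Band used for `prop_epsilon_within` (default 0.1).
#' @return List with `per_agent` (data frame) and `summary` (list).
#' @export
score_recovery <- function(truth, fits, epsilon_tolerance = 0.1) {
  if (is.list(fits) && !is.data.frame(fits)) fits <- fits_to_df(fits)
  if (!setequal(truth$participant_id, fits$participant_id)) {
    stop("participant ids of truth and fits do not match", call. = FALSE)
  }
  fits <- fits[match(truth$participant_id, fits$participant_id), ]
  per <- data.frame(
    participant_id = truth$participant_id,
    jaccard = mapply(function(a, b) jaccard(parse_toolbox(a), parse_toolbox(b)),
                     truth$toolbox, fits$toolbox, USE.NAMES = FALSE),
    delta_error = fits$delta - truth$delta,
    epsilon_error = fits$epsilon - truth$epsilon,
    stringsAsFactors = FALSE
  )
  cor_or_na <- function(x, y) {
    if (stats::sd(x) < 1e-12 || stats::sd(y) < 1e-12) return(NA_real_)
    stats::cor(x, y)
  }
  list(
    per_agent = per,
    summary = list(
      mean_jaccard = mean(per$jaccard),
      mean_abs_delta_error = mean(abs(per$delta_error)),
      mean_abs_epsilon_error = mean(abs(per$epsilon_error)),
      prop_epsilon_within = mean(abs(per$epsilon_error) <= epsilon_tolerance),
      cor_delta = cor_or_na(truth$delta, fits$delta),
      cor_epsilon = cor_or_na(truth$epsilon, fits$epsilon)
    )
  )
}

#' Expected Jaccard overlap of random toolboxes
#'
#' Monte-Carlo baseline for recovery scoring: the expected Jaccard overlap
#' when the recovered toolbox is a uniformly random subset of the same size
#' as the fitted one, paired with the true toolboxes.
#'
#' @param truth Ground-truth table from [generate_population()].
#' @param fits Fits table (sizes are taken from it).
#' @param n_draws Monte-Carlo draws (default 2000).
#' @param seed Optional integer seed.
#' @return Expected Jaccard under random subsets.
#' @export
random_jaccard_baseline <- function(truth, fits, n_draws = 2000, seed = NULL) {
  if (is.list(fits) && !is.data.frame(fits)) fits <- fits_to_df(fits)
  fits <- fits[match(truth$participant_id, fits$participant_id), ]
  run <- function() {
    mean(vapply(seq_len(n_draws), function(i) {
      j <- sample.int(nrow(truth), 1L)
      true_tb <- parse_toolbox(truth$toolbox[j])
      size <- length(parse_toolbox(fits$toolbox[j]))
      jaccard(true_tb, sample(strategy_ids(), size))
    }, numeric(1)))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
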