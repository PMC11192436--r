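#' Agent parameters of the resource-rational strategy-selection model
#'
#' An agent is characterized by a toolbox `S` of candidate strategies, a
#' cost weight `delta` >= 0 trading off a strategy's expected payoff against
#' its cognitive cost, and a trembling-hand error `epsilon` in [0, 0.5]: the
#' probability of executing the opposite of the selected strategy's choice.
#'
#' @param toolbox Character vector of strategy ids (nonempty, no duplicates).
#' @param delta Cost weight, >= 0.
#' @param epsilon Trembling-hand error in [0, 0.5].
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(toolbox, delta, epsilon) {
  toolbox <- as.character(toolbox)
  if (length(toolbox) < 1L) stop("toolbox must be nonempty", call. = FALSE)
  if (anyDuplicated(toolbox) > 0L) stop("toolbox must not contain duplicates", call. = FALSE)
  bad <- setdiff(toolbox, strategy_ids())
  if (length(bad) > 0L) stop("unknown strategies: ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(is.numeric(delta), length(delta) == 1L, delta >= 0)
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0, epsilon <= 0.5)
  structure(list(toolbox = toolbox, delta = delta, epsilon = epsilon),
            class = "agent_params")
}

#' @export
print.agent_params <- function(x, ...) {
  cat(sprintf("<agent_params> S = {%s}, delta = %g, epsilon = %g\n",
              paste(x$toolbox, collapse = ", "), x$delta, x$epsilon))
  invisible(x)
}

stats_column <- function(stats, problem_id) {
  if (is.numeric(problem_id)) {
    stopifnot(problem_id >= 1, problem_id <= length(stats$problem_ids))
    return(as.integer(problem_id))
  }
  col <- match(problem_id, stats$problem_ids)
  if (is.na(col)) stop("no statistics for problem ", problem_id, call. = FALSE)
  col
}

#' Select a strategy by the payoff--cost trade-off
#'
#' Implements the resource-rational selection rule: the strategy maximizing
#' `r - delta * c` over the toolbox, where `r` and `c` are the strategy's
#' expected payoff and expected cost on the problem. Exact score ties
#' (tolerance 1e-9) are resolved uniformly at random using R's current
#' random number stream.
#'
#' @param toolbox Character vector of strategy ids.
#' @param delta Cost weight.
#' @param stats A [compute_strategy_stats()] result covering the toolbox.
#' @param problem_id Problem id (or column index into `stats`).
#' @return A single strategy id.
#' @export
select_strategy <- function(toolbox, delta, stats, problem_id) {
  stats_subset(stats, toolbox)
  col <- stats_column(stats, problem_id)
  scores <- stats$r[toolbox, col] - delta * stats$cost[toolbox, col]
  top <- which(scores >= max(scores) - 1e-9)
  if (length(top) > 1L) top <- top[sample.int(length(top), 1L)]
  toolbox[top]
}

# Run-category proportions for one (toolbox, delta) cell.
# scores: |T| x P matrix of r - delta*c; pa: |T| x P structural P(A) in
# {0, 0.5, 1}. Returns P x 3 matrix q: proportion of simulation runs whose
# selected strategy has P(A) = 0, 0.5, 1. Consumes randomness only for
# problems where the selection rule is exactly tied.
run_category_props <- function(scores, pa, reps) {
  n_s <- nrow(scores)
  n_p <- ncol(scores)
  q <- matrix(0, n_p, 3L)
  if (n_s == 1L) {
    cat_idx <- round(pa[1L, ] * 2) + 1L
    q[cbind(seq_len(n_p), cat_idx)] <- 1
    return(q)
  }
  top_idx <- max.col(t(scores), ties.method = "first")
  mx <- scores[cbind(top_idx, seq_len(n_p))]
  at_top <- scores >= rep(mx - 1e-9, each = n_s)
  n_top <- colSums(at_top)
  unique_cols <- which(n_top == 1L)
  if (length(unique_cols) > 0L) {
    cat_idx <- round(pa[cbind(top_idx[unique_cols], unique_cols)] * 2) + 1L
    q[cbind(unique_cols, cat_idx)] <- 1
  }
  for (j in which(n_top > 1L)) {
    cat_idx <- round(pa[at_top[, j], j] * 2) + 1L
    if (all(cat_idx == cat_idx[1L])) {
      # tied strategies all make the same choice: no randomness needed
      q[j, cat_idx[1L]] <- 1
      next
    }
    draws <- tabulate(sample.int(length(cat_idx), reps, replace = TRUE),
                      nbins = length(cat_idx)) / reps
    for (k in seq_along(cat_idx)) {
      q[j, cat_idx[k]] <- q[j, cat_idx[k]] + draws[k]
    }
  }
  q
}

cell_props <- function(params, stats, cols, reps) {
  toolbox <- params$toolbox
  stats_subset(stats, toolbox)
  scores <- stats$r[toolbox, cols, drop = FALSE] -
    params$delta * stats$cost[toolbox, cols, drop = FALSE]
  run_category_props(scores, stats$p_a[toolbox, cols, drop = FALSE], reps)
}

#' Choice probability under the model
#'
#' Monte-Carlo estimate of the probability of choosing option A: the
#' selection rule picks a strategy per simulation run (selection ties
#' uniform at random), the strategy's structural choice probability is
#' averaged across runs, and the trembling-hand error mixes in the opposite
#' choice, so the result is bounded in `[epsilon, 1 - epsilon]` and
#' P(A) + P(B) = 1 exactly.
#'
#' @param p A [choice_problem()] or a problem id present in `stats`.
#' @param params An [agent_params()].
#' @param stats A [compute_strategy_stats()] result.
#' @param reps Simulation runs (default 100).
#' @param seed Optional integer seed.
#' @return Probability of choosing A.
#' @export
choice_probability <- function(p, params, stats, reps = 100, seed = NULL) {
  pid <- if (inherits(p, "choice_problem")) p$id else p
  col <- stats_column(stats, pid)
  run <- function() {
    q <- cell_props(params, stats, col, reps)
    p_bar <- sum(q * c(0, 0.5, 1))
    p_bar * (1 - params$epsilon) + (1 - p_bar) * params$epsilon
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

obs_counts <- function(data, stats, cols) {
  pid <- stats$problem_ids[cols]
  n_a <- as.numeric(table(factor(data$problem_id[data$choice == "A"], levels = pid)))
  n_b <- as.numeric(table(factor(data$problem_id[data$choice == "B"], levels = pid)))
  list(n_a = n_a, n_b = n_b)
}

ll_coefficients <- function(q, n_a, n_b) {
  # LL(eps) = A*log(1-eps) + B*log(eps) + C*log(0.5)
  c(A = sum(n_a * q[, 3] + n_b * q[, 1]),
    B = sum(n_a * q[, 1] + n_b * q[, 3]),
    C = sum((n_a + n_b) * q[, 2]))
}

ll_from_coefficients <- function(co, epsilon) {
  stopifnot(length(epsilon) == 1L)
  if (epsilon == 0 && co[["B"]] > 0) {
    stop("epsilon = 0 with a deterministic prediction contradicting an observed choice: log-likelihood is -Inf",
         call. = FALSE)
  }
  out <- co[["A"]] * log1p(-epsilon) + co[["C"]] * log(0.5)
  if (co[["B"]] > 0) out <- out + co[["B"]] * log(epsilon)
  out
}

#' Log-likelihood of one participant's choices
#'
#' Per simulation run the selection rule (ties random) fixes a strategy for
#' every problem; the run's choice probability for each trial follows the
#' trembling-hand mixture; and the per-run log-likelihood is summed over
#' trials. The reported value is the average of the per-run log-likelihoods
#' across `reps` runs (averaging on the log scale).
#'
#' @param data Data frame with columns `problem_id` and `choice` for one
#'   participant.
#' @param params An [agent_params()].
#' @param stats A [compute_strategy_stats()] result covering the data's
#'   problems.
#' @param reps Simulation runs to average over (default 100).
#' @param seed Optional integer seed.
#' @return Log-likelihood (<= 0).
#' @export
log_likelihood <- function(data, params, stats, reps = 100, seed = NULL) {
  if (nrow(data) == 0L) stop("empty choice data", call. = FALSE)
  cols <- vapply(unique(data$problem_id), stats_column, integer(1), stats = stats)
  run <- function() {
    q <- cell_props(params, stats, cols, reps)
    oc <- obs_counts(data, stats, cols)
    ll_from_coefficients(ll_coefficients(q, oc$n_a, oc$n_b), params$epsilon)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Grid presets for model fitting
#'
#' `"desk"` is the default reduced grid (toolbox sizes 1-4, delta 0-20 in
#' steps of 0.5, epsilon 0.05-0.5 in steps of 0.05, 20 simulation runs)
#' sized for interactive use and testing; `"full"` is the complete grid
#' (toolbox sizes 1-7, delta steps of 0.1, epsilon 0.01-0.5 in steps of
#' 0.01, 100 runs).
#'
#' @param grid `"desk"` or `"full"`.
#' @return List with `toolbox_sizes`, `delta_grid`, `epsilon_grid`, `reps`.
#' @export
rrss_grid <- function(grid = c("desk", "full")) {
  grid <- match.arg(grid)
  if (grid == "desk") {
    list(toolbox_sizes = 1:4, delta_grid = seq(0, 20, by = 0.5),
         epsilon_grid = seq(0.05, 0.5, by = 0.05), reps = 20)
  } else {
    list(toolbox_sizes = 1:7, delta_grid = seq(0, 20, by = 0.1),
         epsilon_grid = seq(0.01, 0.5, by = 0.01), reps = 100)
  }
}

#' Fit the strategy-selection model to one participant
#'
#' Exhaustive grid search over strategy toolboxes (all subsets of the
#' candidate strategies at the given sizes), the cost weight `delta`, and
#' the trembling-hand error `epsilon`, maximizing the run-averaged
#' log-likelihood. Among equally good maxima, combinations with smaller
#' toolboxes are preferred; remaining ties are resolved at random and their
#' number is reported as `n_ties_at_max`.
#'
#' @param data Data frame with columns `problem_id` and `choice` for one
#'   participant.
#' @param stats A [compute_strategy_stats()] result covering the data's
#'   problems and all candidate strategies.
#' @param candidate_strategies Candidate strategy ids (default all 11).
#' @param grid `"desk"` (default) or `"full"`, see [rrss_grid()].
#' @param toolbox_sizes,delta_grid,epsilon_grid,reps Optional overrides of
#'   the preset grid.
#' @param seed Optional integer seed; the same stream is replayed for every
#'   grid cell so results are reproducible and comparable across cells.
#' @return An object of class `rrss_fit`: `params` ([agent_params()]),
#'   `log_lik`, `n_ties_at_max`, and `grid_spec`.
#' @export
fit_participant <- function(data, stats,
                            candidate_strategies = stats$strategies,
                            grid = c("desk", "full"),
                            toolbox_sizes = NULL, delta_grid = NULL,
                            epsilon_grid = NULL, reps = NULL, seed = NULL) {
  if (nrow(data) == 0L) stop("empty choice data", call. = FALSE)
  if (length(candidate_strategies) == 0L) stop("empty candidate strategy set", call. = FALSE)
  stats_subset(stats, candidate_strategies)
  g <- rrss_grid(grid)
  if (!is.null(toolbox_sizes)) g$toolbox_sizes <- toolbox_sizes
  if (!is.null(delta_grid)) g$delta_grid <- delta_grid
  if (!is.null(epsilon_grid)) g$epsilon_grid <- epsilon_grid
  if (!is.null(reps)) g$reps <- reps
  if (any(g$epsilon_grid < 0) || any(g$epsilon_grid > 0.5)) {
    stop("epsilon grid must lie in [0, 0.5]", call. = FALSE)
  }
  g$toolbox_sizes <- g$toolbox_sizes[g$toolbox_sizes <= length(candidate_strategies)]
  if (length(g$toolbox_sizes) == 0L) stop("no feasible toolbox size", call. = FALSE)

  cols <- vapply(unique(data$problem_id), stats_column, integer(1), stats = stats)
  oc <- obs_counts(data, stats, cols)
  r_all <- stats$r[candidate_strategies, cols, drop = FALSE]
  c_all <- stats$cost[candidate_strategies, cols, drop = FALSE]
  pa_all <- stats$p_a[candidate_strategies, cols, drop = FALSE]
  log_eps <- log(g$epsilon_grid)
  log_1meps <- log1p(-g$epsilon_grid)
  log_half <- log(0.5)
  tol <- 1e-9

  best_ll <- -Inf
  ties <- list()
  n_cells <- 0L
  eval_cell <- function(toolbox_idx, delta) {
    # every cell replays the same stream so values are comparable across the
    # grid and reproducible by log_likelihood() with the same seed
    if (!is.null(seed)) set.seed(seed)
    scores <- r_all[toolbox_idx, , drop = FALSE] - delta * c_all[toolbox_idx, , drop = FALSE]
    q <- run_category_props(scores, pa_all[toolbox_idx, , drop = FALSE], g$reps)
    co <- ll_coefficients(q, oc$n_a, oc$n_b)
    co[["A"]] * log_1meps + co[["B"]] * log_eps + co[["C"]] * log_half
  }

  search <- function() {
    for (size in sort(g$toolbox_sizes)) {
      combos <- utils::combn(candidate_strategies, size, simplify = FALSE)
      for (toolbox in combos) {
        idx <- match(toolbox, candidate_strategies)
        for (delta in g$delta_grid) {
          ll_vec <- eval_cell(idx, delta)
          n_cells <<- n_cells + length(ll_vec)
          vmax <- max(ll_vec)
          if (vmax > best_ll + tol) {
            best_ll <<- vmax
            ties <<- list()
          }
          if (vmax >= best_ll - tol) {
            best_ll <<- max(best_ll, vmax)
            for (ei in which(ll_vec >= best_ll - tol)) {
              ties[[length(ties) + 1L]] <<- list(
                toolbox = toolbox, delta = delta,
                epsilon = g$epsilon_grid[ei], ll = ll_vec[ei])
            }
          }
        }
      }
    }
  }
  if (is.null(seed)) search() else withr::with_preserve_seed(search())
  # drop ties that were superseded by a later, higher maximum
  lls <- vapply(ties, `[[`, numeric(1), "ll")
  ties <- ties[lls >= best_ll - tol]
  sizes <- vapply(ties, function(t) length(t$toolbox), integer(1))
  ties <- ties[sizes == min(sizes)]
  pick <- if (length(ties) == 1L) 1L else {
    if (is.null(seed)) sample.int(length(ties), 1L)
    else withr::with_seed(seed + 1L, sample.int(length(ties), 1L))
  }
  chosen <- ties[[pick]]
  structure(
    list(
      params = agent_params(chosen$toolbox, chosen$delta, chosen$epsilon),
      log_lik = chosen$ll,
      n_ties_at_max = length(ties),
      grid_spec = list(candidates = candidate_strategies,
                       toolbox_sizes = g$toolbox_sizes,
                       delta_grid = g$delta_grid, epsilon_grid = g$epsilon_grid,
                       reps = g$reps, seed = seed, n_cells = n_cells)
    ),
    class = "rrss_fit"
  )
}

#' @export
print.rrss_fit <- function(x, ...) {
  cat(sprintf("<rrss_fit> LL = %.3f (%d grid cells, %d tie(s) at max)\n",
              x$log_lik, x$grid_spec$n_cells, x$n_ties_at_max))
  print(x$params)
  invisible(x)
}

#' Simulate choices from agent parameters
#'
#' Forward simulation of the model: for each repetition and problem a
#' strategy is selected by the payoff--cost rule (selection ties random),
#' applied (decision ties random), and the resulting choice is flipped with
#' probability `epsilon`. Each repetition forms one synthetic participant.
#'
#' @param params An [agent_params()].
#' @param problems List of [choice_problem()] objects.
#' @param n_reps Number of synthetic participants to simulate.
#' @param seed Optional integer seed; fixed seeds give identical datasets.
#' @param stats Optional precomputed [compute_strategy_stats()]; computed
#'   from `problems` when omitted.
#' @param id_prefix Participant id prefix.
#' @param age_group Age-group label for the synthetic participants.
#' @return Choice data frame with columns `participant_id`, `age_group`,
#'   `problem_id`, `choice`, plus the selected `strategy` per trial.
#' @export
simulate_choices <- function(params, problems, n_reps = 1, seed = NULL,
                             stats = NULL, id_prefix = "sim",
                             age_group = "unspecified") {
  stopifnot(n_reps >= 1)
  run <- function() {
    if (is.null(stats)) {
      stats <- compute_strategy_stats(params$toolbox, problems)
    }
    stats_subset(stats, params$toolbox)
    out <- vector("list", n_reps)
    for (rep_i in seq_len(n_reps)) {
      strategy <- character(length(problems))
      choice <- character(length(problems))
      for (pi in seq_along(problems)) {
        p <- problems[[pi]]
        s <- select_strategy(params$toolbox, params$delta, stats, p$id)
        d <- apply_strategy(s, p)
        ch <- d$choice
        if (params$epsilon > 0 && stats::runif(1) < params$epsilon) {
          ch <- if (ch == "A") "B" else "A"
        }
        strategy[pi] <- s
        choice[pi] <- ch
      }
      out[[rep_i]] <- data.frame(
        participant_id = sprintf("%s_%03d", id_prefix, rep_i),
        age_group = age_group,
        problem_id = vapply(problems, function(p) p$id, character(1)),
        choice = choice,
        strategy = strategy,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Posterior predictive check of a fitted model
#'
#' Simulates choices from the fitted parameters and compares them with the
#' observed data: the proportion of simulated choices matching the observed
#' ones, decision quality and risk aversion of the simulated choices by
#' domain, the strategy counts normalized by the number of simulation runs
#' (so they sum to the number of trials), and the mean cost of the selected
#' strategies.
#'
#' @param fit An [fit_participant()] result (or an [agent_params()]).
#' @param problems List of [choice_problem()] covering the data.
#' @param data Observed choice data frame (`problem_id`, `choice`).
#' @param stats Optional precomputed [compute_strategy_stats()].
#' @param reps Simulation runs (default 100).
#' @param seed Optional integer seed.
#' @return List with `match_proportion`, `decision_quality`,
#'   `risk_aversion` (overall and by domain), `strategy_counts`, and
#'   `mean_selected_cost`.
#' @export
posterior_predictive <- function(fit, problems, data, stats = NULL,
                                 reps = 100, seed = NULL) {
  params <- if (inherits(fit, "rrss_fit")) fit$params else fit
  pid <- vapply(problems, function(p) p$id, character(1))
  if (!all(data$problem_id %in% pid)) {
    stop("data refers to problems not in `problems`", call. = FALSE)
  }
  if (is.null(stats)) stats <- compute_strategy_stats(params$toolbox, problems, seed = seed)
  sim <- simulate_choices(params, problems, n_reps = reps, seed = seed,
                          stats = stats)
  by_problem <- split(sim, sim$problem_id)
  obs_choice <- stats::setNames(data$choice, data$problem_id)

  match_vals <- unlist(lapply(names(by_problem), function(id) {
    if (!id %in% names(obs_choice)) return(NULL)
    mean(by_problem[[id]]$choice == obs_choice[[id]])
  }))
  # per-problem lookup tables keep the reps x problems loop vectorized
  domains <- stats::setNames(vapply(problems, function(p) p$domain, character(1)), pid)
  lut <- function(fun) {
    m <- vapply(problems, function(p) c(A = fun(p, "A"), B = fun(p, "B")), numeric(2))
    colnames(m) <- pid
    m
  }
  metric <- function(fun) {
    tab <- lut(fun)
    v <- tab[cbind(match(sim$choice, c("A", "B")), match(sim$problem_id, pid))]
    d <- domains[sim$problem_id]
    keep <- !is.na(v)
    c(overall = mean(v[keep]),
      tapply(v[keep], factor(d[keep], c("gain", "loss", "mixed")), mean))
  }
  counts <- table(factor(sim$strategy, levels = stats$strategies)) / reps
  sel_cost <- mean(stats$cost[cbind(match(sim$strategy, stats$strategies),
                                    match(sim$problem_id, stats$problem_ids))])
  list(
    match_proportion = mean(match_vals),
    decision_quality = metric(decision_quality),
    risk_aversion = metric(risk_aversion_indicator),
    strategy_counts = c(counts),
    mean_selected_cost = sel_cost
  )
}
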