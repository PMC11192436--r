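#' Cohen's d for two groups
#'
#' Standardized mean difference with the pooled standard deviation.
#'
#' @param x,y Numeric vectors.
#' @return Cohen's d (x minus y).
#' @export
cohens_d <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp <- sqrt(((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2))
  (mean(x) - mean(y)) / sp
}

#' Cramer's V for a contingency table
#'
#' @param tab A two-way contingency table (matrix of nonnegative counts).
#' @return Cramer's V in [0, 1].
#' @export
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  n <- sum(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - expected)^2 / expected)
  sqrt(chi2 / (n * (min(dim(tab)) - 1)))
}

observed_behavior <- function(choices, problems) {
  pid <- vapply(problems, function(p) p$id, character(1))
  prob_by_id <- stats::setNames(problems, pid)
  per_trial <- data.frame(
    participant_id = choices$participant_id,
    domain = vapply(choices$problem_id, function(id) prob_by_id[[id]]$domain, character(1)),
    dq = mapply(function(id, ch) decision_quality(prob_by_id[[id]], ch),
                choices$problem_id, choices$choice, USE.NAMES = FALSE),
    ra = mapply(function(id, ch) risk_aversion_indicator(prob_by_id[[id]], ch),
                choices$problem_id, choices$choice, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  per_trial
}

#' Group-level summary of fits and posterior predictive checks
#'
#' Aggregates per-participant fits and posterior-predictive results into the
#' group-level quantities of interest: mean and SD of the selected-strategy
#' cost, toolbox size, cost weight `delta` and trembling-hand error
#' `epsilon`; the normalized strategy-frequency table per group; and
#' decision quality and risk aversion by domain, both observed and
#' simulated. Cohen's d between the two groups and Cramer's V of the
#' strategy-frequency table are reported as closed-form effect sizes.
#'
#' @param fits Named list of [fit_participant()] results keyed by
#'   participant id (or a [fits_to_df()] table plus `ppc` carrying costs).
#' @param ppc Named list of [posterior_predictive()] results keyed by
#'   participant id.
#' @param choices Observed choice data frame (with `age_group`).
#' @param problems List of [choice_problem()] objects.
#' @return An object of class `group_summary`: `params` (per-group
#'   mean/SD table), `strategy_frequencies`, `behavior` (observed and
#'   simulated decision quality / risk aversion by domain and group),
#'   `match_proportion` per group, and `effect_sizes`.
#' @export
summarize_groups <- function(fits, ppc, choices, problems) {
  stopifnot(length(fits) > 0L, length(ppc) > 0L)
  fits_df <- if (is.data.frame(fits)) fits else fits_to_df(fits)
  ids <- fits_df$participant_id
  missing_ppc <- setdiff(ids, names(ppc))
  if (length(missing_ppc) > 0L) {
    stop("missing posterior predictive results for: ",
         paste(utils::head(missing_ppc, 5), collapse = ", "), call. = FALSE)
  }
  group_of <- stats::setNames(choices$age_group, choices$participant_id)
  fits_df$age_group <- unname(group_of[fits_df$participant_id])
  if (anyNA(fits_df$age_group)) {
    stop("fits exist for participants absent from the choice data", call. = FALSE)
  }
  fits_df$toolbox_size <- vapply(strsplit(fits_df$toolbox, ","), length, integer(1))
  fits_df$selected_cost <- vapply(ids, function(id) ppc[[id]]$mean_selected_cost, numeric(1))
  fits_df$match_proportion <- vapply(ids, function(id) ppc[[id]]$match_proportion, numeric(1))

  groups <- unique(fits_df$age_group)
  if (any(table(fits_df$age_group) == 0L)) stop("empty group", call. = FALSE)
  agg <- function(var) {
    do.call(rbind, lapply(groups, function(g) {
      v <- fits_df[[var]][fits_df$age_group == g]
      data.frame(age_group = g, variable = var, mean = mean(v),
                 sd = stats::sd(v), stringsAsFactors = FALSE)
    }))
  }
  params_tab <- do.call(rbind, lapply(
    c("selected_cost", "toolbox_size", "delta", "epsilon", "match_proportion"), agg))

  freq <- do.call(rbind, lapply(groups, function(g) {
    counts <- Reduce(`+`, lapply(fits_df$participant_id[fits_df$age_group == g],
                                 function(id) ppc[[id]]$strategy_counts))
    data.frame(age_group = g, strategy = names(counts), count = as.numeric(counts),
               stringsAsFactors = FALSE)
  }))

  obs <- observed_behavior(choices, problems)
  obs$age_group <- unname(group_of[obs$participant_id])
  behavior <- do.call(rbind, lapply(groups, function(g) {
    rows_obs <- obs[obs$age_group == g, ]
    sim_ids <- fits_df$participant_id[fits_df$age_group == g]
    per_domain <- lapply(c("gain", "loss", "mixed", "overall"), function(d) {
      sel <- if (d == "overall") rep(TRUE, nrow(rows_obs)) else rows_obs$domain == d
      key <- if (d == "overall") "overall" else d
      sim_dq <- mean(vapply(sim_ids, function(id) ppc[[id]]$decision_quality[[key]], numeric(1)))
      sim_ra <- mean(vapply(sim_ids, function(id) ppc[[id]]$risk_aversion[[key]], numeric(1)))
      data.frame(
        age_group = g, domain = d,
        observed_decision_quality = mean(rows_obs$dq[sel], na.rm = TRUE),
        observed_risk_aversion = mean(rows_obs$ra[sel], na.rm = TRUE),
        simulated_decision_quality = sim_dq,
        simulated_risk_aversion = sim_ra,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_domain)
  }))

  effect_sizes <- list()
  if (length(groups) == 2L) {
    g1 <- fits_df$age_group == groups[1]
    effect_sizes <- list(
      groups = groups,
      cohens_d = c(
        selected_cost = cohens_d(fits_df$selected_cost[g1], fits_df$selected_cost[!g1]),
        toolbox_size = cohens_d(fits_df$toolbox_size[g1], fits_df$toolbox_size[!g1]),
        delta = cohens_d(fits_df$delta[g1], fits_df$delta[!g1]),
        epsilon = cohens_d(fits_df$epsilon[g1], fits_df$epsilon[!g1])
      ),
      cramers_v_strategies = cramers_v(
        stats::xtabs(count ~ age_group + strategy, data = freq))
    )
  }
  structure(
    list(params = params_tab, strategy_frequencies = freq, behavior = behavior,
         per_participant = fits_df, effect_sizes = effect_sizes),
    class = "group_summary"
  )
}

#' @export
print.group_summary <- function(x, ...) {
  cat("<group_summary>\n")
  print(x$params, row.names = FALSE)
  invisible(x)
}

#' Write a group summary to disk
#'
#' Emits tidy CSVs (`group_params.csv`, `strategy_frequencies.csv`,
#' `behavior_by_domain.csv`, `per_participant.csv`) and a short markdown
#' report. Figures mirroring the usual group plots are written only when
#' `figures = TRUE` and ggplot2 is installed; with the default no plotting
#' code is touched.
#'
#' @param summary A [summarize_groups()] result.
#' @param path Output directory (created if needed).
#' @param figures Also write figures (default FALSE).
#' @return The output directory, invisibly.
#' @export
write_report <- function(summary, path, figures = FALSE) {
  stopifnot(inherits(summary, "group_summary"))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(path)) stop("cannot create output directory ", path, call. = FALSE)
  }
  wr <- function(df, name) {
    utils::write.csv(df, file.path(path, name), row.names = FALSE, quote = FALSE)
  }
  wr(summary$params, "group_params.csv")
  wr(summary$strategy_frequencies, "strategy_frequencies.csv")
  wr(summary$behavior, "behavior_by_domain.csv")
  wr(summary$per_participant, "per_participant.csv")

  lines <- c(
    "# Strategy-selection study report", "",
    "## Group parameter summaries", "",
    utils::capture.output(print(summary$params, row.names = FALSE)), "",
    "## Behavior by domain (observed vs simulated)", "",
    utils::capture.output(print(summary$behavior, row.names = FALSE))
  )
  if (length(summary$effect_sizes) > 0L) {
    lines <- c(lines, "", "## Effect sizes", "",
               utils::capture.output(utils::str(summary$effect_sizes)))
  }
  writeLines(lines, file.path(path, "report.md"))

  if (figures) {
    if (!requireNamespace("ggplot2", quietly = TRUE)) {
      stop("figures = TRUE requires ggplot2", call. = FALSE)
    }
    gg <- ggplot2::ggplot(summary$strategy_frequencies,
                          ggplot2::aes(x = strategy, y = count, fill = age_group)) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(y = "normalized strategy count")
    ggplot2::ggsave(file.path(path, "strategy_frequencies.pdf"), gg,
                    width = 7, height = 4)
  }
  invisible(path)
}

#' Run the full synthetic study pipeline
#'
#' Generates a problem set and an agent population, computes strategy
#' statistics, fits the strategy-selection model to every agent, runs
#' posterior predictive checks, scores parameter recovery against the
#' ground truth, and summarizes by group. Fixed seeds make the whole run
#' reproducible.
#'
#' @param problem_config A [problem_set_config()].
#' @param pop_config A [population_config()].
#' @param grid Fit grid preset, see [rrss_grid()].
#' @param stats_reps Simulation repetitions for strategy statistics.
#' @param ppc_reps Posterior-predictive simulation runs.
#' @param seed Integer seed driving every stage.
#' @param out_dir Optional directory for [write_report()] output.
#' @param ... Further arguments passed to [fit_participant()] (e.g. grid
#'   overrides).
#' @return List with `problems`, `population`, `stats`, `fits`, `ppc`,
#'   `recovery`, and `summary`.
#' @export
run_study <- function(problem_config = problem_set_config(),
                      pop_config = population_config(),
                      grid = "desk", stats_reps = 100, ppc_reps = 100,
                      seed = 1, out_dir = NULL, ...) {
  problems <- generate_problem_set(problem_config, seed = seed)
  stats <- compute_strategy_stats(strategy_ids(), problems, reps = stats_reps,
                                  seed = seed + 1L)
  population <- generate_population(pop_config, problems, seed = seed + 2L,
                                    stats = stats)
  ids <- unique(population$choices$participant_id)
  fits <- list()
  ppc <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    data_i <- population$choices[population$choices$participant_id == id, ]
    fits[[id]] <- fit_participant(data_i, stats, grid = grid,
                                  seed = seed + 10L + i, ...)
    ppc[[id]] <- posterior_predictive(fits[[id]], problems, data_i,
                                      stats = stats, reps = ppc_reps,
                                      seed = seed + 1000L + i)
  }
  recovery <- score_recovery(population$truth, fits_to_df(fits))
  summary <- summarize_groups(fits, ppc, population$choices, problems)
  if (!is.null(out_dir)) write_report(summary, out_dir)
  list(problems = problems, population = population, stats = stats,
       fits = fits, ppc = ppc, recovery = recovery, summary = summary)
}
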