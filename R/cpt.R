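#' Cumulative prospect theory parameters
#'
#' Six-parameter CPT: outcome sensitivity separately for gains and losses
#' (`alpha_gain`, `alpha_loss`), loss aversion (`lambda`), probability
#' sensitivity separately for gains and losses (`gamma_gain`, `gamma_loss`),
#' and choice sensitivity (`theta`). All parameters are bounded to [0, 2]
#' for fitting. The value function is the standard power form
#' `v(x) = x^alpha_gain` for gains and `v(x) = -lambda * (-x)^alpha_loss`
#' for losses; probabilities are transformed by the one-parameter inverse-S
#' weighting function `w(p) = p^gamma / (p^gamma + (1-p)^gamma)^(1/gamma)`,
#' applied rank-dependently and separately per sign.
#'
#' @param alpha_gain,alpha_loss Outcome-sensitivity exponents.
#' @param lambda Loss-aversion weight.
#' @param gamma_gain,gamma_loss Probability-sensitivity exponents.
#' @param theta Choice sensitivity of the softmax rule.
#' @param bounds Declared parameter bounds (default `c(0, 2)`).
#' @return An object of class `cpt_params`.
#' @export
cpt_params <- function(alpha_gain, alpha_loss, lambda, gamma_gain, gamma_loss,
                       theta, bounds = c(0, 2)) {
  par <- c(alpha_gain = alpha_gain, alpha_loss = alpha_loss, lambda = lambda,
           gamma_gain = gamma_gain, gamma_loss = gamma_loss, theta = theta)
  if (any(!is.finite(par))) stop("CPT parameters must be finite", call. = FALSE)
  if (any(par < bounds[1] - 1e-12) || any(par > bounds[2] + 1e-12)) {
    stop("CPT parameters must lie within the declared bounds", call. = FALSE)
  }
  structure(c(as.list(par), list(bounds = bounds)), class = "cpt_params")
}

#' @export
print.cpt_params <- function(x, ...) {
  cat(sprintf("<cpt_params> a+ = %.3f, a- = %.3f, lambda = %.3f, g+ = %.3f, g- = %.3f, theta = %.3f\n",
              x$alpha_gain, x$alpha_loss, x$lambda, x$gamma_gain, x$gamma_loss, x$theta))
  invisible(x)
}

# inverse-S probability weighting; gamma floored at 1e-4 so the form stays
# finite at the lower parameter bound
cpt_weight <- function(p, gamma) {
  gamma <- max(gamma, 1e-4)
  out <- p^gamma / (p^gamma + (1 - p)^gamma)^(1 / gamma)
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

#' Rank-dependent decision weights of a gamble
#'
#' Returns the CPT decision weights, split by sign. Within each sign the
#' weights telescope so they sum to the weighting-function value of the
#' total probability of that sign. Zero outcomes carry no value and receive
#' no weight.
#'
#' @param g A [gamble()].
#' @param params A [cpt_params()].
#' @return List with components `gain` and `loss`, each a list of `payoffs`
#'   and `weights` (possibly empty).
#' @export
cpt_decision_weights <- function(g, params) {
  side <- function(payoffs, probs, gamma) {
    if (length(payoffs) == 0L) {
      return(list(payoffs = numeric(0), weights = numeric(0)))
    }
    # rank from the most extreme outcome inward
    ord <- order(abs(payoffs), decreasing = TRUE)
    p_sorted <- probs[ord]
    cum <- cumsum(p_sorted)
    w <- cpt_weight(cum, gamma) - cpt_weight(c(0, cum[-length(cum)]), gamma)
    list(payoffs = payoffs[ord], weights = w)
  }
  pos <- g$payoffs > 0
  neg <- g$payoffs < 0
  list(
    gain = side(g$payoffs[pos], g$probs[pos], params$gamma_gain),
    loss = side(g$payoffs[neg], g$probs[neg], params$gamma_loss)
  )
}

#' Subjective value of a gamble under cumulative prospect theory
#'
#' Sum of the nonlinearly transformed outcomes weighted by rank-dependent
#' decision weights, computed separately for gains and losses. With all
#' transformation parameters equal to 1 the value reduces to the expected
#' value.
#'
#' @param g A [gamble()].
#' @param params A [cpt_params()].
#' @return Subjective value (real).
#' @export
cpt_value <- function(g, params) {
  dw <- cpt_decision_weights(g, params)
  v_gain <- if (length(dw$gain$payoffs) > 0L) {
    sum(dw$gain$weights * dw$gain$payoffs^params$alpha_gain)
  } else 0
  v_loss <- if (length(dw$loss$payoffs) > 0L) {
    -params$lambda * sum(dw$loss$weights * (-dw$loss$payoffs)^params$alpha_loss)
  } else 0
  v_gain + v_loss
}

#' CPT choice probability
#'
#' Softmax (logistic) choice rule on the subjective value difference:
#' `P(A) = logistic(theta * (V_A - V_B))`.
#'
#' @param p A [choice_problem()].
#' @param params A [cpt_params()].
#' @return Probability of choosing option A, in (0, 1).
#' @export
cpt_choice_probability <- function(p, params) {
  stats::plogis(params$theta * (cpt_value(p$a, params) - cpt_value(p$b, params)))
}

#' CPT log-likelihood of observed choices
#'
#' @param data Data frame with `problem_id` and `choice`.
#' @param params A [cpt_params()].
#' @param problems List of [choice_problem()] covering the data.
#' @return Summed log-likelihood.
#' @export
cpt_log_likelihood <- function(data, params, problems) {
  pid <- vapply(problems, function(p) p$id, character(1))
  prob_by_id <- stats::setNames(problems, pid)
  sum(vapply(seq_len(nrow(data)), function(i) {
    p <- prob_by_id[[data$problem_id[i]]]
    pa <- cpt_choice_probability(p, params)
    pr <- if (data$choice[i] == "A") pa else 1 - pa
    log(max(pr, 1e-300))
  }, numeric(1)))
}

# gain part G(alpha, gamma) = sum of weights * x^alpha over positive
# outcomes, and loss magnitude part M(alpha, gamma) = sum of weights *
# (-x)^alpha over negative outcomes, so V = G - lambda * M
cpt_side_value <- function(payoffs, probs, alpha, gamma) {
  if (length(payoffs) == 0L) return(0)
  ord <- order(payoffs, decreasing = TRUE)
  p_sorted <- probs[ord]
  cum <- cumsum(p_sorted)
  w <- cpt_weight(cum, gamma) - cpt_weight(c(0, cum[-length(cum)]), gamma)
  sum(w * payoffs[ord]^alpha)
}

#' Simulate choices from CPT parameters
#'
#' Draws one Bernoulli choice per problem from the softmax choice
#' probabilities.
#'
#' @param params A [cpt_params()].
#' @param problems List of [choice_problem()] objects.
#' @param seed Optional integer seed.
#' @param id Participant id for the returned data frame.
#' @return Choice data frame (`participant_id`, `age_group`, `problem_id`,
#'   `choice`).
#' @export
simulate_cpt_choices <- function(params, problems, seed = NULL, id = "cpt_sim") {
  run <- function() {
    pa <- vapply(problems, cpt_choice_probability, numeric(1), params = params)
    data.frame(
      participant_id = id,
      age_group = "unspecified",
      problem_id = vapply(problems, function(p) p$id, character(1)),
      choice = ifelse(stats::runif(length(problems)) < pa, "A", "B"),
      stringsAsFactors = FALSE
    )
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Maximum-likelihood CPT fit for one participant
#'
#' Two-stage estimation: a full grid search over the six-dimensional
#' parameter space (`n_grid` equally spaced values per parameter between the
#' bounds), followed by bounded L-BFGS-B refinement from the `n_starts`
#' best grid points. The refined optimum can only improve on the grid
#' optimum.
#'
#' @param data Data frame with `problem_id` and `choice` for one participant.
#' @param problems List of [choice_problem()] covering the data.
#' @param n_grid Grid resolution per parameter (default 15).
#' @param n_starts Number of refinement starts (default 30).
#' @param bounds Parameter bounds (default `c(0, 2)`).
#' @return An object of class `cpt_fit`: `params`, `log_lik`, and
#'   `diagnostics` (grid optimum, convergence codes, failed starts).
#' @export
fit_cpt <- function(data, problems, n_grid = 15, n_starts = 30, bounds = c(0, 2)) {
  if (nrow(data) == 0L) stop("empty choice data", call. = FALSE)
  pid <- vapply(problems, function(p) p$id, character(1))
  if (!all(data$problem_id %in% pid)) {
    stop("data refers to problems not in `problems`", call. = FALSE)
  }
  used <- problems[match(unique(data$problem_id), pid)]
  upid <- vapply(used, function(p) p$id, character(1))
  sign_obs <- ifelse(data$choice == "A", 1, -1)
  obs_idx <- match(data$problem_id, upid)
  P <- length(used)
  grid_vals <- seq(bounds[1], bounds[2], length.out = n_grid)

  split_g <- function(g) {
    pos <- g$payoffs > 0
    neg <- g$payoffs < 0
    list(gp = g$payoffs[pos], gpr = g$probs[pos],
         lp = -g$payoffs[neg], lpr = g$probs[neg])
  }
  parts <- lapply(used, function(p) list(a = split_g(p$a), b = split_g(p$b)))

  # grid arrays of the gain part and loss magnitude part per option
  side_grid <- function(getter, which_side) {
    arr <- array(0, dim = c(P, n_grid, n_grid))
    for (i in seq_len(P)) {
      s <- getter(parts[[i]])
      pay <- if (which_side == "gain") s$gp else s$lp
      pr <- if (which_side == "gain") s$gpr else s$lpr
      if (length(pay) == 0L) next
      for (ia in seq_len(n_grid)) {
        for (ig in seq_len(n_grid)) {
          arr[i, ia, ig] <- cpt_side_value(pay, pr, grid_vals[ia], grid_vals[ig])
        }
      }
    }
    arr
  }
  dG <- side_grid(function(x) x$a, "gain") - side_grid(function(x) x$b, "gain")
  dM <- side_grid(function(x) x$a, "loss") - side_grid(function(x) x$b, "loss")

  # trial multiplicity: n trials can share a problem
  ll_arr <- array(NA_real_, dim = rep(n_grid, 6))
  for (ia_g in seq_len(n_grid)) {
    for (ig_g in seq_len(n_grid)) {
      dg <- dG[, ia_g, ig_g]
      for (ia_l in seq_len(n_grid)) {
        for (ig_l in seq_len(n_grid)) {
          dm <- dM[, ia_l, ig_l]
          # dv[p, il] = dg[p] - lambda_il * dm[p]
          dv <- matrix(dg, P, n_grid) - outer(dm, grid_vals)
          x_obs <- sign_obs * dv[obs_idx, , drop = FALSE]
          llmat <- vapply(grid_vals, function(theta) {
            colSums(stats::plogis(theta * x_obs, log.p = TRUE))
          }, numeric(n_grid))
          ll_arr[ia_g, ig_g, ia_l, ig_l, , ] <- llmat
        }
      }
    }
  }
  top <- order(ll_arr, decreasing = TRUE)[seq_len(min(n_starts, length(ll_arr)))]
  top_idx <- arrayInd(top, dim(ll_arr))
  grid_best_ll <- ll_arr[top[1]]

  # flattened rank-dependent structures so the objective is fully vectorized:
  # per side, the sorted payoffs of every problem concatenated, with the
  # cumulative probabilities bracketing each outcome and its problem index
  flatten_side <- function(getter, which_side) {
    idx <- integer(0); pay <- numeric(0); cum <- numeric(0); cum_prev <- numeric(0)
    for (i in seq_len(P)) {
      s <- getter(parts[[i]])
      x <- if (which_side == "gain") s$gp else s$lp
      pr <- if (which_side == "gain") s$gpr else s$lpr
      if (length(x) == 0L) next
      ord <- order(x, decreasing = TRUE)
      cs <- cumsum(pr[ord])
      idx <- c(idx, rep(i, length(x)))
      pay <- c(pay, x[ord])
      cum <- c(cum, cs)
      cum_prev <- c(cum_prev, c(0, cs[-length(cs)]))
    }
    list(idx = idx, pay = pay, cum = cum, cum_prev = cum_prev)
  }
  sides <- list(
    ga = flatten_side(function(x) x$a, "gain"), gb = flatten_side(function(x) x$b, "gain"),
    la = flatten_side(function(x) x$a, "loss"), lb = flatten_side(function(x) x$b, "loss")
  )
  side_sum <- function(s, alpha, gamma) {
    out <- numeric(P)
    if (length(s$idx) == 0L) return(out)
    w <- cpt_weight(s$cum, gamma) - cpt_weight(s$cum_prev, gamma)
    acc <- rowsum(w * s$pay^alpha, s$idx)
    out[as.integer(rownames(acc))] <- acc
    out
  }
  neg_ll <- function(par) {
    dv <- side_sum(sides$ga, par[1], par[4]) - side_sum(sides$gb, par[1], par[4]) -
      par[3] * (side_sum(sides$la, par[2], par[5]) - side_sum(sides$lb, par[2], par[5]))
    ll <- sum(stats::plogis(par[6] * sign_obs * dv[obs_idx], log.p = TRUE))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL
  n_failed <- 0L
  codes <- integer(0)
  for (k in seq_len(nrow(top_idx))) {
    start <- grid_vals[top_idx[k, ]]
    res <- tryCatch(
      stats::optim(start, neg_ll, method = "L-BFGS-B",
                   lower = rep(bounds[1], 6), upper = rep(bounds[2], 6)),
      error = function(e) NULL
    )
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      next
    }
    codes <- c(codes, res$convergence)
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stop("CPT optimization failed on all ", nrow(top_idx), " starts", call. = FALSE)
  }
  refined_ll <- max(-best$value, grid_best_ll)
  par <- if (-best$value >= grid_best_ll) best$par else grid_vals[top_idx[1, ]]
  structure(
    list(
      params = cpt_params(par[1], par[2], par[3], par[4], par[5], par[6], bounds),
      log_lik = refined_ll,
      diagnostics = list(grid_best_ll = grid_best_ll, n_grid = n_grid,
                         n_starts = nrow(top_idx), n_failed = n_failed,
                         convergence = codes)
    ),
    class = "cpt_fit"
  )
}

#' @export
print.cpt_fit <- function(x, ...) {
  cat(sprintf("<cpt_fit> LL = %.3f (grid optimum %.3f)\n",
              x$log_lik, x$diagnostics$grid_best_ll))
  print(x$params)
  invisible(x)
}
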