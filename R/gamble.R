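#' Construct a gamble
#'
#' A gamble is a finite probability distribution over monetary outcomes. A
#' "safe option" is the degenerate case of a single outcome with probability
#' one.
#'
#' @param payoffs Numeric vector of signed monetary outcomes.
#' @param probs Numeric vector of outcome probabilities, same length as
#'   `payoffs`; must sum to one (tolerance 1e-9).
#' @return An object of class `gamble`.
#' @examples
#' g <- gamble(c(4, 0), c(0.8, 0.2))
#' expected_value(g)
#' @export
gamble <- function(payoffs, probs) {
  payoffs <- as.numeric(payoffs)
  probs <- as.numeric(probs)
  if (length(payoffs) < 1L) {
    stop("a gamble needs at least one outcome", call. = FALSE)
  }
  if (length(payoffs) != length(probs)) {
    stop("payoffs and probs must have the same length", call. = FALSE)
  }
  if (anyNA(payoffs) || anyNA(probs)) {
    stop("payoffs and probs must not contain NA", call. = FALSE)
  }
  if (any(probs < -1e-12) || any(probs > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  structure(list(payoffs = payoffs, probs = probs), class = "gamble")
}

#' @export
print.gamble <- function(x, ...) {
  cat("<gamble> ",
      paste(sprintf("(%g, %g)", x$payoffs, x$probs), collapse = " "),
      "\n", sep = "")
  invisible(x)
}

is_gamble <- function(x) inherits(x, "gamble")

is_safe_option <- function(g) length(g$payoffs) == 1L

#' Expected value of a gamble
#'
#' @param g A [gamble()].
#' @return Sum of payoff times probability.
#' @export
expected_value <- function(g) {
  stopifnot(is_gamble(g))
  sum(g$payoffs * g$probs)
}

#' Coefficient of variation of a gamble
#'
#' Dispersion per unit of absolute expected value: SD of the outcome
#' distribution divided by |EV|. Used as the behavioral yardstick of an
#' option's riskiness; the option with the lower CV is the less risky one.
#' Undefined (returned as `NA`) when the expected value is zero, since the
#' ratio would be infinite; problems with an undefined CV are excluded from
#' risk-aversion averages.
#'
#' @param g A [gamble()].
#' @return Nonnegative ratio, or `NA_real_` when EV = 0.
#' @export
coefficient_of_variation <- function(g) {
  stopifnot(is_gamble(g))
  ev <- expected_value(g)
  if (abs(ev) < 1e-12) {
    return(NA_real_)
  }
  sqrt(sum(g$probs * (g$payoffs - ev)^2)) / abs(ev)
}

#' Construct a choice problem
#'
#' A choice problem is a pair of gambles (options A and B) with a domain
#' label. The domain is derived from the outcome signs: `gain` if all payoffs
#' are nonnegative, `loss` if all are nonpositive, `mixed` otherwise.
#' Degenerate problems (identical options, or all payoffs zero) are rejected.
#'
#' @param option_a,option_b [gamble()] objects.
#' @param id Identifier (coerced to character).
#' @param domain Optional domain label; validated against the derived domain
#'   if supplied.
#' @return An object of class `choice_problem`.
#' @examples
#' p <- choice_problem(gamble(c(4, 0), c(0.8, 0.2)), gamble(3, 1), id = "p1")
#' p$domain
#' @export
choice_problem <- function(option_a, option_b, id = "p", domain = NULL) {
  stopifnot(is_gamble(option_a), is_gamble(option_b))
  if (identical_gambles(option_a, option_b)) {
    stop("degenerate problem: options A and B are identical", call. = FALSE)
  }
  p <- structure(
    list(id = as.character(id), a = option_a, b = option_b, domain = NA_character_),
    class = "choice_problem"
  )
  p$domain <- classify_domain(p)
  if (!is.null(domain)) {
    domain <- match.arg(domain, c("gain", "loss", "mixed"))
    if (!identical(domain, p$domain)) {
      stop(sprintf("declared domain '%s' inconsistent with outcomes ('%s')",
                   domain, p$domain), call. = FALSE)
    }
  }
  p
}

identical_gambles <- function(g1, g2) {
  o1 <- order(g1$payoffs, g1$probs)
  o2 <- order(g2$payoffs, g2$probs)
  isTRUE(all.equal(g1$payoffs[o1], g2$payoffs[o2], tolerance = 1e-12)) &&
    isTRUE(all.equal(g1$probs[o1], g2$probs[o2], tolerance = 1e-12))
}

#' @export
print.choice_problem <- function(x, ...) {
  cat(sprintf("<choice_problem %s> [%s]\n", x$id, x$domain))
  cat("  A: "); print(x$a)
  cat("  B: "); print(x$b)
  invisible(x)
}

problem_payoffs <- function(p) c(p$a$payoffs, p$b$payoffs)

#' Classify the domain of a choice problem
#'
#' @param p A [choice_problem()] (or a bare list with gambles `a` and `b`).
#' @return `"gain"`, `"loss"`, or `"mixed"`. All-zero problems are an error.
#' @export
classify_domain <- function(p) {
  x <- problem_payoffs(p)
  if (all(x == 0)) {
    stop("degenerate problem: all payoffs are zero", call. = FALSE)
  }
  if (all(x >= 0)) return("gain")
  if (all(x <= 0)) return("loss")
  "mixed"
}

option_of <- function(p, choice) {
  choice <- match.arg(choice, c("A", "B"))
  if (choice == "A") p$a else p$b
}

#' Decision quality of a choice
#'
#' Indicator that the chosen option has the strictly higher expected value.
#' `NA` when the two options' EVs tie (such trials are excluded from
#' averages).
#'
#' @param p A [choice_problem()].
#' @param choice `"A"` or `"B"`.
#' @return 1, 0, or `NA`.
#' @export
decision_quality <- function(p, choice) {
  choice <- match.arg(choice, c("A", "B"))
  ev_a <- expected_value(p$a)
  ev_b <- expected_value(p$b)
  if (abs(ev_a - ev_b) < 1e-9) {
    return(NA_real_)
  }
  better <- if (ev_a > ev_b) "A" else "B"
  as.numeric(choice == better)
}

#' Risk-aversion indicator of a choice
#'
#' Indicator that the chosen option has the strictly lower coefficient of
#' variation. `NA` when either CV is undefined (EV = 0) or the CVs tie.
#'
#' @inheritParams decision_quality
#' @return 1, 0, or `NA`.
#' @export
risk_aversion_indicator <- function(p, choice) {
  choice <- match.arg(choice, c("A", "B"))
  cv_a <- coefficient_of_variation(p$a)
  cv_b <- coefficient_of_variation(p$b)
  if (is.na(cv_a) || is.na(cv_b) || abs(cv_a - cv_b) < 1e-9) {
    return(NA_real_)
  }
  safer <- if (cv_a < cv_b) "A" else "B"
  as.numeric(choice == safer)
}

# ---- delimited-table interfaces ----------------------------------------------

#' Write choice problems to CSV
#'
#' Schema: `id`, `domain`, then outcome/probability column pairs per option
#' (`o_a1`, `p_a1`, ..., `o_b1`, `p_b1`, ...). Safe options leave trailing
#' pairs empty.
#'
#' @param problems List of [choice_problem()] objects.
#' @param path Output file path.
#' @export
write_problems <- function(problems, path) {
  stopifnot(length(problems) > 0L)
  n_a <- max(vapply(problems, function(p) length(p$a$payoffs), integer(1)))
  n_b <- max(vapply(problems, function(p) length(p$b$payoffs), integer(1)))
  pad <- function(x, n) c(x, rep(NA_real_, n - length(x)))
  vals <- do.call(rbind, lapply(problems, function(p) {
    c(rbind(pad(p$a$payoffs, n_a), pad(p$a$probs, n_a)),
      rbind(pad(p$b$payoffs, n_b), pad(p$b$probs, n_b)))
  }))
  df <- data.frame(
    id = vapply(problems, function(p) p$id, character(1)),
    domain = vapply(problems, function(p) p$domain, character(1)),
    vals, stringsAsFactors = FALSE
  )
  names(df) <- c("id", "domain",
                 paste0(c("o_a", "p_a"), rep(seq_len(n_a), each = 2)),
                 paste0(c("o_b", "p_b"), rep(seq_len(n_b), each = 2)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read choice problems from CSV
#'
#' Inverse of [write_problems()]. The `domain` column is optional; when
#' present it is validated against the outcome signs.
#'
#' @param path CSV file path.
#' @return List of [choice_problem()] objects.
#' @export
read_problems <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("problem file must have an 'id' column", call. = FALSE)
  has_domain <- "domain" %in% names(df)
  a_idx <- grep("^o_a[0-9]+$", names(df))
  b_idx <- grep("^o_b[0-9]+$", names(df))
  if (length(a_idx) == 0L || length(b_idx) == 0L) {
    stop("problem file must have o_a*/p_a* and o_b*/p_b* column pairs", call. = FALSE)
  }
  read_option <- function(row, prefix, n) {
    o <- as.numeric(row[paste0("o_", prefix, seq_len(n))])
    pr <- as.numeric(row[paste0("p_", prefix, seq_len(n))])
    keep <- !is.na(o) & !is.na(pr)
    gamble(o[keep], pr[keep])
  }
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, , drop = FALSE]
    choice_problem(
      read_option(row, "a", length(a_idx)),
      read_option(row, "b", length(b_idx)),
      id = row$id,
      domain = if (has_domain) row$domain else NULL
    )
  })
}

#' Validate a choice dataset
#'
#' A choice dataset records one choice per participant and problem, with
#' columns `participant_id`, `age_group` (`younger`, `older`, or
#' `unspecified`), `problem_id`, and `choice` (`A`/`B`).
#'
#' @param choices A data frame.
#' @param problems Optional list of problems; if given, every `problem_id`
#'   must be present.
#' @return The validated data frame, invisibly usable downstream.
#' @export
validate_choices <- function(choices, problems = NULL) {
  need <- c("participant_id", "age_group", "problem_id", "choice")
  missing_cols <- setdiff(need, names(choices))
  if (length(missing_cols) > 0L) {
    stop("choice data missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(choices$choice %in% c("A", "B"))) {
    stop("choice must be 'A' or 'B'", call. = FALSE)
  }
  if (!all(choices$age_group %in% c("younger", "older", "unspecified"))) {
    stop("age_group must be younger, older, or unspecified", call. = FALSE)
  }
  if (anyDuplicated(choices[c("participant_id", "problem_id")]) > 0L) {
    stop("each (participant, problem) pair may appear at most once", call. = FALSE)
  }
  if (!is.null(problems)) {
    ids <- vapply(problems, function(p) p$id, character(1))
    unknown <- setdiff(unique(choices$problem_id), ids)
    if (length(unknown) > 0L) {
      stop("choice data refers to unknown problems: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  choices
}

#' Read a choice dataset from CSV
#' @param path CSV with columns participant_id, age_group, problem_id, choice.
#' @return Validated data frame.
#' @export
read_choices <- function(path) {
  validate_choices(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write a choice dataset to CSV
#' @param choices Validated choice data frame.
#' @param path Output path.
#' @export
write_choices <- function(choices, path) {
  utils::write.csv(validate_choices(choices), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
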