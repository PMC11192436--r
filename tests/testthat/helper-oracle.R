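# Independent re-implementation of the eleven heuristics, written directly
# from their verbal rule descriptions, without EIP tracing and without any
# code shared with the package. Returns "A", "B", or "tie". Shared
# conventions (stated, not code): probability ties when locating the most
# likely outcome go to the higher payoff; duplicated payoff values pool
# their probabilities; a strategy with nothing left to compare is "tie".

oracle_decision <- function(strategy, p) {
  xa <- p$a$payoffs; pa <- p$a$probs
  xb <- p$b$payoffs; pb <- p$b$probs
  verdict <- function(va, vb) {
    if (is.infinite(va) && is.infinite(vb) && va == vb) return("tie")
    if (abs(va - vb) < 1e-9) "tie" else if (va > vb) "A" else "B"
  }
  ml_payoff <- function(x, pr, rank = 1) {
    ord <- order(pr, x, decreasing = TRUE)
    x[ord[min(rank, length(x))]]
  }
  p_of_worst <- function(x, pr) sum(pr[x == min(x)])
  p_of_best <- function(x, pr) sum(pr[x == max(x)])

  switch(strategy,
    MINI = verdict(min(xa), min(xb)),
    MAXI = verdict(max(xa), max(xb)),
    LL = verdict(-p_of_worst(xa, pa), -p_of_worst(xb, pb)),
    ML = verdict(ml_payoff(xa, pa), ml_payoff(xb, pb)),
    BTA = {
      grand <- mean(c(xa, xb))
      verdict(sum(xa >= grand - 1e-12), sum(xb >= grand - 1e-12))
    },
    EQW = verdict(sum(xa), sum(xb)),
    TALLY = oracle_tally(p),
    PROB = {
      avg <- function(x, pr) {
        probable <- x[pr >= 0.5 - 1e-12]
        if (length(probable) == 0) -Inf else mean(probable)
      }
      verdict(avg(xa, pa), avg(xb, pb))
    },
    LEX = {
      first <- verdict(ml_payoff(xa, pa), ml_payoff(xb, pb))
      if (first != "tie") first
      else verdict(ml_payoff(xa, pa, 2), ml_payoff(xb, pb, 2))
    },
    PH = oracle_priority(p),
    WADD = verdict(sum(xa * pa), sum(xb * pb))
  )
}

# Tallying, gain version: a mark for the higher minimum gain, the higher
# maximum gain, the lower probability of the minimum gain, the higher
# probability of the maximum gain. Loss version per the stated substitution
# ("gain" -> "loss", "higher" <-> "lower"), computed here on loss
# magnitudes. Mixed problems use the gain version on signed payoffs.
oracle_tally <- function(p) {
  mark <- function(better_a) {
    if (is.na(better_a)) c(0, 0) else if (better_a) c(1, 0) else c(0, 1)
  }
  cmp <- function(va, vb) if (abs(va - vb) < 1e-9) NA else va > vb
  tally_gain <- function(xa, pa, xb, pb) {
    p_min <- function(x, pr) sum(pr[x == min(x)])
    p_max <- function(x, pr) sum(pr[x == max(x)])
    t <- mark(cmp(min(xa), min(xb))) +
      mark(cmp(max(xa), max(xb))) +
      mark(cmp(p_min(xb, pb), p_min(xa, pa))) +   # lower p(min) is better
      mark(cmp(p_max(xa, pa), p_max(xb, pb)))
    t
  }
  tally_loss <- function(xa, pa, xb, pb) {
    la <- -xa; lb <- -xb  # loss magnitudes
    p_min <- function(l, pr) sum(pr[l == min(l)])
    p_max <- function(l, pr) sum(pr[l == max(l)])
    t <- mark(cmp(min(lb), min(la))) +            # lower minimum loss
      mark(cmp(max(lb), max(la))) +               # lower maximum loss
      mark(cmp(p_min(la, pa), p_min(lb, pb))) +   # higher p(minimum loss)
      mark(cmp(p_max(lb, pb), p_max(la, pa)))     # lower p(maximum loss)
    t
  }
  t <- if (p$domain == "loss") {
    tally_loss(p$a$payoffs, p$a$probs, p$b$payoffs, p$b$probs)
  } else {
    tally_gain(p$a$payoffs, p$a$probs, p$b$payoffs, p$b$probs)
  }
  if (t[1] == t[2]) "tie" else if (t[1] > t[2]) "A" else "B"
}

# Priority heuristic: minimum outcome, probability of the minimum, maximum
# outcome; stop when minima differ by at least a tenth of the largest
# outcome at stake (largest gain, or largest absolute loss for loss
# problems), then when the probabilities differ by at least 0.1.
oracle_priority <- function(p) {
  xa <- p$a$payoffs; pa <- p$a$probs
  xb <- p$b$payoffs; pb <- p$b$probs
  min_a <- min(xa); min_b <- min(xb)
  p_min_a <- sum(pa[xa == min_a]); p_min_b <- sum(pb[xb == min_b])
  all_x <- c(xa, xb)
  scale_ref <- if (p$domain == "loss") max(abs(all_x)) else max(all_x)
  verdict <- function(va, vb) {
    if (abs(va - vb) < 1e-9) "tie" else if (va > vb) "A" else "B"
  }
  if (abs(min_a - min_b) >= 0.1 * scale_ref - 1e-9) {
    return(verdict(min_a, min_b))
  }
  if (abs(p_min_a - p_min_b) >= 0.1 - 1e-9) {
    return(verdict(p_min_b, p_min_a))  # lower probability of the worst
  }
  verdict(max(xa), max(xb))
}

# choice/tie agreement between the package decision and the oracle verdict
agrees_with_oracle <- function(strategy, p) {
  d <- rrchoice:::strategy_decision(strategy, p)
  o <- oracle_decision(strategy, p)
  if (o == "tie") is.na(d$choice) else identical(d$choice, o)
}
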