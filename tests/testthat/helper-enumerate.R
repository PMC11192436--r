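# Brute-force fitting oracle: exhaustively enumerates a (micro) grid via the
# public log_likelihood() and reports the maximum and all argmax cells.
enumerate_fit <- function(data, stats, candidates, sizes, delta_grid,
                          epsilon_grid, reps, seed) {
  recs <- list()
  for (size in sizes) {
    for (tb in utils::combn(candidates, size, simplify = FALSE)) {
      for (d in delta_grid) {
        for (e in epsilon_grid) {
          ll <- log_likelihood(data, agent_params(tb, d, e), stats,
                               reps = reps, seed = seed)
          recs[[length(recs) + 1L]] <- list(toolbox = tb, delta = d,
                                            epsilon = e, ll = ll)
        }
      }
    }
  }
  lls <- vapply(recs, `[[`, numeric(1), "ll")
  best <- max(lls)
  argmax <- recs[lls >= best - 1e-9]
  list(
    best_ll = best,
    argmax = argmax,
    min_size = min(vapply(argmax, function(r) length(r$toolbox), integer(1)))
  )
}

fit_in_argmax <- function(fit, oracle) {
  any(vapply(oracle$argmax, function(r) {
    setequal(r$toolbox, fit$params$toolbox) &&
      isTRUE(all.equal(r$delta, fit$params$delta)) &&
      isTRUE(all.equal(r$epsilon, fit$params$epsilon))
  }, logical(1)))
}

# cost of the strategy picked by the selection rule, ties resolved to the
# cheapest tied strategy so the quantity is deterministic
selected_cost <- function(toolbox, delta, stats, col) {
  scores <- stats$r[toolbox, col] - delta * stats$cost[toolbox, col]
  top <- which(scores >= max(scores) - 1e-9)
  min(stats$cost[toolbox, col][top])
}
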