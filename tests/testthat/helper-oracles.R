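# Exhaustive dynamic program: minimum number of schedule points over all
# grid subsets containing the endpoints, subject to the adjacent-gap
# constraint. Independent of the greedy implementation in the package.
dp_min_windows <- function(grid, F, threshold, gap_mode = "interval",
                           tol = 1e-9) {
  n <- length(grid)
  gap <- function(i, j) {
    if (gap_mode == "endpoint") abs(F[j] - F[i])
    else max(abs(F[(i + 1):j] - F[i]))
  }
  best <- rep(Inf, n)
  best[1] <- 1
  for (j in 2:n) for (i in 1:(j - 1)) {
    if (is.finite(best[i]) && gap(i, j) <= threshold + tol)
      best[j] <- min(best[j], best[i] + 1)
  }
  best[n]
}
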