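# Independent oracles used across tests.  These re-derive results from first
# principles (brute force, enumeration, closed forms) and never call the
# package code paths they check.

# Brute-force grid search for the least-squares line through (log x, log y):
# iteratively zoomed 41 x 41 grid over (intercept, slope).  Each iteration
# recentres on the best grid point and shrinks the half-width to two grid
# cells, so 12 iterations take the resolution far below 1e-8.
grid_search_loglog <- function(x, y, n_grid = 41, n_iter = 40) {
  lx <- log(x)
  ly <- log(y)
  # parameterise the line as a0 + b * (lx - mean(lx)) so the two grid axes
  # are decoupled; the intercept at lx = 0 is recovered at the end
  cx <- lx - mean(lx)
  ctr <- c(mean(ly), 0)
  half <- c(max(abs(ly - mean(ly))) + 5, 10)
  for (it in seq_len(n_iter)) {
    as <- seq(ctr[1] - half[1], ctr[1] + half[1], length.out = n_grid)
    bs <- seq(ctr[2] - half[2], ctr[2] + half[2], length.out = n_grid)
    g <- expand.grid(a = as, b = bs)
    sse <- vapply(seq_len(nrow(g)), function(i) {
      sum((ly - (g$a[i] + g$b[i] * cx))^2)
    }, numeric(1))
    best <- which.min(sse)
    ctr <- c(g$a[best], g$b[best])
    # shrink a dimension only when its optimum is interior to the box
    ia <- (best - 1L) %% n_grid + 1L
    ib <- (best - 1L) %/% n_grid + 1L
    shrink <- c(ia > 1L && ia < n_grid, ib > 1L && ib < n_grid)
    half[shrink] <- half[shrink] * 4 / (n_grid - 1)
    if (all(half < 1e-9)) break
  }
  c(intercept = ctr[1] - ctr[2] * mean(lx), slope = ctr[2])
}

# Closed-form OLS slope/intercept (normal equations), independent of lm().
ols_closed_form <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(intercept = mean(y) - b * mean(x), slope = b)
}

# ANOSIM R statistic computed directly from its definition.
anosim_r_oracle <- function(d, grouping) {
  d <- as.matrix(d)
  rv <- rank(d[lower.tri(d)])
  idx <- which(lower.tri(d), arr.ind = TRUE)
  between <- grouping[idx[, 1]] != grouping[idx[, 2]]
  N <- nrow(d)
  (mean(rv[between]) - mean(rv[!between])) / (N * (N - 1) / 4)
}

# Exact ANOSIM p over all distinct assignments of group labels to samples
# (enumerated via subsets, which cover every label permutation's R value).
anosim_exact_p_oracle <- function(d, grouping) {
  N <- length(grouping)
  g1 <- unique(grouping)[1]
  n1 <- sum(grouping == g1)
  r_obs <- anosim_r_oracle(d, grouping)
  sets <- utils::combn(N, n1)
  r_all <- apply(sets, 2, function(s) {
    g <- rep("b", N)
    g[s] <- "a"
    anosim_r_oracle(d, g)
  })
  mean(r_all >= r_obs - 1e-12)
}

# Hand Bray-Curtis on two relative-abundance vectors.
bray_oracle <- function(p, q) sum(abs(p - q)) / sum(p + q)
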