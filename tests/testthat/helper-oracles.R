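# Independent oracles used to cross-check the implementation on tiny problems.

# Stable fixed points of a scalar map dx/dt = g(x) on [0, 1]: dense grid for
# sign changes of g, bisection via uniroot, stability from the sign of the
# numerical derivative of g at the root. Endpoints with g pointing inward and
# vanishing are handled by the grid (roots at 0/1 are caught when |g| ~ 0).
stable_fixed_points_1d <- function(g, lower = 0, upper = 1, grid_n = 4001,
                                   tol = 1e-12) {
  xs <- seq(lower, upper, length.out = grid_n)
  gs <- vapply(xs, g, numeric(1))
  roots <- numeric(0)
  for (i in seq_len(grid_n - 1)) {
    if (gs[i] == 0) {
      roots <- c(roots, xs[i])
    } else if (gs[i] * gs[i + 1] < 0) {
      roots <- c(roots, stats::uniroot(g, c(xs[i], xs[i + 1]), tol = tol)$root)
    }
  }
  if (gs[grid_n] == 0) roots <- c(roots, xs[grid_n])
  roots <- sort(unique(round(roots, 10)))
  h <- 1e-6
  stable <- vapply(roots, function(r) {
    lo <- max(lower, r - h)
    hi <- min(upper, r + h)
    (g(hi) - g(lo)) / (hi - lo) < 0
  }, logical(1))
  roots[stable]
}

# Exact hypergeometric upper tail P(X >= k) by enumerating every size-n draw
# from a universe of N genes of which the first K are marked.
brute_hypergeom_upper <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  overlap <- colSums(draws <= K)
  mean(overlap >= k)
}

# Small annotated network shared by classification tests: two modules with
# promoting and inhibiting members.
make_module_network <- function() {
  network(
    data.frame(
      id = c("cc1", "cc2", "ccI", "ap1"),
      module = c("cell_cycle", "cell_cycle", "cell_cycle", "apoptosis"),
      module_role = c("promotes", "promotes", "inhibits", "promotes")
    )
  )
}

# All 64 assignments of active/inactive over the six hallmark modules.
all_module_assignments <- function() {
  mods <- setdiff(functional_modules(), "other")
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(mods)))
  names(grid) <- mods
  grid
}
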