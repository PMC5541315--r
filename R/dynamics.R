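# Hill-function network dynamics and attractor enumeration --------------------
#
# Each node x_k in [0,1] obeys dx_k/dt = f_k(x) - x_k / tau_k, where f_k is a
# product of one pooled Hill activation factor and one pooled Hill inhibition
# factor over the node's in-edges. Attractors are found by explicit-Euler
# fixed-point iteration from many random initial states.

#' Dynamics parameters
#'
#' Bundles the parameters of the Hill-function dynamical system and of the
#' fixed-point iteration. The switch-like regime requires a Hill coefficient
#' between 3 and 10 with kinetic constant a of the order of 2^n; the defaults
#' n = 3, a = 8 are the standard working point. The degradation constant tau is
#' simplified to 1 for every node.
#'
#' @param n Hill coefficient (3 <= n <= 10).
#' @param a Kinetic constant (> 0), a ~ 2^n.
#' @param tau Degradation constant, recycled per node.
#' @param dt Explicit-Euler step (0 < dt <= 1).
#' @param max_iter Iteration cap per start.
#' @param epsilon Convergence tolerance on the state change `max|v_{l+1}-v_l|`.
#' @param delta Convergence tolerance on the derivative `max|f(v_l)|`.
#' @param n_starts Number of uniform-random initial state vectors.
#' @param merge_tol Max-norm distance below which converged states are merged
#'   into one attractor.
#' @param no_regulator How nodes lacking regulators of a sign behave:
#'   `"constitutive"` sets the missing factor to 1 (an unregulated node relaxes
#'   to tau); `"zero"` sets a missing activation factor to 0 (unactivated nodes
#'   decay to 0). Missing inhibitors always give an inhibition factor of 1.
#' @param seed RNG seed used by [find_attractors()] for the random starts.
#' @return A list of class `endo_dynamics_params`.
#' @export
dynamics_params <- function(n = 3, a = 8, tau = 1, dt = 0.01,
                            max_iter = 40000, epsilon = 1e-4, delta = 1e-4,
                            n_starts = 1000, merge_tol = 0.01,
                            no_regulator = c("constitutive", "zero"),
                            seed = NULL) {
  no_regulator <- match.arg(no_regulator)
  stopifnot(n >= 3, n <= 10, a > 0, dt > 0, dt <= 1, max_iter >= 1,
            epsilon > 0, delta > 0, n_starts >= 1, merge_tol >= 0,
            all(tau > 0))
  structure(list(n = n, a = a, tau = tau, dt = dt, max_iter = max_iter,
                 epsilon = epsilon, delta = delta, n_starts = n_starts,
                 merge_tol = merge_tol, no_regulator = no_regulator,
                 seed = seed),
            class = "endo_dynamics_params")
}

.check_activity <- function(x) {
  if (any(is.na(x)) || any(x < 0) || any(x > 1)) {
    stop("activity values must lie in [0, 1]")
  }
  invisible(x)
}

#' Hill activation factor
#'
#' `a * x^n / (1 + a * x^n)`: a sigmoid rising from 0 at x = 0 to
#' `a / (1 + a)` at x = 1, strictly increasing on the activity range.
#'
#' @param x Activity in \[0, 1\] (vectorised).
#' @param n Hill coefficient.
#' @param a Kinetic constant.
#' @return Activation factor(s) in \[0, a/(1+a)\].
#' @export
#' @examples
#' hill_activation(0.5, 3, 8)  # 0.5
hill_activation <- function(x, n = 3, a = 8) {
  .check_activity(x)
  s <- a * x^n
  s / (1 + s)
}

#' Hill inhibition factor
#'
#' `1 / (1 + a * x^n)`: strictly decreasing from 1 at x = 0 to `1/(1+a)` at
#' x = 1.
#'
#' @inheritParams hill_activation
#' @return Inhibition factor(s) in \[1/(1+a), 1\].
#' @export
#' @examples
#' hill_inhibition(0.5, 3, 8)  # 0.5
hill_inhibition <- function(x, n = 3, a = 8) {
  .check_activity(x)
  1 / (1 + a * x^n)
}

# Signed incidence matrices: element [k, i] = 1 iff node i regulates node k
# with the given sign. Regulators of one sign are pooled inside a single Hill
# denominator, generalising the multi-regulator combination rule.
.incidence <- function(net, sign) {
  ids <- net$nodes$id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  e <- net$edges[net$edges$sign == sign, , drop = FALSE]
  if (nrow(e)) m[cbind(match(e$target, ids), match(e$source, ids))] <- 1
  m
}

# Integer powers by repeated multiplication (x^3 elementwise is the hot path).
.pow_int <- function(x, n) {
  if (n == round(n)) {
    out <- x
    for (i in seq_len(n - 1)) out <- out * x
    out
  } else {
    x^n
  }
}

.as_state_matrix <- function(state, ids) {
  if (is.null(names(state))) {
    if (length(state) != length(ids)) {
      stop("state must name every network node or match the node count")
    }
    names(state) <- ids
  }
  if (!setequal(names(state), ids)) {
    stop("state must have exactly one value per network node; missing: ",
         paste(setdiff(ids, names(state)), collapse = ", "))
  }
  matrix(state[ids], ncol = 1, dimnames = list(ids, NULL))
}

#' Production rate of one node
#'
#' The pooled Hill production term `f = A * I` where
#' `A = S_act / (1 + S_act)` with `S_act = sum over activators of a * x^n`
#' (taken as 1 in `"constitutive"` mode, 0 in `"zero"` mode, when the node has
#' no activators), and `I = 1 / (1 + S_inh)` with the analogous inhibitor sum
#' (1 when there are no inhibitors).
#'
#' @param node A node id.
#' @param state Named numeric vector of activities covering every node.
#' @param net An [network()] object.
#' @param params [dynamics_params()].
#' @return The production rate, a scalar in \[0, 1\].
#' @export
production_rate <- function(node, state, net, params = dynamics_params()) {
  stopifnot(inherits(net, "endo_network"), node %in% net$nodes$id)
  X <- .as_state_matrix(state, net$nodes$id)
  .check_activity(X)
  f <- .production_matrix(X, net, params)
  unname(f[node, 1])
}

.production_matrix <- function(X, net, params, cache = NULL) {
  if (is.null(cache)) cache <- .dynamics_cache(net, params)
  H <- params$a * .pow_int(X, params$n)
  Sa <- cache$act %*% H
  Si <- cache$inh %*% H
  Fa <- Sa / (1 + Sa)
  if (any(!cache$has_act)) {
    Fa[!cache$has_act, ] <- if (params$no_regulator == "constitutive") 1 else 0
  }
  Fa * (1 / (1 + Si))
}

.dynamics_cache <- function(net, params) {
  act <- .incidence(net, "activation")
  inh <- .incidence(net, "inhibition")
  list(act = act, inh = inh,
       has_act = rowSums(act) > 0,
       tau = rep_len(params$tau, nrow(net$nodes)))
}

#' Time derivative of the full state
#'
#' Per node k: `dx_k/dt = production_rate(k) - x_k / tau_k`.
#'
#' @param state Named numeric vector of activities covering every node.
#' @inheritParams production_rate
#' @return Named numeric vector of rates, one per node.
#' @export
state_derivative <- function(state, net, params = dynamics_params()) {
  stopifnot(inherits(net, "endo_network"))
  X <- .as_state_matrix(state, net$nodes$id)
  .check_activity(X)
  cache <- .dynamics_cache(net, params)
  f <- .production_matrix(X, net, params, cache)
  stats::setNames(as.vector(f - X / cache$tau), net$nodes$id)
}

# Vectorised explicit-Euler engine over a matrix of starts (nodes x starts).
# Converged columns are frozen and dropped from further iteration. Also tracks
# the global min/max visited by any iterate (forward-invariance diagnostics).
.simulate_matrix <- function(X, net, params) {
  cache <- .dynamics_cache(net, params)
  ids <- net$nodes$id
  m <- ncol(X)
  out <- X
  converged_at <- rep(NA_integer_, m)
  residual <- rep(NA_real_, m)
  active <- seq_len(m)
  Xa <- X
  rng <- c(min(X), max(X))
  dt <- params$dt
  for (l in seq_len(params$max_iter)) {
    f <- .production_matrix(Xa, net, params, cache)
    D <- f - Xa / cache$tau
    Xn <- Xa + dt * D
    if (anyNA(Xn)) stop("numerical failure: NaN in state at iteration ", l)
    rng[1] <- min(rng[1], min(Xn))
    rng[2] <- max(rng[2], max(Xn))
    done <- (colSums(abs(Xn - Xa) >= params$epsilon) == 0L) &
      (colSums(abs(D) >= params$delta) == 0L)
    if (any(done)) {
      idx <- active[done]
      converged_at[idx] <- l
      residual[idx] <- apply(abs(D[, done, drop = FALSE]), 2, max)
      out[, idx] <- Xn[, done]
      if (all(done)) {
        active <- integer(0)
        break
      }
      active <- active[!done]
      Xa <- Xn[, !done, drop = FALSE]
    } else {
      Xa <- Xn
    }
  }
  if (length(active)) out[, active] <- Xa
  rownames(out) <- ids
  list(states = out, converged_at = converged_at, residual = residual,
       range = rng)
}

.new_attractor <- function(state, residual, basin_count, converged_at) {
  structure(list(state = state, residual = residual,
                 basin_count = basin_count, converged_at = converged_at),
            class = "endo_attractor")
}

#' @export
print.endo_attractor <- function(x, ...) {
  cat(sprintf("<endo_attractor> residual %.2g, basin %d, converged at %d\n",
              x$residual, x$basin_count, x$converged_at))
  print(round(x$state, 4))
  invisible(x)
}

#' Iterate one initial state to an attractor
#'
#' Explicit-Euler fixed-point iteration `v_{l+1} = v_l + dt * f(v_l)` until
#' both `max|v_{l+1} - v_l| < epsilon` and `max|f(v_l)| < delta`, or the
#' iteration cap is hit.
#'
#' @param v0 Named numeric vector of initial activities in \[0, 1\], one per
#'   node.
#' @inheritParams production_rate
#' @return On convergence, an `endo_attractor`: list with `state` (named
#'   activities), `residual` (max |dx/dt| at convergence), `basin_count`
#'   (1 here) and `converged_at` (iteration index). On non-convergence, `NULL`
#'   with a warning.
#' @export
iterate_to_attractor <- function(v0, net, params = dynamics_params()) {
  stopifnot(inherits(net, "endo_network"))
  X <- .as_state_matrix(v0, net$nodes$id)
  .check_activity(X)
  sim <- .simulate_matrix(X, net, params)
  if (is.na(sim$converged_at[1])) {
    warning("no convergence within ", params$max_iter, " iterations")
    return(NULL)
  }
  .new_attractor(stats::setNames(sim$states[, 1], net$nodes$id),
                 sim$residual[1], 1L, sim$converged_at[1])
}

# Greedy max-norm merge of converged states. The representative of a cluster is
# the member with the smallest residual, so every reported attractor satisfies
# the convergence criterion when re-evaluated.
.merge_attractors <- function(states, residual, converged_at, merge_tol) {
  reps <- integer(0)           # column indices of representatives
  members <- list()
  for (j in seq_len(ncol(states))) {
    hit <- 0L
    for (r in seq_along(reps)) {
      if (max(abs(states[, reps[r]] - states[, j])) < merge_tol) {
        hit <- r
        break
      }
    }
    if (hit == 0L) {
      reps <- c(reps, j)
      members[[length(reps)]] <- j
    } else {
      members[[hit]] <- c(members[[hit]], j)
      if (residual[j] < residual[reps[hit]]) reps[hit] <- j
    }
  }
  list(reps = reps, members = members)
}

#' Enumerate attractors from random initial states
#'
#' Runs [iterate_to_attractor()] from `n_starts` uniform-random initial
#' vectors, merges converged states closer than `merge_tol` in max-norm, and
#' returns the distinct attractors sorted by descending basin count (the number
#' of starts mapped to each).
#'
#' @inheritParams production_rate
#' @return An `endo_attractor_set`: list with `attractors` (list of
#'   `endo_attractor`), `n_starts`, `n_converged`, `nonconverged_fraction`,
#'   `state_range` (min/max activity visited by any iterate) and `params`.
#' @export
find_attractors <- function(net, params = dynamics_params()) {
  stopifnot(inherits(net, "endo_network"))
  if (!is.null(params$seed)) set.seed(params$seed)
  nN <- nrow(net$nodes)
  X0 <- matrix(stats::runif(nN * params$n_starts), nrow = nN,
               dimnames = list(net$nodes$id, NULL))
  sim <- .simulate_matrix(X0, net, params)
  ok <- !is.na(sim$converged_at)
  if (!any(ok)) {
    stop(sprintf("no start converged within %d iterations (%.0f%% non-convergent)",
                 params$max_iter, 100 * mean(!ok)))
  }
  merged <- .merge_attractors(sim$states[, ok, drop = FALSE],
                              sim$residual[ok], sim$converged_at[ok],
                              params$merge_tol)
  res_ok <- sim$residual[ok]
  conv_ok <- sim$converged_at[ok]
  st_ok <- sim$states[, ok, drop = FALSE]
  attractors <- lapply(seq_along(merged$reps), function(r) {
    j <- merged$reps[r]
    .new_attractor(stats::setNames(st_ok[, j], net$nodes$id),
                   res_ok[j], length(merged$members[[r]]), conv_ok[j])
  })
  ord <- order(vapply(attractors, `[[`, integer(1), "basin_count"),
               decreasing = TRUE)
  structure(list(attractors = attractors[ord],
                 n_starts = params$n_starts,
                 n_converged = sum(ok),
                 nonconverged_fraction = mean(!ok),
                 state_range = sim$range,
                 params = params),
            class = "endo_attractor_set")
}

#' @export
print.endo_attractor_set <- function(x, ...) {
  cat(sprintf("<endo_attractor_set> %d attractor(s) from %d starts (%d converged)\n",
              length(x$attractors), x$n_starts, x$n_converged))
  print(attractor_table(x), digits = 4)
  invisible(x)
}

#' Tabulate an attractor set
#'
#' One row per node, one column per attractor (named A1, A2, ... in basin
#' order), plus `basin_count` and `residual` attribute rows appended at the
#' bottom.
#'
#' @param aset An `endo_attractor_set` from [find_attractors()].
#' @param rescale If `TRUE`, divide activities by a/(1+a) so the reportable
#'   range spans exactly 0 to 1 (steady states are otherwise bounded by the
#'   Hill ceiling a/(1+a)).
#' @return A data frame.
#' @export
attractor_table <- function(aset, rescale = FALSE) {
  stopifnot(inherits(aset, "endo_attractor_set"))
  states <- vapply(aset$attractors, `[[`, numeric(length(aset$attractors[[1]]$state)),
                   "state")
  states <- matrix(states, ncol = length(aset$attractors),
                   dimnames = list(names(aset$attractors[[1]]$state),
                                   paste0("A", seq_along(aset$attractors))))
  if (rescale) {
    a <- aset$params$a
    states <- states * (1 + a) / a
  }
  out <- as.data.frame(states)
  extras <- rbind(
    basin_count = vapply(aset$attractors, `[[`, integer(1), "basin_count"),
    residual = vapply(aset$attractors, `[[`, numeric(1), "residual")
  )
  colnames(extras) <- colnames(states)
  rbind(out, as.data.frame(extras))
}
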