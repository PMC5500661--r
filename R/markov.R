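#' Jump rates of the activity Markov chain
#'
#' The chain \eqn{X^{P,N}} lives on \eqn{\{0, 1/N, \dots, 1\}^P} and jumps
#' one coordinate by \eqn{\pm 1/N} at a time. The balance-seeking rates
#' (variant `"balance"`, the model this package is built around) are
#' \deqn{q(x, x + e_k/N) = N F'(F^{-1}(x_k))\Big(-F^{-1}(x_k)
#'   + \sum_j w_{kj}x_j\Big)_+,}
#' \deqn{q(x, x - e_k/N) = N F'(F^{-1}(x_k))\Big(-F^{-1}(x_k)
#'   + \sum_j w_{kj}x_j\Big)_-,}
#' i.e. the time-averaged activity moves toward balance
#' \eqn{a = F(u)} between activity and synaptic input, at speed
#' proportional to the imbalance and to the sensitivity \eqn{F'}. At a
#' balanced state both rates vanish — fluctuations die out at the stable
#' fixed points where \eqn{F' \ll 1}.
#'
#' Variant `"classical"` implements the classical activity-based rates
#' \eqn{\tilde q(x, x + e_k/N) = N F(\sum_j w_{kj}x_j)},
#' \eqn{\tilde q(x, x - e_k/N) = N x_k}, which share the same deterministic
#' limit structure but keep jumping at balanced states with high activity —
#' the qualitative contrast the package's experiments reproduce.
#'
#' Boundary convention: a coordinate at 0 or 1 has both rates set to 0 for
#' the `"balance"` variant (the one-sided limit of the rate formula, since
#' \eqn{F' \to 0} faster than \eqn{F^{-1}} diverges); the interior
#' \eqn{\{1/N, \dots, 1-1/N\}^P} is invariant for \eqn{N \ge N_0}
#' ([interior_threshold()]), so these guards are never hit in ordinary use.
#'
#' @param x state vector (entries in \[0, 1\], typically multiples of 1/N).
#' @param W P x P weight matrix.
#' @param F gain function.
#' @param N population size.
#' @param variant `"balance"` (balance-seeking) or `"classical"` (activity-based).
#' @return list with vectors `up` and `down`; per coordinate at most one of
#'   the two is positive for the `"balance"` variant.
#' @export
jump_rates <- function(x, W, F, N, variant = c("balance", "classical")) {
  variant <- match.arg(variant)
  stopifnot(all(x >= 0 & x <= 1), N >= 1)
  s <- as.vector(W %*% x)
  interior <- x > 0 & x < 1
  up <- down <- numeric(length(x))
  if (variant == "balance") {
    i <- which(interior)
    u <- gain_inverse(F, x[i])
    d <- s[i] - u
    fp <- gain_eval(F, u, 1L)
    up[i] <- N * fp * pmax(d, 0)
    down[i] <- N * fp * pmax(-d, 0)
  } else {
    up <- N * gain_eval(F, s)
    down <- N * x
    up[x >= 1] <- 0
    down[x <= 0] <- 0
  }
  list(up = up, down = down)
}

#' Interior-invariance population size threshold
#'
#' Smallest \eqn{N_0} such that for \eqn{N \ge N_0} the boundary-adjacent
#' states cannot escape: the up rate at \eqn{x_k = 1 - 1/N} vanishes
#' because \eqn{F^{-1}(1 - 1/N)} exceeds any attainable synaptic input
#' (at most 1 for row-substochastic weights and activities in \[0, 1\]),
#' and symmetrically the down rate at \eqn{x_k = 1/N} vanishes because
#' \eqn{F^{-1}(1/N) < 0}. Found by scanning N.
#'
#' @param F gain function.
#' @param input_range attainable range of \eqn{\sum_j w_{kj} x_j}.
#' @param N_max scan cap.
#' @return integer \eqn{N_0}.
#' @export
interior_threshold <- function(F, input_range = c(0, 1), N_max = 100000L) {
  for (N in 2:N_max) {
    if (gain_inverse(F, 1 - 1 / N) >= input_range[2L] &&
        gain_inverse(F, 1 / N) <= input_range[1L])
      return(N)
  }
  stop("no interior-invariance threshold found below N_max")
}

#' Exact stochastic simulation of the activity Markov chain
#'
#' Direct Gillespie algorithm: exponential waiting time at the total rate,
#' categorical jump choice proportional to the individual rates, with the
#' synaptic input updated incrementally per jump. Alongside the state the
#' simulator accumulates, exactly (the integrands are piecewise constant
#' between jumps), the compensator \eqn{\int_0^t Q\pi_k(X_s)\,ds} and the
#' bracket \eqn{\langle M_k \rangle_t = \int_0^t (q^+_k + q^-_k)/N^2\,ds},
#' so the martingale decomposition is available at the evaluation times.
#'
#' @param x0 initial state; entries are snapped to the 1/N grid.
#' @param W weight matrix.
#' @param F gain function.
#' @param N population size.
#' @param T time horizon.
#' @param eval_times grid at which the state and integrals are recorded
#'   (defaults to 65 equispaced times on \[0, T\]).
#' @param variant rate variant, see [jump_rates()].
#' @param seed optional integer seed (applied via `set.seed`).
#' @param record_path also return the full event list (time, coordinate,
#'   direction) — intended for short runs.
#' @param max_jumps safety cap.
#' @return object of class `markov_path`: `states` (times x P),
#'   `drift_int`, `bracket`, `martingale` (\eqn{M(t) = X_t - X_0 -}
#'   compensator), `eval_times`, `n_jumps`, and optionally `path`.
#' @export
simulate_ssa <- function(x0, W, F, N, T, eval_times = NULL,
                         variant = c("balance", "classical"), seed = NULL,
                         record_path = FALSE, max_jumps = 5e7) {
  variant <- match.arg(variant)
  stopifnot(inherits(F, "gain_function"), N >= 1, T > 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(eval_times)) eval_times <- seq(0, T, length.out = 65L)
  stopifnot(!is.unsorted(eval_times), max(eval_times) <= T + 1e-12)
  x0 <- round(x0 * N) / N
  res <- .ssa_core(x0, as.integer(N), as.matrix(W), F$gamma, F$kappa,
                   as.numeric(T), as.numeric(eval_times),
                   if (variant == "balance") 0L else 1L,
                   record_path, as.integer(max_jumps))
  if (res$overflow) warning("max_jumps reached before T")
  M <- sweep(res$states, 2L, res$states[1L, ]) - res$drift_int
  structure(list(states = res$states, drift_int = res$drift_int,
                 bracket = res$bracket, martingale = M,
                 eval_times = eval_times, n_jumps = res$n_jumps,
                 x0 = x0, N = N, variant = variant,
                 path = res$path),
            class = "markov_path")
}

#' @export
print.markov_path <- function(x, ...) {
  cat(sprintf("SSA path: P = %d, N = %d, %d jumps on [0, %g] (%s rates)\n",
              ncol(x$states), x$N, x$n_jumps, max(x$eval_times), x$variant))
  invisible(x)
}

#' Apply the Markov generator to a function of the state
#'
#' \deqn{Q^{P,N} f(x) = \sum_k \big[q^+_k (f(x + e_k/N) - f(x))
#'   + q^-_k (f(x - e_k/N) - f(x))\big].}
#' For smooth \eqn{f} this converges as \eqn{N \to \infty} to the
#' transport generator \eqn{L^P f = \sum_k F'(F^{-1}(x_k))(-F^{-1}(x_k)
#'  + \sum_j w_{kj}x_j)\,\partial_k f} of the deterministic limit flow.
#'
#' @param f function of the state vector returning a scalar.
#' @param x state vector.
#' @param W,F,N,variant as in [jump_rates()].
#' @return scalar \eqn{Q^{P,N} f(x)}.
#' @export
generator_apply <- function(f, x, W, F, N, variant = "balance") {
  r <- jump_rates(x, W, F, N, variant)
  fx <- f(x)
  s <- 0
  for (k in seq_along(x)) {
    if (r$up[k] > 0) {
      xp <- x; xp[k] <- xp[k] + 1 / N
      s <- s + r$up[k] * (f(xp) - fx)
    }
    if (r$down[k] > 0) {
      xm <- x; xm[k] <- xm[k] - 1 / N
      s <- s + r$down[k] * (f(xm) - fx)
    }
  }
  s
}

#' Martingale decomposition along a recorded event path
#'
#' Reference (pure R) reconstruction of the compensated martingale
#' \eqn{M_k(t) = X_k(t) - X_k(0) - \int_0^t Q\pi_k(X_s)\,ds} and its
#' bracket from the full event list of a [simulate_ssa()] run with
#' `record_path = TRUE`; the integrals are exact between jumps. Serves as
#' an independent cross-check of the accumulators built into the
#' simulation core.
#'
#' @param sp a `markov_path` with a recorded event list.
#' @param W,F as used for the simulation.
#' @param eval_times times at which to evaluate.
#' @return list with matrices `martingale` and `bracket`
#'   (length(eval_times) x P).
#' @export
martingale_decompose <- function(sp, W, F, eval_times) {
  stopifnot(inherits(sp, "markov_path"), !is.null(sp$path))
  P <- ncol(sp$states)
  x <- sp$x0
  tprev <- 0
  cum_drift <- cum_brk <- numeric(P)
  M <- B <- matrix(0, length(eval_times), P)
  iev <- 1L
  events <- c(sp$path$time, Inf)
  advance <- function(tto) {
    r <- jump_rates(x, W, F, sp$N, sp$variant)
    tau <- tto - tprev
    cum_drift <<- cum_drift + tau * (r$up - r$down) / sp$N
    cum_brk <<- cum_brk + tau * (r$up + r$down) / sp$N^2
  }
  for (j in seq_along(sp$path$time)) {
    tj <- sp$path$time[j]
    while (iev <= length(eval_times) && eval_times[iev] < tj) {
      r <- jump_rates(x, W, F, sp$N, sp$variant)
      tau <- eval_times[iev] - tprev
      M[iev, ] <- x - sp$x0 - (cum_drift + tau * (r$up - r$down) / sp$N)
      B[iev, ] <- cum_brk + tau * (r$up + r$down) / sp$N^2
      iev <- iev + 1L
    }
    advance(tj)
    tprev <- tj
    k <- sp$path$coord[j]
    x[k] <- x[k] + sp$path$dir[j] / sp$N
  }
  while (iev <= length(eval_times)) {
    r <- jump_rates(x, W, F, sp$N, sp$variant)
    tau <- eval_times[iev] - tprev
    M[iev, ] <- x - sp$x0 - (cum_drift + tau * (r$up - r$down) / sp$N)
    B[iev, ] <- cum_brk + tau * (r$up + r$down) / sp$N^2
    iev <- iev + 1L
  }
  list(martingale = M, bracket = B)
}

#' Export an SSA event list to CSV plus metadata JSON
#'
#' @param sp a `markov_path` with recorded events.
#' @param path CSV destination (columns time, coord, dir).
#' @return invisibly, `path`.
#' @export
write_ssa_events <- function(sp, path) {
  stopifnot(inherits(sp, "markov_path"), !is.null(sp$path))
  utils::write.csv(data.frame(time = sp$path$time, coord = sp$path$coord,
                              dir = sp$path$dir), path, row.names = FALSE)
  meta <- list(P = ncol(sp$states), N = sp$N, variant = sp$variant,
               n_jumps = sp$n_jumps, T = max(sp$eval_times))
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paste0(path, ".json"))
  invisible(path)
}
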