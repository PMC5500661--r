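#' Standard parameter fixtures
#'
#' Self-contained parameter bundles used throughout the experiments, all
#' passing [validate_assumptions()]:
#' * `"symmetric_standing"`: gamma = 8, kappa = 0.5, exponential kernel
#'   (scale 1). The logistic symmetry \eqn{F(0.5+x) + F(0.5-x) = 1} makes
#'   the problem invariant under \eqn{u \mapsto 1 - u, x \mapsto -x}, so
#'   the unique wave stands still (c = 0) and \eqn{a_1 + a_2 = 1}.
#' * `"asymmetric_traveling"`: gamma = 8, kappa = 0.55, gaussian kernel
#'   (scale 1); the low-activity state invades, c is moderate (about 0.19).
#' * `"fast_wave"`: gamma = 8, kappa = 0.6, gaussian kernel (scale 1);
#'   stronger asymmetry, c about 0.46. (At gamma = 8 the bistability is
#'   lost beyond kappa about 0.64, so this is close to the fastest wave
#'   the family supports.)
#'
#' @param name fixture name.
#' @return list with `F` (gain), `w` (kernel), `name`, and default noise
#'   correlation length `eps` and cutoff fraction `delta_frac`.
#' @export
fixture_generator <- function(name = c("symmetric_standing",
                                       "asymmetric_traveling",
                                       "fast_wave")) {
  name <- match.arg(name)
  pars <- switch(name,
    symmetric_standing = list(gamma = 8, kappa = 0.5,
                              family = "exponential"),
    asymmetric_traveling = list(gamma = 8, kappa = 0.55,
                                family = "gaussian"),
    fast_wave = list(gamma = 8, kappa = 0.6, family = "gaussian"))
  list(name = name,
       F = logistic_gain(pars$gamma, pars$kappa),
       w = synaptic_kernel(pars$family, 1),
       eps = 0.25, delta_frac = 0.1)
}

#' Measure a front speed by level-set tracking
#'
#' For each time the position where the (spatially monotone) field crosses
#' a level is located by linear interpolation between grid points; the
#' speed is the least-squares slope of position versus time.
#'
#' @param field matrix (times x grid) of field values.
#' @param grid spatial grid.
#' @param times time vector.
#' @param level crossing level (default: midpoint of the first row range).
#' @return list with `speed`, `positions`, `times`.
#' @export
front_speed_measure <- function(field, grid, times,
                                level = mean(range(field[1L, ]))) {
  pos <- apply(field, 1L, function(u) front_position(u, grid, level))
  if (anyNA(pos)) stop("field does not cross the level at some time")
  fit <- stats::lm.fit(cbind(1, times), pos)
  list(speed = unname(fit$coefficients[2L]), positions = pos, times = times)
}

#' Level-crossing position of a monotone-in-space profile
#'
#' @param u field values.
#' @param grid spatial grid.
#' @param level crossing level.
#' @return interpolated crossing position (NA if the level is not crossed).
#' @export
front_position <- function(u, grid, level) {
  s <- u - level
  i <- which(s[-length(s)] * s[-1L] <= 0 & s[-length(s)] != s[-1L])
  if (length(i) == 0L) return(NA_real_)
  i <- i[1L]
  grid[i] + (grid[i + 1L] - grid[i]) * (level - u[i]) / (u[i + 1L] - u[i])
}

#' Law-of-large-numbers scaling experiment
#'
#' For each population size N, simulates the activity Markov chain
#' `n_rep` times from a common initial condition and records the supremum
#' over an evaluation grid of the Euclidean distance to the mean-field ODE
#' trajectory. The mean deviation should scale like \eqn{N^{-1/2}}; the
#' report fits a log-log slope with a confidence interval.
#'
#' @param W weight matrix.
#' @param F gain function.
#' @param x0 interior initial activities.
#' @param T horizon.
#' @param N_levels increasing population sizes.
#' @param n_rep replicas per level.
#' @param seed base seed (one stream per trajectory, derived).
#' @param n_eval evaluation-grid size on \[0, T\].
#' @return object of class `scaling_report`: `levels`, `errors` (mean sup
#'   deviation per level), `slope`, `slope_ci`, and per-replica values.
#' @export
run_lln_experiment <- function(W, F, x0, T = 2, N_levels = c(100, 400, 1600),
                               n_rep = 100L, seed = 1L, n_eval = 64L) {
  stopifnot(!is.unsorted(N_levels))
  tt <- seq(0, T, length.out = n_eval)
  ref <- integrate_meanfield(x0, W, F, tt)
  per <- matrix(NA_real_, n_rep, length(N_levels))
  for (j in seq_along(N_levels)) {
    N <- N_levels[j]
    for (r in seq_len(n_rep)) {
      sp <- simulate_ssa(x0, W, F, N, T, eval_times = tt,
                         seed = seed + 7919L * j + r)
      per[r, j] <- max(sqrt(rowSums((sp$states - ref)^2)))
    }
  }
  errors <- colMeans(per)
  fit <- stats::lm(log(errors) ~ log(N_levels))
  ci <- stats::confint(fit)[2L, ]
  structure(list(levels = N_levels, errors = errors,
                 slope = unname(stats::coef(fit)[2L]),
                 slope_ci = unname(ci), per_replica = per,
                 kind = "lln", seed = seed),
            class = "scaling_report")
}

#' @export
print.scaling_report <- function(x, ...) {
  cat(sprintf("Scaling experiment (%s): slope %.3f [%.3f, %.3f]\n",
              x$kind, x$slope, x$slope_ci[1L], x$slope_ci[2L]))
  print(data.frame(level = x$levels, error = x$errors))
  invisible(x)
}

#' Central-limit-theorem experiment for the compensated martingale
#'
#' Simulates `n_rep` chains at one population size, extracts the
#' compensated martingale \eqn{M^{P,N}(T)}, and compares the empirical
#' variance of \eqn{\sqrt N M_k(T)} with the limiting bracket
#' \deqn{\int_0^T F'(F^{-1}(X^P_k))\,\Big|-F^{-1}(X^P_k) +
#'   \sum_j w_{kj}X^P_j\Big|\,ds}
#' integrated along the mean-field path (trapezoid on a fine grid). Also
#' reports cross-population covariance z-scores (the single-jump structure
#' makes distinct coordinates uncorrelated in the limit) and a normality
#' check on the coordinate with the largest bracket.
#'
#' @param W,F,x0,T,seed as in [run_lln_experiment()].
#' @param N population size.
#' @param n_rep replicas.
#' @return list with `var_ratio` (pooled empirical/theoretical),
#'   `var_ratio_k` per coordinate, `bracket_theory`, `offdiag_z` matrix,
#'   `shapiro_p`, and the raw scaled martingale sample.
#' @export
run_clt_experiment <- function(W, F, x0, T = 1, N = 1600L, n_rep = 500L,
                               seed = 1L) {
  P <- length(x0)
  tt <- seq(0, T, length.out = 257L)
  ref <- integrate_meanfield(x0, W, F, tt)
  # limiting bracket along the mean-field path
  integrand <- t(apply(ref, 1L, function(x) {
    u <- gain_inverse(F, x)
    gain_eval(F, u, 1L) * abs(-u + as.vector(W %*% x))
  }))
  th <- rep(1, length(tt)); th[c(1L, length(tt))] <- 0.5
  bracket_theory <- (T / (length(tt) - 1L)) * colSums(integrand * th)
  Ms <- matrix(NA_real_, n_rep, P)
  for (r in seq_len(n_rep)) {
    sp <- simulate_ssa(x0, W, F, N, T, eval_times = c(0, T),
                       seed = seed + r)
    Ms[r, ] <- sqrt(N) * sp$martingale[2L, ]
  }
  v <- apply(Ms, 2L, stats::var)
  cv <- stats::cov(Ms)
  n <- n_rep
  # z-scores of off-diagonal covariances against their sampling error
  se <- sqrt((outer(v, v) + cv^2) / (n - 1))
  z <- cv / se
  diag(z) <- 0
  k_star <- which.max(bracket_theory)
  list(var_ratio = sum(v) / sum(bracket_theory),
       var_ratio_k = v / bracket_theory,
       bracket_theory = bracket_theory, empirical_var = v,
       offdiag_z = z, k_star = k_star,
       shapiro_p = stats::shapiro.test(Ms[, k_star])$p.value,
       mean_M = colMeans(Ms), se_M = sqrt(v / n_rep),
       sample = Ms, N = N, n_rep = n_rep)
}

#' Lattice-to-continuum convergence experiment (matched noise)
#'
#' Couples the continuum stochastic field equation and a family of lattice
#' diffusion networks of increasing density m (with growing half-length
#' L^m) to a single Q-Wiener realization per replica: the lattice systems
#' are driven by the quarter-interval averages of the same increments that
#' drive the continuum equation. Reports the Monte Carlo mean of
#' \eqn{\sup_{t\le T}\|u^m - u\|_{L^2(-L^m, L^m)}^2}, which the
#' convergence theory sends to zero as m grows; at desk scale the check is
#' a strict decrease over the m levels.
#'
#' @param wave traveling wave with c > 0.
#' @param eps noise correlation half-width.
#' @param m_levels increasing lattice densities.
#' @param L_m half-lengths per level (growing with m).
#' @param N population size.
#' @param T horizon, `dt` step.
#' @param L_dom,h continuum window half-length and grid spacing.
#' @param n_rep replicas.
#' @param delta cutoff level.
#' @param seed base seed.
#' @return `scaling_report` with `levels = m_levels` and mean sup-L2
#'   squared errors, plus the per-replica matrix.
#' @export
run_continuum_experiment <- function(wave, eps = 0.25,
                                     m_levels = c(4L, 8L, 16L),
                                     L_m = c(2, 3, 4), N = 100,
                                     T = 0.5, dt = 2e-3,
                                     L_dom = 6, h = 1 / 64,
                                     n_rep = 50L,
                                     delta = 0.1 * max(wave$u_hat_x),
                                     seed = 1L) {
  stopifnot(wave$c > 0, length(L_m) == length(m_levels))
  F <- wave$gain
  grid <- seq(-L_dom, L_dom - h, by = h)
  noise <- noise_model(eps, grid)
  cvg <- fw_conv_op(wave$kernel, grid)
  Fa1 <- gain_eval(F, wave$a1); Fa2 <- gain_eval(F, wave$a2)
  geoms <- lapply(seq_along(m_levels), function(j)
    discretize_weights(wave$kernel, m_levels[j], L_m[j]))
  projs <- lapply(seq_along(m_levels), function(j)
    phi_m_weights(noise, m_levels[j], L_m[j]))
  # lattice cells I^m_k inside (-L^m, L^m) for the restricted L2 norm
  cellof <- lapply(seq_along(m_levels), function(j) {
    g <- geoms[[j]]
    findInterval(grid, c(g$positions, g$L), rightmost.closed = FALSE)
  })
  nstep <- ceiling(T / dt - 1e-9)
  per <- matrix(0, n_rep, length(m_levels))
  for (r in seq_len(n_rep)) {
    set.seed(seed + 331L * r)
    u <- evaluate_wave(wave, grid, 0)$u
    um <- lapply(geoms, function(g) evaluate_wave(wave, g$positions, 0)$u)
    sup_err <- numeric(length(m_levels))
    for (s in seq_len(nstep)) {
      t <- (s - 1L) * dt
      dW <- sample_qwiener_increment(noise, dt)
      ev <- evaluate_wave(wave, grid, t)
      corr_cont <- (gain_eval(F, ev$u, 2L) / gain_eval(F, ev$u, 1L)^2) *
        ev$u_t / (2 * N)
      drift <- -u + cvg$apply(gain_eval(F, u), Fa1, Fa2) + corr_cont
      sig <- sigma_continuum(t, u, grid, wave, N, delta, conv = cvg)
      u_new <- u + dt * drift + sig * dW
      for (j in seq_along(m_levels)) {
        g <- geoms[[j]]
        evm <- evaluate_wave(wave, g$positions, t)
        co <- diffusion_coefficients_m(t, g, wave, F, delta)
        bu <- drift_bm(t, um[[j]], g, F, wave)
        bw <- co$minus_b * -1
        corr_m <- (gain_eval(F, evm$u, 2L) / gain_eval(F, evm$u, 1L)^2) *
          bw / (2 * N)
        sg <- sigma_m_apply(t, um[[j]], co, g, wave, N)
        dWm <- as.vector(projs[[j]] %*% dW)
        um[[j]] <- um[[j]] + dt * (bu + corr_m) + sg * dWm
        # piecewise-constant embedding, restricted L2 error on (-L^m, L^m)
        idx <- cellof[[j]]
        inside <- idx >= 1L & idx <= g$P
        diffv <- um[[j]][idx[inside]] - u_new[inside]
        sup_err[j] <- max(sup_err[j], sum(diffv^2) * h)
      }
      u <- u_new
    }
    per[r, ] <- sup_err
  }
  errors <- colMeans(per)
  fit <- stats::lm(log(errors) ~ log(m_levels))
  ci <- if (length(m_levels) > 2L) unname(stats::confint(fit)[2L, ])
        else c(NA_real_, NA_real_)
  structure(list(levels = m_levels, errors = errors,
                 slope = unname(stats::coef(fit)[2L]),
                 slope_ci = ci,
                 per_replica = per, kind = "continuum", seed = seed),
            class = "scaling_report")
}
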