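#' Cutoff diffusion coefficients on the lattice
#'
#' The linear-noise (diffusion) approximation around the traveling wave has
#' dispersion \eqn{\sigma^m(t,u) = \frac{1}{\sqrt N}\big(\alpha^m + \beta^m
#' (u - \pi^m u^{TW}_t) - \gamma^m\, \pi^m(w * (\pi^m F'(u^{TW}_t)(u - \pi^m
#' u^{TW}_t)))\big)} with coefficients evaluated along the wave:
#' \deqn{\alpha^m = \sqrt{\frac{-b^m(t, \pi^m u^{TW}_t)}{\pi^m F'(u^{TW}_t)}},
#' \qquad \gamma^m = \frac{1}{2\sqrt{-b^m \,\pi^m F'}},}
#' \deqn{\beta^m = \gamma^m \Big(-\frac{\pi^m F''}{\pi^m F'}(-b^m) + 1\Big),}
#' all multiplied by the indicator of the moving front region
#' \eqn{\{\partial_x u^{TW}_t \ge \delta\}}: the cutoff keeps the noise
#' square-integrable while retaining the fluctuations in the sensitive
#' regime away from the stable fixed points. Requires a strictly traveling
#' wave, \eqn{c > 0}: the expansion rests on \eqn{-b^m(t, \pi^m u^{TW}_t)
#' \approx c\,\hat u_x > 0} (for a standing wave the leading drift at the
#' wave vanishes and the square-root expansion breaks down, so this errors).
#'
#' @param t time.
#' @param g a [discretize_weights()] geometry.
#' @param wave a [solve_wave()] profile with `c > 0`.
#' @param F gain function (defaults to the wave's).
#' @param delta cutoff level on \eqn{\partial_x u^{TW}}; default 10% of
#'   the maximal slope.
#' @return object of class `thm_coefficients`: vectors `alpha`, `beta`,
#'   `gamma_c` over populations (zero outside the mask), logical `mask`,
#'   `delta`, and the wave drift `minus_b` used.
#' @export
diffusion_coefficients_m <- function(t, g, wave, F = wave$gain,
                                     delta = 0.1 * max(wave$u_hat_x)) {
  stopifnot(inherits(g, "network_geometry"), inherits(wave, "wave_profile"))
  if (wave$c <= 1e-8)   # standing waves: the expansion breaks down
    stop("diffusion coefficients require a strictly positive wave speed")
  if (delta <= 0) stop("cutoff delta must be positive")
  ev <- evaluate_wave(wave, g$positions, t)
  mask <- ev$u_x >= delta
  Fp <- gain_eval(F, ev$u, 1L)
  Fpp <- gain_eval(F, ev$u, 2L)
  minus_b <- -drift_bm(t, ev$u, g, F, wave)
  if (any(mask & (minus_b <= 0)))
    stop(paste("drift positivity -b^m(t, wave) > 0 fails on the cutoff set;",
               "increase the domain half-length L"))
  alpha <- beta <- gamma_c <- numeric(g$P)
  i <- which(mask)
  rt <- sqrt(minus_b[i] * Fp[i])
  alpha[i] <- sqrt(minus_b[i] / Fp[i])
  gamma_c[i] <- 1 / (2 * rt)
  beta[i] <- gamma_c[i] * (-(Fpp[i] / Fp[i]) * minus_b[i] + 1)
  structure(list(alpha = alpha, beta = beta, gamma_c = gamma_c,
                 mask = mask, delta = delta, t = t, minus_b = minus_b,
                 wave_u = ev$u, wave_ux = ev$u_x, Fp = Fp),
            class = "thm_coefficients")
}

#' Apply the lattice dispersion operator
#'
#' Evaluates \eqn{\sigma^m(t, u)} for a lattice voltage field `u`, using
#' coefficients from [diffusion_coefficients_m()] for the same time; the
#' inner convolution is the discrete-weight sum
#' \eqn{\sum_l w^m_{kl} F'(u^{TW}_t(l/m)) v_l} with
#' \eqn{v = u - \pi^m u^{TW}_t}.
#'
#' @param t time (must match the coefficients).
#' @param u lattice voltage vector.
#' @param coeffs a `thm_coefficients` object.
#' @param g geometry.
#' @param wave wave profile.
#' @param N population size (enters only through the 1/sqrt(N) prefactor).
#' @return dispersion vector of length P.
#' @export
sigma_m_apply <- function(t, u, coeffs, g, wave, N) {
  stopifnot(inherits(coeffs, "thm_coefficients"),
            isTRUE(all.equal(t, coeffs$t)))
  v <- u - coeffs$wave_u
  convv <- as.vector(g$W %*% (coeffs$Fp * v))
  sig <- (coeffs$alpha + coeffs$beta * v - coeffs$gamma_c * convv) / sqrt(N)
  sig[!coeffs$mask] <- 0
  sig
}

#' Euler-Maruyama simulation of the lattice diffusion network
#'
#' Integrates the coupled diffusion system
#' \deqn{du_k = \Big[\hat b^m_k(t,u) + \frac{1}{2N}
#'   \frac{F''(u^{TW}_t(k/m))}{F'(u^{TW}_t(k/m))^2}\,
#'   \hat b^m_k(t, u^{TW}_t)\Big]dt + \sigma^m_k(t,u)\,dW_k}
#' approximating the activity Markov chain's voltage fluctuations around
#' the traveling wave. The driving motions are either independent
#' (appropriate while the populations do not overlap, lattice density
#' \eqn{m < 1/(4\varepsilon)}) or the quarter-interval averages
#' \eqn{W^m_k = 2m\langle W^Q, 1_{J^m_k}\rangle} of a spatially correlated
#' Q-Wiener process, supplied through a [noise_model()].
#'
#' @param u0 initial lattice voltages (default: the wave at t = 0).
#' @param g geometry.
#' @param wave wave profile with c > 0.
#' @param N population size.
#' @param T horizon; `dt` fixed step.
#' @param delta cutoff level (see [diffusion_coefficients_m()]).
#' @param noise `"independent"` or a [noise_model()] for correlated driving.
#' @param seed optional seed.
#' @param save_every record every so many steps (1 = all).
#' @param deterministic drop the noise term (the N -> infinity drift flow).
#' @return list with `times`, `u` (times x P matrix), and the geometry.
#' @export
simulate_diffusion_network <- function(u0 = NULL, g, wave, N, T, dt,
                                       delta = 0.1 * max(wave$u_hat_x),
                                       noise = "independent", seed = NULL,
                                       save_every = 1L,
                                       deterministic = FALSE) {
  stopifnot(inherits(g, "network_geometry"), inherits(wave, "wave_profile"))
  if (!is.null(seed)) set.seed(seed)
  F <- wave$gain
  if (is.null(u0)) u0 <- evaluate_wave(wave, g$positions, 0)$u
  correlated <- inherits(noise, "noise_model")
  if (correlated) proj <- phi_m_weights(noise, g$m, g$L)
  nstep <- ceiling(T / dt - 1e-9)
  u <- u0
  isave <- unique(c(seq(0L, nstep, by = save_every), nstep))
  out <- matrix(NA_real_, length(isave), g$P)
  times <- isave * dt
  out[1L, ] <- u
  row <- 2L
  for (s in seq_len(nstep)) {
    t <- (s - 1L) * dt
    ev <- evaluate_wave(wave, g$positions, t)
    bu <- drift_bm(t, u, g, F, wave)
    bw <- drift_bm(t, ev$u, g, F, wave)
    corr <- (gain_eval(F, ev$u, 2L) / gain_eval(F, ev$u, 1L)^2) * bw /
      (2 * N)
    drift <- bu + corr
    if (deterministic) {
      u <- u + dt * drift
    } else {
      co <- diffusion_coefficients_m(t, g, wave, F, delta)
      sig <- sigma_m_apply(t, u, co, g, wave, N)
      dW <- if (correlated) {
        dWq <- sample_qwiener_increment(noise, dt)
        as.vector(proj %*% dWq)
      } else stats::rnorm(g$P, sd = sqrt(dt))
      u <- u + dt * drift + sig * dW
    }
    if (s %in% isave) { out[row, ] <- u; row <- row + 1L }
  }
  list(times = times, u = out, geometry = g, N = N, dt = dt)
}

#' Experimental: full square-root multiplicative SDE for the voltages
#'
#' Euler-Maruyama for the un-linearized voltage SDE whose diffusion
#' coefficient is \eqn{\sqrt{|\hat b^m_k(t,u)| / F'(u_k)}/\sqrt N}. The
#' square root is not Lipschitz near 0, so this equation has no standard
#' existence theory; the integrator clips the argument at zero and is
#' provided for numerical exploration only (it backs the Taylor-remainder
#' comparison with the linearized dispersion in the test-suite, nothing
#' else).
#'
#' @inheritParams simulate_diffusion_network
#' @return list with `times` and `u`.
#' @export
simulate_sqrt_sde <- function(u0 = NULL, g, wave, N, T, dt, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  F <- wave$gain
  if (is.null(u0)) u0 <- evaluate_wave(wave, g$positions, 0)$u
  nstep <- ceiling(T / dt - 1e-9)
  u <- u0
  out <- matrix(NA_real_, nstep + 1L, g$P)
  out[1L, ] <- u
  for (s in seq_len(nstep)) {
    t <- (s - 1L) * dt
    bu <- drift_bm(t, u, g, F, wave)
    sig <- sqrt(pmax(abs(bu) / gain_eval(F, u, 1L), 0) / N)
    u <- u + dt * bu + sig * stats::rnorm(g$P, sd = sqrt(dt))
    out[s + 1L, ] <- u
  }
  list(times = (0:nstep) * dt, u = out)
}

# diffusion coefficient of the full square-root SDE, used to check the
# linearization error of sigma_m_apply on the cutoff set
sqrt_sde_sigma <- function(t, u, g, wave, N, F = wave$gain) {
  bu <- drift_bm(t, u, g, F, wave)
  sqrt(pmax(abs(bu) / gain_eval(F, u, 1L), 0) / N)
}
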