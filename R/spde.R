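#' Continuum dispersion coefficient around the traveling wave
#'
#' The continuum analogue of the lattice dispersion: on the front region
#' \eqn{\{\partial_x u^{TW}_t \ge \delta\}},
#' \deqn{\sigma(t,u) = \frac{1}{\sqrt N}\Big(\alpha(t) + \beta(t)(u -
#'   u^{TW}_t) - \gamma(t)\, w * \big(F'(u^{TW}_t)(u - u^{TW}_t)\big)\Big)}
#' with
#' \eqn{\alpha = \sqrt{c\,\partial_x u^{TW}_t / F'(u^{TW}_t)}},
#' \eqn{\gamma = 1/(2\sqrt{c\,\partial_x u^{TW}_t\, F'(u^{TW}_t)})}, and
#' \eqn{\beta = \gamma\,(-(F''/F')\, c\,\partial_x u^{TW}_t + 1)}.
#' Along the wave itself (\eqn{u = u^{TW}_t}) the noise is purely additive
#' with amplitude \eqn{\alpha/\sqrt N}: the movement of the front is the
#' leading source of finite-size noise. Requires wave speed \eqn{c > 0}.
#'
#' @param t time.
#' @param u field values on `grid`.
#' @param grid uniform spatial grid.
#' @param wave a [solve_wave()] profile with c > 0.
#' @param N population size.
#' @param delta cutoff level; default 10% of the maximal wave slope.
#' @param conv optional precomputed convolution operator
#'   (`fw_conv_op(wave$kernel, grid)`) to avoid rebuilding it per step.
#' @return dispersion field on the grid (zero outside the cutoff region).
#' @export
sigma_continuum <- function(t, u, grid, wave, N,
                            delta = 0.1 * max(wave$u_hat_x), conv = NULL) {
  stopifnot(inherits(wave, "wave_profile"))
  if (wave$c <= 1e-8)   # standing waves: the expansion breaks down
    stop("continuum dispersion requires a strictly positive wave speed")
  F <- wave$gain
  ev <- evaluate_wave(wave, grid, t)
  mask <- ev$u_x >= delta
  v <- u - ev$u
  Fp <- gain_eval(F, ev$u, 1L)
  Fpp <- gain_eval(F, ev$u, 2L)
  if (is.null(conv)) conv <- fw_conv_op(wave$kernel, grid)
  convv <- conv$apply(Fp * v, 0, 0)
  sig <- numeric(length(grid))
  i <- which(mask)
  cux <- wave$c * ev$u_x[i]
  rt <- sqrt(cux * Fp[i])
  gamma_c <- 1 / (2 * rt)
  alpha <- sqrt(cux / Fp[i])
  beta <- gamma_c * (-(Fpp[i] / Fp[i]) * cux + 1)
  sig[i] <- (alpha + beta * v[i] - gamma_c * convv[i]) / sqrt(N)
  sig
}

#' Euler-Maruyama integration of the stochastic neural field equation
#'
#' Integrates
#' \deqn{du_t = \Big(-u_t + w * F(u_t) + \frac{1}{2N}
#'   \frac{F''(u^{TW}_t)}{F'(u^{TW}_t)^2}\,\partial_t u^{TW}_t\Big)dt
#'   + \sigma(t, u_t)\, dW^Q_t}
#' on a uniform grid, with the field clamped to the asymptotic levels
#' \eqn{a_1, a_2} outside the window (the deviation \eqn{u - u^{TW}} is
#' square integrable, so the wave sits far from the boundary by
#' construction), FFT-free dense convolution, and Q-Wiener increments from
#' a [noise_model()] on the same grid. With the noise off and the 1/(2N)
#' correction dropped this reduces to an explicit integrator for the
#' deterministic field equation, for which the traveling wave is an exact
#' solution.
#'
#' @param u0 initial field on `grid` (default: the wave at t = 0).
#' @param grid uniform spatial grid.
#' @param wave traveling wave (supplies gain, kernel, asymptotics).
#' @param noise a [noise_model()] on the same grid (may be `NULL` when
#'   `noise_on = FALSE`).
#' @param N population size.
#' @param T horizon, `dt` step.
#' @param delta cutoff for the dispersion.
#' @param seed optional seed.
#' @param noise_on set `FALSE` for the deterministic drift flow.
#' @param correction_on include the 1/(2N) Ito-correction drift term.
#' @param save_every record every so many steps.
#' @param increments optional pre-drawn Q-Wiener increments (grid x nstep
#'   matrix), used to couple several systems to one noise realization.
#' @return list with `times`, `u` (times x grid matrix), `grid`.
#' @export
integrate_spde <- function(u0 = NULL, grid, wave, noise = NULL, N, T, dt,
                           delta = 0.1 * max(wave$u_hat_x), seed = NULL,
                           noise_on = TRUE, correction_on = TRUE,
                           save_every = 1L, increments = NULL) {
  stopifnot(inherits(wave, "wave_profile"))
  if (!is.null(seed)) set.seed(seed)
  F <- wave$gain
  if (is.null(u0)) u0 <- evaluate_wave(wave, grid, 0)$u
  stopifnot(length(u0) == length(grid))
  if (noise_on && is.null(increments))
    stopifnot(inherits(noise, "noise_model"),
              isTRUE(all.equal(noise$grid, grid)))
  cv <- fw_conv_op(wave$kernel, grid)
  Fa1 <- gain_eval(F, wave$a1); Fa2 <- gain_eval(F, wave$a2)
  nstep <- ceiling(T / dt - 1e-9)
  u <- u0
  isave <- unique(c(seq(0L, nstep, by = save_every), nstep))
  out <- matrix(NA_real_, length(isave), length(grid))
  out[1L, ] <- u
  row <- 2L
  for (s in seq_len(nstep)) {
    t <- (s - 1L) * dt
    drift <- -u + cv$apply(gain_eval(F, u), Fa1, Fa2)
    if (correction_on) {
      ev <- evaluate_wave(wave, grid, t)
      drift <- drift + (gain_eval(F, ev$u, 2L) / gain_eval(F, ev$u, 1L)^2) *
        ev$u_t / (2 * N)
    }
    if (noise_on) {
      sig <- sigma_continuum(t, u, grid, wave, N, delta, conv = cv)
      dW <- if (is.null(increments)) sample_qwiener_increment(noise, dt)
            else increments[, s]
      u <- u + dt * drift + sig * dW
    } else {
      u <- u + dt * drift
    }
    if (s %in% isave) { out[row, ] <- u; row <- row + 1L }
  }
  list(times = isave * dt, u = out, grid = grid, N = N, dt = dt)
}
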