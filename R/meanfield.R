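#' Mean-field drift of the activity network
#'
#' Right-hand side of the infinite-population limit of the activity Markov
#' chain: for activities \eqn{x \in (0,1)^P},
#' \deqn{\dot x_k = F'(F^{-1}(x_k))\Big(-F^{-1}(x_k) + \sum_j w_{kj} x_j\Big).}
#' Under the substitution \eqn{u = F^{-1}(x)} this is the voltage-based
#' network equation \eqn{\dot u_k = -u_k + \sum_j w_{kj} F(u_j)}.
#'
#' @param x activity vector, all entries in (0, 1).
#' @param W P x P weight matrix (e.g. the `W` of a [discretize_weights()]
#'   geometry).
#' @param F a [logistic_gain()] object.
#' @return drift vector of length P.
#' @export
meanfield_rhs <- function(x, W, F) {
  if (any(x <= 0 | x >= 1))
    stop("mean-field drift undefined at the boundary of [0,1]^P")
  u <- gain_inverse(F, x)
  gain_eval(F, u, 1L) * (-u + as.vector(W %*% x))
}

#' Integrate the mean-field activity ODE
#'
#' Solves the deterministic limit dynamics with `deSolve::ode` (lsoda) at
#' tight tolerances; this trajectory is the N -> infinity oracle against
#' which the stochastic simulation algorithm is compared in the law of
#' large numbers experiment.
#'
#' @param x0 interior initial activities.
#' @param W weight matrix.
#' @param F gain function.
#' @param times output times (first entry is the initial time).
#' @param rtol,atol solver tolerances.
#' @return matrix (length(times) x P) of activities; attribute `times`.
#' @export
integrate_meanfield <- function(x0, W, F, times, rtol = 1e-8, atol = 1e-10) {
  stopifnot(all(x0 > 0 & x0 < 1))
  sol <- deSolve::ode(y = x0, times = times,
                      func = function(t, y, parms) {
                        if (any(y <= 0 | y >= 1))
                          stop("mean-field trajectory left (0,1)^P")
                        list(meanfield_rhs(y, W, F))
                      },
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  out <- unname(sol[, -1L, drop = FALSE])
  attr(out, "times") <- times
  out
}

#' Lattice drift around the traveling wave (with boundary input)
#'
#' The voltage drift of the spatially extended network on \eqn{[-L, L]}:
#' \deqn{\hat b^m_k(t,u) = -u_k + \sum_l w^m_{kl} F(u_l)
#'   + w^{m,+}_k F(u^{TW}_t(L)) + w^{m,-}_k F(u^{TW}_t(-L)),}
#' where the boundary terms feed in the analytic wave so that the finite
#' window behaves like a section of the full line.
#'
#' @param t time.
#' @param u voltage vector on the lattice (length P).
#' @param g a [discretize_weights()] geometry.
#' @param F gain function.
#' @param wave a [solve_wave()] profile supplying the boundary values.
#' @return drift vector \eqn{\hat b^m(t, u)}.
#' @export
drift_bm <- function(t, u, g, F, wave) {
  stopifnot(inherits(g, "network_geometry"), length(u) == g$P)
  bL <- evaluate_wave(wave, -g$L, t)$u
  bR <- evaluate_wave(wave, g$L, t)$u
  -u + as.vector(g$W %*% gain_eval(F, u)) +
    g$w_plus * gain_eval(F, bR) + g$w_minus * gain_eval(F, bL)
}

#' Method-of-lines reference integrator for the continuum field equation
#'
#' Integrates \eqn{\partial_t u = -u + w * F(u)} on a uniform grid, with
#' the field clamped to constants outside the computational window (tail
#' contributions of the convolution are exact for constant tails). Used as
#' the independent front-speed oracle for the traveling-wave solver: since
#' the right-hand side contains no spatial derivative, the only spatial
#' error is convolution quadrature.
#'
#' @param u0 initial field values on `grid`.
#' @param F gain function.
#' @param w synaptic kernel.
#' @param grid uniform spatial grid.
#' @param times output times.
#' @param left,right constant clamp values outside the window (default:
#'   the initial end values).
#' @param rtol,atol `deSolve` tolerances.
#' @return matrix (length(times) x length(grid)); attributes `times`, `grid`.
#' @export
continuum_nfe_integrate <- function(u0, F, w, grid, times,
                                    left = u0[1L], right = u0[length(u0)],
                                    rtol = 1e-10, atol = 1e-12) {
  stopifnot(length(u0) == length(grid))
  cv <- fw_conv_op(w, grid)
  FL <- gain_eval(F, left); FR <- gain_eval(F, right)
  sol <- deSolve::ode(y = u0, times = times,
                      func = function(t, y, parms)
                        list(-y + cv$apply(gain_eval(F, y), FL, FR)),
                      parms = NULL, method = "lsoda",
                      rtol = rtol, atol = atol)
  out <- unname(sol[, -1L, drop = FALSE])
  attr(out, "times") <- times
  attr(out, "grid") <- grid
  out
}
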