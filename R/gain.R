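#' Logistic gain function
#'
#' Constructs the sigmoid gain function
#' \deqn{F(x) = \frac{1}{1 + e^{-\gamma(x-\kappa)}}}
#' mapping the average membrane potential of a population to its activity
#' (the probability that a neuron is in the process of firing an action
#' potential). The bistable regime requires that \eqn{F(x) - x} has exactly
#' three zeros \eqn{0 < a_1 < a < a_2 < 1}, with the outer two stable
#' (\eqn{F'(a_1), F'(a_2) < 1}) and the middle one unstable (\eqn{F'(a) > 1}).
#' These fixed points organize the front dynamics: the traveling wave
#' connects \eqn{a_1} to \eqn{a_2}.
#'
#' @param gamma positive slope (gain) parameter.
#' @param kappa threshold, in (0, 1).
#' @param validate if `TRUE` (default), locate the fixed points at
#'   construction and fail if the bistability conditions are violated.
#' @return an object of class `gain_function` with fields `gamma`, `kappa`
#'   and (when validation succeeds) the cached fixed points `a1`, `a`, `a2`.
#' @examples
#' F <- logistic_gain(8, 0.5)
#' F$a            # middle (unstable) fixed point, 0.5 by symmetry
#' gain_eval(F, 0.5, order = 1)  # gamma/4 at the threshold
#' @export
logistic_gain <- function(gamma, kappa, validate = TRUE) {
  stopifnot(is.numeric(gamma), length(gamma) == 1L, gamma > 0,
            is.numeric(kappa), length(kappa) == 1L, kappa > 0, kappa < 1)
  F <- structure(list(gamma = gamma, kappa = kappa,
                      a1 = NA_real_, a = NA_real_, a2 = NA_real_),
                 class = "gain_function")
  if (validate) {
    fp <- gain_fixed_points(F)
    F$a1 <- fp$roots[1L]; F$a <- fp$roots[2L]; F$a2 <- fp$roots[3L]
  }
  F
}

#' @export
print.gain_function <- function(x, ...) {
  cat(sprintf("Logistic gain: gamma = %g, kappa = %g\n", x$gamma, x$kappa))
  if (!is.na(x$a1))
    cat(sprintf("  fixed points: a1 = %.10f, a = %.10f, a2 = %.10f\n",
                x$a1, x$a, x$a2))
  invisible(x)
}

#' Evaluate the gain function or one of its derivatives
#'
#' Closed-form logistic derivatives: with \eqn{s = F(x)},
#' \eqn{F' = \gamma s(1-s)}, \eqn{F'' = \gamma^2 s(1-s)(1-2s)},
#' \eqn{F''' = \gamma^3 s(1-s)(1 - 6s + 6s^2)}. All four orders are bounded
#' on the real line, as the model requires.
#'
#' @param F a [logistic_gain()] object.
#' @param x numeric vector of potentials.
#' @param order derivative order, one of 0, 1, 2, 3.
#' @return numeric vector of the same length as `x`.
#' @export
gain_eval <- function(F, x, order = 0L) {
  stopifnot(inherits(F, "gain_function"))
  if (!(length(order) == 1L && order %in% 0:3))
    stop("`order` must be one of 0, 1, 2, 3")
  s <- stats::plogis(F$gamma * (x - F$kappa))
  g <- F$gamma
  switch(as.character(order),
         "0" = s,
         "1" = g * s * (1 - s),
         "2" = g^2 * s * (1 - s) * (1 - 2 * s),
         "3" = g^3 * s * (1 - s) * (1 - 6 * s + 6 * s^2))
}

#' Inverse of the logistic gain (closed-form logit)
#'
#' Returns the potential \eqn{x} with \eqn{F(x) = y}:
#' \eqn{F^{-1}(y) = \kappa + \log(y/(1-y))/\gamma}. The inverse appears in
#' the jump rates of the activity Markov chain, where \eqn{F^{-1}(x_i)}
#' plays the role of the potential sustaining activity level \eqn{x_i}.
#'
#' @param F a [logistic_gain()] object.
#' @param y numeric vector of activities, each in (0, 1).
#' @return numeric vector of potentials.
#' @export
gain_inverse <- function(F, y) {
  stopifnot(inherits(F, "gain_function"))
  if (any(y <= 0 | y >= 1)) stop("gain_inverse requires y in (0, 1)")
  F$kappa + stats::qlogis(y) / F$gamma
}

#' Locate the fixed points of F(x) - x
#'
#' Dense sign-change scan of \eqn{F(x) - x} on \eqn{[-0.5, 1.5]} (step 1e-4)
#' followed by bracketed root refinement to tolerance 1e-12. The bistability
#' assumption demands exactly three roots; any other count aborts with an
#' error naming the violated condition.
#'
#' @param F a [logistic_gain()] object (validation may be pending).
#' @param tol root-finding tolerance.
#' @return list with `roots` (increasing), `stable` (logical, from
#'   \eqn{F' < 1} at each root) and `fprime` (derivative values at roots).
#' @export
gain_fixed_points <- function(F, tol = 1e-12) {
  stopifnot(inherits(F, "gain_function"))
  f <- function(x) gain_eval(F, x) - x
  xs <- seq(-0.5, 1.5, by = 1e-4)
  fx <- f(xs)
  # treat exact zeros on the grid as their own roots to avoid double counting
  zero <- which(fx == 0)
  sgn <- sign(fx)
  cross <- which(sgn[-1L] * sgn[-length(sgn)] < 0)
  roots <- c(xs[zero],
             vapply(cross, function(i)
               stats::uniroot(f, c(xs[i], xs[i + 1L]), tol = tol)$root,
               numeric(1)))
  roots <- sort(unique(roots))
  if (length(roots) != 3L)
    stop(sprintf(paste0("bistability condition (ii) violated: F(x) - x has %d",
                        " zero(s) on the scan grid, 3 required"),
         length(roots)), call. = FALSE)
  fp <- gain_eval(F, roots, order = 1L)
  ok <- fp[1L] < 1 && fp[3L] < 1 && fp[2L] > 1 &&
    roots[1L] > 0 && roots[3L] < 1
  if (!ok)
    stop("stability condition (iv) violated at the fixed points", call. = FALSE)
  list(roots = roots, stable = fp < 1, fprime = fp)
}
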