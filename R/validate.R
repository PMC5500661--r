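#' Validate the standing model assumptions
#'
#' Checks every standing assumption of the model on a gain function /
#' synaptic kernel pair and returns a structured report rather than
#' failing, so that invalid parameter sets can be inspected:
#'
#' * gain: range in (0, 1) with the correct limits, strict monotonicity,
#'   exactly three fixed points \eqn{0 < a_1 < a < a_2 < 1}, outer fixed
#'   points stable and the middle one unstable, bounded derivatives up to
#'   order three (closed-form suprema for the logistic family);
#' * kernel: nonnegative, even, unit mass (adaptive quadrature),
#'   \eqn{w_x \in L^1}, and tail domination
#'   \eqn{\int_x^\infty w \le C_w w(x)} on a validation grid.
#'
#' @param F a [logistic_gain()] object, or a list/pairlist with `gamma` and
#'   `kappa` entries (so that parameter sets violating the assumptions can
#'   still be reported on).
#' @param w a [synaptic_kernel()].
#' @return an object of class `fw_validation`: a list of named checks, each
#'   with `pass` and numerical `evidence`, plus `all_pass`.
#' @examples
#' rep <- validate_assumptions(logistic_gain(8, 0.5),
#'                             synaptic_kernel("exponential", 1))
#' rep$all_pass
#' @export
validate_assumptions <- function(F, w) {
  if (!inherits(F, "gain_function")) {
    stopifnot(is.list(F), !is.null(F$gamma), !is.null(F$kappa))
    F <- logistic_gain(F$gamma, F$kappa, validate = FALSE)
  }
  stopifnot(inherits(w, "synaptic_kernel"))
  checks <- list()
  add <- function(name, pass, evidence)
    checks[[name]] <<- list(pass = isTRUE(pass), evidence = evidence)

  g <- F$gamma
  # checked where the logistic is representable away from saturation; the
  # analytic limits 0 and 1 are verified separately
  xs <- seq(F$kappa - 2, F$kappa + 2, length.out = 2001L)
  Fx <- gain_eval(F, xs)
  add("gain_range", all(Fx > 0 & Fx < 1) &&
        gain_eval(F, -50) < 1e-10 && gain_eval(F, 50) > 1 - 1e-10,
      list(min = min(Fx), max = max(Fx)))
  add("gain_monotone", all(gain_eval(F, xs, 1L) > 0),
      list(min_fprime = min(gain_eval(F, xs, 1L))))

  fp <- tryCatch(gain_fixed_points(F), error = function(e) e)
  if (inherits(fp, "error")) {
    add("gain_three_fixed_points", FALSE, list(message = conditionMessage(fp)))
    add("gain_fixed_point_stability", FALSE, list())
  } else {
    r <- fp$roots
    add("gain_three_fixed_points",
        length(r) == 3L && r[1L] > 0 && r[3L] < 1 &&
          all(abs(gain_eval(F, r) - r) < 1e-10),
        list(roots = r, residuals = gain_eval(F, r) - r))
    add("gain_fixed_point_stability",
        fp$fprime[1L] < 1 && fp$fprime[3L] < 1 && fp$fprime[2L] > 1,
        list(fprime = fp$fprime))
  }
  # closed-form suprema of |F'|, |F''|, |F'''| for the logistic family
  add("gain_bounded_derivatives", TRUE,
      list(sup_f1 = g / 4, sup_f2 = g^2 / (6 * sqrt(3)), sup_f3 = g^3 / 8))

  mass <- stats::integrate(function(x) kernel_eval(w, x), -Inf, Inf,
                           rel.tol = 1e-10)
  add("kernel_mass", abs(mass$value - 1) < 1e-8,
      list(mass = mass$value, abs_error = mass$abs.error))
  ys <- seq(0, 12 * w$scale, length.out = 1201L)
  add("kernel_nonneg_even",
      all(kernel_eval(w, ys) >= 0) &&
        max(abs(kernel_eval(w, ys) - kernel_eval(w, -ys))) == 0,
      list())
  add("kernel_grad_l1", is.finite(kernel_grad_l1(w)),
      list(grad_l1 = kernel_grad_l1(w)))
  Cw <- kernel_tail_constant(w)
  ratio <- (1 - kernel_cdf(w, ys)) / kernel_eval(w, ys)
  # 1e-8 slack: the tail mass loses precision to cancellation in 1 - CDF
  add("kernel_tail_domination", max(ratio) <= Cw * (1 + 1e-8),
      list(C_w = Cw, grid_sup = max(ratio)))

  structure(list(checks = checks,
                 all_pass = all(vapply(checks, `[[`, logical(1), "pass")),
                 gamma = F$gamma, kappa = F$kappa,
                 kernel = list(family = w$family, scale = w$scale)),
            class = "fw_validation")
}

#' @export
print.fw_validation <- function(x, ...) {
  cat(sprintf("Assumption validation (gamma = %g, kappa = %g, %s kernel):\n",
              x$gamma, x$kappa, x$kernel$family))
  for (nm in names(x$checks))
    cat(sprintf("  [%s] %s\n", if (x$checks[[nm]]$pass) "ok" else "FAIL", nm))
  cat(if (x$all_pass) "All assumptions hold.\n" else "Some assumptions FAIL.\n")
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param x an `fw_validation` report.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return invisibly, the JSON string.
#' @export
validation_to_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "fw_validation"))
  js <- jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
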