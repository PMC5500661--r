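test_that("jump rates vanish in balance and never push both ways", {
  fx <- sym_fixture()
  g <- lln_geometry()
  F <- fx$F
  # balanced state: x = F(u) with u the self-consistent input is a fixed
  # point of the rate imbalance; the homogeneous a2 state with weights
  # renormalized to row sums 1 is exactly balanced
  W1 <- g$W / rowSums(g$W)
  xb <- rep(F$a2, g$P)
  r <- jump_rates(xb, W1, F, N = 100)
  expect_equal(r$up, rep(0, g$P))
  expect_equal(r$down, rep(0, g$P))
  # complementarity everywhere
  set.seed(11)
  for (i in 1:20) {
    x <- stats::runif(g$P, 0.05, 0.95)
    r <- jump_rates(x, g$W, F, N = 57)
    expect_true(all(r$up * r$down == 0))
    expect_true(all(r$up >= 0 & r$down >= 0))
  }
})

test_that("single-population rates match an independent transcription", {
  F <- logistic_gain(8, 0.5)
  W <- matrix(1, 1, 1)
  N <- 200
  x <- 0.01   # below a1: input x exceeds the sustaining potential
  r <- jump_rates(x, W, F, N)
  # independent second implementation of the same formula
  u <- 0.5 + log(x / (1 - x)) / 8
  fp <- 8 * (1 / (1 + exp(-8 * (u - 0.5)))) * (1 - 1 / (1 + exp(-8 * (u - 0.5))))
  expect_gt(x - u, 0)
  expect_equal(r$up, N * fp * (x - u), tolerance = 1e-12)
  expect_equal(r$down, 0)
})

test_that("saturated coordinates have zero rates; interior threshold is correct", {
  F <- logistic_gain(8, 0.5)
  W <- diag(2)
  r <- jump_rates(c(0, 1), W, F, N = 100)
  expect_equal(c(r$up, r$down), rep(0, 4))
  N0 <- interior_threshold(F)
  expect_identical(N0, 56L)
  # at N0 the boundary-adjacent rates vanish for any input in [0, 1]
  expect_gte(gain_inverse(F, 1 - 1 / N0), 1)
  expect_lte(gain_inverse(F, 1 / N0), 0)
  expect_lt(gain_inverse(F, 1 - 1 / (N0 - 1)), 1)
})

test_that("tilde rates keep jumping at a balanced high-activity state", {
  F <- logistic_gain(8, 0.5)
  # worked 2-population state at the high-activity fixed point
  W <- matrix(0.5, 2, 2)
  x <- rep(F$a2, 2)            # balance: F(sum w x) = F(a2) = a2 = x
  rp <- jump_rates(x, W, F, N = 100, variant = "balance")
  rt <- jump_rates(x, W, F, N = 100, variant = "classical")
  expect_equal(sum(rp$up) + sum(rp$down), 0)
  expect_equal(rt$up, rep(100 * F$a2, 2))
  expect_equal(rt$down, rep(100 * F$a2, 2))
  expect_gt(sum(rt$up) + sum(rt$down), 0)
})

test_that("SSA trajectories are reproducible, single-jump, and stay interior", {
  fx <- sym_fixture()
  g <- lln_geometry()
  x0 <- lln_x0()
  sp1 <- simulate_ssa(x0, g$W, fx$F, N = 200, T = 1, seed = 5,
                      record_path = TRUE)
  sp2 <- simulate_ssa(x0, g$W, fx$F, N = 200, T = 1, seed = 5,
                      record_path = TRUE)
  expect_identical(sp1$states, sp2$states)
  expect_identical(sp1$path$time, sp2$path$time)
  expect_true(all(diff(sp1$path$time) > 0))
  # single-jump structure on the recorded grid: activities on the 1/N grid
  expect_true(all(abs(sp1$states * 200 - round(sp1$states * 200)) < 1e-9))
  # interior invariance across an ensemble (N = 200 >= N0 = 56)
  for (r in 1:25) {
    sp <- simulate_ssa(x0, g$W, fx$F, N = 200, T = 1, seed = 100 + r)
    expect_true(all(sp$states > 0 & sp$states < 1))
  }
  # a lattice state in exact balance has zero total rate and never jumps:
  # the middle fixed point a = 1/2 lies on the 1/N grid for even N, and
  # row-stochastic weights make the input equal F^{-1}(1/2) exactly
  W1 <- g$W / rowSums(g$W)
  spf <- simulate_ssa(rep(0.5, g$P), W1, fx$F, N = 200, T = 1, seed = 1)
  expect_identical(spf$n_jumps, 0L)
  expect_true(all(spf$states == 0.5))
})

test_that("first-jump times follow the exponential law at the initial rates", {
  F <- logistic_gain(8, 0.5)
  W <- matrix(1, 1, 1)
  x0 <- 0.1
  r <- jump_rates(x0, W, F, N = 50)
  total <- sum(r$up) + sum(r$down)
  set.seed(99)
  n <- 4000L
  first <- vapply(seq_len(n), function(i) {
    sp <- simulate_ssa(x0, W, F, N = 50, T = 50, seed = 2000 + i,
                       record_path = TRUE, eval_times = c(0, 50))
    sp$path$time[1L]
  }, numeric(1))
  expect_equal(mean(first), 1 / total,
               tolerance = 3 * (1 / total) / sqrt(n) / (1 / total))
})

test_that("generator on projections telescopes to the drift and converges", {
  fx <- sym_fixture()
  g <- lln_geometry()
  F <- fx$F
  x <- lln_x0()
  x <- round(x * 1000) / 1000
  # constant functions are annihilated
  expect_equal(generator_apply(function(z) 1, x, g$W, F, N = 1000), 0)
  # coordinate projection: exact telescoping to the drift
  k <- 8L
  gen <- generator_apply(function(z) z[k], x, g$W, F, N = 1000)
  expect_equal(gen, meanfield_rhs(x, g$W, F)[k], tolerance = 1e-10)
  # smooth f: relative error of the generator against the transport limit
  # decays like 1/N
  f <- function(z) sum(sin(z))
  lim <- sum(cos(x) * meanfield_rhs(x, g$W, F))
  errs <- vapply(c(100, 1000, 10000), function(N) {
    xg <- round(x * N) / N
    abs(generator_apply(f, xg, g$W, F, N) -
          sum(cos(xg) * meanfield_rhs(xg, g$W, F)))
  }, numeric(1))
  expect_lt(errs[3L], errs[1L] / 20)
  expect_lt(abs(generator_apply(f, x, g$W, F, 10000) - lim), 1e-3)
})

test_that("martingale decomposition: zero mean, bracket-matched variance, cross independence", {
  fx <- sym_fixture()
  g <- lln_geometry()
  x0 <- lln_x0()
  N <- 400L
  n_rep <- 300L
  T <- 1
  Ms <- matrix(NA_real_, n_rep, g$P)
  Bk <- matrix(NA_real_, n_rep, g$P)
  for (r in seq_len(n_rep)) {
    sp <- simulate_ssa(x0, g$W, fx$F, N, T, eval_times = c(0, T),
                       seed = 7000 + r)
    Ms[r, ] <- sp$martingale[2L, ]
    Bk[r, ] <- sp$bracket[2L, ]
  }
  se <- sqrt(apply(Ms, 2L, stats::var) / n_rep)
  expect_true(all(abs(colMeans(Ms)) < 3.5 * se))
  # empirical variance of sqrt(N) M matches N times the mean bracket
  ratio <- sum(apply(sqrt(N) * Ms, 2L, stats::var)) /
    sum(N * colMeans(Bk))
  expect_gt(ratio, 0.85); expect_lt(ratio, 1.15)
  # representative cross-population covariances consistent with zero
  cv <- stats::cov(Ms)
  v <- diag(cv)
  for (pr in list(c(1L, 2L), c(8L, 9L), c(1L, 16L))) {
    sehat <- sqrt((v[pr[1L]] * v[pr[2L]] + cv[pr[1L], pr[2L]]^2) /
                    (n_rep - 1))
    expect_lt(abs(cv[pr[1L], pr[2L]]), 3 * sehat)
  }
})

test_that("path-based decomposition agrees with the in-simulation accumulators", {
  fx <- sym_fixture()
  g <- lln_geometry()
  x0 <- lln_x0()
  tt <- seq(0, 0.5, length.out = 9L)
  sp <- simulate_ssa(x0, g$W, fx$F, N = 100, T = 0.5, eval_times = tt,
                     seed = 31, record_path = TRUE)
  md <- martingale_decompose(sp, g$W, fx$F, tt)
  expect_equal(md$martingale, sp$martingale, tolerance = 1e-10)
  expect_equal(md$bracket, sp$bracket, tolerance = 1e-10)
  expect_equal(sp$martingale[1L, ], rep(0, g$P))
  expect_true(all(diff(sp$bracket[, 3L]) >= 0))
})
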