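test_that("cutoff coefficients vanish off the front and are N-free", {
  p <- asym_wave()
  fx <- asym_fixture()
  g <- discretize_weights(fx$w, 8L, 4)
  co <- diffusion_coefficients_m(0.2, g, p)
  expect_true(all(co$alpha[!co$mask] == 0))
  expect_true(all(co$beta[!co$mask] == 0))
  expect_true(all(co$gamma_c[!co$mask] == 0))
  expect_true(all(co$alpha[co$mask] > 0))
  # positivity of -b on the cutoff set (reported, not assumed)
  expect_true(all(co$minus_b[co$mask] > 0))
  # N enters only through the 1/sqrt(N) prefactor of the dispersion
  u <- evaluate_wave(p, g$positions, 0.2)$u + 0.01
  s1 <- sigma_m_apply(0.2, u, co, g, p, N = 100)
  s2 <- sigma_m_apply(0.2, u, co, g, p, N = 400)
  expect_equal(s1, 2 * s2, tolerance = 1e-12)
})

test_that("standing waves are rejected by the diffusion approximation", {
  ps <- sym_wave()
  fx <- sym_fixture()
  g <- discretize_weights(fx$w, 4L, 4)
  expect_error(diffusion_coefficients_m(0, g, ps), "positive wave speed")
  h <- 1 / 64
  grid <- seq(-4, 4 - h, by = h)
  expect_error(sigma_continuum(0, evaluate_wave(ps, grid, 0)$u, grid, ps,
                               N = 100), "positive wave speed")
})

test_that("lattice coefficients converge to the continuum expressions", {
  p <- asym_wave()
  fx <- asym_fixture()
  errs <- vapply(c(8L, 16L, 32L), function(m) {
    g <- discretize_weights(fx$w, m, 4)
    co <- diffusion_coefficients_m(0, g, p)
    ev <- evaluate_wave(p, g$positions, 0)
    i <- which(co$mask)
    Fp <- gain_eval(fx$F, ev$u[i], 1L)
    alpha_cont <- sqrt(p$c * ev$u_x[i] / Fp)
    max(abs(co$alpha[i] - alpha_cont))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3L], 0.015)
})

test_that("dispersion at the wave is additive and Lipschitz in the field", {
  p <- asym_wave()
  fx <- asym_fixture()
  g <- discretize_weights(fx$w, 8L, 4)
  t <- 0.1
  co <- diffusion_coefficients_m(t, g, p)
  uw <- evaluate_wave(p, g$positions, t)$u
  sig <- sigma_m_apply(t, uw, co, g, p, N = 100)
  expect_equal(sig, co$alpha / sqrt(100), tolerance = 1e-12)
  # empirical Lipschitz constant over random pairs, stable in m
  lip <- vapply(c(8L, 16L), function(m) {
    gm <- discretize_weights(fx$w, m, 4)
    com <- diffusion_coefficients_m(t, gm, p)
    uwm <- evaluate_wave(p, gm$positions, t)$u
    set.seed(8)
    max(vapply(1:100, function(i) {
      u1 <- uwm + stats::rnorm(gm$P, sd = 0.05)
      u2 <- uwm + stats::rnorm(gm$P, sd = 0.05)
      s1 <- sigma_m_apply(t, u1, com, gm, p, N = 1)
      s2 <- sigma_m_apply(t, u2, com, gm, p, N = 1)
      sqrt(sum((s1 - s2)^2) / m) / sqrt(sum((u1 - u2)^2) / m)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(is.finite(lip)))
  expect_lt(abs(lip[2L] - lip[1L]) / lip[1L], 0.5)
})

test_that("linearized dispersion matches the square-root coefficient to O(1/N)", {
  p <- asym_wave()
  fx <- asym_fixture()
  g <- discretize_weights(fx$w, 8L, 4)
  t <- 0.1
  co <- diffusion_coefficients_m(t, g, p)
  uw <- evaluate_wave(p, g$positions, t)$u
  # Taylor-remainder oracle: |sqrt(|b(u)|/F'(u)) - sqrt(N) sigma| = O(v^2).
  # Restricted to the core of the front, where the square root is far from
  # its degeneracy; near the cutoff edge the expansion needs much larger N.
  ev <- evaluate_wave(p, g$positions, t)
  core <- which(co$mask & ev$u_x >= 0.5 * max(p$u_hat_x))
  errN <- vapply(c(1e4, 1e6), function(N) {
    set.seed(17)
    v <- stats::rnorm(g$P, sd = 1 / sqrt(N))
    u <- uw + v
    full <- finitewave:::sqrt_sde_sigma(t, u, g, p, N = 1)  # sqrt(|b|/F')
    lin <- sqrt(N) * sigma_m_apply(t, u, co, g, p, N)
    max(abs(full[core] - lin[core]))
  }, numeric(1))
  expect_lt(errN[2L], errN[1L] / 20)   # ~ 1/N decay (factor 100 in N)
})

test_that("the diffusion network drifts at the wave speed as the lattice refines", {
  p <- asym_wave()
  fx <- asym_fixture()
  lev <- p$a
  lattice_speed <- function(m, L) {
    g <- discretize_weights(fx$w, m, L)
    det <- simulate_diffusion_network(g = g, wave = p, N = 1e8, T = 1,
                                      dt = 2e-3, deterministic = TRUE,
                                      save_every = 100L)
    pos <- vapply(seq_along(det$times), function(i)
      front_position(det$u[i, ], g$positions, lev), numeric(1))
    unname(stats::lm.fit(cbind(1, det$times), pos)$coefficients[2L])
  }
  # the left-endpoint cell convention biases the lattice speed by
  # ~ 1/(2m): the bias halves when the density doubles ...
  b16 <- lattice_speed(16L, 3) - p$c
  b32 <- lattice_speed(32L, 3) - p$c
  expect_gt(b16, 0)
  expect_equal(b32 / b16, 0.5, tolerance = 0.15)
  # ... and at m = 64 the deterministic front runs within 5% of c
  expect_lt(abs(lattice_speed(64L, 3) - p$c) / p$c, 0.05)
  # stochastic ensemble at the same density: mean front displacement at
  # the wave speed
  g <- discretize_weights(fx$w, 64L, 3)
  n_rep <- 60L
  posT <- vapply(seq_len(n_rep), function(r) {
    sol <- simulate_diffusion_network(g = g, wave = p, N = 1e4, T = 1,
                                      dt = 2e-3, seed = 400 + r,
                                      save_every = 500L)
    front_position(sol$u[nrow(sol$u), ], g$positions, lev)
  }, numeric(1))
  pos0 <- front_position(evaluate_wave(p, g$positions, 0)$u, g$positions, lev)
  speed <- mean(posT) - pos0
  expect_lt(abs(speed - p$c) / p$c, 0.05)
})

test_that("independent vs quarter-interval-averaged driving changes the increment covariance", {
  p <- asym_wave()
  fx <- asym_fixture()
  g <- discretize_weights(fx$w, 4L, 2)
  h <- 1 / 64
  grid <- seq(-3, 3 - h, by = h)
  eps <- 0.25
  nm <- noise_model(eps, grid)
  # lattice Brownian increments via the averaging map
  set.seed(12)
  dW <- sample_qwiener_increment(nm, dt = 1, n = 6000L)
  Wm <- phi_m_project(dW, nm, g$m, g$L)
  emp <- stats::cov(t(Wm))
  # oracle: 4 m^2 int_J int_J' q*q, quadrature on the triangular covariance
  hq <- eps / 100
  half <- 1 / (4 * g$m)
  theor <- function(k, l) {
    y1 <- seq(g$positions[k] - half, g$positions[k] + half, by = hq)
    y2 <- seq(g$positions[l] - half, g$positions[l] + half, by = hq)
    4 * g$m^2 * sum(outer(y1, y2, function(a, b)
      q_convolution(nm, a - b))) * hq^2
  }
  for (pr in list(c(4L, 4L), c(4L, 5L), c(4L, 6L))) {
    th <- theor(pr[1L], pr[2L])
    se <- sqrt((emp[pr[1L], pr[1L]] * emp[pr[2L], pr[2L]] + th^2) / 6000)
    expect_lt(abs(emp[pr[1L], pr[2L]] - th), 4 * se)
  }
  # m = 4 >= 1/(4 eps) = 1: neighboring populations are correlated here
  expect_gt(emp[4L, 5L], 0.5)
})
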