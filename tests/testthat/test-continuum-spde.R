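test_that("sampled increments carry the triangular covariance of the box kernel", {
  h <- 1 / 64
  grid <- seq(-4, 4 - h, by = h)
  eps <- 0.25
  nm <- noise_model(eps, grid)
  expect_true(nm$exact)
  dt <- 0.02
  set.seed(3)
  dW <- sample_qwiener_increment(nm, dt, n = 10000L)
  # point variance dt/(2 eps)
  v <- stats::var(dW[256L, ])
  expect_lt(abs(v - dt / (2 * eps)), 3 * sqrt(2 / 10000) * dt / (2 * eps))
  # lag covariance matches dt * q*q at several lags; zero beyond 2 eps
  for (lag in c(8L, 16L, 24L)) {
    th <- dt * q_convolution(nm, lag * h)
    emp <- mean(dW[256L, ] * dW[256L + lag, ])
    se <- sqrt((v^2 + th^2) / 10000)
    expect_lt(abs(emp - th), 4 * se)
  }
  expect_equal(q_convolution(nm, 2 * eps + 1e-9), 0)
  far <- mean(dW[100L, ] * dW[100L + 40L, ])       # 40 h > 2 eps
  expect_lt(abs(far), 4 * sqrt(v^2 / 10000))
  # interval statistic: Var <1_A, dW> against the double integral of q*q
  A <- abs(grid) <= 2 * eps                         # interval of length 4 eps
  ip <- h * colSums(dW[A, , drop = FALSE])
  yy <- grid[A]
  th2 <- dt * sum(outer(yy, yy, function(a, b) q_convolution(nm, a - b))) *
    h^2
  expect_lt(abs(stats::var(ip) - th2), 3 * sqrt(2 / 10000) * th2)
})

test_that("averaging preserves constants and decorrelates a sparse lattice", {
  h <- 1 / 256
  grid <- seq(-1.5, 1.5 - h, by = h)
  nm <- noise_model(1 / 32, grid)
  cns <- phi_m_project(rep(2.5, length(grid)), nm, m = 4, L = 1)
  expect_equal(cns, rep(2.5, 8L), tolerance = 1e-10)
  # m = 4 < 1/(4 eps) = 8: quarter intervals are farther apart than 2 eps,
  # so the averaged motions are independent
  set.seed(5)
  dW <- sample_qwiener_increment(nm, dt = 1, n = 10000L)
  pr <- phi_m_project(dW, nm, m = 4, L = 1)
  cc <- stats::cor(pr[4L, ], pr[5L, ])
  expect_lt(abs(cc), 3 / sqrt(10000))
})

test_that("the averaged-kernel bound holds and decays like 1/m", {
  vals <- vapply(c(4L, 8L, 16L), function(m) {
    r <- remark_kernel_bound_check(0.25, m)
    expect_true(r$pass)                       # repaired constant 1/(2 eps^2 m)
    expect_equal(r$bound, 1 / (2 * 0.25^2 * m))
    expect_equal(r$bound_printed, 1 / (4 * 0.25^2 * m))
    r$sup_sq
  }, numeric(1))
  expect_lt(vals[2L], vals[1L] / 1.9)
  expect_lt(vals[3L], vals[2L] / 1.9)
})

test_that("continuum dispersion is additive on the wave and Hilbert-Schmidt", {
  p <- asym_wave()
  h <- 1 / 64
  grid <- seq(-6, 6 - h, by = h)
  nm <- noise_model(0.25, grid)
  t <- 0.3
  uw <- evaluate_wave(p, grid, t)$u
  sig <- sigma_continuum(t, uw, grid, p, N = 100)
  ev <- evaluate_wave(p, grid, t)
  mask <- ev$u_x >= 0.1 * max(p$u_hat_x)
  alpha <- sqrt(p$c * ev$u_x[mask] / gain_eval(p$gain, ev$u[mask], 1L))
  expect_equal(sig[mask], alpha / 10, tolerance = 1e-10)
  expect_true(all(sig[!mask] == 0))
  # Hilbert-Schmidt norm: box kernel identity ||sigma||^2 / (2 eps)
  hs <- hilbert_schmidt_norm(sig, nm, grid)
  expect_equal(hs, sum(sig^2) * h / (2 * 0.25), tolerance = 1e-12)
  expect_lte(hs, (1 / (2 * 0.25)) * sum(sig^2) * h + 1e-12)
  expect_equal(hilbert_schmidt_norm(numeric(length(grid)), nm, grid), 0)
  # Lipschitz in the field, stable under grid refinement
  lips <- vapply(c(64L, 128L), function(den) {
    hh <- 1 / den
    gg <- seq(-6, 6 - hh, by = hh)
    cv <- finitewave:::fw_conv_op(p$kernel, gg)
    uwg <- evaluate_wave(p, gg, t)$u
    set.seed(9)
    max(vapply(1:40, function(i) {
      v1 <- stats::rnorm(length(gg), sd = 0.05) * exp(-gg^2 / 8)
      v2 <- stats::rnorm(length(gg), sd = 0.05) * exp(-gg^2 / 8)
      s1 <- sigma_continuum(t, uwg + v1, gg, p, N = 1, conv = cv)
      s2 <- sigma_continuum(t, uwg + v2, gg, p, N = 1, conv = cv)
      sqrt(sum((s1 - s2)^2) * hh) / sqrt(sum((v1 - v2)^2) * hh)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(is.finite(lips)))
  expect_lt(abs(lips[2L] - lips[1L]) / lips[1L], 0.3)
})

test_that("lattice dispersion approaches the continuum one along a test path", {
  p <- asym_wave()
  t <- 0.2
  h <- 1 / 64
  grid <- seq(-6, 6 - h, by = h)
  uref <- evaluate_wave(p, grid, t)$u + 0.05 * exp(-grid^2 / 2)
  sig_cont <- sigma_continuum(t, uref, grid, p, N = 100)
  errs <- vapply(c(4L, 8L, 16L), function(m) {
    g <- discretize_weights(p$kernel, m, 4)
    co <- diffusion_coefficients_m(t, g, p)
    # restrict the test path to the lattice window, lattice-sample it
    idx <- findInterval(g$positions, grid)
    um <- uref[idx]
    sg <- sigma_m_apply(t, um, co, g, p, N = 100)
    # compare as piecewise-constant fields on the window
    cell <- findInterval(grid, c(g$positions, g$L))
    inside <- cell >= 1L & cell <= g$P
    sqrt(sum((sg[cell[inside]] - sig_cont[inside])^2) * h)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("without noise the integrator transports the wave exactly", {
  p <- asym_wave()
  h <- 1 / 64
  grid <- seq(-8, 8 - h, by = h)
  sol <- integrate_spde(grid = grid, wave = p, noise = NULL, N = 100,
                        T = 1, dt = 1e-3, noise_on = FALSE,
                        correction_on = FALSE, save_every = 1000L)
  uT <- sol$u[nrow(sol$u), ]
  expect_lt(max(abs(uT - evaluate_wave(p, grid, 1)$u)), 5e-4)
})

test_that("deviation moments stay bounded and reproducible across seeds", {
  p <- asym_wave()
  h <- 1 / 64
  grid <- seq(-6, 6 - h, by = h)
  nm <- noise_model(0.25, grid)
  dev2 <- vapply(1:40, function(r) {
    sol <- integrate_spde(grid = grid, wave = p, noise = nm, N = 1000,
                          T = 0.5, dt = 5e-3, seed = 600 + r,
                          save_every = 20L)
    max(vapply(seq_along(sol$times), function(i)
      sum((sol$u[i, ] - evaluate_wave(p, grid, sol$times[i])$u)^2) * h,
      numeric(1)))
  }, numeric(1))
  expect_true(all(is.finite(dev2)))
  expect_lt(mean(dev2), 0.05)
  s1 <- integrate_spde(grid = grid, wave = p, noise = nm, N = 1000,
                       T = 0.1, dt = 5e-3, seed = 1)
  s2 <- integrate_spde(grid = grid, wave = p, noise = nm, N = 1000,
                       T = 0.1, dt = 5e-3, seed = 1)
  expect_identical(s1$u, s2$u)
})

test_that("matched-noise coupling reuses one realization across systems", {
  p <- asym_wave()
  r <- run_continuum_experiment(p, m_levels = c(4L, 8L), L_m = c(2, 3),
                                N = 100, T = 0.1, dt = 2e-3, L_dom = 5,
                                n_rep = 3L, seed = 2)
  expect_true(all(is.finite(r$errors)))
  expect_lt(r$errors[2L], r$errors[1L])
  r2 <- run_continuum_experiment(p, m_levels = c(4L, 8L), L_m = c(2, 3),
                                 N = 100, T = 0.1, dt = 2e-3, L_dom = 5,
                                 n_rep = 3L, seed = 2)
  expect_identical(r$errors, r2$errors)
})
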