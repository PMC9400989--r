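test_that("exchange propagator matches the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  p <- c(0.24, 0.76)
  expect_equal(exchange_propagator(14, p, 0), diag(2))
  Pinf <- exchange_propagator(14, p, 1e6)
  expect_equal(Pinf, matrix(p, 2, 2), tolerance = 1e-12)
  for (tau in c(0, 1e-3, 1e-1, 10))
    expect_equal(colSums(exchange_propagator(14, p, tau)), c(1, 1),
                 tolerance = 1e-12)
  set.seed(21)
  for (i in 1:25) {
    k <- runif(1, 0, 60); p1 <- runif(1, 0.05, 0.95); tau <- runif(1, 0, 0.5)
    P <- exchange_propagator(k, c(p1, 1 - p1), tau)
    K <- rate_matrix(k, c(p1, 1 - p1))
    expect_equal(P, as.matrix(Matrix::expm(K * tau)), tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # frozen cross-site fraction at the cell-suspension operating point
  P <- exchange_propagator(14, p, 0.010)
  cross <- P[2, 1] * p[1] + P[1, 2] * p[2]
  expect_equal(cross, 0.04765812, tolerance = 1e-6)
  expect_error(exchange_propagator(14, p, -1e-3), ">= 0")
})

test_that("diffusion blur is a unit-mass Gaussian convolution with padding", {
  n <- 101; dz <- 2e-6
  v <- rep(3, n)
  expect_identical(diffusion_blur(v, dz, 3.6e-9, 0, pad_value = 0), v)
  expect_equal(diffusion_blur(v, dz, 3.6e-9, 0.05, pad_value = 3), v,
               tolerance = 1e-12)
  # near-delta spike spreads to sd sqrt(2 D tau) = 26.8 um (moment matching)
  spike <- numeric(1001); spike[501] <- 1
  out <- diffusion_blur(spike, 1e-6, 3.6e-9, 0.1, pad_value = 0)
  x <- (seq_along(out) - 501) * 1e-6
  sd_emp <- sqrt(sum(out * x^2) / sum(out))
  expect_equal(sd_emp, 2.683282e-5, tolerance = 1e-3)
  # mass conservation on the periodic extension
  set.seed(4)
  v2 <- runif(64)
  out2 <- diffusion_blur(v2, 2e-6, 2e-9, 0.03, periodic = TRUE)
  expect_equal(sum(out2), sum(v2), tolerance = 1e-9)
  expect_error(diffusion_blur(v, dz, -1e-9, 0.1), ">= 0")
  expect_error(diffusion_blur(v, dz, 1e-9, -0.1), ">= 0")
})

test_that("mixing reduces to its factors in the decoupled limits", {
  scn <- small_scenario()
  samp <- scn$sample
  prof <- encode(samp, scn$encoding, scn$instrument, n_z = 64)
  # tau_M = 0 is the identity
  mix0 <- apply_mixing(prof, samp, 0)
  expect_equal(mix0$profiles$M, prof$M)
  expect_equal(mix0$joint_weights, diag(c(0.24, 0.76)), ignore_attr = TRUE)
  # k = 0, negligible D: profiles unchanged
  frozen <- two_site_sample(list(exchange_site("intra", 1e-30, 0.24),
                                 exchange_site("extra", 2e-30, 0.76)), k = 0)
  proff <- encode(frozen, scn$encoding, scn$instrument, n_z = 64)
  mixf <- apply_mixing(proff, frozen, 0.1, n_substeps = 8)
  expect_equal(mixf$profiles$M, proff$M, tolerance = 1e-9)
  # negligible D: exact pointwise exchange propagator (substeps compose)
  slow <- two_site_sample(list(exchange_site("intra", 1e-30, 0.24),
                               exchange_site("extra", 2e-30, 0.76)), k = 14)
  profs <- encode(slow, scn$encoding, scn$instrument, n_z = 64)
  mixs <- apply_mixing(profs, slow, 0.05, n_substeps = 16)
  P <- exchange_propagator(14, c(0.24, 0.76), 0.05)
  expect_equal(mixs$profiles$M[, 1],
               P[1, 1] * profs$M[, 1] + P[1, 2] * profs$M[, 2],
               tolerance = 1e-10)
  # k = 0: independent blurs per site (substeps compose to one full blur)
  nofx <- two_site_sample(list(exchange_site("intra", 1.4e-9, 0.24),
                               exchange_site("extra", 3.6e-9, 0.76)), k = 0)
  profn <- encode(nofx, scn$encoding, scn$instrument, n_z = 64)
  mixn <- apply_mixing(profn, nofx, 0.05, n_substeps = 8)
  dz <- diff(profn$z_grid[1:2])
  for (j in 1:2) {
    ref <- diffusion_blur(profn$M[, j], dz, c(1.4e-9, 3.6e-9)[j], 0.05,
                          pad_value = profn$pad_values[j])
    expect_equal(mixn$profiles$M[, j], ref, tolerance = 1e-7,
                 ignore_attr = TRUE)
  }
})

test_that("operator splitting self-converges and blurring grows with tau_M", {
  scn <- scenario()
  prof <- encode(scn$sample, scn$encoding, scn$instrument, n_z = 128)
  m32 <- apply_mixing(prof, scn$sample, 0.1, n_substeps = 32)
  m64 <- apply_mixing(prof, scn$sample, 0.1, n_substeps = 64)
  rel <- max(abs(m32$profiles$M - m64$profiles$M)) / max(m64$profiles$M)
  expect_lt(rel, 0.01)
  expect_equal(sum(m32$joint_weights), 1, tolerance = 1e-12)
  # encoded-profile contrast is non-increasing in tau_M
  contrast <- vapply(c(0, 0.01, 0.03, 0.1, 0.3), function(tau) {
    M <- apply_mixing(prof, scn$sample, tau, n_substeps = 16)$profiles$M
    tot <- rowSums(M)
    max(tot) - min(tot)
  }, numeric(1))
  expect_true(all(diff(contrast) <= 1e-12))
})

test_that("two-state jump simulation confirms the propagator cross fraction", {
  set.seed(1234)
  g <- gillespie_cross_fraction(14, 0.24, 0.010, n_particles = 1e5)
  p <- c(0.24, 0.76)
  P <- exchange_propagator(14, p, 0.010)
  cross <- P[2, 1] * p[1] + P[1, 2] * p[2]
  expect_lt(abs(g$mean - cross), 3 * g$se)
})
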