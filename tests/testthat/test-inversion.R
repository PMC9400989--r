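scn <- scenario()

test_that("basis surfaces are well conditioned and site-distinguishable", {
  B <- basis_surfaces(scn$sample, scn$encoding, scn$cpmg, scn$instrument, 0.03)
  expect_equal(B$dim, c(128, 64))
  # Gram-matrix condition number of the four vectorized surfaces
  expect_lt(kappa(crossprod(B$B), exact = TRUE), 1e6)
  for (a in 1:3) for (b in (a + 1):4)
    expect_gt(max(abs(B$B[, a] / sum(B$B[, a]) - B$B[, b] / sum(B$B[, b]))), 1e-6)
  same <- two_site_sample(list(exchange_site("intra", 2e-9, 0.24),
                               exchange_site("extra", 2e-9, 0.76)), k = 14)
  expect_warning(
    basis_surfaces(same, scn$encoding, scn$cpmg, scn$instrument, 0.03),
    "rank deficient")
})

test_that("noiseless linear combinations are recovered to 1e-6", {
  B <- basis_surfaces(scn$sample, scn$encoding, scn$cpmg, scn$instrument, 0.03)
  w_true <- c(0.18, 0.06, 0.06, 0.70)
  S <- matrix(B$B %*% w_true, nrow = 128)
  raw <- raw_data2d(S, depth_grid(scn$encoding, scn$instrument, 128),
                    scn$cpmg$t_E, scn$instrument,
                    provenance = list(tau_M = 0.03))
  m <- fit_map(raw, B)
  expect_equal(as.vector(t(m$w)), w_true, tolerance = 1e-6)
  expect_lt(m$residual, 1e-9)
  # a single basis surface maps to weight one
  raw1 <- raw_data2d(matrix(B$B[, 2], nrow = 128) * 3.3,
                     depth_grid(scn$encoding, scn$instrument, 128),
                     scn$cpmg$t_E, scn$instrument)
  m1 <- fit_map(raw1, B)
  expect_equal(as.vector(t(m1$w)), c(0, 1, 0, 0), tolerance = 1e-8)
  # amplitude invariance: scaling the data leaves the normalized map fixed
  raw_c <- raw; raw_c$S <- raw$S * 7.7
  expect_equal(fit_map(raw_c, B)$w, m$w, tolerance = 1e-10)
})

test_that("degenerate inputs are rejected with diagnostics", {
  B <- basis_surfaces(scn$sample, scn$encoding, scn$cpmg, scn$instrument, 0.03)
  z <- depth_grid(scn$encoding, scn$instrument, 128)
  zero <- raw_data2d(matrix(0, 128, 64), z, scn$cpmg$t_E, scn$instrument)
  expect_error(fit_map(zero, B), "all-zero")
  same <- two_site_sample(list(exchange_site("intra", 2e-9, 0.24),
                               exchange_site("extra", 2e-9, 0.76)), k = 14)
  Bsame <- suppressWarnings(
    basis_surfaces(same, scn$encoding, scn$cpmg, scn$instrument, 0.03))
  raw <- raw_data2d(matrix(Bsame$B[, 1], 128), z, scn$cpmg$t_E, scn$instrument)
  expect_error(fit_map(raw, Bsame, kappa_max = 1e6), "condition number")
  small <- raw_data2d(matrix(1, 10, 10), seq_len(10) * 1e-6, scn$cpmg$t_E,
                      scn$instrument)
  expect_error(fit_map(small, B), "mismatched")
})

test_that("no-exchange data decompose with vanishing cross weights", {
  nofx <- yeast_sample(k = 0)
  scn0 <- scenario(sample = nofx, snr = Inf)
  raw <- simulate_experiment(scn0, 1e-6, seed = 1L)
  B <- basis_surfaces(nofx, scn0$encoding, scn0$cpmg, scn0$instrument, 1e-6)
  m <- fit_map(raw, B)
  expect_lt(m$w[1, 2] + m$w[2, 1], 1e-6)
  expect_equal(unname(m$w[1, 1]), 0.24, tolerance = 0.01)
})

test_that("weights stay within 0.02 of truth at SNR 280 in >=90% of reps", {
  tau <- 0.03
  prof <- encode(scn$sample, scn$encoding, scn$instrument, n_z = 128)
  mix <- apply_mixing(prof, scn$sample, tau, n_substeps = 32)
  noiseless <- simulate_raw(mix, scn$cpmg, scn$instrument, scn$sample)
  B <- basis_surfaces(scn$sample, scn$encoding, scn$cpmg, scn$instrument, tau)
  Q <- mix$joint_weights  # truth: P(tau) %*% diag(p), [end, start]
  truth <- c(Q[1, 1], Q[2, 1], Q[1, 2], Q[2, 2])
  ok <- vapply(1:100, function(r) {
    noisy <- add_noise(noiseless, 280, seed = 4000L + r)
    w <- as.vector(t(fit_map(noisy, B)$w))
    all(abs(w - truth) <= 0.02)
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("exchange maps round-trip through their text format", {
  m1 <- exchange_map(0.01, matrix(c(0.2, 0.05, 0.05, 0.7), 2, byrow = TRUE),
                     residual = 0.3)
  m2 <- exchange_map(0.03, matrix(c(0.15, 0.1, 0.1, 0.65), 2, byrow = TRUE),
                     residual = 0.4)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_maps(list(m1, m2), f)
  back <- read_maps(f)
  expect_length(back, 2)
  expect_equal(back[[1]]$w, m1$w, ignore_attr = TRUE)
  expect_equal(back[[2]]$tau_M, 0.03)
  expect_error(exchange_map(0.01, matrix(c(0.5, 0.2, 0.2, 0.4), 2)), "sum to 1")
})
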