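#' Two-site exchange propagator over an interval
#'
#' Closed-form matrix exponential of the two-site rate matrix: P(tau) =
#' P_inf + exp(-k tau) (I - P_inf), where both columns of P_inf equal the
#' stationary populations. Entry (i, j) is the probability that a molecule
#' starting in site j is in site i after `tau`.
#'
#' @param k overall exchange rate in s^-1.
#' @param p stationary populations (two positive numbers summing to 1).
#' @param tau interval in seconds (nonnegative).
#' @return Column-stochastic 2x2 transition matrix.
#' @export
exchange_propagator <- function(k, p, tau) {
  if (!is_num1(k) || k < 0) stop_domain("k must be >= 0")
  check_populations(p)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop_domain("tau must be >= 0")
  Pinf <- matrix(p, nrow = 2L, ncol = 2L)
  Pinf + exp(-k * tau) * (diag(2) - Pinf)
}

# Spectral application of the free-diffusion propagator on a circular grid:
# multiplies the DFT by exp(-(2 pi f)^2 D tau), the exact Fourier symbol of
# the Gaussian kernel of variance 2 D tau. Exactly mass-conserving and
# exactly composable: blur(dt) applied n times equals blur(n dt).
spectral_blur <- function(values, dz, sigma2) {
  n <- length(values)
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / (n * dz)
  mult <- exp(-0.5 * sigma2 * (2 * pi * f)^2)
  Re(stats::fft(stats::fft(values) * mult, inverse = TRUE)) / n
}

#' Free-diffusion blurring of a depth profile
#'
#' Convolves a profile sampled on a uniform grid with the free-diffusion
#' Gaussian propagator of standard deviation sqrt(2 D tau). Beyond the grid
#' the profile is extended with `pad_value`, modelling in-/outflow of
#' magnetization across the encoding-region boundary. The convolution is
#' evaluated spectrally on a zero-deviation extended grid, so it is exact
#' for any ratio of sqrt(2 D tau) to the grid step.
#'
#' @param values profile samples on a uniform grid.
#' @param dz grid step in metres.
#' @param D diffusion coefficient in m^2 s^-1 (nonnegative).
#' @param tau diffusion interval in seconds (nonnegative).
#' @param pad_value constant extension value outside the grid.
#' @param periodic if `TRUE` blur on the periodic extension of the grid
#'   instead of padding (mass-conserving; used for verification).
#' @return Blurred profile of the same length.
#' @export
diffusion_blur <- function(values, dz, D, tau, pad_value = 0,
                           periodic = FALSE) {
  if (!is_num1(D) || D < 0) stop_domain("D must be >= 0")
  if (!is_num1(tau) || tau < 0) stop_domain("tau must be >= 0")
  if (!is_num1(dz) || dz <= 0) stop_domain("dz must be > 0")
  sigma2 <- 2 * D * tau
  if (sigma2 == 0) return(values)
  if (periodic) return(spectral_blur(values, dz, sigma2))
  n <- length(values)
  m <- blur_margin(sqrt(sigma2), dz)
  ext <- c(rep(0, m), values - pad_value, rep(0, m))
  spectral_blur(ext, dz, sigma2)[(m + 1L):(m + n)] + pad_value
}

# margin (in grid cells) after which the Gaussian tail and the circular
# wrap-around are below ~1e-8 of the deviation amplitude
blur_margin <- function(sigma, dz) max(8L, as.integer(ceiling(6.5 * sigma / dz)))

#' Evolve encoded magnetization through the mixing period
#'
#' Propagates the per-site encoded magnetization through the mixing time by
#' Lie operator splitting between free-diffusion blurring (each joint
#' component with the diffusivity of its current site) and pointwise
#' two-site exchange. In- and outflow across the encoding-region boundary
#' is modelled by decomposing the field into the spatially constant
#' unencoded reservoir (the pad magnetization, which evolves by exchange
#' alone) plus a deviation field that diffuses freely with zero far-field
#' value; free-diffusion kernels compose exactly across substeps, so the
#' boundary model is independent of the substep count and only the
#' blur/exchange commutator limits convergence. The evolution is tracked
#' jointly over (start site, current site) so that the readout can
#' attenuate each fraction with the diffusivity of its post-mixing site.
#'
#' @param profile a `magnetization_profile` from [encode()].
#' @param sample a [two_site_sample()]; supplies k, D and (optionally
#'   finite) T1 values.
#' @param tau_M mixing time in seconds.
#' @param n_substeps number of splitting substeps (>= 1).
#' @param pad_decay if `TRUE`, the unencoded pad magnetization decays with
#'   the site T1 over the elapsed mixing time; default keeps it constant.
#' @return An object of class `mixing_result` with fields `W` (array
#'   n_z x 2 x 2 of magnetization by \[depth, current site, start site\]),
#'   `profiles` (the marginal per-current-site profile), `joint_weights`
#'   (2x2 kinetic fractions start -> current, summing to 1), `tau_M`,
#'   `n_substeps`.
#' @export
apply_mixing <- function(profile, sample, tau_M, n_substeps = 32,
                         pad_decay = FALSE) {
  stopifnot(inherits(profile, "magnetization_profile"),
            inherits(sample, "two_site_sample"))
  if (!is_num1(tau_M) || tau_M < 0) stop_domain("tau_M must be >= 0")
  if (!is_num1(n_substeps) || n_substeps < 1)
    stop_domain("n_substeps must be >= 1")
  n_substeps <- as.integer(n_substeps)
  z <- profile$z_grid
  dz <- z[2] - z[1]
  p <- sample_populations(sample)
  D <- sample_D(sample)
  T1 <- sample_T1(sample)
  n <- length(z)
  # V[, i, j]: deviation from the unencoded reservoir of the fraction that
  # started in site j and is currently in site i; V = 0 far outside the
  # grid. Kept on a grid extended by the total diffusion length so that
  # magnetization flowing out during one substep can flow back later.
  pad0 <- profile$pad_values  # H * p_j
  m <- blur_margin(sqrt(2 * max(D) * tau_M), dz)
  N <- n + 2L * m
  idx <- (m + 1L):(m + n)
  V <- array(0, dim = c(N, 2L, 2L))
  V[idx, 1L, 1L] <- profile$M[, 1L] - pad0[1]
  V[idx, 2L, 2L] <- profile$M[, 2L] - pad0[2]
  if (tau_M > 0) {
    dt <- tau_M / n_substeps
    P <- exchange_propagator(sample$k, p, dt)
    s2 <- 2 * D * dt
    for (s in seq_len(n_substeps)) {
      for (j in 1:2) for (i in 1:2)
        if (s2[i] > 0) V[, i, j] <- spectral_blur(V[, i, j], dz, s2[i])
      for (j in 1:2) {
        v1 <- P[1, 1] * V[, 1L, j] + P[1, 2] * V[, 2L, j]
        v2 <- P[2, 1] * V[, 1L, j] + P[2, 2] * V[, 2L, j]
        V[, 1L, j] <- v1
        V[, 2L, j] <- v2
      }
      if (any(is.finite(T1))) {
        fac <- exp(-dt / T1)
        V[, 1L, ] <- V[, 1L, ] * fac[1]
        V[, 2L, ] <- V[, 2L, ] * fac[2]
      }
    }
  }
  V <- V[idx, , , drop = FALSE]
  # reservoir after the full mixing time: exchange (and optional decay) only
  Ptau <- exchange_propagator(sample$k, p, tau_M)
  R <- Ptau %*% diag(pad0)
  if (pad_decay && any(is.finite(T1))) R <- diag(exp(-tau_M / T1)) %*% R
  W <- V
  for (j in 1:2) for (i in 1:2) W[, i, j] <- V[, i, j] + R[i, j]
  marg <- cbind(W[, 1L, 1L] + W[, 1L, 2L], W[, 2L, 1L] + W[, 2L, 2L])
  colnames(marg) <- colnames(profile$M)
  profiles <- profile
  profiles$M <- marg
  Q <- exchange_propagator(sample$k, p, tau_M) %*% diag(p)
  structure(list(W = W, profiles = profiles, joint_weights = Q,
                 tau_M = tau_M, n_substeps = n_substeps),
            class = "mixing_result")
}

#' @export
print.mixing_result <- function(x, ...) {
  cat(sprintf("Mixing result: tau_M = %.3g ms, %d substeps\n",
              x$tau_M * 1e3, x$n_substeps))
  cat("  kinetic joint weights (start -> current):\n")
  print(round(x$joint_weights, 4))
  invisible(x)
}
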