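#' Per-echo CPMG attenuation under a constant gradient
#'
#' Attenuation of the n-th CPMG echo from diffusion in the constant readout
#' gradient plus transverse relaxation:
#' exp(-n \[(2 pi gammabar)^2 G^2 t_E^3 D / 12 + t_E / T2\]).
#' In the strong built-in gradient of a single-sided magnet the diffusion
#' term usually dominates the T2 term.
#'
#' @param D diffusion coefficient in m^2 s^-1.
#' @param T2 transverse relaxation time in seconds (`Inf` allowed).
#' @param t_E echo time in seconds (positive).
#' @param n echo index (>= 0, vectorized).
#' @param instrument an [instrument_spec()] supplying G and gammabar.
#' @return Attenuation factor(s) in (0, 1].
#' @export
cpmg_attenuation <- function(D, T2, t_E, n, instrument) {
  stopifnot(inherits(instrument, "instrument_spec"))
  if (!is_num1(D) || D < 0) stop_domain("D must be >= 0")
  if (!is.numeric(T2) || T2 <= 0) stop_domain("T2 must be > 0")
  if (!is_num1(t_E) || t_E <= 0) stop_domain("t_E must be > 0")
  if (any(n < 0)) stop_domain("echo index must be >= 0")
  gam <- 2 * pi * instrument$gammabar
  rate <- gam^2 * instrument$G^2 * t_E^3 * D / 12 + t_E / T2
  exp(-n * rate)
}

#' Construct a raw UF DEXSY 2D data object
#'
#' @param S matrix over (depth/frequency index, echo index).
#' @param depth_axis depths in metres (length = nrow(S)).
#' @param t_E echo time in seconds.
#' @param instrument an [instrument_spec()]; fixes the frequency axis
#'   f = gammabar * G * depth.
#' @param sigma noise standard deviation already present in `S` (0 for
#'   noiseless).
#' @param seed RNG seed used to draw the noise, or `NA`.
#' @param provenance named list recording simulation parameters or file
#'   origin.
#' @return An object of class `raw_data2d`.
#' @export
raw_data2d <- function(S, depth_axis, t_E, instrument, sigma = 0, seed = NA,
                       provenance = list()) {
  S <- as.matrix(S)
  if (nrow(S) != length(depth_axis))
    stop_domain("depth axis length must match nrow(S)")
  if (any(!is.finite(S))) stop_domain("matrix contains non-finite entries")
  freq <- instrument$gammabar * instrument$G * depth_axis
  structure(list(S = S, depth_axis = as.numeric(depth_axis),
                 freq_axis = freq, t_E = t_E, sigma = sigma, seed = seed,
                 provenance = provenance),
            class = "raw_data2d")
}

#' @export
print.raw_data2d <- function(x, ...) {
  cat(sprintf("UF DEXSY raw data: %d depth points x %d echoes, t_E = %.3g us\n",
              nrow(x$S), ncol(x$S), x$t_E * 1e6))
  cat(sprintf("  depth span %.3g um, frequency span %.3g kHz, noise sigma = %.3g\n",
              diff(range(x$depth_axis)) * 1e6,
              diff(range(x$freq_axis)) / 1e3, x$sigma))
  invisible(x)
}

#' Simulate the single-scan CPMG readout of mixed magnetization
#'
#' Forms the noiseless raw matrix S(q, n) by summing, over the four joint
#' (start site, current site) magnetization fractions, the detection-weighted
#' profile times the CPMG attenuation of the current site:
#' S(q, n) = sum_ij C(z_q) W_ij(z_q) A_i(n). Echo indexing starts at 1. The
#' model works directly in the post-Fourier-transform (depth/frequency)
#' domain.
#'
#' @param mix a `mixing_result` from [apply_mixing()].
#' @param cpmg a [cpmg_spec()].
#' @param instrument an [instrument_spec()].
#' @param sample the [two_site_sample()] that generated the magnetization.
#' @return A [raw_data2d()].
#' @export
simulate_raw <- function(mix, cpmg, instrument, sample) {
  stopifnot(inherits(mix, "mixing_result"), inherits(cpmg, "cpmg_spec"))
  z <- mix$profiles$z_grid
  D <- sample_D(sample)
  T2 <- sample_T2(sample)
  Cz <- eval_coil(instrument$coil, z)
  n_idx <- seq_len(cpmg$n_echoes)
  S <- matrix(0, nrow = length(z), ncol = cpmg$n_echoes)
  for (i in 1:2) {
    A <- cpmg_attenuation(D[i], T2[i], cpmg$t_E, n_idx, instrument)
    prof_i <- Cz * (mix$W[, i, 1L] + mix$W[, i, 2L])
    S <- S + outer(prof_i, A)
  }
  raw_data2d(S, z, cpmg$t_E, instrument,
             provenance = list(kind = "simulation", tau_M = mix$tau_M,
                               n_substeps = mix$n_substeps,
                               H = mix$profiles$H))
}

#' Add measurement noise to a raw matrix
#'
#' Adds zero-mean Gaussian noise with standard deviation max|S| / snr to
#' every matrix entry. The draw is reproducible for a fixed seed, and sigma
#' and the seed are recorded on the returned object.
#'
#' @param data a [raw_data2d()].
#' @param snr target signal-to-noise ratio (> 0; `Inf` returns the input
#'   unchanged apart from bookkeeping).
#' @param seed integer RNG seed.
#' @return A [raw_data2d()] with noise added.
#' @export
add_noise <- function(data, snr, seed = 1L) {
  stopifnot(inherits(data, "raw_data2d"))
  if (!is.numeric(snr) || length(snr) != 1L || is.na(snr) || snr <= 0)
    stop_domain("snr must be > 0")
  if (!is.finite(snr)) {
    data$sigma <- 0
    data$seed <- seed
    return(data)
  }
  sigma <- max(abs(data$S)) / snr
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  noise <- matrix(stats::rnorm(length(data$S), sd = sigma), nrow = nrow(data$S))
  data$S <- data$S + noise
  data$sigma <- sigma
  data$seed <- as.integer(seed)
  data
}

#' Diagnostic slices of a raw matrix
#'
#' Returns the first-echo row (the spatially encoded diffusion decay
#' modulated by coil and edge weights) and the echo-train column at the
#' depth of maximum first-echo signal (a two-term exponential mixture) —
#' the two marginal traces customarily plotted alongside the 2D raw data.
#'
#' @param data a [raw_data2d()].
#' @return A list with elements `encoding` (data frame depth_m, freq_Hz,
#'   signal at echo 1) and `cpmg` (data frame echo, signal at the
#'   maximum-signal depth).
#' @export
raw_slices <- function(data) {
  stopifnot(inherits(data, "raw_data2d"))
  q_max <- which.max(data$S[, 1L])
  list(encoding = data.frame(depth_m = data$depth_axis,
                             freq_Hz = data$freq_axis,
                             signal = data$S[, 1L]),
       cpmg = data.frame(echo = seq_len(ncol(data$S)),
                         signal = data$S[q_max, ]))
}
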