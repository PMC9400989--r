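#' ufdexsy: ultrafast diffusion exchange spectroscopy on single-sided magnets
#'
#' Forward simulation and analysis of single-scan (ultrafast) DEXSY
#' experiments performed in the strong constant gradient of a single-sided
#' NMR instrument. The pipeline covers the spatially encoded stimulated-echo
#' diffusion weighting, mixing-time evolution of two exchanging pools
#' (first-order site exchange, free-diffusion blurring of the encoded
#' layers, inflow of unencoded magnetization), CPMG readout, basis-surface
#' inversion to 2x2 exchange maps, and a two-site kinetics fit across mixing
#' times yielding the exchange rate, pool populations and residence
#' lifetimes.
#'
#' @keywords internal
"_PACKAGE"

#' Proton gyromagnetic ratio
#'
#' CODATA value of the proton gyromagnetic ratio divided by 2*pi, in Hz per
#' tesla. Used as the package-wide default wherever a gyromagnetic ratio is
#' needed.
#'
#' @format A length-one numeric, 42.577478461e6 Hz T^-1.
#' @export
GAMMABAR_1H <- 42.577478461e6

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) {
  stop(structure(class = c("ufdexsy_domain_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Larmor frequency of protons in a static field
#'
#' @param B0 static magnetic field in tesla (must be nonnegative).
#' @param gammabar gyromagnetic ratio over 2*pi in Hz T^-1.
#' @return Resonance frequency in Hz.
#' @examples
#' larmor_frequency(0.3) / 1e6  # ~12.8 MHz, the working field of a
#'                              # single-sided 0.3 T instrument
#' @export
larmor_frequency <- function(B0, gammabar = GAMMABAR_1H) {
  if (!is.numeric(B0) || any(!is.finite(B0)) || any(B0 < 0))
    stop_domain("B0 must be finite and nonnegative")
  if (!is_num1(gammabar) || gammabar <= 0)
    stop_domain("gammabar must be a positive scalar")
  gammabar * B0
}

#' Spatial extent addressed by a frequency band in a constant gradient
#'
#' In a constant gradient G the resonance frequency maps linearly onto depth,
#' so a chirp pulse of bandwidth `delta_f` addresses a slab of thickness
#' `delta_f / (gammabar * G)`.
#'
#' @param delta_f bandwidth in Hz (positive).
#' @param G gradient magnitude in T m^-1 (positive).
#' @param gammabar gyromagnetic ratio over 2*pi in Hz T^-1.
#' @return Extent in metres.
#' @examples
#' encoding_extent(93e3, 7.28) * 1e6  # ~300 micrometres
#' @export
encoding_extent <- function(delta_f, G, gammabar = GAMMABAR_1H) {
  if (!is_num1(delta_f) || delta_f <= 0) stop_domain("delta_f must be > 0")
  if (!is_num1(G) || G <= 0) stop_domain("G must be > 0")
  if (!is_num1(gammabar) || gammabar <= 0) stop_domain("gammabar must be > 0")
  delta_f / (gammabar * G)
}

#' Two-site first-order exchange rate matrix
#'
#' Builds the 2x2 rate matrix K of a two-site exchange process with overall
#' rate `k` (the magnitude of the nonzero eigenvalue) and stationary
#' populations `p`. Columns index the starting site, so that populations
#' evolve as dp/dt = K p. Detailed balance fixes the site-leaving rates to
#' k_out_1 = k * p2 and k_out_2 = k * p1.
#'
#' @param k overall exchange rate in s^-1 (nonnegative).
#' @param p numeric vector of two positive populations summing to 1.
#' @return A 2x2 numeric matrix with zero column sums, nonnegative
#'   off-diagonal entries, stationary vector `p` and nonzero eigenvalue `-k`.
#' @export
rate_matrix <- function(k, p) {
  if (!is_num1(k) || k < 0) stop_domain("k must be a nonnegative scalar")
  check_populations(p)
  kout1 <- k * p[2]
  kout2 <- k * p[1]
  matrix(c(-kout1, kout1, kout2, -kout2), nrow = 2L)
}

check_populations <- function(p) {
  if (!is.numeric(p) || length(p) != 2L || any(!is.finite(p)))
    stop_domain("p must be two finite numbers")
  if (any(p <= 0) || any(p >= 1) || abs(sum(p) - 1) > 1e-8)
    stop_domain("populations must lie in (0,1) and sum to 1")
  invisible(p)
}

#' Instrument description for a single-sided constant-gradient magnet
#'
#' @param B0 static field in tesla.
#' @param G constant gradient magnitude in T m^-1.
#' @param gammabar gyromagnetic ratio over 2*pi in Hz T^-1.
#' @param coil a [coil_profile()] giving the depth-dependent combined
#'   excitation/detection sensitivity; default is a flat profile.
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(B0 = 0.3, G = 7.28, gammabar = GAMMABAR_1H,
                            coil = flat_coil_profile()) {
  if (!is_num1(B0) || B0 <= 0) stop_domain("B0 must be > 0")
  if (!is_num1(G) || G <= 0) stop_domain("G must be > 0")
  if (!is_num1(gammabar) || gammabar <= 0) stop_domain("gammabar must be > 0")
  stopifnot(inherits(coil, "coil_profile"))
  structure(list(B0 = B0, G = G, gammabar = gammabar, coil = coil),
            class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("Single-sided instrument: B0 = %.3g T (%.1f MHz), G = %.3g T/m\n",
              x$B0, larmor_frequency(x$B0, x$gammabar) / 1e6, x$G))
  cat(sprintf("  coil profile: %d nodes over [%.3g, %.3g] mm\n",
              length(x$coil$depth), min(x$coil$depth) * 1e3,
              max(x$coil$depth) * 1e3))
  invisible(x)
}

#' Coil excitation/detection sensitivity profile
#'
#' Normalizes a 1D image of a homogeneous sample (depth, intensity) into a
#' relative sensitivity profile with peak 1, evaluated by interpolation
#' between the nodes and clamped to the boundary node values outside.
#'
#' @param depth strictly increasing node depths in metres (>= 2 nodes).
#' @param sensitivity nonnegative intensities at the nodes, not all zero.
#' @param interpolation interpolation rule between nodes; only
#'   `"linear"` is implemented.
#' @return An object of class `coil_profile`; evaluate it with
#'   [eval_coil()].
#' @export
coil_profile <- function(depth, sensitivity, interpolation = "linear") {
  if (length(depth) < 2L || length(depth) != length(sensitivity))
    stop_domain("need >= 2 (depth, sensitivity) nodes of equal length")
  if (any(!is.finite(depth)) || any(diff(depth) <= 0))
    stop_domain("depths must be finite and strictly increasing")
  if (any(!is.finite(sensitivity)) || any(sensitivity < 0))
    stop_domain("sensitivities must be finite and nonnegative")
  if (max(sensitivity) == 0) stop_domain("all-zero sensitivity image")
  interpolation <- match.arg(interpolation)
  structure(list(depth = as.numeric(depth),
                 sensitivity = as.numeric(sensitivity) / max(sensitivity),
                 interpolation = interpolation),
            class = "coil_profile")
}

#' Flat (ideal) coil profile
#'
#' @param z_range depth range in metres over which the profile is defined.
#' @return A `coil_profile` with sensitivity 1 everywhere.
#' @export
flat_coil_profile <- function(z_range = c(0, 1e-2)) {
  coil_profile(z_range, c(1, 1))
}

#' Evaluate a coil profile at given depths
#'
#' @param coil a [coil_profile()].
#' @param z depths in metres; values outside the node range are clamped to
#'   the boundary sensitivities.
#' @return Relative sensitivities in \[0, 1\].
#' @export
eval_coil <- function(coil, z) {
  stopifnot(inherits(coil, "coil_profile"))
  stats::approx(coil$depth, coil$sensitivity, xout = z, method = "linear",
                rule = 2)$y
}

#' @export
print.coil_profile <- function(x, ...) {
  cat(sprintf("Coil sensitivity profile: %d nodes, depth %.3g-%.3g mm, %s interpolation\n",
              length(x$depth), min(x$depth) * 1e3, max(x$depth) * 1e3,
              x$interpolation))
  invisible(x)
}

#' Bell-shaped synthetic coil profile
#'
#' A Gaussian-bump stand-in for the measured 1D spin-echo image of a
#' homogeneous sample that defines the coil sensitivity of a single-sided
#' instrument. The true node values of any particular coil are
#' instrument-specific; this synthetic default peaks at the centre of the
#' requested depth range and falls to `floor` at the edges.
#'
#' @param z_min,z_max depth range in metres.
#' @param n number of nodes.
#' @param width Gaussian width as a fraction of the range.
#' @param floor minimum relative sensitivity at the range edges.
#' @return A `coil_profile`.
#' @export
bell_coil_profile <- function(z_min = 0, z_max = 3e-4, n = 65,
                              width = 0.4, floor = 0.3) {
  z <- seq(z_min, z_max, length.out = n)
  mid <- (z_min + z_max) / 2
  sd <- width * (z_max - z_min)
  s <- floor + (1 - floor) * exp(-(z - mid)^2 / (2 * sd^2))
  coil_profile(z, s)
}

#' Spatial-encoding (stimulated-echo chirp) parameters
#'
#' @param chirp_bandwidth chirp bandwidth in Hz; with an instrument's
#'   gradient it fixes the encoded extent L = bandwidth / (gammabar * G).
#' @param delta_max maximal effective gradient-pulse length in seconds
#'   (reached at the bottom of the encoding region).
#' @param storage_interval storage (diffusion) interval Delta in seconds;
#'   must exceed `delta_max`.
#' @param edge_depth relative depth `a` in \[0, 1\] of the two Gaussian
#'   signal drops at the chirp sweep edges.
#' @param edge_width_frac width of the edge Gaussians as a fraction of the
#'   encoding extent L.
#' @return An object of class `encoding_spec`.
#' @export
encoding_spec <- function(chirp_bandwidth = 93e3, delta_max = 160e-6,
                          storage_interval = 5e-3, edge_depth = 1,
                          edge_width_frac = 0.05) {
  if (!is_num1(chirp_bandwidth) || chirp_bandwidth <= 0)
    stop_domain("chirp_bandwidth must be > 0")
  if (!is_num1(delta_max) || delta_max <= 0)
    stop_domain("delta_max must be > 0")
  if (!is_num1(storage_interval) || storage_interval <= delta_max)
    stop_domain("storage_interval must exceed delta_max")
  if (!is_num1(edge_depth) || edge_depth < 0 || edge_depth > 1)
    stop_domain("edge_depth must be in [0, 1]")
  if (!is_num1(edge_width_frac) || edge_width_frac <= 0)
    stop_domain("edge_width_frac must be > 0")
  structure(list(chirp_bandwidth = chirp_bandwidth, delta_max = delta_max,
                 storage_interval = storage_interval, edge_depth = edge_depth,
                 edge_width_frac = edge_width_frac),
            class = "encoding_spec")
}

#' Encoded extent of an encoding spec on a given instrument
#'
#' @param spec an [encoding_spec()].
#' @param instrument an [instrument_spec()].
#' @return Encoding extent L in metres.
#' @export
spec_extent <- function(spec, instrument) {
  stopifnot(inherits(spec, "encoding_spec"),
            inherits(instrument, "instrument_spec"))
  encoding_extent(spec$chirp_bandwidth, instrument$G, instrument$gammabar)
}

#' CPMG readout parameters
#'
#' @param t_E echo time in seconds.
#' @param n_echoes number of echoes acquired.
#' @param points_per_echo samples acquired per echo.
#' @param dwell_time sampling dwell time in seconds; the acquisition
#'   bandwidth 1/dwell_time must cover the chirp bandwidth being read out.
#' @return An object of class `cpmg_spec`.
#' @export
cpmg_spec <- function(t_E = 600e-6, n_echoes = 64, points_per_echo = 128,
                      dwell_time = 4e-6) {
  if (!is_num1(t_E) || t_E <= 0) stop_domain("t_E must be > 0")
  if (!is_num1(n_echoes) || n_echoes < 1) stop_domain("n_echoes must be >= 1")
  if (!is_num1(points_per_echo) || points_per_echo < 1)
    stop_domain("points_per_echo must be >= 1")
  if (!is_num1(dwell_time) || dwell_time <= 0)
    stop_domain("dwell_time must be > 0")
  structure(list(t_E = t_E, n_echoes = as.integer(n_echoes),
                 points_per_echo = as.integer(points_per_echo),
                 dwell_time = dwell_time),
            class = "cpmg_spec")
}

#' One site of a two-site exchange system
#'
#' @param label site name, e.g. `"intra"` or `"extra"`.
#' @param D self-diffusion coefficient in m^2 s^-1.
#' @param p equilibrium population fraction in (0, 1).
#' @param T1,T2 longitudinal/transverse relaxation times in seconds;
#'   `Inf` disables the corresponding decay.
#' @return An object of class `exchange_site`.
#' @export
exchange_site <- function(label, D, p, T1 = Inf, T2 = Inf) {
  if (!is_num1(D) || D <= 0) stop_domain("D must be > 0")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop_domain("p must be in (0, 1)")
  if (!is.numeric(T1) || T1 <= 0) stop_domain("T1 must be > 0")
  if (!is.numeric(T2) || T2 <= 0) stop_domain("T2 must be > 0")
  structure(list(label = as.character(label), D = D, p = p, T1 = T1, T2 = T2),
            class = "exchange_site")
}

#' Two-site exchanging sample
#'
#' @param sites list of exactly two [exchange_site()]s with populations
#'   summing to 1.
#' @param k overall exchange rate in s^-1 (the magnitude of the nonzero
#'   eigenvalue of the rate matrix).
#' @return An object of class `two_site_sample`.
#' @export
two_site_sample <- function(sites, k) {
  if (!is.list(sites) || length(sites) != 2L ||
      !all(vapply(sites, inherits, TRUE, "exchange_site")))
    stop_domain("sites must be a list of exactly two exchange_site objects")
  check_populations(c(sites[[1]]$p, sites[[2]]$p))
  if (!is_num1(k) || k < 0) stop_domain("k must be >= 0")
  structure(list(sites = sites, k = k), class = "two_site_sample")
}

#' Default two-pool water sample of a yeast cell suspension
#'
#' Intra- and extracellular water with diffusion coefficients 1.4 and
#' 3.6e-9 m^2 s^-1, intracellular population 0.24 and overall exchange rate
#' 14 s^-1 — the operating point of a hyperpolarized yeast suspension at
#' about 40 degrees C.
#'
#' @param k overall exchange rate in s^-1.
#' @param p_intra intracellular population fraction.
#' @param D_intra,D_extra site diffusion coefficients in m^2 s^-1.
#' @param T1,T2 relaxation times applied to both sites, seconds.
#' @return A [two_site_sample()].
#' @export
yeast_sample <- function(k = 14, p_intra = 0.24, D_intra = 1.4e-9,
                         D_extra = 3.6e-9, T1 = Inf, T2 = Inf) {
  two_site_sample(list(
    exchange_site("intra", D_intra, p_intra, T1 = T1, T2 = T2),
    exchange_site("extra", D_extra, 1 - p_intra, T1 = T1, T2 = T2)), k)
}

#' @export
print.two_site_sample <- function(x, ...) {
  cat("Two-site exchange sample:\n")
  for (s in x$sites)
    cat(sprintf("  %-6s D = %.3g m^2/s  p = %.3g  T1 = %.3g s  T2 = %.3g s\n",
                s$label, s$D, s$p, s$T1, s$T2))
  cat(sprintf("  overall exchange rate k = %.3g /s\n", x$k))
  invisible(x)
}

sample_populations <- function(sample) c(sample$sites[[1]]$p, sample$sites[[2]]$p)
sample_D <- function(sample) c(sample$sites[[1]]$D, sample$sites[[2]]$D)
sample_T1 <- function(sample) c(sample$sites[[1]]$T1, sample$sites[[2]]$T1)
sample_T2 <- function(sample) c(sample$sites[[1]]$T2, sample$sites[[2]]$T2)
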