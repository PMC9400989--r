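#' Four fixed-diffusivity basis surfaces for exchange-map inversion
#'
#' Builds, for each (start site j, end site k) pair, the unit-amplitude raw
#' surface of magnetization that was diffusion-encoded with D_j, blurred
#' with D_j over the mixing time (with unit unencoded inflow), and read out
#' with the CPMG attenuation of D_k. The site diffusivities are fixed
#' inputs, not fitted; all nonlinear physics lives in these surfaces so that
#' the pool weights enter the inversion linearly.
#'
#' @param sample a [two_site_sample()] supplying the fixed D (and T2)
#'   values.
#' @param spec an [encoding_spec()].
#' @param cpmg a [cpmg_spec()].
#' @param instrument an [instrument_spec()].
#' @param tau_M mixing time in seconds.
#' @param n_z depth points (must match the data being inverted).
#' @param warn_degenerate warn when D_intra == D_extra (rank-deficient
#'   bases).
#' @return A list of class `basis_surfaces`: `B` (matrix n_z*n_echoes x 4,
#'   columns in order 1->1, 1->2, 2->1, 2->2 of (start, end)), `dim`,
#'   `labels`, `tau_M`, `kappa` (condition number of the basis matrix).
#' @export
basis_surfaces <- function(sample, spec, cpmg, instrument, tau_M,
                           n_z = 128, warn_degenerate = TRUE) {
  stopifnot(inherits(sample, "two_site_sample"))
  D <- sample_D(sample)
  T2 <- sample_T2(sample)
  if (warn_degenerate && abs(D[1] - D[2]) <= 1e-9 * max(D))
    warning("D_intra == D_extra: basis surfaces are rank deficient")
  z <- depth_grid(spec, instrument, n_z)
  dz <- z[2] - z[1]
  L <- spec_extent(spec, instrument)
  b <- b_value_profile(z, spec, instrument)
  Cz <- eval_coil(instrument$coil, z)
  ez <- edge_attenuation(z, spec, L)
  n_idx <- seq_len(cpmg$n_echoes)
  labels <- character(4)
  Bm <- matrix(0, nrow = n_z * cpmg$n_echoes, ncol = 4L)
  col <- 0L
  site_lab <- vapply(sample$sites, `[[`, "", "label")
  for (j in 1:2) {
    enc <- exp(-b * D[j]) * Cz * ez           # excitation-weighted encoding
    for (k in 1:2) {
      col <- col + 1L
      # molecules ending in k != j switched at a roughly uniform time during
      # the mixing period, so their blur diffusivity is the site average;
      # unit unencoded reservoir beyond the region feeds the boundary inflow
      D_blur <- if (j == k) D[j] else (D[j] + D[k]) / 2
      blurred <- diffusion_blur(enc, dz, D_blur, tau_M, pad_value = 1)
      A <- cpmg_attenuation(D[k], T2[k], cpmg$t_E, n_idx, instrument)
      Bm[, col] <- as.vector(outer(Cz * blurred, A))
      labels[col] <- paste0(site_lab[j], "->", site_lab[k])
    }
  }
  kappa <- kappa(Bm, exact = TRUE)
  structure(list(B = Bm, dim = c(n_z, cpmg$n_echoes), labels = labels,
                 tau_M = tau_M, kappa = kappa,
                 z_grid = z, t_E = cpmg$t_E),
            class = "basis_surfaces")
}

#' Normalized 2x2 exchange map
#'
#' @param tau_M mixing time in seconds.
#' @param w 2x2 matrix of nonnegative intensities (rows: start site,
#'   columns: end site) summing to 1.
#' @param residual residual norm of the fit that produced the map.
#' @param diagnostics named list of fit diagnostics.
#' @return An object of class `exchange_map`.
#' @export
exchange_map <- function(tau_M, w, residual = NA_real_, diagnostics = list()) {
  w <- as.matrix(w)
  if (!all(dim(w) == c(2L, 2L))) stop_domain("w must be 2x2")
  if (any(w < -1e-12)) stop_domain("map intensities must be nonnegative")
  w[w < 0] <- 0
  if (abs(sum(w) - 1) > 1e-6) stop_domain("map intensities must sum to 1")
  structure(list(tau_M = tau_M, w = w / sum(w), residual = residual,
                 diagnostics = diagnostics),
            class = "exchange_map")
}

#' @export
print.exchange_map <- function(x, ...) {
  cat(sprintf("Exchange map at tau_M = %.3g ms (residual %.3g):\n",
              x$tau_M * 1e3, x$residual))
  print(round(x$w, 4))
  invisible(x)
}

#' Invert a raw matrix onto basis surfaces
#'
#' Solves the nonnegative least-squares problem min ||S - sum w_jk B_jk||^2
#' over the four pool weights and normalizes them to unit sum, yielding the
#' 2x2 exchange map of the measurement. Cross-term symmetry is not imposed;
#' it is a property of the kinetics model checked downstream.
#'
#' @param data a [raw_data2d()].
#' @param bases a [basis_surfaces()] on the same grid.
#' @param kappa_max largest acceptable basis condition number.
#' @return An [exchange_map()] with the raw (unnormalized) weights, the
#'   residual norm and the basis condition number in `diagnostics`.
#' @export
fit_map <- function(data, bases, kappa_max = 1e8) {
  stopifnot(inherits(data, "raw_data2d"), inherits(bases, "basis_surfaces"))
  if (!all(dim(data$S) == bases$dim))
    stop_domain("data and bases have mismatched grids")
  if (max(abs(data$S)) == 0) stop_domain("all-zero data matrix")
  if (!is.finite(bases$kappa) || bases$kappa > kappa_max)
    stop_domain(sprintf("rank-deficient bases: condition number %.3g", bases$kappa))
  y <- as.vector(data$S)
  sol <- pracma::lsqnonneg(bases$B, y)
  w_raw <- sol$x
  if (sum(w_raw) <= 0) stop_domain("degenerate fit: all weights zero")
  w <- matrix(0, 2L, 2L,
              dimnames = list(start = c("1", "2"), end = c("1", "2")))
  # basis column order: (j=1,k=1), (1,2), (2,1), (2,2)
  w[1, 1] <- w_raw[1]; w[1, 2] <- w_raw[2]
  w[2, 1] <- w_raw[3]; w[2, 2] <- w_raw[4]
  exchange_map(bases$tau_M, w / sum(w),
               residual = sqrt(sum((y - bases$B %*% w_raw)^2)),
               diagnostics = list(kappa = bases$kappa, w_raw = w_raw,
                                  labels = bases$labels))
}

#' Write / read exchange maps as delimited text
#'
#' One row per map: tau_M_s, w_11, w_12, w_21, w_22, residual.
#'
#' @param maps a list of [exchange_map()]s (or a single map).
#' @param path file path.
#' @return `write_maps` returns `path` invisibly; `read_maps` returns a
#'   list of `exchange_map`s.
#' @export
write_maps <- function(maps, path) {
  if (inherits(maps, "exchange_map")) maps <- list(maps)
  rows <- vapply(maps, function(m)
    sprintf("%.17g %.17g %.17g %.17g %.17g %.17g", m$tau_M,
            m$w[1, 1], m$w[1, 2], m$w[2, 1], m$w[2, 2], m$residual),
    character(1))
  writeLines(c("# ufdexsy exchange maps",
               "# columns = tau_M_s w_11 w_12 w_21 w_22 residual", rows), path)
  invisible(path)
}

#' @rdname write_maps
#' @export
read_maps <- function(path) {
  lines <- readLines(path)
  d <- utils::read.table(text = lines[!grepl("^#", lines)])
  if (ncol(d) != 6L) stop_domain("malformed exchange-map file: expected 6 columns")
  lapply(seq_len(nrow(d)), function(i)
    exchange_map(d[i, 1], matrix(as.numeric(d[i, 2:5]), 2L, byrow = TRUE),
                 residual = d[i, 6]))
}
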