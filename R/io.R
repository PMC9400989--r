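#' Write / read a raw 2D matrix as delimited text
#'
#' The format is a block of '#'-prefixed `key = value` header lines
#' (depth axis, echo time, noise sigma, seed and provenance) followed by the
#' whitespace-delimited matrix, one depth row per line. The reader validates
#' the header, the shape and rejects non-finite entries.
#'
#' @param data a [raw_data2d()].
#' @param path file path.
#' @return `write_matrix` returns `path` invisibly; `read_matrix` returns a
#'   [raw_data2d()].
#' @export
write_matrix <- function(data, path) {
  stopifnot(inherits(data, "raw_data2d"))
  prov <- vapply(data$provenance, function(v) paste(format(v, digits = 17),
                                                    collapse = " "), "")
  hdr <- c("# ufdexsy raw_data2d",
           sprintf("# n_depth = %d", nrow(data$S)),
           sprintf("# n_echo = %d", ncol(data$S)),
           sprintf("# depth_axis_m = %s",
                   paste(sprintf("%.17g", data$depth_axis), collapse = " ")),
           sprintf("# freq_axis_Hz = %s",
                   paste(sprintf("%.17g", data$freq_axis), collapse = " ")),
           sprintf("# t_E_s = %.17g", data$t_E),
           sprintf("# sigma = %.17g", data$sigma),
           sprintf("# seed = %s", format(data$seed)),
           sprintf("# provenance.%s = %s", names(prov), prov))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(format(data$S, digits = 17, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

header_value <- function(hdr, key, path) {
  ln <- grep(paste0("^# ", key, " = "), hdr, value = TRUE)
  if (length(ln) != 1L)
    stop_domain(sprintf("%s: missing or duplicated header key '%s'", path, key))
  sub(paste0("^# ", key, " = "), "", ln)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop_domain(path, ": no such file")
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  n_depth <- as.integer(header_value(hdr, "n_depth", path))
  n_echo <- as.integer(header_value(hdr, "n_echo", path))
  depth <- as.numeric(strsplit(header_value(hdr, "depth_axis_m", path), " ")[[1]])
  if (length(depth) != n_depth)
    stop_domain(sprintf("%s: depth axis length %d does not match n_depth = %d",
                        path, length(depth), n_depth))
  if (length(body) != n_depth)
    stop_domain(sprintf("%s: found %d matrix rows, expected %d",
                        path, length(body), n_depth))
  S <- do.call(rbind, lapply(seq_along(body), function(i) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "[[:space:]]+")[[1]]))
    if (length(row) != n_echo)
      stop_domain(sprintf("%s: row %d has %d entries, expected %d",
                          path, i, length(row), n_echo))
    if (any(!is.finite(row)))
      stop_domain(sprintf("%s: non-finite entry in matrix row %d (column %d)",
                          path, i, which(!is.finite(row))[1]))
    row
  }))
  t_E <- as.numeric(header_value(hdr, "t_E_s", path))
  sigma <- as.numeric(header_value(hdr, "sigma", path))
  seed <- suppressWarnings(as.integer(header_value(hdr, "seed", path)))
  prov_lines <- grep("^# provenance\\.", hdr, value = TRUE)
  prov <- list()
  for (pl in prov_lines) {
    key <- sub("^# provenance\\.([^ ]+) = .*$", "\\1", pl)
    val <- sub("^# provenance\\.[^ ]+ = ", "", pl)
    num <- suppressWarnings(as.numeric(strsplit(val, " ")[[1]]))
    prov[[key]] <- if (any(is.na(num))) val else num
  }
  freq <- as.numeric(strsplit(header_value(hdr, "freq_axis_Hz", path), " ")[[1]])
  out <- structure(list(S = S, depth_axis = depth, freq_axis = freq,
                        t_E = t_E, sigma = sigma, seed = seed,
                        provenance = prov),
                   class = "raw_data2d")
  out
}

#' Write / read a coil profile file
#'
#' Two-column delimited text (depth_m, relative sensitivity), '#' comments
#' allowed; the reader normalizes through [coil_profile()].
#'
#' @param coil a [coil_profile()].
#' @param path file path.
#' @return `write_coil` returns `path` invisibly; `read_coil` a
#'   [coil_profile()].
#' @export
write_coil <- function(coil, path) {
  stopifnot(inherits(coil, "coil_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# ufdexsy coil profile: depth_m sensitivity", con)
  utils::write.table(cbind(coil$depth, coil$sensitivity), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_coil
#' @export
read_coil <- function(path) {
  if (!file.exists(path)) stop_domain(path, ": no such file")
  d <- utils::read.table(path, comment.char = "#")
  if (ncol(d) != 2L) stop_domain(path, ": expected two columns (depth_m, sensitivity)")
  coil_profile(d[[1]], d[[2]])
}

# --- flat key-value run configuration ---------------------------------------

config_schema <- function() {
  # key -> multiplier to SI (values with unit suffixes in the key name)
  c("instrument.B0_T" = 1, "instrument.G_Tm" = 1,
    "instrument.gammabar_HzT" = 1,
    "encoding.bandwidth_kHz" = 1e3, "encoding.bandwidth_Hz" = 1,
    "encoding.delta_max_us" = 1e-6, "encoding.delta_max_s" = 1,
    "encoding.Delta_ms" = 1e-3, "encoding.Delta_s" = 1,
    "encoding.edge_depth" = 1, "encoding.edge_width_frac" = 1,
    "cpmg.tE_us" = 1e-6, "cpmg.tE_s" = 1, "cpmg.n_echoes" = 1,
    "cpmg.points_per_echo" = 1, "cpmg.dwell_us" = 1e-6, "cpmg.dwell_s" = 1,
    "sample.k_per_s" = 1, "sample.intra.D_m2s" = 1, "sample.extra.D_m2s" = 1,
    "sample.intra.p" = 1, "sample.intra.T1_s" = 1, "sample.intra.T2_s" = 1,
    "sample.extra.T1_s" = 1, "sample.extra.T2_s" = 1,
    "scenario.tauM_ms" = 1e-3, "scenario.tauM_s" = 1,
    "scenario.snr" = 1, "scenario.seed" = 1,
    "pipeline.n_z" = 1, "pipeline.n_substeps" = 1,
    "pipeline.coil_file" = NA)
}

#' Read a flat key-value run configuration
#'
#' One `key = value` pair per line, '#' comments allowed. Keys are
#' namespaced and carry explicit unit suffixes (e.g. `instrument.B0_T`,
#' `encoding.delta_max_us`, `scenario.tauM_ms`); values are converted to SI
#' on read. Unknown keys are rejected. `scenario.tauM_*` may hold a
#' space-separated list.
#'
#' @param path config file path.
#' @return A [scenario()] assembled from the file over the package
#'   defaults.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_domain(path, ": no such file")
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  schema <- config_schema()
  cfg <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop_domain("malformed config line: ", ln)
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (!key %in% names(schema)) stop_domain("unknown config key: ", key)
    cfg[[key]] <- if (is.na(schema[[key]])) val
                  else as.numeric(strsplit(val, "[[:space:]]+")[[1]]) * schema[[key]]
  }
  build_scenario_from_config(cfg)
}

build_scenario_from_config <- function(cfg) {
  g <- function(key, default) cfg[[key]] %||% default
  coil <- if (!is.null(cfg[["pipeline.coil_file"]]))
    read_coil(cfg[["pipeline.coil_file"]]) else NULL
  G <- g("instrument.G_Tm", 7.28)
  gb <- g("instrument.gammabar_HzT", GAMMABAR_1H)
  bw <- g("encoding.bandwidth_kHz", g("encoding.bandwidth_Hz", 93e3))
  if (is.null(coil)) {
    L <- encoding_extent(bw, G, gb)
    coil <- bell_coil_profile(z_min = -0.2 * L, z_max = 1.2 * L)
  }
  instrument <- instrument_spec(B0 = g("instrument.B0_T", 0.3), G = G,
                                gammabar = gb, coil = coil)
  enc <- encoding_spec(
    chirp_bandwidth = bw,
    delta_max = g("encoding.delta_max_us", g("encoding.delta_max_s", 160e-6)),
    storage_interval = g("encoding.Delta_ms", g("encoding.Delta_s", 5e-3)),
    edge_depth = g("encoding.edge_depth", 1),
    edge_width_frac = g("encoding.edge_width_frac", 0.05))
  cp <- cpmg_spec(t_E = g("cpmg.tE_us", g("cpmg.tE_s", 600e-6)),
                  n_echoes = g("cpmg.n_echoes", 64),
                  points_per_echo = g("cpmg.points_per_echo", 128),
                  dwell_time = g("cpmg.dwell_us", g("cpmg.dwell_s", 4e-6)))
  p_intra <- g("sample.intra.p", 0.24)
  samp <- two_site_sample(list(
    exchange_site("intra", g("sample.intra.D_m2s", 1.4e-9), p_intra,
                  T1 = g("sample.intra.T1_s", Inf),
                  T2 = g("sample.intra.T2_s", Inf)),
    exchange_site("extra", g("sample.extra.D_m2s", 3.6e-9), 1 - p_intra,
                  T1 = g("sample.extra.T1_s", Inf),
                  T2 = g("sample.extra.T2_s", Inf))),
    k = g("sample.k_per_s", 14))
  scenario(sample = samp, instrument = instrument, encoding = enc, cpmg = cp,
           tau_M = g("scenario.tauM_ms", g("scenario.tauM_s", c(0.010, 0.030, 0.100))),
           snr = g("scenario.snr", 280),
           seed = as.integer(g("scenario.seed", 1)),
           n_z = as.integer(g("pipeline.n_z", 128)),
           n_substeps = as.integer(g("pipeline.n_substeps", 32)))
}
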