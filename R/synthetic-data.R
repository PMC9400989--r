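#' Simulation scenario: sample, instrument, sequence and acquisition design
#'
#' Bundles everything needed to generate a complete synthetic UF DEXSY
#' dataset with known ground truth. The defaults reproduce the operating
#' point of a hyperpolarized yeast-suspension measurement on a 0.3 T,
#' 7.28 T m^-1 single-sided instrument: D = (1.4, 3.6)e-9 m^2 s^-1,
#' p_intra = 0.24, k = 14 s^-1, mixing times 10/30/100 ms, SNR 280, and a
#' bell-shaped coil sensitivity across the 300 um encoding region.
#'
#' @param sample a [two_site_sample()].
#' @param instrument an [instrument_spec()].
#' @param encoding an [encoding_spec()].
#' @param cpmg a [cpmg_spec()].
#' @param tau_M mixing times in seconds (distinct, positive).
#' @param snr signal-to-noise ratio of the raw matrices.
#' @param seed master seed; all per-mixing-time and per-repetition seeds
#'   derive from it.
#' @param n_z depth grid points.
#' @param n_substeps mixing operator-splitting substeps.
#' @param H_range range of the log-uniform per-experiment hyperpolarization
#'   amplitude factor (a fresh hyperpolarized sample per mixing time).
#' @return An object of class `scenario`.
#' @export
scenario <- function(sample = yeast_sample(),
                     instrument = default_instrument(),
                     encoding = encoding_spec(),
                     cpmg = cpmg_spec(),
                     tau_M = c(0.010, 0.030, 0.100),
                     snr = 280, seed = 1L, n_z = 128, n_substeps = 32,
                     H_range = c(0.5, 2)) {
  if (length(tau_M) < 1L || any(tau_M <= 0) || anyDuplicated(tau_M))
    stop_domain("mixing times must be distinct and positive")
  if (!is.numeric(snr) || snr <= 0) stop_domain("snr must be > 0")
  structure(list(sample = sample, instrument = instrument,
                 encoding = encoding, cpmg = cpmg, tau_M = sort(tau_M),
                 snr = snr, seed = as.integer(seed), n_z = as.integer(n_z),
                 n_substeps = as.integer(n_substeps), H_range = H_range),
            class = "scenario")
}

#' Default single-sided instrument with a bell-shaped coil profile
#'
#' @param ... passed to [instrument_spec()] to override fields.
#' @return An [instrument_spec()].
#' @export
default_instrument <- function(...) {
  args <- list(...)
  L <- encoding_extent(93e3, args$G %||% 7.28, args$gammabar %||% GAMMABAR_1H)
  defaults <- list(B0 = 0.3, G = 7.28,
                   coil = bell_coil_profile(z_min = -0.2 * L, z_max = 1.2 * L))
  do.call(instrument_spec, utils::modifyList(defaults, args))
}

#' @export
print.scenario <- function(x, ...) {
  cat("UF DEXSY scenario:\n")
  print(x$sample)
  cat(sprintf("  tau_M = %s ms, snr = %.3g, seed = %d, grid %d x %d\n",
              paste(x$tau_M * 1e3, collapse = "/"), x$snr, x$seed,
              x$n_z, x$cpmg$n_echoes))
  invisible(x)
}

# deterministic counter-based child-seed derivation, kept below 2^31
derive_seed <- function(master, counter) {
  as.integer((as.double(master) * 48271 + as.double(counter) * 16807 + 12345) %%
               2147483647)
}

#' Simulate one noisy raw matrix at a given mixing time
#'
#' Full forward model: spatial encoding, mixing-period evolution, CPMG
#' readout, additive Gaussian noise.
#'
#' @param scn a [scenario()].
#' @param tau_M mixing time in seconds.
#' @param H hyperpolarization amplitude.
#' @param seed noise seed.
#' @return A [raw_data2d()].
#' @export
simulate_experiment <- function(scn, tau_M, H = 1, seed = 1L) {
  stopifnot(inherits(scn, "scenario"))
  prof <- encode(scn$sample, scn$encoding, scn$instrument, H = H, n_z = scn$n_z)
  mix <- apply_mixing(prof, scn$sample, tau_M, n_substeps = scn$n_substeps)
  raw <- simulate_raw(mix, scn$cpmg, scn$instrument, scn$sample)
  add_noise(raw, scn$snr, seed = seed)
}

#' Generate a complete synthetic UF DEXSY dataset
#'
#' Simulates one noisy raw matrix per mixing time. Each experiment gets a
#' fresh hyperpolarization amplitude drawn log-uniformly from the scenario's
#' `H_range` (a new hyperpolarized sample is prepared per mixing time, so
#' absolute intensities are not comparable across experiments) and its own
#' derived noise seed. With an output directory, matrices and a ground-truth
#' manifest are written as plain text.
#'
#' @param scn a [scenario()].
#' @param out_dir optional directory to write `raw_tauM_*.dat` files and
#'   `manifest.txt`.
#' @param master_seed overrides the scenario seed.
#' @return A list of class `uf_dataset`: `raw` (list of [raw_data2d()]),
#'   `truth` (named list of generating parameters), `scenario`.
#' @export
generate_dataset <- function(scn, out_dir = NULL, master_seed = scn$seed) {
  stopifnot(inherits(scn, "scenario"))
  raws <- vector("list", length(scn$tau_M))
  H_all <- numeric(length(scn$tau_M))
  for (i in seq_along(scn$tau_M)) {
    seed_H <- derive_seed(master_seed, 2L * i - 1L)
    seed_noise <- derive_seed(master_seed, 2L * i)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed_H)
    H <- exp(stats::runif(1, log(scn$H_range[1]), log(scn$H_range[2])))
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    H_all[i] <- H
    raws[[i]] <- simulate_experiment(scn, scn$tau_M[i], H = H, seed = seed_noise)
    raws[[i]]$provenance$master_seed <- master_seed
  }
  truth <- list(k = scn$sample$k,
                p_intra = sample_populations(scn$sample)[1],
                D = sample_D(scn$sample), tau_M = scn$tau_M,
                snr = scn$snr, H = H_all, master_seed = master_seed)
  ds <- structure(list(raw = raws, truth = truth, scenario = scn),
                  class = "uf_dataset")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(raws))
      write_matrix(raws[[i]],
                   file.path(out_dir, sprintf("raw_tauM_%03dms.dat",
                                              round(scn$tau_M[i] * 1e3))))
    write_manifest(truth, file.path(out_dir, "manifest.txt"))
  }
  ds
}

#' Invert every raw matrix of a dataset and fit the exchange kinetics
#'
#' The analysis half of the closed loop: basis surfaces are built per mixing
#' time from the scenario's fixed site diffusivities, each raw matrix is
#' decomposed by nonnegative least squares into a normalized exchange map,
#' and the two-site model is fitted across the mixing times.
#'
#' @param ds a `uf_dataset` from [generate_dataset()] (or a list of
#'   [raw_data2d()] plus an explicit scenario).
#' @param scn scenario carrying the fixed analysis parameters; defaults to
#'   the one stored in the dataset.
#' @param bases optional precomputed list of [basis_surfaces()] (one per
#'   mixing time), e.g. when analysing many datasets of one design.
#' @return A list with `maps` (list of [exchange_map()]) and `fit`
#'   (an `exchange_fit`).
#' @export
analyze_dataset <- function(ds, scn = ds$scenario, bases = NULL) {
  raws <- if (inherits(ds, "uf_dataset")) ds$raw else ds
  tau <- vapply(raws, function(r) r$provenance$tau_M, numeric(1))
  if (is.null(bases))
    bases <- lapply(tau, function(t)
      basis_surfaces(scn$sample, scn$encoding, scn$cpmg, scn$instrument, t,
                     n_z = scn$n_z))
  maps <- Map(fit_map, raws, bases)
  list(maps = maps, fit = fit_exchange(maps))
}

#' Seeded closed-loop parameter-recovery experiment
#'
#' Repeats generate -> invert -> fit with child seeds derived from the
#' master seed and aggregates the recovered (k, p_intra) into bias, RMSE
#' and empirical coverage of the nominal 68% intervals.
#'
#' @param scn a [scenario()] (its `sample` carries the ground truth).
#' @param n_reps number of repetitions (>= 2).
#' @param master_seed master seed for the whole experiment.
#' @param bases optional precomputed basis surfaces (one per mixing time).
#' @return An object of class `recovery_report` with `estimates` (data
#'   frame: rep, seed, k, p_intra, se_k, se_p), `summary` (per-parameter
#'   bias, median error, RMSE, 68% coverage), `truth`, `n_reps`,
#'   `master_seed`, `failures`.
#' @export
recovery_experiment <- function(scn, n_reps = 50, master_seed = scn$seed,
                                bases = NULL) {
  if (!is_num1(n_reps) || n_reps < 2) stop_domain("n_reps must be >= 2")
  if (is.null(bases))
    bases <- lapply(scn$tau_M, function(t)
      basis_surfaces(scn$sample, scn$encoding, scn$cpmg, scn$instrument, t,
                     n_z = scn$n_z))
  truth_k <- scn$sample$k
  truth_p <- sample_populations(scn$sample)[1]
  rows <- vector("list", n_reps)
  failures <- 0L
  for (r in seq_len(n_reps)) {
    rep_seed <- derive_seed(master_seed, 1000L + r)
    res <- tryCatch({
      ds <- generate_dataset(scn, master_seed = rep_seed)
      an <- analyze_dataset(ds, scn, bases = bases)
      data.frame(rep = r, seed = rep_seed, k = an$fit$k,
                 p_intra = an$fit$p_intra, se_k = an$fit$se[["k"]],
                 se_p = an$fit$se[["p_intra"]])
    }, error = function(e) {
      warning(sprintf("repetition %d failed: %s", r, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) failures <- failures + 1L else rows[[r]] <- res
  }
  if (failures > n_reps / 2)
    stop_domain("more than half of the repetitions failed")
  est <- do.call(rbind, rows)
  summ <- data.frame(
    parameter = c("k", "p_intra"),
    truth = c(truth_k, truth_p),
    median = c(stats::median(est$k), stats::median(est$p_intra)),
    bias = c(mean(est$k) - truth_k, mean(est$p_intra) - truth_p),
    median_abs_err = c(stats::median(abs(est$k - truth_k)),
                       stats::median(abs(est$p_intra - truth_p))),
    rmse = c(sqrt(mean((est$k - truth_k)^2)),
             sqrt(mean((est$p_intra - truth_p)^2))),
    coverage68 = c(mean(abs(est$k - truth_k) <= est$se_k),
                   mean(abs(est$p_intra - truth_p) <= est$se_p)))
  structure(list(estimates = est, summary = summ,
                 truth = list(k = truth_k, p_intra = truth_p),
                 n_reps = n_reps, master_seed = master_seed,
                 failures = failures),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery: %d repetitions (%d failed), master seed %d\n",
              x$n_reps, x$failures, x$master_seed))
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a recovery report to key-value / tabular text
#'
#' @param report a `recovery_report`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# ufdexsy recovery report",
               sprintf("n_reps = %d", report$n_reps),
               sprintf("master_seed = %d", report$master_seed),
               sprintf("failures = %d", report$failures),
               sprintf("truth_k_per_s = %.17g", report$truth$k),
               sprintf("truth_p_intra = %.17g", report$truth$p_intra),
               "# summary"), con)
  utils::write.table(format(report$summary, digits = 17), con,
                     row.names = FALSE, quote = FALSE)
  writeLines("# estimates", con)
  utils::write.table(format(report$estimates, digits = 17), con,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

write_manifest <- function(truth, path) {
  writeLines(c("# ufdexsy ground-truth manifest",
               sprintf("k_per_s = %.17g", truth$k),
               sprintf("p_intra = %.17g", truth$p_intra),
               sprintf("D_intra_m2s = %.17g", truth$D[1]),
               sprintf("D_extra_m2s = %.17g", truth$D[2]),
               sprintf("tau_M_s = %s", paste(sprintf("%.17g", truth$tau_M), collapse = " ")),
               sprintf("snr = %.17g", truth$snr),
               sprintf("H = %s", paste(sprintf("%.17g", truth$H), collapse = " ")),
               sprintf("master_seed = %d", truth$master_seed)), path)
  invisible(path)
}

#' Read a ground-truth manifest written by [generate_dataset()]
#'
#' @param path manifest file path.
#' @return Named list of the generating parameters.
#' @export
read_manifest <- function(path) {
  lines <- grep("^#", readLines(path), value = TRUE, invert = TRUE)
  kv <- strsplit(lines, " = ", fixed = TRUE)
  out <- stats::setNames(lapply(kv, function(x)
    as.numeric(strsplit(x[2], " ")[[1]])), vapply(kv, `[[`, "", 1))
  out$master_seed <- as.integer(out$master_seed)
  out
}
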