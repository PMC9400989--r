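# Independent simulation oracles used to validate the closed-form physics.
# These deliberately share no code with the package internals.

# Brownian random-walk phase accumulation through the stimulated-echo
# timing: two gradient-on intervals of length delta whose leading edges are
# separated by Delta; phase accrues only while transverse. Returns the mean
# echo attenuation and its standard error.
mc_stimulated_echo <- function(delta, Delta, G, D, gammabar = GAMMABAR_1H,
                               n_walkers = 1e5, n_steps = 60) {
  gam <- 2 * pi * gammabar
  dt <- delta / n_steps
  z <- numeric(n_walkers)
  phi1 <- numeric(n_walkers)
  for (s in seq_len(n_steps)) {
    z <- z + stats::rnorm(n_walkers, sd = sqrt(2 * D * dt))
    phi1 <- phi1 + gam * G * z * dt
  }
  z <- z + stats::rnorm(n_walkers, sd = sqrt(2 * D * (Delta - delta)))
  phi2 <- numeric(n_walkers)
  for (s in seq_len(n_steps)) {
    z <- z + stats::rnorm(n_walkers, sd = sqrt(2 * D * dt))
    phi2 <- phi2 + gam * G * z * dt
  }
  att <- cos(phi1 - phi2)
  list(mean = mean(att), se = stats::sd(att) / sqrt(n_walkers))
}

# Brownian random-walk CPMG under a constant gradient: pi pulses at
# t_E/2, 3 t_E/2, ... flip the sign of subsequent phase accrual; the echo
# amplitude at echo n is E[cos(phase)].
mc_cpmg <- function(G, D, t_E, n_echoes, gammabar = GAMMABAR_1H,
                    n_walkers = 1e5, steps_per_half = 20) {
  gam <- 2 * pi * gammabar
  dt <- t_E / 2 / steps_per_half
  z <- numeric(n_walkers)
  phi <- numeric(n_walkers)
  out <- matrix(NA_real_, n_echoes, 2)
  sgn <- 1
  for (h in seq_len(2L * n_echoes)) {  # half-periods of length t_E/2
    for (s in seq_len(steps_per_half)) {
      z <- z + stats::rnorm(n_walkers, sd = sqrt(2 * D * dt))
      phi <- phi + sgn * gam * G * z * dt
    }
    if (h %% 2L == 1L) sgn <- -sgn  # pi pulse at t_E/2, 3 t_E/2, ...
    else {
      att <- cos(phi)               # echo forms at t = (h/2) t_E
      out[h %/% 2L, ] <- c(mean(att), stats::sd(att) / sqrt(n_walkers))
    }
  }
  out
}

# Gillespie-style two-state jump simulation: exact first-order kinetics by
# exponential waiting times; returns the fraction of particles whose state
# at time tau differs from their (equilibrium-drawn) initial state.
gillespie_cross_fraction <- function(k, p_intra, tau, n_particles = 1e5) {
  rates <- c(k * (1 - p_intra), k * p_intra)  # leaving rate of state 1, 2
  state0 <- ifelse(stats::runif(n_particles) < p_intra, 1L, 2L)
  state <- state0
  t_now <- numeric(n_particles)
  active <- rep(TRUE, n_particles)
  while (any(active)) {
    idx <- which(active)
    wait <- stats::rexp(length(idx), rate = rates[state[idx]])
    t_new <- t_now[idx] + wait
    jump <- t_new <= tau
    state[idx[jump]] <- 3L - state[idx[jump]]
    t_now[idx] <- t_new
    active[idx] <- jump
  }
  x <- state != state0
  list(mean = mean(x), se = stats::sd(x) / sqrt(n_particles))
}

# A small, fast scenario for pipeline tests: coarser grids, fewer echoes.
small_scenario <- function(...) {
  scenario(cpmg = cpmg_spec(n_echoes = 32, points_per_echo = 64),
           n_z = 64, n_substeps = 16, ...)
}
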