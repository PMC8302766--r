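# Fixtures built in code: exact model curves used as oracles across tests.

make_debye_curve <- function(Rg = 30, I0 = 1, q = seq(0.004, 0.25, length.out = 120),
                             sigmaI = NULL, t_after_mix = NA_real_) {
  saxs_curve(q, I0 * debye_form_factor(q, Rg), sigmaI = sigmaI,
             t_after_mix = t_after_mix)
}

make_guinier_curve <- function(Rg = 25, I0 = 2.5,
                               q = seq(0.004, 0.12, length.out = 80)) {
  saxs_curve(q, I0 * exp(-q^2 * Rg^2 / 3))
}

chaotic_flow_pars <- list(R_base = 26, A_collapse = 2, tau_collapse = 470e-6,
                          A_growth = 3, tau_growth = 36e-3)

# analytic stationary distribution of the closed small-system birth-death
# chain (single site, n_tot monomers): states 0 (no cluster), 2, ..., n_tot
small_system_stationary <- function(params, n_tot) {
  kp <- function(N, M) params$D * cluster_radius(max(N, 1), params$c_den) *
    (M / params$V)
  km <- function(N) {
    R <- cluster_radius(N, params$c_den)
    params$D * R * params$c_sat * (1 + 2 * params$Gamma_cap / R)
  }
  states <- c(0, 2:n_tot)
  pi_u <- numeric(length(states))
  pi_u[1] <- 1
  # detailed balance along the chain 0 -> 2 -> 3 -> ... (0 -> 2 consumes 2)
  pi_u[2] <- pi_u[1] * kp(1, n_tot) / km(2)
  if (n_tot > 2) {
    for (j in 3:n_tot) {
      pi_u[j] <- pi_u[j - 1] * kp(j - 1, n_tot - (j - 1)) / km(j)
    }
  }
  setNames(pi_u / sum(pi_u), states)
}

# time-weighted occupancy of cluster sizes from an event log, with
# batch-means Monte-Carlo standard errors
occupancy_from_log <- function(ev, levels, n_batches = 100) {
  st <- c(0, ev$size[-nrow(ev)])    # state held before each event fires
  dt <- diff(c(0, ev$time))
  occ_of <- function(ix) {
    o <- tapply(dt[ix], factor(st[ix], levels = levels), sum)
    o[is.na(o)] <- 0
    o / sum(o)
  }
  bid <- cut(seq_len(nrow(ev)), n_batches, labels = FALSE)
  bm <- sapply(split(seq_len(nrow(ev)), bid), occ_of)
  list(occ = occ_of(seq_len(nrow(ev))),
       se = apply(bm, 1, sd) / sqrt(n_batches))
}
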