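#' Classical nucleation theory parameters
#'
#' Surface and volume coefficients of the cluster free energy
#' \deqn{\Delta G(R) = 4\pi R^2 \gamma + \tfrac{4}{3}\pi R^3 \epsilon,}
#' in reduced units: `gamma` is the surface-energy coefficient (energy per
#' area, always unfavorable) and `epsilon` the volume free-energy density
#' (negative above saturation, where condensation is favorable).
#'
#' @param gamma Surface-energy coefficient, `>= 0`.
#' @param epsilon Volume free-energy density.
#' @return Object of class `cnt_params`.
#' @export
cnt_params <- function(gamma, epsilon) {
  if (gamma < 0) stop_invalid_parameter("gamma must be non-negative")
  structure(list(gamma = gamma, epsilon = epsilon), class = "cnt_params")
}

#' Free energy of forming a cluster of radius R
#'
#' @param R Cluster radius (vectorized, `R >= 0`).
#' @param params A [cnt_params].
#' @return Free energy `4*pi*R^2*gamma + (4/3)*pi*R^3*epsilon`.
#' @export
cluster_free_energy <- function(R, params) {
  stopifnot(inherits(params, "cnt_params"))
  if (any(R < 0)) stop_invalid_parameter("R must be non-negative")
  4 * pi * R^2 * params$gamma + (4 / 3) * pi * R^3 * params$epsilon
}

#' Critical radius and nucleation barrier
#'
#' For `gamma > 0` and `epsilon < 0` the surface and volume terms balance at
#' the critical radius `R_crit = -2*gamma/epsilon`, where the free energy is
#' maximal: `dG_barrier = (16*pi/3) * gamma^3 / epsilon^2`. Clusters below
#' `R_crit` tend to shrink, those above tend to grow.
#'
#' @param params A [cnt_params] with `gamma > 0`, `epsilon < 0`.
#' @return List with `R_crit` and `dG_barrier`.
#' @export
critical_radius_and_barrier <- function(params) {
  stopifnot(inherits(params, "cnt_params"))
  if (params$epsilon >= 0) {
    stop(pk_condition("phasekin_no_barrier",
                      "epsilon >= 0: phase separation not favored, no finite barrier"))
  }
  if (params$gamma <= 0) stop_invalid_parameter("gamma must be positive")
  R_crit <- -2 * params$gamma / params$epsilon
  dG <- (16 * pi / 3) * params$gamma^3 / params$epsilon^2
  list(R_crit = R_crit, dG_barrier = dG)
}

#' Stochastic nucleation simulation parameters
#'
#' Parameters of the cluster birth-death integrator, in reduced units by
#' default (`D = 1`, `c_sat = 1`). The capillary length
#' `Gamma_cap = gamma / c_den` controls the Gibbs-Thomson enhancement of
#' dissolution for small clusters.
#'
#' @param D Monomer diffusion coefficient, length^2/time.
#' @param c_sat Saturation concentration, number/length^3.
#' @param c_den Dense-phase concentration, number/length^3 (`> c_sat`).
#' @param gamma Surface tension entering the capillary length.
#' @param c0 Initial monomer concentration, number/length^3.
#' @param V Simulation volume, length^3.
#' @param N_threshold Cluster size above which a cluster counts as
#'   nucleated (default 20 monomers).
#' @return Object of class `nucleation_params`.
#' @export
nucleation_params <- function(D = 1, c_sat = 1, c_den = 50, gamma = 6,
                              c0 = 2, V = 2000, N_threshold = 20L) {
  if (D <= 0 || c_sat <= 0 || c_den <= 0 || V <= 0) {
    stop_invalid_parameter("D, c_sat, c_den and V must be positive")
  }
  if (c_den <= c_sat) stop_invalid_parameter("c_den must exceed c_sat")
  if (N_threshold < 2) stop_invalid_parameter("N_threshold must be >= 2")
  if (c0 < 0) stop_invalid_parameter("c0 must be non-negative")
  structure(list(D = D, c_sat = c_sat, c_den = c_den, gamma = gamma,
                 Gamma_cap = gamma / c_den, c0 = c0, V = V,
                 N_threshold = as.integer(N_threshold)),
            class = "nucleation_params")
}

#' @export
print.nucleation_params <- function(x, ...) {
  cat("Nucleation simulation parameters (reduced units)\n")
  cat(sprintf("  D = %s, c_sat = %s, c_den = %s, gamma = %s (Gamma_cap = %s)\n",
              fmt_num(x$D), fmt_num(x$c_sat), fmt_num(x$c_den),
              fmt_num(x$gamma), fmt_num(x$Gamma_cap)))
  cat(sprintf("  c0 = %s, V = %s (total monomers %d), N_threshold = %d\n",
              fmt_num(x$c0), fmt_num(x$V), round(x$c0 * x$V), x$N_threshold))
  invisible(x)
}

#' Quench state: bulk concentration and supersaturation
#'
#' Supersaturation is defined in ratio form by default,
#' `sigma = c_inf/c_sat - 1`; the difference form `c_inf - c_sat` is
#' available for comparison.
#'
#' @param c_inf Current bulk monomer concentration.
#' @param c_sat Saturation concentration.
#' @param form `"ratio"` (default) or `"difference"`.
#' @return Object of class `quench_state` with `c_inf`, `sigma`.
#' @export
quench_state <- function(c_inf, c_sat = 1, form = c("ratio", "difference")) {
  form <- match.arg(form)
  if (c_inf < 0 || c_sat <= 0) {
    stop_invalid_parameter("concentrations must be non-negative, c_sat > 0")
  }
  sigma <- if (form == "ratio") c_inf / c_sat - 1 else c_inf - c_sat
  structure(list(c_inf = c_inf, c_sat = c_sat, sigma = sigma, form = form),
            class = "quench_state")
}

#' Cluster radius from aggregation number
#'
#' `R(N) = (3N / (4*pi*c_den))^(1/3)`: the radius of a spherical cluster of
#' `N` monomers at the dense-phase concentration.
#'
#' @param N Aggregation number (vectorized, `N >= 1`).
#' @param c_den Dense-phase concentration.
#' @return Radius in simulation length units.
#' @export
cluster_radius <- function(N, c_den) {
  if (any(N < 1)) stop_invalid_parameter("N must be >= 1")
  (3 * N / (4 * pi * c_den))^(1 / 3)
}

#' Attachment and detachment rates of a cluster
#'
#' The diffusion-limited flux law split into attachment and detachment
#' channels: `k_plus = D * R(N) * c_inf` and, under the enhanced-dissolution
#' Gibbs-Thomson convention (default),
#' `k_minus = D * R(N) * c_sat * (1 + 2*Gamma_cap/R(N))`, so the net drift
#' `k_plus - k_minus` vanishes at the critical radius
#' `R* = 2*Gamma_cap/sigma`. The literal printed sign
#' (`1 - 2*Gamma_cap/R`, which removes the barrier) is available with
#' `gibbs_thomson = "printed"`.
#'
#' @param N Cluster size in monomers (`N >= 1`).
#' @param quench A [quench_state] (or a bare numeric `c_inf`).
#' @param params A [nucleation_params].
#' @param gibbs_thomson `"enhanced"` (default) or `"printed"`.
#' @return List with `k_plus`, `k_minus` (events/time) and `R`.
#' @export
attachment_detachment_rates <- function(N, quench, params,
                                        gibbs_thomson = c("enhanced",
                                                          "printed")) {
  stopifnot(inherits(params, "nucleation_params"))
  gibbs_thomson <- match.arg(gibbs_thomson)
  if (any(N < 1)) stop_invalid_parameter("N must be >= 1")
  c_inf <- if (inherits(quench, "quench_state")) quench$c_inf else
    as.numeric(quench)
  R <- cluster_radius(N, params$c_den)
  k_plus <- params$D * R * c_inf
  curv <- 2 * params$Gamma_cap / R
  k_minus <- if (gibbs_thomson == "enhanced") {
    params$D * R * params$c_sat * (1 + curv)
  } else {
    pmax(params$D * R * params$c_sat * (1 - curv), 0)
  }
  list(k_plus = k_plus, k_minus = k_minus, R = R)
}

#' Run the stochastic cluster nucleation simulation
#'
#' Exact event-driven (Gillespie-type) simulation of `n_sites` cluster seeds
#' sharing one monomer pool. Each empty site carries a dimerization channel
#' with rate `dimer_penalty * D * R(1) * c_inf`; each occupied site carries
#' the attachment/detachment channels of
#' [attachment_detachment_rates()]. The bulk concentration
#' `c_inf = free_monomers / V` is recomputed after every event (global
#' mean-field depletion), so total monomer count is conserved exactly.
#'
#' @param params A [nucleation_params].
#' @param t_max End time of the simulation (`> 0`).
#' @param n_sites Number of independent cluster seeds sharing the pool.
#' @param out_times Output time grid; default 200 evenly spaced times.
#' @param seed Optional RNG seed (simulation is a deterministic function of
#'   seed and parameters).
#' @param initial_sizes Optional integer vector of initial cluster sizes per
#'   site (0 = empty); monomers they contain are taken from `c0 * V`.
#' @param dimer_penalty Scale factor `<= 1` on the dimerization rate,
#'   encoding an unfavorable first association step (default 1 = pure
#'   homogeneous nucleation).
#' @param gibbs_thomson Gibbs-Thomson sign convention, see
#'   [attachment_detachment_rates()].
#' @param record_events If `TRUE` (only with `n_sites = 1`), record the full
#'   event log (time, free monomers, cluster size) for small-system
#'   analyses.
#' @param max_events Safety cap on the number of events.
#' @return Object of class `simulation_trace`: a data frame with columns
#'   `times`, `nucleated_mass_fraction`, `n_clusters_above`, with the
#'   parameters, event count, final state and (optionally) the event log as
#'   attributes.
#' @export
simulate_nucleation <- function(params, t_max, n_sites = 20L,
                                out_times = NULL, seed = NULL,
                                initial_sizes = NULL,
                                dimer_penalty = 1,
                                gibbs_thomson = c("enhanced", "printed"),
                                record_events = FALSE,
                                max_events = 2e7) {
  stopifnot(inherits(params, "nucleation_params"))
  gibbs_thomson <- match.arg(gibbs_thomson)
  if (t_max <= 0) stop_invalid_parameter("t_max must be positive")
  if (n_sites < 1) stop_invalid_parameter("n_sites must be >= 1")
  if (dimer_penalty <= 0) stop_invalid_parameter("dimer_penalty must be > 0")
  if (is.null(out_times)) {
    out_times <- seq(0, t_max, length.out = 201L)[-1]
  }
  out_times <- sort(as.numeric(out_times))
  if (any(out_times <= 0) || any(out_times > t_max + 1e-12)) {
    stop_invalid_parameter("out_times must lie in (0, t_max]")
  }
  M0 <- round(params$c0 * params$V)
  sizes0 <- rep(0L, n_sites)
  if (!is.null(initial_sizes)) {
    if (length(initial_sizes) != n_sites) {
      stop_invalid_parameter("initial_sizes must have length n_sites")
    }
    sizes0 <- as.integer(initial_sizes)
    if (any(sizes0 == 1L) || any(sizes0 < 0L)) {
      stop_invalid_parameter("initial sizes must be 0 (empty) or >= 2")
    }
  }
  total <- M0 + sum(sizes0)
  if (total < 2 && all(sizes0 == 0L)) {
    stop_invalid_parameter("fewer than 2 monomers in the system")
  }
  if (record_events && n_sites != 1L) {
    stop_invalid_parameter("record_events requires n_sites = 1")
  }
  res <- with_seed(seed, sim_nucleation_cpp(
    D = params$D, c_sat = params$c_sat, c_den = params$c_den,
    Gamma = params$Gamma_cap, M0 = as.integer(M0), V = params$V,
    sizes0 = sizes0, N_threshold = params$N_threshold,
    t_max = t_max, out_times = out_times,
    dimer_penalty = dimer_penalty,
    printed_sign = (gibbs_thomson == "printed"),
    record_events = record_events, max_events = as.double(max_events)))
  trace <- data.frame(times = out_times,
                      nucleated_mass_fraction = res$mass_frac,
                      n_clusters_above = as.integer(res$n_above))
  if (isTRUE(res$exhausted)) {
    message("simulate_nucleation: all channels extinguished before t_max; ",
            "trace holds the final state")
  }
  structure(trace,
            params = params, n_sites = n_sites, n_events = res$n_events,
            final_sizes = res$final_sizes, final_free = res$final_free,
            total_monomers = total, exhausted = isTRUE(res$exhausted),
            event_log = if (record_events) {
              data.frame(time = res$ev_time, free = res$ev_free,
                         size = res$ev_size)
            },
            class = c("simulation_trace", "data.frame"))
}

#' @export
print.simulation_trace <- function(x, ...) {
  cat("Nucleation simulation trace\n")
  cat(sprintf("  %d output times up to t = %s; %s events\n", nrow(x),
              fmt_num(max(x$times)), format(attr(x, "n_events"), big.mark = ",")))
  cat(sprintf("  final nucleated mass fraction = %s (%d clusters > threshold)\n",
              fmt_num(x$nucleated_mass_fraction[nrow(x)]),
              x$n_clusters_above[nrow(x)]))
  invisible(x)
}

#' Time at half completion of assembly
#'
#' Returns the first time at which the nucleated mass fraction crosses half
#' of its plateau (taken as the maximum of the trace), linearly interpolated
#' between output samples. Used as a proxy for the nucleation time.
#'
#' @param trace A `simulation_trace`, or any data frame / list with `times`
#'   and a second numeric series (`nucleated_mass_fraction` or `y`).
#' @param min_plateau Minimum plateau value below which the system counts as
#'   not assembled (default 0.02).
#' @return Crossing time, or `NA_real_` (the not-assembled sentinel) when
#'   the trace never rises above `min_plateau`.
#' @export
time_to_half_assembly <- function(trace, min_plateau = 0.02) {
  tt <- trace$times
  y <- if (!is.null(trace$nucleated_mass_fraction)) {
    trace$nucleated_mass_fraction
  } else {
    trace$y
  }
  if (is.null(tt) || is.null(y)) {
    stop_invalid_parameter("trace needs 'times' and a mass-fraction series")
  }
  plateau <- max(y)
  if (!is.finite(plateau) || plateau < min_plateau) return(NA_real_)
  half <- plateau / 2
  i <- which(y >= half)[1]
  if (i == 1L) return(tt[1])
  # linear interpolation between the bracketing samples
  t0 <- tt[i - 1]; t1 <- tt[i]; y0 <- y[i - 1]; y1 <- y[i]
  if (y1 == y0) return(t1)
  t0 + (half - y0) * (t1 - t0) / (y1 - y0)
}

#' Barrier scaling of nucleation times with supersaturation
#'
#' Classical nucleation predicts the time to half assembly to be
#' exponentially dependent on the free-energy barrier, which scales as
#' `1/sigma^2` with quench depth. Fits `ln(t_half) = a + B / sigma^2` by
#' ordinary least squares.
#'
#' @param t_half Vector of half-assembly times (all finite and positive; the
#'   caller must exclude not-assembled sentinels).
#' @param sigma Vector of supersaturations, same length.
#' @return List with `B` (slope), `intercept`, `r_squared`, and the `lm` fit.
#' @export
barrier_scaling_check <- function(t_half, sigma) {
  if (length(t_half) != length(sigma)) {
    stop_invalid_parameter("t_half and sigma must have equal length")
  }
  if (length(t_half) < 3) {
    stop_insufficient_data("need >= 3 (sigma, t_half) pairs")
  }
  if (any(!is.finite(t_half)) || any(t_half <= 0)) {
    stop_invalid_parameter(
      "t_half must be finite and positive; exclude not-assembled sentinels")
  }
  if (any(sigma <= 0)) stop_invalid_parameter("sigma must be positive")
  fit <- lm(log(t_half) ~ I(1 / sigma^2))
  list(B = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit))$r.squared, fit = fit)
}
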