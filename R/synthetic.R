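#' Generator configuration
#'
#' Shared configuration for the seeded synthetic-data generators. With a
#' fixed seed every generator is a deterministic function of its parameters.
#'
#' @param seed Integer RNG seed (or `NULL` for the session RNG).
#' @param noise_model `"gaussian_fractional"` (multiplicative Gaussian,
#'   default) or `"poisson_like"` (sigma proportional to sqrt(I), for raw
#'   scattering curves).
#' @param noise_level Fractional noise level (default 0.02, i.e. 2 percent).
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(seed = NULL,
                             noise_model = c("gaussian_fractional",
                                             "poisson_like"),
                             noise_level = 0.02) {
  noise_model <- match.arg(noise_model)
  if (noise_level < 0) stop_invalid_parameter("noise_level must be >= 0")
  structure(list(seed = seed, noise_model = noise_model,
                 noise_level = noise_level),
            class = "generator_config")
}

apply_noise <- function(I, cfg) {
  if (cfg$noise_level == 0) {
    return(list(I = I, sigma = rep(0, length(I))))
  }
  if (cfg$noise_model == "gaussian_fractional") {
    sigma <- cfg$noise_level * abs(I)
    list(I = I * (1 + cfg$noise_level * rnorm(length(I))), sigma = sigma)
  } else {
    # Poisson-like: sigma ~ sqrt(I), scaled so the fractional error at the
    # maximum intensity equals noise_level
    sigma <- cfg$noise_level * sqrt(abs(I) * max(abs(I)))
    list(I = I + sigma * rnorm(length(I)), sigma = sigma)
  }
}

#' Logarithmic time grid
#'
#' @param t_min,t_max Grid bounds, seconds.
#' @param n Number of points.
#' @return Log-spaced vector of times.
#' @export
log_time_grid <- function(t_min, t_max, n) {
  if (t_min <= 0 || t_max <= t_min) stop_invalid_parameter("need 0 < t_min < t_max")
  exp(seq(log(t_min), log(t_max), length.out = n))
}

#' Generate a time series of synthetic SAXS curves
#'
#' Emulates the time evolution of the form factor in laminar-flow TR-SAXS:
#' `I(q, t) = I0 P(q) + A(t) q^(-p) + noise`, a disordered-monomer form
#' factor plus a low-angle power-law upturn from mesoscopic clusters whose
#' amplitude follows the supplied schedule.
#'
#' @param monomer A [form_factor_model].
#' @param times Curve times after mixing, seconds.
#' @param upturn_amplitude Either a numeric vector (one amplitude per time)
#'   or a function of time.
#' @param q_grid Momentum-transfer grid, inverse angstrom.
#' @param cfg A [generator_config].
#' @param power Power-law exponent `p` of the upturn (default 2,
#'   mass-fractal-like clusters).
#' @return List of [saxs_curve] objects with `t_after_mix` set.
#' @export
gen_saxs_series <- function(monomer, times, upturn_amplitude, q_grid,
                            cfg = generator_config(), power = 2) {
  stopifnot(inherits(monomer, "form_factor_model"))
  A <- if (is.function(upturn_amplitude)) upturn_amplitude(times) else
    rep_len(as.numeric(upturn_amplitude), length(times))
  if (any(A < 0)) stop_invalid_parameter("upturn amplitudes must be >= 0")
  base <- form_factor_intensity(monomer, q_grid)
  with_seed(cfg$seed, lapply(seq_along(times), function(i) {
    I <- base + A[i] * q_grid^(-power)
    nz <- apply_noise(I, cfg)
    saxs_curve(q_grid, nz$I,
               sigmaI = if (cfg$noise_level > 0) nz$sigma else NULL,
               t_after_mix = times[i],
               label = sprintf("synthetic t=%.6g s", times[i]))
  }))
}

#' Generate synthetic R_G(t) collapse-and-growth traces
#'
#' Emulates chaotic-flow chain-compaction kinetics: the collapse+growth
#' model evaluated on a log-spaced grid covering the 69 microsecond to 17
#' millisecond observation window, plus multiplicative noise. The default
#' parameters are the shipped chaotic-flow scenario: collapse time constant
#' 470 microseconds and growth time constant 36 milliseconds.
#'
#' @param pars Named list with `R_base`, `A_collapse`, `tau_collapse`,
#'   `A_growth`, `tau_growth` (angstrom / seconds).
#' @param t_grid Time grid, seconds; default 80 log-spaced points on
#'   69e-6 to 17e-3 s.
#' @param n_replicates Number of replicate traces.
#' @param cfg A [generator_config].
#' @return A [kinetic_trace] (one replicate) or list of them.
#' @export
gen_rg_trace <- function(pars = list(R_base = 26, A_collapse = 2,
                                     tau_collapse = 470e-6, A_growth = 3,
                                     tau_growth = 36e-3),
                         t_grid = log_time_grid(69e-6, 17e-3, 80),
                         n_replicates = 1L, cfg = generator_config()) {
  need <- c("R_base", "A_collapse", "tau_collapse", "A_growth", "tau_growth")
  if (!all(need %in% names(pars))) {
    stop_invalid_parameter(paste("pars needs", paste(need, collapse = ", ")))
  }
  if (pars$tau_collapse <= 0 || pars$tau_growth <= 0) {
    stop_invalid_parameter("time constants must be positive")
  }
  y0 <- cg_model(t_grid, pars$R_base, pars$A_collapse, pars$tau_collapse,
                 pars$A_growth, pars$tau_growth)
  traces <- with_seed(cfg$seed, lapply(seq_len(n_replicates), function(r) {
    nz <- apply_noise(y0, cfg)
    kinetic_trace(t_grid, nz$I,
                  y_err = if (cfg$noise_level > 0) nz$sigma else NULL,
                  replicate_id = r)
  }))
  if (n_replicates == 1L) traces[[1]] else traces
}

#' Generate stochastic assembly-metric trajectories
#'
#' Two modes. `"weibull_step"` (phenomenological): each replicate is a unit
#' step at an onset time drawn from a Weibull distribution, scaled by
#' `amplitude` — the per-time scatter across replicates then encodes the
#' onset-time distribution. `"simulator"` (mechanistic): replicates are
#' nucleated-mass-fraction traces from [simulate_nucleation()], scaled by
#' `amplitude`.
#'
#' @param t_grid Common time grid, seconds.
#' @param n_replicates Number of replicates (`>= 1`).
#' @param mode `"weibull_step"` or `"simulator"`.
#' @param scale_lambda,stretch_k Weibull onset-time parameters (mode
#'   `"weibull_step"`).
#' @param amplitude Plateau value of each trajectory.
#' @param sim_params A [nucleation_params] (mode `"simulator"`).
#' @param n_sites Sites per simulation (mode `"simulator"`).
#' @param cfg A [generator_config]; noise is added on top of the trajectory.
#' @return List of [kinetic_trace] replicates.
#' @export
gen_assembly_trajectories <- function(t_grid, n_replicates,
                                      mode = c("weibull_step", "simulator"),
                                      scale_lambda = 40e-3, stretch_k = 2,
                                      amplitude = 1, sim_params = NULL,
                                      n_sites = 20L,
                                      cfg = generator_config()) {
  mode <- match.arg(mode)
  if (n_replicates < 1) stop_invalid_parameter("n_replicates must be >= 1")
  with_seed(cfg$seed, lapply(seq_len(n_replicates), function(r) {
    y <- if (mode == "weibull_step") {
      onset <- rweibull(1, shape = stretch_k, scale = scale_lambda)
      amplitude * as.numeric(t_grid >= onset)
    } else {
      if (is.null(sim_params)) {
        stop_invalid_parameter("mode 'simulator' needs sim_params")
      }
      tr <- simulate_nucleation(sim_params, t_max = max(t_grid),
                                n_sites = n_sites, out_times = t_grid)
      amplitude * tr$nucleated_mass_fraction
    }
    if (cfg$noise_level > 0) {
      y <- y + cfg$noise_level * amplitude * rnorm(length(y))
    }
    kinetic_trace(t_grid, y, replicate_id = r)
  }))
}

#' Generate a synthetic sedimentation isotherm
#'
#' Forward-models the weight-average sedimentation coefficient on a
#' concentration grid and adds fractional noise. The shipped nonideal
#' scenario uses a non-associating monomer with `kS = 28` mL/g.
#'
#' @param model An [association_model].
#' @param c_grid Concentrations, mg/mL.
#' @param cfg A [generator_config].
#' @return Data frame with columns `c_mgml`, `s_w_S`, and `err` when noisy.
#' @export
gen_auc_isotherm <- function(model, c_grid, cfg = generator_config()) {
  sw <- weight_average_s(c_grid, model)
  with_seed(cfg$seed, {
    nz <- apply_noise(sw, cfg)
    out <- data.frame(c_mgml = c_grid, s_w_S = nz$I)
    if (cfg$noise_level > 0) out$err <- nz$sigma
    out
  })
}

#' Generate a synthetic FCS correlation trace
#'
#' Closed-form single-component correlation plus fractional noise.
#'
#' @param pars Named list with `G0`, `tau_D`, `kappa`.
#' @param lag_grid Lag times, seconds.
#' @param cfg A [generator_config].
#' @return Data frame with columns `lag_s`, `G`, and `err` when noisy.
#' @export
gen_fcs_trace <- function(pars = list(G0 = 1, tau_D = 1e-3, kappa = 5),
                          lag_grid = log_time_grid(1e-6, 1, 120),
                          cfg = generator_config()) {
  G <- fcs_model(lag_grid, pars$G0, pars$tau_D, pars$kappa)
  with_seed(cfg$seed, {
    nz <- apply_noise(G, cfg)
    out <- data.frame(lag_s = lag_grid, G = nz$I)
    if (cfg$noise_level > 0) out$err <- nz$sigma
    out
  })
}
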