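#' Dilution of the protein stream in a rapid mixer
#'
#' A chaotic-flow mixer dilutes the protein stock `fold`-fold into the salt
#' buffer: `c_final = c_stock / fold`.
#'
#' @param c_stock Stock concentration (`>= 0`).
#' @param fold Dilution factor (`> 1`).
#' @return Final concentration, same units as `c_stock`.
#' @export
mixer_dilution <- function(c_stock, fold) {
  if (fold <= 1) stop_invalid_parameter("fold must exceed 1 (no dilution)")
  if (any(c_stock < 0)) stop_invalid_parameter("c_stock must be >= 0")
  c_stock / fold
}

#' Sheath (buffer) concentration needed to reach a mixing target
#'
#' The protein stream carries no excess salt, so after `fold`-fold dilution
#' the salt concentration is `c_sheath * (fold - 1) / fold`. To reach a
#' target final concentration the sheath must be prepared at
#' `c_sheath = c_target * fold / (fold - 1)` — e.g. 375 mM for a 300 mM
#' target at 5x dilution.
#'
#' @param c_final_target Target final concentration (`>= 0`).
#' @param fold Dilution factor (`> 1`).
#' @return Required sheath concentration.
#' @export
sheath_concentration <- function(c_final_target, fold) {
  if (fold <= 1) stop_invalid_parameter("fold must exceed 1")
  if (any(c_final_target < 0)) stop_invalid_parameter("target must be >= 0")
  c_final_target * fold / (fold - 1)
}

#' Laminar-mixer salt concentration schedule
#'
#' Phenomenological exponential approach of the in-stream salt concentration
#' to its maximum, `c(t) = c_max (1 - exp(-t/tau))`. Reports the dead time
#' (first crossing of 50 percent of `c_max`) and whether the values inside a
#' supplied observation window stay within the configured fractional band
#' (e.g. 88-92 percent of the maximum).
#'
#' @param t Times, seconds.
#' @param c_max Asymptotic concentration.
#' @param tau Mixing time constant, seconds.
#' @param plateau_fraction_band Fractional band `c(lo, hi)` within `(0, 1]`.
#' @param window Optional observation window `c(t_lo, t_hi)`, seconds.
#' @return List with `c` (values at `t`), `dead_time`, and, when `window`
#'   is given, `in_band` (logical) and `window_fraction_range`.
#' @export
mixing_schedule <- function(t, c_max, tau, plateau_fraction_band = c(0.88, 0.92),
                            window = NULL) {
  if (length(plateau_fraction_band) != 2 ||
      plateau_fraction_band[1] >= plateau_fraction_band[2]) {
    stop_invalid_parameter("plateau_fraction_band must be c(lo, hi), lo < hi")
  }
  if (any(plateau_fraction_band <= 0) || any(plateau_fraction_band > 1)) {
    stop_invalid_parameter("band must lie in (0, 1]")
  }
  if (tau <= 0) stop_invalid_parameter("tau must be positive")
  cc <- c_max * (1 - exp(-t / tau))
  dead_time <- tau * log(2)  # closed-form first crossing of c_max/2
  out <- list(c = cc, dead_time = dead_time)
  if (!is.null(window)) {
    frac <- 1 - exp(-seq(window[1], window[2], length.out = 200) / tau)
    out$window_fraction_range <- range(frac)
    out$in_band <- all(frac >= plateau_fraction_band[1] &
                         frac <= plateau_fraction_band[2])
  }
  out
}

#' Load a run configuration from YAML
#'
#' Validates the schema: a `scenario` name, a `seed`, and optional parameter
#' blocks. Unknown top-level keys are rejected so typos fail before any
#' computation.
#'
#' @param path YAML file path.
#' @return Object of class `run_config` (a named list).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A named list with the same structure as the YAML file.
#' @export
run_config <- function(cfg) {
  allowed <- c("scenario", "seed", "noise_level", "output_dir", "units",
               "params")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown)) {
    stop_invalid_parameter(paste("unknown config keys:",
                                 paste(unknown, collapse = ", ")))
  }
  if (is.null(cfg$scenario)) stop_invalid_parameter("config needs a scenario")
  known <- c("chaotic_flow_collapse", "laminar_weibull_series",
             "auc_nonideal", "auc_two_step", "fcs_dilute_dense")
  if (!cfg$scenario %in% known) {
    stop_invalid_parameter(paste0("unknown scenario '", cfg$scenario,
                                  "'; known: ", paste(known, collapse = ", ")))
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (is.null(cfg$noise_level)) cfg$noise_level <- 0.02
  if (is.null(cfg$params)) cfg$params <- list()
  structure(cfg, class = "run_config")
}

#' Run a full generate-analyze-fit pipeline scenario
#'
#' Executes one of the shipped scenarios end to end — synthetic generation,
#' analysis, fitting — and returns a report. Idempotent given the seed.
#'
#' * `chaotic_flow_collapse`: replicate R_G(t) traces, collapse+growth fits,
#'   median time constants.
#' * `laminar_weibull_series`: assembly-metric trajectories at several
#'   quench depths, Weibull fits per depth, barrier-scaling extrapolation to
#'   a shallower quench with an observation-window verdict.
#' * `auc_nonideal`: nonideal monomer isotherm, kS recovery.
#' * `auc_two_step`: two-step isodesmic isotherm, model comparison against
#'   the isodesmic scheme and Gilbert boundary modality.
#' * `fcs_dilute_dense`: dilute/dense FCS traces, diffusion-time ratio.
#'
#' @param config A `run_config` (or plain list accepted by [run_config()]).
#' @return Object of class `pipeline_report`: a list of fit parameters,
#'   uncertainties and seeds, JSON-serializable via [write_report_json()].
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  p <- config$params
  cfg <- generator_config(seed = config$seed, noise_level = config$noise_level)
  result <- switch(
    config$scenario,
    chaotic_flow_collapse = {
      n_rep <- p$n_replicates %||% 100L
      pars <- p$kinetics %||% list(R_base = 26, A_collapse = 2,
                                   tau_collapse = 470e-6, A_growth = 3,
                                   tau_growth = 36e-3)
      traces <- gen_rg_trace(pars, n_replicates = n_rep, cfg = cfg)
      if (inherits(traces, "kinetic_trace")) traces <- list(traces)
      fits <- lapply(traces, function(tr) {
        tryCatch(fit_collapse_growth(tr), error = function(e) NULL)
      })
      fits <- Filter(Negate(is.null), fits)
      list(n_replicates = n_rep, n_converged = length(fits),
           generating = pars,
           median_tau_collapse_s = median(vapply(fits, `[[`, 1, "tau_collapse")),
           median_tau_growth_s = median(vapply(fits, `[[`, 1, "tau_growth")))
    },
    laminar_weibull_series = {
      sigmas <- p$sigmas %||% c(1.0, 1.5, 2.0)
      lambdas <- p$lambdas %||% exp(-4.2 + 1.2 / sigmas^2)
      k <- p$stretch_k %||% 2
      n_rep <- p$n_replicates %||% 50L
      tg <- log_time_grid(p$t_min %||% 1e-3, p$t_max %||% 0.5, 60)
      per_depth <- lapply(seq_along(sigmas), function(i) {
        trs <- gen_assembly_trajectories(
          tg, n_rep, mode = "weibull_step", scale_lambda = lambdas[i],
          stretch_k = k,
          cfg = generator_config(seed = config$seed + i,
                                 noise_level = config$noise_level))
        f <- fit_weibull(trs)
        list(sigma = sigmas[i], lambda = f$scale_lambda, k = f$stretch_k,
             amplitude = f$amplitude)
      })
      lam_fit <- vapply(per_depth, `[[`, 1, "lambda")
      ext <- extrapolate_timescale(sigmas, lam_fit,
                                   sigma_new = p$sigma_new %||% 0.4,
                                   window = p$window %||% 0.08)
      list(per_depth = per_depth,
           extrapolation = ext[c("a", "B", "r_squared", "lambda_pred",
                                 "lower", "upper", "exceeds_window")])
    },
    auc_nonideal = {
      m <- association_model("monomer", s1 = p$s1 %||% 2.0,
                             kS = p$kS %||% 28)
      cg <- p$c_grid %||% seq(0.5, 12, length.out = 10)
      iso <- gen_auc_isotherm(m, cg, cfg)
      f <- fit_isotherm(iso$c_mgml, iso$s_w_S, scheme = "monomer",
                        s_w_err = iso$err, fit_s1 = TRUE, fit_kS = TRUE)
      list(generating = list(s1 = m$s1, kS = m$kS),
           fitted = list(s1 = f$s1, kS = f$kS), stderr = as.list(f$stderr))
    },
    auc_two_step = {
      m <- association_model("two_step_isodesmic", K2 = p$K2 %||% 0.02,
                             K_iso = p$K_iso %||% 0.6, s1 = p$s1 %||% 2.0)
      cg <- p$c_grid %||% seq(0.2, 8, length.out = 12)
      iso <- gen_auc_isotherm(m, cg, cfg)
      f2 <- fit_isotherm(iso$c_mgml, iso$s_w_S, scheme = "two_step_isodesmic",
                         s_w_err = iso$err)
      f1 <- fit_isotherm(iso$c_mgml, iso$s_w_S, scheme = "isodesmic",
                         s_w_err = iso$err)
      g <- gilbert_asymptotic_distribution(max(cg), f2)
      list(generating = list(K2 = m$K2, K_iso = m$K_iso, s1 = m$s1),
           two_step = list(K2 = f2$K2, K_iso = f2$K_iso, s1 = f2$s1,
                           rss = f2$rss),
           isodesmic = list(K_iso = f1$K_iso, s1 = f1$s1, rss = f1$rss),
           gilbert_modality = attr(g, "modality"))
    },
    fcs_dilute_dense = {
      dil <- p$dilute %||% list(G0 = 1, tau_D = 0.2e-3, kappa = 5)
      den <- p$dense %||% list(G0 = 1, tau_D = 20e-3, kappa = 5)
      tr_dil <- gen_fcs_trace(dil, cfg = cfg)
      tr_den <- gen_fcs_trace(den, cfg = generator_config(
        seed = config$seed + 1, noise_level = config$noise_level))
      f_dil <- fcs_fit(tr_dil$lag_s, tr_dil$G, kappa = dil$kappa)
      f_den <- fcs_fit(tr_den$lag_s, tr_den$G, kappa = den$kappa,
                       tau_ref = f_dil$tau_D)
      list(dilute = list(G0 = f_dil$G0, tau_D = f_dil$tau_D),
           dense = list(G0 = f_den$G0, tau_D = f_den$tau_D,
                        relative_tau = f_den$relative_tau))
    })
  structure(list(scenario = config$scenario, seed = config$seed,
                 noise_level = config$noise_level,
                 software_version = as.character(packageVersion("phasekin")),
                 result = result),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("phasekin pipeline report\n")
  cat(sprintf("  scenario: %s (seed %s, noise %s)\n", x$scenario,
              x$seed, fmt_num(x$noise_level)))
  str(x$result, max.level = 2, give.attr = FALSE)
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `pipeline_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom utils str
NULL
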