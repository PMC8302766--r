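#' Binodal (coexistence curve) container
#'
#' Tabulated coexisting dilute-phase (`c_sat`) and dense-phase (`c_den`)
#' concentrations as a function of NaCl concentration. On load the table is
#' checked for `c_den > c_sat` pointwise and for `c_sat` strictly decreasing
#' with NaCl (the observed salting-out trend; override with
#' `allow_nonmonotonic`).
#'
#' @param nacl_mM NaCl concentrations, mM; strictly increasing.
#' @param c_sat Saturation concentrations.
#' @param c_den Dense-phase concentrations.
#' @param units Concentration units flag (`"mg/mL"` or `"mM"`).
#' @param allow_nonmonotonic Skip the monotonicity check on `c_sat`.
#' @return Object of class `binodal` (a data frame).
#' @export
binodal <- function(nacl_mM, c_sat, c_den, units = c("mg/mL", "mM"),
                    allow_nonmonotonic = FALSE) {
  units <- match.arg(units)
  n <- length(nacl_mM)
  if (length(c_sat) != n || length(c_den) != n) {
    stop_invalid_parameter("nacl_mM, c_sat, c_den lengths differ")
  }
  if (n < 2) stop_insufficient_data("binodal needs >= 2 rows")
  if (any(diff(nacl_mM) <= 0)) {
    stop_invalid_parameter("nacl_mM must be strictly increasing")
  }
  if (any(c_den <= c_sat)) {
    stop_invalid_parameter("c_den must exceed c_sat pointwise")
  }
  if (!allow_nonmonotonic && any(diff(c_sat) >= 0)) {
    stop_invalid_parameter(
      "c_sat must decrease strictly with NaCl; use allow_nonmonotonic to override")
  }
  structure(data.frame(nacl_mM = nacl_mM, c_sat = c_sat, c_den = c_den),
            units = units, class = c("binodal", "data.frame"))
}

#' Read a binodal table from CSV
#'
#' Expects columns `nacl_mM`, `csat`, `cden` (or `c_sat`, `c_den`).
#'
#' @param path CSV path.
#' @param ... Passed to [binodal()].
#' @return A [binodal].
#' @export
read_binodal_csv <- function(path, ...) {
  tab <- read.csv(path)
  nm <- names(tab)
  csat <- tab[[intersect(c("csat", "c_sat"), nm)[1]]]
  cden <- tab[[intersect(c("cden", "c_den"), nm)[1]]]
  binodal(tab$nacl_mM, csat, cden, ...)
}

#' Saturation concentration at an arbitrary NaCl concentration
#'
#' Shape-preserving monotone piecewise-cubic interpolation of
#' `log(c_sat)` versus NaCl. Extrapolation beyond the tabulated range is an
#' error unless explicitly allowed.
#'
#' @param bin A [binodal].
#' @param nacl_mM Query NaCl concentrations, mM.
#' @param extrapolate Allow queries outside the tabulated range.
#' @return Interpolated `c_sat` in the binodal's units.
#' @export
csat_at <- function(bin, nacl_mM, extrapolate = FALSE) {
  stopifnot(inherits(bin, "binodal"))
  rng <- range(bin$nacl_mM)
  if (!extrapolate && any(nacl_mM < rng[1] | nacl_mM > rng[2])) {
    stop_extrapolation(sprintf(
      "NaCl %s mM outside tabulated range [%g, %g]; set extrapolate = TRUE",
      paste(nacl_mM[nacl_mM < rng[1] | nacl_mM > rng[2]], collapse = ", "),
      rng[1], rng[2]))
  }
  f <- splinefun(bin$nacl_mM, log(bin$c_sat), method = "monoH.FC")
  exp(f(nacl_mM))
}

#' Supersaturation at a given concentration and NaCl
#'
#' `sigma = c / c_sat(NaCl) - 1` with `c_sat` from monotone interpolation of
#' the binodal. Negative values indicate a subsaturated solution.
#'
#' @param c Total protein concentration, same units as the binodal.
#' @param nacl_mM NaCl concentration, mM.
#' @param bin A [binodal].
#' @param extrapolate Allow NaCl outside the tabulated range.
#' @return Dimensionless supersaturation.
#' @export
supersaturation <- function(c, nacl_mM, bin, extrapolate = FALSE) {
  c / csat_at(bin, nacl_mM, extrapolate = extrapolate) - 1
}

#' Mass-action self-association model
#'
#' Describes reversible oligomerization of the monomer under one of three
#' schemes: `monomer_dimer` (single dimerization constant `K2`), `isodesmic`
#' (one constant `K_iso` for every addition), or `two_step_isodesmic` (a
#' weak dimerization `K2` followed by isodesmic additions at `K_iso`).
#' Oligomer sedimentation coefficients follow the hydrodynamic scaling law
#' `s_n = s1 * n^scaling_exponent` (default exponent 2/3); hydrodynamic
#' nonideality enters as `1/(1 + kS * c)` with `kS` in mL/g and `c` in
#' mg/mL.
#'
#' @param scheme `"monomer"`, `"monomer_dimer"`, `"isodesmic"`, or
#'   `"two_step_isodesmic"`.
#' @param K2 Dimerization association constant, per concentration unit.
#' @param K_iso Elongation association constant, per concentration unit.
#' @param s1 Monomer sedimentation coefficient, Svedberg.
#' @param scaling_exponent Hydrodynamic scaling exponent (default 2/3).
#' @param kS Nonideality coefficient, mL/g (default 0).
#' @return Object of class `association_model`.
#' @export
association_model <- function(scheme = c("monomer", "monomer_dimer",
                                         "isodesmic", "two_step_isodesmic"),
                              K2 = NULL, K_iso = NULL, s1 = 1,
                              scaling_exponent = 2 / 3, kS = 0) {
  scheme <- match.arg(scheme)
  if (s1 <= 0) stop_invalid_parameter("s1 must be positive")
  if (kS < 0) stop_invalid_parameter("kS must be non-negative")
  need <- switch(scheme,
                 monomer = character(),
                 monomer_dimer = "K2",
                 isodesmic = "K_iso",
                 two_step_isodesmic = c("K2", "K_iso"))
  for (p in need) {
    v <- get(p)
    if (is.null(v) || v <= 0) {
      stop_invalid_parameter(sprintf("scheme '%s' requires positive %s",
                                     scheme, p))
    }
  }
  structure(list(scheme = scheme, K2 = K2, K_iso = K_iso, s1 = s1,
                 scaling_exponent = scaling_exponent, kS = kS),
            class = "association_model")
}

#' @export
print.association_model <- function(x, ...) {
  cat("Association model:", x$scheme, "\n")
  if (!is.null(x$K2)) cat(sprintf("  K2 = %s\n", fmt_num(x$K2)))
  if (!is.null(x$K_iso)) cat(sprintf("  K_iso = %s\n", fmt_num(x$K_iso)))
  cat(sprintf("  s1 = %s S, scaling exponent = %s, kS = %s mL/g\n",
              fmt_num(x$s1), fmt_num(x$scaling_exponent), fmt_num(x$kS)))
  invisible(x)
}

# Count the modes of a binned density: smooth lightly, take local maxima
# above a noise floor, then merge peaks not separated by a substantial dip
# (at least 25% below the lower peak). Robust to the +/- one-count jitter
# that binning a finite grid produces.
count_modes <- function(g, floor_frac = 0.02, dip_frac = 0.75,
                        smooth_width = 5L) {
  n <- length(g)
  if (n < 3) return(if (max(g) > 0) 1L else 0L)
  k <- min(smooth_width, n)
  gs <- as.numeric(stats::filter(g, rep(1 / k, k), sides = 2))
  gs[is.na(gs)] <- g[is.na(gs)]
  thr <- floor_frac * max(gs)
  gp <- c(-Inf, gs, -Inf)
  cand <- which(vapply(seq_len(n), function(j) {
    gp[j + 1] > thr && gp[j + 1] >= gp[j] && gp[j + 1] >= gp[j + 2]
  }, logical(1)))
  if (!length(cand)) return(0L)
  runs <- split(cand, cumsum(c(1, diff(cand) != 1)))
  cand <- vapply(runs, function(r) r[which.max(gs[r])], numeric(1))
  cand <- cand[order(-gs[cand])]
  acc <- cand[1]
  for (cd in cand[-1]) {
    distinct <- TRUE
    for (a in acc) {
      valley <- min(gs[seq(min(a, cd), max(a, cd))])
      if (valley > dip_frac * min(gs[cd], gs[a])) { distinct <- FALSE; break }
    }
    if (distinct) acc <- c(acc, cd)
  }
  length(acc)
}

# Free monomer concentration solving the mass balance for each scheme.
solve_monomer <- function(c_tot, model) {
  switch(model$scheme,
         monomer = c_tot,
         monomer_dimer = {
           # rationalized quadratic root, stable as K2 -> 0
           K <- model$K2
           2 * c_tot / (1 + sqrt(1 + 8 * K * c_tot))
         },
         isodesmic = {
           # c_tot = c1 / (1 - K c1)^2; rationalized root with K c1 < 1,
           # stable as K -> 0
           K <- model$K_iso
           2 * c_tot / (1 + 2 * K * c_tot + sqrt(1 + 4 * K * c_tot))
         },
         two_step_isodesmic = {
           K2 <- model$K2; K <- model$K_iso
           g <- function(c1) {
             x <- K * c1
             c1 + (K2 / K^2) * (x / (1 - x)^2 - x) - c_tot
           }
           up <- min(c_tot, (1 - 1e-12) / K)
           out <- tryCatch(
             uniroot(g, c(min(1e-300, up / 2), up), tol = 1e-14 * max(c_tot, 1)),
             error = function(e) stop(pk_condition(
               "phasekin_mass_balance_error",
               paste("no monomer concentration with K_iso*c1 < 1:",
                     conditionMessage(e)))))
           out$root
         })
}

#' Species size distribution of a self-associating system
#'
#' Solves the mass balance for the free-monomer concentration and returns
#' the oligomer concentrations: isodesmic `c_n = c1 (K_iso c1)^(n-1)`;
#' two-step `c_2 = K2 c1^2`, `c_n = c_2 (K_iso c1)^(n-2)` for `n >= 2`.
#' `n_max` is grown automatically until the truncated tail carries less than
#' `1e-6` of the total mass.
#'
#' @param c_tot Total monomer-equivalent concentration (`> 0`).
#' @param model An [association_model].
#' @param n_max Initial truncation size (auto-grown).
#' @return Object of class `species_distribution`: data frame with columns
#'   `n`, `c_n`, `mass_fraction`; the free-monomer concentration is attached
#'   as attribute `c1`.
#' @export
species_distribution <- function(c_tot, model, n_max = 200L) {
  stopifnot(inherits(model, "association_model"))
  if (c_tot <= 0) stop_invalid_parameter("c_tot must be positive")
  c1 <- solve_monomer(c_tot, model)
  conc_of <- function(n) {
    switch(model$scheme,
           monomer = ifelse(n == 1, c1, 0),
           monomer_dimer = ifelse(n == 1, c1,
                           ifelse(n == 2, model$K2 * c1^2, 0)),
           isodesmic = c1 * (model$K_iso * c1)^(n - 1),
           two_step_isodesmic = ifelse(
             n == 1, c1,
             model$K2 * c1^2 * (model$K_iso * c1)^(n - 2)))
  }
  if (model$scheme %in% c("monomer", "monomer_dimer")) {
    n <- if (model$scheme == "monomer") 1L else 1:2
  } else {
    n_max <- max(as.integer(n_max), 10L)
    repeat {
      n <- seq_len(n_max)
      cn <- conc_of(n)
      tail_mass <- c_tot - sum(n * cn)
      if (tail_mass < 1e-6 * c_tot || n_max >= 1e6) break
      n_max <- n_max * 4L
    }
  }
  cn <- conc_of(n)
  out <- data.frame(n = as.integer(n), c_n = cn,
                    mass_fraction = n * cn / c_tot)
  structure(out, c1 = c1, c_tot = c_tot, model = model,
            class = c("species_distribution", "data.frame"))
}

#' Weight-average sedimentation coefficient
#'
#' `s_w = sum(n c_n s_n) / sum(n c_n)` with `s_n = s1 * n^scaling_exponent`,
#' multiplied by the nonideality factor `1/(1 + kS * c/1000)` when `kS > 0`
#' (`kS` in mL/g, `c_tot` in mg/mL).
#'
#' @param c_tot Total concentration, mg/mL (vectorized).
#' @param model An [association_model].
#' @return Weight-average sedimentation coefficient(s), Svedberg.
#' @export
weight_average_s <- function(c_tot, model) {
  stopifnot(inherits(model, "association_model"))
  vapply(c_tot, function(ct) {
    sp <- species_distribution(ct, model)
    sn <- model$s1 * sp$n^model$scaling_exponent
    sw <- sum(sp$n * sp$c_n * sn) / sum(sp$n * sp$c_n)
    if (model$kS > 0) sw <- sw / (1 + model$kS * ct / 1000)
    sw
  }, numeric(1))
}

#' Fit a self-association model to an s_w isotherm
#'
#' Nonlinear least-squares fit of [weight_average_s()] to measured
#' weight-average sedimentation coefficients versus concentration.
#'
#' @param c Concentrations, mg/mL (`>= 5` points).
#' @param s_w Weight-average sedimentation coefficients, Svedberg.
#' @param scheme Association scheme, see [association_model()].
#' @param s_w_err Optional uncertainties (inverse-variance weights).
#' @param fit_s1 Fit the monomer s-value (default `TRUE`).
#' @param fit_kS Fit the nonideality coefficient (default `FALSE`).
#' @param s1,kS Fixed values (or start values when fitted).
#' @param scaling_exponent Hydrodynamic scaling exponent, fixed.
#' @param start Optional named list of start values for the constants.
#' @return An [association_model] with `stderr`, `rss`, `aic`, `n_points`.
#' @export
fit_isotherm <- function(c, s_w, scheme = c("monomer", "monomer_dimer",
                                            "isodesmic",
                                            "two_step_isodesmic"),
                         s_w_err = NULL, fit_s1 = TRUE, fit_kS = FALSE,
                         s1 = NULL, kS = 0, scaling_exponent = 2 / 3,
                         start = NULL) {
  scheme <- match.arg(scheme)
  if (length(c) != length(s_w)) stop_invalid_parameter("c and s_w lengths differ")
  if (length(c) < 5) stop_insufficient_data("need >= 5 concentrations")
  d <- data.frame(c = c, s_w = s_w)
  w <- if (!is.null(s_w_err) && all(s_w_err > 0)) 1 / s_w_err^2 else
    rep(1, length(c))

  s1_0 <- if (!is.null(s1)) s1 else min(s_w) / max(1e-12, 1)
  p0 <- list()
  lower <- c(); upper <- c()
  add_par <- function(p0, name, value, lo = 1e-12, hi = Inf) {
    p0[[name]] <- value
    lower <<- c(lower, setNames(lo, name))
    upper <<- c(upper, setNames(hi, name))
    p0
  }
  if (scheme %in% c("monomer_dimer", "two_step_isodesmic")) {
    p0 <- add_par(p0, "K2", 1 / max(c))
  }
  if (scheme %in% c("isodesmic", "two_step_isodesmic")) {
    p0 <- add_par(p0, "K_iso", 1 / max(c))
  }
  if (fit_s1) p0 <- add_par(p0, "s1", s1_0)
  if (fit_kS) p0 <- add_par(p0, "kS", max(kS, 1))
  if (!is.null(start)) p0 <- modifyList(p0, start[names(start) %in% names(p0)])
  if (length(p0) == 0) stop_invalid_parameter("nothing to fit")

  fwd <- function(c, K2 = NA, K_iso = NA, s1_par = s1_0, kS_par = kS) {
    m <- association_model(scheme,
                           K2 = if (is.na(K2)) NULL else K2,
                           K_iso = if (is.na(K_iso)) NULL else K_iso,
                           s1 = s1_par, scaling_exponent = scaling_exponent,
                           kS = kS_par)
    weight_average_s(c, m)
  }
  # assemble the nls formula respecting which parameters are free
  args <- c("c",
            if ("K2" %in% names(p0)) "K2 = K2" else
              if (scheme %in% c("monomer_dimer", "two_step_isodesmic")) "K2 = NA",
            if ("K_iso" %in% names(p0)) "K_iso = K_iso" else
              if (scheme %in% c("isodesmic", "two_step_isodesmic")) "K_iso = NA",
            if (fit_s1) "s1_par = s1" else sprintf("s1_par = %.17g", s1_0),
            if (fit_kS) "kS_par = kS" else sprintf("kS_par = %.17g", kS))
  form <- as.formula(paste("s_w ~ fwd(", paste(args, collapse = ", "), ")"),
                     env = environment())
  fit <- tryCatch(
    nlsLM(form, data = d, start = p0, weights = w,
          lower = unname(lower[names(p0)]), upper = unname(upper[names(p0)]),
          control = nls.control(maxiter = 500)),
    error = function(e) stop_fit_failure(
      paste("isotherm fit did not converge:", conditionMessage(e)),
      diagnostics = list(start = p0)))
  cf <- as.list(coef(fit))
  at_bound <- names(cf)[vapply(names(cf), function(nm) {
    isTRUE(abs(cf[[nm]] - lower[[nm]]) < 1e-10 * max(abs(cf[[nm]]), 1))
  }, logical(1))]
  out <- association_model(
    scheme,
    K2 = if ("K2" %in% names(cf)) cf$K2 else
      if (scheme %in% c("monomer_dimer", "two_step_isodesmic")) NULL else NULL,
    K_iso = if ("K_iso" %in% names(cf)) cf$K_iso else NULL,
    s1 = if (fit_s1) cf$s1 else s1_0,
    scaling_exponent = scaling_exponent,
    kS = if (fit_kS) cf$kS else kS)
  out$stderr <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                         error = function(e) NULL)
  out$rss <- sum(w * (d$s_w - predict(fit))^2)
  out$aic <- AIC(fit)
  out$n_points <- length(c)
  out$at_bound <- at_bound
  out
}

#' Gilbert asymptotic boundary shape
#'
#' Diffusion-free, rapid-exchange asymptotic sedimentation boundary of a
#' self-associating system. Each concentration level `c` moves with the
#' constituent-flux velocity `s*(c) = d(c * s_w(c))/dc`; the boundary shape
#' is `g(s*) = dc/ds*`, computed by binning the mass `dc` of a fine
#' concentration grid into `s*` bins so that the integral of `g` equals the
#' plateau concentration regardless of whether `s*(c)` is monotone (a
#' non-monotone branch is reported via the `multivalued` attribute rather
#' than raised as an error).
#'
#' @param c_plateau Plateau (loading) concentration, mg/mL.
#' @param model An [association_model].
#' @param n_bins Number of `s*` bins for the returned shape.
#' @param n_c Size of the internal concentration grid.
#' @param noise_floor Fraction of the maximum of `g` below which local
#'   maxima are ignored when counting modes.
#' @return Object of class `gilbert_distribution`: data frame with columns
#'   `s_star` (bin centers) and `g`, with attributes `integral`, `modality`,
#'   `spike` (logical: non-associating single-velocity boundary) and
#'   `multivalued`.
#' @export
gilbert_asymptotic_distribution <- function(c_plateau, model, n_bins = 120L,
                                            n_c = 4000L,
                                            noise_floor = 0.02) {
  stopifnot(inherits(model, "association_model"))
  if (c_plateau <= 0) stop_invalid_parameter("c_plateau must be positive")
  cg <- seq(c_plateau * 1e-4, c_plateau, length.out = n_c)
  sw <- weight_average_s(cg, model)
  sstar <- grid_gradient(cg * sw, cg)
  dc <- c(cg[1], diff(cg))  # mass below the first grid point included

  if (diff(range(sstar)) < 1e-9 * max(abs(sstar))) {
    # constant boundary velocity: all mass sediments as a single spike
    out <- data.frame(s_star = mean(sstar), g = NA_real_)
    return(structure(out, integral = c_plateau, modality = 1L,
                     spike = TRUE, multivalued = FALSE,
                     class = c("gilbert_distribution", "data.frame")))
  }
  multivalued <- any(diff(sstar) < 0)
  edges <- seq(min(sstar), max(sstar), length.out = n_bins + 1)
  idx <- findInterval(sstar, edges, rightmost.closed = TRUE, all.inside = TRUE)
  mass <- vapply(seq_len(n_bins), function(j) sum(dc[idx == j]), numeric(1))
  width <- diff(edges)
  g <- mass / width
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  modality <- count_modes(g, floor_frac = noise_floor)
  structure(data.frame(s_star = centers, g = g),
            integral = sum(mass), modality = as.integer(modality),
            spike = FALSE, multivalued = multivalued,
            class = c("gilbert_distribution", "data.frame"))
}

#' @export
print.gilbert_distribution <- function(x, ...) {
  cat("Gilbert asymptotic boundary shape\n")
  if (isTRUE(attr(x, "spike"))) {
    cat(sprintf("  single-velocity spike at s* = %s S (mass %s)\n",
                fmt_num(x$s_star[1]), fmt_num(attr(x, "integral"))))
  } else {
    cat(sprintf("  s* in [%s, %s] S, %d bins, integral = %s, modality = %d%s\n",
                fmt_num(min(x$s_star)), fmt_num(max(x$s_star)), nrow(x),
                fmt_num(attr(x, "integral")), attr(x, "modality"),
                if (isTRUE(attr(x, "multivalued")))
                  " (multi-valued s*(c) branch folded in)" else ""))
  }
  invisible(x)
}

#' Single-component FCS correlation model
#'
#' `G(tau) = G0 * (1 + tau/tau_D)^-1 * (1 + tau/(kappa^2 tau_D))^-1/2`:
#' 3D diffusion through a Gaussian confocal volume with axial ratio `kappa`.
#'
#' @param tau Lag times, seconds.
#' @param G0 Correlation amplitude.
#' @param tau_D Diffusion lag time, seconds.
#' @param kappa Axial ratio of the confocal volume (`> 1`).
#' @return Model correlation values.
#' @export
fcs_model <- function(tau, G0, tau_D, kappa) {
  if (tau_D <= 0) stop_invalid_parameter("tau_D must be positive")
  if (kappa <= 1) stop_invalid_parameter("kappa must exceed 1")
  G0 / (1 + tau / tau_D) / sqrt(1 + tau / (kappa^2 * tau_D))
}

#' Fit the FCS correlation model
#'
#' Least-squares fit of [fcs_model()]; `kappa` may be fixed (default) or
#' fitted. When a reference diffusion time is supplied, the relative
#' diffusion time (viscosity proxy) is reported.
#'
#' @param lags Lag times, seconds.
#' @param G Correlation values.
#' @param kappa Axial ratio; fixed unless `fit_kappa = TRUE`.
#' @param fit_kappa Fit `kappa` as a free parameter.
#' @param tau_ref Optional reference `tau_D` for `relative_tau`.
#' @return Object of class `fcs_fit` with `G0`, `tau_D`, `kappa`,
#'   `relative_tau`, `stderr`, `rss`.
#' @export
fcs_fit <- function(lags, G, kappa = 5, fit_kappa = FALSE, tau_ref = NULL) {
  if (length(lags) != length(G)) stop_invalid_parameter("lags and G lengths differ")
  d <- data.frame(tau = lags, G = G)
  tau0 <- lags[which.min(abs(G - max(G) / 2))]
  s <- list(G0 = max(G), tau_D = tau0)
  if (fit_kappa) s$kappa <- kappa
  fit <- tryCatch({
    if (fit_kappa) {
      nlsLM(G ~ fcs_model(tau, G0, tau_D, kappa), data = d, start = s,
            lower = c(G0 = 1e-12, tau_D = 1e-12, kappa = 1 + 1e-6),
            control = nls.control(maxiter = 500))
    } else {
      kap <- kappa
      nlsLM(G ~ fcs_model(tau, G0, tau_D, kap), data = d, start = s,
            lower = c(G0 = 1e-12, tau_D = 1e-12),
            control = nls.control(maxiter = 500))
    }
  }, error = function(e) stop_fit_failure(
    paste("FCS fit did not converge:", conditionMessage(e)),
    diagnostics = list(start = s)))
  cf <- as.list(coef(fit))
  if (!fit_kappa) cf$kappa <- kappa
  structure(list(G0 = cf$G0, tau_D = cf$tau_D, kappa = cf$kappa,
                 relative_tau = if (!is.null(tau_ref)) cf$tau_D / tau_ref else
                   NA_real_,
                 stderr = tryCatch(summary(fit)$coefficients[, "Std. Error"],
                                   error = function(e) NULL),
                 rss = sum((d$G - predict(fit))^2)),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat("FCS correlation fit\n")
  cat(sprintf("  G0 = %s, tau_D = %s s, kappa = %s\n", fmt_num(x$G0),
              fmt_num(x$tau_D), fmt_num(x$kappa)))
  if (!is.na(x$relative_tau)) {
    cat(sprintf("  relative tau_D = %s\n", fmt_num(x$relative_tau)))
  }
  invisible(x)
}

#' Quadratic trend of relative diffusion time with NaCl
#'
#' Least-squares second-order polynomial of the relative FCS diffusion time
#' (apparent dense-phase viscosity) against NaCl concentration.
#'
#' @param nacl_mM NaCl concentrations, mM (`>= 4` points).
#' @param relative_tau Relative diffusion times.
#' @return List with `coefficients` (intercept, linear, quadratic),
#'   `r_squared`, and the `lm` fit.
#' @export
viscosity_trend <- function(nacl_mM, relative_tau) {
  if (length(nacl_mM) != length(relative_tau)) {
    stop_invalid_parameter("lengths differ")
  }
  if (length(nacl_mM) < 4) {
    stop_insufficient_data("need >= 4 points for a quadratic trend")
  }
  fit <- lm(relative_tau ~ nacl_mM + I(nacl_mM^2))
  list(coefficients = setNames(coef(fit),
                               c("intercept", "linear", "quadratic")),
       r_squared = suppressWarnings(summary(fit))$r.squared, fit = fit)
}

#' @importFrom stats AIC as.formula
#' @importFrom utils read.csv
NULL
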