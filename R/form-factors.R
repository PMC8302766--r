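#' Debye form factor of an ideal Gaussian chain
#'
#' P(q) = 2 (exp(-x) + x - 1) / x^2 with x = (q Rg)^2. This is the default
#' scattering model for the disordered monomer; P(0) = 1 and P decreases
#' monotonically with q.
#'
#' @param q Momentum transfer, inverse angstrom (vectorized, `q >= 0`).
#' @param Rg Radius of gyration, angstrom (`Rg > 0`).
#' @return Dimensionless P(q) in (0, 1].
#' @export
debye_form_factor <- function(q, Rg) {
  if (!is.numeric(Rg) || length(Rg) != 1L || !is.finite(Rg) || Rg <= 0) {
    stop_invalid_parameter("Rg must be a single positive number")
  }
  if (any(q < 0)) stop_invalid_parameter("q must be non-negative")
  x <- (q * Rg)^2
  p <- ifelse(x < 1e-8,
              1 - x / 3 + x^2 / 12,     # series, avoids 0/0 at q = 0
              2 * (exp(-x) + x - 1) / x^2)
  as.numeric(p)
}

#' Generalized polymer form factor with scaling exponent nu
#'
#' Form factor of a polymer with apparent Flory scaling exponent `nu`
#' (excluded-volume generalized Gaussian coil, written with lower incomplete
#' gamma functions):
#' \deqn{P(q) = \frac{1}{\nu U^{1/2\nu}}\gamma(1/2\nu, U) -
#'              \frac{1}{\nu U^{1/\nu}}\gamma(1/\nu, U)}
#' with \eqn{U = (2\nu+1)(2\nu+2) q^2 R_g^2 / 6}. At `nu = 0.5` this reduces
#' exactly to [debye_form_factor()]; `nu < 0.5` models compacted chains.
#'
#' @param q Momentum transfer, inverse angstrom (`q >= 0`).
#' @param Rg Radius of gyration, angstrom (`Rg > 0`).
#' @param nu Apparent scaling exponent, in `[0.33, 1]`.
#' @return Dimensionless P(q); P(0) = 1.
#' @export
generalized_polymer_form_factor <- function(q, Rg, nu) {
  if (!is.numeric(Rg) || length(Rg) != 1L || !is.finite(Rg) || Rg <= 0) {
    stop_invalid_parameter("Rg must be a single positive number")
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) ||
      nu < 0.33 || nu > 1) {
    stop_invalid_parameter("nu must lie in [0.33, 1]")
  }
  if (any(q < 0)) stop_invalid_parameter("q must be non-negative")
  U <- (2 * nu + 1) * (2 * nu + 2) * (q * Rg)^2 / 6
  a1 <- 1 / (2 * nu)
  a2 <- 1 / nu
  lig <- function(a, u) pgamma(u, shape = a) * gamma(a)  # lower incomplete
  p <- numeric(length(U))
  tiny <- U < 1e-10
  p[tiny] <- 1
  u <- U[!tiny]
  if (length(u)) {
    p[!tiny] <- lig(a1, u) / (nu * u^a1) - lig(a2, u) / (nu * u^a2)
  }
  as.numeric(p)
}

#' Form-factor model container
#'
#' @param kind `"gaussian_chain"` (Debye) or `"generalized_polymer"`.
#' @param Rg Radius of gyration, angstrom.
#' @param I0 Forward intensity.
#' @param nu Scaling exponent (generalized kind only).
#' @return An object of class `form_factor_model`.
#' @export
form_factor_model <- function(kind = c("gaussian_chain", "generalized_polymer"),
                              Rg, I0 = 1, nu = NULL) {
  kind <- match.arg(kind)
  if (Rg <= 0) stop_invalid_parameter("Rg must be positive")
  if (I0 <= 0) stop_invalid_parameter("I0 must be positive")
  if (kind == "generalized_polymer") {
    if (is.null(nu)) stop_invalid_parameter("generalized_polymer needs nu")
    if (nu < 0.33 || nu > 1) stop_invalid_parameter("nu must lie in [0.33, 1]")
  } else {
    nu <- NULL
  }
  structure(list(kind = kind, Rg = Rg, I0 = I0, nu = nu),
            class = "form_factor_model")
}

#' Evaluate a form-factor model intensity I(q)
#'
#' @param model A [form_factor_model].
#' @param q Momentum transfer, inverse angstrom.
#' @return Model intensity `I0 * P(q)`.
#' @export
form_factor_intensity <- function(model, q) {
  stopifnot(inherits(model, "form_factor_model"))
  p <- if (model$kind == "gaussian_chain") {
    debye_form_factor(q, model$Rg)
  } else {
    generalized_polymer_form_factor(q, model$Rg, model$nu)
  }
  model$I0 * p
}

#' @export
print.form_factor_model <- function(x, ...) {
  cat("Form-factor model:", x$kind, "\n")
  cat(sprintf("  Rg = %s Angstrom, I0 = %s", fmt_num(x$Rg), fmt_num(x$I0)))
  if (!is.null(x$nu)) cat(sprintf(", nu = %s", fmt_num(x$nu)))
  cat("\n")
  if (!is.null(x$stderr)) {
    cat("  stderr:", paste(names(x$stderr), fmt_num(x$stderr, 3),
                           sep = " = ", collapse = ", "), "\n")
  }
  if (!is.null(x$rel_rms)) {
    cat(sprintf("  relative RMS residual = %s%s\n", fmt_num(x$rel_rms, 3),
                if (isTRUE(x$flagged)) "  [FLAGGED: poor fit]" else ""))
  }
  invisible(x)
}

#' Fit a monomer form factor to a SAXS curve
#'
#' Least-squares fit of `I0 * P(q; Rg[, nu])` to a curve, optionally
#' restricted to a q-window. Weighted by `1/sigmaI^2` when uncertainties are
#' present. The relative RMS residual is reported and the fit is flagged when
#' it exceeds `flag_threshold` — the signature of a low-angle upturn from
#' mesoscopic clusters contaminating the monomer window.
#'
#' @param curve A [saxs_curve].
#' @param model_kind `"gaussian_chain"` or `"generalized_polymer"`.
#' @param q_window Optional `c(q_lo, q_hi)` restricting the fitted range.
#' @param flag_threshold Relative RMS residual above which the fit is
#'   flagged (default 0.02, i.e. 2 percent).
#' @param start Optional named list of start values (`I0`, `Rg`, `nu`).
#' @return A [form_factor_model] with additional fields `stderr`, `rel_rms`,
#'   `flagged`, `n_points`, `q_window`.
#' @export
fit_form_factor <- function(curve,
                            model_kind = c("gaussian_chain",
                                           "generalized_polymer"),
                            q_window = NULL, flag_threshold = 0.02,
                            start = NULL) {
  stopifnot(inherits(curve, "saxs_curve"))
  model_kind <- match.arg(model_kind)
  dat <- as.data.frame(curve)
  if (!is.null(q_window)) {
    if (length(q_window) != 2 || q_window[1] >= q_window[2]) {
      stop_invalid_parameter("q_window must be c(q_lo, q_hi) with q_lo < q_hi")
    }
    dat <- dat[dat$q >= q_window[1] & dat$q <= q_window[2], , drop = FALSE]
  }
  if (nrow(dat) < 5) stop_insufficient_data("fewer than 5 points in q-window")
  w <- if (!is.null(dat$sigmaI) && all(dat$sigmaI > 0)) 1 / dat$sigmaI^2 else
    rep(1, nrow(dat))

  # crude Guinier-style start values from the lowest-q third of the window
  nlo <- max(5L, ceiling(nrow(dat) / 3))
  lo <- head(dat, nlo)
  sl <- unname(coef(lm(log(pmax(lo$I, .Machine$double.eps)) ~ I(lo$q^2))))
  Rg0 <- if (is.finite(sl[2]) && sl[2] < 0) sqrt(-3 * sl[2]) else 1 / mean(dat$q)
  I00 <- exp(sl[1])
  s <- list(I0 = I00, Rg = Rg0)
  if (model_kind == "generalized_polymer") s$nu <- 0.5
  if (!is.null(start)) s <- modifyList(s, start)

  fit <- tryCatch({
    if (model_kind == "gaussian_chain") {
      nlsLM(I ~ I0 * debye_form_factor(q, Rg), data = dat,
            start = s[c("I0", "Rg")], weights = w,
            lower = c(I0 = 1e-12, Rg = 1e-6),
            control = nls.control(maxiter = 200))
    } else {
      nlsLM(I ~ I0 * generalized_polymer_form_factor(q, Rg, nu), data = dat,
            start = s[c("I0", "Rg", "nu")], weights = w,
            lower = c(I0 = 1e-12, Rg = 1e-6, nu = 0.33),
            upper = c(I0 = Inf, Rg = Inf, nu = 1),
            control = nls.control(maxiter = 200))
    }
  }, error = function(e) {
    stop_fit_failure(paste("form-factor fit did not converge:",
                           conditionMessage(e)),
                     diagnostics = list(start = s, n_points = nrow(dat)))
  })
  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  pred <- predict(fit)
  rel_rms <- sqrt(mean(((dat$I - pred) / pred)^2))
  out <- form_factor_model(model_kind, Rg = cf[["Rg"]], I0 = cf[["I0"]],
                           nu = if ("nu" %in% names(cf)) cf[["nu"]] else NULL)
  out$stderr <- setNames(as.numeric(se), names(cf))
  out$rel_rms <- rel_rms
  out$flagged <- rel_rms > flag_threshold
  out$n_points <- nrow(dat)
  out$q_window <- range(dat$q)
  out
}

#' Guinier analysis of a SAXS curve
#'
#' Linear fit of `ln I` against `q^2` on a low-q window selected iteratively
#' so that `q * Rg <= qRg_max`. Returns `Rg = sqrt(-3 * slope)` and `I0`,
#' with standard errors propagated from the linear regression.
#'
#' @param curve A [saxs_curve].
#' @param qRg_max Upper bound on `q * Rg` for the fitted window
#'   (default 1.3, standard practice).
#' @param min_points Minimum number of points required in the window.
#' @return An object of class `guinier_result` with fields `Rg`, `I0`,
#'   `q_window`, `stderr_Rg`, `stderr_I0`, `n_points`, `qRg_max`.
#' @export
guinier_fit <- function(curve, qRg_max = 1.3, min_points = 5L) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (qRg_max <= 0) stop_invalid_parameter("qRg_max must be positive")
  dat <- as.data.frame(curve)
  if (any(dat$I <= 0)) {
    dat <- dat[dat$I > 0, , drop = FALSE]
  }
  n <- nrow(dat)
  if (n < min_points) stop_insufficient_data("too few positive-I points")

  fit_window <- function(d) {
    w <- if (!is.null(d$sigmaI) && all(d$sigmaI > 0)) (d$I / d$sigmaI)^2 else
      rep(1, nrow(d))
    lm(log(I) ~ I(q^2), data = d, weights = w)
  }

  # start from the lowest-q points, then iterate the q*Rg cut
  idx_max <- max(min_points, ceiling(n / 3))
  sel <- seq_len(min(idx_max, n))
  Rg <- NA_real_
  for (iter in 1:25) {
    fw <- fit_window(dat[sel, , drop = FALSE])
    slope <- coef(fw)[2]
    if (!is.finite(slope) || slope >= 0) {
      stop(pk_condition("phasekin_non_guinier",
                        "non-negative Guinier slope: not a Guinier regime"))
    }
    Rg_new <- sqrt(-3 * slope)
    sel_new <- which(dat$q * Rg_new <= qRg_max)
    if (length(sel_new) < min_points) {
      stop_insufficient_data(sprintf(
        "only %d points satisfy q*Rg <= %.3g (Rg estimate %.3g Angstrom)",
        length(sel_new), qRg_max, Rg_new))
    }
    if (identical(sel_new, sel) && is.finite(Rg) &&
        abs(Rg_new - Rg) < 1e-10 * Rg_new) {
      Rg <- Rg_new
      break
    }
    converged_window <- identical(sel_new, sel)
    sel <- sel_new
    Rg <- Rg_new
    if (converged_window) break
  }
  fw <- fit_window(dat[sel, , drop = FALSE])
  sm <- suppressWarnings(summary(fw))$coefficients  # zero-residual data warns
  slope <- fw$coefficients[2]
  Rg <- sqrt(-3 * slope)
  se_slope <- sm[2, "Std. Error"]
  se_Rg <- (3 / (2 * Rg)) * se_slope
  I0 <- exp(fw$coefficients[1])
  se_I0 <- I0 * sm[1, "Std. Error"]
  structure(list(Rg = as.numeric(Rg), I0 = as.numeric(I0),
                 q_window = range(dat$q[sel]),
                 stderr_Rg = as.numeric(se_Rg), stderr_I0 = as.numeric(se_I0),
                 n_points = length(sel), qRg_max = qRg_max),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat("Guinier fit\n")
  cat(sprintf("  Rg = %s +/- %s Angstrom\n", fmt_num(x$Rg),
              fmt_num(x$stderr_Rg, 3)))
  cat(sprintf("  I0 = %s +/- %s\n", fmt_num(x$I0), fmt_num(x$stderr_I0, 3)))
  cat(sprintf("  window: q in [%s, %s] (%d points, q*Rg <= %s)\n",
              fmt_num(x$q_window[1]), fmt_num(x$q_window[2]), x$n_points,
              fmt_num(x$qRg_max)))
  invisible(x)
}

#' Low-angle assembly metric
#'
#' Quantifies mesoscopic cluster volume as the excess of measured intensity
#' over the calculated monomer form factor at the smallest measured angles:
#' the mean over a low-q window of `I_exp - I_monomer`, by default divided by
#' the monomer forward intensity so the metric is dimensionless and
#' comparable across quench depths. Zero for a pure monomer curve; grows
#' linearly with added low-angle excess.
#'
#' @param curve A [saxs_curve].
#' @param monomer A [form_factor_model] describing the monomer.
#' @param q_window Optional `c(q_lo, q_hi)`; default the 5 lowest-q points.
#' @param normalization `"monomer_I0"` (default) or `"none"`.
#' @return An object of class `assembly_metric_point`: a list with
#'   `t_after_mix`, `value`, `n_points_used`.
#' @export
assembly_metric <- function(curve, monomer, q_window = NULL,
                            normalization = c("monomer_I0", "none")) {
  stopifnot(inherits(curve, "saxs_curve"),
            inherits(monomer, "form_factor_model"))
  normalization <- match.arg(normalization)
  dat <- as.data.frame(curve)
  if (is.null(q_window)) {
    sel <- seq_len(min(5L, nrow(dat)))
  } else {
    if (q_window[1] < min(dat$q) - 1e-12 || q_window[2] > max(dat$q) + 1e-12) {
      stop_invalid_parameter("q_window must lie inside the curve's q-range")
    }
    sel <- which(dat$q >= q_window[1] & dat$q <= q_window[2])
  }
  if (length(sel) < 3) {
    stop_insufficient_data("assembly metric window needs >= 3 points")
  }
  excess <- dat$I[sel] - form_factor_intensity(monomer, dat$q[sel])
  value <- mean(excess)
  if (normalization == "monomer_I0") value <- value / monomer$I0
  structure(list(t_after_mix = attr(curve, "t_after_mix"),
                 value = as.numeric(value),
                 n_points_used = length(sel),
                 normalization = normalization),
            class = "assembly_metric_point")
}

#' @export
print.assembly_metric_point <- function(x, ...) {
  cat(sprintf("Assembly metric: %s (%d points, normalization %s",
              fmt_num(x$value), x$n_points_used, x$normalization))
  if (!is.na(x$t_after_mix)) cat(sprintf(", t = %s s", fmt_num(x$t_after_mix)))
  cat(")\n")
  invisible(x)
}

#' Assembly-metric time series from a list of curves
#'
#' Applies [assembly_metric()] to each curve and collects a tidy time series.
#'
#' @param curves List of [saxs_curve] objects with `t_after_mix` set.
#' @param monomer A [form_factor_model].
#' @param ... Passed to [assembly_metric()].
#' @return Data frame with columns `t_s`, `metric`, `n_points`.
#' @export
assembly_metric_series <- function(curves, monomer, ...) {
  pts <- lapply(curves, assembly_metric, monomer = monomer, ...)
  data.frame(t_s = vapply(pts, `[[`, numeric(1), "t_after_mix"),
             metric = vapply(pts, `[[`, numeric(1), "value"),
             n_points = vapply(pts, `[[`, integer(1), "n_points_used"))
}

#' Write an assembly-metric time series to CSV
#'
#' @param series Data frame from [assembly_metric_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assembly_series_csv <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' @importFrom stats pgamma
#' @importFrom utils write.csv
NULL
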