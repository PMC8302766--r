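#' Kinetic trace container
#'
#' A time series of one kinetic observable: chain radius of gyration (R_G,
#' angstrom) or the dimensionless assembly metric.
#'
#' @param t Time, seconds; strictly increasing, positive.
#' @param y Observable values, finite.
#' @param y_err Optional uncertainties, same units as `y`.
#' @param replicate_id Optional replicate identifier.
#' @return Object of class `kinetic_trace` (a data frame).
#' @export
kinetic_trace <- function(t, y, y_err = NULL, replicate_id = NA) {
  t <- as.numeric(t); y <- as.numeric(y)
  if (length(t) != length(y)) stop_invalid_parameter("t and y lengths differ")
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop_invalid_parameter("t must be finite and positive")
  }
  if (any(diff(t) <= 0)) stop_invalid_parameter("t must be strictly increasing")
  if (any(!is.finite(y))) stop_invalid_parameter("y must be finite")
  df <- data.frame(t = t, y = y)
  if (!is.null(y_err)) {
    if (length(y_err) != length(t)) {
      stop_invalid_parameter("y_err length must match t")
    }
    df$y_err <- as.numeric(y_err)
  }
  structure(df, replicate_id = replicate_id,
            class = c("kinetic_trace", "data.frame"))
}

cg_model <- function(t, R_base, A_collapse, tau_collapse, A_growth,
                     tau_growth) {
  R_base + A_collapse * exp(-t / tau_collapse) +
    A_growth * (1 - exp(-t / tau_growth))
}

#' Fit the collapse-and-growth model to an R_G(t) trace
#'
#' Fits the sum of an exponential collapse and an exponential growth,
#' \deqn{y(t) = R_{base} + A_c e^{-t/\tau_c} + A_g (1 - e^{-t/\tau_g}),}
#' describing fast chain compaction followed by slower assembly-driven
#' growth of the apparent radius of gyration. `y(0) = R_base + A_c`; the
#' long-time plateau is `R_base + A_g`. Weighted by `1/y_err^2` when
#' uncertainties are present. The two time constants must come out ordered
#' (`tau_collapse < tau_growth`); otherwise a fit-failure condition carrying
#' diagnostics is raised.
#'
#' @param trace A [kinetic_trace] of R_G versus time.
#' @param start Optional named list of start values.
#' @param fixed Optional named list of parameters held fixed at known
#'   values (e.g. amplitudes from a generating scenario). With the slow
#'   component only partially covered by the observation window, the
#'   amplitude-timescale ridge makes the joint fit ill-conditioned;
#'   parameter-recovery studies of the time constants fix the amplitudes.
#' @return Object of class `collapse_growth_fit` with the five parameters,
#'   their standard errors (`stderr`, free parameters only), `rss`, the
#'   names of fixed parameters, and a `model` function of `t`.
#' @export
fit_collapse_growth <- function(trace, start = NULL, fixed = NULL) {
  stopifnot(inherits(trace, "kinetic_trace"))
  d <- as.data.frame(trace)
  pnames <- c("R_base", "A_collapse", "tau_collapse", "A_growth",
              "tau_growth")
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), pnames)
    if (length(bad)) {
      stop_invalid_parameter(paste("unknown fixed parameters:",
                                   paste(bad, collapse = ", ")))
    }
  }
  free <- setdiff(pnames, names(fixed))
  if (length(free) == 0) stop_invalid_parameter("no free parameters")
  if (nrow(d) < length(free) + 1L) {
    stop_insufficient_data("more parameters than points")
  }
  w <- if (!is.null(d$y_err) && all(d$y_err > 0)) 1 / d$y_err^2 else
    rep(1, nrow(d))
  # variable-projection initialization: scan (tau_c, tau_g) on a log grid,
  # solving the free linear amplitudes exactly for each pair; robust to
  # noise where point-heuristics (e.g. the location of the minimum) are not
  s <- {
    tau_grid <- function(nm) {
      if (nm %in% names(fixed)) fixed[[nm]] else
        exp(seq(log(min(d$t) / 2), log(max(d$t) * 10), length.out = 18))
    }
    lin_fixed <- intersect(c("R_base", "A_collapse", "A_growth"),
                           names(fixed))
    best <- NULL
    for (tc in tau_grid("tau_collapse")) for (tg in tau_grid("tau_growth")) {
      if (tc >= tg) next
      X <- cbind(R_base = rep(1, nrow(d)),
                 A_collapse = exp(-d$t / tc),
                 A_growth = 1 - exp(-d$t / tg))
      off <- if (length(lin_fixed)) {
        X[, lin_fixed, drop = FALSE] %*% unlist(fixed[lin_fixed])
      } else 0
      Xf <- X[, setdiff(colnames(X), lin_fixed), drop = FALSE]
      fitl <- lm.wfit(Xf, d$y - off, w)
      rss <- sum(w * fitl$residuals^2)
      if (is.null(best) || rss < best$rss) {
        best <- list(rss = rss, tc = tc, tg = tg, beta = fitl$coefficients)
      }
    }
    s0 <- list(tau_collapse = best$tc, tau_growth = best$tg)
    for (nm in names(best$beta)) {
      s0[[nm]] <- if (nm == "R_base") unname(best$beta[nm]) else
        max(unname(best$beta[nm]), 1e-3)
    }
    s0 <- s0[free]
    if (!is.null(start)) s0 <- modifyList(s0, start[names(start) %in% free])
    s0
  }
  # fixed parameters ride along as constant data columns, so the model
  # formula stays the same whatever is held fixed
  dd <- d
  for (nm in names(fixed)) dd[[nm]] <- fixed[[nm]]
  lower_all <- c(R_base = -Inf, A_collapse = 0, tau_collapse = 1e-12,
                 A_growth = 0, tau_growth = 1e-12)
  fit <- tryCatch(
    nlsLM(y ~ cg_model(t, R_base, A_collapse, tau_collapse, A_growth,
                       tau_growth),
          data = dd, start = s, weights = w,
          lower = unname(lower_all[names(s)]),
          control = nls.control(maxiter = 500)),
    error = function(e) {
      stop_fit_failure(paste("collapse+growth fit did not converge:",
                             conditionMessage(e)),
                       diagnostics = list(start = s))
    })
  cf <- as.list(coef(fit))
  for (nm in names(fixed)) cf[[nm]] <- fixed[[nm]]
  cf <- cf[pnames]
  if (cf$tau_collapse >= cf$tau_growth) {
    stop_fit_failure(
      sprintf("time constants not ordered: tau_collapse = %.3g >= tau_growth = %.3g",
              cf$tau_collapse, cf$tau_growth),
      diagnostics = list(coef = cf))
  }
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(free)))
  structure(c(cf,
              list(stderr = se,
                   rss = sum((d$y - predict(fit))^2),
                   fixed = names(fixed),
                   model = function(t) do.call(cg_model, c(list(t = t), cf)),
                   fit = fit)),
            class = "collapse_growth_fit")
}

#' @export
print.collapse_growth_fit <- function(x, ...) {
  cat("Collapse + growth fit\n")
  cat(sprintf("  R_base = %s, A_collapse = %s, A_growth = %s\n",
              fmt_num(x$R_base), fmt_num(x$A_collapse), fmt_num(x$A_growth)))
  cat(sprintf("  tau_collapse = %s s (%.4g us), tau_growth = %s s (%.4g ms)\n",
              fmt_num(x$tau_collapse), x$tau_collapse * 1e6,
              fmt_num(x$tau_growth), x$tau_growth * 1e3))
  invisible(x)
}

#' Scaled Weibull cumulative distribution model
#'
#' The phenomenological nucleation-kinetics model for the assembly metric:
#' `amplitude * (1 - exp(-(t/lambda)^k))`, zero at `t = 0` and monotonically
#' saturating. `lambda` (seconds) is the timescale over which the transition
#' occurs; the stretching exponent `k > 1` means the nucleation probability
#' increases with time.
#'
#' @param t Time, seconds (`t >= 0`).
#' @param fit Optional `weibull_fit`; alternatively give the three
#'   parameters directly.
#' @param amplitude,scale_lambda,stretch_k Parameters used when `fit` is not
#'   supplied.
#' @return Model values, same units as the amplitude.
#' @export
weibull_cdf_model <- function(t, fit = NULL, amplitude = 1, scale_lambda = 1,
                              stretch_k = 2) {
  if (!is.null(fit)) {
    amplitude <- fit$amplitude
    scale_lambda <- fit$scale_lambda
    stretch_k <- fit$stretch_k
  }
  if (any(t < 0)) stop_invalid_parameter("t must be non-negative")
  if (scale_lambda <= 0 || stretch_k <= 0) {
    stop_invalid_parameter("scale_lambda and stretch_k must be positive")
  }
  amplitude * (1 - exp(-(t / scale_lambda)^stretch_k))
}

#' Fit the scaled Weibull CDF to assembly-metric traces
#'
#' Joint least-squares fit of [weibull_cdf_model()] over all points of one
#' or more replicates. Refuses to fit when no rise above the early-time
#' noise floor is detected.
#'
#' @param traces One [kinetic_trace] or a list of them.
#' @param amplitude Optional fixed amplitude (free by default).
#' @param start Optional named list of start values.
#' @return Object of class `weibull_fit` with fields `amplitude`,
#'   `scale_lambda`, `stretch_k`, `stderr`, `rss`, `n_points`.
#' @export
fit_weibull <- function(traces, amplitude = NULL, start = NULL) {
  if (inherits(traces, "kinetic_trace")) traces <- list(traces)
  d <- do.call(rbind, lapply(traces, function(tr) {
    stopifnot(inherits(tr, "kinetic_trace"))
    as.data.frame(tr)[c("t", "y", if ("y_err" %in% names(tr)) "y_err")]
  }))
  ymax <- max(d$y)
  # noise floor from the earliest distinct time points (at least 3 values)
  tu <- sort(unique(d$t))
  i <- 1
  repeat {
    early <- d$y[d$t <= tu[i]]
    if (length(early) >= 3 || i == length(tu)) break
    i <- i + 1
  }
  floor_ <- max(sd(early), 1e-12 * max(abs(ymax), 1))
  if (ymax < 3 * floor_ || ymax <= 0) {
    stop_no_transition("no rise detected: max signal below 3x early noise floor")
  }
  w <- if (!is.null(d$y_err) && all(d$y_err > 0)) 1 / d$y_err^2 else
    rep(1, nrow(d))
  lam0 <- d$t[which(d$y >= ymax / 2)[1]]
  s <- list(amplitude = ymax, scale_lambda = lam0, stretch_k = 2)
  if (!is.null(start)) s <- modifyList(s, start)
  fixed_amp <- !is.null(amplitude)
  fit <- tryCatch({
    if (fixed_amp) {
      amp <- amplitude
      nlsLM(y ~ weibull_cdf_model(t, amplitude = amp,
                                  scale_lambda = scale_lambda,
                                  stretch_k = stretch_k),
            data = d, start = s[c("scale_lambda", "stretch_k")], weights = w,
            lower = c(scale_lambda = 1e-12, stretch_k = 1e-3),
            control = nls.control(maxiter = 500))
    } else {
      nlsLM(y ~ weibull_cdf_model(t, amplitude = amplitude,
                                  scale_lambda = scale_lambda,
                                  stretch_k = stretch_k),
            data = d, start = s, weights = w,
            lower = c(amplitude = 1e-12, scale_lambda = 1e-12,
                      stretch_k = 1e-3),
            control = nls.control(maxiter = 500))
    }
  }, error = function(e) {
    stop_fit_failure(paste("Weibull fit did not converge:",
                           conditionMessage(e)),
                     diagnostics = list(start = s))
  })
  cf <- as.list(coef(fit))
  if (fixed_amp) cf$amplitude <- amplitude
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  structure(list(amplitude = cf$amplitude,
                 scale_lambda = cf$scale_lambda,
                 stretch_k = cf$stretch_k,
                 stderr = se,
                 rss = sum((d$y - predict(fit))^2),
                 n_points = nrow(d), amplitude_fixed = fixed_amp),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Scaled Weibull CDF fit\n")
  cat(sprintf("  amplitude = %s%s, lambda = %s s, k = %s\n",
              fmt_num(x$amplitude), if (x$amplitude_fixed) " (fixed)" else "",
              fmt_num(x$scale_lambda), fmt_num(x$stretch_k)))
  cat(sprintf("  mean onset time = %s s (%d points)\n",
              fmt_num(x$scale_lambda * gamma(1 + 1 / x$stretch_k)),
              x$n_points))
  invisible(x)
}

#' Weibull probability density and mean onset time
#'
#' Transforms a Weibull CDF fit into the corresponding probability density
#' of nucleation onset times,
#' `pdf(t) = (k/lambda) (t/lambda)^(k-1) exp(-(t/lambda)^k)`, and its mean
#' `lambda * Gamma(1 + 1/k)`.
#'
#' @param fit A `weibull_fit` (or a list with `scale_lambda`, `stretch_k`).
#' @return List with `pdf` (a function of `t`) and `mean_time` (seconds).
#' @export
weibull_pdf_and_mean <- function(fit) {
  lam <- fit$scale_lambda; k <- fit$stretch_k
  if (is.null(lam) || is.null(k) || lam <= 0 || k <= 0) {
    stop_invalid_parameter("fit must carry positive scale_lambda and stretch_k")
  }
  list(pdf = function(t) dweibull(t, shape = k, scale = lam),
       mean_time = lam * gamma(1 + 1 / k))
}

#' Correspondence between replicate scatter and the Weibull PDF
#'
#' For stochastic nucleation, the per-time standard deviation across
#' replicates of the assembly metric peaks where the nucleation-onset
#' probability density is largest. Computes the per-time standard deviation
#' across replicates (all sharing one time grid), the fitted PDF, the
#' difference in their peak locations, and a normalized overlap score in
#' `[0, 1]` (both curves scaled to unit sum; score = sum of pointwise
#' minima), which is invariant to uniform amplitude rescaling.
#'
#' @param traces List of `kinetic_trace` replicates on a common time grid.
#' @param fit A `weibull_fit` for the pooled traces.
#' @return List with `t`, `sd_curve`, `pdf_curve`, `peak_dt` (seconds),
#'   `peak_dt_steps` (in units of the local grid step), `overlap`.
#' @export
pdf_variance_correspondence <- function(traces, fit) {
  if (length(traces) < 20) stop_insufficient_data("need >= 20 replicates")
  tg <- traces[[1]]$t
  for (tr in traces) {
    if (length(tr$t) != length(tg) || any(abs(tr$t - tg) > 1e-12 * max(tg))) {
      stop_alignment("replicates do not share a common time grid")
    }
  }
  Y <- vapply(traces, function(tr) tr$y, numeric(length(tg)))
  sd_curve <- apply(Y, 1, sd)
  pdfm <- weibull_pdf_and_mean(fit)
  pdf_curve <- pdfm$pdf(tg)
  i_sd <- which.max(sd_curve)
  i_pdf <- which.max(pdf_curve)
  step <- if (i_sd < length(tg)) tg[i_sd + 1] - tg[i_sd] else
    tg[i_sd] - tg[i_sd - 1]
  overlap <- if (sum(sd_curve) <= 0 || sum(pdf_curve) <= 0) 0 else
    sum(pmin(sd_curve / sum(sd_curve), pdf_curve / sum(pdf_curve)))
  list(t = tg, sd_curve = sd_curve, pdf_curve = pdf_curve,
       peak_dt = tg[i_sd] - tg[i_pdf],
       peak_dt_steps = abs(i_sd - i_pdf),
       overlap = overlap)
}

#' Extrapolate the Weibull timescale across quench depths
#'
#' Fits `ln(lambda) = a + B / sigma^2` (the classical-nucleation barrier
#' scaling of the transition timescale with supersaturation) and predicts
#' `lambda` at a new quench depth with a propagated confidence band. When an
#' observation window is supplied, also reports whether the predicted
#' timescale exceeds it — i.e. whether assembly would not be observed.
#'
#' @param sigma Supersaturations of the fitted datasets (`> 0`, length >= 3).
#' @param scale_lambda Fitted Weibull timescales, seconds.
#' @param sigma_new Quench depth at which to predict (`> 0`).
#' @param window Optional observation window, seconds.
#' @param level Confidence level for the band (default 0.95).
#' @return List with `a`, `B`, `r_squared`, `lambda_pred`, `lower`, `upper`,
#'   and `exceeds_window` (logical or `NA` when no window given).
#' @export
extrapolate_timescale <- function(sigma, scale_lambda, sigma_new,
                                  window = NULL, level = 0.95) {
  if (length(sigma) != length(scale_lambda)) {
    stop_invalid_parameter("sigma and scale_lambda lengths differ")
  }
  if (length(sigma) < 3) stop_insufficient_data("need >= 3 (sigma, lambda) pairs")
  if (any(sigma <= 0) || any(scale_lambda <= 0)) {
    stop_invalid_parameter("sigma and scale_lambda must be positive")
  }
  if (sigma_new <= 0) stop_invalid_parameter("sigma_new must be positive")
  x <- 1 / sigma^2
  fit <- lm(log(scale_lambda) ~ x)
  pr <- predict(fit, newdata = data.frame(x = 1 / sigma_new^2), se.fit = TRUE)
  tq <- qt(1 - (1 - level) / 2, df = fit$df.residual)
  lp <- exp(pr$fit)
  lo <- exp(pr$fit - tq * pr$se.fit)
  hi <- exp(pr$fit + tq * pr$se.fit)
  list(a = unname(coef(fit)[1]), B = unname(coef(fit)[2]),
       r_squared = suppressWarnings(summary(fit))$r.squared,
       lambda_pred = unname(lp), lower = unname(lo), upper = unname(hi),
       exceeds_window = if (is.null(window)) NA else unname(lp > window),
       fit = fit)
}

#' @importFrom stats quantile lm.wfit
NULL
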