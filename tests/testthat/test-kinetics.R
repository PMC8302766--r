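test_that("collapse+growth fit is exact on noiseless data and honors nesting", {
  tr <- gen_rg_trace(chaotic_flow_pars, t_grid = log_time_grid(69e-6, 80e-3, 100),
                     cfg = generator_config(noise_level = 0))
  f <- fit_collapse_growth(tr)
  expect_equal(f$tau_collapse, 470e-6, tolerance = 1e-4)
  expect_equal(f$tau_growth, 36e-3, tolerance = 1e-4)
  expect_equal(f$R_base, 26, tolerance = 1e-4)
  expect_equal(f$A_collapse, 2, tolerance = 1e-4)
  expect_equal(f$A_growth, 3, tolerance = 1e-4)
  # t -> infinity asymptote equals R_base + A_growth
  expect_equal(f$model(1e6), f$R_base + f$A_growth, tolerance = 1e-8)

  # A_growth = 0 reduces to a single-exponential decay (growth channel
  # held at zero via `fixed`, since a free zero-amplitude component leaves
  # its timescale undetermined)
  pars0 <- modifyList(chaotic_flow_pars, list(A_growth = 0))
  tr0 <- gen_rg_trace(pars0, cfg = generator_config(noise_level = 0))
  f0 <- fit_collapse_growth(tr0, fixed = list(A_growth = 0, tau_growth = 1))
  expect_equal(f0$tau_collapse, 470e-6, tolerance = 1e-6)
  expect_equal(f0$R_base, 26, tolerance = 1e-6)
})

test_that("collapse+growth fit is exact over random admissible parameter draws", {
  draws <- with_seed(99, lapply(1:25, function(i) {
    list(R_base = runif(1, 15, 35), A_collapse = runif(1, 0.5, 5),
         tau_collapse = 10^runif(1, -3.6, -3),
         A_growth = runif(1, 0.5, 5), tau_growth = 10^runif(1, -2, -1.2))
  }))
  for (p in draws) {
    tr <- gen_rg_trace(p, t_grid = log_time_grid(69e-6, 120e-3, 120),
                       cfg = generator_config(noise_level = 0))
    f <- fit_collapse_growth(tr)
    expect_equal(f$tau_collapse, p$tau_collapse, tolerance = 1e-4)
    expect_equal(f$tau_growth, p$tau_growth, tolerance = 1e-4)
  }
})

test_that("Weibull CDF model matches its closed-form anchor points", {
  expect_equal(weibull_cdf_model(40e-3, amplitude = 2, scale_lambda = 40e-3,
                                 stretch_k = 2),
               2 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(weibull_cdf_model(20e-3, amplitude = 1, scale_lambda = 40e-3,
                                 stretch_k = 2),
               1 - exp(-0.25), tolerance = 1e-12)
  expect_identical(weibull_cdf_model(0, amplitude = 3), 0)
  # k = 1 is exponential saturation
  tt <- seq(0, 0.2, length.out = 50)
  expect_equal(weibull_cdf_model(tt, amplitude = 1, scale_lambda = 0.05,
                                 stretch_k = 1),
               1 - exp(-tt / 0.05), tolerance = 1e-12)
  expect_error(weibull_cdf_model(-1), class = "phasekin_invalid_parameter")
})

test_that("Weibull fitting: exact self-consistency, stochastic recovery, nesting", {
  tt <- log_time_grid(1e-3, 0.4, 80)
  tr <- kinetic_trace(tt, weibull_cdf_model(tt, amplitude = 1,
                                            scale_lambda = 40e-3,
                                            stretch_k = 2))
  f <- fit_weibull(tr)
  expect_equal(f$scale_lambda, 40e-3, tolerance = 1e-6)
  expect_equal(f$stretch_k, 2, tolerance = 1e-6)
  expect_equal(f$amplitude, 1, tolerance = 1e-6)

  # 200 stochastic step replicates: per-point scatter encodes the PDF
  trs <- gen_assembly_trajectories(log_time_grid(1e-3, 0.3, 60), 200,
                                   scale_lambda = 40e-3, stretch_k = 2,
                                   cfg = generator_config(seed = 2,
                                                          noise_level = 0))
  fs <- fit_weibull(trs)
  expect_gte(fs$stretch_k, 1.8)
  expect_lte(fs$stretch_k, 2.2)
  expect_equal(fs$scale_lambda, 40e-3, tolerance = 0.10)

  # fixing k to 1 on k = 2 data must fit strictly worse
  fk1 <- local({
    d <- as.data.frame(tr)
    m <- minpack.lm::nlsLM(y ~ weibull_cdf_model(t, amplitude = amplitude,
                                                 scale_lambda = scale_lambda,
                                                 stretch_k = 1),
                           data = d,
                           start = list(amplitude = 1, scale_lambda = 0.04))
    sum((d$y - predict(m))^2)
  })
  expect_lt(f$rss, fk1)

  # flat traces refuse to fit
  flat <- kinetic_trace(tt, rep(0, length(tt)))
  expect_error(fit_weibull(flat), class = "phasekin_no_transition")
})

test_that("Weibull PDF and mean follow the closed forms and integrate to 1", {
  f <- list(scale_lambda = 10e-3, stretch_k = 1)
  expect_equal(weibull_pdf_and_mean(f)$mean_time, 10e-3, tolerance = 1e-12)
  f2 <- list(scale_lambda = 40e-3, stretch_k = 2)
  pm <- weibull_pdf_and_mean(f2)
  expect_equal(pm$mean_time, 40e-3 * gamma(1.5), tolerance = 1e-12)
  expect_equal(integrate(pm$pdf, 0, 50 * 40e-3, rel.tol = 1e-9)$value, 1,
               tolerance = 1e-6)
  # numerical derivative of the CDF matches the PDF on a log grid
  tt <- log_time_grid(1e-3, 0.3, 200)
  h <- tt * 1e-6
  dcdf <- (weibull_cdf_model(tt + h, amplitude = 1, scale_lambda = 40e-3,
                             stretch_k = 2) -
           weibull_cdf_model(tt - h, amplitude = 1, scale_lambda = 40e-3,
                             stretch_k = 2)) / (2 * h)
  expect_equal(dcdf, pm$pdf(tt), tolerance = 1e-4)
})

test_that("replicate scatter peaks where the fitted PDF peaks", {
  tg <- seq(5e-3, 0.15, length.out = 30)  # one point per beam position
  trs <- gen_assembly_trajectories(tg, 500, scale_lambda = 40e-3,
                                   stretch_k = 2,
                                   cfg = generator_config(seed = 8,
                                                          noise_level = 0))
  fit <- fit_weibull(trs)
  rep_ <- pdf_variance_correspondence(trs, fit)
  expect_lte(rep_$peak_dt_steps, 1)
  expect_gt(rep_$overlap, 0.5)

  # identical replicates: zero scatter, zero overlap
  same <- lapply(1:25, function(i) kinetic_trace(tg, weibull_cdf_model(
    tg, amplitude = 1, scale_lambda = 40e-3, stretch_k = 2)))
  rep0 <- pdf_variance_correspondence(same, fit)
  expect_true(all(rep0$sd_curve == 0))
  expect_identical(rep0$overlap, 0)

  # overlap invariant to uniform amplitude rescaling
  scaled <- lapply(trs, function(tr) kinetic_trace(tr$t, 13 * tr$y))
  expect_equal(pdf_variance_correspondence(scaled, fit)$overlap,
               rep_$overlap, tolerance = 1e-12)

  # unmatched grids are an alignment error
  bad <- c(trs[1:19], list(kinetic_trace(tg * 1.01, trs[[20]]$y)))
  expect_error(pdf_variance_correspondence(bad, fit),
               class = "phasekin_alignment_error")
})

test_that("timescale extrapolation recovers exact scaling and flags windows", {
  sig <- c(0.5, 1, 2)
  lam <- exp(1 + 2 / sig^2)
  ex <- extrapolate_timescale(sig, lam, sigma_new = 0.25)
  expect_equal(ex$a, 1, tolerance = 1e-10)
  expect_equal(ex$B, 2, tolerance = 1e-10)
  expect_equal(ex$lambda_pred, exp(33), tolerance = 1e-8)

  # shallow-quench prediction exceeding the 80 ms observation window
  sig2 <- c(1, 1.5, 2, 3)
  lam2 <- exp(-4.2 + 1.2 / sig2^2)   # 20-50 ms at the fitted depths
  ex2 <- extrapolate_timescale(sig2, lam2, sigma_new = 0.4, window = 0.08)
  expect_true(ex2$exceeds_window)
  expect_gt(ex2$lambda_pred, 0.08)

  # equivariance under time-unit rescaling: B unchanged, prediction scales
  ex_ms <- extrapolate_timescale(sig2, lam2 * 1e3, sigma_new = 0.4)
  expect_equal(ex_ms$B, ex2$B, tolerance = 1e-10)
  expect_equal(ex_ms$lambda_pred, ex2$lambda_pred * 1e3, tolerance = 1e-8)

  expect_error(extrapolate_timescale(sig[1:2], lam[1:2], 0.3),
               class = "phasekin_insufficient_data")
  expect_error(extrapolate_timescale(sig, lam, -1),
               class = "phasekin_invalid_parameter")
})
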