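test_that("Debye form factor matches its closed form and limits", {
  expect_identical(debye_form_factor(0, 30), 1)
  # x = (q Rg)^2 = 1  ->  2/e
  expect_equal(debye_form_factor(1 / 30, 30), 2 * exp(-1), tolerance = 1e-12)
  # high-q asymptote 2/x^2 at q Rg = 10 (within 1%)
  expect_equal(debye_form_factor(10 / 25, 25), 2 / 100, tolerance = 0.01)
  # monotone decreasing on a dense grid, bounded in (0, 1]
  q <- seq(0, 2, length.out = 2000)
  p <- debye_form_factor(q, 30)
  expect_true(all(diff(p) < 0))
  expect_true(all(p > 0 & p <= 1))
  expect_error(debye_form_factor(0.1, -1), class = "phasekin_invalid_parameter")
})

test_that("generalized polymer form factor reduces to Debye at nu = 1/2", {
  for (Rg in c(15, 30, 60)) {
    q <- seq(0, 3 / Rg, length.out = 50)
    expect_equal(generalized_polymer_form_factor(q, Rg, 0.5),
                 debye_form_factor(q, Rg), tolerance = 1e-8)
  }
  expect_identical(generalized_polymer_form_factor(0, 30, 0.6), 1)
  expect_error(generalized_polymer_form_factor(0.1, 30, 0.2),
               class = "phasekin_invalid_parameter")
  expect_error(generalized_polymer_form_factor(0.1, 30, 1.2),
               class = "phasekin_invalid_parameter")
})

test_that("nu-dependence of the generalized form factor matches a quadrature oracle", {
  # independent oracle: numerical integration of the defining double sum
  # P(q) = 2 * int_0^1 (1-s) exp(-U(q) * s^(2 nu) * c_nu) ds with the
  # segment-separation variance of the generalized chain; equivalently
  # evaluate the incomplete-gamma form by direct quadrature of
  # d/du expressions. Here we integrate the closed integral representation
  # P = 2 int_0^1 (1-x) exp(-(q Rg)^2 ((2nu+1)(2nu+2)/6) x^(2nu)) dx.
  oracle <- function(q, Rg, nu) {
    U <- (2 * nu + 1) * (2 * nu + 2) * (q * Rg)^2 / 6
    f <- function(x) 2 * (1 - x) * exp(-U * x^(2 * nu))
    integrate(f, 0, 1, rel.tol = 1e-10)$value
  }
  for (nu in c(0.4, 0.5, 0.6)) {
    for (qr in c(0.5, 1, 2)) {
      expect_equal(generalized_polymer_form_factor(qr / 30, 30, nu),
                   oracle(qr / 30, 30, nu), tolerance = 1e-6,
                   label = sprintf("nu=%g qRg=%g", nu, qr))
    }
  }
  # compaction (nu = 0.6 vs 0.5) changes the q Rg = 2 value away from Debye
  expect_gt(abs(generalized_polymer_form_factor(2 / 30, 30, 0.6) -
                debye_form_factor(2 / 30, 30)), 1e-3)
})

test_that("form-factor fitting recovers exact parameters and resists noise", {
  cv <- make_debye_curve(Rg = 30, I0 = 1)
  f <- fit_form_factor(cv)
  expect_equal(f$Rg, 30, tolerance = 1e-4)
  expect_equal(f$I0, 1, tolerance = 1e-4)
  expect_false(f$flagged)

  # median recovery within 2% under 2% noise (Monte-Carlo over seeds)
  rgs <- with_seed(42, vapply(1:100, function(i) {
    I <- cv$I * (1 + 0.02 * rnorm(nrow(cv)))
    fit_form_factor(saxs_curve(cv$q, I, sigmaI = 0.02 * cv$I))$Rg
  }, numeric(1)))
  expect_equal(median(rgs), 30, tolerance = 0.02)

  # generalized fit recovers nu on exact data
  q <- seq(0.004, 0.15, length.out = 100)
  cv2 <- saxs_curve(q, 2 * generalized_polymer_form_factor(q, 28, 0.42))
  f2 <- fit_form_factor(cv2, "generalized_polymer")
  expect_equal(f2$nu, 0.42, tolerance = 1e-3)
  expect_equal(f2$Rg, 28, tolerance = 1e-3)
})

test_that("low-angle upturns are excluded by the q-window and flagged otherwise", {
  # mesoscopic clusters are much larger than the chain, so their power-law
  # tail is steep; a q^-3 term dominates at the lowest angles but is
  # negligible above q ~ 0.04
  q <- seq(0.004, 0.25, length.out = 150)
  upturn <- 1e-6 * q^-3
  cv <- saxs_curve(q, debye_form_factor(q, 30) + upturn)
  windowed <- fit_form_factor(cv, q_window = c(0.04, 0.25))
  expect_equal(windowed$Rg, 30, tolerance = 0.03)
  full <- fit_form_factor(cv)
  expect_true(full$flagged)
})

test_that("Guinier analysis is exact on noiseless Guinier data", {
  for (pars in list(c(25, 2.5), c(12, 0.7), c(45, 10))) {
    Rg <- pars[1]; I0 <- pars[2]
    cv <- make_guinier_curve(Rg, I0, q = seq(0.002, 1.2 / Rg, length.out = 60))
    g <- guinier_fit(cv)
    expect_equal(g$Rg, Rg, tolerance = 1e-7)
    expect_equal(g$I0, I0, tolerance = 1e-7)
    expect_lte(g$q_window[2] * g$Rg, g$qRg_max + 1e-9)
  }
})

test_that("Guinier window arithmetic flags out-of-range chains", {
  # Rg = 120 A with q_min = 0.008: window q*Rg <= 1.3 is nearly empty
  q <- seq(0.008, 0.2, length.out = 100)
  cv <- saxs_curve(q, exp(-q^2 * 120^2 / 3))
  expect_error(guinier_fit(cv), class = "phasekin_insufficient_data")
  # flat (non-decaying) curve is not a Guinier regime
  cv2 <- saxs_curve(q, seq(1, 1.5, length.out = length(q)))
  expect_error(guinier_fit(cv2), class = "phasekin_non_guinier")
})

test_that("Guinier standard errors are calibrated against simulation", {
  cv0 <- make_guinier_curve(25, 2.5, q = seq(0.004, 0.052, length.out = 40))
  sims <- with_seed(7, lapply(1:200, function(i) {
    I <- cv0$I * (1 + 0.02 * rnorm(nrow(cv0)))
    tryCatch(guinier_fit(saxs_curve(cv0$q, I, sigmaI = 0.02 * cv0$I)),
             error = function(e) NULL)
  }))
  sims <- Filter(Negate(is.null), sims)
  cover <- vapply(sims, function(g) abs(g$Rg - 25) <= 1.96 * g$stderr_Rg,
                  logical(1))
  # nominal 95% coverage within Monte-Carlo error (binomial sd ~1.5%)
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("fit_form_factor and guinier_fit agree on noiseless Debye curves", {
  # the Guinier approximation of the Debye function carries a known
  # systematic bias that grows with the window: ln P = -x/3 + x^2/36 + ...
  # Agreement is within 3% for windows q*Rg <= 0.8 and within 7% at the
  # conventional 1.3 cutoff.
  for (Rg in c(20, 35)) {
    q <- seq(0.003, 1.3 / Rg, length.out = 60)
    cv <- saxs_curve(q, debye_form_factor(q, Rg))
    expect_equal(guinier_fit(cv, qRg_max = 0.8)$Rg, fit_form_factor(cv)$Rg,
                 tolerance = 0.03)
    expect_equal(guinier_fit(cv)$Rg, fit_form_factor(cv)$Rg,
                 tolerance = 0.07)
  }
})

test_that("assembly metric is zero for monomer, linear in upturn, scale-invariant", {
  mono <- form_factor_model("gaussian_chain", Rg = 30, I0 = 2)
  q <- seq(0.004, 0.25, length.out = 120)
  pure <- saxs_curve(q, form_factor_intensity(mono, q))
  expect_equal(assembly_metric(pure, mono)$value, 0, tolerance = 1e-12)

  mk <- function(A) saxs_curve(q, form_factor_intensity(mono, q) + A * q^-2)
  m1 <- assembly_metric(mk(1e-4), mono)$value
  m2 <- assembly_metric(mk(2e-4), mono)$value
  expect_gt(m1, 0)
  expect_equal(m2 / m1, 2, tolerance = 1e-9)

  # scale invariance under joint rescaling with monomer-I0 normalization
  scaled_curve <- saxs_curve(q, 7.3 * (form_factor_intensity(mono, q) + 1e-4 * q^-2))
  scaled_mono <- form_factor_model("gaussian_chain", Rg = 30, I0 = 7.3 * 2)
  expect_equal(assembly_metric(scaled_curve, scaled_mono)$value, m1,
               tolerance = 1e-9)

  expect_error(assembly_metric(pure, mono, q_window = c(0.004, 0.0045)),
               class = "phasekin_insufficient_data")
})

test_that("SAXS curves round-trip through the plain-text format", {
  cv <- make_debye_curve(sigmaI = rep(0.01, 120), t_after_mix = 0.018)
  path <- tempfile(fileext = ".dat")
  write_saxs_dat(cv, path)
  rt <- read_saxs_dat(path)
  expect_equal(rt$q, cv$q, tolerance = 1e-8)
  expect_equal(rt$I, cv$I, tolerance = 1e-8)
  expect_equal(rt$sigmaI, cv$sigmaI, tolerance = 1e-8)
  expect_equal(attr(rt, "t_after_mix"), 0.018)

  # 2-column files and inverse-nanometre unit headers
  path2 <- tempfile(fileext = ".dat")
  writeLines(c("# q (1/nm)  I", paste(cv$q[1:20] * 10, cv$I[1:20])), path2)
  rt2 <- read_saxs_dat(path2)
  expect_equal(rt2$q, cv$q[1:20], tolerance = 1e-8)
  expect_false("sigmaI" %in% names(rt2))
})

test_that("logarithmic display binning preserves the curve on average", {
  cv <- make_debye_curve()
  b <- log_bin_curve(cv, n_bins = 30)
  expect_lte(nrow(b), 30)
  expect_equal(sum(b$n), nrow(cv))
  expect_true(all(diff(b$q) > 0))
})

test_that("curve validation rejects malformed input", {
  expect_error(saxs_curve(c(1, 2), c(1, 2)), class = "phasekin_invalid_parameter")
  expect_error(saxs_curve(seq(8, 1), rep(1, 8)), class = "phasekin_invalid_parameter")
  expect_error(saxs_curve(1:8, c(1:7, Inf)), class = "phasekin_invalid_parameter")
  expect_error(saxs_curve(1:8, 1:8, sigmaI = rep(-1, 8)),
               class = "phasekin_invalid_parameter")
})
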