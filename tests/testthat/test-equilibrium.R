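test_that("binodal validation and monotone supersaturation lookup", {
  b <- read_binodal_csv(system.file("extdata", "binodal_synthetic.csv",
                                    package = "phasekin"))
  expect_s3_class(b, "binodal")
  # definition anchors
  expect_equal(supersaturation(b$c_sat[4], b$nacl_mM[4], b), 0,
               tolerance = 1e-9)
  expect_equal(supersaturation(2 * b$c_sat[4], b$nacl_mM[4], b), 1,
               tolerance = 1e-9)
  # monotone interpolation: midpoint c_sat lies between neighbours
  for (i in 1:(nrow(b) - 1)) {
    mid <- csat_at(b, (b$nacl_mM[i] + b$nacl_mM[i + 1]) / 2)
    expect_lt(mid, b$c_sat[i])
    expect_gt(mid, b$c_sat[i + 1])
  }
  expect_error(csat_at(b, 2000), class = "phasekin_extrapolation_error")
  expect_error(binodal(c(50, 100), c(10, 12), c(300, 310)),
               class = "phasekin_invalid_parameter")  # c_sat not decreasing
  expect_error(binodal(c(50, 100), c(10, 5), c(8, 310)),
               class = "phasekin_invalid_parameter")  # c_den < c_sat
})

test_that("isodesmic species distribution matches the quadratic closed form", {
  # c_tot = 0.25, K = 1: c1 = 3 - 2 sqrt(2), monomer mass fraction ~0.6863
  sp <- species_distribution(0.25, association_model("isodesmic", K_iso = 1))
  expect_equal(attr(sp, "c1"), 3 - 2 * sqrt(2), tolerance = 1e-10)
  expect_equal(sp$mass_fraction[1], (3 - 2 * sqrt(2)) / 0.25, tolerance = 1e-9)
  # independent polynomial-root oracle for other (K, c_tot)
  for (pars in list(c(2, 0.3), c(0.5, 1.4))) {
    K <- pars[1]; ct <- pars[2]
    roots <- polyroot(c(ct, -(2 * K * ct + 1), K^2 * ct))
    c1_or <- min(Re(roots[abs(Im(roots)) < 1e-9 & Re(roots) > 0]))
    sp2 <- species_distribution(ct, association_model("isodesmic", K_iso = K))
    expect_equal(attr(sp2, "c1"), c1_or, tolerance = 1e-9)
  }
})

test_that("species distributions conserve mass and respect scheme reductions", {
  draws <- with_seed(17, lapply(1:60, function(i) {
    list(scheme = sample(c("monomer_dimer", "isodesmic",
                           "two_step_isodesmic"), 1),
         K = 10^runif(1, -2, 1), K2 = 10^runif(1, -3, 0),
         ct = 10^runif(1, -2, 1))
  }))
  for (d in draws) {
    m <- switch(d$scheme,
                monomer_dimer = association_model("monomer_dimer", K2 = d$K2),
                isodesmic = association_model("isodesmic", K_iso = d$K),
                two_step_isodesmic = association_model("two_step_isodesmic",
                                                       K2 = d$K2,
                                                       K_iso = d$K))
    sp <- species_distribution(d$ct, m)
    expect_equal(sum(sp$n * sp$c_n), d$ct, tolerance = 1e-6,
                 label = paste("mass balance", d$scheme))
    expect_true(all(sp$c_n >= 0))
  }
  # two-step with K2 = K_iso collapses onto the isodesmic scheme
  sp_iso <- species_distribution(0.8, association_model("isodesmic",
                                                        K_iso = 0.7))
  sp_two <- species_distribution(0.8, association_model("two_step_isodesmic",
                                                        K2 = 0.7, K_iso = 0.7))
  n <- seq_len(min(nrow(sp_iso), nrow(sp_two)))
  expect_equal(sp_two$c_n[n], sp_iso$c_n[n], tolerance = 1e-8)
  # K2 -> 0 puts all mass in the monomer
  sp0 <- species_distribution(1, association_model("monomer_dimer", K2 = 1e-12))
  expect_equal(sp0$mass_fraction[1], 1, tolerance = 1e-9)
})

test_that("weight-average s honors scaling and nonideality anchors", {
  m0 <- association_model("monomer", s1 = 2)
  expect_equal(weight_average_s(5, m0), 2, tolerance = 1e-12)
  # forced pure dimer: the 2/3-power law gives s1 * 2^(2/3)
  big <- association_model("monomer_dimer", K2 = 1e12, s1 = 2)
  expect_equal(weight_average_s(50, big) / 2, 2^(2 / 3), tolerance = 1e-3)
  # nonideality half-point: kS * c = 1 at c = 1000/28 mg/mL for kS = 28 mL/g
  mni <- association_model("monomer", s1 = 2, kS = 28)
  expect_equal(weight_average_s(1000 / 28, mni), 1, tolerance = 1e-12)
  # monotonicity: increasing in c for ideal associating systems,
  # decreasing for nonideal monomers
  cc <- seq(0.2, 10, length.out = 30)
  expect_true(all(diff(weight_average_s(
    cc, association_model("isodesmic", K_iso = 0.5, s1 = 2))) > 0))
  expect_true(all(diff(weight_average_s(cc, mni)) < 0))
})

test_that("isotherm fitting recovers generating parameters and discriminates schemes", {
  cgrid <- seq(0.2, 8, length.out = 12)
  # two-step self-consistency
  m2 <- association_model("two_step_isodesmic", K2 = 0.02, K_iso = 0.6,
                          s1 = 2)
  iso2 <- gen_auc_isotherm(m2, cgrid, generator_config(noise_level = 0))
  f2 <- fit_isotherm(iso2$c_mgml, iso2$s_w_S, "two_step_isodesmic")
  expect_equal(f2$K2, 0.02, tolerance = 1e-3)
  expect_equal(f2$K_iso, 0.6, tolerance = 1e-3)
  expect_equal(f2$s1, 2, tolerance = 1e-3)

  # nonideal monomer-only: kS recovered to 3 digits on noiseless data
  mni <- association_model("monomer", s1 = 2, kS = 28)
  isoN <- gen_auc_isotherm(mni, seq(0.5, 12, length.out = 10),
                           generator_config(noise_level = 0))
  fN <- fit_isotherm(isoN$c_mgml, isoN$s_w_S, "monomer", fit_kS = TRUE)
  expect_equal(fN$kS, 28, tolerance = 1e-3)
  expect_equal(fN$s1, 2, tolerance = 1e-3)

  # the isodesmic scheme fits two-step (K2 << K_iso) data strictly worse
  fi <- fit_isotherm(iso2$c_mgml, iso2$s_w_S, "isodesmic")
  expect_gt(fi$rss, f2$rss)
  expect_error(fit_isotherm(cgrid[1:4], iso2$s_w_S[1:4], "isodesmic"),
               class = "phasekin_insufficient_data")
})

test_that("Gilbert boundary shapes: spike, monomodal, bimodal; mass conserved", {
  # non-associating monomer: single-velocity spike at s1
  g0 <- gilbert_asymptotic_distribution(5, association_model("monomer", s1 = 2))
  expect_true(attr(g0, "spike"))
  expect_equal(g0$s_star[1], 2, tolerance = 1e-6)
  expect_equal(attr(g0, "integral"), 5, tolerance = 1e-9)

  # isodesmic: monomodal with the maximum at the highest s-value
  mi <- association_model("isodesmic", K_iso = 0.6, s1 = 2)
  gi <- gilbert_asymptotic_distribution(8, mi)
  expect_identical(attr(gi, "modality"), 1L)
  expect_identical(which.max(gi$g), nrow(gi))
  expect_equal(attr(gi, "integral"), 8, tolerance = 1e-3)

  # two-step with weak dimerization: bimodal boundary
  m2 <- association_model("two_step_isodesmic", K2 = 0.02, K_iso = 0.6,
                          s1 = 2)
  g2 <- gilbert_asymptotic_distribution(8, m2)
  expect_gte(attr(g2, "modality"), 2L)
  expect_equal(attr(g2, "integral"), 8, tolerance = 1e-3)

  # two-step -> isodesmic reduction holds for the boundary shape as well
  m2r <- association_model("two_step_isodesmic", K2 = 0.6, K_iso = 0.6,
                           s1 = 2)
  g2r <- gilbert_asymptotic_distribution(8, m2r)
  expect_equal(g2r$g, gi$g, tolerance = 1e-6)
})

test_that("FCS model and fit are mutually consistent", {
  # closed-form anchor: G(tau_D) with kappa = 5
  expect_equal(fcs_model(1e-3, 1, 1e-3, 5), 0.5 / sqrt(1 + 1 / 25),
               tolerance = 1e-12)
  draws <- with_seed(31, lapply(1:10, function(i) {
    list(G0 = runif(1, 0.5, 2), tau_D = 10^runif(1, -4, -2))
  }))
  for (d in draws) {
    tr <- gen_fcs_trace(list(G0 = d$G0, tau_D = d$tau_D, kappa = 5),
                        cfg = generator_config(noise_level = 0))
    f <- fcs_fit(tr$lag_s, tr$G, kappa = 5)
    expect_equal(f$G0, d$G0, tolerance = 1e-6)
    expect_equal(f$tau_D, d$tau_D, tolerance = 1e-6)
  }
  # relative tau of a fit against itself is 1
  tr <- gen_fcs_trace(cfg = generator_config(noise_level = 0))
  f <- fcs_fit(tr$lag_s, tr$G)
  f2 <- fcs_fit(tr$lag_s, tr$G, tau_ref = f$tau_D)
  expect_equal(f2$relative_tau, 1, tolerance = 1e-9)
})

test_that("viscosity trend fits a quadratic exactly and flags scarce data", {
  nacl <- c(60, 150, 300, 500, 750)
  y <- 0.8 + 0.002 * nacl + 3e-6 * nacl^2
  v <- viscosity_trend(nacl, y)
  expect_equal(unname(v$coefficients), c(0.8, 0.002, 3e-6), tolerance = 1e-9)
  # constant data: higher-order coefficients vanish
  v0 <- viscosity_trend(nacl, rep(1.7, 5))
  expect_equal(unname(v0$coefficients[2:3]), c(0, 0), tolerance = 1e-12)
  expect_error(viscosity_trend(nacl[1:3], y[1:3]),
               class = "phasekin_insufficient_data")
  # noisy recovery: median coefficients within 10% over 100 seeds
  coefs <- with_seed(5, t(vapply(1:100, function(i) {
    yn <- y * (1 + 0.03 * rnorm(5))
    unname(viscosity_trend(nacl, yn)$coefficients)
  }, numeric(3))))
  expect_equal(median(coefs[, 2]), 0.002, tolerance = 0.1)
  expect_equal(median(coefs[, 3]), 3e-6, tolerance = 0.1)
})
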