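test_that("theoretical Debye length matches an independent evaluation", {
  # hand evaluation of sqrt(eps0 eps_r R T / (2 F^2 c)) with c in mol/m^3
  ref <- 1e9 * sqrt(8.8541878128e-12 * 78.5 * 8.314462618 * 298.15 /
                      (2 * 96485.33212^2 * 0.1 * 1e3))
  expect_lt(rel_err(debye_length_theoretical(0.1, 298.15, 78.5), ref), 1e-6)
  # square-root concentration law is exact
  k1 <- debye_length_theoretical(1e-3)
  expect_equal(debye_length_theoretical(1e-1), k1 / 10, tolerance = 1e-12)
  # about 9.8 nm at 1 mM monovalent electrolyte, room temperature
  expect_lt(abs(k1 - 9.8) / 9.8, 0.05)
})

test_that("the electrostatic region is detected on segmented curves", {
  errs <- sapply(21:25, function(s) {
    sim <- simulate_approach_curve(approach_truth(Z1 = -300,
                                                  noise_sd = 0.005),
                                   seed = s)
    ft <- process_approach(sim$curve)
    expect_equal(ft$status, "ok")
    abs(ft$Z1 - (-300))
  })
  sp <- 1500 / 2699
  expect_lt(median(errs), sp)

  # an all-noise curve has no stable onset
  set.seed(22)
  flat <- force_curve(seq(-1000, 200, length.out = 1500),
                      rnorm(1500, 0, 0.01), "approach")
  expect_equal(process_approach(flat)$status, "no_electrostatic")

  # onset threshold semantics: z_c sits where the exponential crosses tau
  sim0 <- simulate_approach_curve(ref_truth(0), seed = 1)
  cv <- preprocess_curve(sim0$curve)
  seg <- segment_curve(cv, r = 2L, k_max = 6L, eps = 0)
  det <- detect_electrostatic_region(cv, seg, tau = 1e-3)
  z_c_expected <- -log(0.05 / 1e-3) / 0.1      # Z1 - ln(A/tau)/kappa
  expect_lt(abs(det$z_c - z_c_expected), 10)
})

test_that("electrostatic fitting recovers (A, kappa) and degrades sanely", {
  sim <- simulate_approach_curve(ref_truth(0), seed = 1)
  cv <- preprocess_curve(sim$curve)
  ft <- fit_electrostatic(cv, -120, 0)
  expect_lt(rel_err(ft$A, 0.05), 0.005)
  expect_lt(rel_err(1 / ft$kappa, 10), 0.005)

  # constant force: kappa pinned at the lower bound, A near the constant
  cvc <- force_curve(seq(-60, 5, length.out = 120), rep(0.04, 120),
                     "approach", preprocessed = TRUE)
  ftc <- fit_electrostatic(cvc, -60, 0, kappa_bounds = c(1 / 200, 2))
  expect_lt(ftc$kappa, 1.2 / 200)
  expect_lt(rel_err(ftc$A, 0.04), 0.25)

  # all non-positive forces cannot be electrostatic repulsion
  cvn <- force_curve(seq(-60, 5, length.out = 120),
                     rep(-0.01, 120), "approach", preprocessed = TRUE)
  expect_equal(fit_electrostatic(cvn, -60, 0)$status, "no_electrostatic")

  expect_error(fit_electrostatic(cv, -0.5, 0), "fewer than 5")
})

test_that("electrostatic recovery holds under noise (seeded replicates)", {
  z <- seq(-250, 20, by = 0.55)
  model <- 0.05 * exp(-0.1 * pmax(0 - z, 0))   # clean exponential, no drift
  errs <- t(sapply(1:30, function(s) {
    set.seed(300 + s)
    cv <- force_curve(z, model + rnorm(length(z), 0, 0.005), "approach",
                      preprocessed = TRUE)
    ft <- fit_electrostatic(cv, -120, 0)
    c(rel_err(ft$A, 0.05), rel_err(1 / ft$kappa, 10))
  }))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("electrostatic fit is equivariant to a shift of the z frame", {
  sim <- simulate_approach_curve(ref_truth(0.01), seed = 33)
  cv <- preprocess_curve(sim$curve)
  ft1 <- fit_electrostatic(cv, -120, 0)
  shifted <- force_curve(cv$z + 500, cv$F, "approach", preprocessed = TRUE)
  ft2 <- fit_electrostatic(shifted, -120 + 500, 0 + 500)
  expect_lt(abs(ft1$A - ft2$A), 1e-9)
  expect_lt(abs(ft1$kappa - ft2$kappa), 1e-9)
})

test_that("indentation has the correct rigid and compliant limits", {
  k_c <- 0.0104
  z <- seq(0, 50, length.out = 60)
  # infinitely stiff surface: all piezo travel goes into deflection
  rigid <- force_curve(c(seq(-100, -1, length.out = 60), z),
                       c(rep(0, 60), k_c * z), "approach", k_c = k_c,
                       preprocessed = TRUE)
  ind <- compute_indentation(rigid, 0, k_c)
  expect_lt(max(abs(ind$delta)), 1e-9)

  # constant force past contact: delta equals piezo travel
  soft <- force_curve(c(seq(-100, -1, length.out = 60), z),
                      c(rep(0.2, 60), rep(0.2, 60)), "approach", k_c = k_c,
                      preprocessed = TRUE)
  ind2 <- compute_indentation(soft, 0, k_c)
  expect_equal(sort(ind2$delta), z, tolerance = 1e-9)

  # forward map delta -> (z, F) -> delta round-trips
  delta <- seq(0, 80, length.out = 100)
  a <- 5.94e-4
  F1 <- 0.05
  F <- F1 + a * delta^2
  zc <- delta + (F - F1) / k_c
  cvr <- force_curve(c(seq(-100, -1, length.out = 50), zc),
                     c(rep(F1, 50), F), "approach", k_c = k_c,
                     preprocessed = TRUE)
  ind3 <- compute_indentation(cvr, 0, k_c)
  expect_lt(max(abs(sort(ind3$delta) - delta)), 1e-9)

  expect_equal(compute_indentation(rigid, 49.9, k_c)$status, "no_contact")
})

test_that("the Hertz-Hooke fit recovers moduli and the degenerate line", {
  cfg <- instrument_config()
  # the conical-tip conversion: E = 1 MPa <-> a = 5.94e-4 nN/nm^2
  a_true <- 2 * 1e-3 * tan(35 * pi / 180) / (pi * (1 - 0.25))
  expect_lt(rel_err(a_true, 5.94e-4), 0.002)

  delta <- seq(0, 90, length.out = 250)
  F1 <- 0.05
  M <- ifelse(delta <= 50, F1 + a_true * delta^2,
              F1 + a_true * 2500 + 0.1 * (delta - 50))
  ft <- fit_contact(delta, M, F1, Delta1_init = 40, config = cfg)
  expect_lt(rel_err(ft$E, 1e6), 0.005)
  expect_lt(rel_err(ft$k_cell, 0.1), 0.005)
  expect_lt(abs(ft$Delta1 - 50), 1)

  # pure linear data: k_cell equals the through-origin OLS slope
  Flin <- F1 + 0.07 * delta
  ftl <- fit_contact(delta, Flin, F1, Delta1_init = 40, config = cfg)
  slope <- sum(delta * (Flin - F1)) / sum(delta^2)
  expect_lt(abs(ftl$k_cell - slope), 1e-6)
})

test_that("contact-fit recovery holds under noise (seeded replicates)", {
  cfg <- instrument_config()
  a_true <- 2 * 1e-3 * tan(35 * pi / 180) / (pi * (1 - 0.25))
  delta <- seq(0, 90, length.out = 250)
  M <- ifelse(delta <= 50, 0.05 + a_true * delta^2,
              0.05 + a_true * 2500 + 0.1 * (delta - 50))
  errs <- t(sapply(1:30, function(s) {
    set.seed(400 + s)
    ft <- fit_contact(delta, M + rnorm(250, 0, 0.02), 0.05,
                      Delta1_init = 40, config = cfg)
    c(rel_err(ft$E, 1e6), rel_err(ft$k_cell, 0.1))
  }))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})

test_that("E and k_cell are stable under subsampling the contact region", {
  sim <- simulate_approach_curve(ref_truth(0.01), seed = 55)
  cv <- preprocess_curve(sim$curve)
  ind <- compute_indentation(cv, 0)
  full <- fit_contact(ind$delta, ind$F, ind$F1, Delta1_init = 40)
  half <- fit_contact(ind$delta[c(TRUE, FALSE)], ind$F[c(TRUE, FALSE)],
                      ind$F1, Delta1_init = 40)
  expect_lt(rel_err(half$E, full$E), 0.1)
  expect_lt(rel_err(half$k_cell, full$k_cell), 0.1)
})

test_that("the full approach pipeline is exact without noise", {
  sim <- simulate_approach_curve(ref_truth(0), seed = 1)
  ft <- process_approach(sim$curve)
  expect_equal(ft$status, "ok")
  expect_lt(rel_err(ft$A, 0.05), 0.01)
  expect_lt(rel_err(ft$kappa_inv, 10), 0.01)
  expect_lt(rel_err(ft$E, 1e6), 0.01)
  expect_lt(rel_err(ft$k_cell, 0.1), 0.01)
  expect_lt(abs(ft$Z1), 0.5)
  expect_lt(abs(ft$delta0), 0.5)
  expect_lt(rel_err(ft$Delta1, 50), 0.02)
})

test_that("cost at the fitted parameters never exceeds cost at the truth", {
  sim <- simulate_approach_curve(ref_truth(0.01), seed = 66)
  cv <- preprocess_curve(sim$curve)
  ft <- fit_electrostatic(cv, -120, 0)
  sel <- cv$z >= -120 & cv$z < 0
  sse_truth <- sum((cv$F[sel] - 0.05 * exp(-0.1 * (0 - cv$z[sel])))^2)
  expect_lte(ft$sse, sse_truth + 1e-12)

  ind <- compute_indentation(cv, 0)
  con <- fit_contact(ind$delta, ind$F, ind$F1, Delta1_init = 40)
  a_true <- 2 * 1e-3 * tan(35 * pi / 180) / (pi * (1 - 0.25))
  M <- ifelse(ind$delta < 0, ind$F1,
              ifelse(ind$delta <= 50, ind$F1 + a_true * ind$delta^2,
                     ind$F1 + a_true * 2500 + 0.1 * (ind$delta - 50)))
  expect_lte(con$sse, sum((ind$F - M)^2) + 1e-12)
})
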