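truth_mueff <- model_extinction(palm_preset(), drs_basis)$values

test_that("noise-free extraction round-trips the generating extinction", {
  # equal detector transients: both single slopes and the dual slope agree
  inst <- equal_detector_instrument()
  ms <- simulate_measurement(palm_preset(), drs_basis, inst, drs_geom)
  for (ext in list(single_slope(ms, 1), single_slope(ms, 2),
                   dual_slope(ms))) {
    expect_true(all(ext$valid_mask))
    expect_equal(ext$mu_eff$values, truth_mueff, tolerance = 1e-12)
  }
  # unequal transients: dual slope still exact, single slopes biased
  ms2 <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom)
  expect_equal(dual_slope(ms2)$mu_eff$values, truth_mueff,
               tolerance = 1e-12)
  expect_gt(max(abs(single_slope(ms2, 1)$mu_eff$values - truth_mueff)),
            1e-3)
})

test_that("dual slope equals the mean of the two single slopes on any input", {
  for (ms in list(
    simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom),
    simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                         list(make_perturbation("D1B", drs_grid)),
                         noise = TRUE, seed = 5),
    simulate_measurement(phantom_preset(), drs_basis, drs_inst, drs_geom,
                         noise = TRUE, seed = 9))) {
    s1 <- single_slope(ms, 1); s2 <- single_slope(ms, 2)
    ds <- dual_slope(ms)
    joint <- s1$valid_mask & s2$valid_mask
    expect_identical(ds$valid_mask, joint)
    expect_equal(ds$mu_eff$values[joint],
                 (s1$mu_eff$values[joint] + s2$mu_eff$values[joint]) / 2,
                 tolerance = 1e-12)
  }
})

test_that("dual slope is invariant to per-channel multiplicative perturbations", {
  ms0 <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom)
  ref <- dual_slope(ms0)$mu_eff$values
  set.seed(31)
  # arbitrary wavelength-dependent transmittances on all four channels
  perts <- lapply(c("S1", "S2", "D1", "D2"), function(ch)
    spectral_perturbation(ch, runif(length(drs_grid), 0.05, 1)))
  ms4 <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                              perts)
  expect_equal(dual_slope(ms4)$mu_eff$values, ref, tolerance = 1e-10)
  # and to a single perturbed channel
  for (ch in c("S1", "S2", "D1", "D2")) {
    ms1 <- simulate_measurement(
      palm_preset(), drs_basis, drs_inst, drs_geom,
      list(spectral_perturbation(ch, runif(length(drs_grid), 0.05, 1))))
    expect_equal(dual_slope(ms1)$mu_eff$values, ref, tolerance = 1e-10)
  }
})

test_that("single slope cancels source perturbations but shifts under detector ones", {
  ms0 <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom)
  s1_0 <- single_slope(ms0, 1)$mu_eff$values
  s2_0 <- single_slope(ms0, 2)$mu_eff$values
  # source perturbation: both single slopes unchanged
  msS <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                              list(flat_perturbation("S1", 0.3)))
  expect_equal(single_slope(msS, 1)$mu_eff$values, s1_0, tolerance = 1e-12)
  expect_equal(single_slope(msS, 2)$mu_eff$values, s2_0, tolerance = 1e-12)
  # flat detector attenuation T: opposite shifts ln(T)/(r_L - r_S)
  T_ <- 0.5
  msD <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                              list(flat_perturbation("D1", T_)))
  shift <- log(T_) / (drs_geom$r_L - drs_geom$r_S)
  expect_equal(single_slope(msD, 1)$mu_eff$values, s1_0 + shift,
               tolerance = 1e-12)
  expect_equal(single_slope(msD, 2)$mu_eff$values, s2_0 - shift,
               tolerance = 1e-12)
})

test_that("extraction is invariant to common scaling and exposure reassignment", {
  ms <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom)
  # common constant on all four spectra cancels
  ms_scaled <- ms
  for (nm in c("I11", "I12", "I21", "I22"))
    ms_scaled[[nm]]$values <- 7.3 * ms[[nm]]$values
  expect_equal(single_slope(ms_scaled, 1)$mu_eff$values,
               single_slope(ms, 1)$mu_eff$values, tolerance = 1e-12)
  expect_equal(dual_slope(ms_scaled)$mu_eff$values,
               dual_slope(ms)$mu_eff$values, tolerance = 1e-12)
  # any alternative exposure assignment changes counts, not mu_eff
  inst_alt <- drs_inst
  inst_alt$exposures <- c(E11 = 33, E12 = 41, E21 = 15, E22 = 90)
  ms_alt <- simulate_measurement(palm_preset(), drs_basis, inst_alt,
                                 drs_geom)
  expect_false(isTRUE(all.equal(ms_alt$I11$values, ms$I11$values)))
  for (m in c("S1D1D2", "S2D1D2", "S1S2D1D2"))
    expect_equal(extract_extinction(ms_alt, m)$mu_eff$values,
                 extract_extinction(ms, m)$mu_eff$values,
                 tolerance = 1e-12)
})

test_that("non-positive ratio arguments are masked, or raised in strict mode", {
  ms <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom)
  ms$I11$values[10] <- -1         # emulate noisy dark over-subtraction
  ms$I11$values[20] <- 0
  s1 <- single_slope(ms, 1)
  expect_false(any(s1$valid_mask[c(10, 20)]))
  expect_true(all(is.na(s1$mu_eff$values[c(10, 20)])))
  expect_true(all(s1$valid_mask[-c(10, 20)]))
  ds <- dual_slope(ms)
  expect_false(any(ds$valid_mask[c(10, 20)]))
  expect_error(single_slope(ms, 1, strict = TRUE), "non-positive")
  # source-2 slope never touches I11: unaffected
  expect_true(all(single_slope(ms, 2)$valid_mask))
})
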