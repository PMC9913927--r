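test_that("fluence matches the diffusion Green's function", {
  g <- drs_grid
  # no absorption: no exponential decay, phi = 3 mu_s' / (4 pi r)
  expect_equal(fluence(2, flat_spec(0), flat_spec(1.5))$values,
               rep(3 * 1.5 / (4 * pi * 2), length(g)))
  # direct evaluation oracle at r = 2, mua = 0.01, musp = 1
  mueff <- sqrt(3 * 0.01 * 1.01)
  expect_equal(fluence(2, flat_spec(0.01), flat_spec(1))$values,
               rep(3 * 1.01 / (4 * pi * 2) * exp(-mueff * 2), length(g)))
  # doubling r: ratio (1/2) * exp(-mueff * r)
  f2 <- fluence(2, flat_spec(0.01), flat_spec(1))$values
  f4 <- fluence(4, flat_spec(0.01), flat_spec(1))$values
  expect_equal(f4 / f2, rep(0.5 * exp(-mueff * 2), length(g)))
  expect_error(fluence(0, flat_spec(0.01), flat_spec(1)), "positive")
})

test_that("noise-free counts are positive, exposure-linear, and perturbations multiply", {
  ms <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom)
  for (nm in c("I11", "I12", "I21", "I22"))
    expect_true(all(ms[[nm]]$values > 0))
  # doubling every exposure doubles every noise-free count
  inst2 <- drs_inst
  inst2$exposures <- 2 * drs_inst$exposures
  ms2 <- simulate_measurement(palm_preset(), drs_basis, inst2, drs_geom)
  for (nm in c("I11", "I12", "I21", "I22"))
    expect_equal(ms2[[nm]]$values, 2 * ms[[nm]]$values)
  # a flat transfer on source channel S1 scales I11 and I12 only
  msp <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                              list(flat_perturbation("S1", 0.6)))
  expect_equal(msp$I11$values, 0.6 * ms$I11$values)
  expect_equal(msp$I12$values, 0.6 * ms$I12$values)
  expect_equal(msp$I21$values, ms$I21$values)
  expect_equal(msp$I22$values, ms$I22$values)
})

test_that("perturbation application commutes with source rescaling", {
  inst_scaled <- drs_inst
  inst_scaled$source_intensity$values <-
    3 * drs_inst$source_intensity$values
  pert <- list(make_perturbation("D1G", drs_grid))
  a <- simulate_measurement(palm_preset(), drs_basis, inst_scaled,
                            drs_geom, pert)
  b <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                            pert)
  for (nm in c("I11", "I12", "I21", "I22"))
    expect_equal(a[[nm]]$values, 3 * b[[nm]]$values)
})

test_that("the ratio identity holds when detector transients are equal", {
  inst <- equal_detector_instrument()
  ms <- simulate_measurement(palm_preset(), drs_basis, inst, drs_geom)
  mueff <- model_extinction(palm_preset(), drs_basis)$values
  rS <- drs_geom$r_S; rL <- drs_geom$r_L
  E <- inst$exposures
  expect_equal(ms$I11$values / ms$I12$values,
               (rL * E[["E11"]]) / (rS * E[["E12"]]) *
                 exp(mueff * (rL - rS)))
})

test_that("simulation is seed-deterministic and flags negative counts", {
  a <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                            noise = TRUE, seed = 123)
  b <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                            noise = TRUE, seed = 123)
  expect_identical(a, b)
  c <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                            noise = TRUE, seed = 124)
  expect_false(identical(a$I11$values, c$I11$values))
  expect_error(simulate_measurement(palm_preset(), drs_basis, drs_inst,
                                    drs_geom, noise = TRUE), "seed")
  expect_error(simulate_measurement(
    palm_preset(), drs_basis, drs_inst, drs_geom,
    list(flat_perturbation("D1", 0.5), flat_perturbation("D1", 0.5))),
    "two perturbations")
})

test_that("noisy counts converge to the noise-free expectation (LLN at 3 sigma)", {
  grid <- spectral_grid(seq(460, 1030, 30))
  basis <- load_chromophore_basis(grid)
  inst <- default_instrument(grid, basis, drs_geom)
  clean <- simulate_measurement(palm_preset(), basis, inst, drs_geom)
  n_rep <- 200
  # accumulate I21 (long SDD, lowest counts) over seeds
  acc <- 0
  for (s in seq_len(n_rep))
    acc <- acc + simulate_measurement(palm_preset(), basis, inst, drs_geom,
                                      noise = TRUE, seed = s)$I21$values
  m <- acc / n_rep
  # theoretical sd of one averaged, dark-subtracted measurement
  S <- clean$I21$values
  navg <- 12
  v1 <- (S + inst$dark_level + inst$readout_sigma^2) / navg +
    (inst$dark_level + inst$readout_sigma^2) / navg
  z <- (m - S) / sqrt(v1 / n_rep)
  # the wavelength-averaged standardized deviation is N(0, 1/N): 3 sigma
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_true(all(abs(z) < 4.5))
})

test_that("perturbation transfer functions match their parametric definitions", {
  d1l <- make_perturbation("D1L", drs_grid)
  expect_equal(d1l$channel, "D1")
  expect_equal(unique(d1l$transfer$values), (105 / 200)^2)
  expect_equal(unique(d1l$transfer$values), 0.275625)
  s1l <- make_perturbation("S1L", drs_grid)
  expect_equal(unique(s1l$transfer$values), (105 / 400)^2)
  init <- make_perturbation("INIT", drs_grid)
  expect_equal(init$channel, "none")
  expect_equal(init$transfer$values, rep(1, length(drs_grid)))
  s1c <- make_perturbation("S1C", drs_grid)
  expect_true(all(s1c$transfer$values > 0.95 & s1c$transfer$values <= 1))
  for (lbl in perturbation_labels()) {
    p <- make_perturbation(lbl, drs_grid)
    expect_true(all(p$transfer$values >= 0 & p$transfer$values <= 1))
  }
  expect_error(make_perturbation("X9Q", drs_grid), "unknown")
})
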