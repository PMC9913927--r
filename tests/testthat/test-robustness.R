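make_ext <- function(values, method = "S1S2D1D2", mask = NULL) {
  e <- manual_extinction(values, method = method)
  if (!is.null(mask)) {
    e$valid_mask <- mask
    e$mu_eff$values[!mask] <- NA_real_
  }
  e
}

test_that("baseline spectrum is the pointwise mean over the joint mask", {
  n <- length(drs_grid)
  a <- make_ext(rep(1, n))
  expect_equal(baseline_spectrum(list(a, a))$values, rep(1, n))
  b <- make_ext(rep(1.4, n))       # flat offset: mean splits it
  expect_equal(baseline_spectrum(list(a, b))$values, rep(1.2, n))
  # six noisy replicates against an independent summation oracle
  set.seed(12)
  reps <- lapply(1:6, function(i) make_ext(rnorm(n, 1, 0.1)))
  oracle <- Reduce(`+`, lapply(reps, function(e) e$mu_eff$values)) / 6
  expect_equal(baseline_spectrum(reps)$values, oracle)
  # masks intersect
  m <- rep(TRUE, n); m[5] <- FALSE
  withmask <- baseline_spectrum(list(make_ext(rep(1, n), mask = m), a))
  expect_true(is.na(withmask$values[5]))
  expect_error(baseline_spectrum(list(a, make_ext(rep(1, n), "S1D1D2"))),
               "mixed")
  expect_error(baseline_spectrum(list(a)), "at least 2")
})

test_that("RMSE deviation matches hand-evaluated cases", {
  n <- length(drs_grid)
  base <- spectrum(rep(0.7, n), drs_grid, "mm^-1")
  expect_equal(rmse_deviation(make_ext(rep(0.7, n)), base), 0)
  # flat offset delta: RMSE = |delta|
  expect_equal(rmse_deviation(make_ext(rep(0.7 - 0.25, n)), base), 0.25)
  # offset on exactly half the wavelengths: |delta| / sqrt(2)
  half <- rep(0.7, n); half[seq_len(n / 2)] <- 0.7 + 0.3
  expect_equal(rmse_deviation(make_ext(half), base),
               0.3 / sqrt(2), tolerance = 1e-3)
  expect_error(rmse_deviation(make_ext(rep(1, n), mask = rep(FALSE, n)),
                              base), "empty")
})

test_that("mean deviation is the arithmetic mean", {
  expect_equal(mean_deviation(0.42), 0.42)
  expect_equal(mean_deviation(c(0.1, 0.2, 0.3)), 0.2)
  set.seed(3)
  x <- runif(3)
  expect_equal(mean_deviation(x), sum(x) / 3)
  expect_error(mean_deviation(numeric(0)), "no deviations")
})

test_that("relative parameter deviations follow the class-averaged definition", {
  p0 <- palm_preset()
  fits_base <- list(manual_fit(p0), manual_fit(p0))
  same <- list(D1C = list(manual_fit(p0)), S1C = list(manual_fit(p0)))
  rep0 <- relative_param_deviations(same, fits_base)
  expect_true(all(rep0$cells$mean_rel_dev == 0))
  # doubling one parameter in one repeat of one perturbation: cell = 1
  p2 <- p0; p2[["C_water"]] <- 2 * p0[["C_water"]]
  p2 <- do.call(tissue_params, as.list(unclass(p2)))
  one <- list(D1C = list(manual_fit(p2)))
  rep1 <- relative_param_deviations(one, fits_base)
  cw <- rep1$cells[rep1$cells$parameter == "C_water", ]
  expect_equal(cw$mean_rel_dev, 1.0)
  # brute-force recomputation oracle on a random small study
  set.seed(8)
  jig <- function() {
    q <- unclass(p0)
    for (nm in c("C_blood", "StO2", "C_water", "a", "f"))
      q[[nm]] <- q[[nm]] * runif(1, 0.8, 1.2)
    manual_fit(do.call(tissue_params, as.list(q)))
  }
  fits <- list(D1L = list(jig(), jig()), D1B = list(jig(), jig()),
               S1L = list(jig(), jig()))
  repx <- relative_param_deviations(fits, fits_base)
  base_vals <- unclass(p0)
  for (cl in c("detector", "source")) {
    labs <- names(fits)[ifelse(startsWith(names(fits), "D"),
                               "detector", "source") == cl]
    for (par in c("C_blood", "StO2", "C_water", "a", "f")) {
      devs <- unlist(lapply(labs, function(P)
        vapply(fits[[P]], function(f)
          abs(unclass(f$params)[[par]] - base_vals[[par]]) /
            base_vals[[par]], numeric(1))))
      cell <- repx$cells$mean_rel_dev[repx$cells$class == cl &
                                        repx$cells$parameter == par]
      expect_equal(cell, mean(devs))
    }
  }
  # near-zero baseline parameters are excluded, not divided by
  pz <- phantom_preset()
  repz <- relative_param_deviations(
    list(D1C = list(manual_fit(pz))), list(manual_fit(pz), manual_fit(pz)))
  expect_true(all(c("C_blood", "C_water", "f") %in% repz$excluded))
})

test_that("a noise-free, jitter-free study reproduces the cancellation identities", {
  cfg <- study_config(noise = FALSE, jitter = 0, n_perturbed = 1,
                      n_unperturbed = 2, fit = FALSE, seed = 1)
  res <- run_study(cfg, basis = drs_basis, instrument = drs_inst,
                   geometry = drs_geom)
  s <- res$deviation$summary
  dual <- s[s$method == "S1S2D1D2", ]
  expect_true(all(dual$mean_delta_mu_eff < 1e-12))
  singles <- s[s$method != "S1S2D1D2", ]
  src <- singles[startsWith(singles$perturbation, "S"), ]
  det <- singles[startsWith(singles$perturbation, "D"), ]
  expect_true(all(src$mean_delta_mu_eff < 1e-12))
  expect_true(all(det$mean_delta_mu_eff > 1e-6))
  # flat detector attenuations: closed-form |ln T| / (r_L - r_S)
  drop <- function(P, T_) {
    got <- det$mean_delta_mu_eff[det$perturbation == P]
    expect_equal(got, rep(abs(log(T_)) / 2, length(got)),
                 tolerance = 1e-10)
  }
  drop("D1L", 0.275625)
  drop("D1C", 0.98)
})

test_that("flat detector attenuation shifts the two single slopes oppositely", {
  ms0 <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom)
  msD <- simulate_measurement(palm_preset(), drs_basis, drs_inst, drs_geom,
                              list(flat_perturbation("D1", 0.6)))
  d1 <- single_slope(msD, 1)$mu_eff$values -
    single_slope(ms0, 1)$mu_eff$values
  d2 <- single_slope(msD, 2)$mu_eff$values -
    single_slope(ms0, 2)$mu_eff$values
  expect_true(all(d1 < 0))
  expect_true(all(d2 > 0))
  expect_equal(d1, -d2, tolerance = 1e-10)
})

test_that("studies are reproducible and noisy dual-slope beats single-slope", {
  cfg <- study_config(perturbations = c("D1L", "D1B"), n_perturbed = 2,
                      n_unperturbed = 3, fit = FALSE, seed = 42)
  a <- run_study(cfg, basis = drs_basis, instrument = drs_inst,
                 geometry = drs_geom)
  b <- run_study(cfg, basis = drs_basis, instrument = drs_inst,
                 geometry = drs_geom)
  expect_identical(a, b)
  s <- a$deviation$summary
  for (P in c("D1L", "D1B")) {
    dual <- s$mean_delta_mu_eff[s$method == "S1S2D1D2" &
                                  s$perturbation == P]
    for (m in c("S1D1D2", "S2D1D2"))
      expect_lt(dual, s$mean_delta_mu_eff[s$method == m &
                                            s$perturbation == P])
  }
})
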