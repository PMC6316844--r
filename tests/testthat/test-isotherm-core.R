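test_that("Beer-Lambert conversion is linear and rejects bad input", {
  spec <- nucleotide_spec("X", 320, 0.02, extinction_coefficient = 10000,
                          wavelength = 260)
  expect_equal(concentration_from_absorbance(0, spec), 0)
  expect_equal(concentration_from_absorbance(0.5, spec, path_length = 1),
               5.0e-5)
  # linearity
  expect_equal(concentration_from_absorbance(c(0.1, 0.2), spec),
               2 * concentration_from_absorbance(c(0.05, 0.1), spec))
  expect_error(concentration_from_absorbance(-0.01, spec), "calibration")
  expect_error(concentration_from_absorbance(0.1, spec, path_length = 0))
})

test_that("extinction coefficient is re-estimated from noisy standards", {
  set.seed(42)
  eps_true <- 11500
  conc <- seq(1e-5, 3e-4, length.out = 12)
  abs_noisy <- eps_true * conc * (1 + rnorm(12, sd = 0.01))
  fit <- fit_extinction(conc, abs_noisy)
  expect_lt(abs(fit$extinction_coefficient / eps_true - 1), 0.02)
  # against the independent regression-through-origin route
  lm_slope <- unname(coef(lm(abs_noisy ~ conc - 1))[1])
  expect_equal(fit$extinction_coefficient, lm_slope, tolerance = 1e-12)
})

test_that("mass balance gives the adsorbed quantity and conserves solute", {
  s <- batch_sample(c0 = 2.0e-3, ceq = 1.5e-3, volume = 1e-3, mass = 0.010)
  expect_equal(as.numeric(adsorbed_quantity(s)), 5.0e-5)
  expect_false(attr(adsorbed_quantity(s), "negative_adsorption"))
  # no depletion
  s0 <- batch_sample(c0 = 1e-3, ceq = 1e-3, volume = 1e-3, mass = 0.01)
  expect_equal(as.numeric(adsorbed_quantity(s0)), 0)
  # conservation identity on random valid samples
  set.seed(7)
  for (i in 1:200) {
    c0 <- runif(1, 0, 3.5e-3); ceq <- runif(1, 0, c0)
    v <- runif(1, 5e-4, 2e-3); m <- runif(1, 0.005, 0.05)
    sm <- batch_sample(c0, ceq, v, m)
    q <- as.numeric(adsorbed_quantity(sm))
    expect_lt(abs(q * m + ceq * v - c0 * v), 1e-12 * c0 * v + 1e-300)
  }
})

test_that("negative adsorption is flagged and carried, never clipped", {
  s <- batch_sample(c0 = 1.0e-3, ceq = 1.2e-3, volume = 1e-3, mass = 0.010)
  expect_warning(q <- adsorbed_quantity(s), "negative adsorption")
  expect_equal(as.numeric(q), -2e-5)
  expect_true(attr(q, "negative_adsorption"))
})

test_that("build_isotherm aggregates replicates and sorts points", {
  mk <- function(c0, ceq, r) batch_sample(c0, ceq, 1e-3, 0.01,
                                          ph = 7, temperature = 25,
                                          salts = c(NaCl = 0.5),
                                          replicate_id = r)
  # replicates with q = {4,5,6}e-5 at one c0 (v/m = 0.1 L/g)
  reps <- list(mk(2e-3, 2e-3 - 4e-4, 1), mk(2e-3, 2e-3 - 5e-4, 2),
               mk(2e-3, 2e-3 - 6e-4, 3), mk(1e-3, 0.8e-3, 1))
  nuc <- nucleotide_spec("X", 320, 0.02)
  min_ <- mineral_spec("M", FALSE, 10, 8, 2)
  iso <- build_isotherm(reps, nuc, min_)
  expect_equal(nrow(iso), 2)
  i <- which.max(iso$c_eq)
  expect_equal(iso$q_ads[i], 5e-5)
  expect_equal(iso$sd_q[i], sd(c(4, 5, 6) * 1e-5))
  expect_equal(iso$sd_q[-i], 0)
  expect_true(all(diff(iso$c_eq) > 0))
  # identical replicates -> sd 0
  iso2 <- build_isotherm(list(mk(1e-3, 8e-4, 1), mk(1e-3, 8e-4, 2),
                              mk(1e-3, 8e-4, 3)), nuc, min_)
  expect_equal(nrow(iso2), 1)
  expect_equal(iso2$sd_q, 0)
})

test_that("build_isotherm is permutation-invariant and rejects mixed conditions", {
  set.seed(11)
  mk <- function(c0, ceq) batch_sample(c0, ceq, 1e-3, 0.01, ph = 7,
                                       temperature = 25,
                                       salts = c(NaCl = 0.5, MgCl2 = 0.05))
  samples <- lapply(seq(2e-4, 3e-3, length.out = 9),
                    function(c0) mk(c0, c0 * runif(1, 0.5, 0.95)))
  nuc <- nucleotide_spec("X", 320, 0.02)
  min_ <- mineral_spec("M", FALSE, 10, 8, 2)
  a <- build_isotherm(samples, nuc, min_)
  b <- build_isotherm(samples[sample(length(samples))], nuc, min_)
  expect_identical(a$c_eq, b$c_eq)
  expect_identical(a$q_ads, b$q_ads)
  bad <- c(samples, list(batch_sample(1e-3, 5e-4, 1e-3, 0.01, ph = 4,
                                      temperature = 25,
                                      salts = c(NaCl = 0.5, MgCl2 = 0.05))))
  expect_error(build_isotherm(bad, nuc, min_), "ph")
  bad2 <- c(samples, list(batch_sample(1e-3, 5e-4, 1e-3, 0.01, ph = 7,
                                       temperature = 25,
                                       salts = c(NaCl = 2))))
  expect_error(build_isotherm(bad2, nuc, min_), "salts")
})

test_that("batch and isotherm CSVs round-trip bit-identically", {
  sim <- gen_isotherm(3, noise = 0.02)
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_batch_csv(sim$samples, tmp, nucleotide = "synGMP",
                  mineral = "synClay-fine")
  back <- read_batch_csv(tmp)
  expect_identical(vapply(back, `[[`, numeric(1), "ceq"),
                   setNames(vapply(sim$samples, `[[`, numeric(1), "ceq"),
                            names(back)))
  iso <- build_isotherm(sim$samples, sim$nucleotide, sim$mineral)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_isotherm_csv(iso, tmp2)
  iso2 <- read_isotherm_csv(tmp2)
  expect_identical(iso$c_eq, iso2$c_eq)
  expect_identical(iso$q_ads, iso2$q_ads)
  expect_identical(iso$sd_q, iso2$sd_q)
  expect_equal(attr(iso2, "nucleotide")$solubility,
               sim$nucleotide$solubility)
  expect_equal(attr(iso2, "mineral")$ssa_edge, sim$mineral$ssa_edge)
  # malformed file is rejected with a diagnostic
  writeLines(c("a,b", "1,2"), tmp2)
  expect_error(read_isotherm_csv(tmp2), "missing columns")
})
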