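test_that("generators are deterministic in the seed", {
  a <- gen_isotherm(42); b <- gen_isotherm(42)
  expect_identical(vapply(a$samples, `[[`, numeric(1), "ceq"),
                   vapply(b$samples, `[[`, numeric(1), "ceq"))
  expect_false(identical(
    vapply(gen_isotherm(43)$samples, `[[`, numeric(1), "ceq"),
    vapply(a$samples, `[[`, numeric(1), "ceq")))
  g1 <- gen_gas_isotherm(7); g2 <- gen_gas_isotherm(7)
  expect_identical(g1$gas$v_ads, g2$gas$v_ads)
  t1 <- gen_trajectory(5, "na", n_frames = 6)
  t2 <- gen_trajectory(5, "na", n_frames = 6)
  expect_identical(t1$frames[[6]]$coords, t2$frames[[6]]$coords)
  expect_identical(t1$truth$states, t2$truth$states)
  # the scenario wrapper reproduces the direct call
  sc <- synthetic_scenario("gas_isotherm", seed = 7)
  expect_identical(generate(sc)$gas$v_ads, g1$gas$v_ads)
  # and the caller's RNG stream is left untouched
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(gen_isotherm(99)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("generated batch samples close the mass balance before noise", {
  sim <- gen_isotherm(1, model = "classic", q_max = 5e-5, k = 2000,
                      noise = 0)
  for (s in sim$samples) {
    q <- langmuir_eval("classic", list(q_max = 5e-5, k = 2000), s$ceq)
    expect_lt(abs(s$ceq + q * s$mass / s$volume - s$c0), 1e-11 * s$c0)
  }
  # inert mineral: no depletion at all
  sim0 <- gen_isotherm(2, q_max = 0, noise = 0)
  expect_true(all(vapply(sim0$samples, function(s) s$ceq == s$c0,
                         logical(1))))
})

test_that("the homologous family collapses by construction", {
  fam <- gen_homologous_family(3, noise = 0.02)
  expect_gte(length(fam$isotherms), 2)
  sols <- vapply(fam$isotherms,
                 function(i) attr(i, "nucleotide")$solubility, numeric(1))
  expect_identical(unname(sols), unname(fam$truth$solubilities))
  red <- collapse_score(lapply(fam$isotherms, reduce_concentration))$score
  raw <- collapse_score(fam$isotherms)$score
  expect_lt(red, raw)
})

test_that("grain pair uptake scales with edge area only", {
  gp <- gen_grain_pair(4, noise = 0)
  q1 <- gp$isotherms[[1]]$q_ads; q2 <- gp$isotherms[[2]]$q_ads
  expect_equal(q1 / q2,
               rep(gp$truth$ssa_edge[1] / gp$truth$ssa_edge[2],
                   length(q1)))
  d1 <- to_density(gp$isotherms[[1]], "edge")
  d2 <- to_density(gp$isotherms[[2]], "edge")
  expect_equal(d1$d, d2$d, tolerance = 1e-12)
  # per-gram and total-basis curves do not coincide
  expect_gt(collapse_score(gp$isotherms)$score,
            collapse_score(list(d1, d2))$score)
})

test_that("gas generator places the derivative peak at the domain energy", {
  g <- gen_gas_isotherm(5, domains = list(local_domain(5, -8, 0)),
                        noise = 0)
  d <- derivative_isotherm(g$gas, smoothing_window = 3)
  i <- which.max(d$dv_du)
  expect_lt(abs(d$u[i] - (-8)), 2 * abs(diff(d$u[1:2])))
})

test_that("trajectory truth is reproduced by the classifier at zero jitter", {
  tr <- gen_trajectory(6, "na", n_frames = 300, jitter = 0)
  ss <- state_series(tr$frames)
  expect_identical(ss$frames$state, tr$truth$states)
  expect_equal(tr$truth$expected_duration_ratio, 0.4)
  # stationary fraction 2/7 under the default Na-like rates
  expect_equal(tr$truth$pi_ads, 2 / 7)
  # Ca-like expected adsorbed charge: -2 + 2 * 2.5 = +3
  trc <- gen_trajectory(6, "ca", n_frames = 4)
  expect_equal(trc$truth$expected_adsorbed_charge, 3)
  expect_error(gen_trajectory(1, "na", n_frames = 4, cutoff = 3),
               "configuration error")
})

test_that("bound-ion counts drive the complex charge exactly", {
  tr <- gen_trajectory(9, "na", n_frames = 60, jitter = 0)
  ss <- state_series(tr$frames)
  expect_equal(ss$frames$complex_charge,
               -2 + tr$truth$cation_charge * tr$truth$bound_counts)
})
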