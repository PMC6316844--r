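make_iso <- function(c_eq, q, solubility = 0.02, ssa = c(92, 80, 12),
                     name = "X") {
  isotherm(c_eq, q,
           nucleotide = nucleotide_spec(name, 320, solubility),
           mineral = mineral_spec("M", TRUE, ssa[1], ssa[2], ssa[3]))
}

test_that("reduced concentration is c_eq / solubility", {
  iso <- make_iso(c(2e-3, 0.1), c(1e-5, 2e-5), solubility = 0.1)
  red <- reduce_concentration(iso)
  expect_equal(red$x, c(0.02, 1))  # saturation point maps to x = 1
  expect_equal(red$d, iso$q_ads)
  expect_identical(attr(red, "concentration_mode"), "reduced")
  noS <- isotherm(c(1e-3, 2e-3), c(1e-5, 2e-5))
  expect_error(reduce_concentration(noS), "solubility")
})

test_that("density normalization divides by the requested surface area", {
  iso <- make_iso(c(1e-3, 2e-3), c(1e-6, 2e-6), ssa = c(92, 80, 10))
  d <- to_density(iso, "edge")
  expect_equal(d$d, c(1e-7, 2e-7))
  expect_identical(attr(d, "basis"), "edge")
  iso0 <- isotherm(c(1e-3, 2e-3), c(1e-6, 2e-6),
                   nucleotide = nucleotide_spec("X", 320, 0.02),
                   mineral = mineral_spec("M", TRUE, 10, 10, 0))
  expect_error(to_density(iso0, "edge"), "basis area unavailable")
  # sd propagates linearly
  iso_sd <- make_iso(c(1e-3, 2e-3), c(1e-6, 2e-6), ssa = c(92, 80, 10))
  iso_sd$sd_q <- c(1e-7, 2e-7)
  expect_equal(to_density(iso_sd, "edge")$sd_d, c(1e-8, 2e-8))
})

test_that("reduce_concentration and to_density commute", {
  iso <- make_iso(seq(1e-4, 3e-3, length.out = 6),
                  seq(1e-6, 5e-6, length.out = 6))
  a <- reduce_concentration(to_density(iso, "edge"))
  b <- to_density(reduce_concentration(iso), "edge")
  expect_equal(a$x, b$x)
  expect_equal(a$d, b$d)
  expect_identical(attr(a, "basis"), attr(b, "basis"))
  expect_identical(attr(a, "concentration_mode"),
                   attr(b, "concentration_mode"))
})

test_that("collapse score is zero for identical curves and has the closed form for flat pairs", {
  x <- seq(0.01, 1, length.out = 20)
  c1 <- normalized_isotherm(x, rep(2, 20))
  expect_equal(collapse_score(list(c1, c1))$score, 0)
  # two flat curves at 1 and 3: sd/mean = sqrt(2)/2 everywhere
  f1 <- normalized_isotherm(x, rep(1, 20))
  f3 <- normalized_isotherm(x, rep(3, 20))
  expect_equal(collapse_score(list(f1, f3))$score, sqrt(2) / 2,
               tolerance = 1e-12)
  # scale invariance: common factor leaves the score unchanged
  set.seed(5)
  g1 <- normalized_isotherm(x, runif(20, 1, 2))
  g2 <- normalized_isotherm(x, runif(20, 1, 2))
  s1 <- collapse_score(list(g1, g2))$score
  g1s <- normalized_isotherm(x, g1$d * 7.3)
  g2s <- normalized_isotherm(x, g2$d * 7.3)
  expect_equal(collapse_score(list(g1s, g2s))$score, s1, tolerance = 1e-12)
  expect_error(collapse_score(list(c1)), "at least 2")
  far <- normalized_isotherm(x + 100, rep(1, 20))
  expect_error(collapse_score(list(c1, far)), "disjoint")
})

test_that("homologous curves collapse on the reduced axis", {
  # shared reduced shape, solubilities 5x apart, no noise
  fam <- gen_homologous_family(1, solubilities = c(a = 0.004, b = 0.02),
                               noise = 0)
  red <- lapply(fam$isotherms, reduce_concentration)
  expect_equal(collapse_score(red)$score, 0, tolerance = 1e-12)
  raw <- collapse_score(fam$isotherms)$score
  expect_gt(raw, 0.1)
})

test_that("plateau density finds flat tails and flags rising curves", {
  x <- seq(0.1, 1, length.out = 12)
  flat <- normalized_isotherm(x, c(seq(1e-6, 2e-6, length.out = 6),
                                   rep(2e-6, 6)))
  p <- plateau_density(flat)
  expect_equal(p$plateau, 2e-6)
  expect_equal(p$sd, 0)
  expect_false(p$no_plateau)
  rising <- normalized_isotherm(x, x * 1e-5)
  expect_true(plateau_density(rising, tail_fraction = 0.5)$no_plateau)
  expect_error(plateau_density(flat, tail_fraction = 0.01), "fewer than 3")
})

test_that("plateau of a saturating Langmuir curve matches q_max / area", {
  q_max <- 2e-6; k <- 5000; s <- 0.02; ssa <- 10
  # x covering >= 10/K in concentration: c up to 10/k
  c_eq <- seq(2 / k, 40 / k, length.out = 30)
  q <- langmuir_eval("classic", list(q_max = q_max * ssa, k = k), c_eq)
  iso <- make_iso(c_eq, q, solubility = s, ssa = c(92, 80, ssa))
  p <- plateau_density(to_density(iso, "edge"))
  expect_lt(abs(p$plateau - q_max) / q_max, 0.05)
})
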