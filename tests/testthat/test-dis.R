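test_that("derivative of a linear adsorption branch is its slope", {
  u <- seq(-10, -3, length.out = 40)
  v <- 5 + 0.8 * u
  gas <- gas_isotherm(exp(u), v)
  d <- derivative_isotherm(gas)
  expect_equal(d$u, u)
  expect_equal(d$dv_du, rep(0.8, 40), tolerance = 1e-10)
  expect_error(derivative_isotherm(gas, smoothing_window = 99), "larger")
})

test_that("derivative of a logistic uptake peaks at u0 with height V_m/4", {
  v_m <- 6; u0 <- -7
  u <- seq(-14, -3, length.out = 300)
  v <- v_m * exp(u - u0) / (1 + exp(u - u0))
  d <- derivative_isotherm(gas_isotherm(exp(u), v), smoothing_window = 3)
  i <- which.max(d$dv_du)
  expect_lt(abs(d$u[i] - u0), diff(u)[1] + 1e-9)
  expect_lt(abs(max(d$dv_du) - v_m / 4) / (v_m / 4), 0.01)
})

test_that("smoothed derivative tracks the analytic derivative under noise", {
  set.seed(21)
  v_m <- 6; u0 <- -7
  u <- seq(-14, -3, length.out = 200)
  v <- v_m * exp(u - u0) / (1 + exp(u - u0))
  vn <- v * (1 + rnorm(200, sd = 0.003))
  d <- suppressWarnings(
    derivative_isotherm(gas_isotherm(exp(u), vn, noise_tol = 0.05),
                        smoothing_window = 7))
  truth <- v_m * exp(u - u0) / (1 + exp(u - u0))^2
  rms <- sqrt(mean((d$dv_du - truth)^2)) / (v_m / 4)
  expect_lt(rms, 0.03)
})

test_that("local derivative isotherms have the stated closed forms", {
  grid <- seq(-15, -1, length.out = 400)
  # omega = 0: logistic
  d0 <- local_domain(2, -8, 0)
  dv0 <- local_derivative(d0, grid)
  truth <- 2 * exp(grid + 8) / (1 + exp(grid + 8))^2
  expect_equal(dv0, truth, tolerance = 1e-8)
  # omega = 2 at half coverage: dv/du = v_m / (4 - 2)
  d2 <- local_domain(2, -8, 2)
  expect_equal(local_derivative(d2, -8), 2 / 2, tolerance = 1e-9)
  # non-negative and unimodal
  dv2 <- local_derivative(d2, grid)
  expect_true(all(dv2 >= 0))
  peak <- which.max(dv2)
  expect_true(all(diff(dv2[1:peak]) >= -1e-12))
  expect_true(all(diff(dv2[peak:length(dv2)]) <= 1e-12))
  # peak height non-decreasing in omega at fixed v_m
  heights <- vapply(c(0, 1, 2, 3, 3.9), function(om)
    max(local_derivative(local_domain(2, -8, om), grid)), numeric(1))
  expect_true(all(diff(heights) > 0))
  expect_error(local_domain(2, -8, 4), "multivalued")
})

test_that("coverage solver matches table inversion of the forward map", {
  # forward map u(theta), inverted by dense table lookup
  for (om in c(0, 1.5, 3.5)) {
    th_tab <- seq(1e-6, 1 - 1e-6, length.out = 200001)
    u_tab <- -8 + log(th_tab / (1 - th_tab)) - om * (th_tab - 0.5)
    u_q <- seq(-13, -3, length.out = 50)
    th_ref <- approx(u_tab, th_tab, xout = u_q)$y
    th <- nucleosorb:::theta_of_u(u_q, -8, om)
    expect_lt(max(abs(th - th_ref)), 1e-6)
    # and the solver satisfies the defining equation to high precision
    resid <- -8 + log(th / (1 - th)) - om * (th - 0.5) - u_q
    expect_lt(max(abs(resid)), 1e-8)
  }
})

test_that("the local derivative integrates to the monolayer capacity", {
  grid <- seq(-30, -1e-4, length.out = 4000)
  for (om in c(0, 2)) {
    dv <- local_derivative(local_domain(3, -9, om), grid)
    expect_lt(abs(pracma::trapz(grid, dv) / 3 - 1), 1e-3)
  }
})

test_that("monolayer volume converts to area through the cross-section", {
  expect_equal(domain_area(0), 0)
  expect_equal(domain_area(22414), 6.02214076e23 * 0.138 * 1e-18,
               tolerance = 1e-9)
  # one-domain data: fitted area equals the truth-domain area
  g <- gen_gas_isotherm(5, domains = list(local_domain(5, -8, 1)),
                        noise = 0)
  f <- fit_dis(derivative_isotherm(g$gas, smoothing_window = 3), 1)
  expect_lt(abs(sum(f$areas) / domain_area(5) - 1), 0.01)
})

test_that("a single noise-free domain is recovered to < 0.5 %", {
  g <- gen_gas_isotherm(2, domains = list(local_domain(5, -8, 1.2)),
                        n_points = 300, noise = 0)
  f <- fit_dis(derivative_isotherm(g$gas, smoothing_window = 3), 1)
  d <- f$domains[[1]]
  expect_lt(abs(d$v_m / 5 - 1), 0.005)
  expect_lt(abs(d$u_half / (-8) - 1), 0.005)
  expect_lt(abs(d$omega / 1.2 - 1), 0.005)
})

test_that("residual is non-increasing as domains are added", {
  g <- gen_gas_isotherm(6)
  d <- suppressWarnings(derivative_isotherm(g$gas))
  r <- vapply(1:3, function(n)
    suppressWarnings(fit_dis(d, n)$residual_rms), numeric(1))
  expect_true(all(diff(r) <= 1e-9))
})

test_that("over-parameterized fits are rejected", {
  g <- gen_gas_isotherm(3, n_points = 20)
  d <- suppressWarnings(derivative_isotherm(g$gas))
  expect_error(suppressWarnings(fit_dis(d, 7)), "over-parameterized")
})
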