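#' Construct a low-pressure gas adsorption isotherm
#'
#' Quasi-equilibrium argon volumetry resolves the very low relative pressures
#' (P/P0 < 0.05) where monolayer adsorption discriminates surface sites by
#' energy: high-energy lateral (edge) faces of clay particles fill before the
#' basal faces.
#'
#' @param p_over_p0 Relative pressures, strictly increasing in (0, 1).
#' @param v_ads Adsorbed volumes, STP cm^3/g, non-decreasing within
#'   `noise_tol` (relative).
#' @param noise_tol Allowed relative decrease between consecutive points.
#' @return A data frame of class `"gas_isotherm"`.
#' @export
gas_isotherm <- function(p_over_p0, v_ads, noise_tol = 0.02) {
  stopifnot(length(p_over_p0) == length(v_ads))
  if (any(p_over_p0 <= 0) || any(p_over_p0 >= 1))
    stop("relative pressures must lie strictly in (0, 1)")
  if (any(diff(p_over_p0) <= 0))
    stop("relative pressures must be strictly increasing")
  vmax <- max(abs(v_ads), 1e-300)
  if (any(diff(v_ads) < -noise_tol * vmax))
    stop("adsorbed volume decreases beyond noise tolerance")
  structure(data.frame(p_over_p0 = p_over_p0, v_ads = v_ads),
            class = c("gas_isotherm", "data.frame"))
}

#' Derivative adsorption isotherm
#'
#' Transforms a gas isotherm into the representation `dV_ads/d(ln(P/P0))`
#' versus `u = ln(P/P0)`; the abscissa is the free energy of adsorption in kT
#' units, so site populations of different energies appear as separate peaks.
#'
#' The derivative is estimated by a local quadratic fit over a centered
#' sliding window of `smoothing_window` points (shrunk near the series ends,
#' never below 3 points). Negative values — numerical artifacts of noise —
#' are clamped to zero; the number clamped is reported in the
#' `n_clamped` attribute.
#'
#' @param gas A [gas_isotherm()] with at least 10 points.
#' @param smoothing_window Odd window length (default 7).
#' @return A data frame of class `"derivative_isotherm"` with columns `u`
#'   (ln P/P0, < 0) and `dv_du` (STP cm^3/g per ln-unit).
#' @export
derivative_isotherm <- function(gas, smoothing_window = 7) {
  stopifnot(inherits(gas, "gas_isotherm"))
  n <- nrow(gas)
  if (n < 10) stop("need at least 10 points")
  if (smoothing_window > n)
    stop("smoothing_window larger than the series")
  half <- smoothing_window %/% 2
  u <- log(gas$p_over_p0)
  v <- gas$v_ads
  dv <- numeric(n)
  for (i in seq_len(n)) {
    # keep the window at full width near the ends (one-sided extension),
    # otherwise boundary estimates get noisy
    lo <- max(1L, i - half); hi <- min(n, i + half)
    if (hi - lo + 1L < max(smoothing_window, 3L)) {
      if (lo == 1L) hi <- min(n, lo + max(smoothing_window, 3L) - 1L)
      else lo <- max(1L, hi - max(smoothing_window, 3L) + 1L)
    }
    uu <- u[lo:hi] - u[i]
    co <- stats::lm.fit(cbind(1, uu, uu^2), v[lo:hi])$coefficients
    dv[i] <- co[2]
  }
  n_clamped <- sum(dv < 0)
  if (n_clamped > 0)
    warning(n_clamped, " negative derivative value(s) clamped to 0")
  dv[dv < 0] <- 0
  structure(data.frame(u = u, dv_du = dv),
            n_clamped = n_clamped,
            class = c("derivative_isotherm", "data.frame"))
}

#' One local adsorption domain
#'
#' A patchwise-homogeneous surface domain whose filling follows a Langmuir
#' isotherm with Bragg-Williams lateral interactions (Hill-de Boer-like in
#' ln P space): coverage `theta(u)` solves
#' `u = u_half + ln(theta/(1-theta)) - omega*(theta - 1/2)`. For
#' `omega < 4` the relation is single-valued since
#' `du/dtheta = 1/(theta(1-theta)) - omega > 0`.
#'
#' @param v_m Monolayer capacity, STP cm^3/g (>= 0).
#' @param u_half ln(P/P0) at half coverage, < 0; proxy for the adsorption
#'   energy in kT.
#' @param omega Lateral interaction energy in kT, in `[0, 4)`.
#' @param label `"edge"`, `"basal"`, or `"unassigned"`.
#' @return A list of class `"local_domain"`.
#' @export
local_domain <- function(v_m, u_half, omega = 0,
                         label = c("unassigned", "edge", "basal")) {
  label <- match.arg(label)
  if (!is.finite(v_m) || v_m < 0) stop("v_m must be >= 0")
  if (!is.finite(u_half) || u_half >= 0) stop("u_half must be < 0")
  if (!is.finite(omega) || omega < 0 || omega >= 4)
    stop("multivalued local isotherm: omega must lie in [0, 4)")
  structure(list(v_m = v_m, u_half = u_half, omega = omega, label = label),
            class = "local_domain")
}

# coverage theta(u) by monotone bisection of
# g(theta) = u_half + ln(theta/(1-theta)) - omega*(theta - 1/2) - u,
# vectorized over u; unique root for omega < 4 since du/dtheta > 0
theta_of_u <- function(u, u_half, omega, tol = 1e-13) {
  lo <- rep(1e-16, length(u)); hi <- rep(1 - 1e-16, length(u))
  g <- function(th) u_half + log(th / (1 - th)) - omega * (th - 0.5) - u
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    pos <- g(mid) > 0
    hi[pos] <- mid[pos]
    lo[!pos] <- mid[!pos]
    if (max(hi - lo) < tol) break
  }
  (lo + hi) / 2
}

#' Local derivative isotherm of one domain
#'
#' Evaluates `dv/du = v_m / (1/(theta(1-theta)) - omega)` on a grid of
#' `u = ln(P/P0)` values. With `omega = 0` this is the logistic derivative
#' (peak `v_m/4` at `u_half`); lateral attraction sharpens the peak (height
#' `v_m/(4 - omega)` at half coverage) without moving its position.
#'
#' @param domain A [local_domain()].
#' @param grid Numeric vector of `u` values.
#' @return Numeric vector of `dv/du` values, same length as `grid`.
#' @export
local_derivative <- function(domain, grid) {
  stopifnot(inherits(domain, "local_domain"))
  th <- theta_of_u(grid, domain$u_half, domain$omega)
  dv <- ifelse(th <= 0 | th >= 1, 0,
               domain$v_m / (1 / (th * (1 - th)) - domain$omega))
  dv
}

# total adsorbed volume of a set of domains at u values
domains_v_ads <- function(domains, u) {
  out <- numeric(length(u))
  for (d in domains) out <- out + d$v_m * theta_of_u(u, d$u_half, d$omega)
  out
}

#' Surface area equivalent of a monolayer capacity
#'
#' Converts an STP monolayer volume into a specific surface area through the
#' molecular cross-section: `area = (v_m / 22414) * N_A * sigma`, with the
#' conventional argon cross-section 0.138 nm^2 at 77 K by default.
#'
#' @param domain A [local_domain()] (or a plain `v_m` number).
#' @param cross_section Molecular cross-section, nm^2.
#' @return Area in m^2/g.
#' @export
domain_area <- function(domain, cross_section = 0.138) {
  v_m <- if (inherits(domain, "local_domain")) domain$v_m else domain
  stopifnot(v_m >= 0, cross_section > 0)
  # cm^3 STP -> mol -> molecules -> nm^2 -> m^2
  (v_m / 22414) * 6.02214076e23 * cross_section * 1e-18
}

# initial u_half guesses: greedy maxima of the (lightly smoothed)
# experimental derivative with an exclusion radius, so noise spikes around
# one strong peak cannot absorb all the starting positions
pick_peaks <- function(u, dv, n, radius = NULL) {
  if (is.null(radius))
    radius <- max(1.5, (max(u) - min(u)) / (2 * n + 1))
  sm <- if (length(dv) >= 9)
    stats::filter(dv, rep(1 / 5, 5), sides = 2) else dv
  sm[is.na(sm)] <- dv[is.na(sm)]
  sm <- as.numeric(sm)
  # only interior local maxima qualify: boundary spikes of the numerical
  # derivative must not absorb a starting position
  n_pts <- length(u)
  interior_max <- c(FALSE, sm[2:(n_pts - 1)] >= sm[1:(n_pts - 2)] &
                      sm[2:(n_pts - 1)] >= sm[3:n_pts], FALSE)
  avail <- if (any(interior_max)) interior_max else rep(TRUE, n_pts)
  u_pk <- h_pk <- numeric(n)
  for (i in seq_len(n)) {
    if (!any(avail)) {
      gap <- seq(min(u), max(u), length.out = n + 2)[i + 1]
      u_pk[i] <- gap; h_pk[i] <- max(dv) / 4
      next
    }
    j <- which(avail)[which.max(sm[avail])]
    u_pk[i] <- u[j]; h_pk[i] <- max(sm[j], max(dv) / 20)
    avail <- avail & abs(u - u[j]) > radius
  }
  list(u = u_pk, h = h_pk)
}

#' Decompose a derivative isotherm into local adsorption domains
#'
#' Derivative Isotherm Summation: fits the experimental
#' `dV/d(ln P/P0)` curve as a sum of `n_domains` local derivative isotherms
#' (see [local_derivative()]), each with parameters `(v_m, u_half, omega)`.
#' Bounded Levenberg-Marquardt least squares with deterministic multi-starts
#' seeded from peak-picking of the experimental derivative. Domains are then
#' labelled `edge` (high energy, low `u_half`) or `basal` by an energy split
#' threshold, and the edge fraction `sum(edge v_m) / sum(v_m)` reported —
#' the relative proportion of lateral to total surface.
#'
#' @param deriv A [derivative_isotherm()] (or the output of
#'   [derivative_isotherm()] applied to a [gas_isotherm()]).
#' @param n_domains Number of local domains (>= 1).
#' @param init Optional list of [local_domain()] starting guesses.
#' @param split_u Energy threshold: domains with `u_half < split_u` are
#'   labelled edge. Default `NULL` picks the `u` of the deepest experimental
#'   minimum inside the largest gap between fitted `u_half` values; supply a
#'   value when one surface class may be absent.
#' @param u_max Fit only `u <= u_max` (default `log(0.05)`, the monolayer
#'   regime).
#' @param cross_section Argon cross-section (nm^2) for per-domain areas.
#' @param n_starts Number of deterministic multi-starts (default 10).
#' @return A list of class `"dis_fit"`: `domains` (list of
#'   [local_domain()]), `edge_fraction`, `total_v_m`, `areas` (m^2/g),
#'   `residual_rms`, `split_u`, `converged`, `fitted` (data frame `u`,
#'   `dv_du`).
#' @export
fit_dis <- function(deriv, n_domains, init = NULL, split_u = NULL,
                    u_max = log(0.05), cross_section = 0.138,
                    n_starts = 10) {
  stopifnot(inherits(deriv, "derivative_isotherm"), n_domains >= 1)
  keep <- deriv$u <= u_max
  u <- deriv$u[keep]; dv <- deriv$dv_du[keep]
  n_par <- 3L * n_domains
  if (length(u) <= n_par)
    stop("over-parameterized: ", n_par, " parameters for ", length(u),
         " points")
  if (length(u) < 5L * n_par)
    warning("fewer than ", 5L * n_par, " points for ", n_domains,
            " domain(s); fit may be unstable")
  u_lo <- min(u); u_hi <- min(max(u), -1e-6)

  # parameter vector: (log(v_m + eps), u_half, omega) per domain
  unpack <- function(th) {
    lapply(seq_len(n_domains), function(i) {
      j <- 3 * (i - 1)
      list(v_m = exp(th[j + 1]), u_half = th[j + 2], omega = th[j + 3])
    })
  }
  model_dv <- function(th) {
    doms <- unpack(th)
    out <- numeric(length(u))
    for (d in doms) {
      thta <- theta_of_u(u, d$u_half, d$omega)
      out <- out + ifelse(thta <= 0 | thta >= 1, 0,
                          d$v_m / (1 / (thta * (1 - thta)) - d$omega))
    }
    out
  }
  resid_fn <- function(th) dv - model_dv(th)
  lower <- rep(c(log(1e-8), u_lo, 0), n_domains)
  upper <- rep(c(log(max(dv) * 50 + 1), u_hi, 3.999), n_domains)

  peaks <- pick_peaks(u, dv, n_domains)
  make_start <- function(k) {
    # alternate omega guesses and jitter u_half deterministically
    om <- c(0, 2, 1, 3, 0.5)[(k - 1) %% 5 + 1]
    shift <- c(0, 0.5, -0.5, 1, -1)[((k - 1) %/% 5) %% 5 + 1]
    uh <- pmin(pmax(peaks$u + shift, u_lo), u_hi)
    vm <- pmax(peaks$h * (4 - om), max(dv) * 0.05)
    as.numeric(rbind(log(vm), uh, rep(om, n_domains)))
  }
  starts <- lapply(seq_len(n_starts), make_start)
  if (!is.null(init)) {
    th0 <- as.numeric(rbind(
      log(pmax(vapply(init, `[[`, numeric(1), "v_m"), 1e-8)),
      vapply(init, `[[`, numeric(1), "u_half"),
      vapply(init, `[[`, numeric(1), "omega")))
    starts <- c(list(th0), starts)
  }
  best <- NULL
  for (th0 in starts) {
    th0 <- pmin(pmax(th0, lower), upper)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 120, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  if (is.null(best))
    stop("DIS fit failed from all starts")
  doms <- unpack(best$par)
  o <- order(vapply(doms, `[[`, numeric(1), "u_half"))
  doms <- doms[o]
  u_halfs <- vapply(doms, `[[`, numeric(1), "u_half")

  if (is.null(split_u)) {
    if (n_domains == 1) {
      split_u <- NA_real_
    } else {
      gaps <- diff(u_halfs)
      gi <- which.max(gaps)
      in_gap <- u > u_halfs[gi] & u < u_halfs[gi + 1]
      split_u <- if (any(in_gap)) u[in_gap][which.min(dv[in_gap])]
                 else (u_halfs[gi] + u_halfs[gi + 1]) / 2
    }
  }
  labels <- if (is.na(split_u)) rep("unassigned", n_domains)
            else ifelse(u_halfs < split_u, "edge", "basal")
  domains <- Map(function(d, lb)
    local_domain(d$v_m, d$u_half, d$omega, label = lb), doms, labels)
  v_ms <- vapply(domains, `[[`, numeric(1), "v_m")
  total_v_m <- sum(v_ms)
  edge_fraction <- if (total_v_m > 0)
    sum(v_ms[labels == "edge"]) / total_v_m else NA_real_
  res <- resid_fn(best$par)
  structure(
    list(domains = domains,
         edge_fraction = edge_fraction,
         total_v_m = total_v_m,
         areas = vapply(domains, domain_area, numeric(1),
                        cross_section = cross_section),
         residual_rms = sqrt(mean(res^2)),
         split_u = split_u,
         converged = best$info %in% 1:4,
         fitted = data.frame(u = u, dv_du = model_dv(best$par),
                             dv_du_obs = dv)),
    class = "dis_fit")
}

#' @export
print.dis_fit <- function(x, ...) {
  cat(sprintf("<dis_fit> %d domain(s)%s, residual RMS %.3g\n",
              length(x$domains),
              if (x$converged) "" else " [NOT CONVERGED]", x$residual_rms))
  for (i in seq_along(x$domains)) {
    d <- x$domains[[i]]
    cat(sprintf("  %d: v_m %.4g cm3/g  u_half %.3f  omega %.3f  %s  (%.2f m2/g)\n",
                i, d$v_m, d$u_half, d$omega, d$label, x$areas[i]))
  }
  cat(sprintf("  edge fraction %.3f (split at u = %.3f)\n",
              x$edge_fraction, x$split_u))
  invisible(x)
}
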