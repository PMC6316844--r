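R_GAS <- 8.314  # J mol^-1 K^-1

#' Evaluate a Langmuir-type isotherm model
#'
#' Two model forms are supported:
#' \describe{
#'   \item{classic}{`q = q_max * K * C / (1 + K * C)` with `K` in L/mol, the
#'     gas/solid Langmuir form carried over to solution data. Useful
#'     descriptively, but its `K` has units, which makes thermodynamic
#'     parameters derived from it convention-dependent.}
#'   \item{modified}{`q = q_max * K_ML * C / (C_s - C + K_ML * C)` — a
#'     solid/liquid form in which concentration is scaled by the solute
#'     saturation concentration `C_s` (here fixed at the solubility), so the
#'     equilibrium constant `K_ML` is dimensionless and
#'     `dG0 = -R*T*ln(K_ML)` is well defined. In the dilute limit
#'     `C << C_s` it reduces to the classic form with `K = K_ML / C_s`; at
#'     `K_ML = 1` it degenerates to the straight line `q = q_max * C / C_s`.}
#' }
#'
#' @param model `"classic"` or `"modified"`.
#' @param params List with `q_max` and `k` (L/mol, classic) or `k_ml`
#'   (dimensionless) plus `c_s` (mol/L) for the modified form.
#' @param c_eq Equilibrium concentration(s), mol/L; for the modified model
#'   strictly below `c_s`.
#' @return Adsorbed quantity in the units of `q_max`.
#' @export
langmuir_eval <- function(model = c("classic", "modified"), params, c_eq) {
  model <- match.arg(model)
  if (any(c_eq < 0)) stop("c_eq must be >= 0")
  if (model == "classic") {
    stopifnot(params$q_max > 0, params$k > 0)
    params$q_max * params$k * c_eq / (1 + params$k * c_eq)
  } else {
    stopifnot(params$q_max > 0, params$k_ml > 0, params$c_s > 0)
    if (any(c_eq >= params$c_s))
      stop("beyond solubility: c_eq >= c_s in modified Langmuir model")
    params$q_max * params$k_ml * c_eq /
      (params$c_s - c_eq + params$k_ml * c_eq)
  }
}

#' Standard free energy from the dimensionless Langmuir constant
#'
#' `dG0 = -R * T * ln(K_ML)` in kJ/mol, with R = 8.314 J mol^-1 K^-1. Only
#' the dimensionless constant of the modified (solid/liquid) model supports
#' this; the classic `K` carries units of L/mol and would make the result
#' depend on the concentration convention.
#'
#' @param k_ml Dimensionless equilibrium constant, > 0.
#' @param temperature Absolute temperature, K.
#' @return Standard free energy of adsorption, kJ/mol.
#' @export
delta_g_from_kml <- function(k_ml, temperature = 298.15) {
  stopifnot(all(k_ml > 0), temperature > 0)
  -R_GAS * temperature * log(k_ml) / 1000
}

#' Inverse of [delta_g_from_kml()]
#' @param delta_g Standard free energy, kJ/mol.
#' @param temperature Absolute temperature, K.
#' @return Dimensionless `k_ml`.
#' @export
kml_from_delta_g <- function(delta_g, temperature = 298.15) {
  exp(-delta_g * 1000 / (R_GAS * temperature))
}

# Linearized reciprocal-form starting values.
# classic:  1/q = 1/qmax + (1/(qmax K)) * (1/C)
# modified: 1/q = 1/qmax + (1/(qmax K_ML)) * ((Cs - C)/C)
langmuir_init <- function(model, c_eq, q, c_s) {
  ok <- c_eq > 0 & q > 0
  x <- if (model == "classic") 1 / c_eq[ok] else (c_s - c_eq[ok]) / c_eq[ok]
  fit <- stats::lm.fit(cbind(1, x), 1 / q[ok])
  a <- fit$coefficients[1]; b <- fit$coefficients[2]
  q_max <- if (is.finite(a) && a > 0) 1 / a else max(q) * 1.2
  k <- if (is.finite(b) && b > 0 && q_max > 0) 1 / (q_max * b) else
    if (model == "classic") 1 / stats::median(c_eq[ok]) else 1
  c(q_max = unname(q_max), k = unname(max(k, 1e-12)))
}

#' Fit a Langmuir model to an adsorption isotherm
#'
#' Weighted nonlinear least squares (Levenberg-Marquardt; weights `1/sd^2`
#' where replicate sds are available and positive, uniform otherwise).
#' Positivity of `q_max` and `K` is enforced by fitting on the log scale;
#' starting values come from the linearized reciprocal form, with a small
#' deterministic multi-start (5 starts) around them to guard against local
#' minima. Parameter standard errors come from the local curvature
#' (Jacobian) at the optimum.
#'
#' The fitted parameters describe the curve; they are not by themselves
#' evidence of a Langmuir mechanism — solution/solid systems violate most of
#' the model's gas-phase assumptions, which is why both the classic and the
#' dimensionless modified form are reported side by side.
#'
#' @param iso An [isotherm()] or [normalized_isotherm()] (>= 4 points with
#'   distinct abscissae). Flagged negative points are dropped with a warning.
#' @param model `"classic"` or `"modified"`.
#' @param c_s Saturation concentration (mol/L) for the modified model;
#'   defaults to the source nucleotide's solubility. Fixed, not fitted:
#'   it is an independently known constant and co-fitting is
#'   ill-conditioned.
#' @param temperature Temperature in K for the free-energy report.
#' @param n_starts Number of deterministic multi-starts.
#' @return An object of class `"langmuir_fit"`: list with `model`, `q_max`,
#'   `k` or `k_ml`, `c_s`, `delta_g` (modified only), `residual_rms`,
#'   `parameter_sd`, `n_points`, `converged`.
#' @export
fit_langmuir <- function(iso, model = c("classic", "modified"), c_s = NULL,
                         temperature = 298.15, n_starts = 5) {
  model <- match.arg(model)
  n <- as_norm(iso)
  c_eq <- n$x; q <- n$d; sdv <- n$sd_d
  keep <- q >= 0
  if (any(!keep)) {
    warning(sum(!keep), " negative-adsorption point(s) dropped before fit")
    c_eq <- c_eq[keep]; q <- q[keep]; sdv <- sdv[keep]
  }
  if (length(unique(c_eq)) < 4)
    stop("need at least 4 points with distinct concentrations")
  if (model == "modified") {
    if (is.null(c_s)) {
      nuc <- attr(n, "nucleotide")
      if (is.null(nuc)) stop("c_s required for the modified model")
      c_s <- nuc$solubility
    }
    stopifnot(is.finite(c_s), c_s > 0)
    if (any(c_eq >= c_s)) stop("beyond solubility: data contain c_eq >= c_s")
  }
  w <- if (all(is.finite(sdv)) && all(sdv > 0)) 1 / sdv^2
       else rep(1, length(q))
  sw <- sqrt(w)
  predict_q <- function(th) {
    p <- exp(th)
    if (model == "classic")
      langmuir_eval("classic", list(q_max = p[1], k = p[2]), c_eq)
    else
      langmuir_eval("modified",
                    list(q_max = p[1], k_ml = p[2], c_s = c_s), c_eq)
  }
  resid_fn <- function(th) sw * (q - predict_q(th))
  init <- langmuir_init(model, c_eq, q, c_s)
  # deterministic multi-start: scale the linearized guess up and down
  factors <- c(1, 0.5, 2, 0.2, 5)[seq_len(n_starts)]
  best <- NULL
  for (f in factors) {
    th0 <- log(c(init["q_max"] * f, init["k"] * f))
    ans <- tryCatch(
      minpack.lm::nls.lm(par = th0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  if (is.null(best))
    stop("Langmuir fit failed to converge from all starts")
  p <- exp(best$par)
  res <- q - predict_q(best$par)
  dof <- max(length(q) - 2L, 1L)
  # parameter sd from the Jacobian at the optimum, delta method for exp()
  cov_log <- tryCatch({
    J <- best$hessian  # nls.lm returns J^T J as hessian
    s2 <- best$deviance / dof
    solve(J) * s2
  }, error = function(e) matrix(NA_real_, 2, 2))
  sd_nat <- sqrt(pmax(diag(cov_log), 0)) * p
  out <- list(model = model, q_max = unname(p[1]),
              c_s = if (model == "modified") c_s else NA_real_,
              residual_rms = sqrt(mean(res^2)),
              parameter_sd = stats::setNames(
                unname(sd_nat),
                c("q_max", if (model == "classic") "k" else "k_ml")),
              n_points = length(q),
              converged = best$info %in% 1:4)
  if (model == "classic") {
    out$k <- unname(p[2])
  } else {
    out$k_ml <- unname(p[2])
    out$delta_g <- delta_g_from_kml(p[2], temperature)
    out$temperature <- temperature
  }
  class(out) <- "langmuir_fit"
  out
}

#' @export
print.langmuir_fit <- function(x, ...) {
  cat(sprintf("<langmuir_fit> %s model, %d points%s\n", x$model, x$n_points,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  q_max = %.4g (+/- %.2g)\n", x$q_max, x$parameter_sd[1]))
  if (x$model == "classic") {
    cat(sprintf("  K     = %.4g L/mol (+/- %.2g)\n", x$k, x$parameter_sd[2]))
  } else {
    cat(sprintf("  K_ML  = %.4g (+/- %.2g), C_s = %.4g mol/L\n",
                x$k_ml, x$parameter_sd[2], x$c_s))
    cat(sprintf("  dG0   = %.3f kJ/mol at %.2f K\n", x$delta_g,
                x$temperature))
  }
  cat(sprintf("  residual RMS = %.3g\n", x$residual_rms))
  invisible(x)
}
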