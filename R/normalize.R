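#' Construct a normalized isotherm
#'
#' @param x Abscissa: raw equilibrium concentration (mol/L) or
#'   solubility-reduced concentration (dimensionless), increasing.
#' @param d Ordinate: adsorbed quantity, mol/g (`basis = "none"`) or areal
#'   density, mol/m^2.
#' @param sd_d Spread of `d`, same units.
#' @param basis One of `"none"`, `"total"`, `"basal"`, `"edge"` — which
#'   specific surface area the ordinate is normalized to.
#' @param concentration_mode `"raw"` (mol/L) or `"reduced"` (Ceq/S).
#' @param nucleotide,mineral Source metadata (may be `NULL`).
#' @return A data frame of class `"normalized_isotherm"`.
#' @export
normalized_isotherm <- function(x, d, sd_d = rep(0, length(x)),
                                basis = c("none", "total", "basal", "edge"),
                                concentration_mode = c("raw", "reduced"),
                                nucleotide = NULL, mineral = NULL) {
  basis <- match.arg(basis)
  concentration_mode <- match.arg(concentration_mode)
  stopifnot(length(x) == length(d), length(sd_d) == length(d))
  if (any(x < 0)) stop("abscissa must be >= 0")
  structure(
    data.frame(x = x, d = d, sd_d = sd_d),
    basis = basis, concentration_mode = concentration_mode,
    nucleotide = nucleotide, mineral = mineral,
    class = c("normalized_isotherm", "data.frame"))
}

#' @export
print.normalized_isotherm <- function(x, ...) {
  cat(sprintf("<normalized_isotherm> basis=%s, concentration=%s, %d points\n",
              attr(x, "basis"), attr(x, "concentration_mode"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

as_norm <- function(iso) {
  if (inherits(iso, "normalized_isotherm")) return(iso)
  stopifnot(inherits(iso, "isotherm"))
  normalized_isotherm(iso$c_eq, iso$q_ads, iso$sd_q, basis = "none",
                      concentration_mode = "raw",
                      nucleotide = attr(iso, "nucleotide"),
                      mineral = attr(iso, "mineral"))
}

#' Reduce the concentration axis by solubility
#'
#' Rescales the equilibrium-concentration axis to `x = Ceq / S`, the
#' dimensionless reduced concentration. Nucleotides are homologous molecules;
#' on this axis isotherms measured for different nucleotides on the same
#' mineral surface superimpose when they share an adsorption mechanism, since
#' solubility differences are what separate the raw curves.
#'
#' @param iso An [isotherm()] or [normalized_isotherm()] whose source
#'   nucleotide has a known solubility.
#' @return A [normalized_isotherm()] with `concentration_mode = "reduced"`;
#'   the ordinate (and its basis) is unchanged.
#' @export
reduce_concentration <- function(iso) {
  n <- as_norm(iso)
  if (attr(n, "concentration_mode") == "reduced") return(n)
  nuc <- attr(n, "nucleotide")
  if (is.null(nuc) || !is.finite(nuc$solubility) || nuc$solubility <= 0)
    stop("solubility unknown for nucleotide '",
         if (is.null(nuc)) "?" else nuc$name, "'")
  normalized_isotherm(n$x / nuc$solubility, n$d, n$sd_d,
                      basis = attr(n, "basis"),
                      concentration_mode = "reduced",
                      nucleotide = nuc, mineral = attr(n, "mineral"))
}

#' Convert per-gram uptake into areal adsorption density
#'
#' Adsorption is an interfacial phenomenon: per-gram uptake scales with grain
#' size (a fine powder apparently adsorbs more than a coarse one), so only
#' adsorption densities `d = q / SSA` in mol per m^2 of the chosen reactive
#' surface are comparable across mineral samples.
#'
#' @param iso An [isotherm()] or [normalized_isotherm()] with per-gram
#'   ordinate; the source mineral must carry the requested area.
#' @param basis Which specific surface area to normalize to: `"total"`,
#'   `"basal"`, or `"edge"` (the lateral faces, where nucleotide adsorption
#'   localizes).
#' @return A [normalized_isotherm()] in mol/m^2; `sd` propagated linearly.
#' @export
to_density <- function(iso, basis = c("total", "basal", "edge")) {
  basis <- match.arg(basis)
  n <- as_norm(iso)
  if (attr(n, "basis") != "none")
    stop("ordinate already normalized to basis '", attr(n, "basis"), "'")
  min_ <- attr(n, "mineral")
  if (is.null(min_)) stop("basis area unavailable: no mineral metadata")
  ssa <- switch(basis, total = min_$ssa_total, basal = min_$ssa_basal,
                edge = min_$ssa_edge)
  if (!is.finite(ssa) || ssa <= 0)
    stop("basis area unavailable: ssa_", basis, " of ", min_$name,
         " is not > 0")
  normalized_isotherm(n$x, n$d / ssa, n$sd_d / ssa, basis = basis,
                      concentration_mode = attr(n, "concentration_mode"),
                      nucleotide = attr(n, "nucleotide"), mineral = min_)
}

#' Quantify how well a family of isotherms superimposes
#'
#' Interpolates every curve (monotone piecewise-linear, no extrapolation)
#' onto a common log-spaced abscissa grid restricted to the shared support,
#' then reports the mean over the grid of the cross-curve coefficient of
#' variation (sample sd / mean). Identical curves score 0; the score is
#' invariant to multiplying all curves by a common constant, so it compares
#' families expressed in different ordinate units on an equal footing.
#'
#' @param curves List of at least two [normalized_isotherm()] (or
#'   [isotherm()]) objects with overlapping abscissa ranges.
#' @param n_grid Number of evaluation abscissae (default 50).
#' @return A list of class `"collapse_report"` with elements `score`, `grid`,
#'   `values` (curves x grid matrix) and `n_curves`.
#' @export
collapse_score <- function(curves, n_grid = 50) {
  if (length(curves) < 2)
    stop("collapse_score needs at least 2 curves")
  curves <- lapply(curves, as_norm)
  lo <- max(vapply(curves, function(cv) min(cv$x[cv$x > 0]), numeric(1)))
  hi <- min(vapply(curves, function(cv) max(cv$x), numeric(1)))
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("curves have disjoint abscissa supports")
  grid <- exp(seq(log(lo), log(hi), length.out = n_grid))
  vals <- t(vapply(curves, function(cv)
    stats::approx(cv$x, cv$d, xout = grid, rule = 1)$y, numeric(n_grid)))
  cv_grid <- apply(vals, 2, function(col) {
    m <- mean(col)
    if (!is.finite(m) || m == 0) return(NA_real_)
    stats::sd(col) / m
  })
  structure(list(score = mean(cv_grid, na.rm = TRUE), grid = grid,
                 values = vals, n_curves = length(curves)),
            class = "collapse_report")
}

#' @export
print.collapse_report <- function(x, ...) {
  cat(sprintf("<collapse_report> %d curves, %d grid points, score %.4g\n",
              x$n_curves, length(x$grid), x$score))
  invisible(x)
}

#' Saturation-plateau density of an isotherm
#'
#' Estimates the plateau as mean +/- sd of the ordinate over the top
#' `tail_fraction` of the abscissa range. A saturation plateau signals full
#' coverage of the reactive (lateral) surface; its absence is flagged when
#' the tail is too dispersed (`sd/mean > no_plateau_cv`), as for a still
#' rising curve.
#'
#' @param curve A [normalized_isotherm()] or [isotherm()] with at least 3
#'   points in the tail window.
#' @param tail_fraction Fraction of the abscissa range treated as the tail
#'   (default 0.25).
#' @param no_plateau_cv Dispersion threshold above which `plateau` is flagged
#'   unreliable (default 0.1).
#' @return List with `plateau`, `sd`, `n` and logical `no_plateau`.
#' @export
plateau_density <- function(curve, tail_fraction = 0.25,
                            no_plateau_cv = 0.1) {
  n <- as_norm(curve)
  x0 <- max(n$x) - tail_fraction * (max(n$x) - min(n$x))
  tail_d <- n$d[n$x >= x0]
  if (length(tail_d) < 3)
    stop("fewer than 3 points in the plateau window; widen tail_fraction")
  m <- mean(tail_d); s <- stats::sd(tail_d)
  list(plateau = m, sd = s, n = length(tail_d),
       no_plateau = is.finite(s) && m != 0 && s / abs(m) > no_plateau_cv)
}
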