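#' Concentration from UV/vis absorbance (Beer-Lambert)
#'
#' Linear calibration `C = A / (epsilon * l)` with the nucleotide's molar
#' extinction coefficient. Linearity is assumed over the 0-3.5 mM working
#' range, which is standard spectrophotometric practice for these solutes.
#'
#' @param absorbance Dimensionless absorbance reading(s), >= 0.
#' @param spec A [nucleotide_spec()] carrying `extinction_coefficient`.
#' @param path_length Cuvette path length in cm (default 1).
#' @return Concentration(s) in mol/L.
#' @export
concentration_from_absorbance <- function(absorbance, spec, path_length = 1) {
  stopifnot(inherits(spec, "nucleotide_spec"))
  if (any(!is.finite(absorbance)) || any(absorbance < 0))
    stop("calibration error: negative or non-finite absorbance")
  if (!is.finite(path_length) || path_length <= 0)
    stop("path_length must be > 0")
  eps <- spec$extinction_coefficient
  if (!is.finite(eps) || eps <= 0)
    stop("no extinction coefficient available for ", spec$name)
  absorbance / (eps * path_length)
}

#' Estimate an extinction coefficient from standards
#'
#' Least-squares line through the origin, `A = epsilon * l * C`, fitted to a
#' multi-point standard curve. The closed-form slope is
#' `sum(A*C) / sum(C^2) / l`.
#'
#' @param concentration Standard concentrations, mol/L.
#' @param absorbance Measured absorbances.
#' @param path_length Path length in cm.
#' @return List with `extinction_coefficient` (L mol^-1 cm^-1) and
#'   `residual_rms` in absorbance units.
#' @export
fit_extinction <- function(concentration, absorbance, path_length = 1) {
  stopifnot(length(concentration) == length(absorbance),
            length(concentration) >= 2)
  if (any(concentration < 0) || any(absorbance < 0))
    stop("calibration error: negative standards")
  slope <- sum(absorbance * concentration) / sum(concentration^2)
  eps <- slope / path_length
  res <- absorbance - slope * concentration
  list(extinction_coefficient = eps,
       residual_rms = sqrt(mean(res^2)))
}

#' Adsorbed quantity from mass balance
#'
#' The difference between initial and equilibrium concentration gives the
#' adsorbed quantity per gram of mineral:
#' `q = (C0 - Ceq) * V / m` (mol adsorbate / g mineral), so that
#' `q*m + Ceq*V = C0*V` exactly.
#'
#' A sample with `Ceq > C0` yields a negative `q` which is returned as-is and
#' flagged via the `"negative_adsorption"` attribute, never clipped: silently
#' forcing such points to zero would bias isotherms near zero coverage, and
#' the flag lets quality control catch desorption or measurement error.
#'
#' @param sample A [batch_sample()].
#' @return Adsorbed quantity in mol/g, with attribute `negative_adsorption`
#'   (logical).
#' @export
adsorbed_quantity <- function(sample) {
  stopifnot(inherits(sample, "batch_sample"))
  q <- (sample$c0 - sample$ceq) * sample$volume / sample$mass
  if (q < 0)
    warning(sprintf("negative adsorption (q = %.3g mol/g): Ceq > C0", q))
  structure(q, negative_adsorption = q < 0)
}

#' Construct an adsorption isotherm
#'
#' Low-level constructor; most users will go through [build_isotherm()].
#'
#' @param c_eq Equilibrium concentrations, mol/L, strictly increasing.
#' @param q_ads Adsorbed quantities, mol/g.
#' @param sd_q Replicate spread of `q_ads`, mol/g (0 for single measurements).
#' @param nucleotide A [nucleotide_spec()].
#' @param mineral A [mineral_spec()].
#' @param conditions List with elements `ph`, `temperature`, `salts`.
#' @return A data frame of class `"isotherm"` with columns `c_eq`, `q_ads`,
#'   `sd_q` and metadata attributes.
#' @export
isotherm <- function(c_eq, q_ads, sd_q = rep(0, length(c_eq)),
                     nucleotide = NULL, mineral = NULL,
                     conditions = list(ph = NA_real_, temperature = NA_real_,
                                       salts = numeric())) {
  stopifnot(length(c_eq) == length(q_ads), length(sd_q) == length(c_eq))
  c_eq <- as.numeric(c_eq); q_ads <- as.numeric(q_ads)
  sd_q <- as.numeric(sd_q)
  if (any(c_eq < 0)) stop("c_eq must be >= 0")
  if (any(sd_q < 0)) stop("sd_q must be >= 0")
  o <- order(c_eq)
  c_eq <- c_eq[o]; q_ads <- q_ads[o]; sd_q <- sd_q[o]
  if (any(diff(c_eq) <= 0))
    stop("duplicated c_eq after aggregation; isotherm points must be distinct")
  structure(
    data.frame(c_eq = c_eq, q_ads = q_ads, sd_q = sd_q),
    nucleotide = nucleotide, mineral = mineral, conditions = conditions,
    class = c("isotherm", "data.frame"))
}

#' @export
print.isotherm <- function(x, ...) {
  nuc <- attr(x, "nucleotide"); min_ <- attr(x, "mineral")
  cat(sprintf("<isotherm> %s on %s, %d points, c_eq %.3g-%.3g mol/L\n",
              if (is.null(nuc)) "?" else nuc$name,
              if (is.null(min_)) "?" else min_$name,
              nrow(x), min(x$c_eq), max(x$c_eq)))
  print.data.frame(x, ...)
  invisible(x)
}

cond_equal <- function(a, b, rtol = 1e-9) {
  num_eq <- function(u, v) {
    if (is.na(u) && is.na(v)) return(TRUE)
    if (is.na(u) || is.na(v)) return(FALSE)
    abs(u - v) <= rtol * max(abs(u), abs(v), 1e-300)
  }
  if (!num_eq(a$ph, b$ph)) return("ph")
  if (!num_eq(a$temperature, b$temperature)) return("temperature")
  sa <- a$salts; sb <- b$salts
  if (length(sa) != length(sb) ||
      !setequal(names(sa), names(sb)) ||
      (length(sa) && any(!mapply(num_eq, sa[sort(names(sa))],
                                 sb[sort(names(sa))]))))
    return("salts")
  NULL
}

#' Assemble an isotherm from batch samples
#'
#' Computes adsorbed quantities by mass balance, aggregates replicates (same
#' initial concentration and conditions, matched to 1e-9 relative tolerance)
#' to mean +/- sample standard deviation, and returns the points sorted by
#' equilibrium concentration. The result is invariant to the input order and
#' idempotent on already-aggregated data.
#'
#' All samples must share pH, temperature and salt composition; a mismatch is
#' rejected naming the offending field.
#'
#' @param samples List of [batch_sample()] objects.
#' @param nucleotide A [nucleotide_spec()].
#' @param mineral A [mineral_spec()].
#' @param rtol Relative tolerance for replicate matching on `c0`.
#' @return An [isotherm()].
#' @export
build_isotherm <- function(samples, nucleotide, mineral, rtol = 1e-9) {
  stopifnot(length(samples) >= 1,
            all(vapply(samples, inherits, logical(1), "batch_sample")))
  cond <- list(ph = samples[[1]]$ph, temperature = samples[[1]]$temperature,
               salts = samples[[1]]$salts)
  for (i in seq_along(samples)) {
    bad <- cond_equal(cond, list(ph = samples[[i]]$ph,
                                 temperature = samples[[i]]$temperature,
                                 salts = samples[[i]]$salts))
    if (!is.null(bad))
      stop("samples mix conditions beyond tolerance: field '", bad, "'")
  }
  c0 <- vapply(samples, `[[`, numeric(1), "c0")
  ceq <- vapply(samples, `[[`, numeric(1), "ceq")
  q <- vapply(samples, function(s) as.numeric(adsorbed_quantity(s)),
              numeric(1))
  # group replicates on c0 within relative tolerance (sorted sweep)
  o <- order(c0, ceq)
  grp <- integer(length(c0)); g <- 0L; last <- -Inf
  for (i in o) {
    if (g == 0L || abs(c0[i] - last) > rtol * max(abs(c0[i]), abs(last))) {
      g <- g + 1L
    }
    grp[i] <- g; last <- c0[i]
  }
  agg_ceq <- tapply(ceq, grp, mean)
  agg_q <- tapply(q, grp, mean)
  agg_sd <- tapply(q, grp, function(v) if (length(v) > 1) stats::sd(v) else 0)
  isotherm(as.numeric(agg_ceq), as.numeric(agg_q), as.numeric(agg_sd),
           nucleotide = nucleotide, mineral = mineral, conditions = cond)
}
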