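#' Describe a nucleotide solute
#'
#' Bundles the physico-chemical constants of a nucleotide that the pipeline
#' needs: molecular weight, molar solubility (the reference scale for the
#' reduced concentration axis), acid dissociation constants, and the molar
#' extinction coefficient used for Beer-Lambert calibration of UV/vis
#' absorbances.
#'
#' @param name Identifier, e.g. `"dGMP"`.
#' @param molecular_weight Molar mass in g/mol (nucleotide monophosphates are
#'   around 320 g/mol).
#' @param solubility Molar solubility in mol/L at the experiment temperature.
#' @param pka_values Numeric vector of pKa values; stored sorted ascending.
#' @param extinction_coefficient Molar extinction coefficient in
#'   L mol^-1 cm^-1 at `wavelength`.
#' @param wavelength Detection wavelength in nm.
#' @return An object of class `"nucleotide_spec"`.
#' @examples
#' nucleotide_spec("dGMP", 347.2, 0.02, c(2.9, 6.4, 9.7), 12000, 253)
#' @export
nucleotide_spec <- function(name, molecular_weight, solubility,
                            pka_values = numeric(),
                            extinction_coefficient = NA_real_,
                            wavelength = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.finite(molecular_weight) || molecular_weight <= 0)
    stop("molecular_weight must be > 0 for ", name)
  if (!is.finite(solubility) || solubility <= 0)
    stop("solubility must be > 0 for ", name)
  if (!is.na(extinction_coefficient) && extinction_coefficient <= 0)
    stop("extinction_coefficient must be > 0 for ", name)
  structure(
    list(name = name,
         molecular_weight = molecular_weight,
         solubility = solubility,
         pka_values = sort(as.numeric(pka_values)),
         extinction_coefficient = extinction_coefficient,
         wavelength = wavelength),
    class = "nucleotide_spec")
}

#' Describe a phyllosilicate mineral sample
#'
#' Clay particles expose two chemically distinct surface classes: large flat
#' basal (siloxane) faces and small lateral (edge) faces bearing pH-dependent
#' metal-hydroxyl groups. Comparing adsorption across samples requires the
#' specific surface area of each class.
#'
#' @param name Identifier, e.g. `"NAu1"`.
#' @param swelling Logical; `TRUE` for smectite-like minerals whose interlayer
#'   hydrates (montmorillonite, nontronite).
#' @param ssa_total Total specific surface area, m^2/g.
#' @param ssa_basal Basal-face specific surface area, m^2/g.
#' @param ssa_edge Lateral (edge) specific surface area, m^2/g.
#' @param point_of_zero_charge Optional pH at which the edge surface carries no
#'   net charge (non-swelling phyllosilicates: typically pH 2.5-4).
#' @param area_tolerance Relative slack allowed in the consistency check
#'   `ssa_basal + ssa_edge <= ssa_total * (1 + area_tolerance)`.
#' @return An object of class `"mineral_spec"`.
#' @examples
#' mineral_spec("NAu1", swelling = TRUE, ssa_total = 90, ssa_basal = 78,
#'              ssa_edge = 12)
#' @export
mineral_spec <- function(name, swelling, ssa_total, ssa_basal, ssa_edge,
                         point_of_zero_charge = NA_real_,
                         area_tolerance = 0.05) {
  stopifnot(is.character(name), length(name) == 1L,
            is.logical(swelling), length(swelling) == 1L)
  areas <- c(ssa_total, ssa_basal, ssa_edge)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("specific surface areas must be finite and >= 0 for ", name)
  if (ssa_basal + ssa_edge > ssa_total * (1 + area_tolerance))
    stop("ssa_basal + ssa_edge exceeds ssa_total beyond tolerance for ", name)
  structure(
    list(name = name, swelling = swelling,
         ssa_total = ssa_total, ssa_basal = ssa_basal, ssa_edge = ssa_edge,
         point_of_zero_charge = point_of_zero_charge),
    class = "mineral_spec")
}

#' @export
print.nucleotide_spec <- function(x, ...) {
  cat(sprintf("<nucleotide_spec> %s  MW %.1f g/mol  S %.3g mol/L\n",
              x$name, x$molecular_weight, x$solubility))
  if (length(x$pka_values))
    cat("  pKa:", paste(format(x$pka_values), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.mineral_spec <- function(x, ...) {
  cat(sprintf(
    "<mineral_spec> %s  %s  SSA total %.1f / basal %.1f / edge %.1f m2/g\n",
    x$name, if (x$swelling) "swelling" else "non-swelling",
    x$ssa_total, x$ssa_basal, x$ssa_edge))
  invisible(x)
}

#' One batch-adsorption sample
#'
#' A single tube of the batch (immersion) method: a known volume of nucleotide
#' solution equilibrated with a weighed mass of mineral powder. Initial and
#' equilibrium concentrations come from spectrophotometry; the adsorbed
#' quantity follows by mass balance.
#'
#' Concentrations are held in mol/L, volume in L, mass in g. Initial
#' concentrations outside the usual working range (0 to 3.5 mM stock
#' solutions) trigger a warning, not an error, so unusual designs still
#' process.
#'
#' @param c0 Initial solute concentration, mol/L.
#' @param ceq Equilibrium solute concentration, mol/L.
#' @param volume Solution volume, L.
#' @param mass Mineral mass, g.
#' @param ph Solution pH.
#' @param temperature Temperature, degrees C.
#' @param salts Named numeric vector of salt molarities, e.g.
#'   `c(NaCl = 0.5, MgCl2 = 0.05)` (the seawater analog).
#' @param replicate_id Integer replicate label.
#' @param c0_range Schema check range for `c0` (warn outside), mol/L.
#' @return An object of class `"batch_sample"` (a one-row list).
#' @export
batch_sample <- function(c0, ceq, volume, mass, ph = NA_real_,
                         temperature = NA_real_, salts = numeric(),
                         replicate_id = 1L,
                         c0_range = c(0, 3.5e-3)) {
  if (!is.finite(volume) || volume <= 0) stop("volume must be > 0")
  if (!is.finite(mass) || mass <= 0) stop("mass must be > 0")
  if (!is.finite(c0) || c0 < 0 || !is.finite(ceq) || ceq < 0)
    stop("concentrations must be finite and >= 0")
  if (c0 < c0_range[1] || c0 > c0_range[2])
    warning(sprintf("c0 = %.3g mol/L outside the usual range [%.3g, %.3g]",
                    c0, c0_range[1], c0_range[2]))
  structure(
    list(c0 = c0, ceq = ceq, volume = volume, mass = mass,
         ph = ph, temperature = temperature, salts = salts,
         replicate_id = as.integer(replicate_id)),
    class = "batch_sample")
}
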