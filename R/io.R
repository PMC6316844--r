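# Shared plain-text readers/writers. All floating point is serialized with
# 17 significant digits so finite decimal inputs round-trip bit-identically.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

parse_salts <- function(s) {
  if (is.na(s) || !nzchar(s)) return(numeric())
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) stop("malformed salts field: '", s, "'")
  stats::setNames(as.numeric(vapply(kv, `[[`, character(1), 2L)),
                  vapply(kv, `[[`, character(1), 1L))
}

format_salts <- function(salts) {
  if (!length(salts)) return("")
  paste(sprintf("%s=%s", names(salts), fmt_num(as.numeric(salts))),
        collapse = ";")
}

#' Read batch-adsorption samples from CSV
#'
#' One row per sample. Required columns: `sample_id`, `nucleotide`, `mineral`,
#' `volume_L`, `mass_g`, `ph`, `temperature_C`, `salts`
#' (semicolon-separated `species=molarity`), `replicate_id`, plus either
#' concentration columns (`c0_mol_per_L`, `ceq_mol_per_L`) or absorbance
#' columns (`absorbance_initial`, `absorbance_equilibrium`) which are
#' converted through Beer-Lambert calibration with `spec`.
#'
#' @param path CSV file path (UTF-8, decimal point, header required).
#' @param spec A [nucleotide_spec()]; required when absorbance columns are
#'   used.
#' @param path_length Cuvette path length in cm for absorbance conversion.
#' @return List of [batch_sample()] objects; names are the `sample_id`s.
#' @export
read_batch_csv <- function(path, spec = NULL, path_length = 1) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "nucleotide", "mineral", "volume_L", "mass_g",
            "ph", "temperature_C", "salts", "replicate_id")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing required columns: ", paste(miss, collapse = ", "))
  has_conc <- all(c("c0_mol_per_L", "ceq_mol_per_L") %in% names(df))
  has_abs <- all(c("absorbance_initial", "absorbance_equilibrium")
                 %in% names(df))
  if (!has_conc && !has_abs)
    stop(path, ": need c0/ceq_mol_per_L or absorbance_* columns")
  samples <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    c0 <- if (has_conc) row$c0_mol_per_L else
      concentration_from_absorbance(row$absorbance_initial, spec, path_length)
    ceq <- if (has_conc) row$ceq_mol_per_L else
      concentration_from_absorbance(row$absorbance_equilibrium, spec,
                                    path_length)
    samples[[i]] <- tryCatch(
      batch_sample(c0 = c0, ceq = ceq, volume = row$volume_L,
                   mass = row$mass_g, ph = row$ph,
                   temperature = row$temperature_C,
                   salts = parse_salts(row$salts),
                   replicate_id = row$replicate_id),
      error = function(e)
        stop(path, " line ", i + 1L, ": ", conditionMessage(e), call. = FALSE))
  }
  names(samples) <- df$sample_id
  samples
}

#' Write batch-adsorption samples to CSV
#'
#' @param samples List of [batch_sample()] objects.
#' @param path Output path.
#' @param nucleotide,mineral Names written to the id columns.
#' @return `path`, invisibly.
#' @export
write_batch_csv <- function(samples, path, nucleotide = "NA", mineral = "NA") {
  df <- data.frame(
    sample_id = sprintf("s%03d", seq_along(samples)),
    nucleotide = nucleotide, mineral = mineral,
    c0_mol_per_L = fmt_num(vapply(samples, `[[`, numeric(1), "c0")),
    ceq_mol_per_L = fmt_num(vapply(samples, `[[`, numeric(1), "ceq")),
    volume_L = fmt_num(vapply(samples, `[[`, numeric(1), "volume")),
    mass_g = fmt_num(vapply(samples, `[[`, numeric(1), "mass")),
    ph = fmt_num(vapply(samples, `[[`, numeric(1), "ph")),
    temperature_C = fmt_num(vapply(samples, `[[`, numeric(1), "temperature")),
    salts = vapply(samples, function(s) format_salts(s$salts), character(1)),
    replicate_id = vapply(samples, `[[`, integer(1), "replicate_id"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an isotherm to CSV
#'
#' Emits a commented `# key=value` metadata preamble (conditions plus the
#' nucleotide and mineral constants needed to rebuild the object) followed by
#' the point table: `nucleotide, mineral, ceq_mol_per_L, q_mol_per_g,
#' sd_q_mol_per_g`.
#'
#' @param iso An [isotherm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotherm_csv <- function(iso, path) {
  stopifnot(inherits(iso, "isotherm"))
  nuc <- attr(iso, "nucleotide"); min_ <- attr(iso, "mineral")
  cond <- attr(iso, "conditions")
  meta <- c(
    if (!is.null(nuc)) c(
      sprintf("# nucleotide.name=%s", nuc$name),
      sprintf("# nucleotide.molecular_weight=%s", fmt_num(nuc$molecular_weight)),
      sprintf("# nucleotide.solubility=%s", fmt_num(nuc$solubility)),
      sprintf("# nucleotide.pka_values=%s",
              paste(fmt_num(nuc$pka_values), collapse = ";")),
      sprintf("# nucleotide.extinction_coefficient=%s",
              fmt_num(nuc$extinction_coefficient)),
      sprintf("# nucleotide.wavelength=%s", fmt_num(nuc$wavelength))),
    if (!is.null(min_)) c(
      sprintf("# mineral.name=%s", min_$name),
      sprintf("# mineral.swelling=%s", min_$swelling),
      sprintf("# mineral.ssa_total=%s", fmt_num(min_$ssa_total)),
      sprintf("# mineral.ssa_basal=%s", fmt_num(min_$ssa_basal)),
      sprintf("# mineral.ssa_edge=%s", fmt_num(min_$ssa_edge)),
      sprintf("# mineral.point_of_zero_charge=%s",
              fmt_num(min_$point_of_zero_charge))),
    sprintf("# conditions.ph=%s", fmt_num(cond$ph)),
    sprintf("# conditions.temperature=%s", fmt_num(cond$temperature)),
    sprintf("# conditions.salts=%s", format_salts(cond$salts)))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("nucleotide,mineral,ceq_mol_per_L,q_mol_per_g,sd_q_mol_per_g",
             con)
  writeLines(sprintf("%s,%s,%s,%s,%s",
                     if (is.null(nuc)) "NA" else nuc$name,
                     if (is.null(min_)) "NA" else min_$name,
                     fmt_num(iso$c_eq), fmt_num(iso$q_ads), fmt_num(iso$sd_q)),
             con)
  invisible(path)
}

read_meta_preamble <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#\\s*", "", meta_lines)
  eqpos <- regexpr("=", kv, fixed = TRUE)
  bad <- which(eqpos < 0)
  if (length(bad))
    stop("malformed metadata line ", bad[1], ": '", meta_lines[bad[1]], "'")
  stats::setNames(substring(kv, eqpos + 1L),
                  substring(kv, 1L, eqpos - 1L))
}

num_or_na <- function(s) {
  if (is.null(s) || is.na(s) || s == "NA") NA_real_ else as.numeric(s)
}

meta_get <- function(meta, key, default = NA_character_) {
  if (key %in% names(meta)) meta[[key]] else default
}

#' Read an isotherm from CSV
#'
#' Inverse of [write_isotherm_csv()]; restores the nucleotide and mineral
#' specifications from the metadata preamble when present.
#'
#' @param path CSV path.
#' @return An [isotherm()].
#' @export
read_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- read_meta_preamble(lines)
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  need <- c("ceq_mol_per_L", "q_mol_per_g", "sd_q_mol_per_g")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  nuc <- NULL
  if (!is.na(meta_get(meta, "nucleotide.name"))) {
    pka_raw <- meta_get(meta, "nucleotide.pka_values", "")
    nuc <- nucleotide_spec(
      meta_get(meta, "nucleotide.name"),
      num_or_na(meta_get(meta, "nucleotide.molecular_weight")),
      num_or_na(meta_get(meta, "nucleotide.solubility")),
      if (nzchar(pka_raw))
        as.numeric(strsplit(pka_raw, ";", fixed = TRUE)[[1]]) else numeric(),
      num_or_na(meta_get(meta, "nucleotide.extinction_coefficient")),
      num_or_na(meta_get(meta, "nucleotide.wavelength")))
  }
  min_ <- NULL
  if (!is.na(meta_get(meta, "mineral.name"))) {
    min_ <- mineral_spec(
      meta_get(meta, "mineral.name"),
      as.logical(meta_get(meta, "mineral.swelling")),
      num_or_na(meta_get(meta, "mineral.ssa_total")),
      num_or_na(meta_get(meta, "mineral.ssa_basal")),
      num_or_na(meta_get(meta, "mineral.ssa_edge")),
      num_or_na(meta_get(meta, "mineral.point_of_zero_charge")))
  }
  cond <- list(ph = num_or_na(meta_get(meta, "conditions.ph")),
               temperature = num_or_na(meta_get(meta, "conditions.temperature")),
               salts = parse_salts(meta_get(meta, "conditions.salts", "")))
  isotherm(df$ceq_mol_per_L, df$q_mol_per_g, df$sd_q_mol_per_g,
           nucleotide = nuc, mineral = min_, conditions = cond)
}

#' Read a low-pressure gas adsorption isotherm from CSV
#'
#' Columns: `p_over_p0`, `v_ads_cm3stp_per_g`.
#'
#' @param path CSV path.
#' @return A [gas_isotherm()].
#' @export
read_gas_isotherm_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("p_over_p0", "v_ads_cm3stp_per_g"), names(df))
  if (length(miss))
    stop(path, ": missing columns: ", paste(miss, collapse = ", "))
  gas_isotherm(df$p_over_p0, df$v_ads_cm3stp_per_g)
}

#' Write a gas adsorption isotherm to CSV
#'
#' @param gas A [gas_isotherm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gas_isotherm_csv <- function(gas, path) {
  stopifnot(inherits(gas, "gas_isotherm"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("p_over_p0,v_ads_cm3stp_per_g", con)
  writeLines(sprintf("%s,%s", fmt_num(gas$p_over_p0),
                     fmt_num(gas$v_ads)), con)
  invisible(path)
}
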