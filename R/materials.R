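#' Material property record
#'
#' One material of the simulation domain with its electromagnetic and thermal
#' constants. Electromagnetic constants are evaluated at the operating
#' frequency (2.45 GHz by default); thermal constants feed the bioheat solve.
#'
#' @param name material label.
#' @param relative_permittivity relative permittivity (dimensionless, >= 1 for
#'   dielectrics/tissue; ignored for perfect conductors).
#' @param electric_conductivity electric conductivity (S/m, >= 0).
#' @param relative_permeability relative permeability (dimensionless).
#' @param density mass density (kg/m^3).
#' @param specific_heat specific heat capacity (J/(kg K)).
#' @param thermal_conductivity thermal conductivity (W/(m K)).
#' @param perfusion_rate blood perfusion rate of the tissue (1/s).
#' @param metabolic_heat metabolic volumetric heat source (W/m^3).
#' @param is_pec treat as perfect electric conductor in the EM solve.
#' @param in_needle part of the applicator (excluded from the thermal domain;
#'   tissue faces adjoining such cells receive the coolant Robin condition).
#' @return an object of class `material_properties` (a named list).
#' @export
material_properties <- function(name,
                                relative_permittivity = 1,
                                electric_conductivity = 0,
                                relative_permeability = 1,
                                density = NA_real_,
                                specific_heat = NA_real_,
                                thermal_conductivity = NA_real_,
                                perfusion_rate = 0,
                                metabolic_heat = 0,
                                is_pec = FALSE,
                                in_needle = FALSE) {
  m <- list(name = as.character(name),
            relative_permittivity = as.numeric(relative_permittivity),
            electric_conductivity = as.numeric(electric_conductivity),
            relative_permeability = as.numeric(relative_permeability),
            density = as.numeric(density),
            specific_heat = as.numeric(specific_heat),
            thermal_conductivity = as.numeric(thermal_conductivity),
            perfusion_rate = as.numeric(perfusion_rate),
            metabolic_heat = as.numeric(metabolic_heat),
            is_pec = isTRUE(is_pec),
            in_needle = isTRUE(in_needle))
  class(m) <- "material_properties"
  validate_material_properties(m)
  m
}

validate_material_properties <- function(m) {
  if (!m$is_pec && m$relative_permittivity < 1)
    stop("material '", m$name, "': relative permittivity must be >= 1", call. = FALSE)
  if (m$electric_conductivity < 0)
    stop("material '", m$name, "': electric conductivity must be >= 0", call. = FALSE)
  thermal <- c(m$density, m$specific_heat, m$thermal_conductivity)
  if (!m$in_needle && (anyNA(thermal) || any(thermal <= 0)))
    stop("material '", m$name, "': density, specific heat and thermal conductivity ",
         "must be > 0 for heat-conducting materials", call. = FALSE)
  if (m$perfusion_rate < 0 || m$metabolic_heat < 0)
    stop("material '", m$name, "': perfusion rate and metabolic heat must be >= 0",
         call. = FALSE)
  invisible(m)
}

#' Blood properties for the Pennes perfusion term
#'
#' @param density blood density (kg/m^3).
#' @param specific_heat blood specific heat (J/(kg K)).
#' @param perfusion_rate baseline blood perfusion rate (1/s).
#' @param temperature arterial blood temperature (K).
#' @return an object of class `blood_properties`.
#' @export
blood_properties <- function(density = 1000,
                             specific_heat = 3639,
                             perfusion_rate = 0.00361,
                             temperature = 310.15) {
  b <- list(density = as.numeric(density),
            specific_heat = as.numeric(specific_heat),
            perfusion_rate = as.numeric(perfusion_rate),
            temperature = as.numeric(temperature))
  if (any(unlist(b) <= 0)) stop("blood properties must be strictly positive", call. = FALSE)
  if (b$temperature < 273 || b$temperature > 320)
    stop("blood temperature outside [273, 320] K", call. = FALSE)
  class(b) <- "blood_properties"
  b
}

# default material sets; dielectric/thermal values for the applicator parts are
# nominal engineering values (copper, PTFE, polymer catheter, ceramic tip,
# cooling water) -- the needle interior is excluded from the thermal solve.
.default_materials <- function(case_kind) {
  liver <- material_properties("liver",
    relative_permittivity = 43.03, electric_conductivity = 1.69,
    density = 1069, specific_heat = 3600, thermal_conductivity = 0.55,
    perfusion_rate = 0.00361, metabolic_heat = 1000)
  tumor <- material_properties("tumor",
    relative_permittivity = 54.8, electric_conductivity = 2,
    density = 1040, specific_heat = 3760, thermal_conductivity = 0.57,
    perfusion_rate = 0.00361, metabolic_heat = 1300)
  # tissue-mimicking polyacrylamide phantom: liver dielectric/thermal values
  # with perfusion and metabolism switched off
  phantom <- material_properties("phantom",
    relative_permittivity = 43.03, electric_conductivity = 1.69,
    density = 1069, specific_heat = 3600, thermal_conductivity = 0.55,
    perfusion_rate = 0, metabolic_heat = 0)
  copper <- material_properties("copper",
    relative_permittivity = 1, electric_conductivity = 0,
    density = 8960, specific_heat = 385, thermal_conductivity = 400,
    is_pec = TRUE, in_needle = TRUE)
  dielectric <- material_properties("dielectric",
    relative_permittivity = 2.03, electric_conductivity = 0,
    density = 2200, specific_heat = 1050, thermal_conductivity = 0.25,
    in_needle = TRUE)
  catheter <- material_properties("catheter",
    relative_permittivity = 2.6, electric_conductivity = 0,
    density = 1200, specific_heat = 1500, thermal_conductivity = 0.2,
    in_needle = TRUE)
  tip <- material_properties("tip",
    relative_permittivity = 9, electric_conductivity = 0,
    density = 3800, specific_heat = 880, thermal_conductivity = 25,
    in_needle = TRUE)
  water <- material_properties("water",
    relative_permittivity = 78, electric_conductivity = 1.5,
    density = 1000, specific_heat = 4180, thermal_conductivity = 0.6,
    in_needle = TRUE)
  if (case_kind == "phantom") {
    list(phantom = phantom, copper = copper, dielectric = dielectric,
         catheter = catheter, tip = tip, water = water)
  } else {
    list(liver = liver, tumor = tumor, copper = copper, dielectric = dielectric,
         catheter = catheter, tip = tip, water = water)
  }
}

.override_field_map <- c(
  eps = "relative_permittivity", sigma = "electric_conductivity",
  mu = "relative_permeability", rho = "density", Cp = "specific_heat",
  k = "thermal_conductivity", omega = "perfusion_rate", Qm = "metabolic_heat")

#' Build the material table for a simulation case
#'
#' Assembles every material needed for a case: the base medium (liver for the
#' clinical case, perfusion-free phantom medium otherwise), tumor (clinical
#' only), the applicator parts (copper conductors, PTFE dielectric, catheter,
#' ceramic tip, cooling water) and the blood properties of the perfusion term.
#'
#' Overrides use keys of the form `<param>_<material>` with `<param>` one of
#' `eps`, `sigma`, `mu`, `rho`, `Cp`, `k`, `omega`, `Qm` (e.g. `sigma_liver`,
#' `eps_tumor`), or `<param>_blood` with `<param>` one of `rho`, `Cp`, `omega`,
#' `T` for the blood record.
#'
#' @param case_kind `"phantom"` or `"clinical"`.
#' @param overrides named list of parameter overrides (see Details).
#' @return an object of class `material_table`: a named list of
#'   [material_properties()] with the blood record in `attr(, "blood")` and the
#'   case kind in `attr(, "case_kind")`.
#' @examples
#' tab <- build_material_table("clinical")
#' tab$tumor$electric_conductivity  # 2 S/m
#' @export
build_material_table <- function(case_kind = c("phantom", "clinical"),
                                 overrides = list()) {
  case_kind <- match.arg(case_kind)
  mats <- .default_materials(case_kind)
  blood <- blood_properties()
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("overrides must be a named list", call. = FALSE)
    for (key in names(overrides)) {
      parts <- strsplit(key, "_", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop("unknown override key '", key, "'", call. = FALSE)
      par <- parts[1]; mat <- parts[2]
      val <- as.numeric(overrides[[key]])
      if (mat == "blood") {
        fld <- c(rho = "density", Cp = "specific_heat", omega = "perfusion_rate",
                 T = "temperature")[par]
        if (is.na(fld)) stop("unknown blood parameter in override '", key, "'", call. = FALSE)
        blood[[fld]] <- val
        next
      }
      if (!mat %in% names(mats))
        stop("unknown material in override '", key, "' (have: ",
             paste(names(mats), collapse = ", "), ")", call. = FALSE)
      fld <- .override_field_map[par]
      if (is.na(fld)) stop("unknown parameter in override '", key, "'", call. = FALSE)
      mats[[mat]][[fld]] <- val
      validate_material_properties(mats[[mat]])
    }
    blood <- blood_properties(blood$density, blood$specific_heat,
                              blood$perfusion_rate, blood$temperature)
  }
  structure(mats, blood = blood, case_kind = case_kind, class = "material_table")
}

#' @export
print.material_table <- function(x, ...) {
  cat("<material_table> case:", attr(x, "case_kind"), "\n")
  df <- do.call(rbind, lapply(x, function(m)
    data.frame(name = m$name, eps_r = m$relative_permittivity,
               sigma = m$electric_conductivity, rho = m$density,
               Cp = m$specific_heat, k = m$thermal_conductivity,
               omega_b = m$perfusion_rate, Qm = m$metabolic_heat,
               pec = m$is_pec, needle = m$in_needle)))
  rownames(df) <- NULL
  print(df, ...)
  b <- attr(x, "blood")
  cat(sprintf("blood: rho=%g Cp=%g omega=%g Tb=%g K\n",
              b$density, b$specific_heat, b$perfusion_rate, b$temperature))
  invisible(x)
}

#' Power delivered at the applicator after cable losses
#'
#' The generator power is attenuated by the feed cable; only the remainder is
#' emitted at the needle (e.g. 120 W with a 65% loss fraction delivers 42 W).
#'
#' @param generator_power generator output power (W, >= 0).
#' @param loss_fraction fraction of power lost in the cable, in \[0, 1\].
#' @return delivered power (W).
#' @examples
#' delivered_power(120, 0.65)  # 42 W
#' @export
delivered_power <- function(generator_power, loss_fraction) {
  if (any(generator_power < 0)) stop("generator power must be >= 0", call. = FALSE)
  if (any(loss_fraction < 0 | loss_fraction > 1))
    stop("loss fraction must be in [0, 1]", call. = FALSE)
  generator_power * (1 - loss_fraction)
}

#' Serialize / read a material table as a YAML config fragment
#'
#' Values that are exactly representable in decimal round-trip bit-exactly.
#'
#' @param table a [build_material_table()] result.
#' @param path file path to write to (or read from).
#' @return `write_material_table` returns `path` invisibly;
#'   `read_material_table` returns a `material_table`.
#' @export
write_material_table <- function(table, path) {
  stopifnot(inherits(table, "material_table"))
  b <- attr(table, "blood")
  out <- list(case_kind = attr(table, "case_kind"),
              blood = list(rho_blood = b$density, Cp_blood = b$specific_heat,
                           omega_blood = b$perfusion_rate, T_blood = b$temperature),
              materials = lapply(unclass(table), function(m) m[setdiff(names(m), "name")]))
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' @rdname write_material_table
#' @export
read_material_table <- function(path) {
  raw <- yaml::read_yaml(path)
  mats <- lapply(names(raw$materials), function(nm)
    do.call(material_properties, c(list(name = nm), raw$materials[[nm]])))
  names(mats) <- names(raw$materials)
  blood <- blood_properties(raw$blood$rho_blood, raw$blood$Cp_blood,
                            raw$blood$omega_blood, raw$blood$T_blood)
  structure(mats, blood = blood, case_kind = raw$case_kind, class = "material_table")
}
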