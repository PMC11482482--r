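#' Coaxial monopole applicator specification
#'
#' Geometry of the water-cooled interstitial applicator: a 15-gauge (1.45 mm
#' outer diameter) coaxial monopole. The internal radii are not published for
#' the commercial device; the defaults follow a 50-ohm PTFE-filled coax within
#' the 1.45 mm outer diameter and are all overridable. The radiating slot is a
#' ring gap in the outer conductor centred ~25 mm above the tip.
#'
#' @param outer_diameter shaft outer diameter (m).
#' @param shaft_length applicator length (m).
#' @param inner_conductor_radius radius of the inner copper conductor (m).
#' @param dielectric_outer_radius outer radius of the coax dielectric (m).
#' @param outer_conductor_outer_radius outer radius of the outer conductor (m).
#' @param catheter_outer_radius outer radius of the catheter sheath (m);
#'   defaults to `outer_diameter / 2`.
#' @param slot_center_offset_from_tip axial distance from tip to slot centre (m).
#' @param slot_width axial extent of the radiating slot (m).
#' @param tip_length length of the ceramic/plastic tip section (m).
#' @param tip_material material label of the tip section.
#' @param coolant_temperature circulating-water temperature (degrees C).
#' @param coolant_heat_transfer_coefficient convective coefficient of the
#'   cooled shaft wall (W/(m^2 K)).
#' @return an object of class `needle_spec`.
#' @export
needle_spec <- function(outer_diameter = 1.45e-3,
                        shaft_length = 0.150,
                        inner_conductor_radius = 0.145e-3,
                        dielectric_outer_radius = 0.50e-3,
                        outer_conductor_outer_radius = 0.60e-3,
                        catheter_outer_radius = outer_diameter / 2,
                        slot_center_offset_from_tip = 25e-3,
                        slot_width = 1.0e-3,
                        tip_length = 5e-3,
                        tip_material = "tip",
                        coolant_temperature = 7,
                        coolant_heat_transfer_coefficient = 500) {
  n <- list(outer_diameter = outer_diameter,
            shaft_length = shaft_length,
            inner_conductor_radius = inner_conductor_radius,
            dielectric_outer_radius = dielectric_outer_radius,
            outer_conductor_outer_radius = outer_conductor_outer_radius,
            catheter_outer_radius = catheter_outer_radius,
            slot_center_offset_from_tip = slot_center_offset_from_tip,
            slot_width = slot_width,
            tip_length = tip_length,
            tip_material = tip_material,
            coolant_temperature = coolant_temperature,
            coolant_heat_transfer_coefficient = coolant_heat_transfer_coefficient)
  class(n) <- "needle_spec"
  validate_needle_spec(n)
  n
}

validate_needle_spec <- function(n) {
  radii <- c(n$inner_conductor_radius, n$dielectric_outer_radius,
             n$outer_conductor_outer_radius, n$catheter_outer_radius)
  if (any(diff(radii) <= 0) || radii[1] <= 0)
    stop("needle radii must be strictly increasing inner -> outer", call. = FALSE)
  if (abs(n$catheter_outer_radius - n$outer_diameter / 2) > 1e-12)
    stop("catheter outer radius must equal outer_diameter / 2", call. = FALSE)
  if (n$slot_center_offset_from_tip >= n$shaft_length)
    stop("slot centre must lie within the shaft length", call. = FALSE)
  if (n$slot_center_offset_from_tip - n$slot_width / 2 <= n$tip_length)
    stop("slot must not overlap the tip section", call. = FALSE)
  if (n$slot_width <= 0 || n$tip_length < 0)
    stop("slot width must be > 0 and tip length >= 0", call. = FALSE)
  invisible(n)
}

#' Simulation domain specification
#'
#' Axisymmetric half-plane domain. z = 0 at the needle tip; the domain spans
#' z in \[-tip_clearance, domain_height - tip_clearance\] and r in
#' \[0, domain_radius\]. Phantom defaults reproduce a cylindrical tube of
#' 102.9 mm inner diameter filled to 125 mm; the clinical tumor defaults are an
#' ellipse of 11 mm (axial) x 8.7 mm (transverse) centred on the axis near the
#' radiating slot.
#'
#' @param case_kind `"phantom"` or `"clinical"`.
#' @param domain_radius radial extent (m).
#' @param domain_height total axial extent (m).
#' @param tip_clearance distance from the bottom domain boundary to the needle
#'   tip (m).
#' @param tumor_half_length tumor half-axis along z (m; clinical only).
#' @param tumor_half_width tumor half-axis along r (m; clinical only).
#' @param tumor_center_z tumor centre height above the tip (m).
#' @param initial_temperature initial (and far-boundary) temperature (K).
#' @return an object of class `domain_spec`.
#' @export
domain_spec <- function(case_kind = c("phantom", "clinical"),
                        domain_radius = 51.45e-3,
                        domain_height = 0.125,
                        tip_clearance = 40e-3,
                        tumor_half_length = 5.5e-3,
                        tumor_half_width = 4.35e-3,
                        tumor_center_z = 25e-3,
                        initial_temperature = NULL) {
  case_kind <- match.arg(case_kind)
  if (is.null(initial_temperature))
    initial_temperature <- if (case_kind == "phantom") 290.15 else 310.15
  d <- list(case_kind = case_kind,
            domain_radius = domain_radius,
            domain_height = domain_height,
            tip_clearance = tip_clearance,
            tumor_half_length = if (case_kind == "clinical") tumor_half_length else NA_real_,
            tumor_half_width = if (case_kind == "clinical") tumor_half_width else NA_real_,
            tumor_center_z = if (case_kind == "clinical") tumor_center_z else NA_real_,
            initial_temperature = initial_temperature,
            z_min = -tip_clearance,
            z_max = domain_height - tip_clearance)
  class(d) <- "domain_spec"
  validate_domain_spec(d)
  d
}

validate_domain_spec <- function(d) {
  if (d$domain_radius <= 0 || d$domain_height <= 0)
    stop("domain radius and height must be > 0", call. = FALSE)
  if (d$tip_clearance <= 0 || d$tip_clearance >= d$domain_height)
    stop("tip clearance must lie inside the domain height", call. = FALSE)
  if (d$case_kind == "clinical") {
    if (d$tumor_half_length <= 0 || d$tumor_half_width <= 0)
      stop("tumor half-axes must be > 0", call. = FALSE)
    if (d$tumor_center_z + d$tumor_half_length > d$z_max ||
        d$tumor_center_z - d$tumor_half_length < d$z_min ||
        d$tumor_half_width > d$domain_radius)
      stop("tumor ellipse must lie fully inside the domain", call. = FALSE)
  }
  invisible(d)
}

#' Build the axisymmetric region description of a case
#'
#' Partitions the half-plane rectangle \[0, domain_radius\] x \[z_min, z_max\]
#' into labelled regions: tip, inner conductor, coax dielectric, outer
#' conductor with its radiating slot (the slot region carries the dielectric
#' material), catheter, optional tumor ellipse and the base medium. Regions are
#' matched in priority order, so the partition is exact by construction.
#'
#' @param needle a [needle_spec()].
#' @param domain a [domain_spec()].
#' @return an object of class `em_geometry` with the ordered region list and a
#'   vectorized point-wise material lookup (see [material_at()]).
#' @export
build_geometry <- function(needle = needle_spec(), domain = domain_spec()) {
  validate_needle_spec(needle)
  validate_domain_spec(domain)
  if (needle$coolant_temperature < -5 || needle$coolant_temperature > 50)
    stop("coolant temperature (degrees C) looks implausible", call. = FALSE)
  zt <- domain$z_max
  if (zt <= needle$slot_center_offset_from_tip + needle$slot_width / 2)
    stop("domain must enclose the radiating slot of the needle", call. = FALSE)
  r_ic <- needle$inner_conductor_radius
  r_di <- needle$dielectric_outer_radius
  r_oc <- needle$outer_conductor_outer_radius
  r_ca <- needle$catheter_outer_radius
  if (r_ca >= domain$domain_radius)
    stop("domain radius must exceed the needle radius", call. = FALSE)
  zc <- needle$slot_center_offset_from_tip
  w2 <- needle$slot_width / 2
  tl <- needle$tip_length
  base <- if (domain$case_kind == "phantom") "phantom" else "liver"
  rect <- function(label, r0, r1, z0, z1)
    list(type = "rect", label = label, r0 = r0, r1 = r1, z0 = z0, z1 = z1)
  # monopole construction: the outer conductor terminates at the top of the
  # feed gap ("slot"); below it the inner conductor continues to the tip with
  # only its dielectric coating, forming the radiating section
  regions <- list(
    rect(needle$tip_material, 0, r_ca, 0, tl),
    rect("copper", 0, r_ic, tl, zt),
    rect("dielectric", r_di, r_oc, zc - w2, zc + w2),  # feed gap (slot)
    rect("dielectric", r_ic, r_di, tl, zt),
    rect("dielectric", r_di, r_oc, tl, zc - w2),       # monopole coating
    rect("copper", r_di, r_oc, zc + w2, zt),
    rect("catheter", r_oc, r_ca, tl, zt))
  if (domain$case_kind == "clinical")
    regions <- c(regions, list(list(type = "ellipse", label = "tumor",
                                    cz = domain$tumor_center_z,
                                    ar = domain$tumor_half_width,
                                    az = domain$tumor_half_length)))
  regions <- c(regions, list(rect(base, 0, domain$domain_radius,
                                  domain$z_min, domain$z_max)))
  g <- list(regions = regions, needle = needle, domain = domain,
            base_material = base)
  class(g) <- "em_geometry"
  g
}

#' Material label at points of the half-plane
#'
#' @param geometry an [build_geometry()] result.
#' @param r,z coordinates (m), recycled to a common length.
#' @return character vector of material labels.
#' @export
material_at <- function(geometry, r, z) {
  stopifnot(inherits(geometry, "em_geometry"))
  n <- max(length(r), length(z))
  r <- rep_len(r, n); z <- rep_len(z, n)
  out <- rep(NA_character_, n)
  for (reg in geometry$regions) {
    todo <- is.na(out)
    if (!any(todo)) break
    inside <- if (reg$type == "rect") {
      r >= reg$r0 & r <= reg$r1 & z >= reg$z0 & z <= reg$z1
    } else {
      (r / reg$ar)^2 + ((z - reg$cz) / reg$az)^2 <= 1
    }
    out[todo & inside] <- reg$label
  }
  if (anyNA(out))
    stop("geometry error: regions do not cover all queried points", call. = FALSE)
  out
}

#' @export
print.em_geometry <- function(x, ...) {
  d <- x$domain
  cat(sprintf("<em_geometry> %s case: r in [0, %.1f] mm, z in [%.1f, %.1f] mm\n",
              d$case_kind, 1e3 * d$domain_radius, 1e3 * d$z_min, 1e3 * d$z_max))
  cat(sprintf("  needle OD %.2f mm, slot at %.1f +/- %.2f mm above tip\n",
              1e3 * x$needle$outer_diameter,
              1e3 * x$needle$slot_center_offset_from_tip,
              1e3 * x$needle$slot_width / 2))
  labs <- vapply(x$regions, `[[`, "", "label")
  cat("  regions:", paste(unique(labs), collapse = ", "), "\n")
  invisible(x)
}
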