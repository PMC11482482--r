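#' Assemble a full case configuration
#'
#' Bundles every stage's parameters for [run_case()]. Defaults reproduce the
#' study conditions: phantom at 35 W delivered power, 7 degree C coolant,
#' 290.15 K start; clinical at 42 W, 20 degree C coolant, 310.15 K start with
#' perfusion and metabolic heat active and an 11 x 8.7 mm tumor near the slot.
#'
#' @param case `"phantom"` or `"clinical"`.
#' @param input_power power delivered at the needle (W); default 35 (phantom)
#'   or 42 (clinical).
#' @param duration ablation time (s).
#' @param material_overrides overrides for [build_material_table()].
#' @param needle arguments for [needle_spec()] (list).
#' @param domain arguments for [domain_spec()] (list).
#' @param resolution a [resolution_policy()].
#' @param thermal arguments for [thermal_config()] (list); perfusion/metabolic
#'   flags and coolant defaults are filled per case.
#' @param damage a [damage_params()].
#' @param voxel_spacing voxel size of the revolved zone volumes (m).
#' @param probes a [probe_set()]; default per case.
#' @param reference optional reference `zone_volume` (or a NIfTI path) to
#'   compare against.
#' @param transform optional [rigid_transform()] (or a 4x4 text-file path)
#'   registering the simulated zone to the reference.
#' @return an object of class `case_config` (a list).
#' @export
case_config <- function(case = c("phantom", "clinical"),
                        input_power = NULL,
                        duration = 600,
                        material_overrides = list(),
                        needle = list(),
                        domain = list(),
                        resolution = resolution_policy(),
                        thermal = list(),
                        damage = damage_params(),
                        voxel_spacing = 0.5e-3,
                        probes = NULL,
                        reference = NULL,
                        transform = NULL) {
  case <- match.arg(case)
  if (is.null(input_power)) input_power <- if (case == "phantom") 35 else 42
  if (is.null(needle$coolant_temperature))
    needle$coolant_temperature <- if (case == "phantom") 7 else 20
  structure(list(case = case, input_power = input_power, duration = duration,
                 material_overrides = material_overrides, needle = needle,
                 domain = domain, resolution = resolution, thermal = thermal,
                 damage = damage, voxel_spacing = voxel_spacing,
                 probes = probes, reference = reference, transform = transform),
            class = "case_config")
}

#' Read a case configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [case_config()]; material overrides
#' use the `<param>_<material>` key style (e.g. `sigma_liver`, `rho_blood`),
#' and `P_in` / `f` set the delivered power and frequency.
#'
#' @param path YAML file path.
#' @return a [case_config()].
#' @export
read_case_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list(case = y$case %||% "phantom")
  for (nm in c("input_power", "duration", "voxel_spacing"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$P_in)) args$input_power <- y$P_in
  if (!is.null(y$overrides)) args$material_overrides <- y$overrides
  for (nm in c("needle", "domain", "thermal"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$resolution))
    args$resolution <- do.call(resolution_policy, y$resolution)
  if (!is.null(y$damage)) args$damage <- do.call(damage_params, y$damage)
  if (!is.null(y$reference)) args$reference <- y$reference
  if (!is.null(y$transform)) args$transform <- y$transform
  do.call(case_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a complete ablation case
#'
#' Executes the full pipeline in order: geometry -> rasterization -> EM solve
#' -> SAR -> power normalization -> bioheat transient -> Arrhenius and
#' critical-temperature damage -> contour extraction -> revolved 3D zones ->
#' (optional) metrics against a reference segmentation. Reruns with the same
#' configuration are bit-identical.
#'
#' @param config a [case_config()] (or a YAML path for [read_case_config()]).
#' @param out_dir optional directory; when given, all artifacts (probe CSV,
#'   masks, surfaces, metrics report, manifest) are written there.
#' @param frequency operating frequency (Hz).
#' @return an object of class `case_bundle`: a list with the grid, fields,
#'   history, probe series, damage fields, 2D masks, contours, revolved
#'   volumes, metrics (or `NULL`) and a run manifest.
#' @export
run_case <- function(config = case_config(), out_dir = NULL,
                     frequency = 2.45e9) {
  if (is.character(config)) config <- read_case_config(config)
  stopifnot(inherits(config, "case_config"))
  t_start <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }
  materials <- stage("materials",
    build_material_table(config$case, config$material_overrides))
  needle <- stage("geometry", do.call(needle_spec, config$needle))
  domain <- stage("geometry",
    do.call(domain_spec, c(list(case_kind = config$case), config$domain)))
  geometry <- stage("geometry", build_geometry(needle, domain))
  grid <- stage("rasterize", rasterize(geometry, config$resolution))

  emc <- em_config(frequency = frequency, input_power = config$input_power,
                   absorbing_boundary_thickness = config$resolution$pml_cells)
  field <- stage("em", solve_em(grid, materials, emc))
  sar <- stage("sar", compute_sar(field, grid, materials))
  sar <- stage("normalize", normalize_to_input_power(sar, grid, config$input_power))

  th_args <- config$thermal
  th_args$duration <- config$duration
  if (is.null(th_args$include_perfusion))
    th_args$include_perfusion <- config$case == "clinical"
  if (is.null(th_args$include_metabolic))
    th_args$include_metabolic <- config$case == "clinical"
  thermal <- do.call(thermal_config, th_args)
  history <- stage("bioheat", run_transient(grid, materials, sar, thermal))

  probes <- config$probes %||% default_probe_set(config$case)
  probe_series <- stage("probes", sample_probes(history, probes))

  degenerate <- config$duration <= 0
  damage <- stage("damage", arrhenius_integral(history, config$damage))
  m_arr <- stage("damage", arrhenius_mask(damage, config$damage))
  m_crit <- stage("damage", critical_temp_mask(history, config$damage))
  c_arr <- stage("zones", extract_contour(m_arr))
  c_crit <- stage("zones", extract_contour(m_crit))
  v_arr <- stage("zones", revolve(c_arr, config$voxel_spacing))
  v_crit <- stage("zones", revolve(c_crit, config$voxel_spacing))

  metrics <- NULL
  reference <- config$reference
  if (is.character(reference)) reference <- read_zone_nifti(reference)
  transform <- config$transform
  if (is.character(transform)) transform <- read_transform(transform)
  if (!is.null(reference) && !degenerate && v_arr$voxel_count > 0) {
    tr <- stage("metrics", register_zones(v_arr, reference, transform))
    metrics <- list(
      arrhenius = stage("metrics", compute_metrics(v_arr, reference, tr)),
      critical_temp = if (v_crit$voxel_count > 0)
        stage("metrics", compute_metrics(v_crit, reference, tr)) else NULL,
      transform = tr)
  }

  manifest <- list(
    case = config$case,
    input_power_W = config$input_power,
    duration_s = config$duration,
    frequency_Hz = frequency,
    material_overrides = config$material_overrides,
    grid = list(nr = grid$nr, nz = grid$nz, cells = grid$nr * grid$nz,
                min_cell_mm = 1e3 * min(grid$dr, grid$dz),
                max_cell_mm = 1e3 * max(grid$dr, grid$dz)),
    thermal = list(time_step_s = thermal$time_step,
                   snapshot_interval_s = thermal$snapshot_interval,
                   include_perfusion = thermal$include_perfusion,
                   include_metabolic = thermal$include_metabolic,
                   coolant_temperature_C = needle$coolant_temperature,
                   coolant_h_W_m2K = needle$coolant_heat_transfer_coefficient),
    damage = unclass(config$damage),
    voxel_spacing_mm = 1e3 * config$voxel_spacing,
    peak_temperature_C = max(history$max_field, na.rm = TRUE) - 273.15,
    zone_volume_mm3 = c(arrhenius = 1e9 * v_arr$volume,
                        critical_temp = 1e9 * v_crit$volume),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))

  bundle <- structure(list(config = config, materials = materials,
                           grid = grid, em = field, sar = sar,
                           history = history, probes = probe_series,
                           damage = damage,
                           masks = list(arrhenius = m_arr, critical_temp = m_crit),
                           contours = list(arrhenius = c_arr, critical_temp = c_crit),
                           volumes = list(arrhenius = v_arr, critical_temp = v_crit),
                           metrics = metrics, manifest = manifest),
                      class = "case_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

#' @export
print.case_bundle <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<case_bundle> %s: %g W, %g s on %d cells\n",
              m$case, m$input_power_W, m$duration_s, m$grid$cells))
  cat(sprintf("  peak %.2f degC | zone volumes (mm^3): Arrhenius %.0f, 60C %.0f\n",
              m$peak_temperature_C, m$zone_volume_mm3[["arrhenius"]],
              m$zone_volume_mm3[["critical_temp"]]))
  if (!is.null(x$metrics))
    cat(sprintf("  metrics (Arrhenius): Dice %.3f, Hausdorff %.2f mm, Euclidean %.2f mm\n",
                x$metrics$arrhenius$dice, x$metrics$arrhenius$hausdorff_mm,
                x$metrics$arrhenius$mean_euclidean_mm))
  invisible(x)
}

#' Write every artifact of a case bundle to a directory
#'
#' Writes the probe series (CSV), the 2D necrosis masks and damage integral
#' (CSV matrices), the revolved volumes (NIfTI), zone surfaces (STL), the
#' metrics report and transform (JSON / text) and the run manifest (JSON).
#'
#' @param bundle a [run_case()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "case_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  utils::write.csv(bundle$probes, p("probes.csv"), row.names = FALSE)
  utils::write.csv(bundle$damage$omega, p("arrhenius_omega.csv"), row.names = FALSE)
  for (nm in names(bundle$masks))
    utils::write.csv(bundle$masks[[nm]]$mask * 1, p(paste0("mask_", nm, ".csv")),
                     row.names = FALSE)
  for (nm in names(bundle$volumes)) {
    v <- bundle$volumes[[nm]]
    if (v$voxel_count > 0) {
      write_zone_nifti(v, p(paste0("zone_", nm, ".nii.gz")))
      if (!is.null(v$surface))
        write_surface(v$surface, p(paste0("zone_", nm, ".stl")), name = nm)
    }
  }
  if (!is.null(bundle$metrics)) {
    write_metrics_report(bundle$metrics$arrhenius, p("metrics_arrhenius.json"))
    if (!is.null(bundle$metrics$critical_temp))
      write_metrics_report(bundle$metrics$critical_temp, p("metrics_critical_temp.json"))
    write_transform(bundle$metrics$transform, p("transform.txt"))
  }
  jsonlite::write_json(bundle$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
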