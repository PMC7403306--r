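# All on-disk tables are plain delimited text with '#' header comments that
# record the schema version and every physical constant actually used: the
# tool's reproducibility depends on constants the literature rarely reports.

SCHEMA_VERSION <- "1"

header_lines <- function(kind, extra = character()) {
  c(sprintf("# cavrheo %s schema_version=%s package_version=%s", kind,
            SCHEMA_VERSION, as.character(utils::packageVersion("cavrheo"))),
    paste0("# ", extra))
}

write_table_with_header <- function(df, path, kind, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines(kind, extra), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a radius-time dataset as delimited text
#'
#' Columns `time_us`, `radius_um`, `replicate_id`, `sample_id` with a
#' commented header; micrometre/microsecond units at the file boundary.
#'
#' @param dataset [lcr_dataset()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  df <- data.frame(time_us = dataset$time * 1e6,
                   radius_um = dataset$radius * 1e6,
                   replicate_id = dataset$replicate_id,
                   sample_id = dataset$sample_id)
  write_table_with_header(df, path, "dataset")
}

#' Read a radius-time dataset
#'
#' Accepts the native `time_us`/`radius_um` columns or SI `time_s`/`radius_m`
#' columns; either is normalized to SI in memory. A header row is mandatory.
#'
#' @param path Input path (tab- or comma-delimited; `#` comments ignored).
#' @return [lcr_dataset()].
#' @export
read_dataset <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (all(c("time_us", "radius_um") %in% names(df))) {
    tm <- df$time_us * 1e-6; rad <- df$radius_um * 1e-6
  } else if (all(c("time_s", "radius_m") %in% names(df))) {
    tm <- df$time_s; rad <- df$radius_m
  } else {
    stop("dataset needs columns time_us/radius_um or time_s/radius_m")
  }
  if (!"replicate_id" %in% names(df)) df$replicate_id <- 1L
  if (!"sample_id" %in% names(df)) df$sample_id <- "sample"
  lcr_dataset(tm, rad, df$replicate_id, df$sample_id[1])
}

#' Export a simulated trajectory as delimited text
#'
#' Columns `time_us`, `radius_um`, `velocity_m_per_s`, `phase`; the header
#' records the full parameter set.
#'
#' @param trajectory An `lcr_trajectory`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  m <- trajectory$material; a <- trajectory$ambient
  g <- trajectory$geometry
  extra <- c(
    sprintf("mode=%s R_max_um=%.6g R_0_um=%.6g R_f_um=%s failed=%s",
            trajectory$mode, g$R_max * 1e6, g$R_0 * 1e6,
            if (is.finite(g$R_f)) sprintf("%.6g", g$R_f * 1e6) else "none",
            trajectory$failed),
    sprintf(paste0("elastic_modulus_Pa=%.6g kinematic_viscosity_m2_per_s=%g ",
                   "density_kg_per_m3=%g surface_tension_N_per_m=%g ",
                   "radial_failure_strain=%s"),
            m$elastic_modulus, m$kinematic_viscosity, m$density,
            m$surface_tension,
            if (is.finite(m$radial_failure_strain))
              format(m$radial_failure_strain) else "none"),
    sprintf(paste0("far_field_pressure_Pa=%g vapor_pressure_Pa=%g ",
                   "adiabatic_index=%g temperature_K=%g T_hg_us=%.6g"),
            a$far_field_pressure, a$vapor_pressure, a$adiabatic_index,
            a$temperature, trajectory$T_hg * 1e6))
  df <- data.frame(time_us = trajectory$states$time * 1e6,
                   radius_um = trajectory$states$radius * 1e6,
                   velocity_m_per_s = trajectory$states$velocity,
                   phase = trajectory$states$phase)
  write_table_with_header(df, path, "trajectory", extra)
}

#' Export a strain field as delimited text
#'
#' Columns `r_ref_over_R0`, `radius_deformed_um`, `strain_rr`, `strain_tt`
#' with the geometry in the header.
#'
#' @param field [strain_field()] output.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_strain_field <- function(field, path) {
  extra <- sprintf("R_max_um=%.6g R_0_um=%.6g R_B_um=%.6g",
                   attr(field, "R_max") * 1e6, attr(field, "R_0") * 1e6,
                   attr(field, "R_B") * 1e6)
  df <- data.frame(r_ref_over_R0 = field$r_ref_over_R0,
                   radius_deformed_um = field$radius_deformed * 1e6,
                   strain_rr = field$strain_rr,
                   strain_tt = field$strain_tt)
  write_table_with_header(df, path, "strain_field", extra)
}

#' Read a frame manifest
#'
#' Delimited text with mandatory header and columns `path`, `delay_us`,
#' `replicate_id`, `sample_id`, `um_per_px`. Relative frame paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest path.
#' @return data.frame.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("path", "delay_us", "replicate_id", "sample_id", "um_per_px")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  rel <- !file.exists(df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df
}

# ---- configuration ---------------------------------------------------------

unit_factors <- c(
  "Pa" = 1, "kPa" = 1e3, "MPa" = 1e6,
  "m" = 1, "mm" = 1e-3, "um" = 1e-6, "µm" = 1e-6, "nm" = 1e-9,
  "s" = 1, "ms" = 1e-3, "us" = 1e-6, "µs" = 1e-6, "ns" = 1e-9,
  "K" = 1, "N/m" = 1, "kg/m3" = 1, "kg/m^3" = 1, "m2/s" = 1, "m^2/s" = 1)

parse_quantity <- function(x, key) {
  if (is.numeric(x)) return(x)  # bare numbers are SI
  if (!is.character(x) || length(x) != 1)
    stop("config value for '", key, "' must be a number or a 'value unit' string")
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*([A-Za-z/^0-9µ]*)\\s*$", x))[[1]]
  if (length(m) < 2 || is.na(suppressWarnings(as.numeric(m[2]))))
    stop("cannot parse config value '", x, "' for key '", key, "'")
  val <- as.numeric(m[2])
  unit <- m[3]
  if (unit == "") return(val)
  if (!unit %in% names(unit_factors))
    stop("unknown unit '", unit, "' for config key '", key,
         "'; known units: ", paste(names(unit_factors), collapse = ", "))
  val * unname(unit_factors[unit])
}

config_schema <- function() {
  list(
    material = c("elastic_modulus", "kinematic_viscosity", "density",
                 "surface_tension", "radial_failure_strain"),
    ambient = c("far_field_pressure", "vapor_pressure", "adiabatic_index",
                "temperature"),
    solver = c("rtol", "atol_radius", "atol_velocity", "max_step_frac",
               "n_out"),
    fit = c("mode", "fit_t0", "maxiter", "ftol", "ptol"),
    protocol = c("delay_step", "delay_min", "delay_max", "replicates",
                 "noise_sigma", "noise_floor", "seed"))
}

#' Default run configuration
#'
#' All defaults of the material, ambient, solver, fit and acquisition
#' protocol blocks, as used when a config file omits them: water viscosity,
#' density and surface tension; atmospheric far field with water vapor
#' pressure at 25 degrees C and adiabatic index 4/3.
#'
#' @return Nested list of class `lcr_config`.
#' @export
default_config <- function() {
  structure(list(
    material = list(elastic_modulus = 0, kinematic_viscosity = 1e-6,
                    density = 997, surface_tension = 0.072,
                    radial_failure_strain = Inf),
    ambient = list(far_field_pressure = 101325, vapor_pressure = 3169,
                   adiabatic_index = 4 / 3, temperature = 298.15),
    solver = list(rtol = 1e-9, atol_radius = 1e-13, atol_velocity = 1e-7,
                  max_step_frac = 0.005, n_out = 400),
    fit = list(mode = "failure", fit_t0 = TRUE, maxiter = 60,
               ftol = 1e-10, ptol = 1e-8),
    protocol = list(delay_step = 1e-6, delay_min = 0, delay_max = 30e-6,
                    replicates = 5, noise_sigma = 0.03, noise_floor = 0,
                    seed = NULL),
    schema_version = SCHEMA_VERSION), class = "lcr_config")
}

#' Load and validate a YAML run configuration
#'
#' Unknown blocks or keys are rejected by name; recognised numeric fields
#' accept either bare SI numbers or `"value unit"` strings (e.g. `"20 kPa"`,
#' `"1 us"`), which are normalized to SI. Missing fields take the defaults of
#' [default_config()]; an empty file yields all defaults.
#'
#' @param path YAML file path.
#' @return Validated `lcr_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  schema <- config_schema()
  cfg <- default_config()
  bad_blocks <- setdiff(names(user), names(schema))
  if (length(bad_blocks))
    stop("unknown config block(s): ", paste(bad_blocks, collapse = ", "),
         " (expected: ", paste(names(schema), collapse = ", "), ")")
  text_keys <- c("mode")
  for (block in names(user)) {
    keys <- names(user[[block]])
    bad <- setdiff(keys, schema[[block]])
    if (length(bad))
      stop("unknown key(s) in config block '", block, "': ",
           paste(bad, collapse = ", "), " (expected: ",
           paste(schema[[block]], collapse = ", "), ")")
    for (key in keys) {
      val <- user[[block]][[key]]
      cfg[[block]][[key]] <-
        if (key %in% text_keys || is.logical(val)) val
        else parse_quantity(val, paste(block, key, sep = "."))
    }
  }
  cfg
}

#' Write a JSON fit report
#'
#' Structured text report of a fit: the estimate with approximate standard
#' errors, the derived circumferential failure strain, the convergence block,
#' an echo of the resolved configuration, and an MD5 checksum of the input
#' data file when given.
#'
#' @param fit An `lcr_fit`.
#' @param path Output path.
#' @param config The `lcr_config` in force (echoed into the report).
#' @param input_path Optional path of the fitted dataset, checksummed.
#' @return The path, invisibly.
#' @export
write_fit_report <- function(fit, path, config = default_config(),
                             input_path = NULL) {
  se <- sqrt(pmax(diag(fit$covariance), 0))
  report <- list(
    package_version = as.character(utils::packageVersion("cavrheo")),
    schema_version = SCHEMA_VERSION,
    mode = fit$mode,
    estimate = list(
      R_max_um = fit$estimate$R_max * 1e6,
      elastic_modulus_kPa = fit$estimate$elastic_modulus * 1e-3,
      radial_failure_strain =
        if (is.finite(fit$estimate$radial_failure_strain))
          fit$estimate$radial_failure_strain else "none",
      circumferential_failure_strain = fit$circumferential_failure_strain,
      t0_us = fit$estimate$t0 * 1e6),
    standard_errors = as.list(se),
    residual_norm_um = fit$residual_norm * 1e6,
    n_points = fit$n_points,
    convergence = fit$convergence,
    config = unclass(config),
    input_md5 = if (!is.null(input_path))
      unname(tools::md5sum(input_path)) else NA)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", null = "null")
  invisible(path)
}

config_material <- function(cfg) {
  do.call(material, cfg$material)
}

config_ambient <- function(cfg) {
  do.call(ambient_conditions, cfg$ambient)
}

config_solver <- function(cfg) {
  do.call(solver_options, cfg$solver)
}

config_protocol <- function(cfg, seed = NULL) {
  p <- cfg$protocol
  if (!is.null(seed)) p$seed <- seed
  do.call(acquisition_protocol, p)
}
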