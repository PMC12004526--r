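# Readers and writers for the tabular interchange formats: spectrum CSV with
# a JSON metadata sidecar, velocity-table CSV, stiffness-tensor JSON, and the
# analysis configuration (YAML or JSON).

sidecar_path <- function(path) paste0(path, ".json")

config_to_list <- function(config) {
  list(lambda_nm = config$lambda_nm, theta_deg = config$theta_deg,
       n = config$n, geometry = config$geometry,
       polarization = config$polarization)
}

config_from_list <- function(x, where = "metadata") {
  req <- c("lambda_nm", "theta_deg", "n", "geometry", "polarization")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    abort_validation(sprintf("%s is missing field(s): %s", where,
                             paste(miss, collapse = ", ")))
  }
  scattering_config(x$lambda_nm, x$theta_deg, x$n,
                    geometry = x$geometry, polarization = x$polarization)
}

#' Write / read a BLS spectrum as CSV plus JSON sidecar
#'
#' The spectrum is stored as a two-column RFC-4180 CSV (`frequency_ghz`,
#' `counts`); the scattering configuration travels in a JSON sidecar at
#' `<path>.json`.
#'
#' @param spectrum A [bls_spectrum()] (with a non-NULL config for writing).
#' @param path CSV file path.
#' @return `write_spectrum_csv` returns `path` invisibly; `read_spectrum_csv`
#'   returns a [bls_spectrum()].
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "bls_spectrum"))
  df <- data.frame(frequency_ghz = spectrum$frequency_ghz,
                   counts = spectrum$intensity)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (!is.null(spectrum$config)) {
    jsonlite::write_json(config_to_list(spectrum$config), sidecar_path(path),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @param metadata Path of the JSON sidecar; defaults to `<path>.json`. Use
#'   `NULL` to read a bare spectrum without configuration.
#' @export
read_spectrum_csv <- function(path, metadata = sidecar_path(path)) {
  df <- read_checked_csv(path, c("frequency_ghz", "counts"))
  config <- NULL
  if (!is.null(metadata) && file.exists(metadata)) {
    config <- config_from_list(jsonlite::read_json(metadata), where = metadata)
  }
  bls_spectrum(df$frequency_ghz, df$counts, config = config)
}

#' Write / read an angle-dependent velocity table
#'
#' CSV with columns `alpha_deg`, `branch`, `c_mps`, `sigma_c_mps`.
#'
#' @param data Data frame as produced by [generate_velocity_dataset()].
#' @param path CSV file path.
#' @export
write_velocity_csv <- function(data, path) {
  data <- check_velocity_data(data)
  write.csv(data[, c("alpha_deg", "branch", "c_mps", "sigma_c_mps")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_velocity_csv
#' @export
read_velocity_csv <- function(path) {
  df <- read_checked_csv(path, c("alpha_deg", "branch", "c_mps"),
                         character_cols = "branch")
  check_velocity_data(df)
}

# CSV reader with per-row validation and line-numbered errors
read_checked_csv <- function(path, required, character_cols = character()) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  if (file.size(path) == 0) abort_validation(sprintf("file is empty: %s", path))
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                 error = function(e) {
                   abort_validation(sprintf("cannot parse %s: %s", path,
                                            conditionMessage(e)))
                 })
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    abort_validation(sprintf("%s is missing column(s): %s", path,
                             paste(miss, collapse = ", ")))
  }
  if (nrow(df) == 0) abort_validation(sprintf("%s has a header but no data rows", path))
  num_cols <- setdiff(required, character_cols)
  for (col in num_cols) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad)) {
      abort_validation(sprintf(
        "%s: non-numeric or missing `%s` at line %s (counting the header as line 1)",
        path, col, paste(bad + 1, collapse = ", ")))
    }
    df[[col]] <- v
  }
  df
}

#' Write / read a stiffness tensor as JSON
#'
#' JSON object with fields `C11, C12, C13, C33, C44, C66` (GPa) and `rho`
#' (kg/m^3).
#'
#' @param tensor A [ti_tensor()].
#' @param path JSON file path.
#' @export
write_tensor_json <- function(tensor, path) {
  stopifnot(inherits(tensor, "ti_tensor"))
  jsonlite::write_json(unclass(tensor), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tensor_json
#' @export
read_tensor_json <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  x <- jsonlite::read_json(path)
  req <- c("C11", "C13", "C33", "C44", "rho")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    abort_validation(sprintf("%s is missing field(s): %s", path,
                             paste(miss, collapse = ", ")))
  }
  ti_tensor(C11 = x$C11, C33 = x$C33, C44 = x$C44, C13 = x$C13,
            C66 = x$C66 %||% x$C44, rho = x$rho)
}

#' Read an analysis configuration from YAML or JSON
#'
#' Expected fields: `lambda_nm`, `theta_deg`, `n`, `geometry`,
#' `polarization` (a scattering block, or a list of such blocks under
#' `scattering`), plus optional `rho` (kg/m^3), `constraint`
#' (`C66_equals_C44`/`C66_free`) and `seed`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `scattering` (list of
#'   [scattering_config()]), `rho`, `constraint`, `seed`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort_validation(sprintf("file not found: %s", path))
  x <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else jsonlite::read_json(path)
  # YAML 1.1 parses a bare `n` key as boolean FALSE; restore the field name
  fix_n <- function(b) { names(b)[names(b) %in% c("FALSE", "false")] <- "n"; b }
  x <- fix_n(x)
  blocks <- if (!is.null(x$scattering)) lapply(x$scattering, fix_n) else list(x)
  scattering <- lapply(blocks, config_from_list, where = path)
  list(scattering = scattering,
       rho = x$rho %||% NULL,
       constraint = x$constraint %||% "C66_equals_C44",
       seed = x$seed %||% 1L)
}

#' Write a tensor-fit report as JSON
#'
#' Serializes a [fit_elastic_tensor()] result (constants with standard
#' errors, chi^2/dof, constraint mode, data size) together with the derived
#' engineering moduli.
#'
#' @param fit A `"tensor_fit"`.
#' @param path JSON file path.
#' @export
write_fit_report <- function(fit, path) {
  stopifnot(inherits(fit, "tensor_fit"))
  mod <- moduli_from_tensor(fit$tensor, fit$covariance)
  report <- list(
    constraint_mode = fit$constraint,
    n_data = fit$n_data,
    chi2_dof = fit$chi2_dof,
    constants_GPa = unclass(fit$tensor)[c("C11", "C12", "C13", "C33", "C44", "C66")],
    constants_se_GPa = as.list(fit$se),
    rho_kg_m3 = fit$tensor$rho,
    moduli_GPa = mod[moduli_names],
    moduli_se = if (!is.null(mod$se)) as.list(mod$se) else NULL
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
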