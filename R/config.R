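# Structured configuration files (YAML or JSON) mirroring film_parameters
# and boundary_conditions, and the CSV profile output dialect.

#' Read a film-model configuration file
#'
#' The file (YAML if the extension is `.yml`/`.yaml`, JSON otherwise)
#' holds up to five blocks, all optional, whose keys are the arguments of
#' the corresponding constructors (SI units):
#' `film` ([film_parameters()]: `thickness`, `v_total`, `d_e`, `d_h2`,
#' `d_o2`, `part_h2`, `part_o2`, `e_total`, `k_o2_v`, `s_o2`, `h2_sat`,
#' `temperature`, `pH`), `mediator` ([redox_couple()]), `kinetics`
#' ([enzyme_kinetics()]), `inactivation` ([inactivation_model()]) and
#' `boundary` ([boundary_conditions()]: `electrode_potential` in V vs SHE,
#' `bulk_h2`, `bulk_o2` in mol m^-3).  A top-level `profile` key selects a
#' [default_parameter_set()] base that the other blocks then override;
#' `n_grid` sets the grid size.
#'
#' @param path configuration file path.
#' @return a list with `params` ([film_parameters]), `bc`
#'   ([boundary_conditions], `NULL` if no `boundary` block) and `n_grid`.
#' @export
read_film_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configuration requires the 'yaml' package",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configuration requires the 'jsonlite' package",
           call. = FALSE)
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  base <- if (!is.null(cfg$profile)) default_parameter_set(cfg$profile)
          else film_parameters()
  film_args <- if (is.null(cfg$film)) list() else cfg$film
  if (!is.null(cfg$mediator))
    film_args$mediator <- do.call(redox_couple, cfg$mediator)
  else film_args$mediator <- base$mediator
  film_args$kinetics <- if (!is.null(cfg$kinetics))
    do.call(enzyme_kinetics, cfg$kinetics) else base$kinetics
  film_args$inactivation <- if (!is.null(cfg$inactivation))
    do.call(inactivation_model, cfg$inactivation) else base$inactivation
  # unspecified film keys inherit from the base profile
  for (key in c("thickness", "v_total", "d_e", "d_h2", "d_o2", "part_h2",
                "part_o2", "e_total", "k_o2_v", "s_o2", "h2_sat",
                "temperature", "pH", "slope"))
    if (is.null(film_args[[key]])) film_args[[key]] <- base[[key]]
  params <- do.call(film_parameters, film_args)
  bc <- if (!is.null(cfg$boundary)) do.call(boundary_conditions, cfg$boundary)
  list(params = params, bc = bc,
       n_grid = if (is.null(cfg$n_grid)) 200L else as.integer(cfg$n_grid))
}

#' Write a species profile to CSV
#'
#' Columns `xi`, `v_ox`, `v_red`, `h2`, `o2`, `e_active`, `e_inactive`,
#' `e_dead`, `e_v_she`, `e_v_rhe`; metadata in `#`-prefixed header lines.
#'
#' @param profile a [species_profile].
#' @param path output file path.
#' @param params the profile's [film_parameters] (defaults to the attached
#'   set).
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path,
                              params = attr(profile, "params")) {
  e_eq <- -params$slope * params$pH
  out <- data.frame(xi = profile$xi, v_ox = profile$v_ox,
                    v_red = profile$v_red, h2 = profile$h2, o2 = profile$o2,
                    e_active = profile$e_active,
                    e_inactive = profile$e_inactive,
                    e_dead = profile$e_dead,
                    e_v_she = profile$e_v,
                    e_v_rhe = profile$e_v - e_eq)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# mediator: %s (E0 = %g V vs SHE)",
                       params$mediator$label, params$mediator$e0),
               sprintf("# pH: %g", params$pH),
               sprintf("# temperature_K: %g", params$temperature),
               "# units: concentrations mol m^-3, potentials V"), con)
  utils::write.table(format(out, digits = 10, scientific = TRUE,
                            trim = TRUE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
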