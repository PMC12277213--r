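# Parameter set: definition, defaults, provenance, file I/O, perturbation.
#
# Thirteen parameters are flagged source = "calibrated": the thermal-time
# anchors of ABA accumulation (ABA_m, ABA_e), the membrane-area coefficient
# (a_mem), the skin-permeability triple (rho_0, rho_min, k_p), the
# conductivity sensitivity (k_L), the turgor yield threshold (Y), and the
# sugar-uptake group (v_m, k_ABA, STP_m, STP_e) plus the ripening
# respiration coefficient (q_r). The packaged numeric values of these are
# a documented in-package calibration against the qualitative season
# dynamics the model is built to reproduce ("placeholder-calibrated");
# values flagged "literature" are standard magnitudes from the
# peach/grape biophysical fruit-model lineage.

param_registry <- function() {
  # name, section, default, units, source, lower, upper, description
  rows <- list(
    # --- ABA / phenology ------------------------------------------------
    list("ABA_0",   "aba",    0.10,    "ug g^-1 dry",  "literature",  0,      1,     "initial ABA concentration"),
    list("ABA_f",   "aba",    32.30,   "ug g^-1 dry",  "literature",  5,      60,    "final (peak) ABA concentration"),
    list("ABA_m",   "aba",    10000,    "K h",          "calibrated",  1000,   20000, "cGDH baseline triggering ABA accumulation"),
    list("ABA_e",   "aba",    22000,   "K h",          "calibrated",  4000,   40000, "cGDH equilibrium point (ABA peak abscissa)"),
    list("T_b",     "aba",    280.15,  "K",            "literature",  268.15, 288.15,"base temperature for growing degree hours"),
    list("T_o",     "aba",    303.15,  "K",            "literature",  293.15, 313.15,"optimal (capping) temperature for GDH"),
    # --- carbon flux ----------------------------------------------------
    list("v_m",     "carbon", 0.025,   "h^-1",         "calibrated",  0.002,  0.2,   "maximal active sugar transport rate per unit dry mass"),
    list("K_m",     "carbon", 0.08,    "mass fraction","literature",  0.01,   0.3,   "Michaelis-Menten constant for sugar transport"),
    list("t_star",  "carbon", 1250,    "h",            "literature",  200,    2000,  "inhibitor midpoint time"),
    list("tau",     "carbon", 150,     "h",            "literature",  10,     600,   "inhibitor time constant"),
    list("k_ABA",   "carbon", 1.6,     "-",            "calibrated",  0.2,    6,     "scaling factor of ABA-modulated sugar uptake"),
    list("STP_m",   "carbon", 0.12,    "-",            "calibrated",  0,      0.6,   "lower ABA_norm threshold for sugar uptake"),
    list("STP_e",   "carbon", 0.65,    "-",            "calibrated",  0.3,    1,     "upper ABA_norm threshold for sugar uptake"),
    list("q_g",     "carbon", 0.084,   "-",            "literature",  0,      0.5,   "growth respiration coefficient"),
    list("q_m_ref", "carbon", 3.5e-4,  "h^-1",         "literature",  0,      0.01,  "maintenance respiration coefficient at T_ref"),
    list("T_ref",   "carbon", 293.15,  "K",            "literature",  283.15, 303.15,"reference temperature for maintenance respiration"),
    list("Q10",     "carbon", 2.03,    "-",            "literature",  1,      4,     "respiration temperature quotient"),
    list("q_r",     "carbon", 0.01,    "mg h^-1",      "calibrated",  0,      1,     "ripening respiration coefficient (ABA signal)"),
    list("p_s",     "carbon", 10,      "cm h^-1",      "literature",  0,      200,   "membrane solute permeability for passive diffusion"),
    list("ssr",     "carbon", 0.60,    "-",            "literature",  0.2,    0.9,   "soluble-sugar fraction of dry mass"),
    # --- water flux -----------------------------------------------------
    list("L_max",   "water",  3.0,     "mg cm^-2 MPa^-1 h^-1", "literature", 0.1, 50, "maximal membrane hydraulic conductivity"),
    list("k_L",     "water",  0.8,     "-",            "calibrated",  0,      6,     "ABA sensitivity of hydraulic conductivity"),
    list("a_mem",   "water",  0.45,    "-",            "calibrated",  0.01,   2,     "fruit surface area to composite membrane area coefficient"),
    list("sigma_p", "water",  0.90,    "-",            "literature",  0,      1,     "phloem membrane reflection coefficient"),
    list("sigma_x", "water",  0.95,    "-",            "literature",  0,      1,     "xylem membrane reflection coefficient"),
    list("rho_min", "water",  15,      "cm h^-1",      "calibrated",  0,      200,   "minimum solute permeability of the fruit skin"),
    list("rho_0",   "water",  110,     "cm h^-1",      "calibrated",  0,      600,   "skin permeability scaling factor"),
    list("k_p",     "water",  3.0,     "-",            "calibrated",  0,      12,    "exponential decay rate of skin permeability vs ABA"),
    list("H_f",     "water",  0.996,   "fraction",     "literature",  0.9,    1,     "relative humidity of the fruit internal air space"),
    list("Y",       "water",  0.15,    "MPa",          "calibrated",  0,      1,     "yield-threshold turgor for Lockhart growth"),
    list("phi_max", "water",  0.04,   "MPa^-1 h^-1",  "literature",  1e-4,   0.5,   "maximal cell-wall extensibility"),
    list("t_phi",   "water",  900,     "h",            "literature",  100,    2000,  "extensibility decay midpoint"),
    list("s_phi",   "water",  250,     "h",            "literature",  10,     1000,  "extensibility decay scale"),
    list("c_area",  "water",  4.84,    "cm^2 g^-2/3",  "literature",  1,      20,    "fresh-mass to surface-area allometry coefficient"),
    list("osm_other","water", 1.0,    "MPa",          "literature",  0,      2,     "non-sugar osmotic contribution (acids, ions)"),
    list("rho_water","water", 1000,    "mg cm^-3",     "literature",  900,    1100,  "density of fruit water"),
    list("rho_dry", "water",  1600,    "mg cm^-3",     "literature",  1000,   2000,  "density of fruit dry matter"),
    # --- initial state --------------------------------------------------
    list("s_0",     "init",   5,       "mg",           "literature",  0.1,    100,   "initial dry mass at anthesis"),
    list("w_0",     "init",   45,      "mg",           "literature",  1,      500,   "initial water mass at anthesis")
  )
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r[[1]], section = r[[2]], default = r[[3]],
               units = r[[4]], source = r[[5]], lower = r[[6]],
               upper = r[[7]], description = r[[8]],
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- df$name
  df
}

#' Names of the calibrated parameters
#'
#' The thirteen parameters whose values are fitted rather than taken from
#' the literature; this is also the default perturbation list of the
#' one-at-a-time sensitivity analysis.
#'
#' @return Character vector of length 13.
#' @export
calibrated_parameter_names <- function() {
  reg <- param_registry()
  reg$name[reg$source == "calibrated"]
}

#' Packaged default parameter set
#'
#' @return A `parameter_set`: named list of values with a provenance
#'   registry attached.
#' @export
default_parameters <- function() {
  reg <- param_registry()
  values <- as.list(stats::setNames(reg$default, reg$name))
  new_parameter_set(values)
}

new_parameter_set <- function(values) {
  ps <- structure(values, class = "parameter_set")
  validate_parameters(ps)
  ps
}

#' Validate a parameter set against its structural invariants
#'
#' Checks non-negativity/bounds of individual values and the cross-
#' parameter constraints (ABA_0 < ABA_f, ABA_m < ABA_e, T_b < T_o,
#' STP_m < STP_e, reflection coefficients in \[0, 1\]).
#'
#' @param params A `parameter_set` or plain named list.
#' @return The validated `parameter_set`, invisibly.
#' @export
validate_parameters <- function(params) {
  reg <- param_registry()
  missing <- setdiff(reg$name, names(params))
  if (length(missing) > 0L) {
    stop(sprintf("parameter set: missing parameter(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  unknown <- setdiff(names(params), reg$name)
  if (length(unknown) > 0L) {
    stop(sprintf("parameter set: unknown parameter(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  p <- params
  check <- function(ok, msg) if (!ok) stop(paste0("parameter set: ", msg),
                                           call. = FALSE)
  for (nm in reg$name) {
    v <- p[[nm]]
    check(is.numeric(v) && length(v) == 1L && is.finite(v),
          sprintf("%s must be a finite scalar", nm))
  }
  nonneg <- setdiff(reg$name, c("s_0", "w_0"))
  for (nm in nonneg) check(p[[nm]] >= 0 || nm %in% c("T_b", "T_o", "T_ref"),
                           sprintf("%s must be >= 0", nm))
  check(p$ABA_0 >= 0 && p$ABA_0 < p$ABA_f, "needs 0 <= ABA_0 < ABA_f")
  check(p$ABA_m >= 0 && p$ABA_m < p$ABA_e, "needs 0 <= ABA_m < ABA_e (both named)")
  check(p$T_b < p$T_o, "needs T_b < T_o")
  check(p$STP_m >= 0 && p$STP_m < p$STP_e && p$STP_e <= 1,
        "needs 0 <= STP_m < STP_e <= 1 (both named)")
  check(p$tau > 0, "tau must be > 0")
  check(p$Q10 >= 1, "Q10 must be >= 1")
  check(p$sigma_p >= 0 && p$sigma_p <= 1, "sigma_p must lie in [0, 1]")
  check(p$sigma_x >= 0 && p$sigma_x <= 1, "sigma_x must lie in [0, 1]")
  check(p$H_f > 0 && p$H_f <= 1, "H_f must lie in (0, 1]")
  check(p$phi_max > 0, "phi_max must be > 0")
  check(p$s_phi > 0, "s_phi must be > 0")
  check(p$rho_water > 0 && p$rho_dry > 0, "densities must be > 0")
  check(p$s_0 > 0 && p$w_0 > 0, "initial masses s_0, w_0 must be > 0")
  invisible(structure(p, class = "parameter_set"))
}

#' Load a parameter file
#'
#' YAML file with sections `aba`, `carbon`, `water`, `init`; keys are
#' parameter names. Unknown keys are rejected; keys absent from the file
#' fall back to the packaged defaults (reported via a message).
#'
#' @param path Path to the YAML parameter file.
#' @param quiet Suppress the fallback message.
#' @return A validated `parameter_set`.
#' @export
load_parameters <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("load_parameters: file not found: %s", path), call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  reg <- param_registry()
  flat <- list()
  for (section in names(cfg)) {
    if (!section %in% unique(reg$section)) {
      stop(sprintf("load_parameters: unknown section '%s'", section),
           call. = FALSE)
    }
    for (key in names(cfg[[section]])) {
      if (!key %in% reg$name[reg$section == section]) {
        stop(sprintf("load_parameters: unknown key '%s' in section '%s'",
                     key, section), call. = FALSE)
      }
      flat[[key]] <- cfg[[section]][[key]]
    }
  }
  defaults <- default_parameters()
  absent <- setdiff(names(defaults), names(flat))
  if (length(absent) > 0L && !quiet) {
    message(sprintf("load_parameters: %d parameter(s) not in file, using packaged defaults: %s",
                    length(absent), paste(absent, collapse = ", ")))
  }
  merged <- utils::modifyList(unclass(defaults), flat)
  new_parameter_set(merged)
}

#' Save a parameter set to a YAML file
#'
#' Writes the canonical sectioned layout; `load_parameters()` of the
#' result reproduces the set (round-trip at 15 significant digits).
#'
#' @param params A `parameter_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_parameters <- function(params, path) {
  params <- validate_parameters(params)
  reg <- param_registry()
  out <- list()
  for (section in unique(reg$section)) {
    keys <- reg$name[reg$section == section]
    out[[section]] <- params[keys]
  }
  writeLines(yaml::as.yaml(out, precision = 15L), path)
  invisible(path)
}

#' Perturb one parameter by a relative amount
#'
#' Returns a copy of `params` with `value * (1 + rel_change)` for the
#' named parameter and everything else untouched. Cross-parameter
#' invariants are not re-enforced here: the one-at-a-time sensitivity
#' analysis must be able to nudge a parameter across a soft constraint.
#'
#' @param params A `parameter_set`.
#' @param name Parameter name.
#' @param rel_change Relative change (0.10 = +10 percent).
#' @return A `parameter_set`.
#' @export
perturb <- function(params, name, rel_change) {
  if (!name %in% names(params)) {
    stop(sprintf("perturb: unknown parameter '%s'", name), call. = FALSE)
  }
  params[[name]] <- params[[name]] * (1 + rel_change)
  params
}

#' Provenance table of a parameter set
#'
#' @param params A `parameter_set`; defaults to the packaged set.
#' @return Data frame with value, units, source, bounds and description
#'   per parameter.
#' @export
describe_parameters <- function(params = default_parameters()) {
  reg <- param_registry()
  data.frame(name = reg$name, section = reg$section,
             value = vapply(reg$name, function(nm) params[[nm]], numeric(1)),
             units = reg$units, source = reg$source,
             lower = reg$lower, upper = reg$upper,
             description = reg$description,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @export
print.parameter_set <- function(x, ...) {
  df <- describe_parameters(x)
  cat(sprintf("<parameter_set> %d parameters (%d calibrated)\n",
              nrow(df), sum(df$source == "calibrated")))
  print(df[, c("name", "value", "units", "source")], row.names = FALSE)
  invisible(x)
}
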