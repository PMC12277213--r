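# One-at-a-time local sensitivity analysis.

#' Normalised local sensitivity coefficient
#'
#' `S = 10 * (dW / W_base) / (dP / P)` in percent: the percentage change
#' of the output corresponding to a standardised +10 percent change of
#' the parameter. For the standard `rel_change = 0.10` this reduces to
#' `100 * (W_pert - W_base) / W_base`.
#'
#' @param W_base Baseline output (> 0).
#' @param W_pert Output under the perturbed parameter.
#' @param rel_change Relative parameter change used (non-zero).
#' @return Sensitivity coefficient, percent.
#' @export
sensitivity_coefficient <- function(W_base, W_pert, rel_change = 0.10) {
  if (any(W_base <= 0)) {
    stop("sensitivity_coefficient: W_base must be > 0", call. = FALSE)
  }
  if (any(rel_change == 0)) {
    stop("sensitivity_coefficient: rel_change must be non-zero", call. = FALSE)
  }
  10 * ((W_pert - W_base) / W_base) / rel_change
}

# Functional category of each calibrated parameter (six groups).
sensitivity_categories <- function() {
  c(ABA_m = "ABA accumulation", ABA_e = "ABA accumulation",
    a_mem = "composite membrane area",
    rho_0 = "fruit surface transpiration",
    rho_min = "fruit surface transpiration",
    k_p = "fruit surface transpiration",
    k_L = "hydraulic conductance", Y = "hydraulic conductance",
    v_m = "sugar uptake", k_ABA = "sugar uptake",
    STP_m = "sugar uptake", STP_e = "sugar uptake",
    q_r = "respiration")
}

#' One-at-a-time sensitivity analysis
#'
#' Perturbs each listed parameter by `rel_change` (default +10 percent),
#' re-runs the model, and reports the normalised sensitivity coefficient
#' of the final dry, water and fresh mass. The baseline run is computed
#' once; n parameters cost n + 1 simulations.
#'
#' @param weather A [weather_series()] (ignored when a custom `runner`
#'   is supplied that does not use it).
#' @param params Baseline `parameter_set`.
#' @param parameters Character vector of parameter names to perturb;
#'   defaults to the 13 calibrated parameters.
#' @param rel_change Relative perturbation; default 0.10.
#' @param runner Function `function(params) -> named numeric` returning
#'   the outputs to differentiate. The default runs [simulate_fruit()]
#'   and returns the final dry, water and fresh mass.
#' @param ... Passed to [simulate_fruit()] by the default runner.
#' @return A `sensitivity_result` data frame: parameter, category, and
#'   one coefficient column per output (percent). Failed perturbed runs
#'   yield NA coefficients with a warning rather than an error.
#' @export
sensitivity_analysis <- function(weather = NULL,
                                 params = default_parameters(),
                                 parameters = calibrated_parameter_names(),
                                 rel_change = 0.10,
                                 runner = NULL, ...) {
  if (is.null(runner)) {
    if (is.null(weather)) {
      stop("sensitivity_analysis: supply `weather` or a custom `runner`",
           call. = FALSE)
    }
    sim_args <- list(...)
    if (is.null(sim_args$warn_clamp)) sim_args$warn_clamp <- FALSE
    runner <- function(p) {
      r <- do.call(simulate_fruit, c(list(weather, p), sim_args))
      n <- nrow(r)
      c(dry = r$s[n], water = r$w[n], fresh = r$fresh[n])
    }
  }
  W_base <- runner(params)
  cats <- sensitivity_categories()
  rows <- lapply(parameters, function(nm) {
    coef <- tryCatch({
      W_pert <- runner(perturb(params, nm, rel_change))
      sensitivity_coefficient(W_base, W_pert, rel_change)
    }, error = function(e) {
      warning(sprintf("sensitivity_analysis: run for '%s' failed: %s",
                      nm, conditionMessage(e)), call. = FALSE)
      stats::setNames(rep(NA_real_, length(W_base)), names(W_base))
    })
    cbind(data.frame(parameter = nm,
                     category = if (nm %in% names(cats)) cats[[nm]] else "other",
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(coef)))
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    data.frame(parameter = character(), category = character())
  }
  attr(out, "rel_change") <- rel_change
  attr(out, "baseline") <- W_base
  class(out) <- c("sensitivity_result", "data.frame")
  out
}
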