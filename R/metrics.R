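# Goodness-of-fit metrics and pairing of observations with simulated
# trajectories.

#' Goodness-of-fit metrics
#'
#' Computes, for paired observed/predicted vectors: mean absolute error
#' (MAE), root mean square error (RMSE), RMSE normalised by the observed
#' range (NRMSE), Willmott's refined index of agreement (d_r) and the
#' Nash-Sutcliffe model efficiency (EF). d_r and EF approach 1 for a
#' perfect fit; EF = 0 marks mean-predictor skill.
#'
#' @param observed,predicted Numeric vectors of equal length >= 2.
#' @return A `fit_metrics` list: `MAE`, `RMSE`, `NRMSE`, `d_r`, `EF`, `n`.
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("fit_metrics: observed and predicted must have equal length",
         call. = FALSE)
  }
  n <- length(observed)
  if (n < 2L) stop("fit_metrics: needs >= 2 pairs", call. = FALSE)
  if (anyNA(observed) || anyNA(predicted)) {
    stop("fit_metrics: missing values are not allowed; filter pairs first",
         call. = FALSE)
  }
  err <- observed - predicted
  mae <- mean(abs(err))
  rmse <- sqrt(mean(err^2))
  y_range <- max(observed) - min(observed)
  if (y_range == 0) {
    stop("fit_metrics: zero observation range; NRMSE/EF/d_r undefined",
         call. = FALSE)
  }
  ybar <- mean(observed)
  sae <- sum(abs(err))
  sad <- sum(abs(observed - ybar))
  d_r <- if (sae <= 2 * sad) 1 - sae / (2 * sad) else 2 * sad / sae - 1
  ef <- 1 - sum(err^2) / sum((observed - ybar)^2)
  structure(list(MAE = mae, RMSE = rmse, NRMSE = rmse / y_range,
                 d_r = d_r, EF = ef, n = n),
            class = "fit_metrics")
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("MAE %.4g | RMSE %.4g | NRMSE %.3f | d_r %.3f | EF %.3f (n = %d)\n",
              x$MAE, x$RMSE, x$NRMSE, x$d_r, x$EF, x$n))
  invisible(x)
}

#' Read an observed fruit time series
#'
#' CSV with columns `daa` and any of `dry_mg`, `water_mg`, `fresh_mg`,
#' `aba_ug_per_g` (missing ABA cells allowed). ABA values below the
#' assay detection threshold are flagged as censored and excluded from
#' ABA pairing.
#'
#' @param path CSV file path.
#' @param detection_threshold ABA detection limit; values strictly below
#'   it are flagged censored. Default 10 ug g^-1 (0.01 ug per mg of dry
#'   mass).
#' @return Data frame of class `observation_series` with a logical
#'   `aba_censored` column.
#' @export
read_observations_csv <- function(path, detection_threshold = 10) {
  if (!file.exists(path)) {
    stop(sprintf("read_observations_csv: file not found: %s", path),
         call. = FALSE)
  }
  obs <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"daa" %in% names(obs)) {
    stop("read_observations_csv: column 'daa' is required", call. = FALSE)
  }
  observation_series(obs, detection_threshold = detection_threshold)
}

#' Construct an observation series
#'
#' @param df Data frame with `daa` (strictly increasing) and observation
#'   columns among `dry_mg`, `water_mg`, `fresh_mg`, `aba_ug_per_g`.
#' @param detection_threshold ABA censoring threshold, ug g^-1.
#' @return An `observation_series` data frame.
#' @export
observation_series <- function(df, detection_threshold = 10) {
  if (is.unsorted(df$daa, strictly = TRUE)) {
    stop("observation_series: daa must be strictly increasing", call. = FALSE)
  }
  for (v in intersect(c("dry_mg", "water_mg", "fresh_mg"), names(df))) {
    if (any(df[[v]] < 0, na.rm = TRUE)) {
      stop(sprintf("observation_series: negative mass in %s", v),
           call. = FALSE)
    }
  }
  if ("aba_ug_per_g" %in% names(df)) {
    df$aba_censored <- !is.na(df$aba_ug_per_g) &
      df$aba_ug_per_g < detection_threshold
  } else {
    df$aba_censored <- rep(FALSE, nrow(df))
  }
  class(df) <- c("observation_series", "data.frame")
  df
}

#' Pair observations with a simulated trajectory
#'
#' Each observation at day `daa` is matched to the simulated hour closest
#' to `daa * 24`. ABA observations flagged censored (below the detection
#' threshold) and missing cells are dropped from their variable's pairs.
#'
#' @param result A `simulation_result`.
#' @param obs An `observation_series`.
#' @param variable One of `"dry"`, `"water"`, `"fresh"`, `"aba"`.
#' @return Data frame with `daa`, `observed`, `predicted`.
#' @export
match_predictions <- function(result, obs, variable = "fresh") {
  variable <- match.arg(variable, c("dry", "water", "fresh", "aba"))
  obs_col <- c(dry = "dry_mg", water = "water_mg", fresh = "fresh_mg",
               aba = "aba_ug_per_g")[[variable]]
  sim_col <- c(dry = "s", water = "w", fresh = "fresh",
               aba = "ABA_conc")[[variable]]
  if (!obs_col %in% names(obs)) {
    stop(sprintf("match_predictions: observations lack column '%s'", obs_col),
         call. = FALSE)
  }
  target_h <- obs$daa * 24
  if (any(target_h < min(result$t) - 0.5 | target_h > max(result$t) + 0.5)) {
    bad <- which(target_h < min(result$t) - 0.5 | target_h > max(result$t) + 0.5)[1]
    stop(sprintf("match_predictions: observation at %g DAA lies outside the simulated span",
                 obs$daa[bad]), call. = FALSE)
  }
  idx <- vapply(target_h, function(h) which.min(abs(result$t - h)), integer(1))
  keep <- !is.na(obs[[obs_col]])
  if (variable == "aba") keep <- keep & !obs$aba_censored
  data.frame(daa = obs$daa[keep], observed = obs[[obs_col]][keep],
             predicted = result[[sim_col]][idx[keep]])
}

#' Evaluate a simulation against observations for several variables
#'
#' @param result A `simulation_result`.
#' @param obs An `observation_series`.
#' @param variables Variables to score.
#' @return Data frame, one row per variable, with the five fit metrics.
#' @export
evaluate_fit <- function(result, obs,
                         variables = c("dry", "water", "fresh")) {
  rows <- lapply(variables, function(v) {
    pairs <- match_predictions(result, obs, v)
    m <- fit_metrics(pairs$observed, pairs$predicted)
    data.frame(variable = v, MAE = m$MAE, RMSE = m$RMSE, NRMSE = m$NRMSE,
               d_r = m$d_r, EF = m$EF, n = m$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
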