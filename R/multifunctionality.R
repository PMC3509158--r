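# Multifunctionality indicators: function transformations, type-wise
# references (maximum = mean of the 3 highest values; mean), the
# proportion-above-threshold and mean-percentage-excess indicators, and
# pairwise jointness.

FUNCTION_KINDS <- c("wood", "forage", "cations", "infiltration")

#' Transform an ecosystem function prior to multifunctionality calculation
#'
#' The four functions are transformed to tame their probability
#' distributions before any indicator is computed: wood biomass by
#' \code{ln(x + 1)} (heavily grazed fallows produce little or no wood, so a
#' zero-safe log is used), forage biomass and steady infiltration rate by
#' square root, and soil base cations by arcsine square root of
#' \code{x / cations_scale} (cations are meq per 100 g, read against a scale
#' constant of 100).
#'
#' @param value Non-negative raw function value(s).
#' @param kind One of \code{"wood"}, \code{"forage"}, \code{"cations"},
#'   \code{"infiltration"}.
#' @param cations_scale Denominator mapping base cations into [0, 1] for the
#'   arcsine square root; default 100.
#' @return Transformed value(s).
#' @export
transform_function <- function(value, kind, cations_scale = 100) {
  kind <- match.arg(kind, FUNCTION_KINDS)
  check_numeric(value, "value", min = 0)
  switch(kind,
    wood = log(value + 1),
    forage = sqrt(value),
    infiltration = sqrt(value),
    cations = {
      if (any(value > cations_scale)) {
        stop_invalid("base cations exceed the arcsine scale constant ",
                     cations_scale)
      }
      asin(sqrt(value / cations_scale))
    }
  )
}

asin_sqrt_prop <- function(p) {
  check_numeric(p, "proportion", min = 0, max = 1)
  asin(sqrt(p))
}

#' Assemble per-plot function profiles
#'
#' Joins the four ecosystem-function indicators into one table with raw and
#' transformed scales.
#'
#' @param plots Plot metadata (\code{plot_id}, \code{fallow_type}, optionally
#'   \code{grazing_class}, \code{year}).
#' @param wood,forage Outputs of \code{\link{wood_biomass}} and
#'   \code{\link{forage_biomass}}; plots absent from the survey get 0.
#' @param soil Output of \code{\link{soil_functions}}.
#' @param cations_scale Passed to \code{\link{transform_function}}.
#' @return Data frame with columns \code{plot_id}, \code{fallow_type},
#'   raw \code{wood}, \code{forage}, \code{cations}, \code{infiltration} and
#'   transformed \code{wood_t}, \code{forage_t}, \code{cations_t},
#'   \code{infiltration_t}.
#' @export
function_profiles <- function(plots, wood, forage, soil, cations_scale = 100) {
  require_columns(plots, c("plot_id", "fallow_type"), "plot table")
  prof <- data.frame(plot_id = as.character(plots$plot_id),
                     fallow_type = as.character(plots$fallow_type),
                     stringsAsFactors = FALSE)
  pick <- function(df, col) {
    v <- df[[col]][match(prof$plot_id, df$plot_id)]
    ifelse(is.na(v), 0, v)
  }
  prof$wood <- pick(wood, "wood_t_ha")
  prof$forage <- pick(forage, "forage_t_ha")
  idx <- match(prof$plot_id, soil$plot_id)
  if (anyNA(idx)) {
    stop_missing_data("no soil functions for plot(s): ",
                      paste(prof$plot_id[is.na(idx)], collapse = ", "))
  }
  prof$cations <- soil$base_cations[idx]
  prof$infiltration <- soil$infiltration_mm_hr[idx]
  for (kind in FUNCTION_KINDS) {
    prof[[paste0(kind, "_t")]] <-
      transform_function(prof[[kind]], kind, cations_scale)
  }
  prof
}

#' Type-wise function references: maximum and mean
#'
#' For each fallow type and ecosystem function the reference maximum
#' \eqn{M_f} is the mean of the 3 highest transformed values in that type
#' (pooled over sampling years), and \eqn{\mu_f} is the mean of all
#' transformed values. Both are computed on the transformed scale, on which
#' all indicators operate.
#'
#' @param profiles Output of \code{\link{function_profiles}}.
#' @return Data frame (\code{fallow_type}, \code{fn}, \code{max3},
#'   \code{mean}).
#' @export
type_reference <- function(profiles) {
  out <- list()
  for (type in unique(profiles$fallow_type)) {
    sub <- profiles[profiles$fallow_type == type, , drop = FALSE]
    if (nrow(sub) < 3) {
      stop_invalid("need >= 3 plots of type '", type,
                   "' to define the mean-of-3-highest maximum")
    }
    for (kind in FUNCTION_KINDS) {
      x <- sub[[paste0(kind, "_t")]]
      m3 <- mean(sort(x, decreasing = TRUE)[1:3])
      if (m3 < mean(x)) {
        warning("degenerate sample: top-3 mean below the mean for ",
                kind, " in type ", type)
      }
      out[[length(out) + 1L]] <- data.frame(
        fallow_type = type, fn = kind, max3 = m3, mean = mean(x),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

reference_lookup <- function(reference, type, what) {
  sub <- reference[reference$fallow_type == type, , drop = FALSE]
  idx <- match(FUNCTION_KINDS, sub$fn)
  if (anyNA(idx)) stop_missing_data("no reference for fallow type '", type, "'")
  stats::setNames(sub[[what]][idx], FUNCTION_KINDS)
}

profile_values <- function(profiles, na_action) {
  x <- as.matrix(profiles[, paste0(FUNCTION_KINDS, "_t")])
  if (anyNA(x) && na_action == "error") {
    stop_missing_data("missing transformed function value(s); set ",
                      "na_action = 'adjust' to score over available functions")
  }
  x
}

#' Proportion of ecosystem functions above a threshold of maximum
#'
#' For each plot, the share of the four (transformed) functions at or above
#' \eqn{\tau \cdot M_f}, where \eqn{M_f} is the type-wise maximum (mean of
#' the 3 highest values). The boundary is inclusive. Also returns the
#' arcsine-square-root transform of the proportion used as the modelling
#' response.
#'
#' @param profiles Output of \code{\link{function_profiles}}.
#' @param reference Output of \code{\link{type_reference}}.
#' @param tau Threshold as a fraction of the maximum (0.25, 0.5 or 0.75 in
#'   the standard analysis; any value in (0, 1]).
#' @param na_action \code{"error"} (default) or \code{"adjust"}: adjust the
#'   denominator to the available functions (logged via warning).
#' @return Data frame (\code{plot_id}, \code{prop_above}, \code{prop_asin}).
#' @export
proportion_above <- function(profiles, reference, tau = 0.5,
                             na_action = c("error", "adjust")) {
  na_action <- match.arg(na_action)
  check_numeric(tau, "tau", min = 1e-12, max = 1)
  x <- profile_values(profiles, na_action)
  if (anyNA(x)) warning("scoring over available functions only")
  prop <- vapply(seq_len(nrow(x)), function(i) {
    m <- reference_lookup(reference, profiles$fallow_type[i], "max3")
    ok <- !is.na(x[i, ])
    sum(x[i, ok] >= tau * m[ok]) / sum(ok)
  }, numeric(1))
  data.frame(plot_id = profiles$plot_id, prop_above = prop,
             prop_asin = asin_sqrt_prop(prop), stringsAsFactors = FALSE)
}

#' Mean percentage excess above mean function values
#'
#' For each plot, the mean over the four functions of the percentage by
#' which its transformed value exceeds the type-wise mean:
#' \deqn{E = \frac{1}{4}\sum_f 100\,(x_f - \mu_f)/\mu_f.}
#' May be negative; averages to exactly zero over the plots that define the
#' means (an algebraic identity, which is why its type means print as 0.0).
#'
#' @inheritParams proportion_above
#' @return Data frame (\code{plot_id}, \code{mpe}).
#' @export
mean_percentage_excess <- function(profiles, reference,
                                   na_action = c("error", "adjust")) {
  na_action <- match.arg(na_action)
  x <- profile_values(profiles, na_action)
  mpe <- vapply(seq_len(nrow(x)), function(i) {
    mu <- reference_lookup(reference, profiles$fallow_type[i], "mean")
    if (any(mu <= 0)) {
      stop_invalid("degenerate (non-positive) transformed function mean; ",
                   "mean percentage excess undefined")
    }
    ok <- !is.na(x[i, ])
    mean(100 * (x[i, ok] - mu[ok]) / mu[ok])
  }, numeric(1))
  data.frame(plot_id = profiles$plot_id, mpe = mpe, stringsAsFactors = FALSE)
}

#' Both multifunctionality indicators at the standard thresholds
#'
#' @inheritParams proportion_above
#' @param thresholds Fractions of maximum for the threshold indicator.
#' @return Data frame per plot: \code{prop_above_<pct>} and
#'   \code{prop_asin_<pct>} for each threshold, plus \code{mpe}.
#' @export
multifunctionality_indicators <- function(profiles, reference = NULL,
                                          thresholds = c(0.25, 0.5, 0.75),
                                          na_action = c("error", "adjust")) {
  na_action <- match.arg(na_action)
  if (is.null(reference)) reference <- type_reference(profiles)
  out <- data.frame(plot_id = profiles$plot_id,
                    fallow_type = profiles$fallow_type,
                    stringsAsFactors = FALSE)
  for (tau in thresholds) {
    pa <- proportion_above(profiles, reference, tau, na_action)
    tag <- sprintf("%.0f", 100 * tau)
    out[[paste0("prop_above_", tag)]] <- pa$prop_above
    out[[paste0("prop_asin_", tag)]] <- pa$prop_asin
  }
  out$mpe <- mean_percentage_excess(profiles, reference, na_action)$mpe
  out
}

#' Pairwise jointness among ecosystem functions
#'
#' A plot exhibits jointness for a pair of functions when both transformed
#' values are at or above the threshold: 50\% of the type-wise maximum
#' (\code{mode = "half_max"}) or the type-wise mean
#' (\code{mode = "above_mean"}).
#'
#' @inheritParams proportion_above
#' @param mode \code{"half_max"} or \code{"above_mean"}.
#' @return Data frame (\code{fallow_type}, \code{fn_a}, \code{fn_b},
#'   \code{mode}, \code{count}, \code{n}, \code{proportion}) over the 6
#'   unordered pairs per type.
#' @export
jointness <- function(profiles, reference = NULL,
                      mode = c("half_max", "above_mean"),
                      na_action = c("error", "adjust")) {
  mode <- match.arg(mode)
  na_action <- match.arg(na_action)
  if (is.null(reference)) reference <- type_reference(profiles)
  x <- profile_values(profiles, na_action)
  pairs <- utils::combn(FUNCTION_KINDS, 2)
  out <- list()
  for (type in unique(profiles$fallow_type)) {
    rows <- profiles$fallow_type == type
    thr <- if (mode == "half_max") {
      0.5 * reference_lookup(reference, type, "max3")
    } else {
      reference_lookup(reference, type, "mean")
    }
    above <- sweep(x[rows, , drop = FALSE], 2, thr, `>=`)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      both <- above[, paste0(a, "_t")] & above[, paste0(b, "_t")]
      out[[length(out) + 1L]] <- data.frame(
        fallow_type = type, fn_a = a, fn_b = b, mode = mode,
        count = sum(both, na.rm = TRUE), n = sum(rows),
        proportion = sum(both, na.rm = TRUE) / sum(rows),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
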