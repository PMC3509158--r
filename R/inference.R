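# Statistical stage: OLS model comparison of multifunctionality indicators
# on diversity and environmental predictors, Pearson correlations with
# Fisher-z intervals, and one-way ANOVA between fallow types.

#' Fit a univariate or additive bivariate linear model
#'
#' Ordinary least squares of a multifunctionality indicator on one or two
#' predictors (no interaction terms). Reports per-coefficient estimates, t
#' statistics and two-sided P values on the error degrees of freedom, and
#' the total model R-squared adjusted for the number of parameters:
#' \deqn{R^2_{adj} = 1 - (1 - R^2)(n - 1)/(n - p - 1).}
#'
#' @param data Data frame holding response and predictors.
#' @param response Name of the response column.
#' @param predictors Character vector of 1 or 2 predictor columns.
#' @return A \code{model_fit}: list with \code{response}, \code{predictors},
#'   \code{intercept}, \code{coefficients} (data frame with
#'   \code{predictor}, \code{estimate}, \code{t}, \code{p}), \code{df}
#'   (model, error), \code{adj_r2}, \code{n}.
#' @export
fit_linear_model <- function(data, response, predictors) {
  if (length(predictors) < 1 || length(predictors) > 2) {
    stop_invalid("supply 1 or 2 predictors (additive, no interactions)")
  }
  require_columns(data, c(response, predictors), "model data")
  cols <- data[, c(response, predictors), drop = FALSE]
  if (anyNA(cols)) stop_missing_data("missing values in model variables")
  n <- nrow(cols)
  p <- length(predictors)
  if (n <= p + 1) stop_invalid("insufficient sample: n = ", n, " with ", p,
                               " predictor(s)")
  fml <- stats::reformulate(predictors, response)
  fit <- stats::lm(fml, data = data)
  if (fit$rank < p + 1) stop_invalid("collinear predictors: design is rank deficient")
  sm <- suppressWarnings(summary(fit))  # toy exact fits trip a summary.lm warning
  co <- sm$coefficients
  structure(list(
    response = response,
    predictors = predictors,
    intercept = co["(Intercept)", "Estimate"],
    coefficients = data.frame(
      predictor = predictors,
      estimate = co[predictors, "Estimate"],
      t = co[predictors, "t value"],
      p = co[predictors, "Pr(>|t|)"],
      row.names = NULL, stringsAsFactors = FALSE),
    df = c(model = p, error = n - p - 1L),
    adj_r2 = sm$adj.r.squared,
    n = n
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("%s ~ %s  (d.f. = %d,%d)\n", x$response,
              paste(x$predictors, collapse = " + "), x$df[1], x$df[2]))
  cat(sprintf("  intercept %.4g, adjusted R^2 = %.3f\n", x$intercept, x$adj_r2))
  for (i in seq_len(nrow(x$coefficients))) {
    cat(sprintf("  %-20s est %.4g  t %.3f  P %.4g\n",
                x$coefficients$predictor[i], x$coefficients$estimate[i],
                x$coefficients$t[i], x$coefficients$p[i]))
  }
  invisible(x)
}

#' Fisher-z confidence interval for a correlation coefficient
#'
#' \deqn{\mathrm{CI} = \tanh(\mathrm{atanh}(r) \pm 1.96/\sqrt{n - 3})}
#' at the 95\% level (the critical value scales with the level).
#'
#' @param r Pearson correlation.
#' @param n Sample size (>= 4).
#' @param level Confidence level.
#' @return List with \code{r}, \code{n}, \code{lo}, \code{hi}, \code{df}
#'   (1, n - 2).
#' @export
fisher_z_ci <- function(r, n, level = 0.95) {
  check_numeric(r, "r", min = -1, max = 1)
  if (n < 4) stop_invalid("need n >= 4 for a Fisher-z interval")
  zcrit <- if (identical(level, 0.95)) 1.96 else stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(r)
  half <- zcrit / sqrt(n - 3)
  list(r = r, n = n, lo = tanh(z - half), hi = tanh(z + half),
       df = c(model = 1L, error = as.integer(n) - 2L))
}

#' Pearson correlation with Fisher-z interval
#'
#' @param x,y Numeric vectors of equal length (n >= 4), no missing values.
#' @inheritParams fisher_z_ci
#' @return As \code{\link{fisher_z_ci}}.
#' @export
pearson_fisher_ci <- function(x, y, level = 0.95) {
  check_numeric(x, "x")
  check_numeric(y, "y")
  if (length(x) != length(y)) stop_invalid("x and y must have equal length")
  if (length(x) < 4) stop_invalid("need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_invalid("undefined correlation: zero variance")
  }
  fisher_z_ci(stats::cor(x, y), length(x), level)
}

#' One-way analysis of variance
#'
#' @param values Numeric response vector.
#' @param groups Group labels (>= 2 groups, each with >= 2 observations).
#' @return List with \code{F}, \code{df} (between, within), \code{p}.
#' @export
oneway_anova <- function(values, groups) {
  check_numeric(values, "values")
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop_invalid("need >= 2 groups")
  if (any(table(droplevels(groups)) < 2)) {
    stop_invalid("each group needs >= 2 observations")
  }
  fit <- stats::anova(stats::lm(values ~ groups))
  list(F = fit$`F value`[1],
       df = c(between = fit$Df[1], within = fit$Df[2]),
       p = fit$`Pr(>F)`[1])
}

#' The full model-comparison suite for one fallow type
#'
#' For each multifunctionality indicator (arcsine-square-root proportion
#' above half-maximum, and mean percentage excess) fits the univariate
#' models on functional diversity, species richness and soil carbon, plus
#' grazing intensity in grazed fallows, and the additive bivariate models
#' pairing each diversity variable with each environmental variable: 8
#' models per indicator for grazed fallows, 5 for improved (which are
#' ungrazed, so grazing intensity never enters). Soil carbon enters on the
#' fraction (g/g) scale; grazing intensity as the cover-class midpoint
#' proportion of its 5-point score.
#'
#' @param data Per-plot data frame with columns \code{prop_asin_50},
#'   \code{mpe}, \code{fd}, \code{richness}, \code{soc} and, for grazed
#'   fallows, \code{grazing}.
#' @param type \code{"grazed"} or \code{"improved"}.
#' @return Data frame, one row per model term, with model identification
#'   columns (\code{indicator}, \code{model}), \code{df_model},
#'   \code{df_error}, \code{intercept}, \code{predictor}, \code{estimate},
#'   \code{t}, \code{p}, \code{adj_r2}.
#' @export
run_model_suite <- function(data, type = c("grazed", "improved")) {
  type <- match.arg(type)
  diversity_vars <- c("fd", "richness")
  env_vars <- if (type == "grazed") c("soc", "grazing") else "soc"
  specs <- c(as.list(c(diversity_vars, env_vars)),
             unlist(lapply(diversity_vars,
                           function(d) lapply(env_vars, function(e) c(d, e))),
                    recursive = FALSE))
  rows <- list()
  for (indicator in c("prop_asin_50", "mpe")) {
    for (preds in specs) {
      fit <- fit_linear_model(data, indicator, preds)
      rows[[length(rows) + 1L]] <- data.frame(
        indicator = indicator,
        model = paste(preds, collapse = "+"),
        df_model = fit$df[["model"]], df_error = fit$df[["error"]],
        intercept = fit$intercept,
        predictor = fit$coefficients$predictor,
        estimate = fit$coefficients$estimate,
        t = fit$coefficients$t, p = fit$coefficients$p,
        adj_r2 = fit$adj_r2,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Diversity effect within one grazing-intensity class
#'
#' Univariate fit of an indicator on functional diversity restricted to the
#' plots of one grazing group. The moderately grazed group gives the most
#' meaningful within-group test of diversity effects: it is the largest
#' group and the one where diversity varies most.
#'
#' @param data Per-plot data frame with \code{grazing_group}, \code{fd} and
#'   the indicator column.
#' @param indicator Response column name.
#' @param group Grazing group label to keep.
#' @return A \code{\link{fit_linear_model}} result.
#' @export
grazing_subgroup_fit <- function(data, indicator = "prop_asin_50",
                                 group = "moderate") {
  sub <- data[!is.na(data$grazing_group) & data$grazing_group == group, ,
              drop = FALSE]
  if (nrow(sub) < 4) {
    stop_invalid("insufficient plots in grazing group '", group, "': ",
                 nrow(sub))
  }
  if (stats::sd(sub$fd) == 0 || stats::sd(sub[[indicator]]) == 0) {
    stop_invalid("zero variance within grazing group '", group, "'")
  }
  fit_linear_model(sub, indicator, "fd")
}
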