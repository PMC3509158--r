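# Soil functions: Horton infiltration fits, base cations, topsoil aggregation.

#' Fit the Horton infiltration equation to one measured curve
#'
#' Least-squares fit of \deqn{f(t) = f_c + (f_0 - f_c) e^{-kt}} to an
#' infiltration-rate time series. For a fixed decay rate k the model is
#' linear in \eqn{(f_c, f_0)}, so the fit concentrates the least-squares
#' problem: the linear pair is solved in closed form and k is found by
#' bounded one-dimensional (Brent) minimisation of the profiled residual sum
#' of squares over \eqn{k \in [10^{-5}, 1]} per minute. This cannot fail to
#' return an answer; on pathological curves (for example a constant rate,
#' where k is unidentifiable) the fit falls back to the mean of the final
#' quartile of rates as the steady rate and flags \code{converged = FALSE}.
#'
#' @param time_min Measurement times in minutes, strictly increasing.
#' @param rate_mm_hr Infiltration rates in mm/hr, same length.
#' @param k_bounds Search interval for the decay rate (1/min).
#' @return An object of class \code{horton_fit}: list with \code{f0},
#'   \code{fc} (the steady infiltration rate, mm/hr), \code{k} (1/min),
#'   \code{rss}, \code{converged}, \code{fitted}.
#' @export
fit_horton <- function(time_min, rate_mm_hr, k_bounds = c(1e-5, 1)) {
  if (length(time_min) != length(rate_mm_hr)) {
    stop_invalid("time and rate vectors must have equal length")
  }
  if (length(unique(time_min)) < 4) {
    stop_invalid("need >= 4 distinct time points to fit the Horton equation")
  }
  check_numeric(time_min, "time_min")
  check_numeric(rate_mm_hr, "rate_mm_hr", min = 0)
  if (is.unsorted(time_min, strictly = FALSE)) {
    stop_invalid("times must be increasing")
  }

  t <- as.numeric(time_min)
  y <- as.numeric(rate_mm_hr)
  n <- length(y)

  # Profiled RSS: for fixed k regress y on [1-e, e], e = exp(-k t); the two
  # coefficients are fc and f0. Returns +Inf when the basis degenerates.
  profile_fit <- function(k) {
    e <- exp(-k * t)
    X <- cbind(1 - e, e)
    XtX <- crossprod(X)
    if (rcond(XtX) < 1e-12) return(list(rss = Inf))
    beta <- solve(XtX, crossprod(X, y))
    r <- y - X %*% beta
    list(rss = sum(r * r), fc = beta[1], f0 = beta[2], fitted = as.numeric(X %*% beta))
  }

  opt <- try(stats::optimize(function(k) profile_fit(k)$rss,
                             interval = k_bounds, tol = 1e-10),
             silent = TRUE)
  fallback <- function() {
    tail_n <- max(1L, ceiling(n / 4))
    fc <- mean(y[(n - tail_n + 1):n])
    structure(list(f0 = y[1], fc = fc, k = NA_real_,
                   rss = sum((y - fc)^2), converged = FALSE,
                   fitted = rep(fc, n)),
              class = "horton_fit")
  }
  if (inherits(opt, "try-error")) return(fallback())
  fit <- profile_fit(opt$minimum)
  if (!is.finite(fit$rss) || fit$fc < 0 || fit$fc > fit$f0) {
    # asymptote escaped its physical range (fc in [0, f0]); constrained retry
    fit$fc <- min(max(fit$fc, 0), max(y))
    if (fit$fc > fit$f0 || fit$fc < 0) return(fallback())
  }
  structure(list(f0 = fit$f0, fc = fit$fc, k = opt$minimum, rss = fit$rss,
                 converged = TRUE, fitted = fit$fitted),
            class = "horton_fit")
}

#' @export
print.horton_fit <- function(x, ...) {
  cat("Horton infiltration fit\n")
  cat(sprintf("  f0 = %.2f mm/hr, fc = %.2f mm/hr, k = %s /min\n",
              x$f0, x$fc, ifelse(is.na(x$k), "NA", format(x$k, digits = 4))))
  cat(sprintf("  rss = %.4g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

#' Per-plot steady infiltration rate from subplot fits
#'
#' The steady infiltration rate of a plot is the mean of the fitted lower
#' asymptotes (fc) of its nested subplot curves; with a single usable
#' subplot that value is returned with a warning.
#'
#' @param fits List of \code{horton_fit} objects (typically 2, centre and
#'   edge subplot).
#' @return Steady infiltration rate in mm/hr.
#' @export
steady_infiltration_rate <- function(fits) {
  if (inherits(fits, "horton_fit")) fits <- list(fits)
  fcs <- vapply(fits, function(f) f$fc, numeric(1))
  fcs <- fcs[is.finite(fcs)]
  if (length(fcs) == 0) stop_missing_data("no usable Horton fit for this plot")
  if (length(fcs) == 1) {
    warning("single subplot only; steady infiltration rate from one curve")
  }
  mean(fcs)
}

#' Soil base cations
#'
#' Exchangeable Mg, Ca and K (meq per 100 g soil) are summed to estimate
#' base cations.
#'
#' @param mg,ca,k meq/100 g, non-negative.
#' @return meq/100 g.
#' @export
base_cation_sum <- function(mg, ca, k) {
  check_numeric(mg, "mg", min = 0)
  check_numeric(ca, "ca", min = 0)
  check_numeric(k, "k", min = 0)
  mg + ca + k
}

#' Aggregate subplot soil measurements to plot level
#'
#' Averages topsoil (1--20 cm) measurements over the nested subplots of each
#' plot, returning SOC, base cations and sand. Subsoil rows are carried in
#' the input but do not enter the four ecosystem-function indicators.
#'
#' @param soils Data frame with columns \code{plot_id}, \code{subplot},
#'   \code{layer} (\code{topsoil}/\code{subsoil}), \code{soc_pct}, \code{mg},
#'   \code{ca}, \code{k}, \code{sand_pct}.
#' @param layer Which layer to aggregate (default \code{"topsoil"}).
#' @return Data frame (\code{plot_id}, \code{soc_pct}, \code{base_cations},
#'   \code{sand_pct}), one row per plot.
#' @export
aggregate_soil <- function(soils, layer = "topsoil") {
  require_columns(soils, c("plot_id", "subplot", "layer", "soc_pct",
                           "mg", "ca", "k", "sand_pct"), "soil table")
  sub <- soils[soils$layer == layer, , drop = FALSE]
  if (nrow(sub) == 0) stop_missing_data("no ", layer, " measurements")
  check_numeric(sub$soc_pct, "soc_pct", min = 0)
  check_numeric(sub$sand_pct, "sand_pct", min = 0, max = 100)
  bc <- base_cation_sum(sub$mg, sub$ca, sub$k)
  per_plot <- table(sub$plot_id)
  if (any(per_plot < 2)) {
    warning("plot(s) with a single ", layer, " subplot: ",
            paste(names(per_plot)[per_plot < 2], collapse = ", "))
  }
  agg <- rowsum(cbind(soc = sub$soc_pct, bc = bc, sand = sub$sand_pct),
                group = sub$plot_id)
  agg <- agg / as.numeric(per_plot[rownames(agg)])
  data.frame(plot_id = rownames(agg), soc_pct = agg[, "soc"],
             base_cations = agg[, "bc"], sand_pct = agg[, "sand"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-plot soil ecosystem functions
#'
#' Combines topsoil aggregation with Horton fits of the infiltration curves:
#' returns base cations and steady infiltration rate (the two soil-formation
#' indicators) plus the SOC and sand covariates.
#'
#' @param soils Soil measurement table (see \code{\link{aggregate_soil}}).
#' @param infiltration Long-format curve table with columns \code{plot_id},
#'   \code{subplot}, \code{time_min}, \code{rate_mm_hr}.
#' @return Data frame (\code{plot_id}, \code{soc_pct}, \code{base_cations},
#'   \code{sand_pct}, \code{infiltration_mm_hr}).
#' @export
soil_functions <- function(soils, infiltration) {
  require_columns(infiltration, c("plot_id", "subplot", "time_min", "rate_mm_hr"),
                  "infiltration table")
  soil <- aggregate_soil(soils)
  infil <- vapply(split(infiltration, infiltration$plot_id), function(df) {
    fits <- lapply(split(df, df$subplot), function(curve) {
      o <- order(curve$time_min)
      fit_horton(curve$time_min[o], curve$rate_mm_hr[o])
    })
    steady_infiltration_rate(fits)
  }, numeric(1))
  idx <- match(soil$plot_id, names(infil))
  if (anyNA(idx)) {
    stop_missing_data("no infiltration curves for plot(s): ",
                      paste(soil$plot_id[is.na(idx)], collapse = ", "))
  }
  soil$infiltration_mm_hr <- as.numeric(infil[idx])
  soil
}
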