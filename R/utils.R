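#' @keywords internal
"_PACKAGE"

# Run code with a temporarily seeded RNG, restoring the caller's stream.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("fallowfun_invalid_argument", "error")))
}

stop_missing_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("fallowfun_missing_data", "error")))
}

stop_missing_trait <- function(species) {
  stop(errorCondition(
    paste0("trait table has no row for species: ", paste(species, collapse = ", ")),
    class = c("fallowfun_missing_trait", "fallowfun_missing_data", "error")
  ))
}

check_numeric <- function(x, name, min = -Inf, max = Inf, allow_na = FALSE) {
  if (!is.numeric(x)) stop_invalid(name, " must be numeric")
  if (!allow_na && anyNA(x)) stop_invalid(name, " contains missing values")
  ok <- is.na(x) | (x >= min & x <= max)
  if (!all(ok)) {
    stop_invalid(name, " must lie in [", min, ", ", max, "]; offending value ",
                 format(x[!ok][1]))
  }
  invisible(x)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_invalid(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}
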