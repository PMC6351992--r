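#' Linear value-set creation-time model
#'
#' Creating a value set in a terminology-management tool costs a fixed
#' setup time plus a roughly constant time per concept added, so
#' creation time is modelled as `minutes = intercept + slope *
#' n_concepts`. `time_model()` builds a model from known coefficients;
#' [fit_time_model()] estimates them from timing observations.
#'
#' `default_time_model()` returns the model shipped with the package,
#' fitted to keyboard-time measurements of value-set construction:
#' 0.4177 min per concept on top of an obligate 3.8707 min (just under
#' 4 minutes of fixed setup, then about 25 seconds per concept).
#'
#' @param slope Minutes per concept.
#' @param intercept Fixed minutes per value set.
#' @return An object of class `time_model`.
#' @seealso [predict_time()], [time_comparison()]
#' @export
time_model <- function(slope, intercept) {
  stopifnot(is.numeric(slope), is.numeric(intercept),
            length(slope) == 1, length(intercept) == 1)
  structure(list(slope = slope, intercept = intercept, fit = NULL),
            class = "time_model")
}

#' @rdname time_model
#' @export
default_time_model <- function() time_model(0.4177, 3.8707)

#' @export
print.time_model <- function(x, ...) {
  cat(sprintf("<time_model: minutes = %.4f * n_concepts + %.4f%s>\n",
              x$slope, x$intercept,
              if (!is.null(x$fit)) sprintf(", fitted to %d observations",
                                           stats::nobs(x$fit)) else ""))
  invisible(x)
}

#' Fit the creation-time model by ordinary least squares
#'
#' @param observations A data frame with columns `n_concepts` and
#'   `minutes` (one row per timed value-set build); a `measured` column,
#'   if present, is ignored here — filtering measured vs estimated rows
#'   is the caller's choice.
#' @return A `time_model` whose `fit` element is the underlying
#'   [stats::lm] object (so [tidy()] and [glance()] work on it).
#' @examples
#' obs <- data.frame(n_concepts = c(0, 10), minutes = c(4, 8))
#' fit_time_model(obs)  # slope 0.4, intercept 4
#' @export
fit_time_model <- function(observations) {
  observations <- as_tibble(observations)
  if (!all(c("n_concepts", "minutes") %in% names(observations))) {
    abort("timing observations need columns n_concepts and minutes",
          class = "phenovset_format_error")
  }
  if (any(observations$n_concepts < 0) || any(observations$minutes < 0)) {
    abort("n_concepts and minutes must be non-negative",
          class = "phenovset_validation_error")
  }
  if (nrow(observations) < 2 || length(unique(observations$n_concepts)) < 2) {
    abort("need at least 2 observations with at least 2 distinct n_concepts",
          class = "phenovset_validation_error")
  }
  fit <- lm(minutes ~ n_concepts, data = observations)
  out <- time_model(unname(coef(fit)["n_concepts"]),
                    unname(coef(fit)["(Intercept)"]))
  out$fit <- fit
  out
}

#' Predict value-set creation time
#'
#' @param model A `time_model`.
#' @param n_concepts Non-negative concept counts (vectorised).
#' @return A tibble with `n_concepts`, `minutes` (unrounded) and
#'   `minutes_rounded` (nearest whole minute, half away from zero).
#' @examples
#' predict_time(default_time_model(), c(0, 233, 441))
#' @export
predict_time <- function(model, n_concepts) {
  stopifnot(inherits(model, "time_model"))
  if (any(n_concepts < 0)) {
    abort("n_concepts must be non-negative", class = "phenovset_validation_error")
  }
  minutes <- model$slope * n_concepts + model$intercept
  tibble(n_concepts = n_concepts, minutes = minutes,
         minutes_rounded = round_half_up(minutes))
}

#' Compare extensional versus intensional creation time
#'
#' @param ext_minutes,int_minutes Creation times in minutes (vectorised;
#'   `int_minutes` must be positive). Pass unrounded values where
#'   available — differencing rounded minutes compounds rounding error.
#' @return A tibble with `difference` (minutes) and `ratio`
#'   (dimensionless, 1 decimal).
#' @examples
#' time_comparison(15.15, 3.1)
#' @export
time_comparison <- function(ext_minutes, int_minutes) {
  if (any(int_minutes <= 0)) {
    abort("intensional creation time must be positive",
          class = "phenovset_undefined_ratio")
  }
  tibble(difference = ext_minutes - int_minutes,
         ratio = round_half_up(ext_minutes / int_minutes, 1))
}

#' @exportS3Method generics::tidy
tidy.time_model <- function(x, ...) {
  if (!is.null(x$fit)) {
    s <- summary(x$fit)$coefficients
    tibble(
      term = c("intercept", "slope"),
      estimate = c(x$intercept, x$slope),
      std.error = unname(s[c("(Intercept)", "n_concepts"), "Std. Error"]),
      statistic = unname(s[c("(Intercept)", "n_concepts"), "t value"]),
      p.value = unname(s[c("(Intercept)", "n_concepts"), "Pr(>|t|)"])
    )
  } else {
    tibble(term = c("intercept", "slope"),
           estimate = c(x$intercept, x$slope))
  }
}

#' @exportS3Method generics::glance
glance.time_model <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble(r.squared = NA_real_, sigma = NA_real_, nobs = NA_integer_))
  }
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, sigma = s$sigma,
         nobs = stats::nobs(x$fit))
}

#' @param object,x A `time_model`.
#' @param ... Passed on / unused.
#' @rdname time_model
#' @exportS3Method ggplot2::autoplot
autoplot.time_model <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(object$fit)) {
    p <- p + ggplot2::geom_point(
      data = object$fit$model,
      ggplot2::aes(x = .data$n_concepts, y = .data$minutes)
    )
  }
  p +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Concepts in value set", y = "Creation time (min)",
                  title = sprintf("minutes = %.4f x concepts + %.4f",
                                  object$slope, object$intercept)) +
    ggplot2::theme_minimal()
}

#' Read timing observations
#'
#' TSV with columns `label`, `n_concepts`, `minutes`, `measured`
#' (0/1): one row per value-set build, `measured = 1` for stopwatch
#' times, 0 for times estimated from the model.
#'
#' @param path Path to the TSV.
#' @return A tibble with those columns (`measured` as logical).
#' @export
read_timing_observations <- function(path) {
  df <- read_tsv_strict(path, c("label", "n_concepts", "minutes", "measured"))
  tibble(
    label = df$label,
    n_concepts = as.integer(df$n_concepts),
    minutes = as.numeric(df$minutes),
    measured = as.integer(df$measured) == 1L
  )
}
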