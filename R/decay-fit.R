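#' Fit a decay model to a biomolecule age profile
#'
#' The central estimator: biomolecule content (or gene copy number) Y against
#' sediment age X is modelled as
#' \itemize{
#'   \item power: \eqn{Y = a \cdot X^b}, fitted by ordinary least squares on
#'     (log X, log Y).  The negative exponent \eqn{k = -b} is the apparent
#'     first-order decay constant and declines in effect with age, so
#'     half-lives grow linearly with age (see [half_life()]).
#'   \item exponential: \eqn{Y = a \cdot e^{bX}}, OLS on (X, log Y).
#'   \item linear: \eqn{Y = a + bX}, OLS on (X, Y).
#' }
#' Multiplicative lognormal error is the natural noise model for contents and
#' copy numbers spanning orders of magnitude, hence the default log-space
#' power fit; a raw-space nonlinear least-squares refinement is available via
#' `method = "nls"` for sensitivity analysis.
#'
#' Zero or negative values (non-detects) cannot enter a log fit: with
#' `zero_policy = "exclude"` (default) they are dropped and counted in
#' `n_excluded`; with `"pseudo"` zero values are replaced by half the smallest
#' positive value of the series.  Ages `<= 0` (surface layer) are always
#' excluded from power fits.
#'
#' A constant series is reported as slope 0 with `r_squared = 0` and
#' `p_slope = 1` (no evidence of decay).
#'
#' @param series An [analyte_series()].
#' @param model `"power"`, `"exponential"`, or `"linear"`.
#' @param log_base Base of the logarithm used for the fitted space (slope,
#'   R-squared and p are base-invariant; the amplitude is back-transformed
#'   accordingly).
#' @param min_points Minimum number of usable points (default 3).
#' @param zero_policy `"exclude"` or `"pseudo"`; see Details.
#' @param method `"ols"` (default) or `"nls"` (power model only): raw-space
#'   nonlinear least squares started from the OLS solution.
#' @return Object of class `"decay_fit"`: amplitude `a`, slope/exponent `b`,
#'   `decay_constant` (`-b`, power model only, `NA` otherwise), `r_squared`
#'   and two-sided slope p-value in the fitted space, `n_points`,
#'   `n_excluded`, and the reliability flag of [flag_fit()].
#' @seealso [fit_power()], [compare_models()], [half_life()]
#' @examples
#' s <- analyte_series(c(1, 10, 100), c(100, 10, 1), "x")
#' f <- fit_power(s)
#' coef(f)                  # a = 100, b = -1
#' predict(f, age = 50)
#' @export
fit_decay <- function(series,
                      model = c("power", "exponential", "linear"),
                      log_base = exp(1), min_points = 3L,
                      zero_policy = c("exclude", "pseudo"),
                      method = c("ols", "nls")) {
  stopifnot(is_analyte_series(series))
  model <- match.arg(model)
  zero_policy <- match.arg(zero_policy)
  method <- match.arg(method)
  pts <- series$points
  age <- pts$age
  value <- pts$value

  if (model %in% c("power", "exponential") && zero_policy == "pseudo" &&
      any(value == 0) && any(value > 0)) {
    value[value == 0] <- min(value[value > 0]) / 2
  }
  usable <- switch(model,
    power = age > 0 & value > 0,
    exponential = value > 0,
    linear = rep(TRUE, length(age))
  )
  n_excluded <- sum(!usable)
  x_raw <- age[usable]
  y_raw <- value[usable]
  n <- length(x_raw)
  if (n < min_points) {
    stop(sprintf("insufficient data: %d usable point(s) for %s fit (need %d)",
                 n, model, min_points))
  }
  x <- if (model == "power") log(x_raw, base = log_base) else x_raw
  y <- if (model == "linear") y_raw else log(y_raw, base = log_base)
  if (isTRUE(all.equal(stats::var(x), 0)) || stats::var(x) == 0) {
    stop("ages must vary among usable points")
  }

  if (stats::var(y) == 0) {
    slope <- 0
    intercept <- y[1L]
    r2 <- 0
    p <- 1
    sigma <- 0
    resid <- rep(0, n)
  } else {
    fit <- lm(y ~ x)
    sf <- suppressWarnings(summary(fit))  # noiseless input: "perfect fit"
    cf <- sf$coefficients
    slope <- cf["x", "Estimate"]
    intercept <- cf["(Intercept)", "Estimate"]
    p <- cf["x", "Pr(>|t|)"]
    if (is.nan(p)) p <- if (slope == 0) 1 else 0  # exact fit: zero residual SE
    r2 <- sf$r.squared
    sigma <- sf$sigma
    resid <- stats::residuals(fit)
  }
  amplitude <- if (model == "linear") intercept else log_base^intercept

  if (method == "nls" && model == "power") {
    nl <- tryCatch(
      stats::nls(y_raw ~ a * x_raw^b, start = list(a = amplitude, b = slope)),
      error = function(e) NULL)
    if (!is.null(nl)) {
      amplitude <- coef(nl)[["a"]]
      slope <- coef(nl)[["b"]]
      p <- summary(nl)$coefficients["b", "Pr(>|t|)"]
      r2 <- 1 - sum(stats::residuals(nl)^2) / sum((y_raw - mean(y_raw))^2)
      resid <- stats::residuals(nl)
      sigma <- sqrt(sum(resid^2) / max(1, n - 2))
    }
  }

  out <- structure(
    list(
      model = model,
      amplitude = unname(amplitude),
      exponent = unname(slope),
      decay_constant = if (model == "power") -unname(slope) else NA_real_,
      r_squared = unname(r2),
      p_slope = unname(p),
      n_points = n,
      n_excluded = n_excluded,
      sigma = unname(sigma),
      log_base = log_base,
      method = method,
      analyte_id = series$analyte_id,
      organism_group = series$organism_group,
      compound_class = series$compound_class,
      units = series$units,
      station_id = series$station_id,
      lake_id = series$lake_id,
      data = data.frame(age = x_raw, value = y_raw),
      residuals = unname(resid)
    ),
    class = "decay_fit"
  )
  out$flagged <- flag_fit(out)
  out
}

#' Convenience wrappers for the three decay models
#'
#' `fit_power()`, `fit_exponential()` and `fit_linear()` call [fit_decay()]
#' with the corresponding model.
#'
#' @param series An [analyte_series()].
#' @param ... Passed to [fit_decay()].
#' @return A `"decay_fit"` object.
#' @export
fit_power <- function(series, ...) fit_decay(series, model = "power", ...)

#' @rdname fit_power
#' @export
fit_exponential <- function(series, ...) {
  fit_decay(series, model = "exponential", ...)
}

#' @rdname fit_power
#' @export
fit_linear <- function(series, ...) fit_decay(series, model = "linear", ...)

#' Reliability flag for a decay fit
#'
#' A fit is flagged as unreliable when its slope is nonsignificant
#' (`p_slope > 0.05`) and/or its coefficient of determination is low
#' (`r_squared < 0.2`); both inequalities are strict, so boundary values are
#' not flagged.  Flagged half-life rows are conventionally marked with an
#' asterisk.
#'
#' @param fit A `"decay_fit"` object, or any list with elements `p_slope`
#'   and `r_squared`.
#' @param alpha Significance level (default 0.05).
#' @param min_r_squared Minimum R-squared (default 0.2).
#' @return Logical.
#' @export
flag_fit <- function(fit, alpha = 0.05, min_r_squared = 0.2) {
  stopifnot(!is.null(fit$p_slope), !is.null(fit$r_squared))
  isTRUE(fit$p_slope > alpha) || isTRUE(fit$r_squared < min_r_squared)
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> %s model for %s\n", x$model,
              x$analyte_id))
  eq <- switch(x$model,
    power = sprintf("Y = %.4g * t^%.4g   (decay constant k = %.4g)",
                    x$amplitude, x$exponent, x$decay_constant),
    exponential = sprintf("Y = %.4g * exp(%.4g t)", x$amplitude, x$exponent),
    linear = sprintf("Y = %.4g + %.4g t", x$amplitude, x$exponent))
  cat(" ", eq, "\n")
  cat(sprintf("  R^2 = %.3f, slope p = %.3g, n = %d (%d excluded)%s\n",
              x$r_squared, x$p_slope, x$n_points, x$n_excluded,
              if (x$flagged) "  [flagged]" else ""))
  invisible(x)
}

#' @export
summary.decay_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  analyte: %s (%s, %s)%s\n", object$analyte_id,
              object$organism_group, object$compound_class,
              if (nzchar(object$units)) paste0(" [", object$units, "]") else ""))
  if (nzchar(object$lake_id) || nzchar(object$station_id)) {
    cat(sprintf("  lake: %s, station: %s\n",
                object$lake_id, object$station_id))
  }
  cat(sprintf("  residual SD in fitted space: %.4g\n", object$sigma))
  invisible(object)
}

#' @export
coef.decay_fit <- function(object, ...) {
  c(amplitude = object$amplitude, exponent = object$exponent)
}

#' Predicted content at given sediment ages
#'
#' @param object A `"decay_fit"`.
#' @param age Ages (years) at which to predict; defaults to the fitted ages.
#' @param ... Unused.
#' @return Predicted contents on the raw response scale.
#' @export
predict.decay_fit <- function(object, age = NULL, ...) {
  age <- age %||% object$data$age
  a <- object$amplitude
  b <- object$exponent
  switch(object$model,
    power = a * age^b,
    exponential = a * exp(b * age),
    linear = a + b * age)
}

#' @export
residuals.decay_fit <- function(object, type = c("fitted_space", "response"),
                                ...) {
  type <- match.arg(type)
  if (type == "fitted_space") return(object$residuals)
  object$data$value - predict(object)
}

#' Simulate replicate profiles from a fitted decay model
#'
#' Draws new series from the fitted curve with the fit's residual standard
#' deviation: multiplicative lognormal noise for power/exponential fits,
#' additive Gaussian noise for linear fits.
#'
#' @param object A `"decay_fit"`.
#' @param nsim Number of replicate series.
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @param ... Unused.
#' @return A list of `nsim` [analyte_series()] objects.
#' @export
simulate.decay_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- predict(object)
  n <- length(mu)
  with_seed(seed, {
    lapply(seq_len(nsim), function(i) {
      val <- if (object$model == "linear") {
        pmax(0, mu + rnorm(n, 0, object$sigma))
      } else {
        mu * object$log_base^rnorm(n, 0, object$sigma)
      }
      analyte_series(object$data$age, val, object$analyte_id,
                     organism_group = object$organism_group,
                     compound_class = object$compound_class,
                     units = object$units, station_id = object$station_id,
                     lake_id = object$lake_id)
    })
  })
}

#' @export
plot.decay_fit <- function(x, n_curve = 100, ...) {
  logaxes <- if (x$model == "power") "xy" else if (x$model == "exponential") "y" else ""
  plot(x$data$age, x$data$value, log = logaxes,
       xlab = "sediment age (y)",
       ylab = if (nzchar(x$units)) x$units else "content",
       main = sprintf("%s (%s fit)", x$analyte_id, x$model), ...)
  rng <- range(x$data$age)
  grid_age <- if (x$model == "power") {
    exp(seq(log(rng[1]), log(rng[2]), length.out = n_curve))
  } else {
    seq(rng[1], rng[2], length.out = n_curve)
  }
  lines(grid_age, predict(x, grid_age), col = "red3")
  invisible(x)
}

#' @export
as.data.frame.decay_fit <- function(x, ...) {
  data.frame(
    lake = x$lake_id, station = x$station_id, analyte = x$analyte_id,
    organism_group = x$organism_group, compound_class = x$compound_class,
    units = x$units, model = x$model, amplitude = x$amplitude,
    exponent = x$exponent, decay_constant = x$decay_constant,
    r_squared = x$r_squared, p_slope = x$p_slope,
    n_points = as.integer(x$n_points), n_excluded = as.integer(x$n_excluded),
    flagged = x$flagged, stringsAsFactors = FALSE
  )
}

#' Rank the three decay models for one series
#'
#' Fits power, exponential and linear models where possible and ranks them by
#' R-squared in their respective fitted spaces.  Ties are broken by preferring
#' power, then exponential, then linear (the power model is the mechanistic
#' default for organic-matter decay whose apparent reactivity declines with
#' age).
#'
#' @param series An [analyte_series()].
#' @param ... Passed to [fit_decay()].
#' @return Object of class `"decay_model_comparison"`: list with the fitted
#'   models (`fits`), a ranking table (`table`), and the `best` model label.
#' @export
compare_models <- function(series, ...) {
  models <- c("power", "exponential", "linear")
  fits <- list()
  for (m in models) {
    f <- tryCatch(fit_decay(series, model = m, ...), error = function(e) NULL)
    if (!is.null(f)) fits[[m]] <- f
  }
  if (!length(fits)) stop("no decay model could be fitted to this series")
  r2 <- vapply(fits, `[[`, numeric(1), "r_squared")
  pref <- match(names(fits), models)
  o <- order(-r2, pref)
  tab <- data.frame(model = names(fits)[o], r_squared = unname(r2[o]),
                    stringsAsFactors = FALSE)
  structure(list(fits = fits[o], table = tab, best = tab$model[1L]),
            class = "decay_model_comparison")
}

#' @export
print.decay_model_comparison <- function(x, ...) {
  cat("<decay_model_comparison> best model:", x$best, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
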