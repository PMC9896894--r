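#' Age-dependent half-life under power-law decay
#'
#' Under \eqn{Y = a t^{-k}} the apparent reactivity of the remaining pool
#' declines with age, so half-lives are not constant but grow linearly with
#' sediment age.  Two formulas are offered:
#' \describe{
#'   \item{`exact_halving` (default)}{the exact halving time, i.e. the
#'     \eqn{\Delta} solving \eqn{(t+\Delta)^{-k} = t^{-k}/2}:
#'     \eqn{\Delta = t (2^{1/k} - 1)}.}
#'   \item{`instantaneous_rate`}{half-life of the instantaneous first-order
#'     rate \eqn{k/t}: \eqn{\Delta = \ln(2)\, t / k}.}
#' }
#' Both are linear in `age`, which is why tabulated half-life schedules scale
#' proportionally across age columns.
#'
#' @param k Decay constant (`k = -b` of the power fit), `> 0` for decay.
#' @param age Sediment age(s) in years, `> 0`.
#' @param formula `"exact_halving"` or `"instantaneous_rate"`.
#' @return Half-life in years (vectorised over `age` and `k`); `Inf` with a
#'   warning for `k <= 0` (no decay).
#' @examples
#' half_life(1, 10)                       # 10 y
#' half_life(2, 100)                      # 100 * (sqrt(2) - 1)
#' @export
half_life <- function(k, age, formula = c("exact_halving",
                                          "instantaneous_rate")) {
  formula <- match.arg(formula)
  if (any(age <= 0)) stop("`age` must be positive")
  out <- switch(formula,
    exact_halving = age * (2^(1 / k) - 1),
    instantaneous_rate = log(2) * age / k)
  if (any(k <= 0)) {
    warning("k <= 0: no decay, half-life is infinite")
    out[rep_len(k <= 0, length(out))] <- Inf
  }
  out
}

#' Calibrate a decay constant from the half-life at age 1 year
#'
#' Inverts the chosen half-life formula at age 1, so
#' `half_life(calibrate_k_from_h1(h1), 1)` returns `h1` exactly.  Used to
#' reproduce tabulated half-life schedules whose underlying decay constants
#' are not printed: the age-1 column pins down `k`, and linearity in age then
#' fixes every other column.
#'
#' @param h1 Half-life at sediment age 1 year (`> 0`).
#' @param formula As in [half_life()].
#' @return The decay constant `k`.
#' @examples
#' k <- calibrate_k_from_h1(0.77)
#' half_life(k, 100)   # 77 y
#' @export
calibrate_k_from_h1 <- function(h1, formula = c("exact_halving",
                                                "instantaneous_rate")) {
  formula <- match.arg(formula)
  if (any(h1 <= 0)) stop("`h1` must be positive")
  switch(formula,
    exact_halving = log(2) / log1p(h1),
    instantaneous_rate = log(2) / h1)
}

#' Half-life schedule over a grid of sediment ages
#'
#' Evaluates the age-dependent half-life at a standard grid of sediment ages
#' (default 1, 20, 50, 100, 200, 500, 1000 years), producing one row of a
#' half-life table.
#'
#' @param k Decay constant; alternatively supply `h1` to calibrate `k` first.
#' @param h1 Optional half-life at age 1 y (used if `k` is missing).
#' @param ages Age grid in years.
#' @param formula As in [half_life()].
#' @param label Row label (e.g. the analyte name).
#' @return Object of class `"half_life_schedule"`: list with `label`, `k`,
#'   `ages`, `half_lives`, `formula`.
#' @examples
#' half_life_schedule(h1 = 2.82, label = "fatty acid C20:5n-3")
#' @export
half_life_schedule <- function(k = NULL, h1 = NULL,
                               ages = c(1, 20, 50, 100, 200, 500, 1000),
                               formula = c("exact_halving",
                                           "instantaneous_rate"),
                               label = "") {
  formula <- match.arg(formula)
  if (is.null(k)) {
    if (is.null(h1)) stop("supply either `k` or `h1`")
    k <- calibrate_k_from_h1(h1, formula)
  }
  if (any(ages <= 0)) stop("`ages` must be positive")
  structure(
    list(label = label, k = k, ages = ages,
         half_lives = half_life(k, ages, formula), formula = formula),
    class = "half_life_schedule"
  )
}

#' @export
print.half_life_schedule <- function(x, ...) {
  cat(sprintf("<half_life_schedule> %s (k = %.4g, %s)\n",
              if (nzchar(x$label)) x$label else "unnamed", x$k, x$formula))
  df <- rbind(age = x$ages, half_life = signif(x$half_lives, 4))
  colnames(df) <- rep("", ncol(df))
  print(df)
  invisible(x)
}

#' @export
as.data.frame.half_life_schedule <- function(x, ...) {
  out <- as.data.frame(as.list(setNames(x$half_lives,
                                        paste0("age_", x$ages))))
  cbind(data.frame(label = x$label, k = x$k, formula = x$formula,
                   stringsAsFactors = FALSE), out)
}

#' Assemble a half-life table from several fits or calibrations
#'
#' @param x A list of `"decay_fit"` objects (power fits; their `k` and labels
#'   are used) or a named numeric vector of age-1 half-lives to calibrate.
#' @param ... Passed to [half_life_schedule()].
#' @return Data frame with one schedule row per entry (flagged fits get an
#'   asterisk appended to their label).
#' @export
half_life_table <- function(x, ...) {
  rows <- if (is.numeric(x)) {
    lapply(seq_along(x), function(i) {
      half_life_schedule(h1 = x[[i]], label = names(x)[i] %||% "", ...)
    })
  } else {
    lapply(x, function(f) {
      stopifnot(inherits(f, "decay_fit"))
      if (f$model != "power") stop("half-life table needs power fits")
      lab <- paste0(f$analyte_id, if (isTRUE(f$flagged)) "*" else "")
      half_life_schedule(k = f$decay_constant, label = lab, ...)
    })
  }
  do.call(rbind, lapply(rows, as.data.frame))
}
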