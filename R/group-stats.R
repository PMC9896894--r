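#' Two-sided Wilcoxon rank-sum test with exact small-sample enumeration
#'
#' Group sizes in decay-constant contrasts are tiny (3 stations per lake, 5
#' lakes), so p-values must be exact: with no ties and `n_x + n_y <= 12` the
#' test enumerates all rank assignments of size `n_x`; with ties it uses
#' mid-ranks and a seeded label-permutation p; for larger samples it falls
#' back to the normal approximation with continuity and tie correction.
#' The statistic reported is the Mann-Whitney U of `x`.
#'
#' @param x,y Numeric samples.
#' @param n_permutations Permutations for the tied small-sample path.
#' @param seed Optional integer seed for the permutation path (RNG state is
#'   restored afterwards).
#' @param exact_max Largest `n_x + n_y` for which full enumeration is used.
#' @param alpha Significance level for the `significant` field.
#' @param label_a,label_b Optional group labels carried into the result.
#' @return Object of class `"pairwise_test"`: `statistic` (U), two-sided
#'   `p_value`, `method`, sample sizes, `significant`, `adjustment`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p_value   # exact 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, n_permutations = 10000, seed = NULL,
                              exact_max = 12L, alpha = 0.05,
                              label_a = "x", label_b = "y") {
  x <- as.numeric(x[!is.na(x)])
  y <- as.numeric(y[!is.na(y)])
  m <- length(x)
  n <- length(y)
  if (m < 1L || n < 1L) stop("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  center <- m * n / 2
  ties <- anyDuplicated(pooled) > 0L
  eps <- sqrt(.Machine$double.eps)

  if (!ties && m + n <= exact_max) {
    # full enumeration: U of a subset S of ranks {1..N} is sum(S) - m(m+1)/2
    sets <- combn(m + n, m)
    u_all <- colSums(matrix(seq_len(m + n)[sets], nrow = m)) - m * (m + 1) / 2
    p <- mean(abs(u_all - center) >= abs(u_obs - center) - eps)
    method <- "exact enumeration"
  } else if (ties && m + n <= exact_max) {
    p <- with_seed(seed, {
      hits <- 0L
      for (i in seq_len(n_permutations)) {
        rp <- sample(r)
        u_star <- sum(rp[seq_len(m)]) - m * (m + 1) / 2
        if (abs(u_star - center) >= abs(u_obs - center) - eps) hits <- hits + 1L
      }
      (1 + hits) / (n_permutations + 1)
    })
    method <- sprintf("mid-rank permutation (%d draws)", n_permutations)
  } else {
    N <- m + n
    tie_tab <- table(pooled)
    sigma2 <- m * n / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
    z <- (abs(u_obs - center) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-max(0, z)))
    method <- "normal approximation with continuity correction"
  }
  structure(
    list(label_a = label_a, label_b = label_b, statistic = u_obs,
         p_value = p, n_a = m, n_b = n, method = method,
         significant = p < alpha, alpha = alpha, adjustment = "none"),
    class = "pairwise_test"
  )
}

#' @export
print.pairwise_test <- function(x, ...) {
  cat(sprintf("<pairwise_test> %s vs %s: U = %g, p = %.4g%s  [%s]\n",
              x$label_a, x$label_b, x$statistic, x$p_value,
              if (x$significant) " *" else "", x$method))
  invisible(x)
}

#' All pairwise Wilcoxon contrasts between groups of decay constants
#'
#' Tests every unordered pair of groups.  The default reports raw p-values
#' (`adjustment = "none"`); Holm correction is available.
#'
#' @param values Numeric vector of decay constants, or a named list of
#'   per-group numeric vectors (then `groups` is ignored).
#' @param groups Group label for each element of `values`.
#' @param adjustment `"none"` or `"holm"`.
#' @param alpha Significance level.
#' @param ... Passed to [wilcoxon_rank_sum()] (e.g. `seed`).
#' @return Data frame of class `"pairwise_contrasts"` with columns
#'   `label_a, label_b, statistic, p_value, p_adjusted, significant`.
#' @export
pairwise_contrasts <- function(values, groups = NULL,
                               adjustment = c("none", "holm"),
                               alpha = 0.05, ...) {
  adjustment <- match.arg(adjustment)
  if (is.list(values)) {
    split_vals <- values
    if (is.null(names(split_vals))) {
      names(split_vals) <- paste0("group", seq_along(split_vals))
    }
  } else {
    stopifnot(length(values) == length(groups))
    split_vals <- split(as.numeric(values), groups)
  }
  sizes <- lengths(split_vals)
  small <- names(split_vals)[sizes < 2L]
  if (length(small)) {
    warning("skipping group(s) with < 2 members: ",
            paste(small, collapse = ", "))
    split_vals <- split_vals[sizes >= 2L]
  }
  if (length(split_vals) < 2L) stop("need at least 2 groups with >= 2 members")
  pairs <- combn(names(split_vals), 2L)
  tests <- lapply(seq_len(ncol(pairs)), function(j) {
    wilcoxon_rank_sum(split_vals[[pairs[1L, j]]], split_vals[[pairs[2L, j]]],
                      label_a = pairs[1L, j], label_b = pairs[2L, j],
                      alpha = alpha, ...)
  })
  p_raw <- vapply(tests, `[[`, numeric(1), "p_value")
  p_adj <- if (adjustment == "holm") p.adjust(p_raw, "holm") else p_raw
  out <- data.frame(
    label_a = pairs[1L, ], label_b = pairs[2L, ],
    statistic = vapply(tests, `[[`, numeric(1), "statistic"),
    p_value = p_raw, p_adjusted = p_adj,
    significant = p_adj < alpha, stringsAsFactors = FALSE
  )
  attr(out, "adjustment") <- adjustment
  attr(out, "alpha") <- alpha
  class(out) <- c("pairwise_contrasts", "data.frame")
  out
}

#' Average decay constants by group
#'
#' Mirrors the convention of reporting a biomolecule's decay constant as the
#' arithmetic mean (with sample SD) of per-station or per-lake power-fit
#' exponents.  Only power-model fits contribute.  Groups whose contents did
#' not decrease over time (mean decay constant `<= 0`) are reported as
#' not applicable (`NA` mean and SD, `applicable = FALSE`).  A single-fit
#' group gets SD 0 and `n_fits = 1`.
#'
#' @param fits List of `"decay_fit"` objects.
#' @param by Field used for grouping: `"analyte_id"` (default),
#'   `"organism_group"`, `"compound_class"`, `"lake_id"`, or a vector of
#'   custom labels (one per fit).
#' @return Data frame of class `"decay_summary"` with columns `label, mean_k,
#'   sd_k, n_fits, applicable`; the member fits of each group are attached as
#'   attribute `"member_fits"`.
#' @export
summarize_decay <- function(fits, by = "analyte_id") {
  if (inherits(fits, "decay_fit")) fits <- list(fits)
  is_power <- vapply(fits, function(f) f$model == "power", logical(1))
  labels <- if (length(by) == 1L && is.character(by) &&
                by %in% c("analyte_id", "organism_group", "compound_class",
                          "lake_id", "station_id")) {
    vapply(fits, `[[`, character(1), by)
  } else {
    stopifnot(length(by) == length(fits))
    as.character(by)
  }
  fits <- fits[is_power]
  labels <- labels[is_power]
  if (!length(fits)) stop("no power-model fits to summarise")
  groups <- split(fits, labels)
  rows <- lapply(names(groups), function(g) {
    k <- vapply(groups[[g]], `[[`, numeric(1), "decay_constant")
    applicable <- mean(k) > 0
    data.frame(
      label = g,
      mean_k = if (applicable) mean(k) else NA_real_,
      sd_k = if (!applicable) NA_real_ else if (length(k) > 1L) sd(k) else 0,
      n_fits = length(k),
      applicable = applicable,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "member_fits") <- groups
  class(out) <- c("decay_summary", "data.frame")
  out
}

#' @export
print.decay_summary <- function(x, ...) {
  cat("<decay_summary> mean decay constants (power fits)\n")
  shown <- as.data.frame(x)
  shown$mean_k <- ifelse(shown$applicable, signif(shown$mean_k, 4), NA)
  shown$note <- ifelse(!shown$applicable, "na (no decrease)",
                       ifelse(shown$n_fits == 1L, "n = 1", ""))
  print(shown[, c("label", "mean_k", "sd_k", "n_fits", "note")],
        row.names = FALSE)
  invisible(x)
}

#' Pearson correlation between two biomolecule series
#'
#' Contents and copy numbers span orders of magnitude, so both variables are
#' log10-transformed by default before correlating; pairs with nonpositive
#' values are then dropped with a warning.
#'
#' @param x,y Paired numeric observations (`n >= 3` complete pairs).
#' @param log_transform Log10-transform both variables first (default TRUE).
#' @return List with `r`, `p_value` (two-sided, t distribution), `n`,
#'   and `log_transform`.
#' @export
pearson_correlation <- function(x, y, log_transform = TRUE) {
  stopifnot(length(x) == length(y))
  ok <- complete.cases(x, y)
  x <- as.numeric(x[ok])
  y <- as.numeric(y[ok])
  if (log_transform) {
    pos <- x > 0 & y > 0
    if (!all(pos)) {
      warning(sprintf("dropping %d pair(s) with nonpositive values before log10",
                      sum(!pos)))
    }
    x <- log10(x[pos])
    y <- log10(y[pos])
  }
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance in x or y")
  }
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       log_transform = log_transform)
}
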