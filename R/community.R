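#' Sample-by-taxon community table with group assignments
#'
#' Holds an amplicon (e.g. 18S rRNA gene) ZOTU/taxon count matrix together
#' with a taxon-to-group map (diatoms, green algae, vascular plants, other),
#' optional per-sample metadata (lake, depth, age, trophic state at
#' deposition), and optional per-sample total gene copy numbers from qPCR.
#'
#' @param counts Nonnegative sample-by-taxon count matrix with dimnames.
#' @param taxon_groups Named character vector mapping every taxon (column) to
#'   exactly one group.
#' @param total_copies Optional named numeric vector of total gene copies per
#'   g dry sediment, names matching sample ids.
#' @param sample_data Optional data frame of per-sample metadata; either with
#'   rownames matching sample ids or a `sample` column.
#' @return Object of class `"community_table"`.
#' @export
community_table <- function(counts, taxon_groups, total_copies = NULL,
                            sample_data = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("`counts` must have sample rownames and taxon colnames")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  miss <- setdiff(colnames(counts), names(taxon_groups))
  if (length(miss)) {
    stop("taxa without group assignment: ", paste(miss, collapse = ", "))
  }
  taxon_groups <- taxon_groups[colnames(counts)]
  if (!is.null(total_copies)) {
    if (is.null(names(total_copies))) {
      stop("`total_copies` must be named by sample")
    }
    if (any(total_copies < 0, na.rm = TRUE)) {
      stop("total_copies must be nonnegative")
    }
  }
  if (!is.null(sample_data)) {
    if ("sample" %in% names(sample_data)) {
      rownames(sample_data) <- sample_data$sample
    }
    sample_data <- sample_data[rownames(counts), , drop = FALSE]
  }
  structure(
    list(counts = counts, taxon_groups = taxon_groups,
         total_copies = total_copies, sample_data = sample_data),
    class = "community_table"
  )
}

#' @export
print.community_table <- function(x, ...) {
  cat(sprintf("<community_table> %d samples x %d taxa (%d groups)%s\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$taxon_groups)),
              if (is.null(x$total_copies)) "" else ", with total copies"))
  invisible(x)
}

get_counts <- function(x) {
  if (inherits(x, "community_table")) x$counts else as.matrix(x)
}

#' Per-sample relative abundances
#'
#' Divides each sample row by its total read count.  Samples with zero reads
#' are excluded with a warning.
#'
#' @param x A [community_table()] or a count matrix.
#' @return Matrix of fractions; each retained row sums to 1.
#' @export
relative_abundances <- function(x) {
  counts <- get_counts(x)
  rs <- rowSums(counts)
  empty <- rs == 0
  if (any(empty)) {
    warning("excluding empty sample row(s): ",
            paste(rownames(counts)[empty], collapse = ", "))
    counts <- counts[!empty, , drop = FALSE]
    rs <- rs[!empty]
  }
  sweep(counts, 1L, rs, "/")
}

#' Group-level read fractions
#'
#' Collapses taxa to their assigned groups, then normalises per sample.
#'
#' @param x A [community_table()].
#' @return Sample-by-group matrix of fractions.
#' @export
group_fractions <- function(x) {
  stopifnot(inherits(x, "community_table"))
  groups <- unique(x$taxon_groups)
  collapsed <- vapply(groups, function(g) {
    rowSums(x$counts[, x$taxon_groups == g, drop = FALSE])
  }, numeric(nrow(x$counts)))
  if (is.null(dim(collapsed))) {
    collapsed <- matrix(collapsed, nrow = 1,
                        dimnames = list(rownames(x$counts), groups))
  }
  relative_abundances(collapsed)
}

#' Partition total gene copies into group-wise absolute abundances
#'
#' Multiplies group-specific relative abundances by the per-sample total gene
#' copy number, converting compositional read fractions into absolute
#' copy-number estimates per group (the cross-check used to corroborate
#' marker-gene decay constants).  Summing the estimates over groups recovers
#' the total by construction.
#'
#' @param fractions Sample-by-group fraction matrix (e.g. from
#'   [group_fractions()]), or a [community_table()] carrying `total_copies`
#'   (then `totals` may be omitted).
#' @param totals Named numeric vector of per-sample totals.
#' @return Sample-by-group matrix of estimated copies per g dry sediment.
#'   Samples without a total are skipped with a warning.
#' @export
partition_total_abundance <- function(fractions, totals = NULL) {
  if (inherits(fractions, "community_table")) {
    totals <- totals %||% fractions$total_copies
    if (is.null(totals)) stop("community table carries no total_copies")
    fractions <- group_fractions(fractions)
  }
  fractions <- as.matrix(fractions)
  if (any(fractions < 0 | fractions > 1)) {
    stop("fractions must lie in [0, 1]")
  }
  have <- rownames(fractions) %in% names(totals)
  if (!all(have)) {
    warning("skipping sample(s) without totals: ",
            paste(rownames(fractions)[!have], collapse = ", "))
    fractions <- fractions[have, , drop = FALSE]
  }
  fractions * totals[rownames(fractions)]
}

#' Bray-Curtis dissimilarity between samples
#'
#' Computed on per-sample relative abundances (so it is invariant to read
#' depth), via `vegan::vegdist`.
#'
#' @param x A [community_table()] or count matrix (`>= 2` samples).
#' @return Symmetric sample-by-sample matrix with zero diagonal, values in
#'   \[0, 1\].
#' @export
bray_curtis <- function(x) {
  ra <- relative_abundances(x)
  if (nrow(ra) < 2L) stop("need at least 2 non-empty samples")
  as.matrix(vegan::vegdist(ra, method = "bray"))
}

anosim_r <- function(rank_vec, between, denom) {
  (mean(rank_vec[between]) - mean(rank_vec[!between])) / denom
}

# all permutations of 1..n (n small), one per column
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- matrix(0L, n, n * ncol(sub))
  col <- 0L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    for (j in seq_len(ncol(sub))) {
      col <- col + 1L
      out[, col] <- c(i, rest[sub[, j]])
    }
  }
  out
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group dissimilarities:
#' \eqn{R = (\bar r_B - \bar r_W) / (M/2)} with \eqn{M = N(N-1)/2} ranked
#' dissimilarities, so \eqn{R \in [-1, 1]}.  The p-value is
#' `(1 + #(permuted R >= observed R)) / (n_permutations + 1)` under seeded
#' random relabellings, or exact over all label permutations when
#' `exhaustive = TRUE` (feasible for small N).
#'
#' @param d Dissimilarity matrix (or `dist`), e.g. from [bray_curtis()].
#' @param grouping Group label per sample (`>= 2` groups, each with `>= 2`
#'   samples).
#' @param n_permutations Number of random permutations (default 999).
#' @param seed Optional integer seed (RNG state restored afterwards).
#' @param exhaustive Enumerate all `N!` label permutations instead of
#'   sampling (N <= 8).
#' @return Object of class `"anosim_test"`: `r_statistic`, `p_value`,
#'   `n_permutations`, `seed`.
#' @export
anosim <- function(d, grouping, n_permutations = 999, seed = NULL,
                   exhaustive = FALSE) {
  d <- as.matrix(d)
  N <- nrow(d)
  grouping <- as.character(grouping)
  stopifnot(length(grouping) == N)
  tab <- table(grouping)
  if (length(tab) < 2L) stop("need at least 2 groups")
  if (any(tab < 2L)) {
    stop("group(s) with a single sample: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  }
  idx <- which(lower.tri(d), arr.ind = TRUE)
  rv <- rank(d[lower.tri(d)])
  denom <- N * (N - 1) / 4
  obs_between <- grouping[idx[, 1L]] != grouping[idx[, 2L]]
  r_obs <- anosim_r(rv, obs_between, denom)
  eps <- sqrt(.Machine$double.eps)
  if (exhaustive) {
    if (N > 8L) stop("exhaustive enumeration limited to N <= 8")
    perms <- all_perms(N)
    r_all <- vapply(seq_len(ncol(perms)), function(j) {
      g <- grouping[perms[, j]]
      anosim_r(rv, g[idx[, 1L]] != g[idx[, 2L]], denom)
    }, numeric(1))
    p <- mean(r_all >= r_obs - eps)
    n_used <- ncol(perms)
  } else {
    hits <- with_seed(seed, {
      h <- 0L
      for (i in seq_len(n_permutations)) {
        g <- sample(grouping)
        if (anosim_r(rv, g[idx[, 1L]] != g[idx[, 2L]], denom) >= r_obs - eps) {
          h <- h + 1L
        }
      }
      h
    })
    p <- (1 + hits) / (n_permutations + 1)
    n_used <- n_permutations
  }
  structure(
    list(r_statistic = r_obs, p_value = p, n_permutations = n_used,
         seed = seed, exhaustive = exhaustive),
    class = "anosim_test"
  )
}

#' @export
print.anosim_test <- function(x, ...) {
  cat(sprintf("<anosim_test> R = %.4f, p = %.4g (%s%d permutations)\n",
              x$r_statistic, x$p_value,
              if (x$exhaustive) "exhaustive, " else "", x$n_permutations))
  invisible(x)
}

#' Regress a taxon's read fraction on sediment age
#'
#' Simple OLS of fraction on age with a two-sided slope t-test; used to ask
#' whether a taxon's relative contribution drifts with time.  A constant
#' fraction is reported as slope 0, `r_squared = 0`, `p = 1`.
#'
#' @param fraction Per-sample fractions (`n >= 3`).
#' @param age Matching sediment ages; must vary.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
fraction_vs_age_regression <- function(fraction, age) {
  ok <- complete.cases(fraction, age)
  fraction <- as.numeric(fraction[ok])
  age <- as.numeric(age[ok])
  if (length(age) < 3L) stop("need at least 3 points")
  if (stats::var(age) == 0) stop("zero variance in age")
  if (stats::var(fraction) == 0) {
    return(list(slope = 0, intercept = fraction[1L], r_squared = 0,
                p_value = 1, n = length(age)))
  }
  fit <- lm(fraction ~ age)
  sf <- suppressWarnings(summary(fit))  # noiseless input: "perfect fit"
  cf <- sf$coefficients
  p <- cf["age", "Pr(>|t|)"]
  list(slope = cf["age", "Estimate"],
       intercept = cf["(Intercept)", "Estimate"],
       r_squared = sf$r.squared,
       p_value = if (is.nan(p)) 0 else p,
       n = length(age))
}
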