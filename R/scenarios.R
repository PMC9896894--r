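#' Classify the preservation scenario supported by a group's decay constants
#'
#' Operationalises a three-way framework for what controls biomolecule
#' degradation in sediments, applied per organism group to station- or
#' lake-level power-fit decay constants:
#' \enumerate{
#'   \item \strong{adsorption/complexation}: DNA is chemically identical
#'     across organisms, so if electrostatic adsorption or complexation
#'     controlled its degradation, DNA decay constants should not differ
#'     between groups.  Rule: all cross-group DNA contrasts nonsignificant.
#'   \item \strong{chemical reactivity}: labile DNA degrades faster than the
#'     group's chemically resistant compounds (lipids, macromolecules).
#'     Rule: within-group DNA-vs-resistant contrast significant with DNA
#'     decaying faster.
#'   \item \strong{biotic exclusion} (physical shielding, e.g. by algaenan-
#'     or lignin-rich cell walls): DNA decays no faster than the resistant
#'     compounds even though DNA decay differs across groups.  Rule:
#'     within-group contrast nonsignificant while some cross-group DNA
#'     contrast is significant.
#' }
#' Rules are evaluated in this order with two-sided exact Wilcoxon rank-sum
#' tests at level `alpha`; anything else is `indeterminate`.  This decision
#' rule is an explicit operationalisation of a narrative argument; note that
#' rule (iii) reads failure to reject as similarity, which conflates low
#' power with equality, so calls based on group sizes below 4 carry a
#' `low_power` warning field in the result.
#'
#' @param k_dna Decay constants of the group's DNA marker (length `>= 2`).
#' @param k_resistant Decay constants of the group's resistant compounds
#'   (length `>= 2`); `NULL`/empty yields an indeterminate call.
#' @param k_dna_other_groups Named list of DNA decay-constant vectors for the
#'   other organism groups.
#' @param alpha Significance level (default 0.05).
#' @param organism_group Label carried into the call.
#' @return Object of class `"scenario_call"`: `scenario`, `evidence` (a data
#'   frame of the tests run), `reason`, `alpha`, `low_power`.
#' @export
classify_group <- function(k_dna, k_resistant, k_dna_other_groups,
                           alpha = 0.05, organism_group = "group") {
  k_dna <- as.numeric(k_dna)
  if (length(k_dna) < 2L) stop("`k_dna` needs at least 2 values")
  stopifnot(is.list(k_dna_other_groups), length(k_dna_other_groups) >= 1L)
  if (is.null(names(k_dna_other_groups))) {
    names(k_dna_other_groups) <- paste0("other", seq_along(k_dna_other_groups))
  }

  ev <- list()
  cross_p <- numeric(0)
  for (g in names(k_dna_other_groups)) {
    t <- wilcoxon_rank_sum(k_dna, as.numeric(k_dna_other_groups[[g]]),
                           alpha = alpha,
                           label_a = paste0(organism_group, "_DNA"),
                           label_b = paste0(g, "_DNA"))
    cross_p[g] <- t$p_value
    ev[[length(ev) + 1L]] <- data.frame(
      comparison = "cross_group_DNA", label_a = t$label_a,
      label_b = t$label_b, n_a = t$n_a, n_b = t$n_b,
      statistic = t$statistic, p_value = t$p_value,
      significant = t$significant, stringsAsFactors = FALSE)
  }

  have_resistant <- !is.null(k_resistant) && length(k_resistant) >= 2L
  within_sig <- NA
  dna_faster <- NA
  if (have_resistant) {
    k_resistant <- as.numeric(k_resistant)
    t <- wilcoxon_rank_sum(k_dna, k_resistant, alpha = alpha,
                           label_a = paste0(organism_group, "_DNA"),
                           label_b = paste0(organism_group, "_resistant"))
    within_sig <- t$significant
    dna_faster <- median(k_dna) > median(k_resistant)
    ev[[length(ev) + 1L]] <- data.frame(
      comparison = "within_group_DNA_vs_resistant", label_a = t$label_a,
      label_b = t$label_b, n_a = t$n_a, n_b = t$n_b,
      statistic = t$statistic, p_value = t$p_value,
      significant = t$significant, stringsAsFactors = FALSE)
  }
  evidence <- do.call(rbind, ev)
  cross_differs <- any(cross_p <= alpha)

  if (!cross_differs) {
    scenario <- "adsorption_complexation"
    reason <- "DNA decay constants do not differ across organism groups"
  } else if (!have_resistant) {
    scenario <- "indeterminate"
    reason <- "no resistant-compound decay constants available (need >= 2)"
  } else if (within_sig && dna_faster) {
    scenario <- "chemical_reactivity"
    reason <- "DNA decays significantly faster than the group's resistant compounds"
  } else if (!within_sig) {
    scenario <- "biotic_exclusion"
    reason <- "DNA decay is indistinguishable from resistant compounds while cross-group DNA decay differs"
  } else {
    scenario <- "indeterminate"
    reason <- "DNA decays significantly slower than resistant compounds; no scenario rule applies"
  }
  structure(
    list(organism_group = organism_group, scenario = scenario,
         reason = reason, evidence = evidence, alpha = alpha,
         low_power = min(c(length(k_dna),
                           if (have_resistant) length(k_resistant),
                           lengths(k_dna_other_groups))) < 4L),
    class = "scenario_call"
  )
}

#' @export
print.scenario_call <- function(x, ...) {
  cat(sprintf("<scenario_call> %s -> %s\n", x$organism_group, x$scenario))
  cat("  ", x$reason, "\n", sep = "")
  if (x$low_power) {
    cat("  note: group sizes < 4; nonsignificance is weak evidence of similarity\n")
  }
  print(x$evidence, row.names = FALSE)
  invisible(x)
}

#' Classify straight from a list of decay fits
#'
#' Extracts per-group decay-constant lists from power fits (DNA class vs the
#' resistant compound classes) and calls [classify_group()] for the focal
#' group.
#'
#' @param fits List of `"decay_fit"` objects (power fits are used).
#' @param focal_group The organism group to classify.
#' @param resistant_classes Compound classes treated as degradation-resistant.
#' @param alpha Significance level.
#' @return A `"scenario_call"`.
#' @export
classify_from_fits <- function(fits, focal_group,
                               resistant_classes = c("fatty_acid", "n_alkane",
                                                     "sterol", "lignin",
                                                     "macromolecule"),
                               alpha = 0.05) {
  is_power <- vapply(fits, function(f) f$model == "power", logical(1))
  fits <- fits[is_power]
  grp <- vapply(fits, `[[`, character(1), "organism_group")
  cls <- vapply(fits, `[[`, character(1), "compound_class")
  k <- vapply(fits, `[[`, numeric(1), "decay_constant")
  k_dna <- k[grp == focal_group & cls == "DNA"]
  k_res <- k[grp == focal_group & cls %in% resistant_classes]
  others <- setdiff(unique(grp[cls == "DNA"]), focal_group)
  k_other <- lapply(setNames(others, others),
                    function(g) k[grp == g & cls == "DNA"])
  k_other <- k_other[lengths(k_other) >= 2L]
  if (!length(k_other)) stop("no other group has >= 2 DNA decay constants")
  classify_group(k_dna, if (length(k_res) >= 2L) k_res else NULL, k_other,
                 alpha = alpha, organism_group = focal_group)
}

#' Structured report over several scenario calls
#'
#' @param calls List of `"scenario_call"` objects (`>= 1`).
#' @param path Optional path; if given, the JSON report is written there.
#' @return Invisibly, the report as a JSON string (class `"json"`); printing
#'   the return of `scenario_report()` shows the JSON, while the calls
#'   themselves print as human-readable sections.
#' @export
scenario_report <- function(calls, path = NULL) {
  if (inherits(calls, "scenario_call")) calls <- list(calls)
  stopifnot(length(calls) >= 1L,
            all(vapply(calls, inherits, logical(1), "scenario_call")))
  payload <- list(
    n_groups = length(calls),
    calls = lapply(calls, function(x) {
      list(organism_group = x$organism_group, scenario = x$scenario,
           alpha = x$alpha, reason = x$reason, low_power = x$low_power,
           evidence = x$evidence)
    })
  )
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  if (!is.null(path)) writeLines(js, path)
  invisible(js)
}
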