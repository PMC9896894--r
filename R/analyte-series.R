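#' Recognised organism groups and compound classes
#'
#' Controlled vocabularies used to tag analyte profiles.  Organism groups
#' follow the three phototroph groups whose biomolecules are tracked downcore
#' (diatoms, green algae, vascular plants) plus a general microalgal pool and
#' a catch-all; compound classes cover DNA marker genes, lipid biomarkers,
#' pigments, lignin and pyrolysis-derived macromolecule classes.
#'
#' @return Character vector of allowed labels.
#' @export
organism_groups <- function() {
  c("diatom", "green_alga", "microalgae_general", "vascular_plant", "other")
}

#' @rdname organism_groups
#' @export
compound_classes <- function() {
  c("DNA", "fatty_acid", "n_alkane", "sterol", "pigment", "lignin",
    "macromolecule", "other")
}

#' Construct an analyte depth-profile series
#'
#' An `analyte_series` holds one biomolecule's content record against sediment
#' age for one station: the response Y (content or gene copies per g dry
#' sediment) and predictor X (sediment age in years) of the decay models.
#' Points are sorted by increasing age and rows with missing age or value are
#' dropped (their count is kept in the `n_dropped` field).
#'
#' @param age Sediment ages in years since deposition.
#' @param value Nonnegative contents (or gene copies) per g dry sediment.
#' @param analyte_id Analyte label, e.g. `"diatom_rbcL"`.
#' @param organism_group One of [organism_groups()].
#' @param compound_class One of [compound_classes()].
#' @param units Free-text units, e.g. `"copies/g"` or `"ug/g"`.
#' @param station_id,lake_id Sampling station and lake labels.
#' @return An object of class `"analyte_series"`.
#' @examples
#' s <- analyte_series(c(5, 1, 50), c(80, 100, 10), "diatom_rbcL",
#'                     organism_group = "diatom", compound_class = "DNA")
#' s$points
#' @export
analyte_series <- function(age, value, analyte_id,
                           organism_group = "other",
                           compound_class = "other",
                           units = "", station_id = "", lake_id = "") {
  if (length(age) != length(value)) {
    stop("`age` and `value` must have the same length")
  }
  age <- as.numeric(age)
  value <- as.numeric(value)
  keep <- !(is.na(age) | is.na(value))
  n_dropped <- sum(!keep)
  age <- age[keep]
  value <- value[keep]
  if (any(value < 0)) stop("`value` must be nonnegative")
  organism_group <- match.arg(organism_group, organism_groups())
  compound_class <- match.arg(compound_class, compound_classes())
  o <- order(age)
  structure(
    list(
      analyte_id = as.character(analyte_id),
      organism_group = organism_group,
      compound_class = compound_class,
      units = as.character(units),
      station_id = as.character(station_id),
      lake_id = as.character(lake_id),
      points = data.frame(age = age[o], value = value[o]),
      n_dropped = n_dropped
    ),
    class = "analyte_series"
  )
}

#' @export
print.analyte_series <- function(x, ...) {
  cat(sprintf("<analyte_series> %s  [%s / %s]\n",
              x$analyte_id, x$organism_group, x$compound_class))
  if (nzchar(x$lake_id) || nzchar(x$station_id)) {
    cat(sprintf("  lake: %s  station: %s\n", x$lake_id, x$station_id))
  }
  cat(sprintf("  %d points, age %.4g-%.4g y%s\n",
              nrow(x$points),
              if (nrow(x$points)) min(x$points$age) else NA,
              if (nrow(x$points)) max(x$points$age) else NA,
              if (nzchar(x$units)) paste0(", units: ", x$units) else ""))
  invisible(x)
}

is_analyte_series <- function(x) inherits(x, "analyte_series")
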