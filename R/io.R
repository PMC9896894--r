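#' Read a long-format profile table into analyte series
#'
#' Reads a tidy CSV with one measurement per row and returns one
#' [analyte_series()] per unique (lake, station, analyte) combination, each
#' sorted by age.  Rows with non-numeric or missing `value`/`age_y` entries
#' are excluded; their 1-based line numbers (counting the header as line 1)
#' are reported in a message and attached as attribute `"skipped_rows"`.
#'
#' @param path Path to a CSV file with header columns
#'   `lake, station, depth_cm, age_y, analyte, value, units, organism_group,
#'   compound_class`.
#' @return Named list of `analyte_series` (names `lake.station.analyte`),
#'   with attribute `"skipped_rows"`.
#' @export
read_profiles <- function(path) {
  required <- c("lake", "station", "depth_cm", "age_y", "analyte", "value",
                "units", "organism_group", "compound_class")
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  age <- suppressWarnings(as.numeric(raw$age_y))
  value <- suppressWarnings(as.numeric(raw$value))
  bad <- which(is.na(age) | is.na(value))
  if (length(bad)) {
    message(sprintf("read_profiles: skipped %d row(s) with missing/non-numeric age or value (lines %s)",
                    length(bad), paste(bad + 1L, collapse = ", ")))
  }
  keep <- setdiff(seq_len(nrow(raw)), bad)
  key <- interaction(raw$lake, raw$station, raw$analyte, drop = TRUE, sep = ".")
  out <- list()
  for (k in levels(droplevels(key[keep]))) {
    i <- keep[key[keep] == k]
    first <- i[1L]
    out[[k]] <- analyte_series(
      age = age[i], value = value[i],
      analyte_id = raw$analyte[first],
      organism_group = raw$organism_group[first],
      compound_class = raw$compound_class[first],
      units = raw$units[first],
      station_id = raw$station[first],
      lake_id = raw$lake[first]
    )
  }
  attr(out, "skipped_rows") <- bad + 1L
  out
}

fit_columns <- function() {
  c("lake", "station", "analyte", "organism_group", "compound_class", "units",
    "model", "amplitude", "exponent", "decay_constant", "r_squared",
    "p_slope", "n_points", "n_excluded", "flagged")
}

#' Collect decay fits into a data frame
#'
#' @param fits A list of [fit_decay()] results (or a single one).
#' @return Data frame with one row per fit.
#' @export
fits_table <- function(fits) {
  if (inherits(fits, "decay_fit")) fits <- list(fits)
  rows <- lapply(fits, as.data.frame)
  if (!length(rows)) {
    df <- as.data.frame(setNames(rep(list(character(0)), length(fit_columns())),
                                 fit_columns()))
    return(df)
  }
  do.call(rbind, rows)
}

#' Write and re-read decay-fit tables
#'
#' `write_fits()` stores one row per fit; numeric columns are written with 17
#' significant digits so `read_fits()` reproduces them exactly (doubles
#' round-trip losslessly at that precision).
#'
#' @param fits List of `decay_fit` objects or a data frame from [fits_table()].
#' @param path Output/input CSV path.
#' @return `write_fits()` returns `path` invisibly; `read_fits()` a data frame.
#' @export
write_fits <- function(fits, path) {
  df <- if (is.data.frame(fits)) fits else fits_table(fits)
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- sprintf("%.17g", out[[col]])
    }
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open '", path, "' for writing: ", conditionMessage(e))
  })
  on.exit(close(con))
  write.csv(out, con, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_fits
#' @export
read_fits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  num <- c("amplitude", "exponent", "decay_constant", "r_squared", "p_slope")
  for (col in intersect(num, names(df))) df[[col]] <- as.numeric(df[[col]])
  for (col in intersect(c("n_points", "n_excluded"), names(df))) {
    df[[col]] <- as.integer(df[[col]])
  }
  if ("flagged" %in% names(df)) df$flagged <- as.logical(df$flagged)
  df
}

#' Read an age-anchor table
#'
#' @param path CSV with columns `lake, station, depth_cm, age_y`.
#' @return Data frame; pass per-station subsets to [age_model()].
#' @export
read_anchors <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("lake", "station", "depth_cm", "age_y")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  df$depth_cm <- as.numeric(df$depth_cm)
  df$age_y <- as.numeric(df$age_y)
  df
}

#' Read a long-format community count table and per-sample totals
#'
#' `read_community()` expects columns `sample, taxon, count, group` and,
#' optionally via `totals_path`, a table `sample, total_copies` of total gene
#' copy numbers per g dry sediment.
#'
#' @param path Community CSV path.
#' @param totals_path Optional totals CSV path.
#' @param sample_data Optional data frame of per-sample metadata with a
#'   `sample` column.
#' @return A [community_table()].
#' @export
read_community <- function(path, totals_path = NULL, sample_data = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "taxon", "count", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  df$count <- as.numeric(df$count)
  samples <- unique(df$sample)
  taxa <- unique(df$taxon)
  counts <- matrix(0, length(samples), length(taxa),
                   dimnames = list(samples, taxa))
  counts[cbind(match(df$sample, samples), match(df$taxon, taxa))] <- df$count
  groups <- setNames(df$group[match(taxa, df$taxon)], taxa)
  totals <- NULL
  if (!is.null(totals_path)) {
    tdf <- read.csv(totals_path, stringsAsFactors = FALSE)
    if (!all(c("sample", "total_copies") %in% names(tdf))) {
      stop("totals table needs columns sample, total_copies")
    }
    totals <- setNames(as.numeric(tdf$total_copies), tdf$sample)
  }
  community_table(counts, taxon_groups = groups, total_copies = totals,
                  sample_data = sample_data)
}
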