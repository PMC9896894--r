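#' Preset analyte panels for synthetic cores
#'
#' Each preset is a small table of analytes (label, organism group, compound
#' class, units, amplitude at age 1 y, decay constant `k`, and whether the
#' analyte is measured at the deep station only, as biomarkers and
#' macromolecules typically are).  The `"paper_like"` panel encodes decay
#' constants near published group-level values for temperate-lake records
#' (diatom DNA ~1.57, green algal DNA ~0.70, vascular plant DNA ~0.12;
#' biomarker values calibrated from their printed age-1 half-lives) — these
#' are calibration inputs for simulation, not ground truth.  The three
#' scenario presets fix the decay-constant structure so that the focal group
#' (attribute `"focal_group"`) is generated under one preservation scenario:
#' `"chemical_reactivity"` (diatom-like: DNA much faster than lipids),
#' `"biotic_exclusion"` (green-alga-like: DNA as slow as lipids but distinct
#' from other groups' DNA), `"adsorption_complexation"` (identical DNA decay
#' across groups).
#'
#' @param scenario Preset name.
#' @param extended Add the general microalgal biomarker/macromolecule panel
#'   (sterols, chlorophylls, short-chain lipids, proteins) to `"paper_like"`.
#' @return Data frame with attribute `"focal_group"`.
#' @export
decay_preset <- function(scenario = c("paper_like", "chemical_reactivity",
                                      "biotic_exclusion",
                                      "adsorption_complexation"),
                         extended = FALSE) {
  scenario <- match.arg(scenario)
  base <- function(k_dna_d, k_dna_g, k_dna_v, k_lip_d, k_lip_g, k_lig_v) {
    data.frame(
      analyte = c("diatom_rbcL", "green_rbcL", "plant_rbcL",
                  "FA_C20_5n3", "FA_C18_2n6", "lignin"),
      organism_group = c("diatom", "green_alga", "vascular_plant",
                         "diatom", "green_alga", "vascular_plant"),
      compound_class = c("DNA", "DNA", "DNA",
                         "fatty_acid", "fatty_acid", "lignin"),
      units = c("copies/g", "copies/g", "copies/g", "ug/g", "ug/g", "mg/g"),
      amplitude = c(1e8, 3e7, 5e5, 120, 90, 3),
      k = c(k_dna_d, k_dna_g, k_dna_v, k_lip_d, k_lip_g, k_lig_v),
      deep_only = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
      stringsAsFactors = FALSE
    )
  }
  panel <- switch(scenario,
    paper_like = base(1.57, 0.70, 0.12, 0.52, 0.45, 0.084),
    chemical_reactivity = base(1.60, 0.70, 0.12, 0.50, 0.66, 0.10),
    biotic_exclusion = base(1.60, 0.70, 0.12, 0.50, 0.66, 0.10),
    adsorption_complexation = base(0.70, 0.70, 0.70, 0.50, 0.66, 0.60))
  if (extended && scenario == "paper_like") {
    panel <- rbind(panel, data.frame(
      analyte = c("diatom_sterols", "chlorophyll_a", "alkanes_C15_C17_C19",
                  "FA_C14_C16_C18", "total_chlorophyll", "proteins"),
      organism_group = c("diatom", rep("microalgae_general", 5)),
      compound_class = c("sterol", "pigment", "n_alkane", "fatty_acid",
                         "macromolecule", "macromolecule"),
      units = c("ug/g", "ug/g", "ug/g", "ug/g", "%pyr", "%pyr"),
      amplitude = c(60, 200, 15, 300, 2, 5),
      k = c(0.61, 0.44, 0.42, 0.40, 0.34, 0.60),
      deep_only = TRUE, stringsAsFactors = FALSE))
  }
  attr(panel, "focal_group") <- switch(scenario,
    paper_like = "diatom",
    chemical_reactivity = "diatom",
    biotic_exclusion = "green_alga",
    adsorption_complexation = "diatom")
  panel
}

#' Simulate one analyte profile from a power-law decay core
#'
#' Forward model of the fitted equation: \eqn{Y_i = a t_i^b e^{\varepsilon_i}}
#' with \eqn{\varepsilon_i \sim N(0, \sigma^2)} — multiplicative lognormal
#' measurement noise, the natural error model for positive contents spanning
#' orders of magnitude.  Values falling below an optional detection limit are
#' censored (dropped; their count is attached as attribute `"n_censored"`).
#'
#' @param ages Age grid in years (empty grid gives an empty series).
#' @param amplitude Content at age 1 y.
#' @param exponent Power exponent `b` (use `-k` for decay).
#' @param sigma_log SD of the log-residuals (natural log), `>= 0`.
#' @param detection_limit Optional censoring threshold.
#' @param seed Optional integer seed (RNG state restored afterwards); when
#'   called inside a larger seeded simulation, leave `NULL` to draw from the
#'   ambient stream.
#' @param analyte_id,organism_group,compound_class,units,station_id,lake_id
#'   Metadata passed to [analyte_series()].
#' @return An [analyte_series()] with attribute `"n_censored"`.
#' @export
simulate_profile <- function(ages, amplitude, exponent, sigma_log = 0.4,
                             detection_limit = NULL, seed = NULL,
                             analyte_id = "sim", organism_group = "other",
                             compound_class = "other", units = "",
                             station_id = "", lake_id = "") {
  stopifnot(sigma_log >= 0)
  ages <- as.numeric(ages)
  values <- with_seed(seed, {
    amplitude * ages^exponent * exp(rnorm(length(ages), 0, sigma_log))
  })
  n_censored <- 0L
  if (!is.null(detection_limit) && length(ages)) {
    keep <- values >= detection_limit
    n_censored <- sum(!keep)
    ages <- ages[keep]
    values <- values[keep]
  }
  out <- analyte_series(ages, values, analyte_id,
                        organism_group = organism_group,
                        compound_class = compound_class, units = units,
                        station_id = station_id, lake_id = lake_id)
  attr(out, "n_censored") <- n_censored
  out
}

#' Simulate a multiproxy sediment core
#'
#' Generates a labelled panel of analyte profiles for one lake: the default
#' panel has the three DNA markers at all three stations plus one
#' group-specific resistant compound per group at the deep station only
#' (12 series), mirroring a design where biomarkers are measured only at the
#' deepest station.  Per-lake decay constants are drawn around the preset
#' values with multiplicative lognormal heterogeneity `tau_k` on `k`,
#' representing between-lake variability in apparent decay rates.
#'
#' Ages follow a uniform depth grid of `n_depths` layer midpoints down to
#' `depth_max` at a constant sedimentation rate (default 0.22 cm/y, a ~40 cm
#' /~180 y core; use ~0.065 cm/y for a ~600 y core).
#'
#' @param scenario Preset name for [decay_preset()].
#' @param seed Integer seed (mandatory: the run must be reproducible).
#' @param lake_id Lake label.
#' @param stations Station labels; the last one is the "deep" station.
#' @param n_depths Sampled layers per station.
#' @param depth_max Core length (cm).
#' @param sed_rate Sedimentation rate (cm/y).
#' @param sigma_log Lognormal measurement-noise SD (natural log).
#' @param tau_k Between-lake SD of `log(k)`.
#' @param detection_limit Optional censoring threshold (applied to all
#'   analytes on their own scale; mainly useful per-analyte via
#'   [simulate_profile()]).
#' @param extended Passed to [decay_preset()].
#' @return List of [analyte_series()]; attributes `"true_k"` (the lake-level
#'   decay constants) and `"focal_group"`.
#' @export
simulate_core <- function(scenario = "paper_like", seed, lake_id = "lake_1",
                          stations = c("shallow", "medium", "deep"),
                          n_depths = 20, depth_max = 40, sed_rate = 0.22,
                          sigma_log = 0.4, tau_k = 0.25,
                          detection_limit = NULL, extended = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory for simulation")
  panel <- decay_preset(scenario, extended = extended)
  with_seed(seed, {
    k_lake <- panel$k * exp(rnorm(nrow(panel), 0, tau_k))
    depths <- seq(depth_max / n_depths / 2, depth_max, length.out = n_depths)
    ages <- depths / sed_rate
    out <- list()
    for (i in seq_len(nrow(panel))) {
      st <- if (panel$deep_only[i]) stations[length(stations)] else stations
      for (s in st) {
        id <- paste(lake_id, s, panel$analyte[i], sep = ".")
        out[[id]] <- simulate_profile(
          ages, panel$amplitude[i], -k_lake[i], sigma_log = sigma_log,
          detection_limit = detection_limit,
          analyte_id = panel$analyte[i],
          organism_group = panel$organism_group[i],
          compound_class = panel$compound_class[i], units = panel$units[i],
          station_id = s, lake_id = lake_id)
      }
    }
    attr(out, "true_k") <- setNames(k_lake, panel$analyte)
    attr(out, "focal_group") <- attr(panel, "focal_group")
    out
  })
}

#' Simulate a multi-lake study
#'
#' Calls [simulate_core()] for `n_lakes` lakes with distinct sedimentation
#' rates (the last lake is a slow, ~600-year core) under one RNG stream, so
#' the whole study is reproducible from a single seed.
#'
#' @param scenario,seed,... As in [simulate_core()].
#' @param n_lakes Number of lakes (default 5).
#' @param sed_rates Per-lake sedimentation rates (cm/y), recycled to
#'   `n_lakes`.
#' @param stations Stations per lake; use `"deep"` alone for the deep-station
#'   panel used in cross-lake contrasts.
#' @return Flat named list of [analyte_series()] with attribute
#'   `"focal_group"`.
#' @export
simulate_study <- function(scenario = "paper_like", seed, n_lakes = 5,
                           sed_rates = c(0.20, 0.25, 0.30, 0.22, 0.065),
                           stations = "deep", ...) {
  if (missing(seed)) stop("`seed` is mandatory for simulation")
  sed_rates <- rep_len(sed_rates, n_lakes)
  out <- with_seed(seed, {
    res <- list()
    for (l in seq_len(n_lakes)) {
      # per-lake sub-seed drawn from the study stream keeps lakes independent
      core <- simulate_core(scenario,
                            seed = sample.int(.Machine$integer.max, 1L),
                            lake_id = sprintf("lake_%d", l),
                            stations = stations, sed_rate = sed_rates[l], ...)
      res <- c(res, core)
    }
    res
  })
  attr(out, "focal_group") <- attr(decay_preset(scenario), "focal_group")
  out
}

#' Preset group intensities for community simulation
#'
#' Group-level 18S-like base intensities (copies per g at age 1 y) and decay
#' constants near reported 18S-based group estimates (diatoms ~1.8, green
#' algae ~0.6, vascular plants ~0.2), plus a slowly decaying background pool
#' of other eukaryotes.
#'
#' @return Data frame with columns `group`, `amplitude`, `k`.
#' @export
community_preset <- function() {
  data.frame(
    group = c("diatom", "green_alga", "vascular_plant", "other"),
    amplitude = c(4e8, 1e8, 5e6, 1e9),
    k = c(1.82, 0.57, 0.22, 0.60),
    stringsAsFactors = FALSE
  )
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {
    # degenerate concentration; fall back to the mean proportions
    return(alpha / sum(alpha))
  }
  g / sum(g)
}

#' Simulate an amplicon community table consistent with power decay
#'
#' Per sample of age `t`, each group's latent intensity is
#' \eqn{I_g(t) = A_g t^{-k_g}}; the total gene copy number is
#' \eqn{\sum_g I_g(t)} times lognormal qPCR noise, and read counts are drawn
#' Dirichlet-multinomial around the exact proportions \eqn{I_g / \sum I}
#' (group intensity split over `n_taxa_per_group` taxa with fixed geometric
#' within-group weights).  Totals and fractions are therefore jointly
#' consistent with per-group power decay, so partitioning the totals by read
#' fractions recovers each group's decay constant.
#'
#' @param ages Sample ages in years (`> 0`).
#' @param groups Data frame `group, amplitude, k` (default
#'   [community_preset()]).
#' @param read_depth Reads per sample (`>= 1`).
#' @param concentration Dirichlet concentration; `Inf` gives exact
#'   multinomial proportions (and with it the no-overdispersion limit).
#' @param n_taxa_per_group Taxa per group.
#' @param total_sigma_log Lognormal SD of the qPCR total-copy noise; 0 for
#'   noiseless totals.
#' @param seed Integer seed (mandatory).
#' @param trophic_state Optional per-sample trophic state labels stored in
#'   the sample metadata.
#' @return A [community_table()] with per-sample ages in `sample_data` and
#'   attribute `"true_k"`.
#' @export
simulate_community <- function(ages, groups = community_preset(),
                               read_depth = 10000, concentration = 50,
                               n_taxa_per_group = 3, total_sigma_log = 0.3,
                               seed, trophic_state = NULL) {
  if (missing(seed)) stop("`seed` is mandatory for simulation")
  stopifnot(all(ages > 0), read_depth >= 1)
  ages <- as.numeric(ages)
  n <- length(ages)
  with_seed(seed, {
    intensity <- sapply(seq_len(nrow(groups)), function(g) {
      groups$amplitude[g] * ages^(-groups$k[g])
    })
    intensity <- matrix(intensity, nrow = n)
    totals_true <- rowSums(intensity)
    totals <- totals_true * exp(rnorm(n, 0, total_sigma_log))
    w <- 0.5^(seq_len(n_taxa_per_group) - 1)
    w <- w / sum(w)
    taxa <- as.vector(t(outer(groups$group, seq_len(n_taxa_per_group),
                              function(g, i) paste0(g, "_t", i))))
    taxon_groups <- setNames(rep(groups$group, each = n_taxa_per_group), taxa)
    prop_taxa <- t(apply(intensity, 1L, function(I) {
      as.vector(t(outer(I / sum(I), w)))
    }))
    colnames(prop_taxa) <- taxa
    counts <- matrix(0L, n, length(taxa),
                     dimnames = list(sprintf("s%02d", seq_len(n)), taxa))
    for (i in seq_len(n)) {
      p <- if (is.finite(concentration)) {
        rdirichlet1(concentration * prop_taxa[i, ])
      } else {
        prop_taxa[i, ]
      }
      counts[i, ] <- rmultinom(1L, size = read_depth, prob = p)[, 1L]
    }
    meta <- data.frame(sample = rownames(counts), age = ages,
                       stringsAsFactors = FALSE)
    if (!is.null(trophic_state)) meta$trophic_state <- trophic_state
    ct <- community_table(counts, taxon_groups = taxon_groups,
                          total_copies = setNames(totals, rownames(counts)),
                          sample_data = meta)
    attr(ct, "true_k") <- setNames(groups$k, groups$group)
    ct
  })
}

#' Write a complete synthetic input bundle
#'
#' Writes `profiles.csv`, `anchors.csv`, `community.csv`, `totals.csv` and a
#' `manifest.json` recording the scenario, parameters and seed, so a whole
#' pipeline run can start from plain CSV inputs.  The same seed yields
#' byte-identical files.
#'
#' @param outdir Output directory (created if needed).
#' @param scenario,seed Passed to [simulate_core()] / [simulate_community()].
#' @param n_depths,depth_max,sed_rate,sigma_log,tau_k,detection_limit,extended
#'   Passed to [simulate_core()].
#' @return Invisibly, the named vector of file paths written.
#' @export
write_fixture_bundle <- function(outdir, scenario = "paper_like", seed,
                                 n_depths = 20, depth_max = 40,
                                 sed_rate = 0.22, sigma_log = 0.4,
                                 tau_k = 0.25, detection_limit = NULL,
                                 extended = FALSE) {
  if (missing(seed)) stop("`seed` is mandatory for simulation")
  ok <- dir.exists(outdir) || dir.create(outdir, recursive = TRUE)
  if (!ok) stop("cannot create output directory '", outdir, "'")
  core <- simulate_core(scenario, seed = seed, n_depths = n_depths,
                        depth_max = depth_max, sed_rate = sed_rate,
                        sigma_log = sigma_log, tau_k = tau_k,
                        detection_limit = detection_limit,
                        extended = extended)
  n_censored <- sum(vapply(core, function(s) attr(s, "n_censored") %||% 0L,
                           integer(1)))
  prof <- do.call(rbind, lapply(core, function(s) {
    data.frame(lake = s$lake_id, station = s$station_id,
               depth_cm = sprintf("%.17g", s$points$age * sed_rate),
               age_y = sprintf("%.17g", s$points$age),
               analyte = s$analyte_id,
               value = sprintf("%.17g", s$points$value),
               units = s$units, organism_group = s$organism_group,
               compound_class = s$compound_class, stringsAsFactors = FALSE)
  }))
  anchor_depths <- seq(0, depth_max, length.out = 5)
  anchors <- do.call(rbind, lapply(unique(prof$station), function(st) {
    data.frame(lake = core[[1]]$lake_id, station = st,
               depth_cm = sprintf("%.17g", anchor_depths),
               age_y = sprintf("%.17g", anchor_depths / sed_rate),
               stringsAsFactors = FALSE)
  }))
  deep_ages <- sort(unique(as.numeric(
    prof$age_y[prof$station == utils::tail(unique(prof$station), 1)])))
  comm_ages <- deep_ages[round(seq(1, length(deep_ages), length.out =
                                     min(10, length(deep_ages))))]
  ct <- simulate_community(comm_ages, seed = seed + 1L)
  comm <- data.frame(
    sample = rep(rownames(ct$counts), times = ncol(ct$counts)),
    taxon = rep(colnames(ct$counts), each = nrow(ct$counts)),
    count = as.vector(ct$counts),
    group = rep(unname(ct$taxon_groups), each = nrow(ct$counts)),
    stringsAsFactors = FALSE)
  totals <- data.frame(sample = names(ct$total_copies),
                       total_copies = sprintf("%.17g", ct$total_copies),
                       stringsAsFactors = FALSE)
  paths <- c(profiles = file.path(outdir, "profiles.csv"),
             anchors = file.path(outdir, "anchors.csv"),
             community = file.path(outdir, "community.csv"),
             totals = file.path(outdir, "totals.csv"),
             manifest = file.path(outdir, "manifest.json"))
  write.csv(prof, paths["profiles"], row.names = FALSE, quote = TRUE)
  write.csv(anchors, paths["anchors"], row.names = FALSE, quote = TRUE)
  write.csv(comm, paths["community"], row.names = FALSE, quote = TRUE)
  write.csv(totals, paths["totals"], row.names = FALSE, quote = TRUE)
  manifest <- list(scenario = scenario, seed = seed, n_depths = n_depths,
                   depth_max = depth_max, sed_rate = sed_rate,
                   sigma_log = sigma_log, tau_k = tau_k,
                   detection_limit = detection_limit, extended = extended,
                   n_series = length(core), n_censored = n_censored,
                   files = as.list(basename(paths[1:4])))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             paths["manifest"])
  if (n_censored > 0) {
    message(sprintf("write_fixture_bundle: %d value(s) censored below the detection limit",
                    n_censored))
  }
  invisible(paths)
}
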