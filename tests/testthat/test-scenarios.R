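# Deterministic decay-constant sets with clear structure
k_fast <- c(1.4, 1.5, 1.6, 1.7, 1.8)      # diatom-DNA-like
k_mid <- c(0.6, 0.65, 0.7, 0.75, 0.8)     # green-algal-DNA-like
k_slow <- c(0.05, 0.1, 0.12, 0.15, 0.2)   # vascular-plant-DNA-like
k_lipid <- c(0.4, 0.45, 0.5, 0.55, 0.6)

test_that("classification follows the ordered three-scenario rule", {
  # DNA much faster than resistant compounds, cross-group differences present
  call_cr <- classify_group(k_fast, k_lipid,
                            list(green = k_mid, plant = k_slow),
                            organism_group = "diatom")
  expect_equal(call_cr$scenario, "chemical_reactivity")

  # DNA as slow as the group's lipid, but distinct from other groups' DNA
  call_be <- classify_group(k_mid, k_mid + 0.02,
                            list(diatom = k_fast, plant = k_slow),
                            organism_group = "green_alga")
  expect_equal(call_be$scenario, "biotic_exclusion")

  # identical DNA decay across groups -> adsorption/complexation, and the
  # rule fires before any within-group comparison is considered
  call_ac <- classify_group(k_mid, k_lipid,
                            list(g2 = k_mid, g3 = k_mid),
                            organism_group = "any")
  expect_equal(call_ac$scenario, "adsorption_complexation")

  # DNA significantly *slower* than resistant compounds fits no rule
  call_ind <- classify_group(k_slow, k_fast, list(other = k_mid))
  expect_equal(call_ind$scenario, "indeterminate")
})

test_that("missing resistant compounds yield an indeterminate call with reason", {
  call <- classify_group(k_fast, NULL, list(green = k_mid))
  expect_equal(call$scenario, "indeterminate")
  expect_match(call$reason, "resistant")
  expect_error(classify_group(1.5, k_lipid, list(g = k_mid)), "at least 2")
})

test_that("calls are deterministic and carry their evidence", {
  c1 <- classify_group(k_fast, k_lipid, list(green = k_mid, plant = k_slow),
                       organism_group = "diatom")
  c2 <- classify_group(k_fast, k_lipid, list(green = k_mid, plant = k_slow),
                       organism_group = "diatom")
  expect_identical(c1, c2)
  expect_s3_class(c1$evidence, "data.frame")
  expect_equal(sum(c1$evidence$comparison == "cross_group_DNA"), 2L)
  expect_equal(sum(c1$evidence$comparison == "within_group_DNA_vs_resistant"),
               1L)
  expect_true(all(c1$evidence$p_value > 0 & c1$evidence$p_value <= 1))
  expect_false(c1$low_power)                   # n = 5 everywhere
  expect_true(classify_group(k_fast[1:3], k_lipid[1:3],
                             list(g = k_mid[1:3]))$low_power)
})

test_that("alpha shifts the decision boundary", {
  # 3 vs 3 groups: the smallest achievable exact p is 0.1, so at alpha = 0.05
  # no cross-group contrast can reject and rule (i) must fire
  call_strict <- classify_group(c(4, 5, 6), c(1, 2, 3),
                                list(g = c(10, 11, 12)), alpha = 0.05)
  expect_equal(call_strict$scenario, "adsorption_complexation")
  # at alpha = 0.2 the same data separate: DNA decays faster than the
  # resistant compounds and differs across groups
  call_loose <- classify_group(c(4, 5, 6), c(1, 2, 3),
                               list(g = c(10, 11, 12)), alpha = 0.2)
  expect_equal(call_loose$scenario, "chemical_reactivity")
})

test_that("scenario_report emits schema-conformant JSON", {
  calls <- list(
    classify_group(k_fast, k_lipid, list(g = k_mid),
                   organism_group = "diatom"),
    classify_group(k_fast, NULL, list(g = k_mid),
                   organism_group = "vascular_plant"),
    classify_group(k_mid, k_mid + 0.02, list(g = k_fast),
                   organism_group = "green_alga"))
  path <- tempfile(fileext = ".json")
  js <- scenario_report(calls, path)
  parsed <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  expect_equal(parsed$n_groups, 3L)
  expect_length(parsed$calls, 3L)
  for (cl in parsed$calls) {
    expect_true(all(c("organism_group", "scenario", "alpha", "reason",
                      "low_power", "evidence") %in% names(cl)))
    expect_true(cl$scenario %in% c("adsorption_complexation",
                                   "chemical_reactivity", "biotic_exclusion",
                                   "indeterminate"))
  }
  # the indeterminate call keeps its stated reason
  expect_match(parsed$calls[[2]]$reason, "resistant")
  expect_output(print(calls[[1]]), "scenario_call")
})

test_that("classify_from_fits wires fits into a call", {
  mk <- function(k, analyte, group, class, lake) {
    s <- analyte_series(c(1, 5, 10, 50, 100),
                        1e6 * c(1, 5, 10, 50, 100)^-k, analyte,
                        organism_group = group, compound_class = class,
                        lake_id = lake)
    fit_power(s)
  }
  fits <- c(
    mapply(mk, k_fast, "d_rbcL", "diatom", "DNA", paste0("l", 1:5),
           SIMPLIFY = FALSE),
    mapply(mk, k_lipid, "d_FA", "diatom", "fatty_acid", paste0("l", 1:5),
           SIMPLIFY = FALSE),
    mapply(mk, k_mid, "g_rbcL", "green_alga", "DNA", paste0("l", 1:5),
           SIMPLIFY = FALSE))
  call <- classify_from_fits(fits, "diatom")
  expect_equal(call$scenario, "chemical_reactivity")
  expect_equal(call$organism_group, "diatom")
})
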