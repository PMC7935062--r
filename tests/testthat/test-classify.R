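test_that("plumage classes binarise at the configurable cut", {
  expect_equal(as.character(binarize_plumage_class(1:4)),
               c("heterochrome", "heterochrome", "androchrome", "androchrome"))
  expect_equal(as.character(binarize_plumage_class(3, androchrome_min_class = 4)),
               "heterochrome")
  expect_error(binarize_plumage_class(5), class = "flpscape_invalid_argument")
  expect_error(binarize_plumage_class(0), class = "flpscape_invalid_argument")
})

test_that("species summaries count females and exclude plumage-sexed specimens", {
  rec <- dplyr::bind_rows(
    make_records("a", c(1, 1, 1, 1, 1, 1, 1, 1, 4, 4)),       # 20% androchrome
    make_records("b", rep(1, 10)),
    tibble::tibble(species = "b", sex = "female", plumage_class = 4L,
                   sexing_method = "plumage"),                 # must be dropped
    tibble::tibble(species = "c", sex = "male", plumage_class = 4L,
                   sexing_method = "gonad"))
  s <- summarize_species(rec, dip = FALSE)
  expect_equal(s$species, c("a", "b", "c"))                    # deterministic order
  expect_equal(s$prop_androchrome[s$species == "a"], 0.2)
  expect_equal(s$prop_androchrome[s$species == "b"], 0)        # plumage-sexed out
  expect_equal(s$n_females[s$species == "c"], 0L)
  expect_true(is.na(s$prop_androchrome[s$species == "c"]))
  expect_equal(s$n_class1 + s$n_class2 + s$n_class3 + s$n_class4, s$n_females)
  expect_equal(nrow(summarize_species(rec[0, ], dip = FALSE)), 0)
})

test_that("detection probability matches its closed form and design point", {
  expect_equal(round(detection_probability(18, 0.10), 2), 0.85)
  expect_equal(detection_probability(18, 0.10), 1 - 0.9^18)
  expect_equal(detection_probability(5, 0), 0)
  expect_equal(detection_probability(1, 1), 1)
  expect_error(detection_probability(5, 1.2), class = "flpscape_invalid_argument")
})

test_that("required sample size equals the brute-force scan", {
  expect_equal(required_sample_size(0.10, 0.849), 18L)
  expect_equal(required_sample_size(0.5, 0.75), 2L)
  expect_equal(required_sample_size(1.0, 0.99), 1L)
  for (freq in c(0.03, 0.1, 0.25, 0.5, 0.9)) {
    for (target in c(0.5, 0.8, 0.95, 0.99)) {
      expect_equal(required_sample_size(freq, target),
                   scan_sample_size(freq, target))
    }
  }
  expect_error(required_sample_size(0, 0.85), class = "flpscape_no_solution")
})

test_that("the presence/absence decision rule classifies as specified", {
  summaries <- tibble::tibble(
    species = c("flp_sp", "absent_sp", "small_sp", "nodip_sp"),
    n_females = c(20L, 19L, 10L, 25L),
    n_class1 = c(17L, 19L, 10L, 20L), n_class2 = 0L, n_class3 = 0L,
    n_class4 = c(3L, 0L, 0L, 5L),
    prop_androchrome = c(0.15, 0, 0, 0.2),
    dip_p = c(0.01, NA, NA, NA))
  dich <- tibble::tibble(species = summaries$species,
                         dichromatism = c("dichromic", "dichromic",
                                          "dichromic", "monochromic"))
  expect_warning(cls <- classify_species(summaries, dich), "nodip_sp")
  st <- setNames(as.character(cls$status), cls$species)
  expect_equal(st[["flp_sp"]], "FLP")
  expect_equal(st[["absent_sp"]], "no_FLP_dichromic")
  expect_equal(st[["small_sp"]], "unclassified")
  expect_equal(st[["nodip_sp"]], "unclassified")   # proportion met, dip missing

  # monochromic flag carried onto no-FLP species
  dich2 <- dich
  dich2$dichromatism[2] <- "monochromic"
  cls2 <- suppressWarnings(classify_species(summaries, dich2))
  expect_equal(as.character(cls2$status[cls2$species == "absent_sp"]),
               "monochromic")

  # prior FLP reports block the absence rule
  dich3 <- dich
  dich3$prior_flp <- c(FALSE, TRUE, FALSE, FALSE)
  cls3 <- suppressWarnings(classify_species(summaries, dich3))
  expect_equal(as.character(cls3$status[cls3$species == "absent_sp"]),
               "unclassified")
})

test_that("classification is invariant to record order", {
  study <- simulate_flp_study(simulation_spec(n_species = 12), seed = 5)
  s1 <- summarize_species(study$specimens, n_boot = 100, seed = 1)
  shuffled <- study$specimens[sample(nrow(study$specimens)), ]
  s2 <- summarize_species(shuffled, n_boot = 100, seed = 1)
  expect_equal(s1, s2)
  expect_equal(classify_species(s1, study$dichromatism),
               classify_species(s2, study$dichromatism))
})

test_that("the default sensitivity grid has eight labelled matrices", {
  g <- default_sensitivity_grid()
  expect_equal(nrow(g), 8)
  expect_false(anyDuplicated(g$matrix_id) > 0)
  study <- simulate_flp_study(simulation_spec(n_species = 10), seed = 2)
  out <- build_sensitivity_matrices(study$specimens, study$dichromatism,
                                    n_boot = 100, seed = 1)
  expect_equal(length(unique(out$matrix_id)), 8)
  expect_equal(nrow(out), 8 * 10)
})

test_that("a one-row grid reproduces classify_species and duplicates error", {
  study <- simulate_flp_study(simulation_spec(n_species = 8), seed = 4)
  g1 <- default_sensitivity_grid()[2, ]
  out <- build_sensitivity_matrices(study$specimens, study$dichromatism, g1,
                                    n_boot = 100, seed = 1)
  cfg <- threshold_config(presence_min_prop = g1$presence_min_prop,
                          androchrome_min_class = g1$androchrome_min_class,
                          absence_min_females = g1$absence_min_females)
  s <- summarize_species(study$specimens, cfg, n_boot = 100, seed = 1)
  direct <- classify_species(s, study$dichromatism, cfg)
  expect_equal(out$status, direct$status)

  gdup <- dplyr::bind_rows(g1, g1)
  expect_error(build_sensitivity_matrices(study$specimens, study$dichromatism,
                                          gdup, n_boot = 100),
               class = "flpscape_invalid_argument")
})

test_that("stricter thresholds only shrink the affected class", {
  study <- simulate_flp_study(simulation_spec(n_species = 25,
                                              androchrome_freq = 0.25),
                              seed = 9)
  out <- build_sensitivity_matrices(study$specimens, study$dichromatism,
                                    n_boot = 150, seed = 2)
  flp_set <- function(id) out$species[out$matrix_id == id & out$status == "FLP"]
  noflp_set <- function(id)
    out$species[out$matrix_id == id &
                  out$status %in% c("no_FLP_dichromic", "monochromic")]
  # raising the presence proportion never adds FLP species
  expect_true(all(flp_set("p10_c3_a19") %in% flp_set("p05_c3_a19")))
  expect_true(all(flp_set("p10_c4_a10") %in% flp_set("p05_c4_a10")))
  # raising the absence threshold never adds no-FLP species
  expect_true(all(noflp_set("p10_c3_a19") %in% noflp_set("p10_c3_a10")))
  expect_true(all(noflp_set("p05_c4_a19") %in% noflp_set("p05_c4_a10")))
})
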