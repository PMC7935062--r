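#' Binarise ordinal plumage classes into morphs
#'
#' Maps the four ordinal androchromy classes to the two female morphs:
#' classes below `androchrome_min_class` are heterochrome, classes at or
#' above it androchrome. The conventional cut (3) corresponds to at least
#' 25% of sexually dimorphic patches being male-like.
#'
#' @param plumage_class Integer vector with values in 1--4.
#' @param androchrome_min_class Lowest class counted as androchrome (3 or 4).
#' @return A factor with levels `heterochrome`, `androchrome`.
#' @examples
#' binarize_plumage_class(c(1, 2, 3, 4))
#' @export
binarize_plumage_class <- function(plumage_class, androchrome_min_class = 3) {
  .assert(androchrome_min_class %in% c(3, 4),
          "`androchrome_min_class` must be 3 or 4.",
          class = "flpscape_invalid_argument")
  ok <- !is.na(plumage_class) & plumage_class %in% 1:4
  .assert(all(ok), "Plumage classes must be integers in 1..4; offending values: ",
          paste(unique(plumage_class[!ok]), collapse = ", "),
          class = "flpscape_invalid_argument")
  factor(ifelse(plumage_class >= androchrome_min_class,
                "androchrome", "heterochrome"),
         levels = c("heterochrome", "androchrome"))
}

#' Classification threshold configuration
#'
#' Holds the decision thresholds of the FLP presence/absence rule: a species
#' exhibits FLP when at least `presence_min_prop` of its females are
#' androchromic and (if `require_bimodality`) the female score distribution
#' rejects unimodality at `dip_alpha`; a species lacks FLP when at least
#' `absence_min_females` females were sampled without meeting the presence
#' rule. The default absence threshold of 19 females gives an 85% chance of
#' catching an androchrome morph at 10% population frequency (see
#' [detection_probability()]).
#'
#' @param presence_min_prop Minimum androchrome proportion for presence.
#' @param androchrome_min_class Lowest class counted as androchrome (3 or 4).
#' @param absence_min_females Minimum sampled females to assert absence.
#' @param dip_alpha Significance level of the dip test.
#' @param require_bimodality Require a significant dip test for presence.
#' @return A list of class `"threshold_config"`.
#' @examples
#' threshold_config()
#' @export
threshold_config <- function(presence_min_prop = 0.10,
                             androchrome_min_class = 3,
                             absence_min_females = 19,
                             dip_alpha = 0.05,
                             require_bimodality = TRUE) {
  .assert(is.numeric(presence_min_prop) && presence_min_prop > 0 &&
            presence_min_prop <= 1, "`presence_min_prop` must be in (0, 1].")
  .assert(androchrome_min_class %in% c(3, 4),
          "`androchrome_min_class` must be 3 or 4.")
  .assert(.is_count(absence_min_females), "`absence_min_females` must be >= 1.")
  .assert(.is_prob(dip_alpha) && dip_alpha > 0, "`dip_alpha` must be in (0, 1].")
  structure(list(presence_min_prop = presence_min_prop,
                 androchrome_min_class = androchrome_min_class,
                 absence_min_females = as.integer(absence_min_females),
                 dip_alpha = dip_alpha,
                 require_bimodality = isTRUE(require_bimodality)),
            class = "threshold_config")
}

# drop records that cannot enter analyses: plumage-sexed specimens (circular)
.ingest_specimens <- function(records) {
  .assert(all(c("species", "sex", "plumage_class") %in% names(records)),
          "Specimen table needs columns species, sex, plumage_class.")
  if ("sexing_method" %in% names(records)) {
    records <- dplyr::filter(records, .data$sexing_method != "plumage")
  }
  records
}

#' Summarise female plumage scores per species
#'
#' Ingests specimen records (excluding plumage-sexed specimens and
#' non-female rows), tabulates ordinal class counts, the androchrome
#' proportion, and (optionally) the bootstrap dip test p-value of the female
#' score distribution. Species are returned in alphabetical order.
#'
#' @param records Specimen tibble with columns `species`, `sex`,
#'   `plumage_class` and optionally `sexing_method`.
#' @param config A [threshold_config()] (supplies the androchrome class cut).
#' @param dip Compute dip test p-values (needs at least 4 females).
#' @param n_boot,seed Passed to [dip_test()].
#' @return A tibble with columns `species`, `n_females`, `n_class1` ..
#'   `n_class4`, `prop_androchrome` and `dip_p` (`NA` when undefined).
#' @examples
#' rec <- tibble::tibble(species = "a", sex = "female",
#'                       plumage_class = c(1, 1, 1, 4, 4),
#'                       sexing_method = "gonad")
#' summarize_species(rec, dip = FALSE)
#' @export
summarize_species <- function(records, config = threshold_config(),
                              dip = TRUE, n_boot = 500, seed = 1L) {
  .assert(inherits(config, "threshold_config"),
          "`config` must come from threshold_config().")
  records <- .ingest_specimens(records)
  if (nrow(records) == 0) {
    return(tibble::tibble(species = character(), n_females = integer(),
                          n_class1 = integer(), n_class2 = integer(),
                          n_class3 = integer(), n_class4 = integer(),
                          prop_androchrome = numeric(), dip_p = numeric()))
  }
  bad <- !(records$plumage_class %in% 1:4)
  .assert(!any(bad), "Plumage classes outside 1..4 in rows: ",
          paste(head(which(bad), 5), collapse = ", "),
          class = "flpscape_invalid_argument")
  females <- dplyr::filter(records, .data$sex == "female")
  min_class <- config$androchrome_min_class
  out <- females |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n_females = dplyr::n(),
      n_class1 = sum(.data$plumage_class == 1),
      n_class2 = sum(.data$plumage_class == 2),
      n_class3 = sum(.data$plumage_class == 3),
      n_class4 = sum(.data$plumage_class == 4),
      prop_androchrome = mean(.data$plumage_class >= min_class),
      .groups = "drop") |>
    dplyr::arrange(.data$species)
  # species with only non-female records still appear, with zero females
  all_sp <- sort(unique(records$species))
  missing <- setdiff(all_sp, out$species)
  if (length(missing) > 0) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      species = missing, n_females = 0L, n_class1 = 0L, n_class2 = 0L,
      n_class3 = 0L, n_class4 = 0L, prop_androchrome = NA_real_)) |>
      dplyr::arrange(.data$species)
  }
  out$dip_p <- NA_real_
  if (dip) {
    scores <- split(females$plumage_class, females$species)
    for (i in seq_len(nrow(out))) {
      sc <- scores[[out$species[i]]]
      if (!is.null(sc) && length(sc) >= 4) {
        out$dip_p[i] <- dip_test(sc, n_boot = n_boot, seed = seed)$p.value
      }
    }
  }
  out
}

#' Detection probability of a rare female morph
#'
#' Probability of sampling at least one androchrome female among `n_females`
#' independent draws when the morph has population frequency `morph_freq`:
#' `1 - (1 - morph_freq)^n_females`. With 18 females and a 10% morph this is
#' 0.85, the design basis of the absence threshold.
#'
#' @param n_females Number of sampled females (vectorised).
#' @param morph_freq Population frequency of the morph, in `[0, 1]`.
#' @return Detection probability in `[0, 1]`.
#' @examples
#' detection_probability(18, 0.10)
#' @export
detection_probability <- function(n_females, morph_freq) {
  .assert(all(is.finite(n_females)) && all(n_females >= 0),
          "`n_females` must be non-negative.")
  .assert(all(is.finite(morph_freq)) && all(morph_freq >= 0) &&
            all(morph_freq <= 1), "`morph_freq` must lie in [0, 1].",
          class = "flpscape_invalid_argument")
  1 - (1 - morph_freq)^n_females
}

#' Minimum sample size to detect a morph
#'
#' Smallest integer `n` with `detection_probability(n, morph_freq) >=
#' target_prob`.
#'
#' @param morph_freq Morph frequency in (0, 1].
#' @param target_prob Required detection probability in (0, 1).
#' @return The minimal sample size (integer).
#' @examples
#' required_sample_size(0.10, 0.849)   # 18, the classic design point
#' @export
required_sample_size <- function(morph_freq, target_prob) {
  .assert(is.numeric(morph_freq) && morph_freq > 0 && morph_freq <= 1,
          "`morph_freq` must be in (0, 1]; a zero-frequency morph can never ",
          "be detected.", class = "flpscape_no_solution")
  .assert(is.numeric(target_prob) && target_prob > 0 && target_prob < 1,
          "`target_prob` must be in (0, 1).")
  if (morph_freq == 1) return(1L)
  n <- ceiling(log1p(-target_prob) / log1p(-morph_freq))
  # guard the boundary against floating-point rounding
  while (n > 1 && detection_probability(n - 1, morph_freq) >= target_prob) n <- n - 1
  while (detection_probability(n, morph_freq) < target_prob) n <- n + 1
  as.integer(n)
}

#' Classify species as exhibiting or lacking FLP
#'
#' Applies the presence/absence decision rule to per-species summaries: FLP
#' when the androchrome proportion reaches `presence_min_prop` and (if
#' required) unimodality is rejected; otherwise no-FLP when at least
#' `absence_min_females` females were sampled (no-FLP species carry their
#' dichromatism flag); otherwise unclassified. A species meeting the
#' presence proportion whose dip p-value is unavailable is reported
#' unclassified with a warning.
#'
#' @param summaries Output of [summarize_species()].
#' @param dichromatism Tibble with columns `species` and `dichromatism`
#'   (values `dichromic`/`monochromic`), optionally `prior_flp` (logical):
#'   species previously reported as FLP are never classified as lacking it.
#' @param config A [threshold_config()].
#' @return A tibble with columns `species`, `status` (factor with levels
#'   `FLP`, `no_FLP_dichromic`, `monochromic`, `unclassified`),
#'   `prop_androchrome`, `n_females`, `dip_p`.
#' @examples
#' rec <- tibble::tibble(species = "a", sex = "female", sexing_method = "gonad",
#'                       plumage_class = rep(c(1, 4), c(15, 5)))
#' s <- summarize_species(rec, n_boot = 200)
#' classify_species(s, tibble::tibble(species = "a", dichromatism = "dichromic"))
#' @export
classify_species <- function(summaries, dichromatism,
                             config = threshold_config()) {
  .assert(inherits(config, "threshold_config"),
          "`config` must come from threshold_config().")
  .assert(all(c("species", "dichromatism") %in% names(dichromatism)),
          "`dichromatism` needs columns species and dichromatism.")
  .assert(all(dichromatism$dichromatism %in% c("dichromic", "monochromic")),
          "`dichromatism` values must be dichromic or monochromic.")
  d <- dplyr::left_join(summaries, dichromatism, by = "species")
  if (!"prior_flp" %in% names(d)) d$prior_flp <- FALSE
  d$prior_flp[is.na(d$prior_flp)] <- FALSE
  status <- character(nrow(d))
  warn_missing_dip <- character(0)
  for (i in seq_len(nrow(d))) {
    prop_ok <- !is.na(d$prop_androchrome[i]) &&
      d$prop_androchrome[i] >= config$presence_min_prop
    if (prop_ok && config$require_bimodality && is.na(d$dip_p[i])) {
      warn_missing_dip <- c(warn_missing_dip, d$species[i])
      status[i] <- "unclassified"
      next
    }
    bimodal_ok <- !config$require_bimodality ||
      (!is.na(d$dip_p[i]) && d$dip_p[i] < config$dip_alpha)
    if (prop_ok && bimodal_ok) {
      status[i] <- "FLP"
    } else if (d$n_females[i] >= config$absence_min_females && !d$prior_flp[i]) {
      status[i] <- if (identical(d$dichromatism[i], "monochromic"))
        "monochromic" else "no_FLP_dichromic"
    } else {
      status[i] <- "unclassified"
    }
  }
  if (length(warn_missing_dip) > 0) {
    warning("Presence proportion met but dip p-value unavailable (",
            "unclassified): ", paste(warn_missing_dip, collapse = ", "))
  }
  tibble::tibble(species = d$species,
                 status = factor(status, levels = c("FLP", "no_FLP_dichromic",
                                                    "monochromic",
                                                    "unclassified")),
                 prop_androchrome = d$prop_androchrome,
                 n_females = d$n_females, dip_p = d$dip_p)
}

#' Map classification statuses to the three Mk states
#'
#' @param classification A [classify_species()] result.
#' @return Named character vector (species -> state) over classified species;
#'   unclassified species are dropped.
#' @examples
#' cls <- tibble::tibble(species = c("a", "b"),
#'                       status = factor(c("FLP", "monochromic"),
#'                         levels = c("FLP", "no_FLP_dichromic",
#'                                    "monochromic", "unclassified")))
#' classification_to_states(cls)
#' @export
classification_to_states <- function(classification) {
  map <- c(FLP = "FLP", no_FLP_dichromic = "dichromic",
           monochromic = "monochromic")
  keep <- classification$status != "unclassified"
  setNames(map[as.character(classification$status[keep])],
           classification$species[keep])
}

#' Default eight-matrix sensitivity grid
#'
#' The factorial grid of presence proportions (5%, 10%), androchrome class
#' cuts (3, 4) and absence thresholds (10, 19 females) used for sensitivity
#' analyses of the classification.
#'
#' @return A tibble with columns `matrix_id`, `presence_min_prop`,
#'   `androchrome_min_class`, `absence_min_females`.
#' @examples
#' default_sensitivity_grid()
#' @export
default_sensitivity_grid <- function() {
  g <- tidyr::expand_grid(presence_min_prop = c(0.05, 0.10),
                          androchrome_min_class = c(3L, 4L),
                          absence_min_females = c(10L, 19L))
  g$matrix_id <- sprintf("p%02d_c%d_a%02d", round(100 * g$presence_min_prop),
                         g$androchrome_min_class, g$absence_min_females)
  dplyr::relocate(g, "matrix_id")
}

#' Sensitivity-grid classifications
#'
#' Classifies every species under each threshold configuration of a grid,
#' producing one classification table per matrix. Dip p-values depend only on
#' the raw female scores, so they are computed once and shared across the
#' grid.
#'
#' @param records Specimen tibble (see [summarize_species()]).
#' @param dichromatism Species-level dichromatism flags (see
#'   [classify_species()]).
#' @param config_grid Tibble of configurations, as from
#'   [default_sensitivity_grid()]; must have unique `matrix_id`s. Missing
#'   threshold columns fall back to [threshold_config()] defaults.
#' @param n_boot,seed Dip test parameters.
#' @return A tibble with columns `matrix_id`, `species`, `status`,
#'   `prop_androchrome`, `n_females`, `dip_p`.
#' @examples
#' study <- simulate_flp_study(simulation_spec(n_species = 10), seed = 1)
#' grids <- build_sensitivity_matrices(study$specimens, study$dichromatism,
#'                                     n_boot = 100)
#' dplyr::count(grids, matrix_id, status)
#' @export
build_sensitivity_matrices <- function(records, dichromatism,
                                       config_grid = default_sensitivity_grid(),
                                       n_boot = 500, seed = 1L) {
  .assert(nrow(config_grid) >= 1, "`config_grid` must be non-empty.")
  .assert(!anyDuplicated(config_grid$matrix_id),
          "Duplicate configuration labels in `config_grid`.",
          class = "flpscape_invalid_argument")
  defaults <- threshold_config()
  # dip p-values depend only on the raw scores: compute once, share
  dips <- summarize_species(records, defaults, dip = TRUE,
                            n_boot = n_boot, seed = seed)[, c("species", "dip_p")]
  purrr::pmap_dfr(config_grid, function(matrix_id, ...) {
    row <- list(...)
    cfg <- threshold_config(
      presence_min_prop = row$presence_min_prop %||% defaults$presence_min_prop,
      androchrome_min_class =
        row$androchrome_min_class %||% defaults$androchrome_min_class,
      absence_min_females =
        row$absence_min_females %||% defaults$absence_min_females,
      dip_alpha = row$dip_alpha %||% defaults$dip_alpha,
      require_bimodality =
        row$require_bimodality %||% defaults$require_bimodality)
    s <- summarize_species(records, cfg, dip = FALSE)
    s$dip_p <- dips$dip_p[match(s$species, dips$species)]
    cls <- classify_species(s, dichromatism, cfg)
    dplyr::bind_cols(tibble::tibble(matrix_id = matrix_id), cls)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
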