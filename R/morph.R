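#' Train a within-species discriminant colour axis
#'
#' Learns, for one species, the linear axis in patch-colour space that
#' separates androchrome males from Class-1 (fully heterochrome) females.
#' The 3 x n_patches channel features are standardised, reduced by principal
#' components (capped at `n_train - 2` components, keeping at least
#' `var_explained` of the variance) and a two-group linear discriminant is
#' fitted on the reduced space. The axis is oriented so androchrome males
#' project positively, with unit-norm weights; scores are then affinely
#' standardised so the male training centroid maps to +1 and the Class-1
#' female centroid to -1 (midpoint 0).
#'
#' The axis is `validated` when leave-one-out classification of the training
#' specimens is error-free and, additionally, the training groups' LD1
#' ranges do not overlap (`validation = "no_overlap"`) or the group means
#' are at least two pooled standard deviations apart (`"sd_separation"`).
#' The cross-validation guard matters because with few training specimens
#' and many colour features two groups are always separable in-sample.
#' Species whose axis fails validation should be excluded from downstream
#' analyses.
#'
#' @param colors Colour tibble (one row per specimen) with columns
#'   `specimen`, `species`, `sex`, `plumage_class` and `patchNN_R/G/B`
#'   channels.
#' @param species Species to train on.
#' @param min_group Minimum specimens per training group (males; Class-1
#'   females).
#' @param var_explained Minimum proportion of channel variance retained by
#'   the principal-component reduction.
#' @param max_components Optional explicit ceiling on the number of retained
#'   principal components.
#' @param validation Validation criterion (see above).
#' @return An object of class `"ld_axis"`: feature standardisation, PCA
#'   rotation, unit-norm discriminant weights, orientation/affine scaling and
#'   a `validated` flag. [tidy()] returns per-feature weights.
#' @examples
#' spec <- simulation_spec(n_species = 1)
#' cm <- simulate_color_morphometrics(spec, seed = 1)
#' ax <- train_discriminant(cm$colors, "sp001")
#' ax$validated
#' @export
train_discriminant <- function(colors, species, min_group = 3,
                               var_explained = 0.95, max_components = NULL,
                               validation = c("no_overlap", "sd_separation")) {
  validation <- match.arg(validation)
  dat <- dplyr::filter(colors, .data$species == !!species)
  .assert(nrow(dat) > 0, "No colour records for species `", species, "`.")
  feat_cols <- grep("^patch\\d+_[RGB]$", names(dat), value = TRUE)
  .assert(length(feat_cols) >= 3, "No patch channel columns found.")
  males <- dat$sex == "male" & dat$plumage_class >= 3
  f1 <- dat$sex == "female" & dat$plumage_class == 1
  .assert(sum(males) >= min_group && sum(f1) >= min_group,
          "Need at least ", min_group, " androchrome males and ", min_group,
          " Class-1 females; have ", sum(males), " and ", sum(f1), ".",
          class = "flpscape_insufficient_data")
  train <- dat[males | f1, , drop = FALSE]
  grp <- factor(ifelse(train$sex == "male", "male", "female1"),
                levels = c("female1", "male"))
  X <- as.matrix(train[, feat_cols])
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  keep <- scl > 1e-9
  .assert(any(keep), "All channel features are constant in the training set.",
          class = "flpscape_numerical_failure")
  Xs <- scale(X[, keep, drop = FALSE], center = ctr[keep], scale = scl[keep])
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  # cap components well below the training size: the discriminant needs a
  # stable pooled covariance, and one specimen per three is a conservative
  # ceiling (never above n_train - 2)
  cap <- min(max(1L, nrow(Xs) - 2L), max(2L, nrow(Xs) %/% 3L))
  if (!is.null(max_components)) cap <- min(cap, as.integer(max_components))
  varprop <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n_pc <- max(1L, min(cap, which(varprop >= var_explained)[1],
                      sum(pc$sdev > 1e-9)))
  Z <- pc$x[, seq_len(n_pc), drop = FALSE]
  ld <- tryCatch(
    MASS::lda(Z, grouping = grp),
    error = function(e) .assert(FALSE, "Discriminant failed (singular pooled ",
                                "covariance after reduction): ", conditionMessage(e),
                                class = "flpscape_numerical_failure"))
  w <- as.vector(ld$scaling[, 1])
  w <- w / sqrt(sum(w^2))                   # unit-norm weights in PC space
  raw <- as.vector(Z %*% w)
  if (mean(raw[grp == "male"]) < mean(raw[grp == "female1"])) {
    w <- -w
    raw <- -raw
  }
  m_m <- mean(raw[grp == "male"])
  m_f <- mean(raw[grp == "female1"])
  center <- (m_m + m_f) / 2
  scale_ <- (m_m - m_f) / 2
  .assert(scale_ > 1e-12, "Training group centroids coincide.",
          class = "flpscape_numerical_failure")
  scores <- (raw - center) / scale_
  # with ~16 training specimens in a dozen retained components any two groups
  # are linearly separable, so validation additionally demands error-free
  # leave-one-out classification (guards against overfitted axes)
  loo <- tryCatch(MASS::lda(Z, grouping = grp, CV = TRUE),
                  error = function(e) NULL)
  loo_ok <- !is.null(loo) && !anyNA(loo$class) && all(loo$class == grp)
  validated <- loo_ok && if (validation == "no_overlap") {
    max(scores[grp == "female1"]) < min(scores[grp == "male"])
  } else {
    pooled <- sqrt(mean(c(var(raw[grp == "male"]), var(raw[grp == "female1"]))))
    (m_m - m_f) >= 2 * pooled
  }
  structure(list(
    species = species, features = feat_cols, kept = feat_cols[keep],
    center = ctr[keep], scale = scl[keep],
    rotation = pc$rotation[, seq_len(n_pc), drop = FALSE],
    weights = w, ld_center = center, ld_scale = scale_,
    n_pc = n_pc, validated = validated, validation = validation,
    n_males = sum(males), n_class1_females = sum(f1),
    training_scores = tibble::tibble(specimen = train$specimen,
                                     group = as.character(grp),
                                     ld1 = scores)), class = "ld_axis")
}

#' @export
print.ld_axis <- function(x, ...) {
  cat("Discriminant colour axis for ", x$species, ": ", x$n_pc,
      " PCs, trained on ", x$n_males, " males / ", x$n_class1_females,
      " Class-1 females; validated = ", x$validated, "\n", sep = "")
  invisible(x)
}

#' Project specimens onto a trained LD1 axis
#'
#' Applies the stored standardisation, principal-component rotation and
#' discriminant weights, returning standardised LD1 scores (male training
#' centroid +1, Class-1 female centroid -1). Higher scores mean more
#' androchromic plumage.
#'
#' @param axis A validated [train_discriminant()] result.
#' @param colors Colour tibble (any species subset; must contain the axis's
#'   feature columns).
#' @param allow_unvalidated Project even if the axis failed validation.
#' @return A tibble `specimen`, `species`, `sex`, `plumage_class`, `ld1`.
#' @examples
#' spec <- simulation_spec(n_species = 1)
#' cm <- simulate_color_morphometrics(spec, seed = 1)
#' ax <- train_discriminant(cm$colors, "sp001")
#' head(project_ld1(ax, cm$colors))
#' @export
project_ld1 <- function(axis, colors, allow_unvalidated = FALSE) {
  .assert(inherits(axis, "ld_axis"), "`axis` must come from train_discriminant().")
  .assert(axis$validated || allow_unvalidated,
          "Axis for ", axis$species, " failed validation; set ",
          "`allow_unvalidated = TRUE` to project anyway.")
  missing <- setdiff(axis$kept, names(colors))
  .assert(length(missing) == 0, "Missing patch channel columns: ",
          paste(head(missing, 6), collapse = ", "),
          class = "flpscape_missing_data")
  X <- as.matrix(colors[, axis$kept])
  .assert(all(is.finite(X)), "Non-finite patch channel values.",
          class = "flpscape_missing_data")
  Xs <- scale(X, center = axis$center, scale = axis$scale)
  raw <- as.vector(Xs %*% axis$rotation %*% axis$weights)
  tibble::tibble(specimen = colors$specimen, species = colors$species,
                 sex = colors$sex, plumage_class = colors$plumage_class,
                 ld1 = (raw - axis$ld_center) / axis$ld_scale)
}

#' Relative morphometric measurements
#'
#' Centres a measurement within species: the specimen's value minus the
#' species mean over all measured specimens of both sexes. `bill_over_wing`
#' uses the ratio of bill to wing length.
#'
#' @param morpho Tibble with columns `specimen`, `species`, `bill_mm`,
#'   `wing_mm` (a `species` column is joined from `colors`-style tables if
#'   absent and a `species` argument is given).
#' @param measurement One of `"bill"`, `"wing"`, `"bill_over_wing"`.
#' @return The input tibble with columns `value` and `relative` added;
#'   relative values sum to zero within each species.
#' @examples
#' m <- tibble::tibble(specimen = c("a1", "a2"), species = "a",
#'                     bill_mm = c(10, 12), wing_mm = c(50, 52))
#' relative_measure(m, "bill")$relative
#' @export
relative_measure <- function(morpho,
                             measurement = c("bill", "wing", "bill_over_wing")) {
  measurement <- match.arg(measurement)
  .assert(all(c("species", "bill_mm", "wing_mm") %in% names(morpho)),
          "`morpho` needs columns species, bill_mm, wing_mm.")
  value <- switch(measurement,
    bill = morpho$bill_mm,
    wing = morpho$wing_mm,
    bill_over_wing = {
      .assert(all(morpho$wing_mm != 0), "Zero wing length: ratio undefined.",
              class = "flpscape_invalid_argument")
      morpho$bill_mm / morpho$wing_mm
    })
  morpho$value <- value
  morpho |>
    dplyr::group_by(.data$species) |>
    dplyr::mutate(relative = {
      .assert(dplyr::n() >= 2, "Need at least 2 measured specimens per species.")
      .data$value - mean(.data$value)
    }) |>
    dplyr::ungroup()
}

#' Regress relative morphometrics on androchromy (LD1)
#'
#' Ordinary least squares of the relative measurement on LD1 over female
#' specimens, with a two-sided t-test on the slope. Males inform the species
#' mean (through [relative_measure()]) and the axis training only.
#'
#' @param data Tibble with columns `ld1`, `relative` and `sex` (one species).
#' @param alpha Per-test significance level (see [bonferroni_alpha()]).
#' @param females_only Restrict the regression to females (default, matching
#'   the design where males define the androchrome pole).
#' @return A one-row tibble: `slope`, `se`, `t`, `p_value`, `n_females`,
#'   `significant`.
#' @examples
#' d <- tibble::tibble(ld1 = c(-1, -0.5, 0, 0.5, 1),
#'                     relative = c(2, 1.2, 0.1, -1, -2.1), sex = "female")
#' fit_morph_slope(d, alpha = 0.0031)
#' @export
fit_morph_slope <- function(data, alpha = 0.0031, females_only = TRUE) {
  .assert(all(c("ld1", "relative", "sex") %in% names(data)),
          "`data` needs columns ld1, relative, sex.")
  d <- if (females_only) dplyr::filter(data, .data$sex == "female") else data
  d <- d[is.finite(d$ld1) & is.finite(d$relative), , drop = FALSE]
  .assert(nrow(d) >= 3, "Need at least 3 female specimens with both values.",
          class = "flpscape_insufficient_data")
  .assert(sd(d$ld1) > 1e-12, "Zero LD1 variance: slope undefined.",
          class = "flpscape_undefined_slope")
  fit <- lm(relative ~ ld1, data = d)
  sm <- summary(fit)$coefficients
  tibble::tibble(slope = sm["ld1", "Estimate"], se = sm["ld1", "Std. Error"],
                 t = sm["ld1", "t value"], p_value = sm["ld1", "Pr(>|t|)"],
                 n_females = nrow(d), significant = sm["ld1", "Pr(>|t|)"] < alpha)
}

#' Bonferroni-corrected per-test significance level
#'
#' @param n_tests Number of tests in the family.
#' @param family_alpha Family-wise error rate.
#' @return The exact per-test level `family_alpha / n_tests`, with the
#'   two-significant-figure report attached as attribute `"rounded"`.
#' @examples
#' bonferroni_alpha(16, 0.05)          # 0.003125, reported as 0.0031
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  .assert(.is_count(n_tests), "`n_tests` must be a positive count.")
  .assert(is.numeric(family_alpha) && family_alpha > 0 && family_alpha < 1,
          "`family_alpha` must be in (0, 1).")
  out <- family_alpha / n_tests
  attr(out, "rounded") <- signif(out, 2)
  out
}

#' Per-species androchromy/morphometric slope table
#'
#' Runs the full within-species pipeline over all species present in the
#' colour table: train the discriminant axis, project LD1 scores, centre the
#' chosen measurement, and regress relative values on LD1 over females.
#' Species whose axis cannot be trained or fails validation are retained in
#' the table with `validated = FALSE` and a `note`.
#'
#' @param colors Colour tibble (see [train_discriminant()]).
#' @param morpho Morphometrics tibble with columns `specimen`, `bill_mm`,
#'   `wing_mm`.
#' @param measurement Passed to [relative_measure()].
#' @param alpha Per-test significance level.
#' @param ... Passed to [train_discriminant()].
#' @return A tibble with one row per species: `species`, `validated`,
#'   `slope`, `se`, `p_value`, `n_females`, `significant`, `note`.
#' @examples
#' spec <- simulation_spec(n_species = 2, planted_slope = -2.5)
#' cm <- simulate_color_morphometrics(spec, seed = 1)
#' androchromy_slopes(cm$colors, cm$morpho)
#' @export
androchromy_slopes <- function(colors, morpho, measurement = "bill",
                               alpha = 0.0031, ...) {
  .assert("specimen" %in% names(morpho), "`morpho` needs a specimen column.")
  sp_list <- sort(unique(colors$species))
  purrr::map_dfr(sp_list, function(sp) {
    base <- tibble::tibble(species = sp, validated = FALSE, slope = NA_real_,
                           se = NA_real_, p_value = NA_real_,
                           n_females = NA_integer_, significant = NA,
                           note = NA_character_)
    ax <- tryCatch(train_discriminant(colors, sp, ...), error = function(e) e)
    if (inherits(ax, "error")) {
      base$note <- conditionMessage(ax)
      return(base)
    }
    if (!ax$validated) {
      base$note <- "axis failed validation"
      return(base)
    }
    sub <- dplyr::filter(colors, .data$species == sp)
    proj <- project_ld1(ax, sub)
    m <- dplyr::inner_join(proj,
                           morpho[, c("specimen", "bill_mm", "wing_mm")],
                           by = "specimen")
    m <- relative_measure(m, measurement)
    res <- tryCatch(fit_morph_slope(m, alpha = alpha), error = function(e) e)
    if (inherits(res, "error")) {
      base$validated <- TRUE
      base$note <- conditionMessage(res)
      return(base)
    }
    tibble::tibble(species = sp, validated = TRUE, slope = res$slope,
                   se = res$se, p_value = res$p_value,
                   n_females = as.integer(res$n_females),
                   significant = res$significant, note = NA_character_)
  })
}

#' Blomberg's K phylogenetic signal
#'
#' Computes Blomberg's K for a continuous trait on a tree: the ratio of the
#' observed mean squared error of tip values around the phylogenetically
#' corrected mean (relative to the variance of phylogenetically standardised
#' contrasts, via the Brownian covariance quadratic form) to its Brownian
#' expectation from trace identities. K is about 1 under Brownian motion and
#' below 1 when close relatives resemble each other less than Brownian
#' motion predicts. The p-value is the fraction of tip-label permutations
#' with K at least as large as observed (one-tailed for signal).
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param values Named numeric vector of trait values (names are tip labels;
#'   at least 4 shared species). The tree is pruned to the shared species.
#' @param n_perm Number of tip-label permutations.
#' @param seed Integer seed for the permutations.
#' @return A one-row tibble: `K`, `p_value`, `n_species`, `n_perm`.
#' @examples
#' tr <- simulate_yule_tree(20, seed = 1)
#' y <- setNames(ape::rTraitCont(tr), tr$tip.label)
#' blomberg_k(tr, y, n_perm = 99, seed = 1)
#' @export
blomberg_k <- function(tree, values, n_perm = 999, seed = 1L) {
  .assert(is.numeric(values) && !is.null(names(values)),
          "`values` must be a named numeric vector.")
  shared <- intersect(tree$tip.label, names(values)[is.finite(values)])
  .assert(length(shared) >= 4, "Need at least 4 species shared between tree ",
          "and values.", class = "flpscape_insufficient_data")
  tr <- prune_to_data(tree, shared)
  y <- values[tr$tip.label]
  .assert(sd(y) > 1e-12, "Constant trait: K undefined.",
          class = "flpscape_undefined_k")
  V <- ape::vcv.phylo(tr)
  Vi <- solve(V)
  n <- length(y)
  one <- rep(1, n)
  denom_exp <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  k_of <- function(yy) {
    a <- sum(Vi %*% yy) / sum(Vi)
    mse0 <- sum((yy - a)^2) / (n - 1)
    mse <- as.numeric(t(yy - a) %*% Vi %*% (yy - a)) / (n - 1)
    (mse0 / mse) / denom_exp
  }
  K <- k_of(y)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) k_of(sample(y)), numeric(1))
  })
  tibble::tibble(K = K, p_value = mean(perm >= K),
                 n_species = n, n_perm = as.integer(n_perm))
}
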