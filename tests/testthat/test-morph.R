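make_color_sim <- function(n_species = 1, planted_slope = 0, sep = 80,
                           noise = 8, seed = 1) {
  spec <- simulation_spec(n_species = n_species, planted_slope = planted_slope,
                          color_separation = sep, color_noise = noise)
  simulate_color_morphometrics(spec, seed = seed)
}

test_that("the discriminant axis separates, orients and validates correctly", {
  cm <- make_color_sim(seed = 3)
  ax <- train_discriminant(cm$colors, "sp001")
  expect_true(ax$validated)
  ts <- ax$training_scores
  expect_gt(min(ts$ld1[ts$group == "male"]), max(ts$ld1[ts$group == "female1"]))
  expect_equal(mean(ts$ld1[ts$group == "male"]), 1, tolerance = 1e-8)
  expect_equal(mean(ts$ld1[ts$group == "female1"]), -1, tolerance = 1e-8)
  expect_equal(sum(ax$weights^2), 1, tolerance = 1e-10)   # unit-norm weights
})

test_that("the axis direction matches a hand-computed Fisher discriminant", {
  cm <- make_color_sim(seed = 5)
  ax <- train_discriminant(cm$colors, "sp001")
  # recompute: standardise, rotate, then w ~ Sw^-1 (mu_m - mu_f)
  dat <- dplyr::filter(cm$colors, species == "sp001")
  train <- dat[(dat$sex == "male" & dat$plumage_class >= 3) |
                 (dat$sex == "female" & dat$plumage_class == 1), ]
  X <- scale(as.matrix(train[, ax$kept]), center = ax$center, scale = ax$scale)
  Z <- X %*% ax$rotation
  male <- train$sex == "male"
  Sw <- ((sum(male) - 1) * cov(Z[male, , drop = FALSE]) +
           (sum(!male) - 1) * cov(Z[!male, , drop = FALSE])) /
    (nrow(Z) - 2)
  w_ref <- solve(Sw, colMeans(Z[male, , drop = FALSE]) -
                   colMeans(Z[!male, , drop = FALSE]))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  alignment <- abs(sum(w_ref * ax$weights))
  expect_gt(alignment, 1 - 1e-6)
})

test_that("duplicating every training specimen leaves the axis unchanged", {
  cm <- make_color_sim(seed = 7)
  # fix the reduction size so the comparison isolates the discriminant
  ax1 <- train_discriminant(cm$colors, "sp001", max_components = 3)
  doubled <- dplyr::bind_rows(cm$colors,
                              dplyr::mutate(cm$colors,
                                            specimen = paste0(specimen, "_b")))
  ax2 <- train_discriminant(doubled, "sp001", max_components = 3)
  l1 <- tidy(ax1)$loading
  l2 <- tidy(ax2)$loading
  expect_gt(abs(sum(l1 * l2) / sqrt(sum(l1^2) * sum(l2^2))), 1 - 1e-6)
})

test_that("projection honours orientation, linearity and missing columns", {
  cm <- make_color_sim(seed = 9)
  ax <- train_discriminant(cm$colors, "sp001")
  proj <- project_ld1(ax, cm$colors)
  expect_gt(mean(proj$ld1[proj$sex == "male"]), 0)
  expect_lt(mean(proj$ld1[proj$plumage_class == 1 & proj$sex == "female"]), 0)

  # midpoint of the two training centroids scores ~0 by linearity
  train_ids <- ax$training_scores
  cols <- ax$kept
  m_mean <- colMeans(cm$colors[cm$colors$specimen %in%
                                 train_ids$specimen[train_ids$group == "male"], cols])
  f_mean <- colMeans(cm$colors[cm$colors$specimen %in%
                                 train_ids$specimen[train_ids$group == "female1"], cols])
  mid <- cm$colors[1, ]
  mid[, cols] <- as.list((m_mean + f_mean) / 2)
  expect_lt(abs(project_ld1(ax, mid)$ld1), 1e-8)

  expect_error(project_ld1(ax, dplyr::select(cm$colors, -dplyr::all_of(cols[1]))),
               class = "flpscape_missing_data")

  cm0 <- make_color_sim(sep = 0, seed = 11)
  ax0 <- train_discriminant(cm0$colors, "sp001")
  expect_false(ax0$validated)
  expect_error(project_ld1(ax0, cm0$colors), "validation")
  expect_s3_class(project_ld1(ax0, cm0$colors, allow_unvalidated = TRUE),
                  "tbl_df")
})

test_that("training group sizes are enforced", {
  cm <- make_color_sim(seed = 13)
  few <- dplyr::filter(cm$colors, !(sex == "male" &
                                      dplyr::row_number() %in% 1:9))
  expect_error(train_discriminant(few, "sp001"),
               class = "flpscape_insufficient_data")
})

test_that("relative measures centre within species", {
  m <- tibble::tibble(specimen = c("a1", "a2", "b1", "b2", "b3"),
                      species = c("a", "a", "b", "b", "b"),
                      bill_mm = c(10, 12, 20, 20, 20),
                      wing_mm = c(50, 52, 60, 61, 62))
  r <- relative_measure(m, "bill")
  expect_equal(r$relative[r$species == "a"], c(-1, 1))
  expect_equal(r$relative[r$species == "b"], c(0, 0, 0))
  expect_lt(abs(sum(r$relative)), 1e-10)

  rw <- relative_measure(m, "bill_over_wing")
  expect_equal(rw$value, m$bill_mm / m$wing_mm)
  m$wing_mm[1] <- 0
  expect_error(relative_measure(m, "bill_over_wing"),
               class = "flpscape_invalid_argument")
})

test_that("morph slopes equal the closed-form OLS ratio", {
  set.seed(17)
  d <- tibble::tibble(ld1 = runif(20, -1, 1), sex = "female")
  d$relative <- -1.4 * d$ld1 + rnorm(20, sd = 0.3)
  res <- fit_morph_slope(d, alpha = 0.05)
  ref <- ols_slope(d$ld1, d$relative)
  expect_equal(res$slope, ref$slope, tolerance = 1e-10)

  expect_error(fit_morph_slope(d[1:2, ]), class = "flpscape_insufficient_data")
  d0 <- tibble::tibble(ld1 = rep(0.5, 5), relative = rnorm(5), sex = "female")
  expect_error(fit_morph_slope(d0), class = "flpscape_undefined_slope")
})

test_that("Bonferroni levels are exact with a two-significant-figure report", {
  a <- bonferroni_alpha(16, 0.05)
  expect_equal(as.numeric(a), 0.003125)
  expect_equal(attr(a, "rounded"), 0.0031)
  expect_equal(as.numeric(bonferroni_alpha(1, 0.05)), 0.05)
  expect_equal(as.numeric(bonferroni_alpha(10, 0.05)), 0.005)
})

test_that("Blomberg's K matches an independent implementation exactly", {
  for (seed in c(2, 3)) {
    tr <- simulate_yule_tree(25, 1, seed = seed)
    y <- withr::with_seed(seed, setNames(ape::rTraitCont(tr), tr$tip.label))
    mine <- blomberg_k(tr, y, n_perm = 99, seed = 1)
    expect_equal(mine$K, as.numeric(picante::Kcalc(y[tr$tip.label], tr)),
                 tolerance = 1e-10)
  }
})

test_that("K is invariant to affine trait transformations", {
  tr <- simulate_yule_tree(20, 1, seed = 23)
  y <- withr::with_seed(1, setNames(ape::rTraitCont(tr), tr$tip.label))
  k1 <- blomberg_k(tr, y, n_perm = 99, seed = 5)
  k2 <- blomberg_k(tr, 3.7 * y + 11, n_perm = 99, seed = 5)
  expect_equal(k1$K, k2$K, tolerance = 1e-10)
  expect_equal(k1$p_value, k2$p_value)
  expect_error(blomberg_k(tr, setNames(rep(1, 20), tr$tip.label)),
               class = "flpscape_undefined_k")
  expect_error(blomberg_k(tr, setNames(1:3, tr$tip.label[1:3])),
               class = "flpscape_insufficient_data")
})

test_that("shuffled traits lose phylogenetic signal", {
  tr <- simulate_yule_tree(60, 1, seed = 29)
  y <- withr::with_seed(2, setNames(ape::rTraitCont(tr), tr$tip.label))
  y_shuf <- withr::with_seed(3, setNames(sample(y), tr$tip.label))
  ks <- blomberg_k(tr, y_shuf, n_perm = 199, seed = 1)
  expect_lt(ks$K, 1)
  expect_gt(ks$p_value, 0.05)
})

test_that("the species battery flags exactly the planted slopes", {
  slopes <- c(-2.5, 1.7, rep(0, 14))
  spec <- simulation_spec(n_species = 16, color_noise = 4)
  st <- tibble::tibble(species = sprintf("sp%03d", 1:16),
                       planted_slope = slopes)
  cm <- simulate_color_morphometrics(spec, seed = 37, species_table = st)
  out <- androchromy_slopes(cm$colors, cm$morpho,
                            alpha = as.numeric(bonferroni_alpha(16, 0.05)))
  flagged <- out$species[which(out$significant)]
  expect_setequal(flagged, c("sp001", "sp002"))
  expect_lt(out$slope[out$species == "sp001"], 0)
  expect_gt(out$slope[out$species == "sp002"], 0)
})
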