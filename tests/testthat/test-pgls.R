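test_that("the Brownian covariance encodes shared path lengths", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  V <- brownian_vcv(tr)
  expect_equal(V["A", "B"], 1)
  expect_equal(V["A", "C"], 0)
  expect_equal(V["A", "A"], 2)

  star <- ape::stree(4)
  star$edge.length <- rep(1, 4)
  Vs <- brownian_vcv(star)
  expect_equal(unclass(Vs), diag(4), ignore_attr = TRUE)

  for (seed in 1:3) {
    Vy <- brownian_vcv(simulate_yule_tree(30, 1, seed = seed))
    expect_gte(min(eigen(Vy, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }
  bad <- tr
  bad$edge.length[1] <- -0.1
  expect_error(brownian_vcv(bad), class = "flpscape_invalid_argument")
})

test_that("identity covariance reduces PGLS exactly to OLS", {
  set.seed(5)
  n <- 40
  d <- tibble::tibble(species = paste0("s", 1:n), x1 = rnorm(n),
                      x2 = rbinom(n, 1, 0.4))
  d$y <- 1 + 0.5 * d$x1 - 0.8 * d$x2 + rnorm(n)
  V <- diag(n)
  dimnames(V) <- list(d$species, d$species)
  fit <- pgls_fit(d, y ~ x1 + x2, vcv = V)
  ref <- summary(lm(y ~ x1 + x2, data = d))$coefficients
  expect_equal(tidy(fit)$estimate, unname(ref[, 1]), tolerance = 1e-10)
  expect_equal(tidy(fit)$std_error, unname(ref[, 2]), tolerance = 1e-10)
  expect_equal(tidy(fit)$p_value, unname(ref[, 4]), tolerance = 1e-10)
})

test_that("rescaling the covariance leaves estimates and tests unchanged", {
  tr <- simulate_yule_tree(30, 1, seed = 7)
  d <- tibble::tibble(species = tr$tip.label,
                      y = withr::with_seed(1, ape::rTraitCont(tr)),
                      x = withr::with_seed(2, rnorm(30)))
  V <- brownian_vcv(tr)
  f1 <- pgls_fit(d, y ~ x, vcv = V)
  f2 <- pgls_fit(d, y ~ x, vcv = 7.3 * V)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-10)
  expect_equal(tidy(f1)$statistic, tidy(f2)$statistic, tolerance = 1e-10)
  expect_equal(tidy(f1)$p_value, tidy(f2)$p_value, tolerance = 1e-10)
})

test_that("consistent row permutations leave the fit unchanged", {
  tr <- simulate_yule_tree(25, 1, seed = 9)
  d <- tibble::tibble(species = tr$tip.label,
                      y = withr::with_seed(3, ape::rTraitCont(tr)),
                      x = withr::with_seed(4, rnorm(25)))
  f1 <- pgls_fit(d, y ~ x, tree = tr)
  f2 <- pgls_fit(d[sample(25), ], y ~ x, tree = tr)
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-10)
})

test_that("PGLS agrees with an independent GLS implementation", {
  tr <- simulate_yule_tree(35, 1, seed = 13)
  d <- tibble::tibble(species = tr$tip.label,
                      y = withr::with_seed(5, ape::rTraitCont(tr)),
                      x = withr::with_seed(6, rnorm(35)))
  fit <- pgls_fit(d, y ~ x, tree = tr)
  ref <- nlme::gls(y ~ x, data = as.data.frame(d),
                   correlation = ape::corBrownian(1, tr, form = ~species),
                   method = "ML")
  expect_equal(tidy(fit)$estimate, unname(coef(ref)), tolerance = 1e-8)
  refsum <- summary(ref)$tTable
  expect_equal(tidy(fit)$statistic, unname(refsum[, "t-value"]),
               tolerance = 1e-6)
})

test_that("Brownian-error regression recovers planted coefficients", {
  tr <- simulate_yule_tree(60, 1, seed = 15)
  V <- brownian_vcv(tr)
  ch <- chol(V)
  beta <- c(0.4, -0.9)
  ests <- withr::with_seed(8, {
    t(replicate(60, {
      x1 <- rnorm(60)
      x2 <- rnorm(60)
      e <- as.vector(t(ch) %*% rnorm(60, sd = 0.5))
      d <- tibble::tibble(species = tr$tip.label, x1 = x1, x2 = x2,
                          y = beta[1] * x1 + beta[2] * x2 + e)
      tidy(pgls_fit(d, y ~ x1 + x2, vcv = V))$estimate[2:3]
    }))
  })
  se <- apply(ests, 2, sd) / sqrt(nrow(ests))
  expect_lt(abs(mean(ests[, 1]) - beta[1]), 4 * se[1] + 0.01)
  expect_lt(abs(mean(ests[, 2]) - beta[2]), 4 * se[2] + 0.01)
})

test_that("rank-deficient designs raise a collinearity error", {
  tr <- simulate_yule_tree(20, 1, seed = 17)
  d <- tibble::tibble(species = tr$tip.label,
                      y = withr::with_seed(9, rnorm(20)),
                      x1 = 1:20, x2 = 2 * (1:20))
  expect_error(pgls_fit(d, y ~ x1 + x2, tree = tr),
               class = "flpscape_collinearity")
})

test_that("the FLP model wrapper filters, prunes and annotates", {
  tr <- simulate_yule_tree(60, 1, seed = 19)
  st <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 19)
  cov <- simulate_covariates(tr, st$tip_states, seed = 19)
  fit <- run_flp_models(cov, tr, "social")
  expect_s3_class(fit, "pgls_fit")
  expect_equal(attr(fit, "model"), "social")
  expect_setequal(tidy(fit)$term,
                  c("(Intercept)", "migratory", "dominance", "body_length"))
  fitc <- run_flp_models(cov, tr, "climate", exclude_monochromic = TRUE)
  expect_equal(fitc$n, sum(cov$chromatism != "monochromic"))

  # with no monochromic species exclusion is a no-op
  cov2 <- dplyr::mutate(cov, chromatism = ifelse(chromatism == "monochromic",
                                                 "dichromic", chromatism))
  f_a <- run_flp_models(cov2, tr, "social", exclude_monochromic = FALSE)
  f_b <- run_flp_models(cov2, tr, "social", exclude_monochromic = TRUE)
  expect_equal(tidy(f_a), tidy(f_b))

  expect_error(run_flp_models(cov[1:5, ], tr, "social"),
               class = "flpscape_insufficient_data")
})

test_that("planted covariate effects are recovered with the right sign", {
  hits <- withr::with_seed(21, {
    sapply(1:10, function(i) {
      tr <- simulate_yule_tree(80, 1, seed = 1000 + i)
      st <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 1000 + i)
      cov <- simulate_covariates(tr, st$tip_states,
                                 effects = c(migratory = -1.5), seed = 2000 + i)
      fit <- run_flp_models(cov, tr, "social", exclude_monochromic = TRUE)
      co <- tidy(fit)
      co$estimate[co$term == "migratory"] < 0
    })
  })
  expect_gte(mean(hits), 0.8)
})
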