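#' Brownian-motion covariance matrix of a tree
#'
#' The expected covariance of a Brownian trait between two tips equals the
#' shared branch length from the root to their most recent common ancestor;
#' the diagonal holds root-to-tip depths. This is the error-covariance
#' kernel equivalent to analysing phylogenetically independent contrasts.
#'
#' @param tree A rooted `phylo` tree with non-negative branch lengths.
#' @return A symmetric positive semi-definite species-by-species matrix.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
#' brownian_vcv(tr)
#' @export
brownian_vcv <- function(tree) {
  .assert(inherits(tree, "phylo") && !is.null(tree$edge.length),
          "`tree` must be a phylo object with branch lengths.")
  .assert(all(tree$edge.length >= 0), "Negative branch lengths.",
          class = "flpscape_invalid_argument")
  ape::vcv.phylo(tree)
}

#' Phylogenetic generalised least squares
#'
#' Fits `y = X b + e` with `e ~ N(0, sigma^2 V)` by generalised least
#' squares: `b = (X' V^-1 X)^-1 X' V^-1 y`, residual variance from the
#' V-weighted residual sum of squares, standard errors from
#' `sigma^2 (X' V^-1 X)^-1`, and two-sided p-values from the t distribution
#' with `n - p` degrees of freedom. With `V` the identity this reduces
#' exactly to ordinary least squares. Computation goes through the Cholesky
#' factor of `V` for numerical stability; a tiny ridge is added (with a
#' message) if `V` is numerically singular.
#'
#' @param data Tibble containing the response and predictors, one row per
#'   species, with a `species` column aligning rows to `vcv`.
#' @param formula Model formula, e.g. `flp ~ migratory + body_length`.
#' @param tree Tree from which the Brownian covariance is built (ignored
#'   when `vcv` is given).
#' @param vcv Optional covariance matrix with dimnames matching `species`.
#' @return An object of class `"pgls_fit"` with the coefficient table,
#'   `sigma2`, `n`, `df_residual` and bookkeeping. [tidy()] returns the
#'   coefficients, [glance()] the fit summary.
#' @examples
#' tr <- simulate_yule_tree(30, seed = 1)
#' d <- tibble::tibble(species = tr$tip.label,
#'                     y = ape::rTraitCont(tr), x = rnorm(30))
#' tidy(pgls_fit(d, y ~ x, tree = tr))
#' @export
pgls_fit <- function(data, formula, tree = NULL, vcv = NULL) {
  .assert("species" %in% names(data), "`data` needs a species column.")
  .assert(!anyDuplicated(data$species), "Duplicate species rows.")
  if (is.null(vcv)) {
    .assert(!is.null(tree), "Supply either `tree` or `vcv`.")
    tr <- prune_to_data(tree, data$species)
    vcv <- brownian_vcv(tr)
  }
  .assert(all(data$species %in% rownames(vcv)),
          "Species missing from the covariance matrix.")
  V <- vcv[data$species, data$species]
  mf <- stats::model.frame(formula, data = data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, data = mf)
  n <- nrow(X)
  p <- ncol(X)
  qrX <- qr(X)
  .assert(qrX$rank == p, "Rank-deficient design; collinear columns: ",
          paste(colnames(X)[qrX$pivot[-seq_len(qrX$rank)]], collapse = ", "),
          class = "flpscape_collinearity")
  .assert(n > p, "More coefficients than species.")
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    message("Covariance numerically singular; adding ridge 1e-10.")
    ch <- chol(V + diag(1e-10 * mean(diag(V)), n))
  }
  # whiten: solve t(ch) %*% z = . ; then OLS on transformed data equals GLS
  yt <- backsolve(ch, y, transpose = TRUE)
  Xt <- backsolve(ch, X, transpose = TRUE)
  fit <- stats::lm.fit(Xt, yt)
  b <- fit$coefficients
  rss <- sum(fit$residuals^2)
  df <- n - p
  sigma2 <- rss / df
  XtX_inv <- chol2inv(qr.R(qr(Xt)))
  se <- sqrt(sigma2 * diag(XtX_inv))
  tval <- b / se
  pval <- 2 * pt(abs(tval), df, lower.tail = FALSE)
  coefs <- tibble::tibble(term = colnames(X), estimate = unname(b),
                          std_error = unname(se), statistic = unname(tval),
                          p_value = unname(pval))
  structure(list(coefficients = coefs, sigma2 = sigma2, n = n,
                 df_residual = df, formula = formula,
                 residuals_whitened = fit$residuals,
                 fitted = as.vector(X %*% b), species = data$species,
                 logLik = -0.5 * (n * log(2 * pi * rss / n) + n +
                                    2 * sum(log(diag(ch))))),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Phylogenetic GLS fit:", deparse(x$formula), "\n")
  cat("  n =", x$n, " sigma^2 =", format(x$sigma2, digits = 4), "\n")
  print(as.data.frame(x$coefficients), digits = 4, row.names = FALSE)
  invisible(x)
}

#' Phylogenetic regressions of FLP on socioecological covariates
#'
#' Fits the binary FLP indicator (treated as a 0/1 Gaussian response under
#' Brownian error covariance) against either the social predictors
#' (`migratory + dominance + body_length`) or the four climate predictors,
#' optionally excluding sexually monochromic species so the contrast is FLP
#' versus dichromic-without-FLP. The tree is pruned to the analysed species.
#'
#' @param covariates Tibble of species-level covariates (see
#'   [simulate_covariates()] for the schema).
#' @param tree A rooted `phylo` tree containing the analysed species.
#' @param model `"social"` or `"climate"`.
#' @param exclude_monochromic Drop species with `chromatism == "monochromic"`.
#' @return A `"pgls_fit"` with attributes `model` and `excluded_monochromic`.
#' @examples
#' tr <- simulate_yule_tree(30, seed = 1)
#' st <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 1)
#' cov <- simulate_covariates(tr, st$tip_states, seed = 1)
#' tidy(run_flp_models(cov, tr, "social"))
#' @export
run_flp_models <- function(covariates, tree, model = c("social", "climate"),
                           exclude_monochromic = FALSE) {
  model <- match.arg(model)
  preds <- switch(model,
    social = c("migratory", "dominance", "body_length"),
    climate = c("mean_temperature", "mean_precipitation",
                "temperature_predictability", "precipitation_predictability"))
  .assert(all(c("species", "flp", "chromatism", preds) %in% names(covariates)),
          "Covariate table lacks required columns for the ", model, " model.")
  d <- covariates[complete.cases(covariates[, c("flp", preds)]), , drop = FALSE]
  if (exclude_monochromic) d <- dplyr::filter(d, .data$chromatism != "monochromic")
  d <- dplyr::filter(d, .data$species %in% tree$tip.label)
  .assert(nrow(d) >= 10, "Fewer than 10 species after filtering.",
          class = "flpscape_insufficient_data")
  form <- stats::reformulate(preds, response = "flp")
  fit <- pgls_fit(d, form, tree = tree)
  attr(fit, "model") <- model
  attr(fit, "excluded_monochromic") <- exclude_monochromic
  fit
}
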