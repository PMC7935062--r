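#' Tidy an Mk model fit
#'
#' @param x A [fit_mk_model()] result.
#' @param ... Unused.
#' @return A tibble with one row per free rate: `rate`, `estimate`.
#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(rate = names(x$rates), estimate = unname(x$rates))
}

#' Glance at an Mk model fit
#'
#' @param x A [fit_mk_model()] result.
#' @param ... Unused.
#' @return A one-row tibble: `model`, `logL`, `k`, `n_tips`, `aicc`,
#'   `converged`.
#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, logL = x$logL, k = x$k, n_tips = x$n_tips,
                 aicc = x$aicc, converged = x$converged)
}

#' Tidy a marginal ancestral-state reconstruction
#'
#' @param x A [marginal_asr()] result.
#' @param ... Unused.
#' @return The per-node probability tibble.
#' @export
tidy.mk_asr <- function(x, ...) x$prob

#' Tidy a phylogenetic GLS fit
#'
#' @param x A [pgls_fit()] result.
#' @param ... Unused.
#' @return The coefficient tibble (`term`, `estimate`, `std_error`,
#'   `statistic`, `p_value`).
#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' Glance at a phylogenetic GLS fit
#'
#' @param x A [pgls_fit()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `sigma2`, `df_residual`, `logLik`.
#' @export
glance.pgls_fit <- function(x, ...) {
  tibble::tibble(n = x$n, sigma2 = x$sigma2, df_residual = x$df_residual,
                 logLik = x$logLik)
}

#' Tidy a discriminant colour axis
#'
#' @param x A [train_discriminant()] result.
#' @param ... Unused.
#' @return A tibble mapping each retained colour feature to its loading on
#'   the (unit-norm) discriminant axis, via the PCA rotation.
#' @export
tidy.ld_axis <- function(x, ...) {
  loading <- as.vector(x$rotation %*% x$weights)
  tibble::tibble(feature = x$kept, loading = loading)
}
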