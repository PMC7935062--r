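#' Hartigan's dip statistic
#'
#' The dip of a sample is the minimax sup-distance between its empirical CDF
#' and the nearest unimodal CDF (convex below the mode, concave above it,
#' with a jump permitted at the mode). Large values indicate departure from
#' unimodality. For n distinct values the dip lies in `[1/(2n), 1/4]`; heavy
#' ties can push it below `1/(2n)` (a point mass has dip 0).
#'
#' The statistic is computed to near machine precision by bisection on the
#' half-width of a band around the empirical CDF, testing at each width
#' whether a unimodal CDF can thread the band (greatest-convex-minorant /
#' least-concave-majorant feasibility with junction constraints at the mode).
#'
#' @param x Numeric vector with at least 4 finite values.
#' @return The dip statistic (a scalar).
#' @examples
#' dip_statistic(c(0, 0, 0, 1, 1, 1))   # maximal: 0.25
#' dip_statistic(1:10)                  # minimal for n = 10: 0.05
#' @export
dip_statistic <- function(x) {
  .assert(is.numeric(x), "`x` must be numeric.")
  x <- x[is.finite(x)]
  .assert(length(x) >= 4, "Need at least 4 finite values.",
          class = "flpscape_insufficient_data")
  .dip_stat_cpp(x)
}

#' Bootstrap dip test of unimodality
#'
#' Calibrates the dip statistic against samples of the same size from the
#' uniform distribution (the conventional, asymptotically least-favourable
#' unimodal null): the p-value is the fraction of `n_boot` uniform samples
#' whose dip is at least the observed dip. Because ordinal plumage scores are
#' heavily tied, tied inputs are (by default) jittered uniformly on
#' `[value - 0.5, value + 0.5]` with a seeded draw before the dip is taken,
#' which restores the continuous-sample calibration while preserving class
#' separation.
#'
#' @param x Numeric vector with at least 4 finite values.
#' @param n_boot Number of uniform bootstrap samples (at least 100).
#' @param seed Integer seed controlling both the jitter and the bootstrap.
#' @param jitter `"ties"` (default: jitter only when ties are present),
#'   `"never"`, or `"always"`.
#' @return An object of class `"htest"` with the observed `statistic` (dip)
#'   and bootstrap `p.value`.
#' @examples
#' dip_test(c(rep(1, 20), rep(4, 20)), n_boot = 200, seed = 1)$p.value
#' @export
dip_test <- function(x, n_boot = 500, seed = 1L,
                     jitter = c("ties", "never", "always")) {
  jitter <- match.arg(jitter)
  .assert(is.numeric(x), "`x` must be numeric.")
  x <- x[is.finite(x)]
  n <- length(x)
  .assert(n >= 4, "Need at least 4 finite values.",
          class = "flpscape_insufficient_data")
  .assert(.is_count(n_boot, min = 100), "`n_boot` must be at least 100.")
  withr::with_seed(seed, {
    do_jitter <- switch(jitter, always = TRUE, never = FALSE,
                        ties = anyDuplicated(x) > 0)
    # jitter the sorted sample so the result is invariant to input order
    xx <- if (do_jitter) sort(x) + runif(n, -0.5, 0.5) else x
    obs <- .dip_stat_cpp(xx)
    null <- .dip_stat_many_cpp(matrix(runif(n * n_boot), nrow = n))
    p <- mean(null >= obs)
    structure(list(
      statistic = c(D = obs), p.value = p,
      parameter = c(n = n, n_boot = n_boot),
      alternative = "non-unimodal (multimodal) distribution",
      method = paste0("Bootstrap dip test of unimodality",
                      if (do_jitter) " (tied values jittered)"),
      data.name = deparse(substitute(x))), class = "htest")
  })
}
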