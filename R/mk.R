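#' Build an Mk instantaneous rate matrix
#'
#' Constructs the rate matrix of a continuous-time Markov (Mk) model of a
#' discrete character under one of the standard constraint schemes: `ER`
#' (equal rates, 1 free rate), `SYM` (symmetric, k(k-1)/2 free rates) or
#' `ARD` (all rates different, k(k-1) free rates). Diagonals are set to minus
#' the row sums.
#'
#' For `SYM` the rates fill the upper triangle column-wise (the
#' `combn(states, 2)` order); for `ARD` they fill the off-diagonals row-wise.
#' Rate names in the returned matrix's `"rate_names"` attribute record the
#' mapping.
#'
#' @param model One of `"ER"`, `"SYM"`, `"ARD"`.
#' @param rates Positive numeric vector of free rates with length 1,
#'   k(k-1)/2 or k(k-1) respectively.
#' @param states Character vector of state labels (default: the three plumage
#'   states `monochromic`, `dichromic`, `FLP`).
#' @return A k x k matrix of class `"q_matrix"` with attributes `model`,
#'   `states` and `rate_names`.
#' @examples
#' build_rate_matrix("ER", 0.9)
#' build_rate_matrix("SYM", c(0.1, 0.2, 0.3))
#' @export
build_rate_matrix <- function(model = c("ER", "SYM", "ARD"), rates,
                              states = .flp_states) {
  model <- match.arg(model)
  k <- length(states)
  .assert(k >= 2, "Need at least two states.")
  .assert(is.numeric(rates) && all(is.finite(rates)) && all(rates > 0),
          "All rates must be positive and finite.",
          class = "flpscape_invalid_argument")
  n_free <- switch(model, ER = 1L, SYM = k * (k - 1L) / 2L, ARD = k * (k - 1L))
  .assert(length(rates) == n_free,
          "`", model, "` needs ", n_free, " rate(s), got ", length(rates), ".",
          class = "flpscape_invalid_argument")
  Q <- matrix(0, k, k, dimnames = list(states, states))
  if (model == "ER") {
    Q[] <- rates[1]
    rate_names <- "rate"
  } else if (model == "SYM") {
    pairs <- utils::combn(k, 2)
    for (j in seq_len(ncol(pairs))) {
      Q[pairs[1, j], pairs[2, j]] <- rates[j]
      Q[pairs[2, j], pairs[1, j]] <- rates[j]
    }
    rate_names <- apply(pairs, 2, function(p)
      paste(states[p[1]], states[p[2]], sep = "<->"))
  } else {
    idx <- which(row(Q) != col(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    Q[idx] <- rates
    rate_names <- paste(states[idx[, 1]], states[idx[, 2]], sep = "->")
  }
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  structure(Q, class = c("q_matrix", "matrix", "array"), model = model,
            states = states, rates = setNames(rates, rate_names),
            rate_names = rate_names)
}

#' Transition probabilities of an Mk model
#'
#' Computes `expm(Q t)` by eigendecomposition, falling back to
#' scaling-and-squaring (via \pkg{expm}) when the eigenvector matrix is
#' ill-conditioned. Entries are clamped to `[0, 1]`; rows sum to 1 within
#' 1e-10.
#'
#' @param q_matrix A `q_matrix` (or plain square matrix with zero row sums).
#' @param t Non-negative elapsed time.
#' @return A k x k stochastic matrix.
#' @examples
#' transition_probabilities(build_rate_matrix("ER", 1), 0.5)
#' @export
transition_probabilities <- function(q_matrix, t) {
  .assert(is.numeric(t) && length(t) == 1 && is.finite(t) && t >= 0,
          "`t` must be a single non-negative number.",
          class = "flpscape_invalid_argument")
  Q <- unclass(q_matrix)
  .assert(is.matrix(Q) && nrow(Q) == ncol(Q) && all(is.finite(Q)),
          "`q_matrix` must be a finite square matrix.",
          class = "flpscape_invalid_argument")
  if (t == 0) {
    P <- diag(nrow(Q))
    dimnames(P) <- dimnames(Q)
    return(P)
  }
  P <- .edge_prob_matrices(Q, t)[[1]]
  dimnames(P) <- dimnames(Q)
  P
}

# eigendecomposition of Q reusable across branch lengths; NULL if unreliable
.q_eigen <- function(Q) {
  ev <- tryCatch(eigen(Q), error = function(e) NULL)
  if (is.null(ev)) return(NULL)
  Vi <- tryCatch(solve(ev$vectors), error = function(e) NULL)
  if (is.null(Vi)) return(NULL)
  # reconstruction check guards near-defective matrices
  recon <- Re(ev$vectors %*% (ev$values * Vi))
  if (max(abs(recon - Q)) > 1e-8 * max(1, max(abs(Q)))) return(NULL)
  list(values = ev$values, V = ev$vectors, Vi = Vi)
}

# E x k^2 matrix of flattened P(t_e) (column (j-1)k+i = P[i,j]), vectorised
# across edges through the shared eigendecomposition
.edge_prob_flat <- function(Q, times) {
  k <- nrow(Q)
  eg <- .q_eigen(Q)
  if (is.null(eg)) {
    Ps <- .edge_prob_matrices(Q, times)
    return(do.call(rbind, lapply(Ps, as.vector)))
  }
  # W[s, (j-1)k+i] = V[i,s] * Vi[s,j]
  W <- matrix(0i, k, k * k)
  for (j in seq_len(k)) for (i in seq_len(k)) {
    W[, (j - 1L) * k + i] <- eg$V[i, ] * eg$Vi[, j]
  }
  Pf <- Re(exp(outer(times, eg$values)) %*% W)
  Pf[Pf < 0] <- 0
  Pf[Pf > 1] <- 1
  for (i in seq_len(k)) {
    rs <- rowSums(Pf[, (seq_len(k) - 1L) * k + i, drop = FALSE])
    .assert(max(abs(rs - 1)) < 1e-8, "Transition matrix rows do not sum to 1.")
    Pf[, (seq_len(k) - 1L) * k + i] <- Pf[, (seq_len(k) - 1L) * k + i] / rs
  }
  Pf
}

# fast likelihood: flattened transition matrices + C++ pruning recursion
.fast_loglik <- function(td, Lmat, Q, root_prior, k) {
  Pf <- .edge_prob_flat(Q, td$len)
  pr <- .mk_prune_cpp(td$edge, Pf, Lmat, td$n_node, td$root)
  if (is.null(pr$root_cond)) return(-Inf)
  Lr <- pr$root_cond
  if (identical(root_prior, "uniform")) {
    log(sum(Lr / k)) + pr$logscale
  } else if (identical(root_prior, "conditional")) {
    log(sum(Lr^2) / sum(Lr)) + pr$logscale
  } else {
    log(sum(root_prior * Lr)) + pr$logscale
  }
}

# list of P(t_e) for a vector of branch lengths
.edge_prob_matrices <- function(Q, times) {
  k <- nrow(Q)
  eg <- .q_eigen(Q)
  out <- vector("list", length(times))
  for (i in seq_along(times)) {
    P <- if (!is.null(eg)) {
      Re(eg$V %*% (exp(eg$values * times[i]) * eg$Vi))
    } else {
      unclass(expm::expm(Q * times[i]))
    }
    P[P < 0] <- 0
    P[P > 1] <- 1
    rs <- rowSums(P)
    .assert(max(abs(rs - 1)) < 1e-8, "Transition matrix rows do not sum to 1.")
    out[[i]] <- P / rs
  }
  out
}

# --- internal tree plumbing ------------------------------------------------

# postorder edge traversal data reused by likelihood and ASR
.tree_data <- function(tree, min_edge = 1e-8) {
  .assert(inherits(tree, "phylo") && !is.null(tree$edge.length),
          "`tree` must be a phylo object with branch lengths.")
  .assert(all(tree$edge.length >= 0), "Branch lengths must be non-negative.")
  tr <- stats::reorder(tree, "postorder")
  len <- pmax(tr$edge.length, min_edge)   # zero lengths perturbed
  list(tree = tr, n_tip = ape::Ntip(tr), n_node = ape::Ntip(tr) + tr$Nnode,
       edge = tr$edge, len = len, root = ape::Ntip(tr) + 1L)
}

# tip state matrix: rows tips, ones for allowed states (ambiguity sets ok)
.tip_state_matrix <- function(td, tip_states, states, allow_missing = FALSE) {
  n_tip <- td$n_tip
  labs <- td$tree$tip.label
  missing <- setdiff(labs, names(tip_states))
  if (length(missing) > 0 && !allow_missing) {
    .assert(FALSE, "Tips without states: ", paste(head(missing, 5), collapse = ", "),
            class = "flpscape_missing_data")
  }
  L <- matrix(1, n_tip, length(states))
  known <- intersect(labs, names(tip_states))
  for (lab in known) {
    s <- tip_states[[lab]]
    if (is.na(s)) next
    .assert(s %in% states, "Unknown state `", s, "` for tip `", lab, "`.",
            class = "flpscape_invalid_argument")
    row <- match(lab, labs)
    L[row, ] <- 0
    L[row, match(s, states)] <- 1
  }
  L
}

.resolve_root_prior <- function(root_prior, k) {
  if (is.character(root_prior)) {
    root_prior <- match.arg(root_prior, c("uniform", "conditional"))
    return(root_prior)
  }
  .assert(is.numeric(root_prior) && length(root_prior) == k &&
            abs(sum(root_prior) - 1) < 1e-8,
          "`root_prior` must be `\"uniform\"`, `\"conditional\"`, or ", k,
          " probabilities summing to 1.")
  root_prior
}

# Felsenstein pruning pass; returns per-node conditional likelihoods (scaled)
# and accumulated log scaling factors
.pruning_pass <- function(td, Lmat_tips, Q) {
  k <- ncol(Lmat_tips)
  n_node <- td$n_node
  Ps <- .edge_prob_matrices(Q, td$len)
  cond <- matrix(1, n_node, k)
  cond[seq_len(td$n_tip), ] <- Lmat_tips
  logscale <- numeric(n_node)
  contrib <- vector("list", nrow(td$edge))  # per-edge P %*% cond[child]
  for (e in seq_len(nrow(td$edge))) {
    p <- td$edge[e, 1L]
    ch <- td$edge[e, 2L]
    part <- as.vector(Ps[[e]] %*% cond[ch, ])
    contrib[[e]] <- part
    cond[p, ] <- cond[p, ] * part
    logscale[p] <- logscale[p] + logscale[ch]
    m <- max(cond[p, ])
    .assert(m > 0, "Zero likelihood encountered; data incompatible with tree.")
    cond[p, ] <- cond[p, ] / m
    logscale[p] <- logscale[p] + log(m)
  }
  list(cond = cond, logscale = logscale, P = Ps, contrib = contrib)
}

.root_loglik <- function(pass, td, root_prior, k) {
  Lr <- pass$cond[td$root, ]
  ls <- pass$logscale[td$root]
  if (identical(root_prior, "uniform")) {
    log(sum(Lr / k)) + ls
  } else if (identical(root_prior, "conditional")) {
    # FitzJohn-style prior: weight each state by its share of the likelihood
    log(sum(Lr^2) / sum(Lr)) + ls
  } else {
    log(sum(root_prior * Lr)) + ls
  }
}

.root_prior_vector <- function(root_prior, Lr, k) {
  if (identical(root_prior, "uniform")) rep(1 / k, k)
  else if (identical(root_prior, "conditional")) Lr / sum(Lr)
  else root_prior
}

#' Mk log-likelihood of tip states on a tree
#'
#' Felsenstein's pruning algorithm: postorder conditional likelihoods with
#' per-node rescaling (numerically stable for hundreds of tips), combined at
#' the root with the root prior.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param tip_states Named character vector (or single-column factor) of
#'   observed states per tip; `NA` marks a fully ambiguous tip when
#'   `allow_missing = TRUE`.
#' @param q_matrix A `q_matrix` from [build_rate_matrix()].
#' @param root_prior `"uniform"` (default), `"conditional"` (the
#'   observed-data, FitzJohn-style prior), or an explicit probability vector.
#' @param allow_missing Treat tips absent from `tip_states` as fully
#'   ambiguous instead of erroring.
#' @return The log-likelihood (a scalar).
#' @examples
#' tr <- simulate_yule_tree(6, seed = 1)
#' sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 1)
#' mk_log_likelihood(tr, sim$tip_states, build_rate_matrix("ER", 0.9))
#' @export
mk_log_likelihood <- function(tree, tip_states, q_matrix,
                              root_prior = "uniform", allow_missing = FALSE) {
  states <- attr(q_matrix, "states")
  .assert(!is.null(states), "`q_matrix` must come from build_rate_matrix().")
  td <- .tree_data(tree)
  k <- length(states)
  root_prior <- .resolve_root_prior(root_prior, k)
  Lmat <- .tip_state_matrix(td, tip_states, states, allow_missing)
  .fast_loglik(td, Lmat, unclass(q_matrix), root_prior, k)
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logL + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param logL Maximised log-likelihood.
#' @param k Number of free parameters.
#' @param n Sample size (number of tips for Mk fits).
#' @return The AICc value.
#' @examples
#' aicc(-10, 1, 100)
#' @export
aicc <- function(logL, k, n) {
  .assert(n > k + 1, "`n` must exceed k + 1 for the AICc correction.",
          class = "flpscape_invalid_argument")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit an Mk model by maximum likelihood
#'
#' Maximises the pruning-algorithm likelihood over log-rates with `nlminb`,
#' using multiple seeded log-uniform starting points; the best converged
#' restart is returned. Rates are bounded in `[1e-9, 100]`.
#'
#' @inheritParams mk_log_likelihood
#' @param model `"ER"`, `"SYM"` or `"ARD"`.
#' @param restarts Number of optimiser starts (first from rate 1, the rest
#'   log-uniform on `[1e-3, 10]`).
#' @param seed Integer seed for the restart draws.
#' @param states State labels; defaults to the levels present plus the
#'   standard plumage states if they match.
#' @param tol Relative convergence tolerance passed to the optimiser.
#' @return An object of class `"mk_fit"`: a list with the fitted `q_matrix`,
#'   `rates`, `logL`, `k`, `n_tips`, `aicc`, `converged` and bookkeeping.
#'   [tidy()] returns the rate table, [glance()] the fit summary.
#' @examples
#' tr <- simulate_yule_tree(40, seed = 1)
#' sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 1)
#' fit <- fit_mk_model(tr, sim$tip_states, "ER", restarts = 2, seed = 1)
#' glance(fit)
#' @export
fit_mk_model <- function(tree, tip_states, model = c("ER", "SYM", "ARD"),
                         restarts = 5, seed = 1L, root_prior = "uniform",
                         states = NULL, allow_missing = FALSE, tol = 1e-8) {
  model <- match.arg(model)
  if (is.null(states)) {
    obs <- unique(stats::na.omit(as.character(tip_states)))
    states <- if (all(obs %in% .flp_states)) .flp_states else sort(obs)
  }
  k_states <- length(states)
  obs_states <- unique(stats::na.omit(as.character(tip_states)))
  if (length(obs_states) < 2) {
    warning("Fewer than two observed states; rates are weakly identified.")
  }
  td <- .tree_data(tree)
  root_prior <- .resolve_root_prior(root_prior, k_states)
  dummyQ <- build_rate_matrix(model, rep(1, switch(model, ER = 1L,
                                                   SYM = k_states * (k_states - 1L) / 2L,
                                                   ARD = k_states * (k_states - 1L))),
                              states = states)
  n_free <- length(attr(dummyQ, "rates"))
  Lmat <- .tip_state_matrix(td, tip_states, states, allow_missing)
  lb <- log(1e-9); ub <- log(100)
  negll <- function(lr) {
    Q <- build_rate_matrix(model, exp(lr), states = states)
    val <- tryCatch(
      -.fast_loglik(td, Lmat, unclass(Q), root_prior, k_states),
      error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  starts <- withr::with_seed(seed, {
    s <- matrix(runif(n_free * restarts, log(1e-3), log(10)), nrow = restarts)
    s[1, ] <- 0   # rate 1 as a neutral first start
    s
  })
  best <- NULL
  any_conv <- FALSE
  for (r in seq_len(restarts)) {
    opt <- tryCatch(
      stats::nlminb(starts[r, ], negll, lower = lb, upper = ub,
                    control = list(rel.tol = tol, iter.max = 500)),
      error = function(e) NULL)
    if (is.null(opt)) next
    conv <- opt$convergence == 0
    any_conv <- any_conv || conv
    if (is.null(best) || opt$objective < best$objective) best <- opt
  }
  .assert(!is.null(best), "All optimiser restarts failed for model ", model, ".",
          class = "flpscape_non_convergence")
  rates <- exp(best$par)
  Q <- build_rate_matrix(model, rates, states = states)
  logL <- -best$objective
  at_bound <- any(rates <= 1.01e-9 | rates >= 99)
  if (at_bound) {
    warning("Fitted rate at the box bound for model ", model,
            "; estimate is degenerate (e.g. constant tip states).")
  }
  structure(list(
    model = model, rates = attr(Q, "rates"), q_matrix = Q, logL = logL,
    k = n_free, n_tips = td$n_tip, aicc = aicc(logL, n_free, td$n_tip),
    converged = any_conv, at_bound = at_bound, root_prior = root_prior,
    states = states, tip_states = tip_states, tree = tree,
    restarts = restarts, seed = seed), class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk model fit (", x$model, "), ", x$n_tips, " tips\n", sep = "")
  cat("  logL = ", format(x$logL, digits = 6),
      ", k = ", x$k, ", AICc = ", format(x$aicc, digits = 6),
      if (!x$converged) "  [NOT CONVERGED]" else "", "\n", sep = "")
  print(round(x$rates, 4))
  invisible(x)
}

#' Rank Mk fits by AICc
#'
#' Orders fits by AICc (ties broken towards fewer parameters) and marks the
#' best-supported set, conventionally all fits with `delta AICc < 2`.
#'
#' @param fits A list of [fit_mk_model()] results (or a single fit).
#' @param delta_best Threshold on the AICc difference defining the best set.
#' @return A tibble with columns `model`, `logL`, `k`, `n_tips`, `aicc`,
#'   `delta_aicc` and `in_best_set`, ordered best first, carrying the fits in
#'   the `"fits"` attribute (aligned with the rows).
#' @examples
#' tr <- simulate_yule_tree(40, seed = 1)
#' sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 1)
#' fits <- lapply(c("ER", "SYM"), function(m)
#'   fit_mk_model(tr, sim$tip_states, m, restarts = 2, seed = 1))
#' select_models(fits)
#' @export
select_models <- function(fits, delta_best = 2) {
  if (inherits(fits, "mk_fit")) fits <- list(fits)
  .assert(length(fits) >= 1 && all(vapply(fits, inherits, TRUE, "mk_fit")),
          "`fits` must be mk_fit objects.")
  conv <- vapply(fits, function(f) isTRUE(f$converged), TRUE)
  .assert(any(conv), "No converged fit to select from.",
          class = "flpscape_non_convergence")
  fits <- fits[conv]
  tab <- tibble::tibble(
    model = vapply(fits, `[[`, "", "model"),
    logL = vapply(fits, function(f) as.numeric(f$logL), 0),
    k = vapply(fits, function(f) as.integer(f$k), 0L),
    n_tips = vapply(fits, function(f) as.integer(f$n_tips), 0L),
    aicc = vapply(fits, function(f) as.numeric(f$aicc), 0))
  ord <- order(tab$aicc, tab$k)
  tab <- tab[ord, ]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$in_best_set <- tab$delta_aicc < delta_best
  attr(tab, "fits") <- fits[ord]
  tab
}

#' Marginal ancestral-state reconstruction
#'
#' Computes, for every node, the marginal posterior probability of each state
#' given all tip data and the supplied rate matrix, via the standard
#' down-pass/up-pass (rerooting-equivalent) algorithm. Tips with observed
#' states carry unit mass on the observed state.
#'
#' @inheritParams mk_log_likelihood
#' @return An object of class `"mk_asr"`: a list with `prob` (tibble with
#'   `node`, `type`, `label` and one `p_<state>` column per state), `logL`,
#'   `states`, `root_prior` and the tree. [tidy()] returns the probability
#'   table.
#' @examples
#' tr <- simulate_yule_tree(6, seed = 1)
#' sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 1)
#' asr <- marginal_asr(tr, sim$tip_states, build_rate_matrix("ER", 0.9))
#' head(tidy(asr))
#' @export
marginal_asr <- function(tree, tip_states, q_matrix, root_prior = "uniform",
                         allow_missing = FALSE) {
  states <- attr(q_matrix, "states")
  .assert(!is.null(states), "`q_matrix` must come from build_rate_matrix().")
  k <- length(states)
  td <- .tree_data(tree)
  root_prior <- .resolve_root_prior(root_prior, k)
  Lmat <- .tip_state_matrix(td, tip_states, states, allow_missing)
  Q <- unclass(q_matrix)
  pass <- .pruning_pass(td, Lmat, Q)
  logL <- .root_loglik(pass, td, root_prior, k)
  prior_vec <- .root_prior_vector(root_prior, pass$cond[td$root, ], k)

  n_node <- td$n_node
  up <- matrix(0, n_node, k)      # likelihood of data outside each node's clade
  up[td$root, ] <- prior_vec
  edges <- td$edge
  # children grouped by parent for sibling products
  kids <- split(seq_len(nrow(edges)), edges[, 1])
  for (e in rev(seq_len(nrow(edges)))) {  # preorder: parents before children
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    sibs <- setdiff(kids[[as.character(p)]], e)
    outer_p <- up[p, ]
    for (s in sibs) outer_p <- outer_p * pass$contrib[[s]]
    up[ch, ] <- as.vector(t(pass$P[[e]]) %*% outer_p)
    m <- max(up[ch, ])
    if (m > 0) up[ch, ] <- up[ch, ] / m
  }
  marg <- pass$cond * up
  marg[td$root, ] <- pass$cond[td$root, ] * prior_vec
  marg <- marg / rowSums(marg)
  colnames(marg) <- paste0("p_", states)
  node_ids <- seq_len(n_node)
  labs <- c(td$tree$tip.label,
            if (!is.null(td$tree$node.label)) td$tree$node.label
            else paste0("node", (td$n_tip + 1L):n_node))
  prob <- dplyr::bind_cols(
    tibble::tibble(node = node_ids,
                   type = rep(c("tip", "internal"), c(td$n_tip, td$tree$Nnode)),
                   label = labs),
    tibble::as_tibble(marg))
  structure(list(prob = prob, logL = logL, states = states,
                 root_prior = root_prior, tree = td$tree,
                 root_marginal = setNames(as.vector(marg[td$root, ]), states)),
            class = "mk_asr")
}

#' @export
print.mk_asr <- function(x, ...) {
  cat("Marginal ancestral-state reconstruction (", length(x$states),
      " states, ", ape::Ntip(x$tree), " tips)\n", sep = "")
  cat("  logL =", format(x$logL, digits = 6), "\n")
  cat("  root: ", paste(sprintf("%s %.3f", x$states, x$root_marginal),
                        collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Count independent evolutionary origins of a state
#'
#' Labels every node focal when its marginal probability of `focal_state`
#' exceeds `threshold` (tips by their observed state) and counts edges whose
#' child is focal while the parent is not; a focal root adds one origin.
#'
#' @param asr A [marginal_asr()] result.
#' @param focal_state The state whose origins are counted (default `"FLP"`).
#' @param threshold Probability cutoff labelling a node focal (default 0.5,
#'   exceeded strictly).
#' @return Integer count of independent origins.
#' @examples
#' tr <- simulate_yule_tree(10, seed = 1)
#' sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 1)
#' asr <- marginal_asr(tr, sim$tip_states, build_rate_matrix("ER", 0.9))
#' count_independent_origins(asr)
#' @export
count_independent_origins <- function(asr, focal_state = "FLP",
                                      threshold = 0.5) {
  .assert(inherits(asr, "mk_asr"), "`asr` must come from marginal_asr().")
  .assert(focal_state %in% asr$states, "Unknown focal state.",
          class = "flpscape_invalid_argument")
  .assert(is.numeric(threshold) && threshold >= 0.5 && threshold <= 1,
          "`threshold` must lie in [0.5, 1].")
  p <- asr$prob[[paste0("p_", focal_state)]]
  .assert(!anyNA(p) && length(p) == ape::Ntip(asr$tree) + asr$tree$Nnode,
          "ASR table misses nodes.", class = "flpscape_invalid_argument")
  focal <- p > threshold
  tr <- asr$tree
  root <- ape::Ntip(tr) + 1L
  origins <- sum(focal[tr$edge[, 2]] & !focal[tr$edge[, 1]])
  origins + as.integer(focal[root])
}

#' Prune a tree to the species present in the data
#'
#' Returns the induced subtree on `labels`; unary nodes are suppressed with
#' their branch lengths summed (so root-to-tip path lengths are preserved).
#'
#' @param tree A `phylo` tree.
#' @param labels Tip labels to keep (at least 2).
#' @return The pruned `phylo` tree.
#' @examples
#' tr <- simulate_yule_tree(6, seed = 1)
#' prune_to_data(tr, c("sp001", "sp002", "sp003"))
#' @export
prune_to_data <- function(tree, labels) {
  .assert(inherits(tree, "phylo"), "`tree` must be a phylo object.")
  missing <- setdiff(labels, tree$tip.label)
  .assert(length(missing) == 0,
          "Labels absent from tree: ", paste(head(missing, 10), collapse = ", "),
          class = "flpscape_missing_tip")
  .assert(length(unique(labels)) >= 2, "Need at least two tips to keep.",
          class = "flpscape_invalid_argument")
  if (setequal(labels, tree$tip.label)) return(tree)
  ape::keep.tip(tree, unique(labels))
}

#' Root-state stability under random tip pruning
#'
#' Repeatedly drops a fraction of tips at random, refits the Mk model (or
#' re-evaluates at the full-data rates) and records the root marginal state
#' probabilities, summarising their mean and standard deviation per state.
#' Low standard deviations indicate that tree composition does not strongly
#' affect the reconstruction.
#'
#' @inheritParams fit_mk_model
#' @param drop_frac Fraction of tips dropped per replicate, in (0, 0.5).
#' @param reps Number of replicates (default 1000).
#' @param refit Refit rates on each pruned tree (default); `FALSE`
#'   re-evaluates at the full-data estimates.
#' @return A tibble with columns `state`, `mean`, `sd` plus attributes
#'   `root_draws` (reps x states matrix) and `full_fit`.
#' @examples
#' tr <- simulate_yule_tree(30, seed = 1)
#' sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 1)
#' root_state_resampling(tr, sim$tip_states, "ER", reps = 3, seed = 1,
#'                       restarts = 2)
#' @export
root_state_resampling <- function(tree, tip_states, model = "ER",
                                  drop_frac = 0.10, reps = 1000, seed = 1L,
                                  refit = TRUE, restarts = 5,
                                  root_prior = "uniform") {
  .assert(is.numeric(drop_frac) && drop_frac > 0 && drop_frac < 0.5,
          "`drop_frac` must lie in (0, 0.5).",
          class = "flpscape_invalid_argument")
  .assert(.is_count(reps, min = 2), "`reps` must be at least 2.")
  n_tip <- ape::Ntip(tree)
  n_drop <- floor(drop_frac * n_tip)
  .assert(n_tip - n_drop >= 3, "Pruning would leave fewer than 3 tips.",
          class = "flpscape_invalid_argument")
  full_fit <- fit_mk_model(tree, tip_states, model, restarts = restarts,
                           seed = seed, root_prior = root_prior)
  states <- full_fit$states
  draws <- withr::with_seed(seed, {
    t(vapply(seq_len(reps), function(r) {
      keep <- sample(tree$tip.label, n_tip - n_drop)
      sub <- prune_to_data(tree, keep)
      Q <- if (refit) {
        fit_mk_model(sub, tip_states[keep], model, restarts = restarts,
                     seed = seed + r, root_prior = root_prior,
                     states = states)$q_matrix
      } else {
        full_fit$q_matrix
      }
      marginal_asr(sub, tip_states[keep], Q, root_prior)$root_marginal
    }, numeric(length(states))))
  })
  out <- tibble::tibble(state = states,
                        mean = colMeans(draws),
                        sd = apply(draws, 2, sd))
  attr(out, "root_draws") <- draws
  attr(out, "full_fit") <- full_fit
  out
}
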