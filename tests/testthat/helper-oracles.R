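# Independent oracles used across the test files.

# Exhaustive-enumeration likelihood and marginals for a discrete character on
# a small tree: sums the probability of every internal-node state assignment,
# with per-edge transition matrices from expm's scaling-and-squaring
# (independent of the package's eigendecomposition path).
enum_mk <- function(tree, tip_states, Q, root_prior) {
  states <- attr(Q, "states")
  k <- length(states)
  tr <- stats::reorder(tree, "postorder")
  n_tip <- ape::Ntip(tr)
  n_node <- n_tip + tr$Nnode
  P <- lapply(pmax(tr$edge.length, 1e-8), function(t)
    unclass(expm::expm(unclass(Q) * t)))
  tip_idx <- match(as.character(tip_states[tr$tip.label]), states)
  internal <- (n_tip + 1L):n_node
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internal))))
  lik_terms <- numeric(nrow(combos))
  marg <- matrix(0, n_node, k)
  for (ci in seq_len(nrow(combos))) {
    assign_all <- integer(n_node)
    assign_all[seq_len(n_tip)] <- tip_idx
    assign_all[internal] <- combos[ci, ]
    pr <- root_prior[assign_all[n_tip + 1L]]
    for (e in seq_len(nrow(tr$edge))) {
      pr <- pr * P[[e]][assign_all[tr$edge[e, 1]], assign_all[tr$edge[e, 2]]]
    }
    lik_terms[ci] <- pr
    for (v in seq_len(n_node)) marg[v, assign_all[v]] <- marg[v, assign_all[v]] + pr
  }
  list(logL = log(sum(lik_terms)), marginal = marg / sum(lik_terms))
}

# closed-form OLS slope (covariance over variance) for regression oracles
ols_slope <- function(x, y) {
  list(slope = cov(x, y) / var(x),
       intercept = mean(y) - cov(x, y) / var(x) * mean(x))
}

# scan-based minimal sample size, the brute-force counterpart of the closed
# form in required_sample_size()
scan_sample_size <- function(freq, target) {
  n <- 1
  while (1 - (1 - freq)^n < target) n <- n + 1
  n
}

# a fixed 6-tip tree with two disjoint clades, used for origin counting
two_clade_tree <- function() {
  ape::read.tree(text = "(((t1:1,t2:1):1,(t3:1,t4:1):1):1,(t5:2,t6:2):1);")
}

# state levels used throughout (kept local to the tests)
.flp_states_test <- function() c("monochromic", "dichromic", "FLP")

# small deterministic specimen table builder
make_records <- function(species, female_classes, n_males = 0,
                         sexing = "gonad") {
  f <- tibble::tibble(species = species, sex = "female",
                      plumage_class = as.integer(female_classes),
                      sexing_method = sexing)
  if (n_males > 0) {
    f <- dplyr::bind_rows(f, tibble::tibble(
      species = species, sex = "male", plumage_class = 4L,
      sexing_method = sexing))
  }
  f
}
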