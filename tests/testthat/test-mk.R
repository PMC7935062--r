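test_that("rate matrices have the specified structure and checks", {
  Q <- build_rate_matrix("ER", 0.9)
  expect_true(all(Q[row(Q) != col(Q)] == 0.9))
  expect_equal(unname(diag(Q)), rep(-1.8, 3))
  expect_equal(unname(rowSums(Q)), rep(0, 3))

  Qs <- build_rate_matrix("SYM", c(0.1, 0.2, 0.3))
  expect_equal(unclass(Qs), t(unclass(Qs)))

  Qa <- build_rate_matrix("ARD", c(1, 2, 3, 4, 5, 6))
  expect_false(isTRUE(all.equal(unclass(Qa), t(unclass(Qa)))))
  expect_equal(Qa["monochromic", "dichromic"], 1)
  expect_equal(Qa["dichromic", "monochromic"], 3)

  expect_error(build_rate_matrix("ER", -1), class = "flpscape_invalid_argument")
  expect_error(build_rate_matrix("SYM", c(1, 2)),
               class = "flpscape_invalid_argument")
})

test_that("transition probabilities obey the closed forms", {
  Q <- build_rate_matrix("ER", 0.7)
  expect_equal(transition_probabilities(Q, 0), diag(3), ignore_attr = TRUE)

  # 2-state symmetric closed form: P_stay = (1 + exp(-2 r t)) / 2
  Q2 <- build_rate_matrix("ER", 0.4, states = c("a", "b"))
  for (t in c(0.1, 1, 5)) {
    P <- transition_probabilities(Q2, t)
    expect_equal(P[1, 1], (1 + exp(-2 * 0.4 * t)) / 2, tolerance = 1e-10)
  }

  # saturation: ER converges to the uniform stationary distribution
  Pinf <- transition_probabilities(Q, 200)
  expect_equal(unclass(Pinf), matrix(1 / 3, 3, 3), ignore_attr = TRUE,
               tolerance = 1e-8)

  # general ARD case against an independent matrix exponential
  Qa <- build_rate_matrix("ARD", c(0.5, 1.2, 0.05, 0.7, 2, 0.3))
  for (t in c(0.2, 1.7)) {
    expect_equal(unclass(transition_probabilities(Qa, t)),
                 unclass(expm::expm(unclass(Qa) * t)),
                 ignore_attr = TRUE, tolerance = 1e-9)
    expect_equal(unname(rowSums(transition_probabilities(Qa, t))), rep(1, 3),
                 tolerance = 1e-10)
  }
  expect_error(transition_probabilities(Qa, -1),
               class = "flpscape_invalid_argument")
})

test_that("pruning likelihood matches exhaustive enumeration on small trees", {
  set.seed(101)
  for (rep in 1:12) {
    n <- sample(4:6, 1)
    tr <- simulate_yule_tree(n, 1, seed = sample.int(1e6, 1))
    model <- sample(c("ER", "SYM", "ARD"), 1)
    rates <- runif(switch(model, ER = 1, SYM = 3, ARD = 6), 0.1, 2)
    Q <- build_rate_matrix(model, rates)
    sim <- simulate_mk_tips(tr, Q, seed = sample.int(1e6, 1))
    prior <- rep(1 / 3, 3)
    oracle <- enum_mk(tr, sim$tip_states, Q, prior)
    expect_equal(mk_log_likelihood(tr, sim$tip_states, Q, prior),
                 oracle$logL, tolerance = 1e-8)
    asr <- marginal_asr(tr, sim$tip_states, Q, prior)
    got <- as.matrix(tidy(asr)[, paste0("p_", attr(Q, "states"))])
    # rows of the enumeration are in the same postorder node numbering
    expect_equal(unname(got), unname(oracle$marginal), tolerance = 1e-8)
  }
})

test_that("likelihood is invariant to tip-state vector order", {
  tr <- simulate_yule_tree(20, 1, seed = 12)
  Q <- build_rate_matrix("ER", 0.9)
  sim <- simulate_mk_tips(tr, Q, seed = 12)
  shuffled <- sim$tip_states[sample(names(sim$tip_states))]
  expect_equal(mk_log_likelihood(tr, sim$tip_states, Q),
               mk_log_likelihood(tr, shuffled, Q))
})

test_that("a two-tip no-change tree reduces to the prior of the shared state", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  Q <- build_rate_matrix("ER", 1e-9)
  ll <- mk_log_likelihood(tr, c(A = "FLP", B = "FLP"), Q)
  expect_equal(ll, log(1 / 3), tolerance = 1e-6)
})

test_that("model nesting keeps the maximised likelihood monotone", {
  tr <- simulate_yule_tree(80, 1, seed = 21)
  sim <- simulate_mk_tips(tr, build_rate_matrix("SYM", c(0.3, 0.8, 0.5)),
                          seed = 21)
  fits <- lapply(c("ER", "SYM", "ARD"), function(m)
    fit_mk_model(tr, sim$tip_states, m, restarts = 3, seed = 2))
  expect_lte(fits[[1]]$logL, fits[[2]]$logL + 1e-4)
  expect_lte(fits[[2]]$logL, fits[[3]]$logL + 1e-4)
})

test_that("AICc follows its formula and asymptotics", {
  expect_equal(aicc(-10, 1, 100), 20 + 2 + 4 / 98)
  expect_equal(aicc(-10, 2, 1e9), -2 * -10 + 4, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), class = "flpscape_invalid_argument")
})

test_that("model selection ranks by AICc with the delta-2 best set", {
  fake <- function(model, logL, k, n) {
    structure(list(model = model, logL = logL, k = k, n_tips = n,
                   aicc = aicc(logL, k, n), converged = TRUE),
              class = "mk_fit")
  }
  # the reported study configuration: ER beats SYM beats ARD
  n <- 198
  fits <- list(fake("ER", -(360.47 - 2 - 4 / (n - 2)) / 2, 1, n),
               fake("ARD", -(367.15 - 12 - 84 / (n - 7)) / 2, 6, n),
               fake("SYM", -(362.95 - 6 - 24 / (n - 4)) / 2, 3, n))
  sel <- select_models(fits)
  expect_equal(sel$model, c("ER", "SYM", "ARD"))
  expect_equal(sel$aicc, c(360.47, 362.95, 367.15), tolerance = 1e-10)
  expect_equal(sel$in_best_set, c(TRUE, FALSE, FALSE))

  close <- list(fake("ER", -48, 1, 100), fake("SYM", -46.5, 3, 100))
  sel2 <- select_models(close)
  expect_true(all(sel2$in_best_set))

  single <- select_models(fake("ER", -10, 1, 50))
  expect_equal(nrow(single), 1)
})

test_that("ASR marginals are normalised and respect the no-change limit", {
  tr <- two_clade_tree()
  Q <- build_rate_matrix("ER", 1e-8)
  tips <- c(t1 = "FLP", t2 = "FLP", t3 = "FLP", t4 = "FLP",
            t5 = "dichromic", t6 = "dichromic")
  asr <- marginal_asr(tr, tips, Q)
  probs <- as.matrix(tidy(asr)[, 4:6])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-10))
  # the ancestor of the all-FLP clade is surely FLP when change is impossible
  tab <- tidy(asr)
  flp_mrca <- ape::getMRCA(tr, c("t1", "t2", "t3", "t4"))
  expect_gt(tab$p_FLP[tab$node == flp_mrca], 0.999)
})

test_that("origin counting follows the parent/child transition rule", {
  # hand-built reconstruction on the fixed 6-tip tree:
  # ((t1,t2),(t3,t4)) and (t5,t6); nodes 7..10 are root, mrca(1:4),
  # mrca(t1,t2), mrca(t3,t4); node 11 is mrca(t5,t6)
  tr <- two_clade_tree()
  manual_asr <- function(p_flp) {
    prob <- tibble::tibble(
      node = seq_len(11L),
      type = rep(c("tip", "internal"), c(6, 5)),
      label = c(tr$tip.label, paste0("node", 7:11)),
      p_monochromic = 0, p_dichromic = 1 - p_flp, p_FLP = p_flp)
    structure(list(prob = prob, states = .flp_states_test(), tree = tr),
              class = "mk_asr")
  }
  # focal tips t1,t2 and t5,t6; their MRCAs focal; root and the rest not:
  # exactly two transition edges
  asr2 <- manual_asr(c(1, 1, 0, 0, 1, 1, 0.2, 0.3, 0.9, 0.1, 0.8))
  expect_equal(count_independent_origins(asr2), 2L)
  # all nodes focal: the single origin is at the root
  expect_equal(count_independent_origins(manual_asr(rep(0.9, 11))), 1L)
  # no focal nodes anywhere
  expect_equal(count_independent_origins(manual_asr(rep(0.1, 11))), 0L)
  # and on a genuine reconstruction: one fully FLP clade under a low rate
  tips <- c(t1 = "FLP", t2 = "FLP", t3 = "dichromic", t4 = "dichromic",
            t5 = "dichromic", t6 = "dichromic")
  asr <- marginal_asr(tr, tips, build_rate_matrix("ER", 0.1))
  expect_equal(count_independent_origins(asr), 1L)
})

test_that("pruning to data preserves path lengths and validates labels", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  expect_identical(prune_to_data(tr, c("A", "B", "C")), tr)
  sub <- prune_to_data(tr, c("A", "C"))
  expect_equal(sort(sub$tip.label), c("A", "C"))
  d <- ape::cophenetic.phylo(sub)
  expect_equal(d["A", "C"], 4)                 # 1 + 1 + 2, as in the full tree
  expect_error(prune_to_data(tr, c("A", "Z")), class = "flpscape_missing_tip")
  expect_error(prune_to_data(tr, "A"), class = "flpscape_invalid_argument")
})

test_that("fits are seed-deterministic and flag degenerate data", {
  tr <- simulate_yule_tree(40, 1, seed = 31)
  sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 31)
  f1 <- fit_mk_model(tr, sim$tip_states, "ER", restarts = 3, seed = 9)
  f2 <- fit_mk_model(tr, sim$tip_states, "ER", restarts = 3, seed = 9)
  expect_identical(f1$rates, f2$rates)

  const <- setNames(rep("FLP", 40), tr$tip.label)
  w <- testthat::capture_warnings(
    fc <- fit_mk_model(tr, const, "ER", restarts = 2, seed = 1,
                       states = .flp_states_test()))
  expect_match(w, "box bound", all = FALSE)
  expect_true(fc$at_bound)
  expect_lt(fc$rates[1], 1e-6)
})

test_that("ER rate estimates agree with an independent implementation", {
  tr <- simulate_yule_tree(120, 1, seed = 44)
  sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 44)
  fit <- fit_mk_model(tr, sim$tip_states, "ER", restarts = 3, seed = 1)
  ace <- ape::ace(factor(sim$tip_states[tr$tip.label]), tr,
                  type = "discrete", model = "ER")
  expect_equal(unname(fit$rates[1]), unname(ace$rates), tolerance = 1e-4)
})

test_that("root-state resampling is deterministic and degenerates to SD 0", {
  tr <- simulate_yule_tree(30, 1, seed = 51)
  sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 51)
  r1 <- root_state_resampling(tr, sim$tip_states, "ER", drop_frac = 0.1,
                              reps = 4, seed = 3, restarts = 2)
  r2 <- root_state_resampling(tr, sim$tip_states, "ER", drop_frac = 0.1,
                              reps = 4, seed = 3, restarts = 2)
  expect_equal(r1$mean, r2$mean)
  expect_equal(r1$sd, r2$sd)

  # with 8 tips a 10% drop removes floor(0.8) = 0 tips: no variation
  tr8 <- simulate_yule_tree(8, 1, seed = 52)
  sim8 <- simulate_mk_tips(tr8, build_rate_matrix("ER", 0.9), seed = 52)
  r0 <- root_state_resampling(tr8, sim8$tip_states, "ER", drop_frac = 0.1,
                              reps = 3, seed = 1, restarts = 2, refit = FALSE)
  expect_equal(unname(r0$sd), rep(0, 3), tolerance = 1e-12)

  expect_error(root_state_resampling(tr, sim$tip_states, "ER",
                                     drop_frac = 0.7, reps = 3),
               class = "flpscape_invalid_argument")
})
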