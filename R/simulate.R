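#' Specification of a synthetic FLP study
#'
#' Bundles every knob of the synthetic-data generators into one validated
#' object. The defaults describe a plausible hummingbird-like study: a
#' moderately sized clade evolving a three-state plumage character
#' (monochromic, dichromic, female-limited polymorphism) at an equal rate of
#' 0.9 transitions per unit tree depth, museum-style specimen series per
#' species, and photographic colour series of about 10 androchrome males,
#' 6 Class-1 females and 11 variable females per species.
#'
#' @param n_species Number of species (tree tips) to simulate.
#' @param birth_rate Speciation rate of the pure-birth (Yule) tree, per unit
#'   time.
#' @param q_true Instantaneous rate matrix (a [build_rate_matrix()] result)
#'   used to evolve the plumage character along the tree.
#' @param n_females,n_males Museum specimens per species entering the ordinal
#'   plumage-score table. The female default (30) reflects a typical museum
#'   series and comfortably exceeds the 19-female absence threshold of the
#'   classification rule; the photographic colour series has its own smaller
#'   counts below.
#' @param androchrome_freq Proportion of females drawn from the androchrome
#'   (Class 3--4) mixture component in species that carry FLP.
#' @param class_noise Probability that a specimen's ordinal class is misread
#'   by one class (symmetric, truncated at classes 1 and 4). Must be below
#'   0.5.
#' @param n_patches Number of plumage patches measured per specimen; each
#'   contributes mean R, G and B channel values.
#' @param color_separation Euclidean distance, in 8-bit channel units, between
#'   the male and Class-1 female cluster centroids in patch-colour space.
#' @param color_noise Isotropic within-cluster standard deviation of channel
#'   values.
#' @param n_class1_females,n_variable_females Photographic colour series sizes
#'   per species: Class-1 (fully heterochrome) females and females spread
#'   along the heterochrome--androchrome continuum.
#' @param planted_slope Change in bill length (mm) per unit LD1 score planted
#'   into the colour/morphometric generator; 0 plants no pleiotropy signal.
#' @param bill_mean,wing_mean Species-average bill and wing lengths in mm.
#' @param bill_noise Residual standard deviation of bill length (mm) around
#'   the planted relationship.
#' @param covariate_effects Named numeric vector of planted FLP associations
#'   for the species-level covariates (in standard-deviation units of the
#'   latent trait); names among `migratory`, `dominance`, `body_length`,
#'   `mean_temperature`, `mean_precipitation`, `temperature_predictability`,
#'   `precipitation_predictability`.
#' @param sexing_method_probs Probabilities of the `gonad`, `unknown` and
#'   `plumage` sexing-method tags on specimen labels.
#' @param seed Default integer seed used by generators when no seed is given.
#'
#' @return A validated list of class `"simulation_spec"`.
#' @examples
#' spec <- simulation_spec(n_species = 20)
#' spec$androchrome_freq
#' @export
simulation_spec <- function(n_species = 40,
                            birth_rate = 1,
                            q_true = build_rate_matrix("ER", 0.9),
                            n_females = 30,
                            n_males = 10,
                            androchrome_freq = 0.30,
                            class_noise = 0.05,
                            n_patches = 17,
                            color_separation = 80,
                            color_noise = 8,
                            n_class1_females = 6,
                            n_variable_females = 11,
                            planted_slope = 0,
                            bill_mean = 20,
                            wing_mean = 60,
                            bill_noise = 0.6,
                            covariate_effects = NULL,
                            sexing_method_probs = c(gonad = 0.38,
                                                    unknown = 0.60,
                                                    plumage = 0.02),
                            seed = 1L) {
  .assert(.is_count(n_species, min = 1), "`n_species` must be a positive count.")
  .assert(is.numeric(birth_rate) && birth_rate > 0, "`birth_rate` must be > 0.")
  .assert(inherits(q_true, "q_matrix"), "`q_true` must come from build_rate_matrix().")
  for (nm in c("n_females", "n_males", "n_patches", "n_class1_females",
               "n_variable_females")) {
    .assert(.is_count(get(nm)), "`", nm, "` must be a positive count.")
  }
  .assert(.is_prob(androchrome_freq), "`androchrome_freq` must lie in [0, 1].")
  .assert(is.numeric(class_noise) && class_noise >= 0 && class_noise < 0.5,
          "`class_noise` must lie in [0, 0.5).")
  .assert(is.numeric(color_separation) && color_separation >= 0,
          "`color_separation` must be >= 0.")
  .assert(is.numeric(color_noise) && color_noise > 0, "`color_noise` must be > 0.")
  .assert(.is_count(seed, min = 0), "`seed` must be a non-negative integer.")
  effects <- c(migratory = 0, dominance = 0, body_length = 0,
               mean_temperature = 0, mean_precipitation = 0,
               temperature_predictability = 0, precipitation_predictability = 0)
  if (!is.null(covariate_effects)) {
    .assert(is.numeric(covariate_effects) && !is.null(names(covariate_effects)) &&
              all(names(covariate_effects) %in% names(effects)),
            "`covariate_effects` must be named after known covariates.")
    effects[names(covariate_effects)] <- covariate_effects
  }
  .assert(abs(sum(sexing_method_probs) - 1) < 1e-8 &&
            all(c("gonad", "unknown", "plumage") %in% names(sexing_method_probs)),
          "`sexing_method_probs` must be named probabilities summing to 1.")
  structure(list(
    n_species = as.integer(n_species), birth_rate = birth_rate, q_true = q_true,
    n_females = as.integer(n_females), n_males = as.integer(n_males),
    androchrome_freq = androchrome_freq, class_noise = class_noise,
    n_patches = as.integer(n_patches), color_separation = color_separation,
    color_noise = color_noise,
    n_class1_females = as.integer(n_class1_females),
    n_variable_females = as.integer(n_variable_females),
    planted_slope = planted_slope, bill_mean = bill_mean,
    wing_mean = wing_mean, bill_noise = bill_noise,
    covariate_effects = effects,
    sexing_method_probs = sexing_method_probs[c("gonad", "unknown", "plumage")],
    seed = as.integer(seed)
  ), class = "simulation_spec")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Lineages split at per-lineage rate `birth_rate`; the process starts from
#' the root bifurcation and stops one exponential waiting time after the
#' n-th lineage appears, so every pendant branch has positive length. The
#' expected root-to-tip depth is \eqn{\sum_{k=2}^{n} 1/(k\,\lambda)}.
#'
#' @param n_tips Number of tips (at least 2).
#' @param birth_rate Speciation rate per lineage per unit time.
#' @param seed Integer seed; identical seeds give identical trees.
#' @return A rooted binary `ape::phylo` tree with positive branch lengths and
#'   tip labels `sp001`, `sp002`, ...
#' @examples
#' tr <- simulate_yule_tree(10, 1, seed = 7)
#' ape::Ntip(tr)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  .assert(.is_count(n_tips, min = 2), "`n_tips` must be at least 2.",
          class = "flpscape_invalid_argument")
  .assert(is.numeric(birth_rate) && birth_rate > 0, "`birth_rate` must be > 0.")
  n_tips <- as.integer(n_tips)
  withr::with_seed(seed, {
    # active lineages: parent node id and birth time of the open branch
    n_nodes_total <- 2L * n_tips - 1L
    root <- n_tips + 1L
    parent <- c(root, root)
    born <- c(0, 0)
    next_internal <- root + 1L
    edges <- matrix(0L, 0L, 2L)
    lens <- numeric(0)
    t_now <- 0
    k <- 2L
    while (k < n_tips) {
      t_now <- t_now + rexp(1L, rate = k * birth_rate)
      i <- sample.int(k, 1L)
      edges <- rbind(edges, c(parent[i], next_internal))
      lens <- c(lens, t_now - born[i])
      parent[i] <- next_internal
      born[i] <- t_now
      parent <- c(parent, next_internal)
      born <- c(born, t_now)
      next_internal <- next_internal + 1L
      k <- k + 1L
    }
    t_end <- t_now + rexp(1L, rate = n_tips * birth_rate)
    tip_ids <- seq_len(n_tips)
    edges <- rbind(edges, cbind(parent, tip_ids))
    lens <- c(lens, t_end - born)
    tr <- list(edge = edges, edge.length = lens,
               tip.label = sprintf("sp%03d", tip_ids),
               Nnode = n_tips - 1L)
    class(tr) <- "phylo"
    attr(tr, "order") <- NULL
    stats::reorder(tr, "cladewise")
  })
}

#' Evolve a discrete character along a tree under a Markov model
#'
#' Draws the root state from `root_prior` and propagates states towards the
#' tips using the transition probabilities `expm(Q t)` on each branch.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param q_matrix A rate matrix from [build_rate_matrix()].
#' @param root_prior Numeric vector of state probabilities at the root
#'   (defaults to uniform).
#' @param seed Integer seed.
#' @return A list with `tip_states` and `node_states`, both named character
#'   vectors, plus the `states` level set.
#' @examples
#' tr <- simulate_yule_tree(8, seed = 1)
#' sim <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.5), seed = 2)
#' table(sim$tip_states)
#' @export
simulate_mk_tips <- function(tree, q_matrix,
                             root_prior = NULL, seed = 1L) {
  .assert(inherits(tree, "phylo") && !is.null(tree$edge.length),
          "`tree` must be a phylo object with branch lengths.")
  .assert(inherits(q_matrix, "q_matrix"),
          "`q_matrix` must come from build_rate_matrix().",
          class = "flpscape_invalid_argument")
  states <- attr(q_matrix, "states")
  k <- length(states)
  if (is.null(root_prior)) root_prior <- rep(1 / k, k)
  .assert(length(root_prior) == k && abs(sum(root_prior) - 1) < 1e-8,
          "`root_prior` must be ", k, " probabilities summing to 1.")
  withr::with_seed(seed, {
    tr <- stats::reorder(tree, "cladewise")   # parents precede children
    n_tip <- ape::Ntip(tr)
    n_node <- n_tip + tr$Nnode
    state <- integer(n_node)
    root <- n_tip + 1L
    state[root] <- sample.int(k, 1L, prob = root_prior)
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1L]
      ch <- tr$edge[e, 2L]
      P <- transition_probabilities(q_matrix, tr$edge.length[e])
      state[ch] <- sample.int(k, 1L, prob = P[state[p], ])
    }
    tips <- setNames(states[state[seq_len(n_tip)]], tr$tip.label)
    node_ids <- (n_tip + 1L):n_node
    labs <- if (!is.null(tr$node.label)) tr$node.label else paste0("node", node_ids)
    nodes <- setNames(states[state[node_ids]], labs)
    list(tip_states = tips, node_states = nodes, states = states)
  })
}

# two-component ordinal class mixture used for female specimens:
# heterochrome over classes {1,2}, androchrome over {3,4}
.female_class_probs <- list(heterochrome = c(0.9, 0.1, 0, 0),
                            androchrome = c(0, 0, 0.1, 0.9))

.apply_class_noise <- function(classes, noise) {
  if (noise <= 0) return(classes)
  flip <- runif(length(classes)) < noise
  step <- sample(c(-1L, 1L), length(classes), replace = TRUE)
  out <- ifelse(flip, classes + step, classes)
  pmin(pmax(out, 1L), 4L)
}

#' Simulate museum specimen plumage scores
#'
#' For each species, female specimens are drawn from a two-component ordinal
#' class mixture: a heterochrome component over Classes 1--2 and an
#' androchrome component over Classes 3--4, the latter with weight
#' `androchrome_freq`. Males are Class 4. Optional symmetric class
#' misreading noise perturbs classes by one, truncated at 1 and 4.
#'
#' @param spec A [simulation_spec()].
#' @param seed Integer seed (defaults to `spec$seed`).
#' @param species_table Optional tibble with columns `species`, `n_females`,
#'   `n_males`, `androchrome_freq` overriding the per-species defaults; used
#'   by [simulate_flp_study()] to give FLP species a non-zero androchrome
#'   frequency and all other species zero.
#' @return A tibble of specimen records with columns `species`, `sex`,
#'   `plumage_class` and `sexing_method`.
#' @examples
#' spec <- simulation_spec(n_species = 3, androchrome_freq = 0)
#' sim <- simulate_specimen_scores(spec, seed = 1)
#' table(sim$plumage_class[sim$sex == "female"])
#' @export
simulate_specimen_scores <- function(spec, seed = spec$seed,
                                     species_table = NULL) {
  .assert(inherits(spec, "simulation_spec"), "`spec` must be a simulation_spec.")
  if (is.null(species_table)) {
    species_table <- tibble::tibble(
      species = sprintf("sp%03d", seq_len(spec$n_species)),
      n_females = spec$n_females, n_males = spec$n_males,
      androchrome_freq = spec$androchrome_freq)
  }
  .assert(all(c("species", "n_females", "n_males", "androchrome_freq") %in%
                names(species_table)),
          "`species_table` lacks required columns.")
  withr::with_seed(seed, {
    rows <- purrr::pmap(species_table, function(species, n_females, n_males,
                                                 androchrome_freq, ...) {
      is_andro <- runif(n_females) < androchrome_freq
      f_class <- integer(n_females)
      n_a <- sum(is_andro)
      if (n_a > 0)
        f_class[is_andro] <- sample(1:4, n_a, replace = TRUE,
                                    prob = .female_class_probs$androchrome)
      if (n_a < n_females)
        f_class[!is_andro] <- sample(1:4, n_females - n_a, replace = TRUE,
                                     prob = .female_class_probs$heterochrome)
      tibble::tibble(
        species = species,
        sex = rep(c("female", "male"), c(n_females, n_males)),
        plumage_class = c(f_class, rep(4L, n_males)))
    })
    out <- dplyr::bind_rows(rows)
    out$plumage_class <- .apply_class_noise(out$plumage_class, spec$class_noise)
    out$sexing_method <- sample(names(spec$sexing_method_probs), nrow(out),
                                replace = TRUE, prob = spec$sexing_method_probs)
    out
  })
}

.patch_cols <- function(n_patches) {
  as.vector(t(outer(sprintf("patch%02d", seq_len(n_patches)),
                    c("R", "G", "B"), paste, sep = "_")))
}

#' Simulate patch-colour and morphometric tables
#'
#' Androchrome males and Class-1 females form two clusters in patch-colour
#' space separated by `color_separation` along a random axis with isotropic
#' channel noise; variable females sit uniformly along the inter-cluster
#' segment. Bill length follows
#' `bill_mean + planted_slope * position + noise`, where position is the
#' specimen's location on the segment expressed on the standardised LD1 scale
#' (Class-1 female centroid at -1, male centroid at +1), so a fitted
#' relative-bill-length ~ LD1 slope recovers `planted_slope`.
#'
#' @inheritParams simulate_specimen_scores
#' @param species_table Optional tibble with columns `species` and
#'   `planted_slope` (and optionally `color_separation`) selecting the
#'   species to photograph and their planted effects.
#' @return A list with tibbles `colors` (one row per specimen: `specimen`,
#'   `species`, `sex`, `plumage_class`, then `patchNN_R/G/B` columns in
#'   `[0, 255]`) and `morpho` (`specimen`, `bill_mm`, `wing_mm`).
#' @examples
#' spec <- simulation_spec(n_species = 2, planted_slope = -2.5)
#' sim <- simulate_color_morphometrics(spec, seed = 3)
#' dim(sim$colors)
#' @export
simulate_color_morphometrics <- function(spec, seed = spec$seed,
                                         species_table = NULL) {
  .assert(inherits(spec, "simulation_spec"), "`spec` must be a simulation_spec.")
  if (is.null(species_table)) {
    species_table <- tibble::tibble(
      species = sprintf("sp%03d", seq_len(spec$n_species)),
      planted_slope = spec$planted_slope,
      color_separation = spec$color_separation)
  }
  if (!"color_separation" %in% names(species_table))
    species_table$color_separation <- spec$color_separation
  p <- 3L * spec$n_patches
  cols <- .patch_cols(spec$n_patches)
  withr::with_seed(seed, {
    sp_out <- purrr::pmap(species_table, function(species, planted_slope,
                                                  color_separation, ...) {
      axis <- rnorm(p)
      axis <- axis / sqrt(sum(axis^2))
      mu_f <- runif(p, 70, 180)
      mu_m <- mu_f + color_separation * axis
      n_m <- spec$n_males
      n_f1 <- spec$n_class1_females
      n_fv <- spec$n_variable_females
      n_all <- n_m + n_f1 + n_fv
      pos <- c(rep(1, n_m), rep(0, n_f1), runif(n_fv))   # position in [0,1]
      centers <- outer(pos, mu_m - mu_f) + rep(mu_f, each = n_all)
      chan <- centers + matrix(rnorm(n_all * p, sd = spec$color_noise), n_all, p)
      chan <- pmin(pmax(chan, 0), 255)
      colnames(chan) <- cols
      cls <- c(rep(4L, n_m), rep(1L, n_f1),
               cut(pos[(n_m + n_f1 + 1):n_all], c(-Inf, 1 / 3, 2 / 3, Inf),
                   labels = FALSE) + 1L)
      ld_pos <- 2 * pos - 1                               # LD1 scale: -1 .. +1
      colors <- dplyr::bind_cols(
        tibble::tibble(
          specimen = sprintf("%s_%03d", species, seq_len(n_all)),
          species = species,
          sex = rep(c("male", "female"), c(n_m, n_f1 + n_fv)),
          plumage_class = cls),
        tibble::as_tibble(chan))
      morpho <- tibble::tibble(
        specimen = colors$specimen,
        bill_mm = spec$bill_mean + planted_slope * ld_pos +
          rnorm(n_all, sd = spec$bill_noise),
        wing_mm = spec$wing_mean + rnorm(n_all, sd = 1.5))
      list(colors = colors, morpho = morpho)
    })
    list(colors = dplyr::bind_rows(purrr::map(sp_out, "colors")),
         morpho = dplyr::bind_rows(purrr::map(sp_out, "morpho")))
  })
}

.std <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0) return(x * 0)
  (x - mean(x)) / s
}

#' Simulate species-level socioecological covariates
#'
#' Continuous covariates evolve by Brownian motion on the tree; binary
#' covariates arise from thresholding a latent Brownian value. Planted FLP
#' associations shift the (standardised) latent trait of FLP species by the
#' requested effect size before thresholding or rescaling, so a phylogenetic
#' regression of FLP on the covariate recovers the planted sign.
#'
#' @param tree A rooted `phylo` tree with branch lengths.
#' @param flp_states Named character vector over all tip labels with values
#'   among `monochromic`, `dichromic`, `FLP`.
#' @param effects Named numeric vector of effect sizes (standard-deviation
#'   units); see [simulation_spec()].
#' @param seed Integer seed.
#' @return A tibble with one row per species: `species`, `flp` (0/1),
#'   `chromatism`, `migratory`, `dominance`, `body_length` (cm, within
#'   6--22), `mean_temperature` (deg C), `mean_precipitation` (mm),
#'   `temperature_predictability` and `precipitation_predictability` (0--1).
#' @examples
#' tr <- simulate_yule_tree(12, seed = 5)
#' st <- simulate_mk_tips(tr, build_rate_matrix("ER", 0.9), seed = 5)
#' cov <- simulate_covariates(tr, st$tip_states, seed = 5)
#' head(cov)
#' @export
simulate_covariates <- function(tree, flp_states, effects = NULL, seed = 1L) {
  .assert(inherits(tree, "phylo"), "`tree` must be a phylo object.")
  missing_tips <- setdiff(tree$tip.label, names(flp_states))
  .assert(length(missing_tips) == 0,
          "`flp_states` misses tips: ", paste(head(missing_tips, 5), collapse = ", "),
          class = "flpscape_invalid_argument")
  base <- c(migratory = 0, dominance = 0, body_length = 0,
            mean_temperature = 0, mean_precipitation = 0,
            temperature_predictability = 0, precipitation_predictability = 0)
  if (!is.null(effects)) {
    .assert(is.numeric(effects) && all(names(effects) %in% names(base)),
            "`effects` must be named after known covariates.")
    base[names(effects)] <- effects
  }
  effects <- base
  flp_states <- flp_states[tree$tip.label]
  flp01 <- as.numeric(flp_states == "FLP")
  withr::with_seed(seed, {
    latent <- function(effect) .std(ape::rTraitCont(tree, model = "BM")) +
      effect * flp01
    mig <- latent(effects["migratory"])
    dom <- latent(effects["dominance"])
    bl <- latent(effects["body_length"])
    tibble::tibble(
      species = tree$tip.label,
      flp = flp01,
      chromatism = unname(flp_states),
      migratory = as.integer(mig > quantile(mig, 0.75)),
      dominance = as.integer(dom > quantile(dom, 0.70)),
      body_length = pmin(pmax(12 + 3 * bl, 6), 22),
      mean_temperature = 20 + 4 * latent(effects["mean_temperature"]),
      mean_precipitation = pmax(1500 + 400 * latent(effects["mean_precipitation"]), 0),
      temperature_predictability =
        pmin(pmax(0.6 + 0.15 * latent(effects["temperature_predictability"]), 0), 1),
      precipitation_predictability =
        pmin(pmax(0.5 + 0.15 * latent(effects["precipitation_predictability"]), 0), 1))
  })
}

#' Simulate a complete synthetic FLP study
#'
#' Chains all generators: a Yule tree, a three-state plumage character evolved
#' under `spec$q_true`, per-species specimen scores (FLP species receive
#' `spec$androchrome_freq`, all others 0), patch-colour and morphometric
#' series for the FLP species, and species-level covariates with any planted
#' effects.
#'
#' @inheritParams simulate_specimen_scores
#' @return A list with `tree`, `specimens`, `colors`, `morpho`, `covariates`,
#'   `dichromatism` (species-level flag tibble) and `truth` (the generating
#'   states and parameters).
#' @examples
#' study <- simulate_flp_study(simulation_spec(n_species = 12), seed = 2)
#' names(study)
#' @export
simulate_flp_study <- function(spec, seed = spec$seed) {
  .assert(inherits(spec, "simulation_spec"), "`spec` must be a simulation_spec.")
  tree <- simulate_yule_tree(spec$n_species, spec$birth_rate, seed = seed)
  mk <- simulate_mk_tips(tree, spec$q_true, seed = seed + 1L)
  st <- tibble::tibble(
    species = tree$tip.label,
    n_females = spec$n_females, n_males = spec$n_males,
    androchrome_freq = ifelse(mk$tip_states[tree$tip.label] == "FLP",
                              spec$androchrome_freq, 0))
  specimens <- simulate_specimen_scores(spec, seed = seed + 2L,
                                        species_table = st)
  flp_sp <- names(mk$tip_states)[mk$tip_states == "FLP"]
  colors <- morpho <- NULL
  if (length(flp_sp) > 0) {
    cm <- simulate_color_morphometrics(
      spec, seed = seed + 3L,
      species_table = tibble::tibble(species = flp_sp,
                                     planted_slope = spec$planted_slope))
    colors <- cm$colors
    morpho <- cm$morpho
  }
  covariates <- simulate_covariates(tree, mk$tip_states,
                                    spec$covariate_effects, seed = seed + 4L)
  dichromatism <- tibble::tibble(
    species = tree$tip.label,
    dichromatism = ifelse(mk$tip_states[tree$tip.label] == "monochromic",
                          "monochromic", "dichromic"))
  list(tree = tree, specimens = specimens, colors = colors, morpho = morpho,
       covariates = covariates, dichromatism = dichromatism,
       truth = list(tip_states = mk$tip_states, node_states = mk$node_states,
                    spec = spec, seed = seed))
}
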