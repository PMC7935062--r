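#' Read a study phylogeny from a Newick file
#'
#' Reads a single rooted tree, checks branch lengths and tip-label
#' uniqueness, and deterministically names unlabelled internal nodes
#' (`node<k>` in preorder numbering). Malformed files raise a parse error
#' with the character offset of the first unbalanced parenthesis.
#'
#' @param path Path to a Newick file containing one tree.
#' @return A `phylo` tree.
#' @examples
#' f <- tempfile(fileext = ".nwk")
#' writeLines("((A:1,B:1):1,C:2);", f)
#' read_study_tree(f)
#' @export
read_study_tree <- function(path) {
  .assert(file.exists(path), "File not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  for (i in seq_len(nchar(txt))) {
    ch <- substr(txt, i, i)
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    .assert(depth >= 0, "Newick parse error: unbalanced ')' at character ", i,
            class = "flpscape_parse_error")
  }
  .assert(depth == 0, "Newick parse error: ", depth,
          " unclosed '(' at end of input (character ", nchar(txt), ").",
          class = "flpscape_parse_error")
  .assert(grepl(";", txt, fixed = TRUE),
          "Newick parse error: missing terminating ';'.",
          class = "flpscape_parse_error")
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) .assert(FALSE, "Newick parse error: ",
                                               conditionMessage(e),
                                               class = "flpscape_parse_error"))
  .assert(inherits(tree, "phylo"),
          "Expected exactly one tree in ", path, ".",
          class = "flpscape_parse_error")
  .assert(!is.null(tree$edge.length), "Tree has no branch lengths.",
          class = "flpscape_parse_error")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  .assert(length(dup) == 0, "Duplicate tip labels: ",
          paste(unique(dup), collapse = ", "), class = "flpscape_validation_error")
  n_tip <- ape::Ntip(tree)
  if (is.null(tree$node.label) || any(!nzchar(tree$node.label))) {
    labs <- if (is.null(tree$node.label)) rep("", tree$Nnode) else tree$node.label
    auto <- paste0("node", (n_tip + 1L):(n_tip + tree$Nnode))
    tree$node.label <- ifelse(nzchar(labs), labs, auto)
  }
  if (!ape::is.binary(tree)) {
    message("Polytomies resolved arbitrarily with zero-length branches.")
    tree <- ape::multi2di(tree)
  }
  tree
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_study_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# generic validated CSV reader: spec = list(column = checker function or NULL)
.read_validated_csv <- function(path, required, row_checks = list()) {
  .assert(file.exists(path), "File not found: ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(tab))
  .assert(length(missing) == 0, "Missing required column(s): ",
          paste(missing, collapse = ", "), class = "flpscape_schema_error")
  bad <- rep(FALSE, nrow(tab))
  reasons <- character(nrow(tab))
  for (col in names(row_checks)) {
    ok <- row_checks[[col]](tab[[col]])
    newly <- !ok & !bad
    reasons[newly] <- paste0("invalid ", col, ": ", tab[[col]][newly])
    bad <- bad | !ok
  }
  rejected <- tibble::tibble(row = which(bad), reason = reasons[bad])
  if (nrow(rejected) > 0) {
    warning(nrow(rejected), " row(s) rejected during validation of ",
            basename(path), "; see attr(, \"rejected\").")
  }
  out <- tab[!bad, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}

#' Read a specimen score table
#'
#' CSV columns: `species`, `sex` (`female`/`male`/`unknown`),
#' `plumage_class` (1--4), `sexing_method` (`gonad`/`unknown`/`plumage`).
#' Invalid rows are rejected (with a warning) and reported in the
#' `"rejected"` attribute; valid rows are kept.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_specimen_table <- function(path) {
  .read_validated_csv(
    path, c("species", "sex", "plumage_class", "sexing_method"),
    list(sex = function(x) x %in% c("female", "male", "unknown"),
         plumage_class = function(x) !is.na(x) & x %in% 1:4,
         sexing_method = function(x) x %in% c("gonad", "unknown", "plumage")))
}

#' Read a patch-colour table
#'
#' CSV columns: `specimen`, `species`, `sex`, `plumage_class` plus
#' `patchNN_R/G/B` channel columns in `[0, 255]`.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_color_table <- function(path) {
  tab <- .read_validated_csv(
    path, c("specimen", "species", "sex", "plumage_class"),
    list(plumage_class = function(x) !is.na(x) & x %in% 1:4))
  chan <- grep("^patch\\d+_[RGB]$", names(tab), value = TRUE)
  .assert(length(chan) >= 3, "No patchNN_R/G/B channel columns found.",
          class = "flpscape_schema_error")
  vals <- as.matrix(tab[, chan])
  ok <- rowSums(!is.finite(vals) | vals < 0 | vals > 255) == 0
  if (!all(ok)) {
    warning(sum(!ok), " row(s) rejected: channel values outside [0, 255].")
    rej <- dplyr::bind_rows(attr(tab, "rejected"),
                            tibble::tibble(row = which(!ok),
                                           reason = "channel outside [0,255]"))
    tab <- tab[ok, , drop = FALSE]
    attr(tab, "rejected") <- rej
  }
  tab
}

#' Read a morphometrics table
#'
#' CSV columns: `specimen`, `bill_mm`, `wing_mm` (positive lengths).
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_morpho_table <- function(path) {
  .read_validated_csv(
    path, c("specimen", "bill_mm", "wing_mm"),
    list(bill_mm = function(x) is.finite(x) & x > 0,
         wing_mm = function(x) is.finite(x) & x > 0))
}

#' Read a species covariate table
#'
#' CSV columns: `species`, `flp` (0/1), `chromatism`, `migratory`,
#' `dominance`, `body_length`, `mean_temperature`, `mean_precipitation`,
#' `temperature_predictability`, `precipitation_predictability`.
#'
#' @param path Path to the CSV file.
#' @return A validated tibble.
#' @export
read_covariate_table <- function(path) {
  .read_validated_csv(
    path, c("species", "flp", "chromatism", "migratory", "dominance",
            "body_length", "mean_temperature", "mean_precipitation",
            "temperature_predictability", "precipitation_predictability"),
    list(flp = function(x) x %in% c(0, 1),
         chromatism = function(x) x %in% c("monochromic", "dichromic", "FLP"),
         migratory = function(x) x %in% c(0, 1),
         dominance = function(x) x %in% c(0, 1),
         body_length = function(x) is.finite(x) & x > 0))
}

#' Reconcile table species against the tree
#'
#' @param species Character vector of species labels from a data table.
#' @param tree A `phylo` tree.
#' @return A list with `shared`, `in_table_not_tree`, `in_tree_not_table`.
#' @examples
#' tr <- simulate_yule_tree(4, seed = 1)
#' reconcile_species(c("sp001", "zzz"), tr)
#' @export
reconcile_species <- function(species, tree) {
  species <- unique(species)
  list(shared = intersect(species, tree$tip.label),
       in_table_not_tree = setdiff(species, tree$tip.label),
       in_tree_not_table = setdiff(tree$tip.label, species))
}

#' Pipeline configuration
#'
#' Either a simulation spec (synthetic study) or paths to real input files
#' (tree plus tables) -- exactly one of the two -- along with analysis
#' settings.
#'
#' @param simulation A [simulation_spec()], or `NULL` when reading files.
#' @param tree_path,specimen_path,color_path,morpho_path,covariate_path,dichromatism_path
#'   Input file paths for a real-data run (`dichromatism_path` points to a
#'   CSV with columns `species`, `dichromatism`).
#' @param config_grid Sensitivity grid (default [default_sensitivity_grid()]).
#' @param models Mk models to fit per matrix.
#' @param asr_matrices Matrix ids to run the ancestral reconstruction on
#'   (default: all in the grid).
#' @param alpha_family,n_tests Family-wise error rate and number of
#'   morphology tests for the Bonferroni correction (`n_tests = NULL` uses
#'   the number of validated species).
#' @param n_boot Dip bootstrap replicates.
#' @param restarts Optimiser restarts per Mk fit.
#' @param seed Master seed recorded in the manifest.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(simulation = NULL, tree_path = NULL,
                            specimen_path = NULL, color_path = NULL,
                            morpho_path = NULL, covariate_path = NULL,
                            dichromatism_path = NULL,
                            config_grid = default_sensitivity_grid(),
                            models = c("ER", "SYM", "ARD"),
                            asr_matrices = NULL,
                            alpha_family = 0.05, n_tests = NULL,
                            n_boot = 500, restarts = 5, seed = 1L) {
  has_sim <- !is.null(simulation)
  has_paths <- !is.null(tree_path)
  .assert(xor(has_sim, has_paths),
          "Supply exactly one of `simulation` or real-data paths.")
  if (has_sim) {
    .assert(inherits(simulation, "simulation_spec"),
            "`simulation` must come from simulation_spec().")
  } else {
    .assert(!is.null(specimen_path) && !is.null(dichromatism_path),
            "Real-data runs need at least tree, specimen and dichromatism paths.")
  }
  .assert(all(models %in% c("ER", "SYM", "ARD")), "Unknown Mk model.")
  structure(list(simulation = simulation, tree_path = tree_path,
                 specimen_path = specimen_path, color_path = color_path,
                 morpho_path = morpho_path, covariate_path = covariate_path,
                 dichromatism_path = dichromatism_path,
                 config_grid = config_grid, models = models,
                 asr_matrices = asr_matrices, alpha_family = alpha_family,
                 n_tests = n_tests, n_boot = n_boot, restarts = restarts,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("Stage [", name, "] failed: ", conditionMessage(e), call. = FALSE)
  })
  log(name, proc.time()[["elapsed"]] - t0)
  res
}

#' Run the full FLP analysis pipeline
#'
#' Executes simulate (optional) -> classify (+ sensitivity grid) -> ancestral
#' reconstruction per matrix -> androchromy/morphometrics -> phylogenetic
#' comparative models, writing every artefact to `out_dir` along with a
#' manifest (inputs, seeds, package version, per-file checksums, per-stage
#' timings) and a human-readable report. Any stage failure halts the run
#' with a stage-labelled error; artefacts written before the failure are
#' retained.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(simulation = simulation_spec(n_species = 15),
#'                        models = "ER", n_boot = 100, restarts = 2)
#' res <- run_pipeline(cfg, tempfile("study"))
#' }
#' @export
run_pipeline <- function(config, out_dir) {
  .assert(inherits(config, "pipeline_config"),
          "`config` must come from pipeline_config().")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  log <- function(name, secs) timings[[name]] <<- round(secs, 3)
  seed <- config$seed

  inputs <- .stage("inputs", log, {
    if (!is.null(config$simulation)) {
      study <- simulate_flp_study(config$simulation, seed = seed)
      write_study_tree(study$tree, file.path(out_dir, "tree.nwk"))
      readr::write_csv(study$specimens, file.path(out_dir, "specimens.csv"))
      if (!is.null(study$colors)) {
        readr::write_csv(study$colors, file.path(out_dir, "colors.csv"))
        readr::write_csv(study$morpho, file.path(out_dir, "morpho.csv"))
      }
      readr::write_csv(study$covariates, file.path(out_dir, "covariates.csv"))
      readr::write_csv(study$dichromatism, file.path(out_dir, "dichromatism.csv"))
      study
    } else {
      tree <- read_study_tree(config$tree_path)
      specimens <- read_specimen_table(config$specimen_path)
      list(tree = tree, specimens = specimens,
           colors = if (!is.null(config$color_path))
             read_color_table(config$color_path),
           morpho = if (!is.null(config$morpho_path))
             read_morpho_table(config$morpho_path),
           covariates = if (!is.null(config$covariate_path))
             read_covariate_table(config$covariate_path),
           dichromatism = readr::read_csv(config$dichromatism_path,
                                          show_col_types = FALSE))
    }
  })

  recon <- reconcile_species(unique(inputs$specimens$species), inputs$tree)

  classifications <- .stage("classify", log, {
    cls <- build_sensitivity_matrices(inputs$specimens, inputs$dichromatism,
                                      config$config_grid,
                                      n_boot = config$n_boot, seed = seed)
    readr::write_csv(cls, file.path(out_dir, "classifications.csv"))
    cls
  })

  asr_ids <- config$asr_matrices
  if (is.null(asr_ids)) asr_ids <- unique(classifications$matrix_id)
  asr_results <- .stage("asr", log, {
    res <- lapply(asr_ids, function(id) {
      cls <- dplyr::filter(classifications, .data$matrix_id == id)
      states <- classification_to_states(cls)
      states <- states[names(states) %in% inputs$tree$tip.label]
      if (length(states) < 4 || length(unique(states)) < 2) return(NULL)
      tr <- prune_to_data(inputs$tree, names(states))
      fits <- lapply(config$models, function(m)
        fit_mk_model(tr, states, m, restarts = config$restarts, seed = seed))
      sel <- select_models(fits)
      best <- attr(sel, "fits")[[1]]
      asr <- marginal_asr(tr, states, best$q_matrix, best$root_prior)
      origins <- count_independent_origins(asr, "FLP")
      readr::write_csv(dplyr::bind_cols(tibble::tibble(matrix_id = id),
                                        tidy(asr)),
                       file.path(out_dir, paste0("asr_", id, ".csv")))
      list(matrix_id = id, selection = sel, best = best, asr = asr,
           origins = origins)
    })
    res <- res[!vapply(res, is.null, TRUE)]
    sel_tab <- purrr::map_dfr(res, function(r)
      dplyr::bind_cols(tibble::tibble(matrix_id = r$matrix_id), r$selection))
    if (nrow(sel_tab) > 0)
      readr::write_csv(sel_tab, file.path(out_dir, "model_selection.csv"))
    org <- tibble::tibble(matrix_id = vapply(res, `[[`, "", "matrix_id"),
                          flp_origins = vapply(res, `[[`, 0L, "origins"))
    readr::write_csv(org, file.path(out_dir, "origin_counts.csv"))
    res
  })

  slopes <- NULL
  k_report <- NULL
  if (!is.null(inputs$colors)) {
    slopes <- .stage("morph", log, {
      n_sp <- length(unique(inputs$colors$species))
      n_tests <- config$n_tests %||% n_sp
      alpha <- bonferroni_alpha(n_tests, config$alpha_family)
      sl <- androchromy_slopes(inputs$colors, inputs$morpho, alpha = alpha)
      readr::write_csv(sl, file.path(out_dir, "slopes.csv"))
      ok <- sl$validated & is.finite(sl$slope)
      if (sum(ok) >= 4 &&
          length(intersect(sl$species[ok], inputs$tree$tip.label)) >= 4) {
        k_report <- blomberg_k(inputs$tree,
                               setNames(sl$slope[ok], sl$species[ok]),
                               n_perm = 999, seed = seed)
        readr::write_csv(k_report, file.path(out_dir, "blomberg_k.csv"))
      }
      sl
    })
  }

  pgls_results <- NULL
  if (!is.null(inputs$covariates)) {
    pgls_results <- .stage("comparative", log, {
      combos <- tidyr::expand_grid(model = c("social", "climate"),
                                   exclude_monochromic = c(FALSE, TRUE))
      res <- purrr::pmap(combos, function(model, exclude_monochromic) {
        fit <- tryCatch(run_flp_models(inputs$covariates, inputs$tree, model,
                                       exclude_monochromic),
                        error = function(e) NULL)
        if (is.null(fit)) return(NULL)
        dplyr::bind_cols(tibble::tibble(model = model,
                                        exclude_monochromic = exclude_monochromic),
                         tidy(fit))
      })
      tab <- dplyr::bind_rows(res)
      readr::write_csv(tab, file.path(out_dir, "pgls_coefficients.csv"))
      tab
    })
  }

  manifest <- .stage("manifest", log, {
    files <- list.files(out_dir, full.names = TRUE)
    files <- files[!basename(files) %in% c("manifest.json", "report.md")]
    m <- list(
      package = "flpscape",
      version = as.character(utils::packageVersion("flpscape")),
      seed = seed,
      inputs = if (!is.null(config$simulation)) "simulated" else "files",
      n_species_tree = ape::Ntip(inputs$tree),
      species_in_table_not_tree = recon$in_table_not_tree,
      stage_seconds = timings,
      checksums = as.list(tools::md5sum(files)))
    jsonlite::write_json(m, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    m
  })

  .stage("report", log, {
    con <- file.path(out_dir, "report.md")
    lines <- c("# FLP study report", "",
               paste0("Seed: ", seed, "; species in tree: ",
                      ape::Ntip(inputs$tree)), "",
               "## Classification counts per sensitivity matrix", "")
    counts <- classifications |>
      dplyr::count(.data$matrix_id, .data$status) |>
      tidyr::pivot_wider(names_from = "status", values_from = "n",
                         values_fill = 0L)
    lines <- c(lines, knitr_kable_fallback(counts))
    if (length(asr_results) > 0) {
      org <- vapply(asr_results, `[[`, 0L, "origins")
      lines <- c(lines, "", "## Independent FLP origins per matrix", "",
                 paste0("- ", vapply(asr_results, `[[`, "", "matrix_id"),
                        ": ", org))
    }
    if (!is.null(slopes)) {
      lines <- c(lines, "", "## Relative bill length ~ LD1 slopes", "",
                 knitr_kable_fallback(slopes[, c("species", "validated",
                                                 "slope", "p_value",
                                                 "significant")]))
    }
    writeLines(lines, con)
    con
  })

  invisible(list(inputs = inputs, classifications = classifications,
                 asr = asr_results, slopes = slopes, k = k_report,
                 pgls = pgls_results, manifest = manifest))
}

# minimal pipe-table formatter (avoids a knitr dependency)
knitr_kable_fallback <- function(df) {
  df <- as.data.frame(df)
  fmt <- function(x) if (is.numeric(x)) format(x, digits = 4) else as.character(x)
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
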