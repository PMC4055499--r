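#' Derive a stage seed from the master seed
#'
#' Child seeds are a deterministic hash of (master seed, stage name), so
#' each stage is reproducible on its own and insensitive to reordering of
#' the other stages.
#'
#' @param master Integer master seed.
#' @param stage Stage name.
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
stage_seed <- function(master, stage) {
  h <- as.double(master) %% 2147483647
  for (k in utf8ToInt(stage)) h <- (h * 31 + k) %% 2147483647
  as.integer(h + 1)
}

#' Pipeline run configuration
#'
#' Bundles the cohort configuration with the analysis parameters of every
#' downstream stage. Defaults keep a full run on a laptop-size budget.
#'
#' @param cohort A [cohort_config()] (its `seed` is overridden by the
#'   stage seed derived from `master_seed`).
#' @param sparsity_grid Sparsity sweep for the network stage.
#' @param n_random Random nulls per sparsity for relative efficiency.
#' @param bootstrap_B Bootstrap replicates for group-level structural
#'   networks.
#' @param variance_threshold PCA variance share for the component count
#'   (0.95 or 0.99).
#' @param z_threshold Threshold for seed-map N/Z summaries.
#' @param kfold Folds for cross-validated classification.
#' @param bonferroni_factor Regional correction factor.
#' @param predict_scores Phenotype scores to predict.
#' @param master_seed Master seed; every stage derives its own from it.
#' @return A `run_config` list.
#' @export
run_config <- function(cohort = cohort_config(),
                       sparsity_grid = seq(0.05, 0.5, by = 0.05),
                       n_random = 5, bootstrap_B = 20,
                       variance_threshold = 0.95, z_threshold = 2.3,
                       kfold = 10, bonferroni_factor = 8,
                       predict_scores = c("ados_module", "iq_full",
                                          "adir_total"),
                       master_seed = 1L) {
  stopifnot(inherits(cohort, "cohort_config"),
            all(sparsity_grid > 0 & sparsity_grid <= 1),
            n_random >= 1, bootstrap_B >= 2,
            variance_threshold > 0 && variance_threshold <= 1,
            kfold >= 2 && kfold <= 10)
  structure(list(cohort = cohort, sparsity_grid = sparsity_grid,
                 n_random = n_random, bootstrap_B = bootstrap_B,
                 variance_threshold = variance_threshold,
                 z_threshold = z_threshold, kfold = kfold,
                 bonferroni_factor = bonferroni_factor,
                 predict_scores = predict_scores,
                 master_seed = as.integer(master_seed)),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes the seven stages in dependency order -- simulate, networks
#' (connectivity matrices, efficiency profiles and group comparison),
#' features, select, classify, predict, stats -- writing every
#' intermediate artifact as TSV/JSON under `out_dir` plus a `manifest.json`
#' (stage list, seeds, parameter echo). Re-running with an identical
#' configuration reproduces identical artifacts.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest list, invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- c("simulate", "networks", "features", "select", "classify",
              "predict", "stats")
  seeds <- vapply(stages, stage_seed, integer(1),
                  master = config$master_seed)
  manifest <- list(package = "asdconnectome",
                   version = as.character(utils::packageVersion("asdconnectome")),
                   master_seed = config$master_seed,
                   stage_seeds = as.list(seeds), stages = list())
  note <- function(stage, outputs)
    manifest$stages[[stage]] <<- list(seed = unname(seeds[stage]),
                                      outputs = outputs)
  run_stage <- function(stage, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  ## simulate ------------------------------------------------------------
  cohort <- NULL
  run_stage("simulate", function() {
    cfg <- config$cohort
    cfg$seed <- seeds[["simulate"]]
    cohort <<- generate_cohort(cfg)
    write_cohort(cohort, file.path(out_dir, "cohort"))
    note("simulate", "cohort/")
  })

  ## networks ------------------------------------------------------------
  run_stage("networks", function() {
    outs <- character(0)
    for (grp in c("TD", "ASD")) {
      m <- structural_covariance_matrix(cohort, "thickness", grp)
      f <- sprintf("covariance_thickness_%s.tsv", grp)
      write_connectivity(m, file.path(out_dir, f))
      outs <- c(outs, f)
    }
    boot <- lapply(c(TD = "TD", ASD = "ASD"), function(grp)
      bootstrap_efficiency_profiles(
        cohort, "thickness", grp, grid = config$sparsity_grid,
        B = config$bootstrap_B, n_random = config$n_random,
        seed = seeds[["networks"]] + (grp == "ASD") * 10000L))
    cmp <- compare_efficiency(boot$ASD, boot$TD, mode = "bootstrap")
    utils::write.table(cmp, file.path(out_dir,
                                      "efficiency_thickness_compare.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    prof <- efficiency_profile(
      structural_covariance_matrix(cohort, "thickness", "TD"),
      grid = config$sparsity_grid, n_random = config$n_random,
      seed = seeds[["networks"]])
    write_profile(prof, file.path(out_dir, "efficiency_thickness_TD.tsv"))
    note("networks", c(outs, "efficiency_thickness_compare.tsv",
                       "efficiency_thickness_TD.tsv"))
  })

  ## features ------------------------------------------------------------
  features <- NULL
  run_stage("features", function() {
    features <<- compute_feature_table(cohort, config$z_threshold)
    utils::write.table(as.data.frame(features),
                       file.path(out_dir, "features.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("features", "features.tsv")
  })

  ## select --------------------------------------------------------------
  selection <- NULL
  run_stage("select", function() {
    normed <- variance_normalize(features)
    k <- component_count(normed, config$variance_threshold)
    selection <<- mrmr_select(normed, features$group, k)
    write_selection(selection, file.path(out_dir, "selection.json"),
                    variance_threshold = config$variance_threshold)
    note("select", "selection.json")
  })

  ## classify ------------------------------------------------------------
  run_stage("classify", function() {
    sel_tab <- features[, c("id", "group", selection$selected)]
    class(sel_tab) <- class(features)
    full <- evaluate("random_tree", sel_tab,
                     protocol = "full_dataset",
                     seed = seeds[["classify"]])
    cv <- evaluate("random_tree", sel_tab, protocol = "kfold",
                   param = config$kfold, seed = seeds[["classify"]])
    model <- fit_random_tree(sel_tab, seed = seeds[["classify"]])
    mc <- margin_curve(model, sel_tab)
    utils::write.table(mc, file.path(out_dir, "margin_curve.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(full_dataset_accuracy = full$accuracy,
           kfold = config$kfold, kfold_accuracy = cv$accuracy,
           fold_accuracies = cv$fold_accuracies,
           selected_features = selection$selected),
      file.path(out_dir, "classify.json"), auto_unbox = TRUE, digits = NA)
    note("classify", c("classify.json", "margin_curve.tsv"))
  })

  ## predict -------------------------------------------------------------
  run_stage("predict", function() {
    asd <- features$group == "ASD"
    res <- lapply(config$predict_scores, function(sc) {
      y <- cohort$phenotypes[[sc]][match(features$id,
                                         cohort$phenotypes$id)]
      use_all <- !all(is.na(y[!asd]))
      idx <- if (use_all) rep(TRUE, nrow(features)) else asd
      tab <- features[idx, , drop = FALSE]
      class(tab) <- class(features)
      pp <- predict_phenotype(tab, selection, y[idx],
                              protocol = "kfold", k = config$kfold,
                              seed = seeds[["predict"]])
      list(score = sc, r = pp$r, slope = pp$slope, p = pp$p,
           n = length(pp$fitted))
    })
    jsonlite::write_json(res, file.path(out_dir, "predict.json"),
                         auto_unbox = TRUE, digits = NA)
    note("predict", "predict.json")
  })

  ## stats ---------------------------------------------------------------
  run_stage("stats", function() {
    for (ms in c("volume", "thickness")) {
      rc <- region_comparison(cohort, ms,
                              bonferroni_factor = config$bonferroni_factor)
      utils::write.table(rc,
                         file.path(out_dir, sprintf("regions_%s.tsv", ms)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    pc <- phenotype_correlations(features, cohort$phenotypes)
    utils::write.table(pc, file.path(out_dir, "phenocorr.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    note("stats", c("regions_volume.tsv", "regions_thickness.tsv",
                    "phenocorr.tsv"))
  })

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
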