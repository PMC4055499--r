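#' Write a cohort to a directory of TSV/JSON artifacts
#'
#' Lays the cohort out as diff-able text files: `subjects.tsv`
#' (demographics, supratentorial volume and phenotype scores),
#' `thickness.tsv` and `volumes.tsv` (subjects x regions), one
#' `timeseries/<id>.tsv` per subject (ROI x time) and `meta.json` (region
#' names, homotopic pairs, seed sets, configuration echo).
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "timeseries"), recursive = TRUE,
             showWarnings = FALSE)
  tsv <- function(x, path) utils::write.table(
    x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  subj <- merge(cohort$subjects, cohort$phenotypes, by = "id", sort = FALSE)
  tsv(subj, file.path(dir, "subjects.tsv"))
  mat_tsv <- function(m, path)
    tsv(data.frame(id = rownames(m), m, check.names = FALSE), path)
  mat_tsv(cohort$thickness, file.path(dir, "thickness.tsv"))
  mat_tsv(cohort$volumes, file.path(dir, "volumes.tsv"))
  for (id in names(cohort$timeseries)) {
    m <- cohort$timeseries[[id]]
    tsv(data.frame(roi = rownames(m), m, check.names = FALSE),
        file.path(dir, "timeseries", paste0(id, ".tsv")))
  }
  # jsonlite drops names on atomic vectors; promote named numerics to
  # objects so the config echo round-trips
  namify <- function(x) {
    if (is.list(x)) lapply(x, namify)
    else if (is.numeric(x) && !is.null(names(x))) as.list(x)
    else x
  }
  meta <- list(region_names = cohort$region_names,
               homotopic_pairs = unname(apply(cohort$homotopic_pairs, 1, c,
                                              simplify = FALSE)),
               cortical_pairs = unname(apply(cohort$cortical_pairs, 1, c,
                                             simplify = FALSE)),
               seed_sets = cohort$seed_sets, networks = cohort$networks,
               feature_volumes = cohort$feature_volumes,
               config = namify(unclass(cohort$config)))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a cohort from a directory
#'
#' Counterpart of [write_cohort()].
#'
#' @param dir Directory containing the cohort artifacts.
#' @return A `cohort` object.
#' @export
read_cohort <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE,
                              simplifyDataFrame = FALSE)
  subj <- utils::read.delim(file.path(dir, "subjects.tsv"),
                            stringsAsFactors = FALSE)
  pheno_cols <- setdiff(names(subj),
                        c("id", "group", "age", "sex", "supratentorial"))
  read_mat <- function(path, key) {
    d <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d[[key]]
    m
  }
  thickness <- read_mat(file.path(dir, "thickness.tsv"), "id")
  volumes <- read_mat(file.path(dir, "volumes.tsv"), "id")
  ts <- lapply(subj$id, function(id) {
    m <- read_mat(file.path(dir, "timeseries", paste0(id, ".tsv")), "roi")
    colnames(m) <- NULL  # time axis carries no labels
    m
  })
  names(ts) <- subj$id
  cfg <- meta$config
  num <- function(x) if (is.null(x)) numeric(0) else unlist(x)
  pm <- lapply(cfg$phenotype_model, function(m) {
    m$beta <- num(m$beta)
    m$range <- num(m$range)
    m
  })
  config <- cohort_config(
    n_per_group = cfg$n_per_group, n_cortical = cfg$n_cortical,
    n_roi = cfg$n_roi, n_timepoints = cfg$n_timepoints,
    tr_seconds = cfg$tr_seconds, n_subcortical = cfg$n_subcortical,
    n_wm = cfg$n_wm,
    volume_effects = num(cfg$volume_effects),
    thickness_effects = num(cfg$thickness_effects),
    covariance_strength = lapply(cfg$covariance_strength, unlist),
    spatial_decay = cfg$spatial_decay,
    seed_connectivity = lapply(cfg$seed_connectivity, unlist),
    homotopic_strength = unlist(cfg$homotopic_strength),
    volume_noise_sd = cfg$volume_noise_sd,
    thickness_noise_sd = cfg$thickness_noise_sd,
    band = num(cfg$band),
    phenotype_model = pm,
    seed = cfg$seed)
  to_pairs <- function(x) {
    m <- if (is.matrix(x)) x else do.call(rbind, x)
    storage.mode(m) <- "integer"
    colnames(m) <- c("left", "right")
    m
  }
  pairs <- to_pairs(meta$homotopic_pairs)
  cpairs <- to_pairs(meta$cortical_pairs)
  structure(list(
    subjects = subj[, c("id", "group", "age", "sex", "supratentorial")],
    thickness = thickness, volumes = volumes, timeseries = ts,
    phenotypes = subj[, c("id", pheno_cols)],
    region_names = meta$region_names,
    homotopic_pairs = pairs, cortical_pairs = cpairs,
    seed_sets = lapply(meta$seed_sets, as.integer),
    networks = lapply(meta$networks, as.integer),
    feature_volumes = meta$feature_volumes,
    config = config), class = "cohort")
}
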