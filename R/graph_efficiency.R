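#' All-pairs shortest path lengths
#'
#' Breadth-first-search distances between every node pair of a binary
#' graph; unreachable pairs are `Inf`, the diagonal is 0.
#'
#' @param g A `binary_graph`.
#' @return Numeric distance matrix.
#' @export
shortest_path_lengths <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  d <- .apsp_bfs(g$adjacency)
  dimnames(d) <- dimnames(g$adjacency)
  d
}

#' Global efficiency
#'
#' Mean inverse shortest-path length over ordered node pairs,
#' \eqn{E_{glob} = \frac{1}{n(n-1)} \sum_{i \ne j} 1/d_{ij}}, with
#' \eqn{1/\infty = 0} so disconnected pairs contribute nothing. Equals 1
#' for the complete graph and 0 for the empty graph.
#'
#' @param g A `binary_graph` with at least 2 nodes.
#' @return Scalar in \[0, 1\].
#' @export
global_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (nrow(g$adjacency) < 2) stop("need at least 2 nodes")
  .global_efficiency_cpp(g$adjacency)
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of the subgraph induced by
#' each node's neighbours; nodes with fewer than 2 neighbours contribute
#' 0. Captures fault-tolerant local clustering.
#'
#' @param g A `binary_graph` with at least 2 nodes.
#' @return Scalar in \[0, 1\].
#' @export
local_efficiency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  if (nrow(g$adjacency) < 2) stop("need at least 2 nodes")
  .local_efficiency_cpp(g$adjacency)
}

#' Small-world efficiency profile over a sparsity grid
#'
#' At each sparsity `s` of the grid the connectivity matrix is binarized
#' ([threshold_at_sparsity()]), absolute global and local efficiency are
#' computed, and relative efficiencies are obtained by dividing by the
#' mean of the same metric over `n_random` degree-matched random rewirings
#' of the thresholded graph. Total efficiency is recorded as the sum of
#' local and global (per variant). Sparsities at which thresholding fails
#' (e.g. too few positive weights) yield `NA` rows with the error message
#' recorded in the `errors` attribute rather than aborting the sweep.
#'
#' @param m A `connectivity_matrix`.
#' @param grid Numeric vector of sparsities in (0, 1]; default
#'   `seq(0.05, 0.5, by = 0.05)`.
#' @param n_random Number of random nulls per sparsity (default 100).
#' @param seed Integer seed for the null rewirings.
#' @param metrics Which absolute metrics to compute: subset of
#'   `c("global", "local")`.
#' @param n_swaps Accepted swaps per rewiring (default 10x edge count).
#' @return An `efficiency_profile`: data frame with columns `sparsity`,
#'   `e_global_abs`, `e_local_abs`, `e_global_rel`, `e_local_rel`,
#'   `e_total_abs`, `e_total_rel`; attributes `n_random`, `seed`,
#'   `errors`.
#' @export
efficiency_profile <- function(m, grid = seq(0.05, 0.5, by = 0.05),
                               n_random = 100, seed = 1L,
                               metrics = c("global", "local"),
                               n_swaps = NULL) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (any(grid <= 0) || any(grid > 1)) stop("grid must lie in (0, 1]")
  if (n_random < 1) stop("n_random must be >= 1")
  metrics <- match.arg(metrics, several.ok = TRUE)
  set.seed(seed)
  k <- length(grid)
  na <- rep(NA_real_, k)
  out <- data.frame(sparsity = grid, e_global_abs = na, e_local_abs = na,
                    e_global_rel = na, e_local_rel = na,
                    e_total_abs = na, e_total_rel = na)
  errors <- character(0)
  for (i in seq_len(k)) {
    g <- tryCatch(threshold_at_sparsity(m, grid[i]), error = identity)
    if (inherits(g, "error")) {
      errors[as.character(grid[i])] <- conditionMessage(g)
      next
    }
    eg <- if ("global" %in% metrics) .global_efficiency_cpp(g$adjacency) else NA_real_
    el <- if ("local" %in% metrics) .local_efficiency_cpp(g$adjacency) else NA_real_
    null_g <- null_l <- numeric(n_random)
    for (b in seq_len(n_random)) {
      r <- degree_matched_random(g, n_swaps = n_swaps)
      null_g[b] <- if ("global" %in% metrics)
        .global_efficiency_cpp(r$adjacency) else NA_real_
      null_l[b] <- if ("local" %in% metrics)
        .local_efficiency_cpp(r$adjacency) else NA_real_
    }
    out$e_global_abs[i] <- eg
    out$e_local_abs[i] <- el
    out$e_global_rel[i] <- eg / mean(null_g)
    out$e_local_rel[i] <- el / mean(null_l)
    out$e_total_abs[i] <- el + eg
    out$e_total_rel[i] <- out$e_local_rel[i] + out$e_global_rel[i]
  }
  structure(out, n_random = n_random, seed = seed, errors = errors,
            class = c("efficiency_profile", "data.frame"))
}

#' Per-subject functional efficiency profiles
#'
#' Convenience sweep: one [efficiency_profile()] per subject from that
#' subject's functional connectivity matrix.
#'
#' @param cohort A `cohort`.
#' @param group Optional group filter (`"TD"`/`"ASD"`).
#' @inheritParams efficiency_profile
#' @return Named list of `efficiency_profile`s.
#' @export
subject_efficiency_profiles <- function(cohort, group = NULL,
                                        grid = seq(0.05, 0.5, by = 0.05),
                                        n_random = 100, seed = 1L,
                                        metrics = c("global", "local"),
                                        n_swaps = NULL) {
  ids <- cohort$subjects$id
  if (!is.null(group)) ids <- ids[cohort$subjects$group == group]
  out <- lapply(seq_along(ids), function(i) {
    m <- functional_connectivity_matrix(cohort$timeseries[[ids[i]]])
    efficiency_profile(m, grid, n_random, seed = seed + i,
                       metrics = metrics, n_swaps = n_swaps)
  })
  names(out) <- ids
  out
}

#' Bootstrap efficiency profiles for a group-level structural network
#'
#' The structural covariance network of a group is a single matrix, so its
#' sampling variability is estimated by resampling subjects with
#' replacement: each bootstrap replicate recomputes the covariance matrix
#' and its efficiency profile.
#'
#' @param cohort A `cohort`.
#' @param measure `"thickness"` or `"volume"`.
#' @param group `"TD"` or `"ASD"`.
#' @param B Number of bootstrap replicates (default 100).
#' @inheritParams efficiency_profile
#' @return List of `B` `efficiency_profile`s.
#' @export
bootstrap_efficiency_profiles <- function(cohort,
                                          measure = c("thickness", "volume"),
                                          group = c("TD", "ASD"),
                                          grid = seq(0.05, 0.5, by = 0.05),
                                          B = 100, n_random = 20,
                                          seed = 1L,
                                          metrics = c("global", "local"),
                                          n_swaps = NULL) {
  measure <- match.arg(measure)
  group <- match.arg(group)
  ids <- cohort$subjects$id[cohort$subjects$group == group]
  set.seed(seed)
  resamples <- replicate(B, sample(ids, length(ids), replace = TRUE),
                         simplify = FALSE)
  lapply(seq_len(B), function(b) {
    m <- structural_covariance_matrix(cohort, measure, group,
                                      subjects = resamples[[b]])
    efficiency_profile(m, grid, n_random, seed = seed + b,
                       metrics = metrics, n_swaps = n_swaps)
  })
}

#' Compare efficiency profiles between two groups
#'
#' In `subject_level` mode (functional networks: one profile per subject)
#' each metric is compared at each sparsity with a two-sample t-test. In
#' `bootstrap` mode (group-level structural networks: one profile per
#' bootstrap replicate) the group difference is summarized by the
#' percentile bootstrap distribution of `A - B`, its 95% interval and a
#' two-sided bootstrap p-value (the add-one-corrected fraction of the
#' difference distribution on the minority side of zero, doubled).
#'
#' @param groupA,groupB Lists of `efficiency_profile`s.
#' @param mode `"subject_level"` or `"bootstrap"`.
#' @param metrics Metric columns to compare.
#' @param variant `"pooled"` or `"welch"` t-test (subject_level mode).
#' @return Data frame with one row per (sparsity, metric): group means and
#'   SDs, and `t`/`p` (subject_level) or `ci_lo`/`ci_hi`/`p` (bootstrap).
#' @export
compare_efficiency <- function(groupA, groupB,
                               mode = c("subject_level", "bootstrap"),
                               metrics = c("e_global_abs", "e_local_abs",
                                           "e_global_rel", "e_local_rel",
                                           "e_total_abs", "e_total_rel"),
                               variant = c("pooled", "welch")) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (mode == "subject_level" && (length(groupA) < 2 || length(groupB) < 2))
    stop("subject_level mode needs at least 2 profiles per group")
  grid <- groupA[[1]]$sparsity
  pull <- function(profiles, metric, i)
    vapply(profiles, function(p) p[[metric]][i], numeric(1))
  rows <- list()
  for (metric in metrics) {
    for (i in seq_along(grid)) {
      a <- pull(groupA, metric, i)
      b <- pull(groupB, metric, i)
      if (all(is.na(a)) || all(is.na(b))) next
      base <- data.frame(sparsity = grid[i], metric = metric,
                         mean_a = mean(a), sd_a = stats::sd(a),
                         mean_b = mean(b), sd_b = stats::sd(b),
                         stringsAsFactors = FALSE)
      if (mode == "subject_level") {
        if (identical(a, b) || (stats::sd(a) == 0 && stats::sd(b) == 0 &&
                                mean(a) == mean(b))) {
          base$t <- 0; base$p <- 1
        } else {
          tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
          base$t <- unname(tt$statistic); base$p <- tt$p.value
        }
      } else {
        nb <- min(length(a), length(b))
        d <- a[seq_len(nb)] - b[seq_len(nb)]
        ci <- stats::quantile(d, c(0.025, 0.975), names = FALSE)
        p_lo <- (sum(d > 0) + 1) / (nb + 1)
        p_hi <- (sum(d < 0) + 1) / (nb + 1)
        base$ci_lo <- ci[1]; base$ci_hi <- ci[2]
        base$p <- min(1, 2 * min(p_lo, p_hi))
      }
      rows[[length(rows) + 1]] <- base
    }
  }
  do.call(rbind, rows)
}

#' Write an efficiency profile as TSV with JSON metadata
#'
#' @param profile An `efficiency_profile`.
#' @param path Output TSV path; metadata goes to `<path>.json`.
#' @return `path` invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_random = attr(profile, "n_random"),
                            seed = attr(profile, "seed"),
                            errors = as.list(attr(profile, "errors"))),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
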