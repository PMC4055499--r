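#' Canonical feature column names
#'
#' The fixed 22-column inventory of the integrated feature table: 9
#' supratentorial-normalized subcortical volumes (bilateral caudate,
#' thalamus, pallidum, hippocampus, plus cerebellum), 8 seed-connectivity
#' summaries (N and mean Z for the caudate, IFG pars opercularis, IFG pars
#' triangularis and DMN seeds), 3 mean fALFF values (caudate and the two
#' IFG seed sets) and 2 global homotopic-connectivity summaries.
#'
#' @return Character vector of length 22, in canonical order.
#' @export
feature_column_names <- function() {
  c("vol_caudate_L", "vol_caudate_R", "vol_thalamus_L", "vol_thalamus_R",
    "vol_pallidum_L", "vol_pallidum_R", "vol_hippocampus_L",
    "vol_hippocampus_R", "vol_cerebellum",
    "fc_caudate_N", "fc_caudate_Z", "fc_ifg_oper_N", "fc_ifg_oper_Z",
    "fc_ifg_tri_N", "fc_ifg_tri_Z", "fc_dmn_N", "fc_dmn_Z",
    "falff_caudate", "falff_ifg_oper", "falff_ifg_tri",
    "vmhc_N", "vmhc_Z")
}

#' Assemble the canonical 22-feature table
#'
#' Combines the per-subject feature sources into one table with exactly
#' the 22 named columns of [feature_column_names()], in canonical order.
#' Volumes must already be supratentorial-normalized.
#'
#' @param subjects Data frame with `id` and `group` columns.
#' @param functional Matrix or data frame of the 13 functional features
#'   (rows aligned with `subjects`), as produced by
#'   [functional_feature_row()].
#' @param volumes Matrix or data frame with the 9 `vol_*` columns.
#' @return A `feature_table`: data frame with `id`, `group` and the 22
#'   feature columns.
#' @export
assemble_features <- function(subjects, functional, volumes) {
  functional <- as.data.frame(functional)
  volumes <- as.data.frame(volumes)
  if (nrow(functional) != nrow(subjects) || nrow(volumes) != nrow(subjects))
    stop("feature sources must cover the same subjects")
  have <- c(names(volumes), names(functional))
  missing <- setdiff(feature_column_names(), have)
  if (length(missing))
    stop("missing feature columns: ", paste(missing, collapse = ", "))
  all_cols <- cbind(volumes, functional)[, feature_column_names()]
  out <- cbind(data.frame(id = subjects$id, group = subjects$group,
                          stringsAsFactors = FALSE), all_cols)
  if (anyNA(out)) stop("feature table must not contain missing values")
  structure(out, class = c("feature_table", "data.frame"))
}

#' Compute the full feature table of a cohort
#'
#' Runs the functional feature extraction ([functional_feature_row()]) on
#' every subject's time series, normalizes the 9 named subcortical volumes
#' to the supratentorial volume ([normalize_volume()]), and assembles the
#' canonical 22-column table.
#'
#' @param cohort A `cohort`.
#' @param z_threshold Threshold for the N/Z summaries (default 2.3).
#' @return A `feature_table`.
#' @export
compute_feature_table <- function(cohort, z_threshold = 2.3) {
  fun <- t(vapply(cohort$subjects$id, function(id)
    functional_feature_row(cohort$timeseries[[id]], cohort$seed_sets,
                           cohort$homotopic_pairs,
                           tr = cohort$config$tr_seconds,
                           z_threshold = z_threshold),
    numeric(13)))
  vols <- normalize_volume(cohort$volumes[, cohort$feature_volumes,
                                          drop = FALSE],
                           cohort$subjects$supratentorial)
  colnames(vols) <- sub("^sc_", "vol_", cohort$feature_volumes)
  assemble_features(cohort$subjects, fun, vols)
}

#' Variance-normalize a feature table
#'
#' Centers each feature column to mean 0 and scales it to variance 1
#' using the population (n-denominator) convention.
#'
#' @param t A `feature_table` (or data frame with feature columns).
#' @return The table with standardized feature columns.
#' @export
variance_normalize <- function(t) {
  cols <- intersect(feature_column_names(), names(t))
  if (!length(cols)) cols <- names(t)[vapply(t, is.numeric, logical(1))]
  for (cn in cols) {
    x <- t[[cn]]
    mu <- mean(x)
    s2 <- mean((x - mu)^2)
    if (s2 == 0) stop("zero-variance feature column: ", cn)
    t[[cn]] <- (x - mu) / sqrt(s2)
  }
  t
}

#' Number of principal components holding a variance share
#'
#' Eigendecomposes the covariance matrix of the (variance-normalized)
#' feature columns and returns the minimal number of leading components
#' whose eigenvalue sum reaches the requested share of the total.
#'
#' @param t A `feature_table`.
#' @param threshold Fraction of variance to retain, in (0, 1\];
#'   conventionally 0.95 or 0.99.
#' @return Integer component count.
#' @export
component_count <- function(t, threshold = 0.95) {
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  cols <- intersect(feature_column_names(), names(t))
  if (!length(cols)) cols <- names(t)[vapply(t, is.numeric, logical(1))]
  x <- as.matrix(t[, cols])
  if (nrow(x) < 2) stop("need at least 2 rows")
  xc <- sweep(x, 2, colMeans(x))
  ev <- eigen(crossprod(xc) / nrow(xc), symmetric = TRUE,
              only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  as.integer(which(cum >= threshold - 1e-12)[1])
}

#' Three-bin discretization at mean +/- one standard deviation
#'
#' Maps a numeric vector onto three states using its own mean and SD:
#' low `(-Inf, mu - sd]`, mid `(mu - sd, mu + sd)`, high `[mu + sd, Inf)`.
#' This is the conventional preparation for mutual-information estimation
#' in mRMR feature selection, and makes the selection invariant to affine
#' rescaling of features.
#'
#' @param x Finite numeric vector.
#' @return Integer vector with values in `1:3`.
#' @export
discretize <- function(x) {
  if (any(!is.finite(x))) stop("values must be finite")
  mu <- mean(x)
  s <- stats::sd(x)
  if (s == 0) stop("cannot discretize a constant vector")
  out <- rep(2L, length(x))
  out[x <= mu - s] <- 1L
  out[x >= mu + s] <- 3L
  out
}

#' Plug-in mutual information of two discrete vectors
#'
#' \eqn{I(X;Y) = \sum_{a,b} p(a,b) \ln \frac{p(a,b)}{p(a)p(b)}} in nats,
#' estimated from the joint contingency table.
#'
#' @param x,y Discrete vectors of equal length (factors, integers or
#'   characters).
#' @return Non-negative scalar (nats).
#' @export
mutual_information <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  j <- table(x, y) / length(x)
  px <- rowSums(j)
  py <- colSums(j)
  e <- outer(px, py)
  nz <- j > 0
  sum(j[nz] * log(j[nz] / e[nz]))
}

#' Greedy mRMR feature selection
#'
#' Minimum-redundancy maximum-relevance forward selection on the
#' discretized features ([discretize()]): the first pick maximizes
#' relevance `I(f; labels)`; each later step maximizes the mRMR criterion
#' -- by default the difference form (MID),
#' `I(f; labels) - mean_{g in S} I(f; g)`, optionally the quotient form
#' (MIQ), `I(f; labels) / mean_{g in S} I(f; g)`. Ties break toward the
#' lower canonical column index.
#'
#' @param t A `feature_table`.
#' @param labels Binary group vector aligned with rows (defaults to the
#'   table's `group` column).
#' @param k Number of features to select (at most the feature count).
#' @param criterion `"difference"` (MID, default) or `"quotient"` (MIQ).
#' @return A `selection_result`: list with `selected` (ordered names),
#'   `k`, `criterion`, and `trace` (per-step relevance, redundancy and
#'   criterion values of the chosen feature).
#' @export
mrmr_select <- function(t, labels = t$group, k,
                        criterion = c("difference", "quotient")) {
  criterion <- match.arg(criterion)
  cols <- intersect(feature_column_names(), names(t))
  if (!length(cols)) cols <- names(t)[vapply(t, is.numeric, logical(1))]
  if (k > length(cols)) stop("k exceeds the number of features")
  if (length(unique(labels)) != 2) stop("labels must be binary")
  disc <- lapply(t[cols], discretize)
  rel <- vapply(disc, mutual_information, numeric(1), y = labels)
  selected <- integer(0)
  trace <- data.frame(feature = character(k), relevance = numeric(k),
                      redundancy = numeric(k), criterion = numeric(k),
                      stringsAsFactors = FALSE)
  for (step in seq_len(k)) {
    cand <- setdiff(seq_along(cols), selected)
    red <- if (length(selected) == 0) rep(0, length(cand)) else
      vapply(cand, function(ci)
        mean(vapply(selected, function(si)
          mutual_information(disc[[ci]], disc[[si]]), numeric(1))),
        numeric(1))
    crit <- if (length(selected) == 0) rel[cand]
            else if (criterion == "difference") rel[cand] - red
            else rel[cand] / pmax(red, .Machine$double.eps)
    best <- cand[which.max(crit)]  # which.max takes the first = lowest index
    selected <- c(selected, best)
    i <- match(best, cand)
    trace[step, ] <- list(cols[best], unname(rel[best]), red[i],
                          unname(crit[i]))
  }
  structure(list(selected = cols[selected], k = k, criterion = criterion,
                 trace = trace), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> k = %d (%s criterion)\n", x$k,
              x$criterion))
  cat("  ", paste(x$selected, collapse = " > "), "\n")
  invisible(x)
}

#' Write a selection result as JSON
#'
#' @param sel A `selection_result`.
#' @param path Output path.
#' @param variance_threshold Optional variance threshold to echo.
#' @return `path` invisibly.
#' @export
write_selection <- function(sel, path, variance_threshold = NULL) {
  jsonlite::write_json(list(selected = sel$selected, k = sel$k,
                            criterion = sel$criterion,
                            variance_threshold = variance_threshold,
                            trace = sel$trace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
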