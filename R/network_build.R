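#' Connectivity matrices and binary graphs
#'
#' A `connectivity_matrix` is a labelled symmetric matrix of Pearson
#' correlations (diagonal set to 0) of kind `functional` (per-subject,
#' across time), `thickness_covariance` or `volume_covariance` (per-group,
#' across subjects). A `binary_graph` is its binarization at a fixed edge
#' density ("sparsity").
#'
#' @param weights Symmetric numeric matrix with entries in \[-1, 1\].
#' @param kind One of `"functional"`, `"thickness_covariance"`,
#'   `"volume_covariance"`.
#' @param labels Region labels (defaults to the matrix dimnames).
#' @return A `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights,
                                kind = c("functional",
                                         "thickness_covariance",
                                         "volume_covariance"),
                                labels = rownames(weights)) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("weights must be square")
  if (max(abs(weights - t(weights))) > 1e-10)
    stop("weights must be symmetric (tolerance 1e-10)")
  diag(weights) <- 0
  if (any(weights < -1 - 1e-8) || any(weights > 1 + 1e-8))
    stop("entries must lie in [-1, 1]")
  if (is.null(labels)) labels <- sprintf("r%03d", seq_len(nrow(weights)))
  dimnames(weights) <- list(labels, labels)
  structure(list(weights = weights, labels = labels, kind = kind),
            class = "connectivity_matrix")
}

#' Functional connectivity from an ROI time-series matrix
#'
#' Pearson correlation of every ROI pair across time; the diagonal is
#' zeroed. Constant rows are rejected by name since their correlation is
#' undefined.
#'
#' @param ts Matrix, ROIs in rows and time points in columns (>= 3).
#' @return A `connectivity_matrix` of kind `functional`.
#' @export
functional_connectivity_matrix <- function(ts) {
  ts <- as.matrix(ts)
  if (ncol(ts) < 3) stop("need at least 3 timepoints")
  s <- apply(ts, 1, stats::sd)
  if (any(s == 0)) {
    bad <- rownames(ts)[s == 0]
    if (is.null(bad)) bad <- which(s == 0)
    stop("constant time series for ROI(s): ", paste(bad, collapse = ", "))
  }
  connectivity_matrix(stats::cor(t(ts)), kind = "functional")
}

#' Structural covariance network of one group
#'
#' Region-by-region Pearson correlation computed across the subjects of one
#' group, from cortical thickness or supratentorial-normalized regional
#' volumes, yielding one group-level matrix (the standard construction of a
#' structural covariance network).
#'
#' @param cohort A `cohort`.
#' @param measure `"thickness"` or `"volume"`.
#' @param group Group label, `"TD"` or `"ASD"`.
#' @param subjects Optional character vector of subject ids (e.g. a
#'   bootstrap resample, possibly with repeats); defaults to all subjects
#'   of `group`.
#' @return A `connectivity_matrix` of kind `thickness_covariance` or
#'   `volume_covariance`.
#' @export
structural_covariance_matrix <- function(cohort,
                                         measure = c("thickness", "volume"),
                                         group = c("TD", "ASD"),
                                         subjects = NULL) {
  measure <- match.arg(measure)
  group <- match.arg(group)
  if (is.null(subjects))
    subjects <- cohort$subjects$id[cohort$subjects$group == group]
  if (length(subjects) < 4) stop("need at least 4 subjects in group ", group)
  if (measure == "thickness") {
    m <- cohort$thickness[subjects, , drop = FALSE]
  } else {
    m <- cohort$volumes[subjects, , drop = FALSE] /
      cohort$subjects$supratentorial[match(subjects, cohort$subjects$id)] *
      1000
  }
  s <- apply(m, 2, stats::sd)
  if (any(s == 0))
    stop("zero-variance region(s): ",
         paste(colnames(m)[s == 0], collapse = ", "))
  connectivity_matrix(stats::cor(m),
                      kind = paste0(measure, "_covariance"))
}

#' Binarize a connectivity matrix at a fixed sparsity
#'
#' Keeps the `floor(s * n(n-1)/2)` edges with the largest positive weight
#' (negative and zero correlations are never eligible), breaking ties by
#' lower row then lower column index, and binarizes. If fewer positive
#' weights exist than requested the graph keeps all of them and the
#' realized sparsity is recorded (with a warning).
#'
#' @param m A `connectivity_matrix`.
#' @param s Requested sparsity, in (0, 1].
#' @return A `binary_graph`: list with `adjacency` (0/1 integer matrix,
#'   zero diagonal), `sparsity` (realized edge fraction), `labels`.
#' @export
threshold_at_sparsity <- function(m, s) {
  stopifnot(inherits(m, "connectivity_matrix"))
  if (s <= 0 || s > 1) stop("sparsity must lie in (0, 1]")
  n <- nrow(m$weights)
  n_pairs <- n * (n - 1) / 2
  k <- floor(s * n_pairs)
  if (k < 1) stop("requested sparsity yields 0 edges")
  ut <- which(upper.tri(m$weights), arr.ind = TRUE)  # col-major: ties by
  w <- m$weights[ut]                                 # (row, then column)
  pos <- w > 0
  if (!any(pos)) stop("no positive weights: nothing to threshold")
  ut <- ut[pos, , drop = FALSE]
  w <- w[pos]
  # order by descending weight; ties by lower row index, then lower column
  o <- order(-w, ut[, 1], ut[, 2])
  if (length(w) < k) {
    warning(sprintf("only %d positive weights for %d requested edges",
                    length(w), k))
    k <- length(w)
  }
  sel <- ut[o[seq_len(k)], , drop = FALSE]
  adj <- matrix(0L, n, n, dimnames = dimnames(m$weights))
  adj[sel] <- 1L
  adj[sel[, c(2, 1), drop = FALSE]] <- 1L
  structure(list(adjacency = adj, sparsity = k / n_pairs,
                 labels = m$labels), class = "binary_graph")
}

#' Build a `binary_graph` from an adjacency matrix
#'
#' @param adjacency Symmetric 0/1 matrix, zero diagonal.
#' @return A `binary_graph`.
#' @export
binary_graph <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  storage.mode(adjacency) <- "integer"
  if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
  if (any(diag(adjacency) != 0)) stop("self-loops are not allowed")
  if (!all(adjacency %in% c(0L, 1L))) stop("adjacency must be 0/1")
  n <- nrow(adjacency)
  structure(list(adjacency = adjacency,
                 sparsity = sum(adjacency) / (n * (n - 1)),
                 labels = rownames(adjacency)),
            class = "binary_graph")
}

#' Degree-preserving random rewiring (double edge swaps)
#'
#' Maslov-Sneppen null model: repeatedly picks two edges (a,b), (c,d) and
#' rewires them to (a,d), (c,b) unless that would create a self-loop or
#' multi-edge. The degree sequence is preserved exactly. Swap proposals are
#' drawn from R's RNG, so the result is reproducible under `seed`.
#'
#' @param g A `binary_graph` with at least 2 edges.
#' @param n_swaps Number of accepted swaps to perform (default 10x the
#'   edge count).
#' @param seed Optional integer seed.
#' @param max_tries Cap on proposals (default `100 * n_swaps`), so graphs
#'   whose degree sequence admits no further swaps still return.
#' @return A rewired `binary_graph` with identical degree sequence.
#' @export
degree_matched_random <- function(g, n_swaps = NULL, seed = NULL,
                                  max_tries = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  m <- sum(g$adjacency) / 2
  if (m < 2) stop("graph must have at least 2 edges")
  if (is.null(n_swaps)) n_swaps <- 10L * m
  if (is.null(max_tries)) max_tries <- 100L * n_swaps
  if (!is.null(seed)) set.seed(seed)
  adj <- .double_edge_swap_cpp(g$adjacency, as.integer(n_swaps),
                               as.integer(max_tries))
  dimnames(adj) <- dimnames(g$adjacency)
  structure(list(adjacency = adj, sparsity = g$sparsity,
                 labels = g$labels), class = "binary_graph")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s, %d regions\n", x$kind,
              nrow(x$weights)))
  invisible(x)
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (sparsity %.3f)\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$sparsity))
  invisible(x)
}

#' Write / read a connectivity matrix as TSV
#'
#' Tab-separated matrix with region labels as header row and first column.
#'
#' @param m A `connectivity_matrix`.
#' @param path Output file.
#' @return `path` invisibly (writer); a `connectivity_matrix` (reader).
#' @export
write_connectivity <- function(m, path) {
  d <- data.frame(region = m$labels, m$weights, check.names = FALSE)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity
#' @param kind Matrix kind for the reader.
#' @export
read_connectivity <- function(path, kind = "functional") {
  d <- utils::read.delim(path, check.names = FALSE)
  w <- as.matrix(d[, -1, drop = FALSE])
  rownames(w) <- d[[1]]
  connectivity_matrix(w, kind = kind)
}

#' Write / read a binary graph as an edge list
#'
#' Edge-list TSV (columns `i`, `j`, 1-based upper-triangle indices) plus a
#' JSON sidecar `<path>.json` holding the node count, realized sparsity
#' and labels.
#'
#' @param g A `binary_graph`.
#' @param path Output TSV file.
#' @return `path` invisibly (writer); a `binary_graph` (reader).
#' @export
write_graph <- function(g, path) {
  stopifnot(inherits(g, "binary_graph"))
  e <- which(g$adjacency == 1L & upper.tri(g$adjacency), arr.ind = TRUE)
  utils::write.table(data.frame(i = e[, 1], j = e[, 2]), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n = nrow(g$adjacency), sparsity = g$sparsity,
                            labels = g$labels),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  e <- utils::read.delim(path)
  adj <- matrix(0L, meta$n, meta$n)
  if (nrow(e)) {
    idx <- cbind(e$i, e$j)
    adj[idx] <- 1L
    adj[idx[, c(2, 1), drop = FALSE]] <- 1L
  }
  if (!is.null(meta$labels) && length(meta$labels) == meta$n)
    dimnames(adj) <- list(meta$labels, meta$labels)
  binary_graph(adj)
}
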