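# Independent oracles and fixture builders used across the suite.

# Floyd-Warshall all-pairs distances (independent of the package's BFS).
fw_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj > 0] <- 1
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], "+"))
  D
}

oracle_global_eff <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  D <- fw_distances(adj)
  off <- D[row(D) != col(D)]
  mean(1 / off)  # 1/Inf = 0
}

oracle_local_eff <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    oracle_global_eff(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(vals)
}

rand_adjacency <- function(n, p) {
  a <- matrix(0L, n, n)
  up <- upper.tri(a)
  a[up] <- as.integer(stats::runif(sum(up)) < p)
  a + t(a)
}

# small, fast cohort configuration (no planted mean effects by default)
small_config <- function(n_per_group = 8, n_cortical = 40, n_roi = 28,
                         n_timepoints = 80, seed = 1,
                         volume_effects = numeric(0),
                         thickness_effects = numeric(0), ...) {
  cohort_config(n_per_group = n_per_group, n_cortical = n_cortical,
                n_roi = n_roi, n_timepoints = n_timepoints,
                n_subcortical = 9, n_wm = 4,
                volume_effects = volume_effects,
                thickness_effects = thickness_effects,
                seed = seed, ...)
}

# random feature-like table with binary labels (no signal unless planted)
random_table <- function(n, d, seed) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * d), n))
  names(x) <- sprintf("f%02d", seq_len(d))
  x$group <- rep(c("A", "B"), length.out = n)
  x
}

# independent mRMR re-evaluation: entropy-based MI, literal greedy steps
oracle_entropy <- function(x) {
  p <- as.vector(table(x)) / length(x)
  -sum(p * log(p))
}
oracle_mi <- function(x, y) {
  oracle_entropy(x) + oracle_entropy(y) -
    oracle_entropy(paste(x, y, sep = "\r"))
}
oracle_disc <- function(x) {
  mu <- mean(x); s <- sd(x)
  ifelse(x <= mu - s, 1L, ifelse(x >= mu + s, 3L, 2L))
}
oracle_mrmr <- function(tab, cols, labels, k, criterion = "difference") {
  disc <- lapply(tab[cols], oracle_disc)
  sel <- character(0)
  for (step in seq_len(k)) {
    cand <- setdiff(cols, sel)
    score <- vapply(cand, function(f) {
      rel <- oracle_mi(disc[[f]], labels)
      if (length(sel) == 0) return(rel)
      red <- mean(vapply(sel, function(g) oracle_mi(disc[[f]], disc[[g]]),
                         numeric(1)))
      if (criterion == "difference") rel - red else rel / max(red, 1e-300)
    }, numeric(1))
    sel <- c(sel, cand[which.max(score)])
  }
  sel
}
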