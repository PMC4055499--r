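test_that("functional connectivity reproduces exact correlation cases", {
  base <- sin(seq(0, 6 * pi, length.out = 40))
  ts <- rbind(a = base, b = base + 0, c = -base,
              d = rnorm(40))
  m <- functional_connectivity_matrix(ts)
  expect_equal(m$weights["a", "b"], 1)
  expect_equal(m$weights["a", "c"], -1)
  expect_equal(diag(m$weights), setNames(rep(0, 4), rownames(ts)))
  expect_error(functional_connectivity_matrix(
    rbind(x = rep(1, 10), y = rnorm(10))), "x")
  expect_error(functional_connectivity_matrix(ts[, 1:2]), "3 timepoints")
})

test_that("factor-model data yields the planted off-diagonal correlation", {
  set.seed(42)
  tp <- 20000
  g <- rnorm(tp)
  ts <- t(sapply(1:5, function(i) sqrt(0.5) * g + sqrt(0.5) * rnorm(tp)))
  m <- functional_connectivity_matrix(ts)
  off <- m$weights[upper.tri(m$weights)]
  expect_true(all(abs(off - 0.5) < 0.05))
})

test_that("structural covariance recovers latent structure and scaling", {
  set.seed(7)
  cfg <- small_config(n_per_group = 500, seed = 31)
  co <- generate_cohort(cfg, components = c("thickness", "volumes"))
  m <- structural_covariance_matrix(co, "thickness", "TD")
  expect_s3_class(m, "connectivity_matrix")
  expect_equal(dim(m$weights), c(40, 40))
  # adjacent regions share the banded field; distant ones nearly don't
  expect_gt(m$weights[1, 2], m$weights[1, 18])

  # volume covariance is invariant to a global rescaling of raw volumes
  m1 <- structural_covariance_matrix(co, "volume", "TD")
  co2 <- co
  co2$volumes <- co$volumes * 2
  co2$subjects$supratentorial <- co$subjects$supratentorial * 2
  m2 <- structural_covariance_matrix(co2, "volume", "TD")
  expect_equal(m1$weights, m2$weights, tolerance = 1e-12)

  expect_error(structural_covariance_matrix(co, "thickness", "TD",
                                            subjects = co$subjects$id[1:3]),
               "4 subjects")
})

test_that("independent regions give small spurious covariance", {
  set.seed(12)
  x <- matrix(rnorm(500 * 12), 500)
  colnames(x) <- sprintf("r%02d", 1:12)
  m <- connectivity_matrix(cor(x), kind = "thickness_covariance")
  expect_lt(max(abs(m$weights[upper.tri(m$weights)])), 0.12)
})

test_that("sparsity thresholding keeps the top positive weights", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9; w[1, 3] <- 0.5; w[1, 4] <- 0.7
  w[2, 3] <- 0.1; w[2, 4] <- 0.3; w[3, 4] <- 0.2
  w <- w + t(w)
  m <- connectivity_matrix(w)
  g <- threshold_at_sparsity(m, 1 / 3)  # floor(6/3) = 2 edges
  expect_equal(sum(g$adjacency) / 2, 2)
  expect_equal(g$adjacency[1, 2], 1L)  # top-2 by brute-force sort
  expect_equal(g$adjacency[1, 4], 1L)

  expect_equal(sum(threshold_at_sparsity(m, 1)$adjacency) / 2, 6)
  expect_error(threshold_at_sparsity(connectivity_matrix(-abs(w)), 0.5),
               "no positive weights")
  expect_error(threshold_at_sparsity(m, 0.01), "0 edges")

  # ties break toward lower row, then lower column index
  wt <- matrix(0, 4, 4)
  wt[1, 3] <- 0.5; wt[2, 4] <- 0.5; wt[1, 2] <- 0.5
  wt <- wt + t(wt)
  gt <- threshold_at_sparsity(connectivity_matrix(wt), 1 / 6)
  expect_equal(gt$adjacency[1, 2], 1L)
  expect_equal(sum(gt$adjacency), 2L)
})

test_that("thresholded graphs are nested across the sparsity grid", {
  set.seed(5)
  w <- matrix(rnorm(30^2), 30); w <- (w + t(w)) / 2; diag(w) <- 0
  m <- connectivity_matrix(w / max(abs(w)))
  prev <- NULL
  for (s in seq(0.1, 0.4, by = 0.1)) {
    g <- threshold_at_sparsity(m, s)
    if (!is.null(prev))
      expect_true(all(g$adjacency[prev$adjacency == 1L] == 1L))
    prev <- g
  }
})

test_that("degree-matched rewiring preserves degrees and randomizes", {
  set.seed(8)
  g <- binary_graph(rand_adjacency(25, 0.25))
  r <- degree_matched_random(g, seed = 99)
  expect_equal(sort(colSums(r$adjacency)), sort(colSums(g$adjacency)))
  expect_equal(rowSums(r$adjacency), colSums(r$adjacency))
  expect_equal(sum(r$adjacency), sum(g$adjacency))
  # determinism under a fixed seed
  expect_identical(degree_matched_random(g, seed = 99)$adjacency,
                   r$adjacency)

  # triangle admits no alternative graph with its degree sequence
  k3 <- binary_graph(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  expect_identical(degree_matched_random(k3, seed = 1)$adjacency,
                   k3$adjacency)

  # rewiring a ring lattice raises global efficiency (BFS oracle both sides)
  n <- 20
  lat <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    lat[i, j] <- lat[j, i] <- 1L
  }
  gl <- binary_graph(lat)
  rl <- degree_matched_random(gl, n_swaps = 200, seed = 17)
  expect_gt(oracle_global_eff(rl$adjacency), oracle_global_eff(gl$adjacency))
})

test_that("connectivity matrices survive a TSV round trip", {
  set.seed(3)
  w <- cor(matrix(rnorm(200), 20))
  m <- connectivity_matrix(w, kind = "volume_covariance",
                           labels = sprintf("reg%02d", 1:10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_connectivity(m, path)
  back <- read_connectivity(path, kind = "volume_covariance")
  expect_equal(back$weights, m$weights, tolerance = 1e-10)
  expect_identical(back$labels, m$labels)
})

test_that("binary graphs survive the edge-list round trip", {
  set.seed(41)
  g <- binary_graph(rand_adjacency(15, 0.3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_graph(g, path)
  back <- read_graph(path)
  expect_equal(unname(back$adjacency), unname(g$adjacency))
  expect_equal(back$sparsity, g$sparsity)
})
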