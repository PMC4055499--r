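test_that("feature assembly yields the canonical 22 columns", {
  cfg <- small_config(n_per_group = 4, n_timepoints = 60, seed = 13)
  co <- generate_cohort(cfg)
  ft <- compute_feature_table(co)
  expect_s3_class(ft, "feature_table")
  expect_identical(setdiff(names(ft), c("id", "group")),
                   feature_column_names())
  expect_equal(length(feature_column_names()), 22L)
  expect_false(anyNA(ft))

  # single-subject table still assembles
  one <- co
  one$subjects <- one$subjects[1, , drop = FALSE]
  one$volumes <- one$volumes[1, , drop = FALSE]
  one$timeseries <- one$timeseries[1]
  ft1 <- compute_feature_table(one)
  expect_equal(nrow(ft1), 1)

  # dropping a source names the missing columns
  fun <- t(vapply(co$subjects$id, function(id)
    functional_feature_row(co$timeseries[[id]], co$seed_sets,
                           co$homotopic_pairs), numeric(13)))
  vols <- normalize_volume(co$volumes[, co$feature_volumes],
                           co$subjects$supratentorial)
  colnames(vols) <- sub("^sc_", "vol_", co$feature_volumes)
  err <- tryCatch(assemble_features(co$subjects,
                                    fun[, !grepl("^vmhc", colnames(fun))],
                                    vols),
                  error = conditionMessage)
  expect_match(err, "vmhc_N")
  expect_match(err, "vmhc_Z")
})

test_that("variance normalization is exact and idempotent", {
  tab <- random_table(50, 5, seed = 1)
  vn <- variance_normalize(tab)
  for (cn in sprintf("f%02d", 1:5)) {
    expect_lt(abs(mean(vn[[cn]])), 1e-12)
    expect_lt(abs(mean(vn[[cn]]^2) - 1), 1e-12)
  }
  vn2 <- variance_normalize(vn)
  expect_equal(vn2, vn, tolerance = 1e-12)
  # population (n) denominator
  expect_equal(variance_normalize(data.frame(f = c(1, 2, 3)))$f,
               c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_error(variance_normalize(data.frame(f = rep(2, 4))),
               "zero-variance")
})

test_that("component counts follow the eigen-spectrum", {
  # rank-1 table: one component suffices
  base <- rnorm(30)
  t1 <- data.frame(a = base, b = 2 * base, c = -base)
  expect_equal(component_count(t1, 0.95), 1L)

  # exactly isotropic 22-feature covariance via orthonormal columns
  set.seed(8)
  q <- qr.Q(qr(cbind(1, matrix(rnorm(30 * 22), 30))))[, 2:23]
  iso <- as.data.frame(q)
  names(iso) <- sprintf("f%02d", 1:22)
  expect_equal(component_count(iso, 0.95), 21L)  # ceil(0.95 * 22)
  expect_equal(component_count(iso, 0.99), 22L)  # ceil(0.99 * 22)

  # monotone in the threshold
  tab <- random_table(40, 10, seed = 3)
  expect_lte(component_count(tab, 0.95), component_count(tab, 0.99))
})

test_that("discretization and mutual information match closed forms", {
  set.seed(11)
  x <- rnorm(20000)
  d <- discretize(x)
  expect_equal(mean(d == 2L), 2 * pnorm(1) - 1, tolerance = 0.02)
  expect_equal(sum(d == 1L), sum(d == 3L), tolerance = 200)
  expect_error(discretize(rep(1, 5)), "constant")

  y <- rep(c(1L, 2L), each = 500)
  expect_equal(mutual_information(y, y), log(2), tolerance = 1e-12)
  expect_equal(mutual_information(y, rep(1L, 1000)), 0)
  x2 <- sample(1:3, 5000, replace = TRUE)
  y2 <- sample(1:2, 5000, replace = TRUE)
  expect_lt(mutual_information(x2, y2), 0.01)
  expect_error(mutual_information(1:4, 1:5), "equal length")
})

test_that("greedy mRMR matches the independent step-by-step oracle", {
  for (seed in 1:8) {
    tab <- random_table(60, 10, seed = seed)
    # plant signal in a couple of columns so relevance varies
    tab$f01 <- tab$f01 + 1.5 * (tab$group == "A")
    tab$f05 <- tab$f05 - 1.0 * (tab$group == "A")
    k <- sample(2:6, 1)
    sel <- mrmr_select(tab, tab$group, k)
    expect_identical(sel$selected,
                     oracle_mrmr(tab, sprintf("f%02d", 1:10), tab$group, k))
  }
  # quotient criterion also matches its oracle
  tab <- random_table(80, 8, seed = 99)
  tab$f02 <- tab$f02 + 2 * (tab$group == "B")
  sel_q <- mrmr_select(tab, tab$group, 4, criterion = "quotient")
  expect_identical(sel_q$selected,
                   oracle_mrmr(tab, sprintf("f%02d", 1:8), tab$group, 4,
                               criterion = "quotient"))
})

test_that("mRMR picks informative features and defers duplicates", {
  set.seed(21)
  n <- 400
  g <- rep(c("A", "B"), each = n / 2)
  informative <- rnorm(n) + 2 * (g == "A")
  tab <- as.data.frame(matrix(rnorm(n * 21), n))
  names(tab) <- sprintf("f%02d", 1:21)
  tab$signal <- informative
  tab$group <- g
  sel <- mrmr_select(tab, g, 1)
  expect_identical(sel$selected, "signal")

  # a duplicated informative feature is deferred behind an independent,
  # moderately informative one by the redundancy penalty
  tab2 <- data.frame(s1 = informative, s2 = informative + rnorm(n, 0, 0.01),
                     mid = rnorm(n) + 0.8 * (g == "A"),
                     noise = rnorm(n), group = g)
  sel2 <- mrmr_select(tab2, g, 2)
  expect_identical(sel2$selected[1], "s1")
  expect_identical(sel2$selected[2], "mid")
})

test_that("selection is invariant to affine feature rescaling", {
  tab <- random_table(100, 6, seed = 5)
  tab$f03 <- tab$f03 + 1.2 * (tab$group == "A")
  sel_a <- mrmr_select(tab, tab$group, 3)
  tab2 <- tab
  tab2$f03 <- tab2$f03 * 40 - 7
  tab2$f01 <- tab2$f01 / 1000
  sel_b <- mrmr_select(tab2, tab2$group, 3)
  expect_identical(sel_a$selected, sel_b$selected)
})
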