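sinusoid <- function(freq, tp = 200, tr = 2)
  sin(2 * pi * freq * seq_len(tp) * tr)

power_of <- function(x) sum((x - mean(x))^2)

test_that("band-pass filtering keeps in-band and removes out-of-band power", {
  s_in <- sinusoid(0.05)
  out <- bandpass_filter(s_in, 0.01, 0.08, tr = 2)
  expect_gte(power_of(out) / power_of(s_in), 0.95)

  s_out <- sinusoid(0.2)
  out2 <- bandpass_filter(s_out, 0.01, 0.08, tr = 2)
  expect_lte(power_of(out2) / power_of(s_out), 0.05)

  expect_equal(bandpass_filter(rep(0, 50), 0.01, 0.08, tr = 2), rep(0, 50))
  expect_error(bandpass_filter(s_in, 0.01, 0.3, tr = 2), "Nyquist")
})

test_that("seed maps standardize and clip correctly", {
  set.seed(4)
  tp <- 180
  seed_rows <- rbind(rnorm(tp), rnorm(tp))
  ref <- colMeans(seed_rows)
  ts <- rbind(seed_rows, dup = ref, neg = -ref, noise = rnorm(tp))
  z <- seed_connectivity_map(ts, 1:2)
  expect_equal(length(z), 3)  # seed rows excluded
  expect_true(is.finite(z[["dup"]]) && z[["dup"]] > 8)
  expect_true(is.finite(z[["neg"]]) && z[["neg"]] < -8)
  expect_error(seed_connectivity_map(rbind(rep(1, 10), rnorm(10)), 1),
               "constant")

  # null: independent white-noise region gives approx N(0,1) z
  zs <- replicate(300, {
    tsn <- rbind(rnorm(tp), rnorm(tp), rnorm(tp))
    seed_connectivity_map(tsn, 1:2)[[1]]
  })
  expect_gte(mean(abs(zs) < 3), 0.99)
})

test_that("seed-map summaries count strict exceedances", {
  s <- summarize_seed_map(c(3.0, 1.0, 2.5), 2.3)
  expect_equal(s$n_suprathreshold, 2)
  expect_equal(s$mean_z, 2.75)
  expect_false(s$empty)

  s0 <- summarize_seed_map(c(1, 2), 2.3)
  expect_equal(s0$n_suprathreshold, 0)
  expect_equal(s0$mean_z, 0)
  expect_true(s0$empty)

  sb <- summarize_seed_map(rep(2.3, 5), 2.3)  # boundary: strict inequality
  expect_equal(sb$n_suprathreshold, 0)

  # monotonicity: raising the threshold never increases N
  set.seed(2)
  zmap <- rnorm(50, 1.5, 1)
  ns <- vapply(seq(0.5, 4, by = 0.5),
               function(th) summarize_seed_map(zmap, th)$n_suprathreshold,
               numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("homotopic connectivity saturates, nulls out, and tracks coupling", {
  set.seed(6)
  tp <- 180
  half <- t(sapply(1:10, function(i) rnorm(tp)))
  ts_dup <- rbind(half, half)  # right hemisphere duplicates the left
  pairs <- cbind(1:10, 11:20)
  v <- vmhc(ts_dup, pairs)
  expect_equal(v$n_suprathreshold, 10)

  # independent hemispheres: suprathreshold pairs are rare
  counts <- replicate(100, {
    tsn <- t(sapply(1:20, function(i) rnorm(tp)))
    vmhc(tsn, pairs)$n_suprathreshold
  })
  expect_lt(mean(counts) / 10, 0.05)

  # stronger homotopic coupling raises the mean pair z
  mk <- function(c_h) {
    l <- t(sapply(1:10, function(i) rnorm(tp)))
    shared <- t(sapply(1:10, function(i) rnorm(tp)))
    a <- sqrt(c_h) * shared + sqrt(1 - c_h) * l
    b <- sqrt(c_h) * shared +
      sqrt(1 - c_h) * t(sapply(1:10, function(i) rnorm(tp)))
    mean(attr(vmhc(rbind(a, b), pairs, z_threshold = 0.1), "z"))
  }
  expect_gt(mk(0.6), mk(0.2))
  expect_error(vmhc(rbind(rep(1, 10), rnorm(10)), cbind(1, 2)), "constant")
})

test_that("fALFF matches spectral expectations", {
  f_in <- falff(sinusoid(0.05), tr = 2)
  expect_gte(f_in[[1]], 0.95)
  f_out <- falff(sinusoid(0.2), tr = 2)
  expect_lte(f_out[[1]], 0.05)

  set.seed(19)
  f_wn <- mean(replicate(50, falff(rnorm(1000), tr = 2)[[1]]))
  expect_equal(f_wn, 0.28, tolerance = 0.02)

  # whole positive-frequency band accounts for everything
  expect_equal(falff(rnorm(100), 0, 0.25, tr = 2)[[1]], 1)
  expect_error(falff(rep(1, 100), tr = 2), "constant")
})

test_that("summaries are invariant to affine rescaling of a region", {
  set.seed(33)
  cfg <- small_config(n_per_group = 2, n_timepoints = 120, seed = 3)
  ts <- generate_timeseries(cfg, "TD", seed = 8)
  lay <- region_layout(cfg)
  row1 <- functional_feature_row(ts, lay$seed_sets, lay$roi_pairs)
  ts2 <- ts
  ts2[7, ] <- 3.5 * ts2[7, ] + 11  # affine map of one non-seed region
  row2 <- functional_feature_row(ts2, lay$seed_sets, lay$roi_pairs)
  expect_equal(row1[setdiff(names(row1), c("falff_caudate", "falff_ifg_oper",
                                           "falff_ifg_tri"))],
               row2[setdiff(names(row2), c("falff_caudate", "falff_ifg_oper",
                                           "falff_ifg_tri"))],
               tolerance = 1e-10)
  # fALFF is computed on the demeaned series, so scaling cancels too
  expect_equal(row1[["falff_caudate"]], row2[["falff_caudate"]],
               tolerance = 1e-10)
})
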