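test_that("cohort generation respects counts, defaults and determinism", {
  cfg <- cohort_config(n_per_group = 20, seed = 3)
  expect_equal(cfg$n_cortical, 148L)
  expect_equal(cfg$n_roi, 112L)
  expect_equal(cfg$n_timepoints, 180L)
  expect_equal(cfg$tr_seconds, 2.0)
  expect_equal(cfg$n_subcortical, 45L)
  expect_equal(cfg$n_wm, 70L)

  cfg <- small_config(n_per_group = 20, seed = 3)
  co <- generate_cohort(cfg, components = c("thickness", "volumes"))
  expect_equal(nrow(co$subjects), 40)
  expect_equal(table(co$subjects$group)[["ASD"]], 20)
  expect_true(all(co$thickness > 0))
  expect_true(all(co$subjects$supratentorial >
                  apply(co$volumes, 1, max)))

  co2 <- generate_cohort(cfg, components = c("thickness", "volumes"))
  expect_identical(co$thickness, co2$thickness)
  expect_identical(co$volumes, co2$volumes)
})

test_that("invalid configurations are rejected", {
  expect_error(cohort_config(n_per_group = 0), "positive")
  expect_error(cohort_config(tr_seconds = 0), "tr_seconds")
  expect_error(cohort_config(volume_effects = c(sc_caudate_R = -1.2)),
               "negative")
  expect_error(cohort_config(
    seed_connectivity = list(TD = c(caudate = 1.0, ifg_oper = 0.4,
                                    ifg_tri = 0.4, dmn = 0.4),
                             ASD = c(caudate = 0.3, ifg_oper = 0.3,
                                     ifg_tri = 0.3, dmn = 0.3))),
    "\\[0, 1\\)")
  expect_error(generate_cohort(small_config(
    volume_effects = c(nonexistent_region = 0.1)),
    components = "volumes"), "unknown volume region")
})

test_that("planted volume effect is recovered by direct averaging", {
  cfg <- small_config(n_per_group = 500, seed = 11,
                      volume_effects = c(sc_caudate_R = 0.10),
                      volume_noise_sd = 0.02)
  co <- generate_cohort(cfg, components = "volumes")
  td <- co$subjects$group == "TD"
  # supratentorial-normalize to cancel the head-size factor, then compare
  v <- co$volumes[, "sc_caudate_R"] / co$subjects$supratentorial
  ratio <- mean(v[!td]) / mean(v[td])
  expect_gt(ratio, 1.08)
  expect_lt(ratio, 1.12)
})

test_that("time-series coupling structure matches the factor model", {
  # zero coupling everywhere: off-diagonal correlations are null-like
  cfg0 <- small_config(
    seed = 5, n_timepoints = 180,
    seed_connectivity = list(TD = c(caudate = 0, ifg_oper = 0,
                                    ifg_tri = 0, dmn = 0),
                             ASD = c(caudate = 0, ifg_oper = 0,
                                     ifg_tri = 0, dmn = 0)),
    homotopic_strength = c(TD = 0, ASD = 0))
  ts <- generate_timeseries(cfg0, "TD", seed = 9)
  expect_equal(ncol(ts), 180)
  expect_true(all(apply(ts, 1, sd) > 0))
  r <- cor(t(ts))
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)

  # strong caudate-network coupling at long series: mean within-network r
  # near the planted c = 0.8
  cfg1 <- small_config(
    n_timepoints = 2000, seed = 6,
    seed_connectivity = list(TD = c(caudate = 0.8, ifg_oper = 0,
                                    ifg_tri = 0, dmn = 0),
                             ASD = c(caudate = 0.8, ifg_oper = 0,
                                     ifg_tri = 0, dmn = 0)),
    homotopic_strength = c(TD = 0, ASD = 0))
  ts1 <- generate_timeseries(cfg1, "TD", seed = 10)
  lay <- region_layout(cfg1)
  net <- lay$networks$caudate
  rn <- cor(t(ts1[net, ]))
  mean_r <- mean(rn[upper.tri(rn)])
  expect_gt(mean_r, 0.7)
  expect_lt(mean_r, 0.9)

  # identical seed, identical matrix
  expect_identical(generate_timeseries(cfg1, "ASD", seed = 4),
                   generate_timeseries(cfg1, "ASD", seed = 4))
})

test_that("phenotype couplings have the planted correlation structure", {
  base_model <- list(
    null_score = list(intercept = 50, scale = 10, sd = 1,
                      beta = numeric(0), range = c(0, 100),
                      integer = FALSE, asd_only = FALSE),
    coupled = list(intercept = 50, scale = 10, sd = sqrt(3),
                   beta = c(fc_caudate_Z = -1), range = c(-1e6, 1e6),
                   integer = FALSE, asd_only = FALSE))
  # beta = -1, sd = sqrt(3): theoretical r = -1/sqrt(1+3) = -0.5
  cfg <- small_config(n_per_group = 250, n_timepoints = 48, seed = 21,
                      phenotype_model = base_model)
  co <- generate_cohort(cfg)
  ft <- compute_feature_table(co)
  r_null <- max(abs(cor(co$phenotypes$null_score,
                        as.matrix(ft[, feature_column_names()]))))
  expect_lt(r_null, 0.15)
  r_pl <- cor(co$phenotypes$coupled, ft$fc_caudate_Z)
  expect_gt(r_pl, -0.6)
  expect_lt(r_pl, -0.4)
  expect_error(generate_phenotypes(co, small_config(phenotype_model = list(
    bad = list(intercept = 0, scale = 1, sd = 1, beta = c(no_such = 1),
               range = c(0, 1), integer = FALSE, asd_only = FALSE)))),
    "unknown features")
})

test_that("cohort round-trips through the directory writer/reader", {
  cfg <- small_config(n_per_group = 4, n_timepoints = 48, seed = 2)
  co <- generate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "subjects.tsv")))
  back <- read_cohort(dir)
  expect_equal(back$thickness, co$thickness, tolerance = 1e-8)
  expect_equal(back$volumes, co$volumes, tolerance = 1e-8)
  expect_equal(back$timeseries[[1]], co$timeseries[[1]], tolerance = 1e-8)
  expect_identical(back$subjects$group, co$subjects$group)
  expect_equal(back$seed_sets, lapply(co$seed_sets, as.integer))
  expect_equal(unname(back$homotopic_pairs), unname(co$homotopic_pairs))
})
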