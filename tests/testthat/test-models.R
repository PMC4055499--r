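gaussian_classes <- function(n, delta, d = 4, seed = 1) {
  set.seed(seed)
  g <- rep(c("A", "B"), each = n / 2)
  x <- matrix(rnorm(n * d), n)
  x[g == "B", 1] <- x[g == "B", 1] + delta
  tab <- as.data.frame(x)
  names(tab) <- sprintf("f%d", seq_len(d))
  tab$group <- g
  tab
}

test_that("random trees memorize consistent data and handle XOR", {
  tab <- gaussian_classes(60, 1.5, seed = 2)
  model <- fit_random_tree(tab, seed = 7)
  expect_equal(mean(predict(model, tab) == tab$group), 1.0)

  xor <- data.frame(f1 = c(0, 0, 1, 1, 0.1, 0.1, 0.9, 0.9),
                    f2 = c(0, 1, 0, 1, 0.1, 0.9, 0.1, 0.9),
                    group = c("A", "B", "B", "A", "A", "B", "B", "A"))
  mx <- fit_random_tree(xor, seed = 3)
  expect_equal(mean(predict(mx, xor) == xor$group), 1.0)

  # identical seed gives an identical tree
  expect_identical(fit_random_tree(tab, seed = 7)$root, model$root)
  expect_error(fit_random_tree(data.frame(f1 = 1:4,
                                          group = rep("A", 4))),
               "single class")
})

test_that("evaluation protocols behave and are seed-deterministic", {
  tab <- gaussian_classes(200, 4, seed = 4)
  full <- evaluate("random_tree", tab, protocol = "full_dataset", seed = 1)
  expect_equal(full$accuracy, 1.0)

  cv <- evaluate("random_tree", tab, protocol = "kfold", param = 10,
                 seed = 5)
  expect_gte(cv$accuracy, 0.9)
  expect_length(cv$fold_accuracies, 10)
  cv2 <- evaluate("random_tree", tab, protocol = "kfold", param = 10,
                  seed = 5)
  expect_identical(cv$predictions, cv2$predictions)

  ps <- evaluate("random_tree", tab, protocol = "percentage_split",
                 param = 0.8, seed = 6)
  expect_equal(sum(!is.na(ps$predictions$predicted)), 40)
  expect_gte(ps$accuracy, 0.85)

  expect_error(evaluate("random_tree", tab, protocol = "kfold", param = 12),
               "2 <= param <= 10")
  expect_error(evaluate("random_tree", tab, protocol = "percentage_split",
                        param = 0.95), "0.1 <= param <= 0.9")
})

test_that("permuted labels give chance-level cross-validated accuracy", {
  tab <- gaussian_classes(200, 3, seed = 8)
  set.seed(9)
  tab$group <- sample(tab$group)
  cv <- evaluate("random_tree", tab, protocol = "kfold", param = 10,
                 seed = 10)
  expect_gte(cv$accuracy, 0.35)
  expect_lte(cv$accuracy, 0.65)
})

test_that("margin curves are conservative and ordered", {
  tab <- gaussian_classes(100, 4, seed = 12)
  model <- fit_random_tree(tab, seed = 1)
  mc <- margin_curve(model, tab)
  expect_equal(nrow(mc), 100)
  expect_equal(mc$cumulative[100], 100)
  expect_true(all(diff(mc$margin) >= 0))
  expect_true(all(mc$margin >= -1 & mc$margin <= 1))
  # a perfectly confident memorizing tree puts every margin at 1
  expect_true(all(mc$margin == 1))

  # an unsplittable node yields coin-flip probabilities, margin 0
  amb <- data.frame(f1 = rep(1, 4), group = c("A", "B", "A", "B"))
  m0 <- fit_random_tree(amb, seed = 2)
  mc0 <- margin_curve(m0, amb)
  expect_true(all(mc0$margin == 0))
})

test_that("richer planted signal dominates at high margins", {
  set.seed(15)
  n <- 120
  g <- rep(c("A", "B"), each = n / 2)
  base <- matrix(rnorm(n * 6), n)
  base[g == "B", 1:6] <- base[g == "B", 1:6] + 0.8
  t6 <- as.data.frame(base); names(t6) <- sprintf("f%d", 1:6); t6$group <- g
  t4 <- t6[, c(sprintf("f%d", 1:4), "group")]
  # out-of-sample margins: fit on half, margins on the other half
  idx <- rep(c(TRUE, FALSE), n / 2)
  m6 <- fit_random_tree(t6[idx, ], seed = 3)
  m4 <- fit_random_tree(t4[idx, ], seed = 3)
  mc6 <- margin_curve(m6, t6[!idx, ], t6$group[!idx])
  mc4 <- margin_curve(m4, t4[!idx, ], t4$group[!idx])
  expect_gte(mean(mc6$margin > 0.5), mean(mc4$margin > 0.5) - 0.05)
})

test_that("the instance regressor interpolates, averages, and recovers", {
  set.seed(18)
  x <- matrix(rnorm(40 * 3), 40)
  y <- rnorm(40)
  # query equal to a unique training point with near-interpolating blend
  model <- fit_instance_regressor(x, y, blend = 1.0001)
  expect_equal(predict(model, x[7, , drop = FALSE]), y[7],
               tolerance = 1e-3)
  # constant targets predict the constant everywhere
  mc <- fit_instance_regressor(x, rep(4.2, 40), blend = 5)
  expect_equal(unname(predict(mc, matrix(rnorm(15), 5))), rep(4.2, 5))
  expect_error(fit_instance_regressor(x[0, , drop = FALSE], numeric(0)),
               "empty")

  # noise-free linear target: held-out r above 0.99 (2 features, so the
  # nearest-neighbour spacing at n = 300 makes interpolation near-exact)
  xt <- matrix(rnorm(400 * 2), 400)
  yt <- drop(xt %*% c(1, -2))
  mtr <- fit_instance_regressor(xt[1:300, ], yt[1:300], blend = 2)
  pred <- predict(mtr, xt[301:400, ])
  expect_gte(cor(pred, yt[301:400]), 0.99)
})

test_that("phenotype prediction reports r and slope faithfully", {
  set.seed(25)
  cfg <- small_config(n_per_group = 30, n_timepoints = 60, seed = 44)
  co <- generate_cohort(cfg)
  ft <- compute_feature_table(co)
  sel <- c("fc_caudate_Z", "vol_caudate_R")
  # deterministic score from the selected features
  score <- 10 + 3 * ft$fc_caudate_Z + 2 * ft$vol_caudate_R
  pp <- predict_phenotype(ft, sel, score, protocol = "full_dataset",
                          blend = 1.05)
  expect_gte(pp$r, 0.99)
  expect_equal(pp$slope, 1, tolerance = 0.05)

  # score independent of the features: weak coupling under CV
  null_score <- rnorm(nrow(ft))
  pn <- predict_phenotype(ft, sel, null_score, protocol = "kfold", k = 5,
                          seed = 2)
  expect_lt(abs(pn$r), 0.45)
  expect_error(predict_phenotype(ft, sel, rep(1, nrow(ft))), "constant")

  # missing scores are dropped
  score_na <- score
  score_na[1:10] <- NA
  pm <- predict_phenotype(ft, sel, score_na, protocol = "full_dataset")
  expect_equal(length(pm$fitted), nrow(ft) - 10)
})
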