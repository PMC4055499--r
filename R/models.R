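entropy_nats <- function(y) {
  p <- table(y) / length(y)
  p <- p[p > 0]
  -sum(p * log(p))
}

feature_matrix <- function(t) {
  cols <- intersect(feature_column_names(), names(t))
  if (!length(cols)) cols <- names(t)[vapply(t, is.numeric, logical(1))]
  as.matrix(as.data.frame(t)[, cols, drop = FALSE])
}

#' Fit a randomized decision tree
#'
#' A single decision tree grown to purity: at each node a random subset of
#' `ceiling(sqrt(d))` features is drawn and the split with the highest
#' information gain over midpoints of consecutive sorted unique values is
#' taken. If none of the drawn features admits an improving split, all
#' features are considered before declaring a leaf, so any consistent
#' training set (no identical rows with conflicting labels) is memorized
#' exactly. Leaves store class frequencies, which serve as class
#' probabilities. Deterministic given `seed`.
#'
#' @param t A `feature_table` (or data frame of numeric features).
#' @param labels Class labels aligned with rows (defaults to `t$group`);
#'   at least 2 instances per class.
#' @param seed Integer seed for the per-node feature draws.
#' @return A `random_tree` model.
#' @export
fit_random_tree <- function(t, labels = t$group, seed = 1L) {
  x <- feature_matrix(t)
  y <- as.character(labels)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("training data contains a single class")
  if (any(table(y) < 2)) stop("need at least 2 subjects per class")
  set.seed(seed)
  mtry <- ceiling(sqrt(ncol(x)))

  best_split <- function(idx, feats) {
    h0 <- entropy_nats(y[idx])
    best <- NULL
    for (f in feats) {
      v <- x[idx, f]
      u <- sort(unique(v))
      if (length(u) < 2) next
      for (thr in (u[-length(u)] + u[-1]) / 2) {
        l <- idx[v <= thr]
        r <- idx[v > thr]
        gain <- h0 - (length(l) * entropy_nats(y[l]) +
                      length(r) * entropy_nats(y[r])) / length(idx)
        # zero-gain splits are admissible (interaction-only structure such
        # as XOR has no first-split gain); ties keep the first candidate
        if (is.null(best) || gain > best$gain + 1e-12) {
          best <- list(feature = f, threshold = thr, gain = gain,
                       left = l, right = r)
        }
      }
    }
    best
  }

  grow <- function(idx) {
    freq <- table(factor(y[idx], levels = classes)) / length(idx)
    if (length(idx) < 2 || length(unique(y[idx])) == 1)
      return(list(leaf = TRUE, prob = as.numeric(freq)))
    feats <- sample(ncol(x), min(mtry, ncol(x)))
    sp <- best_split(idx, feats)
    # if the drawn features admit no split, fall back to all features so
    # consistent training data is always memorized
    if (is.null(sp)) sp <- best_split(idx, seq_len(ncol(x)))
    if (is.null(sp)) return(list(leaf = TRUE, prob = as.numeric(freq)))
    list(leaf = FALSE, feature = sp$feature, threshold = sp$threshold,
         left = grow(sp$left), right = grow(sp$right))
  }

  structure(list(root = grow(seq_len(nrow(x))), classes = classes,
                 features = colnames(x), seed = seed),
            class = "random_tree")
}

#' Class probabilities from a fitted tree
#'
#' @param object A `random_tree`.
#' @param newdata Feature table or matrix.
#' @param ... Unused.
#' @return Matrix of class probabilities (rows = instances, columns =
#'   classes).
#' @export
predict_prob <- function(object, newdata, ...) UseMethod("predict_prob")

#' @export
predict_prob.random_tree <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  x <- x[, object$features, drop = FALSE]
  one <- function(row) {
    node <- object$root
    while (!node$leaf)
      node <- if (row[node$feature] <= node$threshold) node$left
              else node$right
    node$prob
  }
  p <- t(apply(x, 1, one))
  colnames(p) <- object$classes
  p
}

#' @export
predict.random_tree <- function(object, newdata, ...) {
  p <- predict_prob(object, newdata)
  object$classes[max.col(p, ties.method = "first")]
}

#' Evaluate a classifier under a resampling protocol
#'
#' Three protocols: `full_dataset` trains and tests on all instances
#' (memorization ceiling); `kfold` shuffles into stratified folds (2-10)
#' and tests each fold on a model trained on the rest;
#' `percentage_split` shuffles once, trains on the first `param` fraction
#' (0.1-0.9) and tests on the remainder. If a resample leaves a training
#' set or fold without both classes, the shuffle is redrawn once before
#' erroring. Seed-deterministic throughout.
#'
#' @param model_spec `"random_tree"` or a list with elements
#'   `fit(t, labels, seed)` and `predict(model, t)`.
#' @param t A `feature_table`.
#' @param labels Class labels (defaults to `t$group`).
#' @param protocol `"full_dataset"`, `"kfold"` or `"percentage_split"`.
#' @param param Folds (kfold) or training fraction (percentage_split).
#' @param seed Integer seed.
#' @return An `eval_report`: list with `protocol`, `param`, `accuracy`,
#'   `fold_accuracies`, `predictions` (data frame of true/predicted and
#'   class probabilities where available) and `seed`.
#' @export
evaluate <- function(model_spec = "random_tree", t, labels = t$group,
                     protocol = c("full_dataset", "kfold",
                                  "percentage_split"),
                     param = NULL, seed = 1L) {
  protocol <- match.arg(protocol)
  y <- as.character(labels)
  n <- length(y)
  fit_fun <- if (identical(model_spec, "random_tree"))
    function(tt, yy, s) fit_random_tree(tt, yy, seed = s)
  else model_spec$fit
  pred_fun <- if (identical(model_spec, "random_tree"))
    function(m, tt) predict(m, tt)
  else model_spec$predict
  prob_fun <- if (identical(model_spec, "random_tree"))
    function(m, tt) predict_prob(m, tt)
  else model_spec$predict_prob

  set.seed(seed)
  subset_t <- function(idx) {
    tt <- as.data.frame(t)[idx, , drop = FALSE]
    class(tt) <- class(t)
    tt
  }
  preds <- rep(NA_character_, n)

  if (protocol == "full_dataset") {
    model <- fit_fun(t, y, seed)
    preds <- pred_fun(model, t)
    folds_acc <- NULL
  } else if (protocol == "kfold") {
    k <- as.integer(param)
    if (is.na(k) || k < 2 || k > 10) stop("kfold requires 2 <= param <= 10")
    assign_folds <- function() {
      fold <- integer(n)
      for (cl in unique(y)) {
        idx <- sample(which(y == cl))
        fold[idx] <- rep_len(seq_len(k), length(idx))
      }
      fold
    }
    fold <- assign_folds()
    ok <- function(fold) all(vapply(seq_len(k), function(f)
      length(unique(y[fold != f])) == 2, logical(1)))
    if (!ok(fold)) fold <- assign_folds()
    if (!ok(fold)) stop("a fold is missing a class; too few subjects for k")
    folds_acc <- numeric(k)
    for (f in seq_len(k)) {
      test <- which(fold == f)
      model <- fit_fun(subset_t(-test), y[-test], seed + f)
      preds[test] <- pred_fun(model, subset_t(test))
      folds_acc[f] <- mean(preds[test] == y[test])
    }
  } else {
    frac <- as.numeric(param)
    if (is.na(frac) || frac < 0.1 || frac > 0.9)
      stop("percentage_split requires 0.1 <= param <= 0.9")
    draw <- function() sample(n)
    perm <- draw()
    n_train <- max(1, round(frac * n))
    if (length(unique(y[perm[seq_len(n_train)]])) < 2) perm <- draw()
    train <- perm[seq_len(n_train)]
    test <- perm[-seq_len(n_train)]
    if (length(unique(y[train])) < 2)
      stop("training split is missing a class")
    model <- fit_fun(subset_t(train), y[train], seed)
    preds[test] <- pred_fun(model, subset_t(test))
    folds_acc <- NULL
  }

  scored <- !is.na(preds)
  predictions <- data.frame(true = y, predicted = preds,
                            stringsAsFactors = FALSE)
  if (!is.null(prob_fun) && protocol == "full_dataset") {
    p <- prob_fun(model, t)
    predictions <- cbind(predictions, as.data.frame(p))
  }
  structure(list(protocol = protocol, param = param,
                 accuracy = mean(preds[scored] == y[scored]),
                 fold_accuracies = folds_acc,
                 predictions = predictions, seed = seed),
            class = "eval_report")
}

#' Margin curve of a probabilistic classifier
#'
#' Per-instance margin = probability assigned to the true class minus the
#' largest probability assigned to any other class, sorted ascending, with
#' the cumulative instance count at each margin value. Dominance of one
#' curve over another at high margins indicates more confidently correct
#' classifications.
#'
#' @param model A model supporting [predict_prob()].
#' @param t A `feature_table`.
#' @param labels True labels (defaults to `t$group`).
#' @return A `margin_curve`: data frame with columns `margin` (sorted)
#'   and `cumulative`.
#' @export
margin_curve <- function(model, t, labels = t$group) {
  p <- predict_prob(model, t)
  y <- as.character(labels)
  idx <- match(y, colnames(p))
  m <- vapply(seq_len(nrow(p)), function(i) {
    pt <- p[i, idx[i]]
    po <- max(p[i, -idx[i]])
    pt - po
  }, numeric(1))
  m <- sort(m)
  structure(data.frame(margin = m, cumulative = seq_along(m)),
            class = c("margin_curve", "data.frame"))
}

#' Fit an instance-based (memory) regressor
#'
#' Entropic/similarity-weighted memory-based regression in the spirit of
#' K*: the prediction at a query is the Gaussian-kernel weighted mean of
#' all training targets on variance-normalized features,
#' \eqn{\hat y(x) = \sum_i w_i y_i / \sum_i w_i} with
#' \eqn{w_i = \exp(-\|x - x_i\|^2 / 2h^2)}. The bandwidth `h` is set per
#' query so that the effective number of neighbours
#' \eqn{\sum_i w_i / \max_i w_i} matches the `blend` parameter, the
#' analogue of K*'s per-query blend between nearest-neighbour and global
#' averaging.
#'
#' @param t Training `feature_table` (or numeric data frame/matrix).
#' @param targets Numeric target vector.
#' @param blend Effective neighbour count (default 5); values at or above
#'   the training size give the global mean.
#' @return An `instance_regressor` with a [predict()] method.
#' @export
fit_instance_regressor <- function(t, targets, blend = 5) {
  x <- if (is.matrix(t)) t else feature_matrix(t)
  if (nrow(x) < 1) stop("empty training set")
  if (length(targets) != nrow(x)) stop("targets must match training rows")
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[s == 0] <- 1
  structure(list(x = sweep(sweep(x, 2, mu), 2, s, "/"), y = targets,
                 mu = mu, s = s, blend = blend),
            class = "instance_regressor")
}

#' @export
predict.instance_regressor <- function(object, newdata, ...) {
  xq <- if (is.matrix(newdata)) newdata else feature_matrix(newdata)
  if (!is.null(names(object$mu)) && !is.null(colnames(xq)))
    xq <- xq[, names(object$mu), drop = FALSE]
  xq <- sweep(sweep(xq, 2, object$mu), 2, object$s, "/")
  n <- nrow(object$x)
  b <- min(object$blend, n)
  apply(xq, 1, function(q) {
    d2 <- rowSums(sweep(object$x, 2, q)^2)
    if (n == 1 || b >= n || max(d2) - min(d2) < 1e-300)
      return(mean(object$y))
    d2 <- d2 - min(d2)  # stabilize: max weight is then exp(0) = 1
    eff <- function(log_h) sum(exp(-d2 / (2 * exp(2 * log_h))))
    lo <- 0.5 * log(min(d2[d2 > 0]) / 50)
    hi <- 0.5 * log(max(d2) * 50)
    h <- if (eff(lo) >= b) lo else if (eff(hi) <= b) hi else
      stats::uniroot(function(l) eff(l) - b, c(lo, hi))$root
    w <- exp(-d2 / (2 * exp(2 * h)))
    sum(w * object$y) / sum(w)
  })
}

#' Predict a phenotype score from selected imaging features
#'
#' Runs the instance-based regressor on the mRMR-selected feature subset
#' and reports the coupling between fitted and observed scores: Pearson r
#' and the least-squares slope of fitted on observed. Under `kfold` every
#' subject's fitted value is an out-of-fold prediction; under
#' `full_dataset` the model is trained and evaluated on all subjects.
#' Subjects with a missing score are dropped.
#'
#' @param t A `feature_table`.
#' @param selection A `selection_result` (or character vector of feature
#'   names).
#' @param score Numeric score vector aligned with the table rows (may
#'   contain `NA`).
#' @param protocol `"kfold"` (default) or `"full_dataset"`.
#' @param k Folds for `kfold`.
#' @param blend Effective neighbour count of the regressor.
#' @param seed Integer seed (fold shuffling).
#' @return A `phenotype_prediction`: list with `fitted`, `observed`,
#'   `ids`, `r`, `slope`, `p` (correlation test), `protocol`, `seed`.
#' @export
predict_phenotype <- function(t, selection, score,
                              protocol = c("kfold", "full_dataset"),
                              k = 10, blend = 5, seed = 1L) {
  protocol <- match.arg(protocol)
  features <- if (inherits(selection, "selection_result"))
    selection$selected else as.character(selection)
  keep <- !is.na(score)
  if (sum(keep) < 4) stop("fewer than 4 subjects with an observed score")
  y <- score[keep]
  if (stats::sd(y) == 0) stop("score is constant")
  x <- feature_matrix(t)[keep, features, drop = FALSE]
  n <- nrow(x)
  set.seed(seed)
  fitted <- numeric(n)
  if (protocol == "full_dataset") {
    model <- fit_instance_regressor(x, y, blend)
    fitted <- predict(model, x)
  } else {
    k <- min(k, n)
    fold <- rep_len(seq_len(k), n)[sample(n)]
    for (f in seq_len(k)) {
      test <- which(fold == f)
      model <- fit_instance_regressor(x[-test, , drop = FALSE], y[-test],
                                      blend)
      fitted[test] <- predict(model, x[test, , drop = FALSE])
    }
  }
  r <- stats::cor(fitted, y)
  slope <- unname(stats::coef(stats::lm(fitted ~ y))[2])
  p <- stats::cor.test(fitted, y)$p.value
  structure(list(fitted = fitted, observed = y,
                 ids = t$id[keep], r = r, slope = slope, p = p,
                 protocol = protocol, seed = seed),
            class = "phenotype_prediction")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %s%s: accuracy %.3f\n", x$protocol,
              if (!is.null(x$param)) sprintf("(%s)", x$param) else "",
              x$accuracy))
  invisible(x)
}

#' @export
print.phenotype_prediction <- function(x, ...) {
  cat(sprintf("<phenotype_prediction> %s: r = %.3f, slope = %.3f (n = %d)\n",
              x$protocol, x$r, x$slope, length(x$fitted)))
  invisible(x)
}
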