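#' Supratentorial volume normalization
#'
#' Removes head-size effects: `raw / supratentorial * 1000` (unitless).
#'
#' @param raw Regional volume(s); vector or matrix (subjects x regions).
#' @param supratentorial Per-subject supratentorial volume(s), > 0.
#' @return Normalized value(s), same shape as `raw`.
#' @export
normalize_volume <- function(raw, supratentorial) {
  if (any(supratentorial <= 0)) stop("supratentorial volume must be > 0")
  if (is.matrix(raw)) raw / supratentorial * 1000
  else raw / supratentorial * 1000
}

#' Percentage change between group means
#'
#' `(v2 - v1) / v1 * 100`, the percentage difference of the ASD group mean
#' relative to the control group mean (Delta-1 for normalized volumes,
#' Delta-2 for cortical thickness).
#'
#' @param v1 Control (TD) group mean; must be non-zero.
#' @param v2 ASD group mean.
#' @return Percentage change.
#' @export
percent_change <- function(v1, v2) {
  if (any(v1 == 0)) stop("v1 must be non-zero")
  (v2 - v1) / v1 * 100
}

#' Two-sample t-test
#'
#' Pooled-variance (default) or Welch two-sample t statistic with a
#' two-sided p-value.
#'
#' @param a,b Numeric samples, each of length >= 2.
#' @param variant `"pooled"` or `"welch"`.
#' @return List with `t`, `p`, `df`.
#' @export
two_sample_t <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both groups")
  tt <- stats::t.test(a, b, var.equal = (variant == "pooled"))
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Bonferroni correction
#'
#' `min(1, factor * p)`.
#'
#' @param p Raw p-value(s) in \[0, 1\].
#' @param factor Number of comparisons, >= 1.
#' @return Corrected p-value(s), capped at 1.
#' @export
bonferroni <- function(p, factor) {
  if (factor < 1) stop("factor must be >= 1")
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  pmin(1, factor * p)
}

#' Regional group comparison of volumes or thickness
#'
#' Compares every region between the TD and ASD groups: group means (V1 =
#' TD, V2 = ASD; volumes are supratentorial-normalized first, thickness
#' stays in mm), a two-sample t-test, Bonferroni correction with the
#' conventional x8 factor (4 lobes x 2 hemispheres), and the percentage
#' change of the ASD mean relative to the TD mean.
#'
#' @param cohort A `cohort`.
#' @param measure `"volume"` or `"thickness"`.
#' @param bonferroni_factor Correction factor (default 8).
#' @param variant t-test variant, `"pooled"` (default) or `"welch"`.
#' @return Data frame with one row per region: `region`, `v1`, `v2`, `t`,
#'   `p_raw`, `p_corrected`, `pct_change`.
#' @export
region_comparison <- function(cohort, measure = c("volume", "thickness"),
                              bonferroni_factor = 8,
                              variant = c("pooled", "welch")) {
  measure <- match.arg(measure)
  variant <- match.arg(variant)
  td <- cohort$subjects$group == "TD"
  if (measure == "volume") {
    m <- normalize_volume(cohort$volumes, cohort$subjects$supratentorial)
  } else {
    m <- cohort$thickness
  }
  rows <- lapply(colnames(m), function(region) {
    a <- m[!td, region]  # ASD
    b <- m[td, region]   # TD
    tt <- two_sample_t(a, b, variant)
    data.frame(region = region, v1 = mean(b), v2 = mean(a), t = tt$t,
               p_raw = tt$p, p_corrected = bonferroni(tt$p,
                                                      bonferroni_factor),
               pct_change = percent_change(mean(b), mean(a)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-category Bonferroni factors for phenotype correlations
#'
#' Factor = number of score categories (5) times the category's
#' sub-domain test count: ADOS x10, IQ x3, ADI-R x5, SRS x7, VABS x15.
#'
#' @return Named numeric vector of factors per category.
#' @export
phenotype_correction_factors <- function() {
  5 * c(ADOS = 10, IQ = 3, `ADI-R` = 5, SRS = 7, VABS = 15)
}

default_score_categories <- function(tests) {
  cat <- ifelse(grepl("^ados", tests), "ADOS",
         ifelse(grepl("^adir", tests), "ADI-R",
         ifelse(grepl("^iq", tests), "IQ",
         ifelse(grepl("^srs", tests), "SRS",
         ifelse(grepl("^vabs", tests), "VABS", NA)))))
  stats::setNames(cat, tests)
}

#' Feature-phenotype correlation table
#'
#' Pearson correlation of every (imaging feature, clinical score) pair
#' with pairwise deletion of missing scores, a two-sided p-value, and the
#' category-structured Bonferroni correction (5 categories times the
#' category's sub-domain count). Computed within one diagnostic group by
#' default (the clinical scales are mostly specific to the ASD group).
#'
#' @param features A `feature_table`.
#' @param phenotypes Data frame with `id` and score columns, aligned by
#'   `id`.
#' @param categories Named character vector mapping score name ->
#'   category (`ADOS`, `IQ`, `ADI-R`, `SRS`, `VABS`); by default inferred
#'   from the score-name prefix.
#' @param group Restrict to this diagnostic group (default `"ASD"`; `NULL`
#'   for all subjects).
#' @param min_pairs Minimum complete pairs per test (default 4).
#' @return Data frame with `feature`, `test`, `category`, `n`, `r`,
#'   `p_raw`, `p_corrected`.
#' @export
phenotype_correlations <- function(features, phenotypes,
                                   categories = NULL, group = "ASD",
                                   min_pairs = 4) {
  tests <- setdiff(names(phenotypes), "id")
  if (is.null(categories)) categories <- default_score_categories(tests)
  factors <- phenotype_correction_factors()
  keep <- if (is.null(group)) rep(TRUE, nrow(features))
          else features$group == group
  f <- as.data.frame(features)[keep, , drop = FALSE]
  ph <- phenotypes[match(f$id, phenotypes$id), , drop = FALSE]
  cols <- intersect(feature_column_names(), names(f))
  rows <- list()
  for (test in tests) {
    y <- ph[[test]]
    ok <- !is.na(y)
    if (sum(ok) < min_pairs)
      stop("fewer than ", min_pairs, " complete pairs for test ", test)
    cat <- categories[[test]]
    fac <- factors[[cat]]
    if (is.null(fac)) stop("unknown category for test ", test)
    for (feat in cols) {
      x <- f[[feat]][ok]
      if (stats::sd(x) == 0 || stats::sd(y[ok]) == 0) next
      ct <- stats::cor.test(x, y[ok])
      rows[[length(rows) + 1]] <- data.frame(
        feature = feat, test = test, category = cat, n = sum(ok),
        r = unname(ct$estimate), p_raw = ct$p.value,
        p_corrected = bonferroni(ct$p.value, fac),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Published reference group means
#'
#' The published regional group means for the ASD-vs-TD comparison that
#' ships with the package: supratentorial-normalized volumes (V1 = TD,
#' V2 = ASD, scale factor 1000) or cortical thickness in mm (C1/C2),
#' together with the reported raw p-values and percentage changes. Useful
#' as a worked example for [percent_change()] and as a fixed reference in
#' tests.
#'
#' @param measure `"volume"` or `"thickness"`.
#' @return Data frame with columns `region`, `v1`, `v2`, `p_raw`,
#'   `pct_change` (and `tissue` for volumes).
#' @export
reference_group_means <- function(measure = c("volume", "thickness")) {
  measure <- match.arg(measure)
  f <- system.file("extdata",
                   paste0(measure, "_group_means.tsv"),
                   package = "asdconnectome", mustWork = TRUE)
  d <- utils::read.delim(f, stringsAsFactors = FALSE)
  if (measure == "thickness") names(d)[names(d) == "c1"] <- "v1"
  if (measure == "thickness") names(d)[names(d) == "c2"] <- "v2"
  d
}
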